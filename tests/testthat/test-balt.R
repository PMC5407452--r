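truth <- c(B = 6, A = 3, L = 56, T = 4)

test_that("sigmoid midpoint, asymptotes and rise time are exact", {
  expect_equal(balt_evaluate(truth, 56), 7.5)         # B + A/2 at t = L
  expect_equal(balt_evaluate(truth, -1e6), 6)         # early asymptote B
  expect_equal(balt_evaluate(truth, 1e6), 9)          # late asymptote B + A
  # 10%-to-90% crossing times differ by exactly T under f(T) = 2 ln 9 / T
  f <- 2 * log(9) / truth[["T"]]
  t10 <- truth[["L"]] - log(9) / f
  t90 <- truth[["L"]] + log(9) / f
  expect_equal(balt_evaluate(truth, t10), 6 + 0.1 * 3)
  expect_equal(balt_evaluate(truth, t90), 6 + 0.9 * 3)
  expect_equal(t90 - t10, 4)
  expect_error(balt_evaluate(c(B = 6, A = 3, L = 56, T = 0), 50), "T must be > 0")
})

test_that("sigmoid is monotone and bounded between B and B + A", {
  tt <- seq(44, 68, by = 0.5)  # within floating-point resolution of the tails
  up <- balt_evaluate(truth, tt)
  expect_true(all(diff(up) > 0))
  expect_true(all(up > 6 & up < 9))
  down <- balt_evaluate(c(B = 8, A = -2, L = 50, T = 3), tt)
  expect_true(all(diff(down) < 0))
  expect_true(all(down > 6 & down < 8))
  # bounds hold (weakly) arbitrarily far out
  wide <- balt_evaluate(truth, seq(-200, 300, by = 10))
  expect_true(all(wide >= 6 & wide <= 9))
})

test_that("noiseless fits recover the generating parameters to 1e-4", {
  tt <- 45:74
  y <- balt_evaluate(truth, tt)
  fit <- balt_fit(tt, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$params), unname(truth), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
  # down-regulated gene
  tr2 <- c(B = 8, A = -2.5, L = 60, T = 6)
  fit2 <- balt_fit(tt, balt_evaluate(tr2, tt))
  expect_equal(unname(fit2$params), unname(tr2), tolerance = 1e-4)
})

test_that("LM fit matches the grid-search oracle RSS on noisy data", {
  for (seed in 1:3) {
    y <- withr::with_seed(seed, {
      balt_evaluate(truth, 45:74) + stats::rnorm(30, 0, 0.25)
    })
    fit <- balt_fit(45:74, y)
    oracle <- balt_grid_oracle(45:74, y)
    expect_lte(fit$rss, oracle + 1e-6)
  }
})

test_that("noisy localisation estimates are accurate and time-shift equivariant", {
  ls <- vapply(1:50, function(seed) {
    y <- withr::with_seed(seed, {
      balt_evaluate(truth, 45:74) + stats::rnorm(30, 0, 0.25)
    })
    balt_fit(45:74, y)$params[["L"]]
  }, numeric(1))
  expect_lt(stats::median(abs(ls - 56)), 1)
  expect_lt(abs(ls[1] - 56), 2)

  y <- withr::with_seed(1, balt_evaluate(truth, 45:74) + stats::rnorm(30, 0, 0.25))
  f0 <- balt_fit(45:74, y)
  f_shift <- balt_fit(45:74 + 10, y)
  expect_equal(f_shift$params[["L"]], f0$params[["L"]] + 10, tolerance = 1e-3)
  expect_equal(f_shift$params[c("B", "A", "T")], f0$params[c("B", "A", "T")],
               tolerance = 1e-3)
})

test_that("fit preconditions are enforced", {
  expect_error(balt_fit(c(1, 1, 1, 1, 1), rnorm(5)), "distinct time")
  expect_error(balt_fit(1:4, rnorm(4)), "distinct time")
})

test_that("model selection prefers the right model under null and alternative", {
  n_const <- sum(vapply(1:100, function(seed) {
    y <- withr::with_seed(seed, stats::rnorm(30, 6, 0.25))
    select_model(45:74, y)$model == "constant"
  }, logical(1)))
  expect_gte(n_const, 95)

  n_sig <- sum(vapply(1:100, function(seed) {
    y <- withr::with_seed(seed, balt_evaluate(truth, 45:74) + stats::rnorm(30, 0, 0.25))
    select_model(45:74, y)$model == "sigmoid"
  }, logical(1)))
  expect_gte(n_sig, 95)
})

test_that("exact flat input selects the constant model with the right level", {
  sel <- select_model(45:74, rep(6, 30))
  expect_equal(sel$model, "constant")
  expect_equal(unname(sel$params["B"]), 6)
})

test_that("five exact sigmoid points select the sigmoid with ~zero RSS", {
  tt <- c(48, 52, 56, 60, 64)
  sel <- select_model(tt, balt_evaluate(truth, tt))
  expect_equal(sel$model, "sigmoid")
  expect_lt(sel$rss, 1e-8)
})

constant_fit_for_test <- function() {
  select_model(45:74, rep(6, 30))
}

test_that("MCMC intervals are tight, cover the truth, and are seed-stable", {
  y <- withr::with_seed(3, balt_evaluate(truth, 45:74) + stats::rnorm(30, 0, 0.05))
  fit <- balt_fit(45:74, y)
  mc <- balt_mcmc(fit, chains = 2, iter = 3000, burn = 500, seed = 42)
  l_row <- mc$summary[mc$summary$parameter == "L", ]
  expect_lt(l_row$lower, 56)
  expect_gt(l_row$upper, 56)
  expect_lt(l_row$upper - l_row$lower, 2)
  expect_true(l_row$lower <= l_row$median && l_row$median <= l_row$upper)
  expect_gt(mc$acceptance_rate, 0)
  expect_lt(mc$acceptance_rate, 1)

  mc2 <- balt_mcmc(fit, chains = 2, iter = 3000, burn = 500, seed = 42)
  expect_identical(mc$summary, mc2$summary)
  expect_error(balt_mcmc(constant_fit_for_test()), "sigmoid")
})

test_that("MCMC 95% intervals cover the true L in at least 90% of replicates", {
  covered <- vapply(1:50, function(seed) {
    y <- withr::with_seed(seed, balt_evaluate(truth, 45:74) + stats::rnorm(30, 0, 0.25))
    fit <- balt_fit(45:74, y)
    mc <- balt_mcmc(fit, chains = 2, iter = 1500, burn = 300, seed = seed)
    l_row <- mc$summary[mc$summary$parameter == "L", ]
    l_row$lower <= 56 && 56 <= l_row$upper
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("profile classification follows the window rule", {
  w <- c(45, 74)
  stero <- balt_fit(45:74, balt_evaluate(c(B = 6, A = 3, L = 56, T = 4), 45:74))
  expect_equal(classify_profile(stero, w), "switch_up")
  sox9 <- balt_fit(45:74, balt_evaluate(c(B = 7, A = 1, L = 70, T = 25), 45:74))
  expect_equal(classify_profile(sox9, w), "curvilinear_incomplete")
  down <- balt_fit(45:74, balt_evaluate(c(B = 8, A = -2, L = 60, T = 4), 45:74))
  expect_equal(classify_profile(down, w), "switch_down")
  tiny <- balt_fit(45:74, balt_evaluate(c(B = 6, A = 0.3, L = 56, T = 4), 45:74))
  expect_equal(classify_profile(tiny, w), "flat")
  expect_equal(classify_profile(constant_fit_for_test(), w), "flat")
  expect_error(classify_profile(stero, c(74, 45)), "window")
})

test_that("onset summaries cover switch genes only", {
  w <- c(45, 74)
  single <- list(g1 = balt_fit(45:74, balt_evaluate(truth, 45:74)))
  os <- onset_window(single, w)
  expect_equal(os$mean_l, 56, tolerance = 1e-4)
  expect_equal(os$median_l, 56, tolerance = 1e-4)
  expect_equal(diff(os$iqr_l), 0, tolerance = 1e-6)

  mixed <- c(single, list(flat = select_model(45:74, rep(6, 30))))
  os2 <- onset_window(mixed, w)
  expect_equal(os2$n, 1)
  expect_equal(os2$genes, "g1")
  expect_error(onset_window(list(), w), "empty")

  # 8 simulated steroidogenic genes with true L = 55.5 land in 54-57 dpc
  tt <- rep(seq(45, 74, by = 1.5), each = 2)
  fits <- withr::with_seed(42, {
    lapply(1:8, function(i) {
      y <- balt_evaluate(c(B = 6, A = 3, L = 55.5, T = 4), tt) +
        stats::rnorm(length(tt), 0, 0.25)
      balt_fit(tt, y)
    })
  })
  names(fits) <- sprintf("g%d", 1:8)
  os3 <- onset_window(fits, c(45, 74))
  expect_gte(os3$mean_l, 54)
  expect_lte(os3$mean_l, 57)
})

test_that("reference matching recovers the planted curvilinear cohort", {
  w <- c(45, 74)
  tt <- 45:74
  genes <- list(
    SOX9L = c(B = 7, A = 1, L = 70, T = 25),
    CURVA = c(B = 6.5, A = 1.2, L = 68, T = 22),
    CURVB = c(B = 7.2, A = 1.1, L = 69, T = 20),
    STERO = c(B = 6, A = 3, L = 56, T = 4)
  )
  fits <- withr::with_seed(8, lapply(genes, function(p) {
    balt_fit(tt, balt_evaluate(p, tt) + stats::rnorm(30, 0, 0.1))
  }))
  fits$FLATG <- select_model(tt, withr::with_seed(9, stats::rnorm(30, 6, 0.1)))
  hits <- match_reference(fits, "SOX9L", window = w)
  expect_setequal(hits$members, c("SOX9L", "CURVA", "CURVB"))
  # zero tolerance keeps only the reference itself on these noisy fits
  strict <- match_reference(fits, "STERO", tol_l = 0, tol_t = 0, window = w)
  expect_equal(strict$members, "STERO")
  expect_error(match_reference(fits, "FLATG", window = w), "flat")
  expect_error(match_reference(fits, "NOPE", window = w), "not found")
})
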