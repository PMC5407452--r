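sim_two_group <- function(n_genes, na, nb, delta = 0, sd = 0.25, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * (na + nb), 7, sd), n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                paste0("s", seq_len(na + nb))))
    if (length(delta) > 1 || delta != 0) {
      m[seq_along(delta), seq_len(na)] <- m[seq_along(delta), seq_len(na)] + delta
    }
    m
  })
}

test_that("group means and pooled variances match a direct computation", {
  set.seed(10)
  m <- sim_two_group(50, 6, 6, seed = 10)
  groups <- rep(c("A", "B"), each = 6)
  tab <- fit_group_means(m, groups, c("A", "B"))
  for (i in c(1, 17, 50)) {
    a <- m[i, 1:6]; b <- m[i, 7:12]
    expect_equal(tab$log2fc[i], mean(a) - mean(b))
    expect_equal(tab$s2[i], (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 10)
  }
  expect_equal(tab$df[1], 10)

  # identical groups give a zero contrast
  m2 <- cbind(m[, 1:6], m[, 1:6])
  colnames(m2) <- paste0("s", 1:12)
  tab2 <- fit_group_means(m2, groups, c("A", "B"))
  expect_true(all(tab2$log2fc == 0))

  # exact two-point case
  m3 <- matrix(c(5, 5, 3, 3), 1, dimnames = list("g1", paste0("s", 1:4)))
  tab3 <- fit_group_means(m3, c("A", "A", "B", "B"), c("A", "B"))
  expect_equal(tab3$log2fc, 2)
  expect_equal(tab3$s2, 0)

  expect_error(fit_group_means(m, c("A", rep("B", 11)), c("A", "B")),
               ">= 2 samples")
})

test_that("moderated t reduces to its two limiting cases", {
  m <- sim_two_group(200, 8, 6, seed = 2)
  tab <- fit_group_means(m, rep(c("A", "B"), c(8, 6)), c("A", "B"))

  mod0 <- moderate_variances(tab, d0 = 0)
  tt <- apply(m, 1, function(x) {
    stats::t.test(x[1:8], x[9:14], var.equal = TRUE)$statistic
  })
  expect_equal(unname(mod0$t), unname(tt), tolerance = 1e-12)

  modInf <- moderate_variances(tab, d0 = Inf, s0 = 0.3)
  expect_equal(modInf$t, tab$log2fc / (0.3 * sqrt(1 / 8 + 1 / 6)), tolerance = 1e-12)
})

test_that("moderated t interpolates monotonically between the limits", {
  m <- sim_two_group(100, 8, 6, seed = 3)
  tab <- fit_group_means(m, rep(c("A", "B"), c(8, 6)), c("A", "B"))
  s0 <- 0.25
  t_prev <- moderate_variances(tab, d0 = 1e-9, s0 = s0)$t
  t_inf <- tab$log2fc / (s0 * sqrt(1 / 8 + 1 / 6))
  gap_prev <- abs(t_prev - t_inf)
  for (d0 in c(1, 5, 50, 500)) {
    t_d <- moderate_variances(tab, d0 = d0, s0 = s0)$t
    gap <- abs(t_d - t_inf)
    expect_true(all(gap <= gap_prev + 1e-9))
    gap_prev <- gap
  }
})

test_that("hyperparameter estimation agrees with an independent EB oracle", {
  skip_if_not_installed("limma")
  withr::with_seed(5, {
    m <- matrix(stats::rnorm(2000 * 14, 7, sqrt(0.3)), 2000)
    m <- m * sqrt(stats::rchisq(2000, 4) / 4)
    dimnames(m) <- list(sprintf("g%04d", 1:2000), paste0("s", 1:14))
  })
  tab <- fit_group_means(m, rep(c("A", "B"), c(8, 6)), c("A", "B"))
  mod <- moderate_variances(tab)
  sq <- limma::squeezeVar(tab$s2, df = tab$df[1])
  expect_equal(attr(mod, "d0"), sq$df.prior, tolerance = 0.01)
  expect_equal(attr(mod, "s02"), sq$var.prior, tolerance = 0.01)
  post <- (attr(mod, "d0") * attr(mod, "s02") + tab$df[1] * tab$s2) /
    (attr(mod, "d0") + tab$df[1])
  expect_equal(post, sq$var.post, tolerance = 0.005)
})

test_that("null simulation yields approximately uniform p-values", {
  m <- sim_two_group(2000, 8, 6, seed = 7)
  tab <- fit_group_means(m, rep(c("A", "B"), c(8, 6)), c("A", "B"))
  mod <- moderate_variances(tab)
  frac <- mean(mod$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (seed in 1:5) {
    p <- withr::with_seed(seed, stats::runif(200)^2)
    expect_equal(adjust_bh(p), bh_brute_force(p))
  }
  # permutation equivariance
  p <- withr::with_seed(9, stats::runif(50))
  perm <- withr::with_seed(10, sample(50))
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FDR is controlled at the nominal level under the global null", {
  rates <- vapply(1:6, function(seed) {
    m <- sim_two_group(1000, 8, 6, seed = 100 + seed)
    tab <- fit_group_means(m, rep(c("A", "B"), c(8, 6)), c("A", "B"))
    mean(moderate_variances(tab)$q <= 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("threshold selection recovers planted effects and nests", {
  delta <- rep(3, 40)
  m <- sim_two_group(2000, 8, 6, delta = delta, sd = 0.25, seed = 3)
  tab <- fit_group_means(m, rep(c("A", "B"), c(8, 6)), c("A", "B"))
  mod <- moderate_variances(tab)
  hits2 <- select_de(mod, lfc_cut = 2, q_cut = 0.05, direction = "up")
  planted <- toupper(rownames(m)[1:40])
  sens <- length(intersect(hits2$members, planted)) / 40
  fdp <- length(setdiff(hits2$members, planted)) / max(1, length(hits2$members))
  expect_gte(sens, 0.95)
  expect_lte(fdp, 0.10)

  hits1 <- select_de(mod, lfc_cut = 1, q_cut = 0.05, direction = "up")
  expect_true(all(hits2$members %in% hits1$members))
  expect_length(select_de(mod, lfc_cut = Inf, q_cut = 0.05)$members, 0)
  expect_error(select_de(mod, lfc_cut = -1), ">= 0")
  expect_error(select_de(tab, lfc_cut = 1), "moderated")
})

test_that("fold-change conversion and signed variant", {
  expect_equal(log2fc_to_absfc(0), 1)
  expect_equal(log2fc_to_absfc(1), 2)
  fc <- log2fc_to_absfc(c(2, -2), signed = TRUE)
  expect_equal(unname(as.numeric(fc)), c(4, 4))
  expect_equal(attr(fc, "direction"), c("up", "down"))
})

test_that("top_table ranks by log2FC with q and id tie-breaks", {
  tab <- data.frame(
    gene = c("B", "A", "C", "D"),
    log2fc = c(2, 2, 5, 2),
    q = c(0.01, 0.01, 0.2, 0.001)
  )
  class(tab) <- c("de_table", "data.frame")
  expect_equal(top_table(tab, 1)$gene, "C")
  expect_equal(top_table(tab, 4)$gene, c("C", "D", "A", "B"))
  expect_equal(nrow(top_table(tab, 99)), 4)
  # agreement with a full sort oracle on random tables
  rt <- withr::with_seed(4, data.frame(
    gene = sprintf("G%03d", sample(100)),
    log2fc = round(stats::rnorm(100), 1),
    q = round(stats::runif(100), 2)
  ))
  class(rt) <- c("de_table", "data.frame")
  oracle <- rt[order(-rt$log2fc, rt$q, rt$gene), ]
  expect_equal(top_table(rt, 100)$gene, oracle$gene)
})

test_that("delta-delta-Ct fold changes follow the comparative Ct formula", {
  expect_equal(ddct_fold_change(20, 18, 20, 18), 1)
  expect_equal(ddct_fold_change(19, 18, 20, 18), 2)  # ddCt = -1 doubles
  expect_equal(ddct_fold_change(20, 18, 24, 19), 8)  # ddCt = (2) - (5) = -3
  expect_error(ddct_fold_change(20, NA, 24, 19), "positive")
})
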