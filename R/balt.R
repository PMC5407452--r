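#' Evaluate the BALT sigmoid
#'
#' The four-parameter phenomenological model of an expression transition,
#' \deqn{X(t) = B + \frac{A}{1 + e^{f(T)\,(L - t)}},}
#' where `B` ("basis") is the starting log2 expression level, `A`
#' ("amplitude") the signed size of the change (negative for down-regulated
#' genes), `L` ("localisation") the inflexion time in dpc, and `T`
#' ("transition") the duration of the change in days. The rate sub-function
#' is calibrated as `f(T) = 2 ln 9 / T`, which makes `T` exactly the
#' 10%-to-90% rise time of the transition.
#'
#' @param params Named numeric vector or list with `B`, `A`, `L`, `T`
#'   (`T > 0`).
#' @param t Time(s) in dpc; vectorised.
#' @return Log2 expression value(s). Numerically saturates for exponents
#'   beyond +/-700.
#' @examples
#' balt_evaluate(c(B = 6, A = 3, L = 56, T = 4), 56)  # midpoint: 7.5
#' @export
balt_evaluate <- function(params, t) {
  p <- as.list(params)
  if (is.null(p$T) || p$T <= 0) stop("T must be > 0")
  f <- 2 * log(9) / p$T
  expo <- f * (p$L - t)
  expo <- pmin(pmax(expo, -700), 700)
  p$B + p$A / (1 + exp(expo))
}

#' Fitting options for [balt_fit()]
#'
#' @param n_starts Number of multi-start localisation grid points (quantiles
#'   of the observed times).
#' @param l_pad Fraction of the time span by which the `L` bounds extend
#'   beyond the observed range (default half a span on each side).
#' @param t_min_bound Lower bound on `T` in days.
#' @param t_max_factor Upper bound on `T` as a multiple of the time span.
#' @param range_pad Log2 units added around the data range for the `B` and
#'   `A` bounds.
#' @return List of options.
#' @export
balt_options <- function(n_starts = 5, l_pad = 0.5, t_min_bound = 0.1,
                         t_max_factor = 3, range_pad = 2) {
  list(n_starts = n_starts, l_pad = l_pad, t_min_bound = t_min_bound,
       t_max_factor = t_max_factor, range_pad = range_pad)
}

balt_bounds <- function(times, values, opts) {
  span <- diff(range(times))
  rng <- range(values)
  amp <- diff(rng) + opts$range_pad
  list(
    lower = c(B = rng[1] - opts$range_pad, A = -amp,
              L = min(times) - opts$l_pad * span, T = opts$t_min_bound),
    upper = c(B = rng[2] + opts$range_pad, A = amp,
              L = max(times) + opts$l_pad * span, T = opts$t_max_factor * span)
  )
}

#' Fit the BALT sigmoid by bounded Levenberg-Marquardt least squares
#'
#' Minimises the residual sum of squares of [balt_evaluate()] against the
#' observations, with multi-start initialisation over a grid of candidate
#' localisations (the quantiles of the observed times; basis initialised from
#' the earliest tertile of the data, amplitude from the latest, transition
#' from a quarter of the span). Parameters are bounded: `L` within the
#' observed range +/- half a span, `T` in `[0.1, 3 span]` days, `B` and `A`
#' within the data range +/- 2 log2 units. Ties in RSS are broken by smaller
#' `|A|`, then earlier `L` (parsimony).
#'
#' @param times Observation times in dpc (>= 5 distinct values).
#' @param values Log2 expression values, same length.
#' @param opts Options from [balt_options()].
#' @return Object of class `balt_fit`: `params` (B, A, L, T), `model`
#'   (`"sigmoid"`), `rss`, `r2`, `n`, `converged`, `covariance` (4x4, from
#'   the Jacobian at the optimum), plus the data and bounds used.
#' @export
balt_fit <- function(times, values, opts = balt_options()) {
  stopifnot(length(times) == length(values))
  if (length(unique(times)) < 5) {
    stop("need >= 5 distinct time points for the sigmoid model")
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite")
  }
  n <- length(values)
  bounds <- balt_bounds(times, values, opts)
  span <- diff(range(times))

  ord <- order(times)
  tert <- ceiling(n / 3)
  b0 <- mean(values[ord][seq_len(tert)])
  a0 <- mean(values[ord][seq(n - tert + 1, n)]) - b0
  if (abs(a0) < 1e-8) a0 <- 1e-3
  l_grid <- stats::quantile(times, probs = seq(0.1, 0.9, length.out = opts$n_starts),
                            names = FALSE)
  resid_fn <- function(par) {
    values - balt_evaluate(c(B = par[1], A = par[2], L = par[3], T = par[4]), times)
  }

  best <- NULL
  for (l0 in l_grid) {
    start <- pmin(pmax(c(b0, a0, l0, span / 4), bounds$lower), bounds$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn,
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    cand <- list(par = fit$par, rss = rss, info = fit$info, hessian = fit$hessian)
    if (is.null(best) ||
        rss < best$rss - 1e-10 ||
        (abs(rss - best$rss) <= 1e-10 &&
         (abs(cand$par[2]) < abs(best$par[2]) - 1e-12 ||
          (abs(abs(cand$par[2]) - abs(best$par[2])) <= 1e-12 &&
           cand$par[3] < best$par[3])))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("all Levenberg-Marquardt starts failed")

  par <- stats::setNames(best$par, c("B", "A", "L", "T"))
  rss <- best$rss
  tss <- sum((values - mean(values))^2)
  sigma2 <- rss / max(n - 4, 1)
  covariance <- tryCatch({
    co <- sigma2 * solve(best$hessian)
    dimnames(co) <- list(names(par), names(par))
    co
  }, error = function(e) {
    matrix(NA_real_, 4, 4, dimnames = list(names(par), names(par)))
  })
  structure(
    list(params = par, model = "sigmoid", rss = rss,
         r2 = if (tss > 0) 1 - rss / tss else NA_real_,
         n = n, converged = best$info %in% 1:4,
         covariance = covariance, times = times, values = values,
         bounds = bounds),
    class = "balt_fit"
  )
}

constant_fit <- function(times, values) {
  n <- length(values)
  b <- mean(values)
  rss <- sum((values - b)^2)
  tss <- rss
  structure(
    list(params = c(B = b), model = "constant", rss = rss,
         r2 = if (tss > 0) 0 else NA_real_, n = n, converged = TRUE,
         covariance = NULL, times = times, values = values, bounds = NULL),
    class = "balt_fit"
  )
}

#' @export
print.balt_fit <- function(x, ...) {
  cat("<balt_fit> model =", x$model, "\n")
  print(round(x$params, 4))
  cat("rss =", signif(x$rss, 4), " n =", x$n,
      " converged =", x$converged, "\n")
  if (!is.null(x$delta_bic)) cat("delta BIC (constant - sigmoid) =",
                                 signif(x$delta_bic, 4), "\n")
  invisible(x)
}

gaussian_bic <- function(rss, n, k) {
  # k counts mean-model parameters; +1 for the noise variance
  n * log(max(rss, 1e-12) / n) + (k + 1) * log(n)
}

#' Choose between a constant and a sigmoid expression model
#'
#' Fits both the constant model (basis only) and the full sigmoid, and keeps
#' the model with the lower Gaussian BIC (1 vs 4 mean parameters, plus the
#' noise variance in each). Equal-BIC ties go to the constant model.
#'
#' @inheritParams balt_fit
#' @return The winning `balt_fit`, with `delta_bic` (BIC constant minus BIC
#'   sigmoid; positive favours the sigmoid) and both candidate fits attached.
#' @export
select_model <- function(times, values, opts = balt_options()) {
  cfit <- constant_fit(times, values)
  sfit <- balt_fit(times, values, opts)
  n <- length(values)
  bic_c <- gaussian_bic(cfit$rss, n, 1)
  bic_s <- gaussian_bic(sfit$rss, n, 4)
  delta <- bic_c - bic_s
  win <- if (delta > 0) sfit else cfit
  win$delta_bic <- delta
  win$candidates <- list(constant = cfit, sigmoid = sfit)
  win
}

#' MCMC uncertainty quantification for a BALT fit
#'
#' Random-walk Metropolis on `(B, A, L, log T, log sigma^2)` with Gaussian
#' proposals scaled by `2.4^2/5` times the Levenberg-Marquardt covariance
#' (delta-method transformed to the log-T scale), flat priors truncated at
#' the fit bounds, and a Gaussian likelihood. Deterministic given the seed.
#'
#' @param fit Converged sigmoid `balt_fit`.
#' @param times,values The data (default: those stored in the fit).
#' @param chains Number of chains.
#' @param iter Iterations per chain.
#' @param burn Burn-in iterations discarded per chain.
#' @param seed Integer seed.
#' @return Object of class `mcmc_summary`: `summary` data frame (parameter,
#'   median, lower, upper 95% central interval), `acceptance_rate`, `chains`,
#'   `iter`, `burn`, `seed`, and the pooled `draws` matrix.
#' @export
balt_mcmc <- function(fit, times = fit$times, values = fit$values,
                      chains = 4, iter = 5000, burn = 1000, seed = 1) {
  stopifnot(inherits(fit, "balt_fit"))
  if (fit$model != "sigmoid" || !isTRUE(fit$converged)) {
    stop("balt_mcmc requires a converged sigmoid fit")
  }
  n <- length(values)
  par0 <- fit$params
  s2_0 <- max(fit$rss / max(n - 4, 1), 1e-8)
  theta0 <- c(par0[["B"]], par0[["A"]], par0[["L"]], log(par0[["T"]]), log(s2_0))

  lower <- c(fit$bounds$lower[1:3], log(fit$bounds$lower[["T"]]), log(s2_0) - 12)
  upper <- c(fit$bounds$upper[1:3], log(fit$bounds$upper[["T"]]), log(s2_0) + 12)

  log_post <- function(th) {
    if (any(th < lower) || any(th > upper)) return(-Inf)
    s2 <- exp(th[5])
    r <- values - balt_evaluate(c(B = th[1], A = th[2], L = th[3], T = exp(th[4])),
                                times)
    -0.5 * n * (log(2 * pi) + th[5]) - sum(r^2) / (2 * s2)
  }

  # proposal covariance: LM covariance, T row/col mapped to log T
  co <- fit$covariance
  if (is.null(co) || any(!is.finite(co))) {
    co <- diag(c(0.01, 0.01, 0.25, 0.05))
  } else {
    j <- diag(c(1, 1, 1, 1 / par0[["T"]]))
    co <- j %*% co %*% t(j)
  }
  sig <- matrix(0, 5, 5)
  sig[1:4, 1:4] <- co
  sig[5, 5] <- 2 / n
  sig <- sig * (2.4^2 / 5)
  ch <- tryCatch(chol(sig + diag(1e-10, 5)), error = function(e) {
    diag(sqrt(pmax(diag(sig), 1e-6)))
  })

  draws <- vector("list", chains)
  accepted <- 0L
  total <- 0L
  withr_seed(seed, {
    for (c_i in seq_len(chains)) {
      th <- theta0
      lp <- log_post(th)
      keep <- matrix(NA_real_, iter - burn, 5)
      for (i in seq_len(iter)) {
        prop <- th + as.vector(t(ch) %*% stats::rnorm(5))
        lp_prop <- log_post(prop)
        total <- total + 1L
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          th <- prop
          lp <- lp_prop
          accepted <- accepted + 1L
        }
        if (i > burn) keep[i - burn, ] <- th
      }
      draws[[c_i]] <- keep
    }
  })
  pooled <- do.call(rbind, draws)
  pooled[, 4] <- exp(pooled[, 4])
  pooled[, 5] <- exp(pooled[, 5])
  colnames(pooled) <- c("B", "A", "L", "T", "sigma2")
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(
    list(
      summary = data.frame(
        parameter = colnames(pooled),
        median = qs[2, ], lower = qs[1, ], upper = qs[3, ],
        row.names = NULL
      ),
      acceptance_rate = accepted / total,
      chains = chains, iter = iter, burn = burn, seed = seed,
      draws = pooled
    ),
    class = "mcmc_summary"
  )
}

#' Classify a fitted expression profile
#'
#' Maps a model-selected fit onto the dynamic classes observed in the testis
#' time course: `flat` (constant model or amplitude below `min_amplitude`),
#' `switch_up` / `switch_down` (a sigmoid whose transition, `L +/- T/2`,
#' completes inside the observation window -- the steroidogenesis-onset
#' shape), and `curvilinear_incomplete` (a sigmoid still in progress at the
#' window edge -- the SOX9-like shape). A switch call additionally requires
#' the transition interval to clear the window edges by `margin_frac` of the
#' window span: fitted transitions completing right at the boundary are not
#' distinguishable from incomplete ones under noise, so they are assigned to
#' the incomplete class.
#'
#' @param fit A `balt_fit` (ideally from [select_model()]).
#' @param window Length-2 numeric `(t_min, t_max)` observation window in dpc.
#' @param min_amplitude Minimum |A| to call a change (default 0.58 log2,
#'   about 1.5-fold).
#' @param margin_frac Edge buffer as a fraction of the window span
#'   (default 0.1).
#' @return One of `"flat"`, `"switch_up"`, `"switch_down"`,
#'   `"curvilinear_incomplete"`.
#' @export
classify_profile <- function(fit, window, min_amplitude = 0.58,
                             margin_frac = 0.1) {
  stopifnot(inherits(fit, "balt_fit"))
  if (length(window) != 2 || window[1] >= window[2]) stop("invalid window")
  if (fit$model == "constant") return("flat")
  p <- fit$params
  if (abs(p[["A"]]) < min_amplitude) return("flat")
  margin <- margin_frac * diff(window)
  lo <- p[["L"]] - p[["T"]] / 2
  hi <- p[["L"]] + p[["T"]] / 2
  if (lo >= window[1] + margin && hi <= window[2] - margin) {
    if (p[["A"]] > 0) "switch_up" else "switch_down"
  } else {
    "curvilinear_incomplete"
  }
}

#' Summarise transition onsets over a set of switch-classified fits
#'
#' Restricts to fits classified as `switch_up`/`switch_down` and summarises
#' the distribution of the fitted localisation `L` (mean, median, IQR) and
#' the mean transition duration `T`. Applied to the steroidogenic enzymes,
#' this recovers the shared onset window of testicular steroidogenesis.
#'
#' @param fits Named list of `balt_fit` objects.
#' @param window Observation window passed to [classify_profile()].
#' @param min_amplitude Passed to [classify_profile()].
#' @return List of class `onset_summary`: `n`, `mean_l`, `median_l`, `iqr_l`
#'   (lower/upper quartiles), `mean_t`, `genes`.
#' @export
onset_window <- function(fits, window, min_amplitude = 0.58) {
  if (length(fits) == 0) stop("empty fit list")
  labels <- vapply(fits, classify_profile, character(1),
                   window = window, min_amplitude = min_amplitude)
  keep <- labels %in% c("switch_up", "switch_down")
  if (!any(keep)) stop("no switch-classified fits to summarise")
  l <- vapply(fits[keep], function(f) f$params[["L"]], numeric(1))
  tt <- vapply(fits[keep], function(f) f$params[["T"]], numeric(1))
  iqr <- stats::quantile(l, c(0.25, 0.75), names = FALSE)
  structure(
    list(n = sum(keep), mean_l = mean(l), median_l = stats::median(l),
         iqr_l = iqr, mean_t = mean(tt),
         genes = names(fits)[keep]),
    class = "onset_summary"
  )
}

#' Genes with dynamics similar to a reference profile
#'
#' Finds genes whose fitted dynamics match a reference gene's: same profile
#' class, same direction of change, amplitude at least `min_amplitude`, and
#' localisation/transition within the given tolerances. For curvilinear
#' (incomplete) references only `L` is compared, with the tolerance doubled,
#' because `T` is weakly identified when the transition does not complete
#' inside the window. Used to recover the SOX9-like cohort.
#'
#' @param fits Named list of `balt_fit` objects (names = gene ids).
#' @param reference_gene Name of the reference gene in `fits`.
#' @param tol_l,tol_t Tolerances in days on `L` and `T`.
#' @param window Observation window for classification.
#' @param min_amplitude Minimum |A|.
#' @return A [gene_set()] of matching genes (the reference matches itself).
#' @export
match_reference <- function(fits, reference_gene, tol_l = 5, tol_t = 10,
                            window, min_amplitude = 0.58) {
  if (!reference_gene %in% names(fits)) {
    stop("reference gene not found: ", reference_gene)
  }
  labels <- vapply(fits, classify_profile, character(1),
                   window = window, min_amplitude = min_amplitude)
  ref_lab <- labels[[reference_gene]]
  if (ref_lab == "flat") stop("reference gene has a flat fit")
  ref <- fits[[reference_gene]]$params
  hits <- character()
  for (g in names(fits)) {
    if (labels[[g]] != ref_lab) next
    p <- fits[[g]]$params
    if (sign(p[["A"]]) != sign(ref[["A"]])) next
    if (abs(p[["A"]]) < min_amplitude) next
    if (ref_lab == "curvilinear_incomplete") {
      if (abs(p[["L"]] - ref[["L"]]) <= 2 * tol_l) hits <- c(hits, g)
    } else {
      if (abs(p[["L"]] - ref[["L"]]) <= tol_l &&
          abs(p[["T"]] - ref[["T"]]) <= tol_t) {
        hits <- c(hits, g)
      }
    }
  }
  gene_set(paste0("like_", reference_gene), hits,
           provenance = list(reference = reference_gene, tol_l = tol_l,
                             tol_t = tol_t, label = ref_lab))
}
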