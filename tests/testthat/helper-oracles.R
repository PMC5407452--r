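# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force step-up BH: q_(i) = min_{j >= i} m p_(j) / j, capped at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Grid-search BALT oracle: for each (L, T) node solve B, A by linear least
# squares against the logistic regressor, return the best RSS found.
balt_grid_oracle <- function(times, values, n_l = 60, n_t = 40) {
  span <- diff(range(times))
  l_grid <- seq(min(times) - span / 2, max(times) + span / 2, length.out = n_l)
  t_grid <- exp(seq(log(0.1), log(3 * span), length.out = n_t))
  best <- Inf
  for (L in l_grid) {
    for (Tt in t_grid) {
      s <- 1 / (1 + exp(pmin(pmax(2 * log(9) / Tt * (L - times), -700), 700)))
      fit <- stats::lm.fit(cbind(1, s), values)
      rss <- sum(fit$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Brute-force Venn region membership for named member lists.
venn_brute_force <- function(members) {
  universe <- sort(unique(unlist(members)))
  ids <- LETTERS[seq_along(members)]
  out <- list()
  for (k in seq_along(members)) {
    for (combo in utils::combn(seq_along(members), k, simplify = FALSE)) {
      inside <- universe
      for (i in combo) inside <- intersect(inside, members[[i]])
      for (i in setdiff(seq_along(members), combo)) {
        inside <- setdiff(inside, members[[i]])
      }
      out[[paste(ids[combo], collapse = "")]] <- sort(inside)
    }
  }
  out
}

# Small simulated atlas shared by slower tests.
small_sim <- function(seed = 11, n_flat = 60) {
  simulate_atlas(
    build_design("study_mirror", seed = seed),
    default_truth_panel(n_flat = n_flat),
    seed = seed
  )
}
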