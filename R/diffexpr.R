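#' Per-gene two-group contrast statistics
#'
#' Computes, for every gene, the two group means (log2), their difference
#' (log2 fold change, group A minus group B), the pooled within-group
#' variance and its residual degrees of freedom. This is the pre-moderation
#' stage of the moderated-t pipeline.
#'
#' @param matrix Genes-by-samples matrix.
#' @param groups Per-sample group labels (length = ncol).
#' @param contrast Length-2 character vector `c(groupA, groupB)`; the reported
#'   log2FC is mean(A) - mean(B).
#' @return Data frame of class `de_table` with columns `gene`, `mean_a`,
#'   `mean_b`, `log2fc`, `s2`, `df`, `n_a`, `n_b`.
#' @export
fit_group_means <- function(matrix, groups, contrast) {
  validate_matrix(matrix)
  if (length(groups) != ncol(matrix)) stop("group labels must match samples")
  stopifnot(length(contrast) == 2)
  ja <- which(groups == contrast[1])
  jb <- which(groups == contrast[2])
  if (length(ja) < 2 || length(jb) < 2) {
    stop("both contrast groups need >= 2 samples")
  }
  a <- matrix[, ja, drop = FALSE]
  b <- matrix[, jb, drop = FALSE]
  na <- length(ja); nb <- length(jb)
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  df <- na + nb - 2
  out <- data.frame(
    gene = rownames(matrix),
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = mean_a - mean_b,
    s2 = (ss_a + ss_b) / df,
    df = df,
    n_a = na,
    n_b = nb,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- contrast
  class(out) <- c("de_table", "data.frame")
  out
}

# Inverse of trigamma by Newton iteration on 1/trigamma (as in the standard
# method-of-moments scheme for chi-square scale mixtures).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes variance moderation and moderated t
#'
#' Shrinks per-gene residual variances toward a common prior value s0^2 with
#' prior degrees of freedom d0, both estimated by method of moments on the
#' log sample variances (digamma/trigamma matching). The moderated statistic
#' is `t = log2FC / (s_tilde * sqrt(1/nA + 1/nB))` with
#' `s_tilde^2 = (d0 s0^2 + df s^2) / (d0 + df)`, referred to a t distribution
#' on `df + d0` degrees of freedom (two-sided p). When the observed log
#' variances are no more dispersed than chi-square sampling noise the prior
#' dominates and d0 is infinite; if moment estimation fails outright the
#' function falls back to the ordinary t (d0 = 0) with a warning. Adjusted
#' q-values (Benjamini-Hochberg) are appended.
#'
#' @param table A `de_table` from [fit_group_means()].
#' @param d0 Optional forced prior degrees of freedom (0 = ordinary t,
#'   Inf = pure-prior t); default NULL estimates it.
#' @param s0 Optional forced prior standard deviation (used with `d0 = Inf`).
#' @return The table with columns `t`, `p`, `q` (and attributes `d0`, `s02`).
#' @export
moderate_variances <- function(table, d0 = NULL, s0 = NULL) {
  stopifnot(inherits(table, "de_table"))
  s2 <- table$s2
  df <- table$df[1]
  n_eff <- 1 / table$n_a + 1 / table$n_b
  if (all(s2 == 0)) {
    stop("all residual variances are zero; add noise or force d0/s0")
  }

  if (is.null(d0)) {
    if (nrow(table) < 10) {
      warning("fewer than 10 genes; falling back to ordinary t (d0 = 0)")
      d0 <- 0
    } else {
      ok <- s2 > 0
      z <- log(s2[ok])
      e <- z - digamma(df / 2) + log(df / 2)
      ebar <- mean(e)
      evar <- stats::var(e) * (sum(ok) - 1) / sum(ok)
      excess <- evar - trigamma(df / 2)
      if (!is.finite(ebar) || !is.finite(evar)) {
        warning("variance hyperparameter estimation failed; using ordinary t (d0 = 0)")
        d0 <- 0
      } else if (excess <= 0) {
        d0 <- Inf
        s0 <- sqrt(exp(ebar))
      } else {
        d0 <- 2 * trigamma_inverse(excess)
        s0 <- sqrt(exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
      }
    }
  }
  if (d0 == 0) {
    s2_tilde <- s2
    df_total <- df
  } else if (is.infinite(d0)) {
    if (is.null(s0)) stop("d0 = Inf requires s0")
    s2_tilde <- rep(s0^2, length(s2))
    df_total <- Inf
  } else {
    if (is.null(s0)) stop("finite nonzero d0 requires s0")
    s2_tilde <- (d0 * s0^2 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  tstat <- table$log2fc / sqrt(s2_tilde * n_eff)
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  table$t <- tstat
  table$p <- p
  table$q <- adjust_bh(p)
  attr(table, "d0") <- d0
  attr(table, "s02") <- if (is.null(s0)) NA_real_ else s0^2
  table
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) m p_(j) / j`, capped at 1 and mapped back to input
#' order; the false-discovery-rate control used throughout the atlas analysis.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as input.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Construct a named gene set
#'
#' Gene symbols are upper-cased and de-duplicated so sets transcribed from
#' mixed-case tables compare cleanly.
#'
#' @param name Set name.
#' @param members Character vector of gene ids.
#' @param provenance Optional named list recording how the set was built
#'   (contrast, thresholds).
#' @return List of class `gene_set` with `name`, `members`, `provenance`.
#' @export
gene_set <- function(name, members, provenance = NULL) {
  structure(
    list(name = name, members = sort(unique(toupper(as.character(members)))),
         provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Select differentially expressed genes by threshold
#'
#' Applies the study's cut-offs (adjusted p 0.05; log2FC 1 or 2) to a
#' moderated table.
#'
#' @param table Moderated `de_table` (must contain `q`).
#' @param lfc_cut Nonnegative log2 fold-change threshold.
#' @param q_cut Adjusted-p threshold.
#' @param direction `"up"` (log2FC >= lfc_cut), `"down"` (<= -lfc_cut) or
#'   `"both"` (absolute value).
#' @param name Optional set name.
#' @return A [gene_set()] with provenance recording the thresholds.
#' @export
select_de <- function(table, lfc_cut = 1, q_cut = 0.05,
                      direction = c("up", "down", "both"), name = NULL) {
  direction <- match.arg(direction)
  if (lfc_cut < 0) stop("lfc_cut must be >= 0")
  if (!"q" %in% names(table)) stop("table must be moderated and BH-adjusted first")
  keep <- switch(direction,
    up = table$log2fc >= lfc_cut,
    down = table$log2fc <= -lfc_cut,
    both = abs(table$log2fc) >= lfc_cut
  )
  keep <- keep & table$q <= q_cut
  if (is.null(name)) {
    name <- sprintf("%s_lfc%g_q%g", direction, lfc_cut, q_cut)
  }
  gene_set(name, table$gene[keep],
           provenance = list(contrast = attr(table, "contrast"),
                             lfc_cut = lfc_cut, q_cut = q_cut,
                             direction = direction))
}

#' Convert log2 fold change to absolute fold change
#'
#' @param lfc Finite log2 fold change(s).
#' @param signed If TRUE, returns `2^|lfc|` with a `direction` attribute
#'   ("up"/"down") instead of `2^lfc`.
#' @return Positive fold change(s); e.g. `log2fc_to_absfc(6.85)` is 115.4 to
#'   one decimal.
#' @export
log2fc_to_absfc <- function(lfc, signed = FALSE) {
  stopifnot(all(is.finite(lfc)))
  if (!signed) return(2^lfc)
  structure(2^abs(lfc), direction = ifelse(lfc >= 0, "up", "down"))
}

#' Top-ranked genes by log2 fold change
#'
#' @param table A `de_table`.
#' @param n Number of rows (clamped to the table size).
#' @return The top `n` rows by descending log2FC, ties broken by q then gene
#'   id.
#' @export
top_table <- function(table, n = 20) {
  if (n < 1) stop("n must be >= 1")
  q <- if ("q" %in% names(table)) table$q else rep(0, nrow(table))
  ord <- order(-table$log2fc, q, table$gene)
  table[ord[seq_len(min(n, nrow(table)))], , drop = FALSE]
}

#' Comparative-Ct (delta-delta-Ct) fold change
#'
#' qRT-PCR quantification relative to a housekeeping control and a calibrator
#' condition: `dCt = Ct_target - Ct_housekeeping` per condition,
#' `ddCt = dCt_sample - dCt_calibrator`, fold change `2^(-ddCt)`.
#'
#' @param ct_target_sample,ct_hk_sample Target and housekeeping Ct in the
#'   sample condition.
#' @param ct_target_calibrator,ct_hk_calibrator Same for the calibrator.
#' @return Fold change above the calibrator; vectorised.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_hk_sample,
                             ct_target_calibrator, ct_hk_calibrator) {
  args <- list(ct_target_sample, ct_hk_sample, ct_target_calibrator, ct_hk_calibrator)
  if (any(vapply(args, function(x) any(!is.finite(x) | x <= 0), logical(1)))) {
    stop("all Ct values must be positive and finite (housekeeping values required)")
  }
  ddct <- (ct_target_sample - ct_hk_sample) -
    (ct_target_calibrator - ct_hk_calibrator)
  2^(-ddct)
}
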