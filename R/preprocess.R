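#' Validate a genes-by-samples expression matrix
#'
#' @param matrix Numeric matrix, genes in rows (unique rownames,
#'   case-insensitive) and samples in columns (unique colnames), all values
#'   finite log2 expression.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  dup <- duplicated(toupper(rownames(matrix)))
  if (any(dup)) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(matrix)[dup]), collapse = ", "))
  }
  if (anyDuplicated(colnames(matrix))) stop("duplicate sample ids")
  if (any(!is.finite(matrix))) stop("expression matrix contains non-finite values")
  invisible(matrix)
}

#' Quantile-normalise columns of an expression matrix
#'
#' Forces every sample (column) onto the identical reference distribution --
#' the across-sample mean of the sorted columns, with ties averaged. Used as
#' the normalisation step when consuming raw synthetic input in place of an
#' RMA-normalised matrix.
#'
#' @param matrix Genes-by-samples numeric matrix.
#' @return Matrix of the same dimensions with identical column distributions.
#' @export
quantile_normalize <- function(matrix) {
  validate_matrix(matrix)
  if (ncol(matrix) < 2) stop("quantile normalisation needs >= 2 samples")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Remove additive/multiplicative batch effects per gene
#'
#' Two modes. `meanvar` standardises each batch per gene and rescales to the
#' gene's pooled mean and pooled within-batch variance, so per-batch gene
#' means are exactly equalised. `eb` applies ComBat-style empirical-Bayes
#' shrinkage (without covariates): per-gene per-batch location and log-scale
#' estimates are shrunk across genes toward their batch-wise means with
#' inverse-variance weights before subtraction, stabilising the correction
#' for genes with few samples per batch.
#'
#' @param matrix Genes-by-samples matrix.
#' @param batches Per-sample batch labels (length = ncol).
#' @param mode `"meanvar"` or `"eb"`.
#' @return Adjusted matrix, same dimensions.
#' @export
adjust_batch <- function(matrix, batches, mode = c("meanvar", "eb")) {
  mode <- match.arg(mode)
  validate_matrix(matrix)
  if (length(batches) != ncol(matrix)) {
    stop("batch labels must match the number of samples")
  }
  tab <- table(batches)
  if (length(tab) < 2) stop("need >= 2 batches")
  if (any(tab < 2)) {
    stop("each batch needs >= 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  blevels <- names(tab)
  idx <- lapply(blevels, function(b) which(batches == b))
  nb <- lengths(idx)

  g_mean <- rowMeans(matrix)
  b_mean <- vapply(idx, function(j) rowMeans(matrix[, j, drop = FALSE]),
                   numeric(nrow(matrix)))
  b_var <- vapply(idx, function(j) {
    apply(matrix[, j, drop = FALSE], 1, stats::var)
  }, numeric(nrow(matrix)))
  # pooled within-batch variance per gene
  w <- nb - 1
  pooled_var <- as.vector(b_var %*% w) / sum(w)
  pooled_sd <- sqrt(pooled_var)

  if (mode == "meanvar") {
    out <- matrix
    for (b in seq_along(blevels)) {
      j <- idx[[b]]
      sd_b <- sqrt(b_var[, b])
      scale <- ifelse(sd_b > 1e-12 & pooled_sd > 1e-12, pooled_sd / sd_b, 1)
      out[, j] <- (matrix[, j, drop = FALSE] - b_mean[, b]) * scale + g_mean
    }
    return(out)
  }

  # eb mode: standardise per gene, then shrink per-batch location and
  # log-scale estimates across genes toward their batch-wise means with
  # inverse-variance weights before subtracting them
  safe_sd <- ifelse(pooled_sd > 1e-12, pooled_sd, 1)
  z <- (matrix - g_mean) / safe_sd
  zb_mean <- vapply(idx, function(j) rowMeans(z[, j, drop = FALSE]),
                    numeric(nrow(matrix)))
  zb_var <- pmax(vapply(idx, function(j) {
    apply(z[, j, drop = FALSE], 1, stats::var)
  }, numeric(nrow(matrix))), 1e-12)

  gamma_bar <- colMeans(zb_mean)
  tau2 <- pmax(apply(zb_mean, 2, stats::var), 1e-12)
  log_d2_bar <- colMeans(log(zb_var))
  v_pri <- pmax(apply(log(zb_var), 2, stats::var), 1e-12)
  v_dat <- 2 / pmax(nb - 1, 1)  # sampling variance of log s2, large-sample

  out <- matrix
  for (b in seq_along(blevels)) {
    j <- idx[[b]]
    w_dat <- nb[b] / zb_var[, b]
    gamma_star <- (w_dat * zb_mean[, b] + (1 / tau2[b]) * gamma_bar[b]) /
      (w_dat + 1 / tau2[b])
    log_d2_star <- (log(zb_var[, b]) / v_dat[b] + log_d2_bar[b] / v_pri[b]) /
      (1 / v_dat[b] + 1 / v_pri[b])
    delta_star <- sqrt(exp(log_d2_star))
    out[, j] <- ((z[, j, drop = FALSE] - gamma_star) / delta_star) * safe_sd +
      g_mean
  }
  out
}

#' Flag outlying samples by within-tissue correlation
#'
#' For each tissue group with at least 4 samples, each sample's median Pearson
#' correlation to the other samples of that tissue is computed; samples whose
#' median correlation falls below Q1 - k * IQR of the group's distribution are
#' flagged. Mirrors the QC exclusion of an extreme-outlier adrenal sample in
#' the study.
#'
#' @param matrix Genes-by-samples matrix.
#' @param meta Sample table with `sample_id` and `tissue`.
#' @param k Tukey fence multiplier (default 3, "extreme" outliers).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outliers <- function(matrix, meta, k = 3) {
  validate_matrix(matrix)
  stopifnot(all(colnames(matrix) %in% meta$sample_id))
  flagged <- character()
  for (tis in unique(meta$tissue)) {
    ids <- intersect(meta$sample_id[meta$tissue == tis], colnames(matrix))
    if (length(ids) < 4) {
      warning("tissue '", tis, "' has < 4 samples; outlier check skipped")
      next
    }
    cm <- stats::cor(matrix[, ids, drop = FALSE])
    diag(cm) <- NA
    medcor <- apply(cm, 2, stats::median, na.rm = TRUE)
    q <- stats::quantile(medcor, c(0.25, 0.75), names = FALSE)
    thr <- q[1] - k * (q[2] - q[1])
    flagged <- c(flagged, ids[medcor < thr])
  }
  flagged
}

#' Principal-component embedding of samples
#'
#' Projects samples onto the top principal axes of the sample-by-gene matrix
#' after per-gene centring.
#'
#' @param matrix Genes-by-samples matrix.
#' @param k Number of components.
#' @return List of class `pca_result`: `scores` (samples x k) and
#'   `var_frac` (length-k variance fractions).
#' @export
pca_embed <- function(matrix, k = 2) {
  validate_matrix(matrix)
  if (k < 1) stop("k must be >= 1")
  if (k > min(dim(matrix))) stop("k exceeds matrix rank bound")
  x <- sweep(t(matrix), 2, rowMeans(matrix))  # samples x genes, per-gene centred
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var < 1e-24) {
    scores <- matrix(0, ncol(matrix), k,
                     dimnames = list(colnames(matrix), paste0("PC", seq_len(k))))
    return(structure(list(scores = scores, var_frac = rep(0, k)),
                     class = "pca_result"))
  }
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  kk <- min(k, ncol(pr$x))
  scores <- pr$x[, seq_len(kk), drop = FALSE]
  if (kk < k) {
    scores <- cbind(scores, matrix(0, nrow(scores), k - kk))
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  vf <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)]
  vf[is.na(vf)] <- 0
  structure(list(scores = scores, var_frac = vf), class = "pca_result")
}

#' Ward clustering of samples on the most variable genes
#'
#' Hierarchical clustering (Ward's method, `ward.D2`) on Euclidean distances
#' between samples, restricted to the `n_top_genes` most variable genes.
#' Samples are ordered by id before clustering so the tree is invariant to
#' input column order.
#'
#' @param matrix Genes-by-samples matrix.
#' @param n_top_genes Number of most-variable genes to use (ties broken by
#'   gene id).
#' @return An [stats::hclust] object.
#' @export
cluster_samples <- function(matrix, n_top_genes = 500) {
  validate_matrix(matrix)
  if (ncol(matrix) < 3) stop("need >= 3 samples to cluster")
  if (n_top_genes < 2) stop("n_top_genes must be >= 2")
  v <- apply(matrix, 1, stats::var)
  ord <- order(-v, rownames(matrix))
  top <- ord[seq_len(min(n_top_genes, nrow(matrix)))]
  m <- matrix[top, order(colnames(matrix)), drop = FALSE]
  stats::hclust(stats::dist(t(m)), method = "ward.D2")
}

#' Export a sample dendrogram as a Newick string
#'
#' @param hc An [stats::hclust] object from [cluster_samples()].
#' @return Single Newick string (requires the `ape` package).
#' @export
linkage_to_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(hc))
}
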