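#' Study-mirror design configuration
#'
#' Per-tissue sample counts and stage allocation matching the atlas study
#' design: 17 adrenal glands, 20 testes, 10 ovaries and 6 single-organ
#' control samples (spine, brain, muscle, heart, kidney, liver), spread from
#' CS17 to F3. The testis allocation places 9 samples before CS23, 3 at CS23
#' and 8 after it, so the early/late split around CS23 reproduces the study's
#' N = 9 early and N = 8 late groups.
#'
#' @return Data frame with columns `tissue`, `stage`, `n` (and
#'   `control_subtype` for control rows).
#' @export
study_mirror_design <- function() {
  alloc <- rbind(
    data.frame(
      tissue = "adrenal",
      stage = c("CS17", "CS18", "CS19", "CS20", "CS21", "CS22", "CS23", "F1", "F2", "F3"),
      n     = c(1, 2, 2, 2, 2, 2, 2, 2, 1, 1)
    ),
    data.frame(
      tissue = "testis",
      stage = c("CS18", "CS19", "CS20", "CS21", "CS22", "CS23", "F1", "F2", "F3"),
      n     = c(1, 3, 2, 2, 1, 3, 3, 3, 2)
    ),
    data.frame(
      tissue = "ovary",
      stage = c("CS18", "CS19", "CS20", "CS21", "CS22", "CS23", "F1", "F2", "F3"),
      n     = c(1, 1, 1, 1, 1, 1, 1, 1, 2)
    ),
    data.frame(
      tissue = "control",
      stage = c("CS18", "CS19", "CS21", "CS23", "F1", "F3"),
      n     = 1
    )
  )
  alloc$control_subtype <- NA_character_
  alloc$control_subtype[alloc$tissue == "control"] <-
    c("spine", "brain", "muscle", "heart", "kidney", "liver")
  alloc
}

tissue_labels <- c("adrenal", "testis", "ovary", "control")

#' Build a sample design table
#'
#' Expands a per-tissue stage allocation into one record per sample, assigning
#' sample ids, karyotypes (ovary 46,XX; everything else 46,XY, as in the study
#' design), midpoint ages from the stage map, and a seeded balanced split into
#' batches.
#'
#' @param config Either the string `"study_mirror"` or a data frame with
#'   columns `tissue`, `stage`, `n` (optionally `control_subtype`).
#' @param seed Integer seed driving the batch assignment.
#' @param stage_map Stage midpoint map.
#' @param n_batches Number of batches (default 2).
#' @return Data frame (class `sample_table`) with columns `sample_id`,
#'   `tissue`, `control_subtype`, `karyotype`, `stage`, `age_dpc`, `batch`.
#' @examples
#' design <- build_design("study_mirror", seed = 1)
#' table(design$tissue)
#' @export
build_design <- function(config = "study_mirror", seed = 1,
                         stage_map = default_stage_map(), n_batches = 2) {
  if (is.character(config) && length(config) == 1) {
    if (config != "study_mirror") stop("unknown design preset: ", config)
    config <- study_mirror_design()
  }
  stopifnot(is.data.frame(config), all(c("tissue", "stage", "n") %in% names(config)))
  bad <- setdiff(unique(config$tissue), tissue_labels)
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (any(config$n < 0)) stop("sample counts must be >= 0")
  stage_to_dpc(config$stage, stage_map)  # validates labels

  rows <- config[rep(seq_len(nrow(config)), config$n), , drop = FALSE]
  if (nrow(rows) == 0) {
    out <- data.frame(
      sample_id = character(), tissue = character(),
      control_subtype = character(), karyotype = character(),
      stage = character(), age_dpc = numeric(), batch = character(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("sample_table", "data.frame")
    return(out)
  }
  # stable ordering: tissue (fixed order) then stage order
  rows <- rows[order(match(rows$tissue, tissue_labels),
                     match(rows$stage, names(stage_map))), , drop = FALSE]
  prefix <- c(adrenal = "ADR", testis = "TES", ovary = "OVA", control = "CTL")
  idx <- stats::ave(seq_len(nrow(rows)), rows$tissue, FUN = seq_along)
  out <- data.frame(
    sample_id = sprintf("%s%02d", prefix[rows$tissue], idx),
    tissue = rows$tissue,
    control_subtype = if ("control_subtype" %in% names(rows)) {
      rows$control_subtype
    } else {
      NA_character_
    },
    karyotype = ifelse(rows$tissue == "ovary", "46,XX", "46,XY"),
    stage = rows$stage,
    age_dpc = stage_to_dpc(rows$stage, stage_map),
    batch = NA_character_,
    stringsAsFactors = FALSE
  )
  withr_seed(seed, {
    out$batch <- sample(rep(paste0("b", seq_len(n_batches)), length.out = nrow(out)))
  })
  rownames(out) <- NULL
  class(out) <- c("sample_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Evaluate a noise-free truth profile
#'
#' The generator plants four profile shapes observed in the atlas: `flat`
#' (constant baseline), `tissue_offset` (baseline plus a constant offset in
#' target tissues), `sigmoid` (a BALT transition in target tissues, baseline
#' `B` elsewhere), and `pulse` (a transient Gaussian bump in target tissues,
#' the SRY-like shape: high around 45 dpc, decayed by ~57 dpc).
#'
#' Sigmoid profiles additionally accept `plateau_tissues`: tissues in which
#' the transition completed before the observation window, so expression sits
#' at the finishing level `B + A` throughout. This models the fetal adrenal,
#' where steroidogenesis onset precedes 42 dpc while the testis transitions
#' mid-window.
#'
#' @param profile A list/one-row data frame with `profile_class`,
#'   `target_tissues` (character vector or comma-separated string) and the
#'   class parameters (`b`, `d`, `h`, `mu`, `w`, `B`, `A`, `L`, `T`).
#' @param tissue Tissue label of the sample.
#' @param t Age(s) in dpc; vectorised.
#' @return Numeric vector of noise-free log2 expression values.
#' @export
eval_truth_profile <- function(profile, tissue, t) {
  profile <- as.list(profile)
  targets <- profile$target_tissues
  if (is.list(targets)) targets <- targets[[1]]
  if (length(targets) == 1 && is.character(targets)) {
    targets <- strsplit(targets, ",", fixed = TRUE)[[1]]
  }
  targets <- trimws(targets)
  in_target <- tissue %in% targets
  switch(profile$profile_class,
    flat = rep(profile$b, length(t)),
    tissue_offset = rep(profile$b + if (in_target) profile$d else 0, length(t)),
    sigmoid = {
      plateau <- profile$plateau_tissues
      if (is.list(plateau)) plateau <- plateau[[1]]
      if (!is.null(plateau) && length(plateau) == 1 && is.character(plateau)) {
        plateau <- strsplit(plateau, ",", fixed = TRUE)[[1]]
      }
      if (in_target) {
        balt_evaluate(c(B = profile$B, A = profile$A, L = profile$L, T = profile$T), t)
      } else if (tissue %in% trimws(plateau %||% character())) {
        rep(profile$B + profile$A, length(t))
      } else {
        rep(profile$B, length(t))
      }
    },
    pulse = {
      stopifnot(profile$w > 0)
      if (in_target) {
        profile$b + profile$h * exp(-(t - profile$mu)^2 / (2 * profile$w^2))
      } else {
        rep(profile$b, length(t))
      }
    },
    stop("unknown profile_class: ", profile$profile_class)
  )
}

#' Default planted-truth panel
#'
#' The default panel mirrors the profile families the atlas exhibits:
#' \itemize{
#'   \item one Y-chromosomal SRY-like pulse gene, testis only (peak ~45 dpc,
#'     declined by ~57 dpc);
#'   \item 8 steroidogenic sigmoid genes shared by adrenal and testis, onset
#'     localised around 55--56 dpc with 3--5 day transitions and large
#'     amplitudes (5.5--7 log2 units, matching adrenal fold changes of order
#'     50--250x);
#'   \item 3 SOX9-like curvilinear genes (slow incomplete sigmoids, testis);
#'   \item tissue-offset marker genes for each tissue;
#'   \item flat background genes with baselines spread over 4--10 log2 units.
#' }
#' Some planted genes carry secreted-protein flags and functional categories
#' so annotation-driven screens are exercisable against known truth.
#'
#' @param n_flat Number of flat background genes.
#' @param noise_sd Per-gene Gaussian noise sd on the log2 scale.
#' @return Data frame (class `truth_panel`), one row per gene, with profile
#'   parameters plus `chromosome`, `secreted`, `category` annotation columns.
#' @export
default_truth_panel <- function(n_flat = 274, noise_sd = 0.25) {
  stopifnot(n_flat >= 0, noise_sd >= 0)
  blank <- function(n) rep(NA_real_, n)
  stero <- data.frame(
    gene_id = sprintf("STERO%02d", 1:8),
    profile_class = "sigmoid",
    target_tissues = "testis",
    plateau_tissues = "adrenal",
    b = blank(8), d = blank(8), h = blank(8), mu = blank(8), w = blank(8),
    B = c(6, 5.5, 6.5, 6, 5.8, 6.2, 6, 6.4),
    A = c(6, 4.5, 5.5, 5, 7, 4, 6.5, 5.5),
    L = c(54.8, 55.2, 55.5, 55.5, 55.8, 56.2, 55, 56),
    T = c(3, 4, 4, 5, 4, 3.5, 4.5, 4),
    chromosome = c("10", "15", "8", "1", "3", "19", "2", "17"),
    # three planted secreted biomarkers among the late-testis-up genes,
    # mirroring AMH / INHA / INSL3
    secreted = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    category = "steroidogenesis"
  )
  curv <- data.frame(
    gene_id = sprintf("CURV%02d", 1:3),
    profile_class = "sigmoid",
    target_tissues = "testis",
    plateau_tissues = "",
    b = blank(3), d = blank(3), h = blank(3), mu = blank(3), w = blank(3),
    B = c(7, 6.5, 7.2), A = c(1, 1.2, 1.1), L = c(70, 68, 69), T = c(25, 22, 20),
    chromosome = c("17", "5", "12"),
    secreted = FALSE,
    category = "sox9_like"
  )
  pulse <- data.frame(
    gene_id = "SRYP01",
    profile_class = "pulse",
    target_tissues = "testis",
    plateau_tissues = "",
    b = 5, d = NA_real_, h = 1.5, mu = 45, w = 5,
    B = NA_real_, A = NA_real_, L = NA_real_, T = NA_real_,
    chromosome = "Y",
    secreted = FALSE,
    category = "sex_determination"
  )
  # constitutive tissue-identity signatures: 20 genes per tissue, offsets
  # 3-5 log2, so tissue identity dominates within-tissue developmental change
  # in whole-matrix distances, as it does in real transcriptomes
  n_sig <- 20
  offsets <- data.frame(
    gene_id = c(sprintf("ADRSP%02d", seq_len(n_sig)),
                sprintf("OVASP%02d", seq_len(n_sig)),
                sprintf("TESSP%02d", seq_len(n_sig))),
    profile_class = "tissue_offset",
    target_tissues = rep(c("adrenal", "ovary", "testis"), each = n_sig),
    plateau_tissues = "",
    b = rep(c(6, 5.5, 6.5, 6, 7), length.out = 3 * n_sig),
    d = rep(c(3, 3.5, 4, 4.5, 5), length.out = 3 * n_sig),
    h = blank(3 * n_sig), mu = blank(3 * n_sig), w = blank(3 * n_sig),
    B = blank(3 * n_sig), A = blank(3 * n_sig), L = blank(3 * n_sig),
    T = blank(3 * n_sig),
    chromosome = rep(c("2", "7", "11", "4", "20", "6", "9", "14"),
                     length.out = 3 * n_sig),
    secreted = rep(c(TRUE, FALSE, FALSE, FALSE, TRUE,
                     FALSE, FALSE, FALSE, FALSE, FALSE),
                   length.out = 3 * n_sig),
    category = "marker"
  )
  flat <- if (n_flat > 0) {
    data.frame(
      gene_id = sprintf("FLAT%03d", seq_len(n_flat)),
      profile_class = "flat",
      target_tissues = "",
      plateau_tissues = "",
      b = seq(4, 10, length.out = n_flat),
      d = blank(n_flat), h = blank(n_flat), mu = blank(n_flat), w = blank(n_flat),
      B = blank(n_flat), A = blank(n_flat), L = blank(n_flat), T = blank(n_flat),
      chromosome = rep(c(as.character(1:22), "X"), length.out = n_flat),
      secreted = FALSE,
      category = "background"
    )
  } else {
    NULL
  }
  panel <- rbind(pulse, stero, curv, offsets, flat)
  panel$noise_sd <- noise_sd
  rownames(panel) <- NULL
  class(panel) <- c("truth_panel", "data.frame")
  panel
}

#' Simulate a synthetic expression atlas with known ground truth
#'
#' Each matrix entry is the noise-free truth profile value plus an additive
#' per-batch per-gene offset drawn Normal(0, `batch_sd`) and Gaussian
#' measurement noise on the log2 scale. Identical seeds reproduce the matrix
#' bit for bit.
#'
#' @param design Sample table from [build_design()].
#' @param panel Truth panel from [default_truth_panel()] (or compatible).
#' @param seed Integer seed for batch offsets and noise.
#' @param batch_sd Sd of the per-batch per-gene additive offsets (log2 units);
#'   0 disables batch effects.
#' @return List of class `atlas_sim` with elements `matrix` (genes x samples),
#'   `truth`, `design`, `annotation`, `batch_offsets`, `seed`.
#' @examples
#' sim <- simulate_atlas(build_design(seed = 1), default_truth_panel(20), seed = 7)
#' dim(sim$matrix)
#' @export
simulate_atlas <- function(design, panel = default_truth_panel(), seed = 1,
                           batch_sd = 0.3) {
  if (nrow(design) == 0) stop("design is empty")
  if (nrow(panel) == 0) stop("truth panel has zero genes")
  stopifnot(all(panel$noise_sd >= 0), batch_sd >= 0)

  clean <- matrix(0, nrow(panel), nrow(design),
                  dimnames = list(panel$gene_id, design$sample_id))
  for (i in seq_len(nrow(panel))) {
    prof <- as.list(panel[i, ])
    for (j in seq_len(nrow(design))) {
      clean[i, j] <- eval_truth_profile(prof, design$tissue[j], design$age_dpc[j])
    }
  }

  batches <- sort(unique(design$batch))
  mat <- withr_seed(seed, {
    off <- matrix(stats::rnorm(nrow(panel) * length(batches), 0, batch_sd),
                  nrow(panel), length(batches),
                  dimnames = list(panel$gene_id, batches))
    noise <- matrix(stats::rnorm(length(clean)), nrow(clean), ncol(clean)) *
      panel$noise_sd
    list(m = clean + off[, match(design$batch, batches), drop = FALSE] + noise,
         off = off)
  })
  m <- mat$m
  dimnames(m) <- dimnames(clean)
  annotation <- data.frame(
    gene = panel$gene_id,
    chromosome = panel$chromosome,
    secreted = panel$secreted,
    category = panel$category,
    stringsAsFactors = FALSE
  )
  structure(
    list(matrix = m, truth = panel, design = design, annotation = annotation,
         batch_offsets = mat$off, seed = seed),
    class = "atlas_sim"
  )
}
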