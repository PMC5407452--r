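#' Default pipeline configuration
#'
#' @param out_dir Output directory for the run.
#' @param seed Master seed.
#' @param matrix_path,metadata_path,annotation_path Input file paths; when
#'   `NULL` the synthetic study-mirror preset is simulated instead.
#' @param lfc_cut_adrenal Log2FC cut for the adrenal-vs-control "up" set
#'   (default 2).
#' @param lfc_cut_testis Log2FC cut for the late-vs-early testis "up" set and
#'   the tissue-vs-control sets (default 1).
#' @param q_cut Adjusted-p threshold (default 0.05).
#' @param boundary Boundary stage for the early/late testis split.
#' @param batch_mode Batch-adjustment mode, `"meanvar"` or `"eb"`.
#' @param n_flat Background gene count for the synthetic preset.
#' @param noise_sd,batch_sd Synthetic noise and batch-offset sds.
#' @param balt_opts Options from [balt_options()].
#' @return Named list (a `RunConfig`).
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            matrix_path = NULL, metadata_path = NULL,
                            annotation_path = NULL,
                            lfc_cut_adrenal = 2, lfc_cut_testis = 1,
                            q_cut = 0.05, boundary = "CS23",
                            batch_mode = "meanvar",
                            n_flat = 274, noise_sd = 0.25, batch_sd = 0.3,
                            balt_opts = balt_options()) {
  stopifnot(lfc_cut_adrenal > 0, lfc_cut_testis > 0, q_cut > 0,
            seed == as.integer(seed))
  as.list(environment())
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `RunConfig` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

pipe_log <- function(...) message("[baltatlas] ", ...)

#' Run the full atlas analysis pipeline
#'
#' Executes the workflow end to end: simulate the study-mirror atlas (or load
#' the configured inputs), batch-adjust, QC (outliers, PCA, clustering), run
#' the four differential-expression contrasts (adrenal/testis/ovary versus
#' control and late-versus-early testis), fit the BALT model across the
#' testis time course, and apply the candidate screens (tissue Venn,
#' steroidogenesis intersection, chromosome-Y, secreted-protein). All outputs
#' are written as TSV/text plus a machine-readable JSON run log; rerunning
#' with the same configuration and seed reproduces the outputs bit for bit.
#'
#' @param config List from [pipeline_config()] (or [read_config()]).
#' @return Invisibly, a list with the main in-memory results (`matrix`,
#'   `design`, `de`, `fits`, `sets`, `onset`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  synthetic <- is.null(config$matrix_path)

  if (synthetic) {
    pipe_log("simulate: study-mirror design, seed ", config$seed)
    design <- build_design("study_mirror", seed = config$seed)
    panel <- default_truth_panel(n_flat = config$n_flat,
                                 noise_sd = config$noise_sd)
    sim <- simulate_atlas(design, panel, seed = config$seed,
                          batch_sd = config$batch_sd)
    mat <- sim$matrix
    annot <- sim$annotation
    write_matrix(mat, file.path(config$out_dir, "matrix_raw.tsv"))
    utils::write.table(as.data.frame(sim$truth),
                       file.path(config$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  } else {
    pipe_log("load: ", config$matrix_path)
    mat <- read_matrix(config$matrix_path)
    design <- read_metadata(config$metadata_path, matrix = mat)
    annot <- if (!is.null(config$annotation_path)) {
      read_annotation(config$annotation_path)
    } else {
      NULL
    }
  }
  write_metadata(design, file.path(config$out_dir, "metadata.tsv"))
  if (!setequal(colnames(mat), design$sample_id)) {
    stop("validation: matrix samples and metadata sample ids differ")
  }
  mat <- mat[, design$sample_id, drop = FALSE]

  pipe_log("preprocess: batch adjustment (", config$batch_mode, ")")
  mat_adj <- adjust_batch(mat, design$batch, mode = config$batch_mode)
  write_matrix(mat_adj, file.path(config$out_dir, "matrix_adjusted.tsv"))
  outliers <- detect_outliers(mat_adj, design)
  if (length(outliers)) pipe_log("flagged outlier(s): ",
                                 paste(outliers, collapse = ", "))
  pca <- pca_embed(mat_adj, k = 2)
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), pca$scores),
    file.path(config$out_dir, "pca_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  hc <- cluster_samples(mat_adj, n_top_genes = min(500, nrow(mat_adj)))
  if (requireNamespace("ape", quietly = TRUE)) {
    writeLines(linkage_to_newick(hc),
               file.path(config$out_dir, "sample_dendrogram.nwk"))
  }

  pipe_log("diffexpr: four pairwise contrasts")
  groups <- design$tissue
  de <- list()
  for (tis in c("adrenal", "testis", "ovary")) {
    tab <- fit_group_means(mat_adj, groups, c(tis, "control"))
    de[[paste0(tis, "_vs_control")]] <- moderate_variances(tab)
  }
  split <- split_early_late(design, "testis", boundary = config$boundary)
  el_groups <- ifelse(design$sample_id %in% split$late, "late",
                      ifelse(design$sample_id %in% split$early, "early", "other"))
  tab <- fit_group_means(mat_adj, el_groups, c("late", "early"))
  de$testis_late_vs_early <- moderate_variances(tab)
  for (nm in names(de)) {
    write_de_table(de[[nm]], file.path(config$out_dir, paste0("de_", nm, ".tsv")))
  }

  pipe_log("balt: fitting testis time course")
  tes <- design$sample_id[design$tissue == "testis"]
  times <- design$age_dpc[match(tes, design$sample_id)]
  window <- range(times)
  fits <- lapply(rownames(mat_adj), function(g) {
    select_model(times, mat_adj[g, tes], opts = config$balt_opts)
  })
  names(fits) <- rownames(mat_adj)
  write_balt_fits(fits, file.path(config$out_dir, "balt_fits_testis.tsv"), window)
  labels <- vapply(fits, classify_profile, character(1), window = window)
  onset <- if (any(labels %in% c("switch_up", "switch_down"))) {
    onset_window(fits[labels %in% c("switch_up", "switch_down")], window)
  } else {
    NULL
  }

  pipe_log("screens: Venn, candidates, chrY, secreted")
  up_sets <- lapply(c("adrenal", "testis", "ovary"), function(tis) {
    s <- select_de(de[[paste0(tis, "_vs_control")]], config$lfc_cut_testis,
                   config$q_cut, "up", name = paste0(tis, "_up"))
    s
  })
  venn <- venn_counts(up_sets)
  write_venn(venn, file.path(config$out_dir, "venn_up_tissues.tsv"))

  adrenal_up <- select_de(de$adrenal_vs_control, config$lfc_cut_adrenal,
                          config$q_cut, "up", name = "adrenal_up_lfc2")
  testis_late_up <- select_de(de$testis_late_vs_early, config$lfc_cut_testis,
                              config$q_cut, "up", name = "testis_late_up_lfc1")
  candidates <- steroidogenesis_candidates(adrenal_up, testis_late_up,
                                           de$adrenal_vs_control)
  write_gene_set(candidates, file.path(config$out_dir, "candidates.txt"))

  sets <- list(adrenal_up = adrenal_up, testis_late_up = testis_late_up,
               candidates = candidates, venn = venn)
  if (!is.null(annot)) {
    early_groups <- ifelse(
      design$sample_id %in% split_early_late(design, "testis", "CS20")$early,
      "early_testis",
      ifelse(design$tissue == "control", "control", "other")
    )
    early_tab <- moderate_variances(
      fit_group_means(mat_adj, early_groups, c("early_testis", "control"))
    )
    chry <- chrY_screen(early_tab, annot, lfc_cut = config$lfc_cut_testis,
                        q_cut = config$q_cut)
    write_gene_set(chry, file.path(config$out_dir, "chry_hits.txt"))
    secreted <- secreted_screen(testis_late_up, annot)
    write_gene_set(secreted, file.path(config$out_dir, "secreted_candidates.txt"))
    categories <- categorize_candidates(candidates, annot)
    utils::write.table(categories,
                       file.path(config$out_dir, "candidate_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sets$chry <- chry
    sets$secreted <- secreted
  }

  log <- list(
    package = "baltatlas",
    version = as.character(utils::packageVersion("baltatlas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    synthetic = synthetic,
    parameters = config[c("lfc_cut_adrenal", "lfc_cut_testis", "q_cut",
                          "boundary", "batch_mode", "n_flat", "noise_sd",
                          "batch_sd")],
    n_genes = nrow(mat_adj),
    n_samples = ncol(mat_adj),
    outliers = outliers,
    onset = if (!is.null(onset)) {
      list(n = onset$n, mean_l = onset$mean_l, median_l = onset$median_l)
    } else {
      NULL
    }
  )
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(matrix = mat_adj, design = design, de = de, fits = fits,
                 sets = sets, onset = onset, out_dir = config$out_dir))
}
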