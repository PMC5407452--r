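#' Read an expression matrix TSV
#'
#' Expects a tab-separated file whose first column is `gene` and remaining
#' columns are sample ids; values must parse as finite reals.
#'
#' @param path File path.
#' @return Validated genes-by-samples numeric matrix.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be named 'gene'")
  dup <- duplicated(toupper(df$gene))
  if (any(dup)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(df$gene[dup]), collapse = ", "))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.finite(x))
    if (length(bad)) {
      stop("non-numeric or non-finite value at row ", bad[1],
           ", column '", names(vals)[j], "'")
    }
    vals[[j]] <- x
  }
  m <- as.matrix(vals)
  rownames(m) <- df$gene
  validate_matrix(m)
  m
}

#' Write an expression matrix TSV
#'
#' @param matrix Genes-by-samples matrix.
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' Required columns: `sample_id`, `tissue`, `karyotype`, `stage`, `batch`;
#' `age_dpc` is filled from the stage map when absent and checked against it
#' when present.
#'
#' @param path File path.
#' @param stage_map Stage map for age lookup.
#' @param matrix Optional expression matrix; sample ids must then match.
#' @return A `sample_table` data frame.
#' @export
read_metadata <- function(path, stage_map = default_stage_map(), matrix = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "karyotype", "stage", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  age <- stage_to_dpc(df$stage, stage_map)
  if ("age_dpc" %in% names(df)) {
    if (any(abs(df$age_dpc - age) > 1e-8)) {
      stop("age_dpc values inconsistent with the stage map")
    }
  }
  df$age_dpc <- age
  if (!"control_subtype" %in% names(df)) df$control_subtype <- NA_character_
  if (!is.null(matrix)) {
    missing_meta <- setdiff(colnames(matrix), df$sample_id)
    if (length(missing_meta)) {
      stop("matrix sample(s) missing from metadata: ",
           paste(missing_meta, collapse = ", "))
    }
  }
  df <- df[, c("sample_id", "tissue", "control_subtype", "karyotype",
               "stage", "age_dpc", "batch")]
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write a sample metadata TSV
#'
#' @param meta A `sample_table`.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' @param path TSV with columns `gene`, `chromosome` and optionally
#'   `secreted` (logical), `category`, `omim`.
#' @return Annotation data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "chromosome") %in% names(df))) {
    stop("annotation needs columns 'gene' and 'chromosome'")
  }
  valid <- c(as.character(1:22), "X", "Y", "MT", "unknown")
  bad <- setdiff(unique(df$chromosome), valid)
  if (length(bad)) stop("invalid chromosome label(s): ", paste(bad, collapse = ", "))
  if ("secreted" %in% names(df)) df$secreted <- as.logical(df$secreted)
  df
}

#' Read / write gene sets as one-symbol-per-line text
#'
#' Files carry a `# name: <set name>` header line followed by one gene symbol
#' per line.
#'
#' @param path File path.
#' @return For `read_gene_set`, a [gene_set()].
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  name <- "unnamed"
  header <- grepl("^# name:", lines)
  if (any(header)) name <- trimws(sub("^# name:", "", lines[which(header)[1]]))
  members <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  gene_set(name, trimws(members))
}

#' @rdname read_gene_set
#' @param set A [gene_set()].
#' @export
write_gene_set <- function(set, path) {
  writeLines(c(paste0("# name: ", set$name), set$members), path)
  invisible(path)
}

#' Write a differential-expression table as TSV
#'
#' Columns: gene, mean_a, mean_b, log2fc, abs_fc, s2, df, t, p, q.
#'
#' @param table Moderated `de_table`.
#' @param path Output path.
#' @export
write_de_table <- function(table, path) {
  out <- data.frame(
    gene = table$gene, mean_a = table$mean_a, mean_b = table$mean_b,
    log2fc = table$log2fc, abs_fc = log2fc_to_absfc(table$log2fc),
    s2 = table$s2, df = table$df,
    t = if ("t" %in% names(table)) table$t else NA_real_,
    p = if ("p" %in% names(table)) table$p else NA_real_,
    q = if ("q" %in% names(table)) table$q else NA_real_,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-gene BALT fit results as TSV
#'
#' Columns: gene, model, B, A, L, T, rss, r2, converged, label.
#'
#' @param fits Named list of `balt_fit` objects.
#' @param path Output path.
#' @param window Observation window used for classification.
#' @export
write_balt_fits <- function(fits, path, window) {
  rows <- lapply(names(fits), function(g) {
    f <- fits[[g]]
    p <- f$params
    data.frame(
      gene = g, model = f$model,
      B = unname(p["B"]),
      A = if (f$model == "sigmoid") unname(p["A"]) else NA_real_,
      L = if (f$model == "sigmoid") unname(p["L"]) else NA_real_,
      T = if (f$model == "sigmoid") unname(p["T"]) else NA_real_,
      rss = f$rss, r2 = f$r2, converged = f$converged,
      label = classify_profile(f, window),
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write Venn region counts as TSV
#'
#' @param venn A `venn_result`.
#' @param path Output path.
#' @export
write_venn <- function(venn, path) {
  df <- data.frame(
    region = names(venn$regions),
    count = unname(venn$counts),
    members = vapply(venn$regions, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
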