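#' Split a tissue's samples around a boundary stage
#'
#' The onset of testicular steroidogenesis makes CS23 (8 weeks) a natural
#' boundary: samples on either side of it form the "pre-steroidogenesis"
#' (early) and "post-steroidogenesis" (late) groups. Samples at the boundary
#' stage itself sit on neither side and are returned separately. With the
#' study-mirror design and the default CS23 boundary, the testis splits into
#' 9 early (CS18--CS22) and 8 late (F1--F3) samples.
#'
#' @param meta Sample table with `sample_id`, `tissue`, `stage`.
#' @param tissue Tissue to split.
#' @param boundary Boundary stage label (default `"CS23"`).
#' @param stage_map Stage map defining the stage order.
#' @return List with `early`, `late` and `boundary` character vectors of
#'   sample ids; the three together partition the tissue's samples.
#' @export
split_early_late <- function(meta, tissue, boundary = "CS23",
                             stage_map = default_stage_map()) {
  if (!boundary %in% names(stage_map)) {
    stop("unknown boundary stage: ", boundary)
  }
  sub <- meta[meta$tissue == tissue, , drop = FALSE]
  rank <- match(sub$stage, names(stage_map))
  if (any(is.na(rank))) {
    stop("unknown stage label(s): ",
         paste(unique(sub$stage[is.na(rank)]), collapse = ", "))
  }
  b <- match(boundary, names(stage_map))
  list(
    early = sub$sample_id[rank < b],
    late = sub$sample_id[rank > b],
    boundary = sub$sample_id[rank == b]
  )
}

#' Region counts and memberships of a 2- or 3-set Venn partition
#'
#' @param sets List of 2 or 3 [gene_set()] objects.
#' @return Object of class `venn_result`: `set_names`, `regions` (named list
#'   of member vectors, names like `"A"`, `"AB"`, `"ABC"` denoting which sets
#'   a region belongs to), and `counts`.
#' @export
venn_counts <- function(sets) {
  if (!length(sets) %in% 2:3) stop("venn_counts supports 2 or 3 sets only")
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  members <- lapply(sets, `[[`, "members")
  set_names <- vapply(sets, `[[`, character(1), "name")
  universe <- sort(unique(unlist(members)))
  letters_id <- LETTERS[seq_along(sets)]
  key <- vapply(universe, function(g) {
    paste(letters_id[vapply(members, function(m) g %in% m, logical(1))],
          collapse = "")
  }, character(1))
  all_regions <- unlist(lapply(seq_along(sets), function(k) {
    apply(utils::combn(letters_id, k), 2, paste, collapse = "")
  }))
  regions <- lapply(all_regions, function(r) unname(universe[key == r]))
  names(regions) <- all_regions
  structure(
    list(set_names = stats::setNames(set_names, letters_id),
         regions = regions,
         counts = vapply(regions, length, integer(1))),
    class = "venn_result"
  )
}

#' @export
print.venn_result <- function(x, ...) {
  cat("<venn_result>", paste(x$set_names, collapse = " / "), "\n")
  print(x$counts)
  invisible(x)
}

#' Steroidogenesis candidate genes from the adrenal/testis intersection
#'
#' The screen that produced the 45-gene candidate list: genes up-regulated in
#' adrenal versus control (log2FC >= 2) intersected with genes up-regulated in
#' late versus early testis (log2FC >= 1). Warns when either set lacks
#' provenance recording those thresholds.
#'
#' @param adrenal_up [gene_set()] from the adrenal-vs-control contrast.
#' @param testis_late_up [gene_set()] from the late-vs-early testis contrast.
#' @param adrenal_table Optional moderated `de_table` used to sort the
#'   candidates by descending adrenal log2FC.
#' @return A [gene_set()] of candidate genes.
#' @export
steroidogenesis_candidates <- function(adrenal_up, testis_late_up,
                                       adrenal_table = NULL) {
  no_prov <- Filter(
    function(s) is.null(s$provenance) || is.null(s$provenance$lfc_cut),
    list(adrenal_up, testis_late_up)
  )
  if (length(no_prov)) {
    warning("gene set(s) without threshold provenance: ",
            paste(vapply(no_prov, `[[`, character(1), "name"), collapse = ", "))
  }
  hits <- intersect(adrenal_up$members, testis_late_up$members)
  if (!is.null(adrenal_table)) {
    lfc <- adrenal_table$log2fc[match(hits, toupper(adrenal_table$gene))]
    hits <- hits[order(-lfc, hits)]
  }
  out <- gene_set("steroidogenesis_candidates", hits,
                  provenance = list(adrenal = adrenal_up$provenance,
                                    testis = testis_late_up$provenance))
  out$members <- hits  # preserve log2FC ordering when a table was supplied
  out
}

#' Genes exclusive to a target set
#'
#' @param target A [gene_set()].
#' @param others List of [gene_set()] objects to exclude.
#' @return [gene_set()] of `target` minus the union of `others`.
#' @export
exclusive_set <- function(target, others = list()) {
  excl <- unique(unlist(lapply(others, `[[`, "members")))
  gene_set(paste0(target$name, "_exclusive"),
           setdiff(target$members, excl),
           provenance = list(target = target$name,
                             excluded = vapply(others, `[[`, character(1), "name")))
}

#' Y-chromosome differential-expression screen
#'
#' Significant up-regulated genes restricted to chromosome Y -- the screen
#' that singles out SRY in the early-testis-versus-control contrast. Genes
#' absent from the annotation are treated as chromosome unknown and excluded
#' with a warning.
#'
#' @param table Moderated `de_table`.
#' @param annot Gene annotation data frame with columns `gene`, `chromosome`.
#' @param lfc_cut,q_cut Selection thresholds.
#' @return [gene_set()] of chromosome-Y hits.
#' @export
chrY_screen <- function(table, annot, lfc_cut = 1, q_cut = 0.05) {
  hits <- select_de(table, lfc_cut, q_cut, direction = "up", name = "chrY_screen")
  chrom <- annot$chromosome[match(hits$members, toupper(annot$gene))]
  if (any(is.na(chrom))) {
    warning(sum(is.na(chrom)),
            " significant gene(s) not covered by the annotation; excluded")
  }
  if (!any(annot$chromosome == "Y", na.rm = TRUE)) {
    warning("annotation contains no chromosome-Y genes")
  }
  gene_set("chrY_screen", hits$members[!is.na(chrom) & chrom == "Y"],
           provenance = list(lfc_cut = lfc_cut, q_cut = q_cut))
}

#' Secreted-protein screen
#'
#' Restricts a candidate set to genes whose products carry a cleaved signal
#' peptide (annotation-driven secreted flag) -- the screen that recovers the
#' classic testis biomarkers AMH, INHA and INSL3.
#'
#' @param candidates A [gene_set()].
#' @param annot Annotation with columns `gene`, `secreted` (logical).
#' @return [gene_set()] of secreted candidates.
#' @export
secreted_screen <- function(candidates, annot) {
  sec <- annot$secreted[match(candidates$members, toupper(annot$gene))]
  gene_set(paste0(candidates$name, "_secreted"),
           candidates$members[!is.na(sec) & sec],
           provenance = list(source = candidates$name))
}

#' Partition candidates by functional category
#'
#' @param candidates A [gene_set()].
#' @param annot Annotation with columns `gene`, `category`; candidates
#'   without a category are labelled `"Novel"`.
#' @return Data frame with columns `category`, `count`, `genes`
#'   (comma-separated), counts summing to the candidate total.
#' @export
categorize_candidates <- function(candidates, annot) {
  cat_lab <- annot$category[match(candidates$members, toupper(annot$gene))]
  cat_lab[is.na(cat_lab) | cat_lab == ""] <- "Novel"
  split_genes <- split(candidates$members, cat_lab)
  out <- data.frame(
    category = names(split_genes),
    count = vapply(split_genes, length, integer(1)),
    genes = vapply(split_genes, paste, character(1), collapse = ","),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out[order(-out$count, out$category), , drop = FALSE]
}
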