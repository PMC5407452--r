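#' Default Carnegie/fetal stage midpoint map
#'
#' Human embryonic samples are staged with Carnegie stages (CS17--CS23) and
#' early fetal stages (F1--F3); for continuous-time modelling each stage is
#' represented by its midpoint age in days post conception (dpc). The defaults
#' span 42--73 dpc, the window covered by the atlas design.
#'
#' @return Named numeric vector mapping stage label to midpoint dpc, in
#'   developmental order.
#' @examples
#' default_stage_map()[["CS23"]]
#' @export
default_stage_map <- function() {
  c(
    CS17 = 42, CS18 = 45, CS19 = 48, CS20 = 50, CS21 = 52,
    CS22 = 54, CS23 = 56.5, F1 = 60, F2 = 66, F3 = 73
  )
}

#' Read a stage midpoint map from a two-column TSV
#'
#' @param path TSV with columns `stage` and `age_dpc`.
#' @return Named numeric vector in file order.
#' @export
read_stage_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("stage", "age_dpc") %in% names(df))) {
    stop("stage map file must have columns 'stage' and 'age_dpc'")
  }
  map <- stats::setNames(as.numeric(df$age_dpc), df$stage)
  validate_stage_map(map)
  map
}

validate_stage_map <- function(map) {
  if (is.null(names(map)) || anyDuplicated(names(map))) {
    stop("stage map must have unique stage labels")
  }
  if (any(!is.finite(map)) || any(map < 35) || any(map > 80)) {
    stop("stage midpoints must be finite and within [35, 80] dpc")
  }
  if (any(diff(map) <= 0)) {
    stop("stage midpoints must be strictly increasing in stage order")
  }
  invisible(map)
}

#' Look up midpoint ages for stage labels
#'
#' @param stage Character vector of stage labels.
#' @param stage_map Named numeric vector as from [default_stage_map()].
#' @return Numeric vector of midpoint dpc.
#' @export
stage_to_dpc <- function(stage, stage_map = default_stage_map()) {
  unknown <- setdiff(unique(stage), names(stage_map))
  if (length(unknown)) {
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  }
  unname(stage_map[stage])
}
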