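#' Load a pre-filter concentration-response dataset for reproduction runs
#'
#' Reads a published per-chemical-per-endpoint table of fitted curves (the
#' "before filtering" supplementary export of an interference screen) into
#' the layout [call_hits()] consumes. Expected columns: `chem_id`,
#' `endpoint_id` (matching [interference_endpoints()] ids), `ac50_uM`,
#' `efficacy_pct`, `curve_class`, optionally `burst_cutoff_uM`. Rows with a
#' missing AC50 or curve class are treated as unfitted (`converged = FALSE`).
#'
#' @param path CSV file path.
#' @return Fit-table `data.frame` ready for [call_hits()].
#' @export
read_interference_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("supplementary dataset not found at '", path, "'")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chem_id", "endpoint_id", "ac50_uM", "efficacy_pct", "curve_class")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dataset lacks required columns: ", paste(miss, collapse = ", "))
  d$converged <- !(is.na(d$ac50_uM) | is.na(d$curve_class))
  d
}

#' Reproduce the screen summary from a pre-filter dataset
#'
#' Applies the four active-chemical filters to a pre-filter fit table and
#' returns the Table-1-style per-endpoint summary together with the
#' cross-endpoint overlap counts.
#'
#' @param fits Fit table from [read_interference_dataset()].
#' @param library_size Number of chemicals screened (percent-active
#'   denominator).
#' @param config A [hitcall_config()].
#' @return List: `hits`, `summary`, `overlaps`.
#' @export
reproduce_screen_summary <- function(fits, library_size = length(unique(fits$chem_id)),
                                     config = hitcall_config()) {
  hits <- call_hits(fits, config = config)
  list(
    hits = hits,
    summary = summarize_actives(hits, fits, library_size = library_size),
    overlaps = overlap_analysis(hits)
  )
}
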