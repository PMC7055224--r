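#' Normalize compound-well signal to the positive-control range
#'
#' Expresses a raw instrument read as percent activity between the DMSO
#' (negative, 0%) and positive-control (100%) well medians:
#' `Activity(%) = (V_c - V_DMSO) / (V_pos - V_DMSO) * 100`.
#'
#' @param v_c Numeric vector of compound-well signals (RLU/RFU).
#' @param v_dmso Median signal of the DMSO-only wells.
#' @param v_pos Median signal of the positive-control wells.
#' @return Numeric vector of activity percentages.
#' @export
normalize_to_positive <- function(v_c, v_dmso, v_pos) {
  stopifnot(is.numeric(v_c), length(v_dmso) == 1L, length(v_pos) == 1L)
  if (!is.finite(v_pos - v_dmso) || v_pos == v_dmso) {
    stop("degenerate controls: positive-control and DMSO medians coincide")
  }
  (v_c - v_dmso) / (v_pos - v_dmso) * 100
}

#' Normalize compound-well signal to the negative (DMSO) control
#'
#' Fold-change style normalization used when positive-control responses dwarf
#' the library's: `Activity(%) = (V_c - V_DMSO) / V_DMSO * 100`.
#'
#' @inheritParams normalize_to_positive
#' @return Numeric vector of activity percentages.
#' @export
normalize_to_negative <- function(v_c, v_dmso) {
  stopifnot(is.numeric(v_c), length(v_dmso) == 1L)
  if (!is.finite(v_dmso) || v_dmso == 0) {
    stop("degenerate controls: DMSO median is zero")
  }
  (v_c - v_dmso) / v_dmso * 100
}

#' Positional pattern correction from compound-free control plates
#'
#' Subtracts, at every well position, the deviation of the DMSO-plate median
#' signal at that position from the global DMSO-plate median. Uniform control
#' plates therefore leave the input unchanged, and the correction is
#' idempotent on the control plates themselves.
#'
#' @param plate Numeric matrix of raw signals (rows x columns of one plate).
#' @param dmso_plates A numeric matrix with the same dimensions, or a list of
#'   such matrices, read from compound-free (DMSO) control plates.
#' @return Corrected numeric matrix, same dimensions as `plate`.
#' @export
pattern_correct <- function(plate, dmso_plates) {
  stopifnot(is.matrix(plate))
  if (is.matrix(dmso_plates)) dmso_plates <- list(dmso_plates)
  stopifnot(length(dmso_plates) >= 1L)
  for (d in dmso_plates) {
    if (!is.matrix(d) || !identical(dim(d), dim(plate))) {
      stop("geometry mismatch: DMSO control plates must match the assay plate dimensions")
    }
  }
  pos_med <- apply(simplify2array(dmso_plates), c(1, 2), stats::median)
  plate - (pos_med - stats::median(pos_med))
}
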