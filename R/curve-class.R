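#' Assign a signed qHTS curve class to a fitted concentration-response
#'
#' Signed decimal labels following the qHTS convention: `1.x` complete
#' response (both asymptotes supported by tested concentrations), `2.x`
#' incomplete response (upper asymptote not reached), `3` single-point
#' activity above background without a supportable curve, `4` inactive.
#' Sub-class `.1` for efficacy >= 80%, `.2` for 30% <= efficacy < 80%.
#' The sign is negative for inhibition-direction curves; classes 3 and 4
#' are reported unsigned.
#'
#' "Asymptote supported" is operationalized as at least
#' `asymptote_n_required` tested concentrations whose fitted response lies
#' within `asymptote_tol` of the asymptote (as a fraction of the fitted
#' response range). The background band is `background_k` standard
#' deviations of the lowest-concentration replicates around their mean.
#'
#' @param fit A one-row fit from [fit_hill()].
#' @param conc_uM,activity_pct The observed curve the fit was produced from.
#' @param efficacy_high,efficacy_min Sub-class thresholds in activity %
#'   (defaults 80 and 30).
#' @param asymptote_tol Fraction of the fitted range counted as "at" an
#'   asymptote (default 0.1).
#' @param asymptote_n_required Tested concentrations required at the upper
#'   asymptote for it to count as supported (default 2); the lower asymptote
#'   needs one.
#' @param background_k Width of the background band in SDs of the
#'   lowest-concentration replicates (default 3).
#' @return Numeric scalar curve class: one of
#'   `+/-1.1, +/-1.2, +/-2.1, +/-2.2, 3, 4`.
#' @export
assign_curve_class <- function(fit, conc_uM, activity_pct,
                               efficacy_high = 80, efficacy_min = 30,
                               asymptote_tol = 0.1, asymptote_n_required = 2L,
                               background_k = 3) {
  stopifnot(inherits(fit, "hill_fit") || is.data.frame(fit))
  sgn <- if (identical(fit$direction, "inhibition")) -1 else 1
  y <- if (sgn < 0) -activity_pct else activity_pct

  # background band from the lowest-concentration replicates
  low <- conc_uM == min(conc_uM)
  bg_sd <- stats::sd(y[low])
  if (!is.finite(bg_sd) || bg_sd == 0) bg_sd <- 1 # degenerate: 1 activity-% floor
  bg_center <- mean(y[low])
  band <- background_k * bg_sd
  conc_means <- tapply(y, conc_uM, mean)
  n_above <- sum(abs(conc_means - bg_center) > band)

  if (n_above == 0L) return(4) # no point above background: no response
  if (!isTRUE(fit$converged) || fit$efficacy_pct < efficacy_min) {
    return(if (n_above >= 1L) 3 else 4)
  }

  # asymptote support: fitted response at tested concentrations near top/bottom
  cs <- sort(unique(conc_uM))
  pred <- hill_response(cs, fit$ac50_uM, fit$hill_slope, fit$top_pct, fit$bottom_pct)
  rng <- abs(fit$top_pct - fit$bottom_pct)
  # the upper asymptote needs repeated support; the baseline is anchored by
  # the fit and needs only the lowest concentrations to sit near it, so very
  # potent complete responses are not mislabeled incomplete
  near_bottom <- sum(abs(pred - fit$bottom_pct) <= asymptote_tol * rng)
  near_top <- sum(abs(pred - fit$top_pct) <= asymptote_tol * rng)
  complete <- near_top >= asymptote_n_required && near_bottom >= 1L

  major <- if (complete) 1 else 2
  minor <- if (fit$efficacy_pct >= efficacy_high) 0.1 else 0.2
  sgn * (major + minor)
}

#' Fit table + curve classes in one pass
#'
#' Convenience wrapper: runs [fit_hill_table()] then appends a `curve_class`
#' column via [assign_curve_class()].
#'
#' @inheritParams fit_hill_table
#' @param ... Passed to [assign_curve_class()].
#' @return The fit table with a `curve_class` column.
#' @export
classify_curves <- function(titrations, direction = "auto", mode = "pooled", ...) {
  fits <- fit_hill_table(titrations, direction = direction, mode = mode)
  key_t <- paste(titrations$chem_id, titrations$endpoint_id, sep = "\r")
  fits$curve_class <- vapply(seq_len(nrow(fits)), function(i) {
    d <- titrations[key_t == paste(fits$chem_id[i], fits$endpoint_id[i], sep = "\r"), ]
    f <- fits[i, , drop = FALSE]
    class(f) <- c("hill_fit", "data.frame")
    assign_curve_class(f, d$conc_uM, d$activity_pct, ...)
  }, numeric(1))
  fits
}
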