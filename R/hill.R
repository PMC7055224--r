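#' Hill concentration-response function
#'
#' `response(c) = bottom + (top - bottom) / (1 + (ac50 / c)^slope)`.
#'
#' @param conc_uM Concentrations in micromolar (must be > 0).
#' @param ac50_uM Half-maximal concentration (micromolar).
#' @param hill_slope Hill coefficient (> 0).
#' @param top_pct,bottom_pct Upper and lower asymptotes in activity percent.
#' @return Numeric vector of activity percentages.
#' @export
hill_response <- function(conc_uM, ac50_uM, hill_slope, top_pct, bottom_pct) {
  bottom_pct + (top_pct - bottom_pct) / (1 + (ac50_uM / conc_uM)^hill_slope)
}

#' Fit the Hill equation to one concentration-response curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) pooled over
#' replicates, with three AC50 multi-starts (minimum, geometric-mean and
#' maximum tested concentration); the start with the best RMSE wins, ties
#' broken toward the smallest AC50. The AC50 is box-constrained to at most
#' the highest tested concentration so incomplete curves are never
#' extrapolated beyond the tested range, and the slope to `[0.3, 8]`.
#'
#' Inhibition data (signal loss, negative activity on the -100% convention)
#' are fitted on the sign-flipped response and reported as positive-efficacy
#' fits with `direction = "inhibition"`; the sign reappears in the curve
#' class.
#'
#' @param conc_uM Concentrations in micromolar, one per observation
#'   (replicates repeat the concentration).
#' @param activity_pct Observed activity percentages, same length.
#' @param direction `"activation"`, `"inhibition"`, or `"auto"` (inferred
#'   from the sign of the mean response at the two highest concentrations).
#' @param mode `"pooled"` fits all replicate points jointly; `"per_replicate"`
#'   fits each replicate separately and reports the mean AC50 as the
#'   representative value (the other parameters from the best-RMSE replicate).
#' @param replicate Optional replicate index per observation, required for
#'   `mode = "per_replicate"`.
#' @return A one-row `data.frame` of class `hill_fit`: `ac50_uM`,
#'   `efficacy_pct` (response magnitude reached at the top tested
#'   concentration, relative to the fitted baseline), `hill_slope`,
#'   `top_pct`, `bottom_pct`, `rmse`, `converged`, `direction`, `n_conc`,
#'   `max_conc_uM`.
#' @export
fit_hill <- function(conc_uM, activity_pct, direction = c("auto", "activation", "inhibition"),
                     mode = c("pooled", "per_replicate"), replicate = NULL) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(length(conc_uM) == length(activity_pct), all(conc_uM > 0))
  ok <- is.finite(conc_uM) & is.finite(activity_pct)
  conc_uM <- conc_uM[ok]; activity_pct <- activity_pct[ok]
  if (length(unique(conc_uM)) < 4L) {
    stop("fit_hill requires at least 4 distinct concentrations")
  }

  if (direction == "auto") {
    cs <- sort(unique(conc_uM), decreasing = TRUE)[1:2]
    direction <- if (mean(activity_pct[conc_uM %in% cs]) < 0) "inhibition" else "activation"
  }
  y <- if (direction == "inhibition") -activity_pct else activity_pct

  if (mode == "per_replicate") {
    stopifnot(!is.null(replicate), length(replicate) == length(conc_uM))
    fits <- lapply(split(seq_along(y), replicate), function(i) {
      .fit_hill_pooled(conc_uM[i], y[i])
    })
    fits <- fits[vapply(fits, function(f) f$converged, logical(1))]
    if (length(fits) == 0L) {
      fit <- .fit_hill_pooled(conc_uM, y) # all replicates failed; report pooled failure
    } else {
      best <- fits[[which.min(vapply(fits, function(f) f$rmse, numeric(1)))]]
      best$ac50_uM <- mean(vapply(fits, function(f) f$ac50_uM, numeric(1)))
      fit <- best
    }
  } else {
    fit <- .fit_hill_pooled(conc_uM, y)
  }

  out <- data.frame(
    ac50_uM = fit$ac50_uM, efficacy_pct = fit$efficacy_pct,
    hill_slope = fit$hill_slope, top_pct = fit$top_pct, bottom_pct = fit$bottom_pct,
    rmse = fit$rmse, converged = fit$converged, direction = direction,
    n_conc = length(unique(conc_uM)), max_conc_uM = max(conc_uM),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hill_fit", class(out))
  out
}

# Core bounded LM fit on an (already direction-normalized) increasing response.
.fit_hill_pooled <- function(conc, y) {
  cmax <- max(conc); cmin <- min(conc)
  rng <- diff(range(y))
  fail <- list(ac50_uM = NA_real_, efficacy_pct = 0, hill_slope = NA_real_,
               top_pct = NA_real_, bottom_pct = NA_real_,
               rmse = stats::sd(y), converged = FALSE)
  if (rng < .Machine$double.eps^0.5) return(fail) # perfectly flat input

  lower <- c(ac50 = cmin / 100, slope = 0.3, top = min(y) - rng, bottom = min(y) - rng)
  upper <- c(ac50 = cmax,       slope = 8,   top = max(y) + rng, bottom = max(y) + rng)
  starts <- c(cmin, exp(mean(log(range(conc)))), cmax)

  best <- NULL
  for (a0 in starts) {
    st <- list(ac50 = a0, slope = 1,
               top = max(y), bottom = min(y))
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (ac50 / conc)^slope),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(f)) next
    rmse <- sqrt(mean(stats::resid(f)^2))
    cf <- stats::coef(f)
    if (is.null(best) || rmse < best$rmse - 1e-12 ||
        (abs(rmse - best$rmse) <= 1e-12 && cf[["ac50"]] < best$ac50_uM)) {
      best <- list(ac50_uM = cf[["ac50"]], hill_slope = cf[["slope"]],
                   top_pct = cf[["top"]], bottom_pct = cf[["bottom"]], rmse = rmse)
    }
  }
  if (is.null(best)) return(fail)
  # response magnitude actually reached within the tested range
  reached <- hill_response(cmax, best$ac50_uM, best$hill_slope, best$top_pct, best$bottom_pct)
  best$efficacy_pct <- abs(reached - best$bottom_pct)
  best$converged <- TRUE
  best
}

#' Fit Hill curves for every chemical x endpoint in a long titration table
#'
#' @param titrations Long-format `data.frame` with columns `chem_id`,
#'   `endpoint_id`, `conc_uM`, `replicate`, `activity_pct`.
#' @param direction Passed to [fit_hill()]; `"auto"` by default.
#' @param mode Passed to [fit_hill()].
#' @return A `data.frame` with one row per `chem_id` x `endpoint_id` holding
#'   the [fit_hill()] fields.
#' @export
fit_hill_table <- function(titrations, direction = "auto", mode = "pooled") {
  need <- c("chem_id", "endpoint_id", "conc_uM", "replicate", "activity_pct")
  stopifnot(all(need %in% names(titrations)))
  key <- interaction(titrations$chem_id, titrations$endpoint_id, drop = TRUE)
  rows <- lapply(split(titrations, key), function(d) {
    f <- fit_hill(d$conc_uM, d$activity_pct, direction = direction,
                  mode = mode, replicate = d$replicate)
    cbind(data.frame(chem_id = d$chem_id[1], endpoint_id = d$endpoint_id[1],
                     stringsAsFactors = FALSE), f)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$endpoint_id, out$chem_id), , drop = FALSE]
}
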