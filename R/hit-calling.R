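#' Canonical interference assay endpoints
#'
#' The 13 endpoints of the interference screen: one biochemical (cell-free)
#' luciferase-inhibition readout, plus autofluorescence readouts for every
#' combination of cell line (HepG2, HEK-293), culture condition (cell-based,
#' cell-free medium) and detection channel (blue, green, red).
#'
#' @return A `data.frame` with columns `endpoint_id`, `technology`,
#'   `cell_line`, `condition`, `channel`, `direction`.
#' @export
interference_endpoints <- function() {
  af <- expand.grid(cell_line = c("hepg2", "hek293"),
                    condition = c("cell", "free"),
                    channel = c("blue", "green", "red"),
                    stringsAsFactors = FALSE)
  af <- af[order(af$channel, af$cell_line, af$condition), ]
  out <- rbind(
    data.frame(endpoint_id = "luciferase", technology = "luciferase",
               cell_line = "none", condition = "biochemical", channel = "none",
               direction = "inhibition", stringsAsFactors = FALSE),
    data.frame(endpoint_id = paste(af$cell_line, af$condition, af$channel, sep = "_"),
               technology = "autofluorescence", cell_line = af$cell_line,
               condition = af$condition, channel = af$channel,
               direction = "activation", stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Default hit-calling configuration
#'
#' Thresholds of the four-filter active-chemical identification: potency
#' (AC50/IC50 strictly below `potency_max_uM`), curve class (1.x/2.x for
#' activation, -1.x/-2.x for inhibition), efficacy (strictly above
#' `efficacy_min_pct`), and — for autofluorescence endpoints only — the
#' cytotoxicity burst cutoff (AC50 strictly below the per-chemical cutoff,
#' falling back to `burst_default_uM` when none is supplied).
#'
#' @param potency_max_uM Potency filter bound (default 150).
#' @param efficacy_min_pct Efficacy filter bound (default 30).
#' @param burst_default_uM Fallback burst cutoff for autofluorescence records
#'   lacking a per-chemical value (default 150, i.e. non-binding).
#' @param any_sample_active If a chemical was screened as multiple samples,
#'   call it active when any sample passes (default `TRUE`).
#' @return A list of class `hitcall_config`.
#' @export
hitcall_config <- function(potency_max_uM = 150, efficacy_min_pct = 30,
                           burst_default_uM = 150, any_sample_active = TRUE) {
  stopifnot(potency_max_uM > 0, efficacy_min_pct > 0, burst_default_uM > 0)
  structure(list(
    potency_max_uM = potency_max_uM,
    efficacy_min_pct = efficacy_min_pct,
    allowed_classes_activation = c(1.1, 1.2, 2.1, 2.2),
    allowed_classes_inhibition = c(-1.1, -1.2, -2.1, -2.2),
    burst_default_uM = burst_default_uM,
    any_sample_active = any_sample_active
  ), class = "hitcall_config")
}

#' Apply the four active-chemical filters to fitted curves
#'
#' A chemical x endpoint record is active iff every filter passes:
#' AC50 below the potency bound, curve class in the direction's allowed set,
#' efficacy above the minimum, and (autofluorescence only) AC50 below the
#' burst cutoff. Failed filters are enumerated in `reasons`; records without
#' a convergent fit carry `no_fit`.
#'
#' @param fits Fit table from [classify_curves()] (columns `chem_id`,
#'   `endpoint_id`, `ac50_uM`, `efficacy_pct`, `curve_class`, `converged`),
#'   optionally with a per-chemical `burst_cutoff_uM` column.
#' @param endpoints Endpoint metadata, default [interference_endpoints()].
#' @param config A [hitcall_config()].
#' @return `data.frame` with `chem_id`, `endpoint_id`, `active` (logical) and
#'   `reasons` (comma-joined subset of
#'   `potency_fail, class_fail, efficacy_fail, burst_fail, no_fit`;
#'   empty string iff active).
#' @export
call_hits <- function(fits, endpoints = interference_endpoints(), config = hitcall_config()) {
  stopifnot(inherits(config, "hitcall_config"))
  need <- c("chem_id", "endpoint_id", "ac50_uM", "efficacy_pct", "curve_class", "converged")
  stopifnot(all(need %in% names(fits)))
  unknown <- setdiff(unique(fits$endpoint_id), endpoints$endpoint_id)
  if (length(unknown)) stop("unknown endpoint id(s): ", paste(unknown, collapse = ", "))
  tech <- endpoints$technology[match(fits$endpoint_id, endpoints$endpoint_id)]
  dir <- endpoints$direction[match(fits$endpoint_id, endpoints$endpoint_id)]

  burst <- if ("burst_cutoff_uM" %in% names(fits)) fits$burst_cutoff_uM else rep(NA_real_, nrow(fits))
  burst[is.na(burst)] <- config$burst_default_uM

  reasons <- vector("list", nrow(fits))
  for (i in seq_len(nrow(fits))) {
    r <- character(0)
    if (!isTRUE(fits$converged[i]) || is.na(fits$ac50_uM[i])) {
      r <- "no_fit"
    } else {
      allowed <- if (dir[i] == "inhibition") config$allowed_classes_inhibition else config$allowed_classes_activation
      if (!(fits$ac50_uM[i] < config$potency_max_uM)) r <- c(r, "potency_fail")
      if (!any(abs(fits$curve_class[i] - allowed) < 1e-9)) r <- c(r, "class_fail")
      if (!(fits$efficacy_pct[i] > config$efficacy_min_pct)) r <- c(r, "efficacy_fail")
      if (tech[i] == "autofluorescence" && !(fits$ac50_uM[i] < burst[i])) r <- c(r, "burst_fail")
    }
    reasons[[i]] <- r
  }
  out <- data.frame(
    chem_id = fits$chem_id, endpoint_id = fits$endpoint_id,
    active = lengths(reasons) == 0L,
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  if (config$any_sample_active && anyDuplicated(paste(out$chem_id, out$endpoint_id))) {
    # collapse multi-sample chemicals: active if any sample passes
    key <- paste(out$chem_id, out$endpoint_id, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(out)), key), function(i) {
      act <- i[out$active[i]]
      if (length(act)) act[1] else i[1]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-endpoint active-chemical summary
#'
#' One row per endpoint: number of actives, percent of the screened library,
#' and mean and sample SD of AC50/IC50 among actives.
#'
#' @param hits Hit-call table from [call_hits()].
#' @param fits The fit table the hits were derived from.
#' @param library_size Number of chemicals screened (denominator of
#'   `pct_active`); defaults to the number of distinct `chem_id`s in `fits`.
#' @return `data.frame` with `endpoint_id`, `n_active`, `pct_active`,
#'   `mean_ac50_uM`, `sd_ac50_uM` (the last two `NA` when no actives).
#' @export
summarize_actives <- function(hits, fits, library_size = length(unique(fits$chem_id))) {
  eps <- unique(hits$endpoint_id)
  rows <- lapply(eps, function(e) {
    act <- hits$chem_id[hits$endpoint_id == e & hits$active]
    ac50 <- fits$ac50_uM[fits$endpoint_id == e & fits$chem_id %in% act]
    data.frame(
      endpoint_id = e, n_active = length(act),
      pct_active = 100 * length(act) / library_size,
      mean_ac50_uM = if (length(ac50)) mean(ac50) else NA_real_,
      sd_ac50_uM = if (length(ac50) > 1) stats::sd(ac50) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$endpoint_id), , drop = FALSE]
}

#' Cross-endpoint overlap analysis of active chemicals
#'
#' Computes the membership overlaps shown in the screen's Venn analyses:
#' per-channel 4-set overlaps across the culture conditions, the 3-set
#' cross-channel overlap (a chemical belongs to a channel when active under
#' at least one of its conditions), the autofluorescence union, the
#' chemicals active in every autofluorescence endpoint, and the intersection
#' of luciferase actives with the autofluorescence union.
#'
#' @param hits Hit-call table from [call_hits()] covering the 13 endpoints.
#' @param endpoints Endpoint metadata, default [interference_endpoints()].
#' @return A list: `per_channel` (named list of 4-set region counts plus
#'   `all_conditions` count and `pct_all_conditions`), `cross_channel`
#'   (3-set region counts), `autofluorescence_union`,
#'   `all_conditions_all_channels` (count and ids),
#'   `luciferase_x_autofluorescence`.
#' @export
overlap_analysis <- function(hits, endpoints = interference_endpoints()) {
  af <- endpoints[endpoints$technology == "autofluorescence", ]
  actives_of <- function(ep) sort(unique(hits$chem_id[hits$endpoint_id == ep & hits$active]))

  venn_regions <- function(sets) {
    # disjoint region counts for 3- or 4-set overlaps, keyed by membership pattern
    ids <- sort(unique(unlist(sets)))
    if (!length(ids)) return(list())
    memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(ids))
    pat <- apply(memb, 1, function(m) paste(names(sets)[m], collapse = "&"))
    tb <- table(pat)
    stats::setNames(as.list(as.integer(tb)), names(tb))
  }

  per_channel <- list()
  for (ch in c("blue", "green", "red")) {
    eps <- af$endpoint_id[af$channel == ch]
    sets <- stats::setNames(lapply(eps, actives_of), eps)
    u <- sort(unique(unlist(sets)))
    inter <- Reduce(intersect, sets)
    per_channel[[ch]] <- list(
      regions = venn_regions(sets),
      union = length(u),
      all_conditions = length(inter),
      pct_all_conditions = if (length(u)) 100 * length(inter) / length(u) else NA_real_
    )
  }

  chan_sets <- lapply(c(blue = "blue", green = "green", red = "red"), function(ch) {
    sort(unique(unlist(lapply(af$endpoint_id[af$channel == ch], actives_of))))
  })
  af_union <- sort(unique(unlist(chan_sets)))
  all12 <- Reduce(intersect, lapply(af$endpoint_id, actives_of))
  luc <- actives_of("luciferase")

  list(
    per_channel = per_channel,
    cross_channel = list(regions = venn_regions(chan_sets),
                         n_per_channel = lengths(chan_sets)),
    autofluorescence_union = length(af_union),
    all_conditions_all_channels = list(
      n = length(all12), ids = all12,
      pct_of_union = if (length(af_union)) 100 * length(all12) / length(af_union) else NA_real_
    ),
    luciferase_x_autofluorescence = length(intersect(luc, af_union))
  )
}
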