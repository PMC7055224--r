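#' Packaged scaffold pool for the synthetic chemical library
#'
#' A fixed list of ~40 scaffold SMILES: aromatic-rich "interferent-like"
#' structures (every entry carries at least three aromatic rings — fused
#' polycyclics, azo dyes, xanthene- and triphenyl-type cores) and aliphatic
#' "decoy" structures with no aromatic ring. The synthetic library plants
#' its structure-activity link by drawing truth-actives from the
#' interferent pool and truth-inactives from the decoy pool.
#'
#' @return `data.frame` with `name`, `pool` (`interferent`/`decoy`),
#'   `smiles`.
#' @export
scaffold_pool <- function() {
  path <- system.file("extdata", "scaffold_pool.csv", package = "qhtscreen",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Alkyl/ether side chains prepended to a scaffold SMILES to diversify the
# library; the empty string leaves the bare scaffold.
.decorations <- c("", "C", "CC", "CCC", "CCCC", "CCCCC", "OC", "OCC", "CC(C)", "COC")

#' Generate a synthetic chemical library with planted activity labels
#'
#' Draws `round(n_chemicals * active_fraction)` truth-active chemicals from
#' the aromatic interferent scaffold pool and the remainder from the
#' aliphatic decoy pool, decorating each scaffold with a small side chain so
#' the library spans distinct structures. Deterministic under `seed`.
#'
#' @param n_chemicals Library size.
#' @param active_fraction Planted fraction of truth-actives (default 0.1).
#' @param pool Scaffold pool `data.frame` (default [scaffold_pool()]).
#' @param seed Integer seed.
#' @return `data.frame` with `chem_id`, `casrn` (synthetic registry-style
#'   string), `smiles`, `truth_active` (logical), `scaffold`.
#' @export
generate_library <- function(n_chemicals, active_fraction = 0.1,
                             pool = scaffold_pool(), seed = 1L) {
  stopifnot(n_chemicals >= 1, active_fraction >= 0, active_fraction <= 1)
  stopifnot(all(c("name", "pool", "smiles") %in% names(pool)), nrow(pool) > 0)
  bad <- !nzchar(trimws(pool$smiles))
  if (any(bad)) stop("invalid scaffold SMILES for pool entry: ",
                     paste(pool$name[bad], collapse = ", "))
  arom <- pool[pool$pool == "interferent", ]
  alip <- pool[pool$pool == "decoy", ]
  stopifnot(nrow(arom) > 0, nrow(alip) > 0)

  n_active <- round(n_chemicals * active_fraction)
  set.seed(derive_seed(seed, "generate_library"))
  lab <- c(rep(TRUE, n_active), rep(FALSE, n_chemicals - n_active))
  src <- ifelse(lab, sample(nrow(arom), n_chemicals, replace = TRUE),
                sample(nrow(alip), n_chemicals, replace = TRUE))
  deco <- sample(.decorations, n_chemicals, replace = TRUE)
  scaf <- ifelse(lab, arom$name[src], alip$name[src])
  smi <- paste0(deco, ifelse(lab, arom$smiles[src], alip$smiles[src]))
  data.frame(
    chem_id = sprintf("chem_%04d", seq_len(n_chemicals)),
    casrn = sprintf("SYN-%06d-%d", seq_len(n_chemicals), seq_len(n_chemicals) %% 10),
    smiles = smi, truth_active = lab, scaffold = scaf,
    stringsAsFactors = FALSE
  )
}

#' Titration design for a simulated concentration-response
#'
#' Log-spaced concentration series with replicates and Gaussian noise on
#' normalized activity. The default designs mirror the screening formats:
#' 15 concentrations from 1.5 nM to 115 µM in triplicate for the luciferase
#' screen, 5 concentrations from 29 nM to 92 µM for autofluorescence.
#'
#' @param n_concentrations Number of titration points.
#' @param conc_min_uM,conc_max_uM Concentration range in micromolar.
#' @param replicates Replicates per point (>= 1).
#' @param noise_sd Gaussian noise SD in activity-% units (default 5).
#' @return List of class `titration_design` with `concentrations_uM`
#'   (strictly increasing, log-spaced).
#' @export
titration_design <- function(n_concentrations = 15L, conc_min_uM = 0.0015,
                             conc_max_uM = 115, replicates = 3L, noise_sd = 5) {
  stopifnot(n_concentrations >= 2, conc_min_uM > 0, conc_max_uM > conc_min_uM,
            replicates >= 1, noise_sd >= 0)
  structure(list(
    concentrations_uM = exp(seq(log(conc_min_uM), log(conc_max_uM),
                                length.out = n_concentrations)),
    replicates = as.integer(replicates), noise_sd = noise_sd
  ), class = "titration_design")
}

#' @rdname titration_design
#' @export
luciferase_design <- function(noise_sd = 5) {
  titration_design(15L, 0.0015, 115, 3L, noise_sd)
}

#' @rdname titration_design
#' @export
autofluorescence_design <- function(noise_sd = 5) {
  titration_design(5L, 0.029, 92, 3L, noise_sd)
}

#' Simulate one concentration-response titration from Hill-curve truth
#'
#' `activity(c) = bottom + (top - bottom)/(1 + (ac50/c)^slope) + N(0, noise_sd)`
#' per replicate; `noise_sd = 0` returns the exact curve.
#'
#' @param ac50_uM,hill_slope,top_pct,bottom_pct True Hill parameters (an
#'   all-zero response, e.g. `top = bottom = 0`, encodes a true inactive).
#' @param design A [titration_design()].
#' @param seed Integer seed.
#' @return `data.frame` with `conc_uM`, `replicate`, `activity_pct`.
#' @export
simulate_titration <- function(ac50_uM, hill_slope, top_pct, bottom_pct,
                               design = luciferase_design(), seed = 1L) {
  stopifnot(inherits(design, "titration_design"))
  cs <- design$concentrations_uM
  truth <- hill_response(cs, ac50_uM, hill_slope, top_pct, bottom_pct)
  set.seed(derive_seed(seed, "simulate_titration"))
  out <- do.call(rbind, lapply(seq_len(design$replicates), function(r) {
    data.frame(conc_uM = cs, replicate = r,
               activity_pct = truth + stats::rnorm(length(cs), 0, design$noise_sd))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a raw-signal plate with control wells
#'
#' Maps programmed compound activities to raw instrument units through a
#' recorded affine transform (`signal = offset + gain * activity/100 `,
#' defaults gain 1000, offset 5000 RLU) and adds DMSO wells (0% activity)
#' and positive-control wells (100%). With zero noise,
#' [normalize_to_positive()] on the control medians recovers the programmed
#' activities exactly.
#'
#' @param activity_pct Named numeric vector of programmed compound-well
#'   activities (names = chem ids).
#' @param n_dmso,n_pos Control well counts (>= 8 each).
#' @param gain,offset Affine transform to instrument units.
#' @param noise_sd_pct Well noise SD in activity-% units before the
#'   transform (default 0).
#' @param seed Integer seed.
#' @return List: `wells` (`data.frame` well_role, chem_id, signal),
#'   `gain`, `offset`.
#' @export
simulate_plate <- function(activity_pct, n_dmso = 32L, n_pos = 32L,
                           gain = 1000, offset = 5000, noise_sd_pct = 0, seed = 1L) {
  if (n_dmso < 8L || n_pos < 8L) {
    stop("configuration error: at least 8 DMSO and 8 positive-control wells are required")
  }
  ids <- if (!is.null(names(activity_pct))) names(activity_pct) else
    sprintf("chem_%04d", seq_along(activity_pct))
  act <- c(activity_pct, rep(0, n_dmso), rep(100, n_pos))
  role <- c(rep("compound", length(activity_pct)), rep("dmso", n_dmso), rep("pos", n_pos))
  set.seed(derive_seed(seed, "simulate_plate"))
  act <- act + stats::rnorm(length(act), 0, noise_sd_pct)
  list(
    wells = data.frame(
      well_role = role, chem_id = c(ids, rep(NA_character_, n_dmso + n_pos)),
      signal = offset + gain * act / 100, stringsAsFactors = FALSE
    ),
    gain = gain, offset = offset
  )
}

#' Simulate the full interference screen for a synthetic library
#'
#' Plants per-endpoint ground truth and generates every titration: each
#' truth-active chemical inhibits luciferase with probability `p_luciferase`
#' and autofluoresces in each channel with probability `p_channel`
#' (guaranteed at least one technology); within an active channel, each of
#' the four culture conditions is active with probability `p_condition`, so
#' the cross-endpoint overlap structure is non-trivial. Potencies are drawn
#' log-normally around 20 µM, luciferase responses run to -100% (signal
#' loss), autofluorescence responses to 60-120%. Truth-inactive records are
#' flat noise.
#'
#' @param library Library from [generate_library()].
#' @param p_luciferase,p_channel,p_condition Planting probabilities
#'   (defaults 0.5, 0.5, 0.8).
#' @param luc_design,af_design Titration designs (defaults
#'   [luciferase_design()], [autofluorescence_design()]).
#' @param seed Integer seed.
#' @return List: `titrations` (long `data.frame`: chem_id, endpoint_id,
#'   conc_uM, replicate, activity_pct), `truth` (`data.frame`: chem_id,
#'   endpoint_id, truth_active, ac50_uM, hill_slope, top_pct, bottom_pct).
#' @export
simulate_screen <- function(library, p_luciferase = 0.5, p_channel = 0.5,
                            p_condition = 0.8,
                            luc_design = luciferase_design(),
                            af_design = autofluorescence_design(), seed = 1L) {
  eps <- interference_endpoints()
  set.seed(derive_seed(seed, "simulate_screen_truth"))
  truth <- list(); titr <- list()
  for (i in seq_len(nrow(library))) {
    cid <- library$chem_id[i]
    ep_active <- stats::setNames(rep(FALSE, nrow(eps)), eps$endpoint_id)
    if (library$truth_active[i]) {
      luc_on <- stats::runif(1) < p_luciferase
      chan_on <- stats::runif(3) < p_channel
      names(chan_on) <- c("blue", "green", "red")
      if (!luc_on && !any(chan_on)) luc_on <- TRUE # every active hits something
      ep_active["luciferase"] <- luc_on
      for (ch in names(chan_on)[chan_on]) {
        eids <- eps$endpoint_id[eps$channel == ch]
        on <- stats::runif(length(eids)) < p_condition
        if (!any(on)) on[sample(length(eids), 1)] <- TRUE
        ep_active[eids[on]] <- TRUE
      }
    }
    ac50 <- exp(stats::rnorm(nrow(eps), log(20), 0.5))
    slope <- stats::runif(nrow(eps), 1, 3)
    af_top <- stats::runif(nrow(eps), 60, 120)
    for (j in seq_len(nrow(eps))) {
      eid <- eps$endpoint_id[j]
      is_luc <- eps$technology[j] == "luciferase"
      act <- ep_active[[eid]]
      top <- if (!act) 0 else if (is_luc) -100 else af_top[j]
      truth[[length(truth) + 1L]] <- data.frame(
        chem_id = cid, endpoint_id = eid, truth_active = act,
        ac50_uM = if (act) ac50[j] else NA_real_,
        hill_slope = if (act) slope[j] else NA_real_,
        top_pct = top, bottom_pct = 0, stringsAsFactors = FALSE
      )
      des <- if (is_luc) luc_design else af_design
      tt <- simulate_titration(
        ac50_uM = if (act) ac50[j] else 1, hill_slope = if (act) slope[j] else 1,
        top_pct = top, bottom_pct = 0, design = des,
        seed = derive_seed(seed, paste("titr", cid, eid))
      )
      tt$chem_id <- cid; tt$endpoint_id <- eid
      titr[[length(titr) + 1L]] <- tt
    }
  }
  titrations <- do.call(rbind, titr)
  titrations <- titrations[, c("chem_id", "endpoint_id", "conc_uM", "replicate", "activity_pct")]
  rownames(titrations) <- NULL
  list(titrations = titrations, truth = do.call(rbind, truth))
}

#' Generate a descriptor matrix with planted column roles
#'
#' Test fixture for the descriptor-selection and QSAR stages: binary class
#' labels plus columns with known roles — informative (class means differ by
#' `effect_size` standard deviations), pure noise, zero variance, degenerate
#' (one value covering ~95% of rows), and correlated blocks (latent factor
#' plus small independent noise; within-block |rho| > 0.9 by construction).
#'
#' @param n_chemicals Rows.
#' @param n_informative,n_noise,n_null_variance,n_degenerate Column counts
#'   per role.
#' @param n_correlated_blocks,block_size Redundant-block structure.
#' @param effect_size Standardized class separation of informative columns.
#' @param active_fraction Positive-class share (default 0.15, so that
#'   undersampling to a 70/30 modeling set is non-trivial).
#' @param seed Integer seed.
#' @return List: `matrix` (rownames chem ids, colnames role-tagged),
#'   `labels` (named logical), `roles` (named character per column).
#' @export
generate_descriptor_matrix <- function(n_chemicals, n_informative = 5L,
                                       n_noise = 10L, n_null_variance = 2L,
                                       n_degenerate = 2L, n_correlated_blocks = 2L,
                                       block_size = 5L, effect_size = 1,
                                       active_fraction = 0.15, seed = 1L) {
  stopifnot(n_chemicals >= 4, active_fraction > 0, active_fraction < 1)
  set.seed(derive_seed(seed, "generate_descriptor_matrix"))
  n_act <- round(n_chemicals * active_fraction)
  lab <- sample(c(rep(TRUE, n_act), rep(FALSE, n_chemicals - n_act)))
  cols <- list(); roles <- character(0)
  addcol <- function(name, role, x) {
    cols[[name]] <<- x
    roles[name] <<- role
  }
  for (k in seq_len(n_informative)) {
    addcol(sprintf("inf_%02d", k), "informative",
           stats::rnorm(n_chemicals, ifelse(lab, effect_size, 0), 1))
  }
  for (k in seq_len(n_noise)) {
    addcol(sprintf("noise_%02d", k), "noise", stats::rnorm(n_chemicals))
  }
  for (k in seq_len(n_null_variance)) {
    addcol(sprintf("null_%02d", k), "null_variance", rep(k, n_chemicals))
  }
  for (k in seq_len(n_degenerate)) {
    x <- rep(0, n_chemicals)
    n_off <- max(1L, floor(0.05 * n_chemicals))
    x[sample(n_chemicals, n_off)] <- stats::rnorm(n_off)
    addcol(sprintf("degen_%02d", k), "degenerate", x)
  }
  for (b in seq_len(n_correlated_blocks)) {
    z <- stats::rnorm(n_chemicals)
    for (k in seq_len(block_size)) {
      addcol(sprintf("block%d_%02d", b, k), sprintf("correlated_block_%d", b),
             z + stats::rnorm(n_chemicals, 0, 0.2))
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- sprintf("chem_%04d", seq_len(n_chemicals))
  list(matrix = mat, labels = stats::setNames(lab, rownames(mat)), roles = roles)
}
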