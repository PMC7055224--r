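#' Default end-to-end pipeline configuration
#'
#' One nested list with a section per stage; all thresholds default to the
#' screen's stated settings (potency 150 µM, efficacy 30%, correlation 0.9,
#' 70/30 undersampling, 10 repetitions, 10 CV folds, 15 x 15 SOM). The
#' global `seed` fans out to per-stage seeds via [derive_seed()].
#'
#' @param n_chemicals Synthetic library size (default 600).
#' @param seed Global seed.
#' @param endpoints Endpoint ids to simulate and analyze (default all 13).
#' @param qsar_rules Named list of endpoint-rule specifications for the QSAR
#'   stage, see [assemble_endpoint_dataset()].
#' @param ... Overrides merged over the defaults (named sub-lists).
#' @return Nested configuration list.
#' @export
default_config <- function(n_chemicals = 600L, seed = 1L,
                           endpoints = interference_endpoints()$endpoint_id,
                           qsar_rules = list(
                             luciferase = list(rule = "luciferase"),
                             blue = list(rule = "channel_any_condition", channel = "blue")
                           ), ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, curves = TRUE, hitcall = TRUE,
                  chemistry = TRUE, chem_space = TRUE, qsar = TRUE),
    simulate = list(n_chemicals = as.integer(n_chemicals), active_fraction = 0.1,
                    noise_sd = 5, p_luciferase = 0.5, p_channel = 0.5,
                    p_condition = 0.8),
    endpoints = endpoints,
    hitcall = list(potency_max_uM = 150, efficacy_min_pct = 30,
                   burst_default_uM = 150),
    selection = list(corr_threshold = 0.9, degeneracy_threshold = 0.9),
    som = list(grid_rows = 15L, grid_cols = 15L, epochs = 30L),
    qsar = list(learner = "rf", repetitions = 10L, inactive_ratio = 0.7,
                cv_folds = 10L, test_fraction = 0.15, rules = qsar_rules)
  )
  utils::modifyList(cfg, list(...))
}

.write_csv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' Run the full synthetic pipeline and write a run directory
#'
#' Executes simulate -> fit/classify curves -> call hits -> curate ->
#' descriptors -> select -> SOM/Ward -> QSAR ensembles, writing every stage
#' output (CSV/JSON) plus the serialized configuration into `out_dir`.
#' Deterministic: two runs with the same configuration produce byte-identical
#' text outputs.
#'
#' @param config Configuration from [default_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  stopifnot(!missing(out_dir))
  st <- config$stages
  if (is.null(st)) st <- list()
  on_ <- function(nm) !isFALSE(st[[nm]])
  # stage dependency validation before any work
  if (on_("qsar") && (!on_("hitcall") || !on_("chemistry"))) {
    stop("configuration error: the QSAR stage requires hit calling and ",
         "descriptor computation to be enabled (labels and features missing)")
  }
  if ((on_("hitcall") && !on_("curves")) || (on_("curves") && !on_("simulate"))) {
    stop("configuration error: downstream stages require their upstream inputs")
  }
  if (on_("chem_space") && (!on_("chemistry") || !on_("hitcall"))) {
    stop("configuration error: chemical-space analysis requires descriptors and hit calls")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  writeLines(yaml::as.yaml(config), file.path(out_dir, "config.yaml"))

  # stage: simulate
  lib <- generate_library(config$simulate$n_chemicals,
                          active_fraction = config$simulate$active_fraction,
                          seed = derive_seed(seed, "stage_library"))
  eps <- interference_endpoints()
  eps <- eps[eps$endpoint_id %in% config$endpoints, , drop = FALSE]
  scr <- simulate_screen(
    lib, p_luciferase = config$simulate$p_luciferase,
    p_channel = config$simulate$p_channel, p_condition = config$simulate$p_condition,
    luc_design = luciferase_design(config$simulate$noise_sd),
    af_design = autofluorescence_design(config$simulate$noise_sd),
    seed = derive_seed(seed, "stage_screen")
  )
  scr$titrations <- scr$titrations[scr$titrations$endpoint_id %in% eps$endpoint_id, ]
  scr$truth <- scr$truth[scr$truth$endpoint_id %in% eps$endpoint_id, ]
  .write_csv(lib, file.path(out_dir, "library.csv"))
  .write_csv(scr$truth, file.path(out_dir, "truth.csv"))

  # stage: curve fitting + classification
  fits <- hits <- summ <- overlaps <- cur <- desc <- sel <- som <- enr <- NULL
  ensembles <- list()
  if (!on_("curves")) {
    return(invisible(list(library = lib, screen = scr, out_dir = out_dir)))
  }
  fits <- classify_curves(scr$titrations, direction = "auto")
  .write_csv(fits, file.path(out_dir, "fits.csv"))

  # stage: hit calling
  if (on_("hitcall")) {
  hc_cfg <- hitcall_config(potency_max_uM = config$hitcall$potency_max_uM,
                           efficacy_min_pct = config$hitcall$efficacy_min_pct,
                           burst_default_uM = config$hitcall$burst_default_uM)
  hits <- call_hits(fits, endpoints = eps, config = hc_cfg)
  summ <- summarize_actives(hits, fits, library_size = nrow(lib))
  .write_csv(hits, file.path(out_dir, "hitcalls.csv"))
  .write_csv(summ, file.path(out_dir, "summary.csv"))
  overlaps <- if (all(interference_endpoints()$endpoint_id %in% eps$endpoint_id)) {
    ov <- overlap_analysis(hits)
    jsonlite::write_json(ov, file.path(out_dir, "overlaps.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ov
  } else NULL
  }

  # stage: curation + descriptors + selection
  if (on_("chemistry")) {
  cur <- curate_structure(lib$smiles, chem_id = lib$chem_id)
  .write_csv(cur, file.path(out_dir, "curated.csv"))
  desc <- compute_descriptors(cur)
  sel <- select_descriptors(desc$matrix,
                            corr_threshold = config$selection$corr_threshold,
                            degeneracy_threshold = config$selection$degeneracy_threshold,
                            seed = derive_seed(seed, "stage_select"))
  .write_csv(data.frame(chem_id = rownames(sel$matrix), sel$matrix,
                        check.names = FALSE),
             file.path(out_dir, "descriptors_selected.csv"))
  .write_csv(sel$report, file.path(out_dir, "selection_report.csv"))
  }

  # stage: chemical space
  if (on_("chem_space")) {
  som <- train_som(sel$matrix, grid_rows = config$som$grid_rows,
                   grid_cols = config$som$grid_cols, epochs = config$som$epochs,
                   seed = derive_seed(seed, "stage_som"))
  first_ep <- eps$endpoint_id[1]
  enr <- som_enrichment(som, hits$chem_id[hits$active & hits$endpoint_id == first_ep])
  .write_csv(enr$nodes, file.path(out_dir, "som_enrichment.csv"))
  act_union <- unique(hits$chem_id[hits$active])
  act_ids <- intersect(rownames(sel$matrix), act_union)
  if (length(act_ids) >= 2) {
    wc <- ward_cluster(sel$matrix[act_ids, , drop = FALSE])
    writeLines(wc$newick, file.path(out_dir, "actives_dendrogram.nwk"))
  }
  }

  # stage: QSAR ensembles
  if (on_("qsar")) {
  perf_rows <- list()
  for (nm in names(config$qsar$rules)) {
    rl <- config$qsar$rules[[nm]]
    ds <- assemble_endpoint_dataset(hits, sel$matrix, rule = rl$rule,
                                    channel = rl$channel, endpoint_id = rl$endpoint_id,
                                    endpoints = eps)
    if (sum(ds$labels) < 10L || sum(!ds$labels) < 10L) {
      warning("QSAR rule '", nm, "' skipped: too few chemicals per class")
      next
    }
    spec <- ensemble_spec(learner = config$qsar$learner,
                          repetitions = config$qsar$repetitions,
                          inactive_ratio = config$qsar$inactive_ratio,
                          cv_folds = config$qsar$cv_folds,
                          test_fraction = config$qsar$test_fraction,
                          seed = derive_seed(seed, paste0("stage_qsar_", nm)))
    ens <- build_ensemble(ds$X, ds$labels, spec)
    ensembles[[nm]] <- ens
    p <- ens$performance; p$model <- nm
    perf_rows[[nm]] <- p
  }
  if (length(perf_rows)) {
    .write_csv(do.call(rbind, perf_rows), file.path(out_dir, "qsar_performance.csv"))
  }
  }

  invisible(list(library = lib, screen = scr, fits = fits, hits = hits,
                 summary = summ, overlaps = overlaps, curated = cur,
                 selection = sel, som = som, enrichment = enr,
                 ensembles = ensembles, out_dir = out_dir))
}

#' Render a plain-text report for a pipeline run directory
#'
#' Re-parses the stage output files and assembles a human-readable summary:
#' per-endpoint active counts and potency statistics, overlap counts, the
#' top enriched SOM nodes, and the QSAR performance table. Missing stage
#' outputs are reported as explicit gaps rather than errors.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed invisibly usable
#'   via `writeLines`).
#' @export
report_run <- function(run_dir) {
  lines <- c("Interference screen report", paste("run directory:", run_dir), "")
  f <- function(...) file.path(run_dir, ...)
  if (file.exists(f("summary.csv"))) {
    s <- utils::read.csv(f("summary.csv"))
    lines <- c(lines, "Per-endpoint active summary:",
               utils::capture.output(print(s, row.names = FALSE)), "")
  } else lines <- c(lines, "[missing stage output: summary.csv]", "")
  if (file.exists(f("overlaps.json"))) {
    ov <- jsonlite::read_json(f("overlaps.json"))
    lines <- c(lines,
               sprintf("Autofluorescence union: %s chemicals", ov$autofluorescence_union),
               sprintf("Active in all conditions and channels: %s",
                       ov$all_conditions_all_channels$n),
               sprintf("Luciferase x autofluorescence overlap: %s",
                       ov$luciferase_x_autofluorescence), "")
  }
  if (file.exists(f("som_enrichment.csv"))) {
    e <- utils::read.csv(f("som_enrichment.csv"))
    e <- e[e$n_members >= 4 & !is.na(e$pct_active), ]
    e <- e[order(-e$pct_active), ][seq_len(min(5, nrow(e))), ]
    lines <- c(lines, "Top enriched SOM nodes:",
               utils::capture.output(print(e, row.names = FALSE)), "")
  }
  if (file.exists(f("qsar_performance.csv"))) {
    p <- utils::read.csv(f("qsar_performance.csv"))
    lines <- c(lines, "QSAR performance (mean +/- SD over repetitions):",
               utils::capture.output(print(p, row.names = FALSE)), "")
  } else lines <- c(lines, "[missing stage output: qsar_performance.csv]", "")
  lines
}
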