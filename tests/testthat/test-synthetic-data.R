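test_that("library honors size, planted fraction and determinism", {
  lib <- generate_library(100, active_fraction = 0.1, seed = 7)
  expect_equal(nrow(lib), 100)
  expect_equal(sum(lib$truth_active), 10)
  expect_identical(lib, generate_library(100, active_fraction = 0.1, seed = 7))
  expect_false(identical(lib$smiles,
                         generate_library(100, active_fraction = 0.1, seed = 8)$smiles))
})

test_that("an invalid scaffold entry is reported by name", {
  pool <- scaffold_pool()
  pool$smiles[3] <- " "
  expect_error(generate_library(10, pool = pool, seed = 1), pool$name[3])
})

test_that("truth-actives all carry >= 3 aromatic rings (ring-perception oracle)", {
  lib <- generate_library(500, active_fraction = 0.1, seed = 1)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(lib$smiles, lib$chem_id)))
  rc <- ChemmineR::rings(sdf, type = "count", arom = TRUE, inner = TRUE)
  arom <- rc[match(lib$chem_id, rownames(rc)), "AROMATIC"]
  expect_true(all(arom[lib$truth_active] >= 3))
  expect_true(all(arom[!lib$truth_active] == 0))
})

test_that("titrations reproduce the Hill curve exactly at zero noise", {
  des <- titration_design(15, 0.0015, 115, replicates = 3, noise_sd = 0)
  expect_equal(length(des$concentrations_uM), 15)
  expect_true(all(diff(des$concentrations_uM) > 0))
  # log spacing: constant ratio
  steps <- diff(log(des$concentrations_uM))
  expect_equal(length(steps), 14)
  expect_lt(max(abs(steps - steps[1])), 1e-12)
  # AC50 at the geometric center of an odd grid: that point reads exactly 50%
  mid <- sqrt(0.0015 * 115)
  tt <- simulate_titration(mid, 1, 100, 0, design = des, seed = 1)
  expect_equal(tt$activity_pct[8], 50, tolerance = 1e-9)
  expect_lt(tt$activity_pct[which.min(tt$conc_uM)], 0.5) # low-dose asymptote
  expect_equal(nrow(tt), 45)
})

test_that("titration noise has the programmed magnitude (Monte-Carlo)", {
  des <- luciferase_design(noise_sd = 5)
  resid <- unlist(lapply(1:1000, function(s) {
    tt <- simulate_titration(10, 1, 100, 0, design = des, seed = s)
    tt$activity_pct - hill_response(tt$conc_uM, 10, 1, 100, 0)
  }))
  expect_gt(sd(resid), 3.5)
  expect_lt(sd(resid), 6.5)
})

test_that("plates round-trip programmed activities through normalization", {
  act <- stats::setNames(c(-50, 0, 25, 100, 130), paste0("c", 1:5))
  pl <- simulate_plate(act, noise_sd_pct = 0)
  w <- pl$wells
  vd <- stats::median(w$signal[w$well_role == "dmso"])
  vp <- stats::median(w$signal[w$well_role == "pos"])
  rec <- normalize_to_positive(w$signal[w$well_role == "compound"], vd, vp)
  expect_equal(rec, unname(act))
  # negative-control normalization round-trips too (offset is the 0% level)
  expect_equal(normalize_to_negative(w$signal[w$well_role == "dmso"], vd),
               rep(0, sum(w$well_role == "dmso")))
  expect_error(simulate_plate(act, n_dmso = 4), "configuration error")
})

test_that("noisy plate DMSO wells normalize to ~0% activity", {
  meds <- sapply(1:50, function(s) {
    pl <- simulate_plate(stats::setNames(rnorm(100, 0, 10), paste0("c", 1:100)),
                         n_dmso = 32, n_pos = 32, noise_sd_pct = 3, seed = s)
    w <- pl$wells
    vd <- stats::median(w$signal[w$well_role == "dmso"])
    vp <- stats::median(w$signal[w$well_role == "pos"])
    stats::median(normalize_to_positive(w$signal[w$well_role == "dmso"], vd, vp))
  })
  expect_lt(max(abs(meds)), 1)
})

test_that("planted descriptor matrices expose every column role", {
  g <- generate_descriptor_matrix(200, n_informative = 3, n_noise = 4,
                                  n_null_variance = 4, n_degenerate = 2,
                                  n_correlated_blocks = 2, block_size = 5,
                                  effect_size = 1.5, seed = 2)
  expect_equal(ncol(g$matrix), 3 + 4 + 4 + 2 + 10)
  expect_equal(sum(apply(g$matrix, 2, var) == 0), 4)
  # within-block pairwise |rho| > 0.9 by construction (brute force)
  for (b in 1:2) {
    blk <- g$matrix[, g$roles == sprintf("correlated_block_%d", b)]
    cors <- abs(cor(blk))[upper.tri(diag(5))]
    expect_true(all(cors > 0.9))
  }
  # informative columns separate the classes by ~effect_size
  shift <- colMeans(g$matrix[g$labels, g$roles == "informative"]) -
    colMeans(g$matrix[!g$labels, g$roles == "informative"])
  expect_true(all(abs(shift - 1.5) < 0.6))
  expect_identical(g$matrix,
                   generate_descriptor_matrix(200, 3, 4, 4, 2, 2, 5, 1.5, seed = 2)$matrix)
})

test_that("screen simulation plants a coherent truth table", {
  lib <- generate_library(40, active_fraction = 0.25, seed = 3)
  scr <- simulate_screen(lib, seed = 3)
  expect_equal(nrow(scr$truth), 40 * 13)
  # inactive chemicals are inactive on every endpoint
  inact <- lib$chem_id[!lib$truth_active]
  expect_false(any(scr$truth$truth_active[scr$truth$chem_id %in% inact]))
  # every planted active hits at least one endpoint
  act <- lib$chem_id[lib$truth_active]
  hits_per_chem <- tapply(scr$truth$truth_active, scr$truth$chem_id, any)
  expect_true(all(hits_per_chem[act]))
  # luciferase truths are signal-loss curves, autofluorescence signal-gain
  luc <- scr$truth[scr$truth$endpoint_id == "luciferase" & scr$truth$truth_active, ]
  expect_true(all(luc$top_pct == -100))
  af <- scr$truth[scr$truth$endpoint_id != "luciferase" & scr$truth$truth_active, ]
  expect_true(all(af$top_pct >= 60))
  # titration table covers all chemicals x endpoints
  expect_setequal(unique(scr$titrations$chem_id), lib$chem_id)
})

test_that("noise-only screens stay near the noise floor for active calls", {
  lib <- generate_library(60, active_fraction = 0, seed = 5)
  scr <- simulate_screen(lib, seed = 5,
                         luc_design = luciferase_design(noise_sd = 5),
                         af_design = autofluorescence_design(noise_sd = 5))
  sub <- scr$titrations[scr$titrations$endpoint_id %in%
                          c("luciferase", "hepg2_cell_blue", "hek293_free_red"), ]
  fits <- classify_curves(sub)
  hits <- call_hits(fits)
  expect_lte(mean(hits$active), 0.02)
})

test_that("derived seeds are stable, in range and stream-separating", {
  expect_identical(derive_seed(1L, "a"), derive_seed(1L, "a"))
  expect_false(derive_seed(1L, "a") == derive_seed(1L, "b"))
  expect_false(derive_seed(1L, "a") == derive_seed(2L, "a"))
  s <- vapply(1:100, function(i) derive_seed(i, "op"), integer(1))
  expect_true(all(s >= 1 & s < 2^31 - 1))
})
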