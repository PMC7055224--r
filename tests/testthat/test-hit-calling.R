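test_that("the endpoint catalogue enumerates the 13 readouts", {
  eps <- interference_endpoints()
  expect_equal(nrow(eps), 13)
  expect_equal(sum(eps$technology == "luciferase"), 1)
  af <- eps[eps$technology == "autofluorescence", ]
  expect_equal(nrow(af), 12)
  expect_setequal(unique(af$channel), c("blue", "green", "red"))
  expect_false(anyDuplicated(eps$endpoint_id) > 0)
})

test_that("every filter produces its reason code and active means no reasons", {
  fits <- rbind(
    fit_row("potency", "luciferase", 200, 90, -1.1),          # potency_fail
    fit_row("class", "luciferase", 10, 90, 3),                # class_fail
    fit_row("efficacy", "luciferase", 10, 10, -1.1),          # efficacy_fail
    fit_row("burst", "hepg2_cell_blue", 50, 90, 2.1, burst = 40), # burst_fail
    fit_row("nofit", "luciferase", NA, 0, 4, converged = FALSE),  # no_fit
    fit_row("hit_luc", "luciferase", 10, 85, -2.1),
    fit_row("hit_af", "hepg2_cell_blue", 10, 85, 2.1, burst = 40)
  )
  hits <- call_hits(fits)
  got <- stats::setNames(hits$reasons, hits$chem_id)
  expect_equal(got[["potency"]], "potency_fail")
  expect_equal(got[["class"]], "class_fail")
  expect_equal(got[["efficacy"]], "efficacy_fail")
  expect_equal(got[["burst"]], "burst_fail")
  expect_equal(got[["nofit"]], "no_fit")
  expect_equal(got[["hit_luc"]], "")
  expect_equal(got[["hit_af"]], "")
  expect_equal(hits$active, hits$reasons == "")
})

test_that("direction determines the allowed class sign", {
  # activation classes are not hits on the (inhibition-direction) luciferase endpoint
  hits <- call_hits(rbind(fit_row("a", "luciferase", 10, 90, 1.1),
                          fit_row("b", "hepg2_cell_blue", 10, 90, 1.1)))
  expect_false(hits$active[hits$chem_id == "a"])
  expect_true(hits$active[hits$chem_id == "b"])
})

test_that("boundary values are excluded under the strict reading", {
  fits <- rbind(fit_row("at_potency", "luciferase", 150, 90, -1.1),
                fit_row("at_efficacy", "luciferase", 10, 30, -1.1))
  hits <- call_hits(fits)
  expect_false(any(hits$active))
})

test_that("relaxing any threshold never decreases the active count", {
  set.seed(3)
  fits <- do.call(rbind, lapply(1:200, function(i) {
    fit_row(sprintf("c%03d", i), sample(interference_endpoints()$endpoint_id, 1),
            exp(runif(1, log(0.1), log(400))), runif(1, 0, 120),
            sample(c(1.1, 1.2, 2.1, 2.2, -1.1, -2.2, 3, 4), 1),
            burst = exp(runif(1, log(5), log(200))))
  }))
  base <- sum(call_hits(fits)$active)
  relaxed <- list(
    hitcall_config(potency_max_uM = 500),
    hitcall_config(efficacy_min_pct = 5),
    hitcall_config(burst_default_uM = 1000)
  )
  for (cfg in relaxed) expect_gte(sum(call_hits(fits, config = cfg)$active), base)
  # enlarging the allowed class set
  cfg <- hitcall_config()
  cfg$allowed_classes_activation <- c(cfg$allowed_classes_activation, 3)
  cfg$allowed_classes_inhibition <- c(cfg$allowed_classes_inhibition, 3)
  expect_gte(sum(call_hits(fits, config = cfg)$active), base)
  # partition: every record is either active or carries reasons
  hits <- call_hits(fits)
  expect_equal(sum(hits$active) + sum(hits$reasons != ""), nrow(fits))
})

test_that("multi-sample chemicals are active when any sample passes", {
  fits <- rbind(fit_row("dup", "luciferase", 10, 85, -1.1),
                fit_row("dup", "luciferase", 200, 85, -1.1))
  hits <- call_hits(fits)
  expect_equal(nrow(hits), 1)
  expect_true(hits$active)
})

test_that("active summaries compute hand-checkable potency statistics", {
  fits <- rbind(fit_row("a", "luciferase", 10, 85, -1.1),
                fit_row("b", "luciferase", 20, 85, -1.1),
                fit_row("c", "luciferase", 30, 85, -1.1),
                fit_row("d", "luciferase", 200, 85, -1.1))
  hits <- call_hits(fits)
  s <- summarize_actives(hits, fits, library_size = 40)
  expect_equal(s$n_active, 3)
  expect_equal(s$pct_active, 7.5)
  expect_equal(s$mean_ac50_uM, 20)
  expect_equal(s$sd_ac50_uM, 10)
  # empty active set reports absent statistics
  s0 <- summarize_actives(call_hits(fit_row("a", "luciferase", 200, 85, -1.1)),
                          fit_row("a", "luciferase", 200, 85, -1.1), 10)
  expect_equal(s0$n_active, 0)
  expect_true(is.na(s0$mean_ac50_uM))
})

test_that("overlap counts match exhaustive enumeration on a constructed fixture", {
  eps <- interference_endpoints()
  af <- eps[eps$technology == "autofluorescence", ]
  blue <- af$endpoint_id[af$channel == "blue"]
  green <- af$endpoint_id[af$channel == "green"]
  red <- af$endpoint_id[af$channel == "red"]
  membership <- list(
    c1 = c(blue, green, red),            # active everywhere autofluorescent
    c2 = blue,                           # blue only, all conditions
    c3 = blue[1],                        # blue, one condition
    c4 = c(blue[1], green[1]),
    c5 = c(green, red),
    c6 = red[2],
    c7 = c("luciferase", blue),
    c8 = "luciferase"
  )
  hits <- hits_from_membership(membership)
  ov <- overlap_analysis(hits)

  # independent enumeration over all membership patterns
  in_channel <- function(cid, eids) any(membership[[cid]] %in% eids)
  ids <- names(membership)
  blue_set <- ids[vapply(ids, in_channel, logical(1), blue)]
  green_set <- ids[vapply(ids, in_channel, logical(1), green)]
  red_set <- ids[vapply(ids, in_channel, logical(1), red)]
  expect_equal(ov$cross_channel$n_per_channel[["blue"]], length(blue_set))
  expect_equal(ov$autofluorescence_union,
               length(unique(c(blue_set, green_set, red_set))))
  all12 <- ids[vapply(ids, function(c) all(af$endpoint_id %in% membership[[c]]),
                      logical(1))]
  expect_equal(ov$all_conditions_all_channels$n, length(all12))
  expect_equal(ov$all_conditions_all_channels$ids, all12)
  expect_equal(ov$luciferase_x_autofluorescence, 1) # only c7
  # region counts are disjoint and sum to the union
  expect_equal(sum(unlist(ov$cross_channel$regions)),
               ov$autofluorescence_union)
  blue_all4 <- ids[vapply(ids, function(c) all(blue %in% membership[[c]]),
                          logical(1))]
  expect_equal(ov$per_channel$blue$all_conditions, length(blue_all4))
  expect_equal(ov$per_channel$blue$pct_all_conditions,
               100 * length(blue_all4) / length(blue_set))
})

test_that("disjoint actives produce empty intersections", {
  eps <- interference_endpoints()
  af_ids <- eps$endpoint_id[eps$technology == "autofluorescence"]
  membership <- stats::setNames(as.list(af_ids), sprintf("d%02d", seq_along(af_ids)))
  ov <- overlap_analysis(hits_from_membership(membership))
  expect_equal(ov$all_conditions_all_channels$n, 0)
  for (ch in c("blue", "green", "red")) {
    expect_equal(ov$per_channel[[ch]]$all_conditions, 0)
  }
  expect_equal(ov$luciferase_x_autofluorescence, 0)
})
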