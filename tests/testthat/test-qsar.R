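test_that("metrics match their printed formulas on anchor cases", {
  m <- classification_metrics(TP = 10, FP = 0, TN = 10, FN = 0)
  expect_equal(unname(m[c("Acc", "Acc_b", "MCC")]), c(1, 1, 1))
  # degenerate all-inactive predictor: Se = 0 and the MCC zero guard fires
  m <- classification_metrics(TP = 0, FP = 0, TN = 30, FN = 10)
  expect_equal(unname(m[["Se"]]), 0)
  expect_equal(unname(m[["MCC"]]), 0)
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  truth <- c(rep(TRUE, 60), rep(FALSE, 120))
  pred <- c(rep(TRUE, 50), rep(FALSE, 10), rep(TRUE, 20), rep(FALSE, 100))
  cc <- confusion_counts(truth, pred)
  expect_equal(unname(cc), c(50, 20, 100, 10))
  m <- classification_metrics(cc)
  expect_equal(m[["MCC"]], cor(as.numeric(truth), as.numeric(pred)))
})

test_that("undersampling hits the 70/30 ratio and coordinates across reps", {
  lab <- stats::setNames(c(rep(TRUE, 30), rep(FALSE, 1000)), paste0("c", 1:1030))
  ss <- undersample(lab, n_reps = 10, seed = 4)
  expect_true(all(lengths(ss) == 100)) # 30 actives + 70 inactives
  for (s in ss) {
    expect_equal(sum(lab[s]), 30)
    expect_equal(anyDuplicated(s), 0)
  }
  inact_union <- unique(unlist(lapply(ss, function(s) s[!lab[s]])))
  expect_equal(length(inact_union), 700) # without-replacement coverage
  expect_identical(ss, undersample(lab, n_reps = 10, seed = 4))
  # fewer inactives than required: keep all, warn
  lab2 <- stats::setNames(c(rep(TRUE, 40), rep(FALSE, 50)), paste0("d", 1:90))
  expect_warning(ss2 <- undersample(lab2, n_reps = 3, seed = 1), "fewer inactives")
  expect_true(all(lengths(ss2) == 90))
})

test_that("endpoint labeling rules match hand enumeration on a 6-chemical fixture", {
  eps <- interference_endpoints()
  af <- eps[eps$technology == "autofluorescence", ]
  blue <- af$endpoint_id[af$channel == "blue"]
  green <- af$endpoint_id[af$channel == "green"]
  membership <- list(
    m1 = "luciferase", m2 = blue, m3 = blue[1],
    m4 = green, m5 = c(blue[2], green[1]), m6 = character(0)
  )
  hits <- hits_from_membership(membership)
  X <- matrix(rnorm(6 * 3), ncol = 3,
              dimnames = list(names(membership), paste0("v", 1:3)))

  ds <- assemble_endpoint_dataset(hits, X, rule = "luciferase")
  expect_equal(names(ds$labels)[ds$labels], "m1")
  ds <- assemble_endpoint_dataset(hits, X, rule = "channel_any_condition",
                                  channel = "blue")
  expect_setequal(names(ds$labels)[ds$labels], c("m2", "m3", "m5"))
  ds <- assemble_endpoint_dataset(hits, X, rule = "any_channel_all_conditions")
  expect_setequal(names(ds$labels)[ds$labels], c("m2", "m4")) # full blue / full green
  ds <- assemble_endpoint_dataset(hits, X, rule = "single_endpoint",
                                  endpoint_id = green[1])
  expect_setequal(names(ds$labels)[ds$labels], c("m4", "m5"))
  expect_error(assemble_endpoint_dataset(hits, X, rule = "nope"))
  # fixture where nobody is active everywhere: zero positives
  ds0 <- assemble_endpoint_dataset(hits_from_membership(list(z1 = blue[1], z2 = green[1])),
                                   X[1:2, , drop = FALSE][c(1, 2), , drop = FALSE] |>
                                     `rownames<-`(c("z1", "z2")),
                                   rule = "any_channel_all_conditions")
  expect_equal(sum(ds0$labels), 0)
})

test_that("a linearly separable problem is solved perfectly by linear SVM", {
  blobs <- make_blobs(30, p = 4, sep = 8, seed = 3)
  fit <- train_member(blobs$X, blobs$labels, learner = "svm_linear",
                      cv_folds = 5L, seed = 1)
  expect_true(all(fit$cv_mcc_grid == 1))
  expect_equal(fit$cv_metrics[["MCC"]], 1)
})

test_that("tuning is reproducible under seed and ties pick the simplest setting", {
  blobs <- make_blobs(40, p = 5, sep = 4, seed = 5)
  f1 <- train_member(blobs$X, blobs$labels, learner = "rf", cv_folds = 5L, seed = 9)
  f2 <- train_member(blobs$X, blobs$labels, learner = "rf", cv_folds = 5L, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$cv_mcc_grid, f2$cv_mcc_grid)
  # separable data ties all grid rows at MCC 1 -> smallest forest wins
  blobs2 <- make_blobs(30, p = 4, sep = 10, seed = 6)
  f3 <- train_member(blobs2$X, blobs2$labels, learner = "rf", cv_folds = 5L, seed = 2)
  if (all(f3$cv_mcc_grid == 1)) expect_equal(f3$params$ntree, 100)
})

test_that("label-permuted data yields near-zero CV MCC for a fast learner", {
  mccs <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(200 * 5), ncol = 5,
                dimnames = list(sprintf("c%03d", 1:200), paste0("v", 1:5)))
    y <- stats::setNames(sample(rep(c(TRUE, FALSE), 100)), rownames(X))
    train_member(X, y, learner = "lda", cv_folds = 5L, seed = s)$cv_metrics[["MCC"]]
  })
  expect_lt(mean(abs(mccs)), 0.15)
  expect_true(all(abs(mccs) < 0.35))
})

test_that("ensembles report full metric shape, class balance and no leakage", {
  g <- generate_descriptor_matrix(400, effect_size = 1.5, seed = 21)
  spec <- ensemble_spec(learner = "rf", repetitions = 5L, seed = 3,
                        grids = list(rf = data.frame(ntree = 100)))
  ens <- build_ensemble(g$matrix, g$labels, spec)
  expect_s3_class(ens, "classifier_ensemble")
  expect_equal(length(ens$members), 5)
  # 5 metrics x 3 phases x (mean, sd)
  expect_equal(nrow(ens$performance), 15)
  expect_setequal(unique(ens$performance$phase), c("train", "cv", "test"))
  expect_setequal(unique(ens$performance$metric), c("Acc", "Acc_b", "Se", "Sp", "MCC"))
  expect_true(all(is.finite(ens$performance$mean)))
  for (member in ens$members) {
    pool <- c(member$train_ids, member$test_ids)
    # undersampled pool is 30% +/- 1 chemical active
    expect_lt(abs(sum(g$labels[pool]) - 0.3 * length(pool)), 2)
    # no chemical appears in both train and test of a repetition
    expect_equal(length(intersect(member$train_ids, member$test_ids)), 0)
  }
  # ranges of all reported metrics
  rng <- ens$performance
  expect_true(all(rng$mean[rng$metric != "MCC"] >= 0 & rng$mean[rng$metric != "MCC"] <= 1))
  expect_true(all(abs(rng$mean[rng$metric == "MCC"]) <= 1))
})

test_that("CV MCC grows with planted effect size (expectation over seeds)", {
  mean_mcc <- sapply(c(0, 0.5, 1, 2), function(es) {
    mean(sapply(1:10, function(s) {
      g <- generate_descriptor_matrix(300, effect_size = es, seed = 100 + s)
      spec <- ensemble_spec(learner = "rf", repetitions = 2L, cv_folds = 5L,
                            seed = s, grids = list(rf = data.frame(ntree = 100)))
      ens <- build_ensemble(g$matrix, g$labels, spec)
      ens$performance$mean[ens$performance$phase == "cv" &
                             ens$performance$metric == "MCC"]
    }))
  })
  expect_true(all(diff(mean_mcc) > 0))
})

test_that("variable importance singles out the planted signal column", {
  g <- generate_descriptor_matrix(300, n_informative = 1, n_noise = 8,
                                  n_null_variance = 0, n_degenerate = 0,
                                  n_correlated_blocks = 0, effect_size = 3,
                                  seed = 31)
  ens <- build_ensemble(g$matrix, g$labels,
                        ensemble_spec(learner = "rf", repetitions = 5L, seed = 4,
                                      grids = list(rf = data.frame(ntree = 250))))
  vi <- variable_importance(ens)
  # normalization: max importance per member is 1
  expect_equal(unname(apply(vi$importance, 2, max)), rep(1, 5))
  # the informative column ranks first in every member
  expect_true(all(apply(vi$importance, 2, which.max) ==
                    which(rownames(vi$importance) == "inf_01")))
  expect_equal(vi$summary$descriptor[1], "inf_01")
  # permutation fallback agrees on the top column for a non-RF learner
  ens2 <- build_ensemble(g$matrix, g$labels,
                         ensemble_spec(learner = "lda", repetitions = 2L, seed = 5))
  vi2 <- variable_importance(ens2, X = g$matrix, labels = g$labels, seed = 6)
  expect_equal(vi2$summary$descriptor[1], "inf_01")
})

test_that("interference predictions are calibrated ensemble means in [0, 1]", {
  g <- generate_descriptor_matrix(300, effect_size = 2.5, seed = 41)
  ens <- build_ensemble(g$matrix, g$labels,
                        ensemble_spec(learner = "rf", repetitions = 3L, seed = 6,
                                      grids = list(rf = data.frame(ntree = 100))))
  pred <- predict_interference(g$matrix, list(demo = ens))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  # resubstitution sanity: planted actives mostly score above 0.5
  act <- names(g$labels)[g$labels]
  expect_gt(mean(pred$probability[pred$chem_id %in% act] > 0.5), 0.9)
  # duplicated structures give identical probabilities (SMILES route)
  smi <- c(a = "Cc1ccc2cc3ccccc3cc2c1", b = "Cc1ccc2cc3ccccc3cc2c1", bad = "xx(")
  lib <- generate_library(80, active_fraction = 0.5, seed = 7)
  cur <- curate_structure(lib$smiles, lib$chem_id)
  dm <- compute_descriptors(cur)$matrix
  ens2 <- suppressWarnings( # a 50% active library keeps all inactives, with a warning
    build_ensemble(dm, stats::setNames(lib$truth_active, lib$chem_id)[rownames(dm)],
                   ensemble_spec(learner = "rf", repetitions = 2L, seed = 8,
                                 grids = list(rf = data.frame(ntree = 100)))))
  p2 <- predict_interference(smi, list(demo = ens2))
  expect_equal(p2$probability[p2$chem_id == "a"], p2$probability[p2$chem_id == "b"])
  expect_false(p2$curation_passed[p2$chem_id == "bad"])
  expect_true(is.na(p2$probability[p2$chem_id == "bad"]))
})
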