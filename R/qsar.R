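#' Ensemble specification for interference QSAR models
#'
#' Settings of the undersampled ensemble: the learner, ten repetitions over
#' distinct inactive subsamples at 70%/30% inactive/active, hyperparameters
#' grid-tuned to maximize mean MCC over a stratified ten-fold cross
#' validation, and a held-out test fraction (default 0.15, i.e. an ~85/15
#' split of each repetition's subset).
#'
#' @param learner One of `"rf"`, `"svm_linear"`, `"svm_radial"`,
#'   `"svm_sigmoid"`, `"lda"`, `"cart"`, `"nn"`.
#' @param repetitions Number of undersampled members (default 10).
#' @param inactive_ratio Inactive share of each subset (default 0.7).
#' @param cv_folds Cross-validation folds for tuning (default 10).
#' @param test_fraction Held-out fraction per repetition (default 0.15).
#' @param seed Integer seed.
#' @param grids Optional named list of tuning grids overriding
#'   [default_tuning_grids()].
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(learner = "rf", repetitions = 10L, inactive_ratio = 0.7,
                          cv_folds = 10L, test_fraction = 0.15, seed = 1L,
                          grids = default_tuning_grids()) {
  learner <- match.arg(learner, c("rf", "svm_linear", "svm_radial", "svm_sigmoid",
                                  "lda", "cart", "nn"))
  stopifnot(repetitions >= 1, inactive_ratio > 0, inactive_ratio < 1,
            test_fraction > 0, test_fraction < 1, cv_folds >= 2)
  structure(list(learner = learner, repetitions = as.integer(repetitions),
                 inactive_ratio = inactive_ratio, cv_folds = as.integer(cv_folds),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 grids = grids, tuning_metric = "MCC"),
            class = "ensemble_spec")
}

#' Default hyperparameter tuning grids
#'
#' Conventional small grids, ordered simplest-first so MCC ties resolve to
#' the simplest model. SVM `gamma = NA` means `1/p`, resolved at fit time.
#'
#' @return Named list of `data.frame` grids per learner.
#' @export
default_tuning_grids <- function() {
  list(
    rf = data.frame(ntree = c(100, 250, 500)),
    svm_linear = data.frame(cost = c(0.1, 1, 10, 100)),
    svm_radial = expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.1)),
    svm_sigmoid = expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.1)),
    lda = data.frame(dummy = 0),
    cart = data.frame(cp = c(0.05, 0.01, 0.001)),
    nn = expand.grid(size = c(3, 5, 10), decay = c(0, 0.01, 0.1))
  )
}

.needs_scaling <- function(learner) learner %in% c("svm_linear", "svm_radial", "svm_sigmoid", "lda", "nn")

.fit_learner <- function(learner, X, yf, params) {
  df <- data.frame(X, check.names = FALSE)
  switch(learner,
    rf = randomForest::randomForest(x = X, y = yf, ntree = params$ntree),
    svm_linear = e1071::svm(x = X, y = yf, kernel = "linear", cost = params$cost,
                            probability = TRUE, scale = FALSE),
    svm_radial = e1071::svm(x = X, y = yf, kernel = "radial", cost = params$cost,
                            gamma = if (is.na(params$gamma)) 1 / ncol(X) else params$gamma,
                            probability = TRUE, scale = FALSE),
    svm_sigmoid = e1071::svm(x = X, y = yf, kernel = "sigmoid", cost = params$cost,
                             gamma = if (is.na(params$gamma)) 1 / ncol(X) else params$gamma,
                             probability = TRUE, scale = FALSE),
    lda = suppressWarnings(MASS::lda(x = X, grouping = yf)),
    cart = rpart::rpart(.y ~ ., data = cbind(df, .y = yf), method = "class",
                        cp = params$cp),
    nn = nnet::nnet(.y ~ ., data = cbind(df, .y = yf), size = params$size,
                    decay = params$decay, trace = FALSE, maxit = 300,
                    MaxNWts = 10000),
    stop("unknown learner: ", learner)
  )
}

.predict_prob <- function(learner, model, X) {
  df <- data.frame(X, check.names = FALSE)
  p <- switch(learner,
    rf = stats::predict(model, X, type = "prob")[, "active"],
    svm_linear = ,
    svm_radial = ,
    svm_sigmoid = attr(stats::predict(model, X, probability = TRUE),
                       "probabilities")[, "active"],
    lda = stats::predict(model, X)$posterior[, "active"],
    cart = stats::predict(model, newdata = df, type = "prob")[, "active"],
    nn = as.numeric(stats::predict(model, newdata = df, type = "raw")),
    stop("unknown learner: ", learner)
  )
  unname(p)
}

# Seeded stratified fold assignment; guarantees (when feasible) that every
# fold sees both classes.
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid-tune and fit one ensemble member
#'
#' Stratified k-fold cross validation over the learner's grid; the setting
#' with the highest mean fold MCC is selected (ties toward the simplest,
#' i.e. earliest, grid row) and the model refit on the whole subset.
#' Features are standardized on this subset for scale-sensitive learners
#' (SVM, LDA, NN); the standardization parameters are stored with the
#' member.
#'
#' @param X Numeric feature matrix of the repetition's training pool.
#' @param y Logical labels (`TRUE` = active).
#' @param learner Learner name, see [ensemble_spec()].
#' @param grid Tuning grid `data.frame` (default from
#'   [default_tuning_grids()]).
#' @param cv_folds Folds (default 10).
#' @param seed Integer seed (fold assignment and any learner randomness).
#' @return List: `model`, `learner`, `params` (selected row), `cv_metrics`
#'   (mean of the five metrics over folds at the selected setting),
#'   `cv_mcc_grid` (mean CV MCC per grid row), `center`, `scale`,
#'   `features`.
#' @export
train_member <- function(X, y, learner = "rf", grid = default_tuning_grids()[[learner]],
                         cv_folds = 10L, seed = 1L) {
  stopifnot(is.matrix(X), is.logical(y), length(y) == nrow(X), any(y), any(!y))
  center <- NULL; scale <- NULL
  if (.needs_scaling(learner)) {
    Xs <- standardize_matrix(X)
    center <- attr(Xs, "center"); scale <- attr(Xs, "scale")
    X <- Xs
  }
  yf <- factor(ifelse(y, "active", "inactive"), levels = c("inactive", "active"))
  fold <- .stratified_folds(y, cv_folds, derive_seed(seed, "cv_folds"))

  n_grid <- nrow(grid)
  cv_mcc <- numeric(n_grid)
  fold_metrics <- vector("list", n_grid)
  for (gi in seq_len(n_grid)) {
    params <- grid[gi, , drop = FALSE]
    ms <- list()
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next # degenerate fold, skip
      set.seed(derive_seed(seed, paste0("fit_g", gi, "_f", f)))
      m <- .fit_learner(learner, X[tr, , drop = FALSE], yf[tr], params)
      p <- .predict_prob(learner, m, X[!tr, , drop = FALSE])
      ms[[length(ms) + 1L]] <- classification_metrics(confusion_counts(y[!tr], p >= 0.5))
    }
    fm <- do.call(rbind, ms)
    fold_metrics[[gi]] <- colMeans(fm, na.rm = TRUE)
    cv_mcc[gi] <- fold_metrics[[gi]][["MCC"]]
  }
  best <- which.max(cv_mcc) # which.max takes the earliest (simplest) on ties

  set.seed(derive_seed(seed, "final_fit"))
  model <- .fit_learner(learner, X, yf, grid[best, , drop = FALSE])
  list(model = model, learner = learner, params = grid[best, , drop = FALSE],
       cv_metrics = fold_metrics[[best]], cv_mcc_grid = cv_mcc,
       center = center, scale = scale, features = colnames(X))
}

# Apply a member's stored standardization and predict active probability.
.member_prob <- function(member, X) {
  X <- X[, member$features, drop = FALSE]
  if (!is.null(member$center)) {
    X <- standardize_matrix(X, center = member$center, scale = member$scale)
  }
  .predict_prob(member$learner, member$model, X)
}

#' Build an undersampled classifier ensemble with its performance report
#'
#' For each of the `repetitions` subsets from [undersample()]: hold out a
#' stratified `test_fraction`, grid-tune and fit on the remainder
#' ([train_member()]), and evaluate the five metrics on the training pool
#' (resubstitution), the tuning cross-validation, and the held-out test set.
#' Performance is reported as mean and SD over repetitions per phase.
#'
#' @param X Numeric descriptor matrix (rownames = chem ids).
#' @param labels Named logical vector over the same ids (`TRUE` = active).
#' @param spec An [ensemble_spec()].
#' @return List of class `classifier_ensemble`: `members` (each with model,
#'   tuned params, train/test ids, metrics), `performance` (`data.frame`
#'   phase x metric with mean and sd), `spec`, `features`.
#' @export
build_ensemble <- function(X, labels, spec = ensemble_spec()) {
  stopifnot(is.matrix(X), !is.null(rownames(X)),
            all(names(labels) %in% rownames(X)), inherits(spec, "ensemble_spec"))
  labels <- labels[names(labels)] # keep order stable
  subsets <- undersample(labels, n_reps = spec$repetitions,
                         inactive_ratio = spec$inactive_ratio,
                         seed = derive_seed(spec$seed, "ensemble_undersample"))
  grid <- spec$grids[[spec$learner]]
  members <- vector("list", spec$repetitions)
  perf <- list()
  for (r in seq_len(spec$repetitions)) {
    ids <- subsets[[r]]
    y <- labels[ids]
    rep_seed <- derive_seed(spec$seed, paste0("rep_", r))
    set.seed(derive_seed(rep_seed, "test_split"))
    test_ids <- unlist(lapply(split(ids, y), function(g) {
      sample(g, max(1L, round(length(g) * spec$test_fraction)))
    }), use.names = FALSE)
    train_ids <- setdiff(ids, test_ids)

    fit <- tryCatch(
      train_member(X[train_ids, , drop = FALSE], labels[train_ids],
                   learner = spec$learner, grid = grid,
                   cv_folds = spec$cv_folds, seed = rep_seed),
      error = function(e) { warning("repetition ", r, " failed: ", conditionMessage(e)); NULL }
    )
    if (is.null(fit)) next

    Xtr <- X[train_ids, , drop = FALSE]; Xte <- X[test_ids, , drop = FALSE]
    m_train <- classification_metrics(confusion_counts(
      labels[train_ids], .member_prob(fit, Xtr) >= 0.5))
    m_test <- classification_metrics(confusion_counts(
      labels[test_ids], .member_prob(fit, Xte) >= 0.5))
    members[[r]] <- c(fit, list(train_ids = train_ids, test_ids = test_ids,
                                metrics = list(train = m_train, cv = fit$cv_metrics,
                                               test = m_test)))
    for (ph in c("train", "cv", "test")) {
      perf[[ph]] <- rbind(perf[[ph]], members[[r]]$metrics[[ph]])
    }
  }
  members <- members[!vapply(members, is.null, logical(1))]
  if (!length(members)) stop("all ensemble repetitions failed")

  performance <- do.call(rbind, lapply(c("train", "cv", "test"), function(ph) {
    data.frame(phase = ph, metric = colnames(perf[[ph]]),
               mean = colMeans(perf[[ph]]), sd = apply(perf[[ph]], 2, stats::sd),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(members = members, performance = performance, spec = spec,
                 features = colnames(X)),
            class = "classifier_ensemble")
}

#' Per-descriptor variable importance across ensemble members
#'
#' Random-forest members report impurity importance (mean decrease in Gini);
#' other learners fall back to seeded single-pass permutation importance
#' (drop in training MCC when a column is permuted). Importances are
#' normalized to `[0, 1]` within each member (max = 1).
#'
#' @param ensemble A [build_ensemble()] result.
#' @param X The descriptor matrix the ensemble was built on (needed for the
#'   permutation fallback).
#' @param labels Named logical labels over the rows of `X` (needed for the
#'   permutation fallback).
#' @param top_k Rows of the summary table (default 10).
#' @param seed Seed for the permutation fallback.
#' @return List: `importance` (descriptors x members, normalized), `summary`
#'   (`data.frame` ranked by mean normalized importance, top `top_k`).
#' @export
variable_importance <- function(ensemble, X = NULL, labels = NULL, top_k = 10L, seed = 1L) {
  stopifnot(inherits(ensemble, "classifier_ensemble"))
  imp <- sapply(seq_along(ensemble$members), function(r) {
    member <- ensemble$members[[r]]
    if (member$learner == "rf") {
      v <- randomForest::importance(member$model)[, 1]
    } else {
      if (is.null(X) || is.null(labels)) {
        stop("permutation importance for learner '", member$learner,
             "' requires the descriptor matrix X and labels")
      }
      Xtr <- X[member$train_ids, member$features, drop = FALSE]
      ytr <- labels[member$train_ids]
      base <- classification_metrics(confusion_counts(
        ytr, .member_prob(member, Xtr) >= 0.5))[["MCC"]]
      set.seed(derive_seed(seed, paste0("perm_imp_", r)))
      v <- vapply(seq_len(ncol(Xtr)), function(j) {
        Xp <- Xtr
        Xp[, j] <- sample(Xp[, j])
        base - classification_metrics(confusion_counts(
          ytr, .member_prob(member, Xp) >= 0.5))[["MCC"]]
      }, numeric(1))
      names(v) <- colnames(Xtr)
      v <- pmax(v, 0)
    }
    v / max(v, .Machine$double.eps)
  })
  rownames(imp) <- ensemble$members[[1]]$features
  mean_imp <- rowMeans(imp)
  ord <- order(-mean_imp)
  list(importance = imp,
       summary = data.frame(descriptor = rownames(imp)[ord],
                            mean_importance = mean_imp[ord],
                            sd_importance = apply(imp, 1, stats::sd)[ord],
                            row.names = NULL,
                            stringsAsFactors = FALSE)[seq_len(min(top_k, nrow(imp))), ])
}

#' Predict interference probability for new chemicals
#'
#' Curates the input structures, computes descriptors, and scores each
#' chemical with every requested endpoint ensemble: the interference
#' probability is the mean positive-class score over the ensemble's
#' members, with a binary call at `threshold`. Chemicals failing curation
#' are flagged and not scored.
#'
#' @param smiles Named character vector of input SMILES (names = chem ids),
#'   or a precomputed descriptor matrix (rownames = chem ids) covering the
#'   ensembles' features.
#' @param ensembles Named list of [build_ensemble()] results, one per
#'   endpoint.
#' @param threshold Probability cutoff for the binary call (default 0.5).
#' @return `data.frame`: `chem_id`, `endpoint`, `probability`, `call`,
#'   `curation_passed`.
#' @export
predict_interference <- function(smiles, ensembles, threshold = 0.5) {
  stopifnot(is.list(ensembles), length(ensembles) >= 1, !is.null(names(ensembles)))
  for (e in ensembles) stopifnot(inherits(e, "classifier_ensemble"))

  if (is.matrix(smiles)) {
    desc <- smiles
    passed <- rownames(desc)
    failed <- character(0)
  } else {
    if (is.null(names(smiles))) names(smiles) <- paste0("chem_", seq_along(smiles))
    cur <- curate_structure(smiles, chem_id = names(smiles))
    failed <- cur$chem_id[cur$curation_status != "passed"]
    passed <- cur$chem_id[cur$curation_status == "passed"]
    if (length(passed) == 0L) {
      desc <- NULL
    } else {
      desc <- compute_descriptors(cur)$matrix
    }
  }
  out <- list()
  for (ep in names(ensembles)) {
    ens <- ensembles[[ep]]
    if (length(passed)) {
      missing_feat <- setdiff(ens$features, colnames(desc))
      if (length(missing_feat)) {
        stop("descriptor matrix lacks features required by endpoint '", ep, "'")
      }
      probs <- rowMeans(sapply(ens$members, function(member) {
        .member_prob(member, desc[passed, , drop = FALSE])
      }))
      out[[length(out) + 1L]] <- data.frame(
        chem_id = passed, endpoint = ep, probability = unname(probs),
        call = unname(probs) >= threshold, curation_passed = TRUE,
        stringsAsFactors = FALSE)
    }
    if (length(failed)) {
      out[[length(out) + 1L]] <- data.frame(
        chem_id = failed, endpoint = ep, probability = NA_real_,
        call = NA, curation_passed = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
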