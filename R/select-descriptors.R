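#' Select informative, non-redundant descriptors
#'
#' Three-rule selection applied in order: (1) drop zero-variance columns;
#' (2) drop degenerate columns whose single most frequent value covers more
#' than `degeneracy_threshold` of the rows; (3) compute all pairwise Pearson
#' correlations among survivors, connect pairs exceeding `corr_threshold`,
#' take connected components of that graph as redundancy clusters, and keep
#' exactly one uniformly-random member per cluster (under `seed`).
#'
#' By default the correlation rule uses `|rho|` so that anticorrelated
#' duplicates are also collapsed; `absolute = FALSE` restores the signed
#' `rho > threshold` reading.
#'
#' @param mat Numeric matrix (rows = chemicals, columns = descriptors).
#' @param corr_threshold Correlation threshold (default 0.9).
#' @param degeneracy_threshold Maximal modal-value share (default 0.9).
#' @param absolute Use `|rho|` (default `TRUE`).
#' @param seed Integer seed for the random cluster representative.
#' @return A list: `matrix` (selected columns), `selected` (column names),
#'   `report` (`data.frame`: descriptor, action `kept|dropped`, rule
#'   `none|zero_variance|degenerate|correlated`, cluster id for rule-3
#'   members).
#' @export
select_descriptors <- function(mat, corr_threshold = 0.9, degeneracy_threshold = 0.9,
                               absolute = TRUE, seed = 1L) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2, corr_threshold > 0, corr_threshold <= 1,
            degeneracy_threshold > 0, degeneracy_threshold <= 1)
  nm <- colnames(mat)
  stopifnot(!is.null(nm), !anyDuplicated(nm))
  report <- data.frame(descriptor = nm, action = "kept", rule = "none",
                       cluster = NA_integer_, stringsAsFactors = FALSE)

  v <- apply(mat, 2, stats::var)
  zero_var <- !is.finite(v) | v < .Machine$double.eps
  report$action[zero_var] <- "dropped"; report$rule[zero_var] <- "zero_variance"

  modal_share <- apply(mat, 2, function(x) max(table(x)) / length(x))
  degen <- !zero_var & modal_share > degeneracy_threshold
  report$action[degen] <- "dropped"; report$rule[degen] <- "degenerate"

  surv <- nm[!zero_var & !degen]
  if (length(surv) > 1) {
    cm <- stats::cor(mat[, surv, drop = FALSE])
    cm[!is.finite(cm)] <- 0
    score <- if (absolute) abs(cm) else cm
    adj <- score > corr_threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    set.seed(derive_seed(seed, "select_descriptors"))
    for (cl in unique(comp)) {
      members <- surv[comp == cl]
      report$cluster[match(members, nm)] <- cl
      if (length(members) > 1) {
        keep <- sample(members, 1L)
        drop <- setdiff(members, keep)
        report$action[match(drop, nm)] <- "dropped"
        report$rule[match(drop, nm)] <- "correlated"
      }
    }
  }
  sel <- report$descriptor[report$action == "kept"]
  list(matrix = mat[, sel, drop = FALSE], selected = sel, report = report)
}
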