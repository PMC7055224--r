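#' Z-standardize a descriptor matrix
#'
#' Centers and scales each column to zero mean and unit variance. Mixed-unit
#' descriptor blocks must be standardized before any Euclidean-distance
#' analysis (SOM, Ward clustering, PCA).
#'
#' @param mat Numeric matrix.
#' @param center,scale Optional pre-fitted centers/scales (e.g. from a
#'   training pool) to apply instead of fitting on `mat`.
#' @return Standardized matrix with `center`/`scale` attributes.
#' @export
standardize_matrix <- function(mat, center = NULL, scale = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(center)) center <- colMeans(mat)
  if (is.null(scale)) {
    scale <- apply(mat, 2, stats::sd)
    scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  }
  out <- sweep(sweep(mat, 2, center), 2, scale, "/")
  attr(out, "center") <- center; attr(out, "scale") <- scale
  out
}

#' Train a self-organizing map on descriptor space
#'
#' Kohonen batch SOM on a rectangular grid (default 15 x 15 = 225 nodes):
#' codebook vectors are initialized from a seeded sample of the data and
#' refined over `epochs` batch sweeps with a linearly decaying neighborhood
#' radius. Chemicals are assigned to their Euclidean-nearest codebook vector.
#'
#' @param mat Numeric matrix of selected descriptors (rows = chemicals).
#' @param grid_rows,grid_cols Grid dimensions (default 15 x 15).
#' @param epochs Number of batch sweeps (default 30).
#' @param seed Integer seed (codebook initialization).
#' @param standardize Standardize `mat` first (default `TRUE`).
#' @return A list of class `som_model`: `codebook` (nodes x p), `assignment`
#'   (named node index per chemical), `grid_rows`, `grid_cols`, and training
#'   metadata.
#' @export
train_som <- function(mat, grid_rows = 15L, grid_cols = 15L, epochs = 30L,
                      seed = 1L, standardize = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  n_nodes <- grid_rows * grid_cols
  if (n_nodes > nrow(mat)) {
    warning("SOM grid has more nodes than chemicals; many nodes will be empty")
  }
  X <- if (standardize) standardize_matrix(mat) else mat
  set.seed(derive_seed(seed, "train_som"))
  init <- X[sample(nrow(X), n_nodes, replace = n_nodes > nrow(X)), , drop = FALSE]
  grid <- class::somgrid(xdim = grid_cols, ydim = grid_rows, topo = "rectangular")
  radii <- seq(max(grid_rows, grid_cols) / 2, 0.5, length.out = epochs)
  som <- class::batchSOM(X, grid, radii = radii, init = init)
  codebook <- som$codes
  rownames(codebook) <- paste0("node_", seq_len(n_nodes))
  assignment <- som_assign(codebook, X)
  structure(list(
    codebook = codebook, assignment = assignment,
    grid_rows = grid_rows, grid_cols = grid_cols,
    center = attr(X, "center"), scale = attr(X, "scale"),
    meta = list(epochs = epochs, seed = seed,
                radii = range(radii), topology = "rectangular")
  ), class = "som_model")
}

#' Assign rows to their nearest SOM codebook vector
#'
#' @param codebook Codebook matrix (nodes x p).
#' @param X Data matrix on the same (standardized) scale.
#' @return Named integer vector of node indices.
#' @export
som_assign <- function(codebook, X) {
  cross <- X %*% t(codebook)
  d2 <- outer(rowSums(X^2), rowSums(codebook^2), "+") - 2 * cross
  idx <- max.col(-d2, ties.method = "first")
  stats::setNames(idx, rownames(X))
}

#' Activity enrichment per SOM node
#'
#' Colors the map by hit rate: for every node, the member count, active
#' count and percent active, plus summary statistics over occupied nodes.
#'
#' @param som A [train_som()] model.
#' @param active_ids Character vector of active chemical ids for one
#'   endpoint (or endpoint set).
#' @param min_members Minimum node size for the ranked enriched-node table
#'   (default 4).
#' @return A list: `nodes` (`data.frame` node, n_members, n_active,
#'   pct_active), `summary` (mean/sd/max pct_active over occupied nodes,
#'   totals), `ranked` (occupied nodes with `n_members >= min_members`
#'   ordered by decreasing enrichment).
#' @export
som_enrichment <- function(som, active_ids, min_members = 4L) {
  stopifnot(inherits(som, "som_model"))
  n_nodes <- som$grid_rows * som$grid_cols
  ids <- names(som$assignment)
  node <- factor(som$assignment, levels = seq_len(n_nodes))
  n_members <- as.integer(table(node))
  n_active <- as.integer(table(node[ids %in% active_ids]))
  nodes <- data.frame(
    node = seq_len(n_nodes), n_members = n_members, n_active = n_active,
    pct_active = ifelse(n_members > 0, 100 * n_active / n_members, NA_real_)
  )
  occ <- nodes[nodes$n_members > 0, ]
  ranked <- occ[occ$n_members >= min_members, ]
  ranked <- ranked[order(-ranked$pct_active, -ranked$n_active, ranked$node), ]
  list(
    nodes = nodes,
    summary = list(
      n_occupied = nrow(occ), n_empty = n_nodes - nrow(occ),
      mean_pct_active = mean(occ$pct_active), sd_pct_active = stats::sd(occ$pct_active),
      max_pct_active = max(occ$pct_active),
      total_active = sum(nodes$n_active), total_members = sum(nodes$n_members)
    ),
    ranked = ranked
  )
}

#' Ward hierarchical clustering of active chemicals
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on the
#' Euclidean distance matrix of (standardized) descriptors. The leaf order
#' is made reproducible by recursively placing the tighter (lower-height)
#' subtree first, breaking ties by the lexicographically smallest chemical
#' id in the subtree.
#'
#' @param mat Numeric descriptor matrix of the active chemicals (rownames =
#'   chem ids).
#' @param annotations Optional `data.frame` keyed by `chem_id` (e.g. AC50
#'   per culture condition) re-emitted in leaf order for heatmap rendering.
#' @param standardize Standardize first (default `TRUE`).
#' @return A list: `hclust`, `leaf_order` (chem ids), `newick` (tree
#'   string), `annotations` (reordered, or `NULL`).
#' @export
ward_cluster <- function(mat, annotations = NULL, standardize = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2, !is.null(rownames(mat)))
  X <- if (standardize) standardize_matrix(mat) else mat
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")

  # deterministic leaf order: tighter subtree first, lexicographic tie-break
  subtree <- function(k) { # k: row of merge (positive) or -leaf
    if (k < 0) {
      list(order = -k, height = 0, min_id = hc$labels[-k])
    } else {
      a <- subtree(hc$merge[k, 1]); b <- subtree(hc$merge[k, 2])
      first_a <- a$height < b$height ||
        (a$height == b$height && a$min_id <= b$min_id)
      o <- if (first_a) c(a$order, b$order) else c(b$order, a$order)
      list(order = o, height = hc$height[k], min_id = min(a$min_id, b$min_id))
    }
  }
  hc$order <- subtree(nrow(hc$merge))$order
  leaf_order <- hc$labels[hc$order]
  newick <- ape::write.tree(ape::as.phylo(hc))
  ann <- NULL
  if (!is.null(annotations)) {
    stopifnot("chem_id" %in% names(annotations))
    ann <- annotations[match(leaf_order, annotations$chem_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  list(hclust = hc, leaf_order = leaf_order, newick = newick, annotations = ann)
}

#' Fit a PCA on a reference library and project a query set
#'
#' Principal components are fitted on the standardized reference matrix;
#' the query matrix (same descriptor columns) is projected into the same
#' axes. Used for library-coverage maps.
#'
#' @param reference,query Numeric matrices sharing column names (`query`
#'   defaults to the reference itself).
#' @param n_components Components to return (default 2).
#' @return A list: `reference_coords`, `query_coords`,
#'   `explained_variance` (fraction per returned component), `fit`
#'   (the `prcomp` object).
#' @export
pca_project <- function(reference, query = reference, n_components = 2L) {
  stopifnot(is.matrix(reference), is.matrix(query))
  if (!identical(colnames(reference), colnames(query))) {
    stop("schema error: query descriptor columns must match the reference")
  }
  sds <- apply(reference, 2, stats::sd)
  keep <- is.finite(sds) & sds > .Machine$double.eps
  fit <- stats::prcomp(reference[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(fit$rotation))
  list(
    reference_coords = fit$x[, seq_len(k), drop = FALSE],
    query_coords = stats::predict(fit, query[, keep, drop = FALSE])[, seq_len(k), drop = FALSE],
    explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)],
    fit = fit
  )
}
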