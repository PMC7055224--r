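# Element lookup tables used by the 2D descriptor provider: atomic number,
# mass, Pauling electronegativity, atomic polarizability (A^3), covalent
# radius (A), standard organic valence and valence-electron count.
.elem_props <- local({
  tab <- rbind(
    H  = c(1,   1.008,  2.20, 0.667, 0.31, 1, 1),
    B  = c(5,  10.811,  2.04, 3.030, 0.84, 3, 3),
    C  = c(6,  12.011,  2.55, 1.760, 0.76, 4, 4),
    N  = c(7,  14.007,  3.04, 1.100, 0.71, 3, 5),
    O  = c(8,  15.999,  3.44, 0.802, 0.66, 2, 6),
    F  = c(9,  18.998,  3.98, 0.557, 0.57, 1, 7),
    Si = c(14, 28.086,  1.90, 5.380, 1.11, 4, 4),
    P  = c(15, 30.974,  2.19, 3.630, 1.07, 3, 5),
    S  = c(16, 32.066,  2.58, 2.900, 1.05, 2, 6),
    Cl = c(17, 35.453,  3.16, 2.180, 1.02, 1, 7),
    Se = c(34, 78.971,  2.55, 3.770, 1.20, 2, 6),
    Br = c(35, 79.904,  2.96, 3.050, 1.20, 1, 7),
    I  = c(53, 126.904, 2.66, 5.350, 1.39, 1, 7)
  )
  colnames(tab) <- c("Z", "mass", "en", "pol", "rcov", "valence", "zv")
  tab
})

#' Default 2D molecular descriptor provider
#'
#' Computes a block of constitutional, topological-index and
#' 2D-autocorrelation descriptors from the molecular graph of each curated
#' SMILES: element/bond/ring counts, hydrogen-bond donor and acceptor
#' counts, unsaturation measures, degree statistics, Zagreb and
#' Randic/Kier-Hall connectivity indices (simple and valence), kappa shape
#' indices, Wiener and Balaban indices, eccentricity-derived indices, and
#' Moreau-Broto/Moran/Geary autocorrelations at topological lags 1-8 over
#' five atomic properties (atomic number, mass, electronegativity,
#' polarizability, covalent radius). Roughly 170 columns.
#'
#' @param smiles Character vector of curated SMILES.
#' @return Numeric matrix, one row per structure (rownames from `names(smiles)`
#'   when set), one named column per descriptor. Structures that fail to
#'   parse produce all-`NA` rows (imputed downstream by
#'   [compute_descriptors()]).
#' @export
descriptor_provider_2d <- function(smiles) {
  ids <- if (!is.null(names(smiles))) names(smiles) else paste0("s", seq_along(smiles))
  rows <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    rows[[i]] <- tryCatch(.descriptors_one(smiles[[i]]), error = function(e) NULL)
  }
  template <- rows[[which(!vapply(rows, is.null, logical(1)))[1]]]
  if (is.null(template)) stop("no structure could be parsed by the descriptor provider")
  out <- matrix(NA_real_, nrow = length(smiles), ncol = length(template),
                dimnames = list(ids, names(template)))
  for (i in seq_along(rows)) if (!is.null(rows[[i]])) out[i, ] <- rows[[i]]
  out
}

.descriptors_one <- function(smi) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smi, "m"))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  elems <- sub("_.*", "", rownames(ab))
  known <- elems %in% rownames(.elem_props)
  n <- length(elems)
  bb <- ChemmineR::bondblock(mol)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) %/% 7, ncol = 7, byrow = FALSE)
  m <- if (n > 1 && nrow(bb) > 0) nrow(bb) else 0L

  P <- .elem_props[ifelse(known, elems, "C"), , drop = FALSE] # fallback keeps dims; rare
  deg <- numeric(n); bond_order_sum <- numeric(n)
  edges <- if (m > 0) cbind(bb[, 1], bb[, 2]) else matrix(0, 0, 2)
  orders <- if (m > 0) bb[, 3] else numeric(0)
  for (k in seq_len(m)) {
    deg[edges[k, ]] <- deg[edges[k, ]] + 1
    bond_order_sum[edges[k, ]] <- bond_order_sum[edges[k, ]] + orders[k]
  }
  h_impl <- pmax(0, P[, "valence"] - bond_order_sum)

  # ring perception (SSSR-style inner rings) and aromaticity
  ringinfo <- tryCatch(ChemmineR::rings(mol, type = "all", arom = TRUE, inner = TRUE),
                       error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
  ringlist <- ringinfo$RINGS
  arom_rings <- if (length(ringlist)) ringlist[which(ringinfo$AROMATIC)] else list()
  ring_atoms <- unique(unlist(ringlist))
  arom_atoms <- unique(unlist(arom_rings))
  idx_of <- function(labels) match(labels, rownames(ab))
  in_ring <- seq_len(n) %in% idx_of(ring_atoms)
  in_arom <- seq_len(n) %in% idx_of(arom_atoms)

  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (m > 0) g <- igraph::add_edges(g, t(edges))
  D <- igraph::distances(g)
  D[!is.finite(D)] <- 0 # disconnected guard; curated structures are single fragments

  out <- c()
  add <- function(name, value) {
    v <- if (is.finite(value)) value else 0
    out[[name]] <<- v
  }

  # constitutional
  counts <- table(factor(elems, levels = rownames(.elem_props)))
  add("nAtoms", n); add("nBonds", m)
  for (e in c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")) add(paste0("n", e), counts[[e]])
  add("nHal", sum(counts[c("F", "Cl", "Br", "I")]))
  add("nHet", n - counts[["C"]])
  add("nHImplicit", sum(h_impl))
  add("MW", sum(P[, "mass"]) + 1.008 * sum(h_impl))
  add("nSingle", sum(orders == 1)); add("nDouble", sum(orders == 2)); add("nTriple", sum(orders == 3))
  nH <- sum(h_impl)
  add("DBE", (2 * counts[["C"]] + 2 + counts[["N"]] + counts[["P"]] -
                nH - sum(counts[c("F", "Cl", "Br", "I")])) / 2)
  add("unsaturationRatio", if (m > 0) sum(orders > 1) / m else 0)
  add("HBA", counts[["N"]] + counts[["O"]])
  add("HBD", sum(elems %in% c("N", "O") & h_impl >= 1))

  # rings & aromaticity
  add("nRings", length(ringlist)); add("nAromRings", length(arom_rings))
  add("nRingAtoms", sum(in_ring)); add("nAromAtoms", sum(in_arom))
  add("fracAromAtoms", if (n > 0) sum(in_arom) / n else 0)
  ring_sizes <- lengths(ringlist)
  for (sz in 3:8) add(paste0("nRing", sz), sum(ring_sizes == sz))
  bridge_idx <- if (m > 1) igraph::bridges(g) else seq_len(m)
  ring_bond <- rep(TRUE, m); ring_bond[as.integer(bridge_idx)] <- FALSE
  add("nRingBonds", sum(ring_bond))
  rot <- orders == 1 & !ring_bond & deg[edges[, 1]] > 1 & deg[edges[, 2]] > 1
  add("nRotBonds", sum(rot))

  # degree statistics, Zagreb and connectivity indices
  for (d in 1:4) add(paste0("nDeg", d), sum(deg == d))
  add("Zagreb1", sum(deg^2))
  add("Zagreb2", if (m > 0) sum(deg[edges[, 1]] * deg[edges[, 2]]) else 0)
  dv <- pmax(P[, "zv"] - h_impl, 0.5) # Kier-Hall valence delta, floored for stability
  add("chi0", sum(1 / sqrt(pmax(deg, 1))))
  add("chi0v", sum(1 / sqrt(dv)))
  if (m > 0) {
    add("chi1", sum(1 / sqrt(deg[edges[, 1]] * deg[edges[, 2]])))
    add("chi1v", sum(1 / sqrt(dv[edges[, 1]] * dv[edges[, 2]])))
  } else { add("chi1", 0); add("chi1v", 0) }
  # paths of length 2 through each center atom
  p2 <- sum(choose(deg, 2))
  chi2 <- 0; chi2v <- 0
  if (n >= 3) {
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (k in seq_len(m)) {
      adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
      adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
    }
    for (c0 in seq_len(n)) {
      nb <- adj[[c0]]
      if (length(nb) >= 2) {
        prs <- utils::combn(nb, 2)
        chi2 <- chi2 + sum(1 / sqrt(deg[prs[1, ]] * pmax(deg[c0], 1) * deg[prs[2, ]]))
        chi2v <- chi2v + sum(1 / sqrt(dv[prs[1, ]] * dv[c0] * dv[prs[2, ]]))
      }
    }
  }
  add("chi2", chi2); add("chi2v", chi2v)

  # kappa shape indices
  p3 <- sum(D == 3) / 2
  add("kappa1", if (m > 0) n * (n - 1)^2 / m^2 else 0)
  add("kappa2", if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0)
  add("kappa3", if (p3 > 0) {
    if (n %% 2 == 0) (n - 3) * (n - 2)^2 / p3^2 else (n - 1) * (n - 3)^2 / p3^2
  } else 0)

  # distance-based indices
  add("Wiener", sum(D) / 2)
  ecc <- apply(D, 1, max)
  add("radius", min(ecc)); add("diameter", max(ecc))
  add("petitjean", if (min(ecc) > 0) (max(ecc) - min(ecc)) / min(ecc) else 0)
  add("eccConn", sum(ecc * deg))
  if (m > 0) {
    mu <- m - n + 1
    s <- rowSums(D)
    bal <- m / (mu + 1) * sum(1 / sqrt(s[edges[, 1]] * s[edges[, 2]]))
    add("BalabanJ", bal)
  } else add("BalabanJ", 0)

  # 2D autocorrelations over atomic properties, lags 1..8
  props <- list(Z = P[, "Z"], m = P[, "mass"], en = P[, "en"],
                pol = P[, "pol"], r = P[, "rcov"])
  for (pn in names(props)) {
    w <- props[[pn]]
    wc <- w - mean(w)
    varw <- sum(wc^2) / n
    for (lag in 1:8) {
      pair <- which(D == lag & upper.tri(D), arr.ind = TRUE)
      npair <- nrow(pair)
      ats <- if (npair) sum(w[pair[, 1]] * w[pair[, 2]]) else 0
      add(paste0("ATS", lag, "_", pn), log1p(ats))
      moran <- if (npair && varw > 0) {
        (sum(wc[pair[, 1]] * wc[pair[, 2]]) / npair) / varw
      } else 0
      add(paste0("MATS", lag, "_", pn), moran)
      geary <- if (npair && varw > 0) {
        (sum((w[pair[, 1]] - w[pair[, 2]])^2) / (2 * npair)) / (sum(wc^2) / (n - 1))
      } else 0
      add(paste0("GATS", lag, "_", pn), geary)
    }
  }
  unlist(out)
}

#' Compute a descriptor matrix for curated structures
#'
#' Applies one or more descriptor providers to the curated structures and
#' column-concatenates their outputs. A provider is any function mapping a
#' character vector of curated SMILES to a numeric matrix with one named
#' column per descriptor. Missing values (provider failures, undefined
#' descriptors) are imputed by the column median, and every imputation is
#' recorded.
#'
#' @param curated A curation table from [curate_structure()] (only rows with
#'   `curation_status == "passed"` are used), or a named character vector of
#'   curated SMILES.
#' @param providers Named list of provider functions; default the packaged
#'   2D provider.
#' @return A list: `matrix` (numeric, rownames = chem ids, unique column
#'   names prefixed by provider name), `provenance` (provider of each
#'   column), `imputed` (`data.frame` of chem_id/descriptor imputations).
#' @export
compute_descriptors <- function(curated, providers = list(topo2d = descriptor_provider_2d)) {
  if (is.data.frame(curated)) {
    keep <- curated$curation_status == "passed"
    smiles <- stats::setNames(curated$curated_smiles[keep], curated$chem_id[keep])
  } else {
    smiles <- curated
    if (is.null(names(smiles))) names(smiles) <- paste0("chem_", seq_along(smiles))
  }
  stopifnot(length(smiles) > 0, length(providers) >= 1, !is.null(names(providers)))

  blocks <- lapply(names(providers), function(pn) {
    b <- providers[[pn]](smiles)
    stopifnot(is.matrix(b), nrow(b) == length(smiles))
    colnames(b) <- paste(pn, colnames(b), sep = ".")
    b
  })
  mat <- do.call(cbind, blocks)
  rownames(mat) <- names(smiles)
  stopifnot(!anyDuplicated(colnames(mat)))

  imputed <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(imputed)) {
    med <- apply(mat, 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    mat[imputed] <- med[imputed[, 2]]
    warning(sprintf("imputed %d missing descriptor values by column median", nrow(imputed)))
  }
  list(
    matrix = mat,
    provenance = stats::setNames(rep(names(providers), vapply(blocks, ncol, integer(1))),
                                 colnames(mat)),
    imputed = data.frame(
      chem_id = rownames(mat)[imputed[, 1]],
      descriptor = colnames(mat)[imputed[, 2]],
      stringsAsFactors = FALSE
    )
  )
}
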