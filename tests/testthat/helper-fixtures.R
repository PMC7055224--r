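# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures.

# Two labeled Gaussian clouds in p dimensions, separated by `sep` SDs on
# every coordinate.
make_blobs <- function(n_per_class = 50, p = 4, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
  rownames(X) <- sprintf("b_%03d", seq_len(2 * n_per_class))
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, labels = stats::setNames(rep(c(FALSE, TRUE), each = n_per_class),
                                       rownames(X)))
}

# Independent brute-force metric computation from raw binary vectors,
# written against the printed formulas with none of the package's code.
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  se <- tp / (tp + fn); sp <- tn / (tn + fp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(Acc = (tp + tn) / length(truth), Acc_b = (se + sp) / 2, Se = se, Sp = sp,
    MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# A fit table row in the layout call_hits() consumes.
fit_row <- function(chem_id, endpoint_id, ac50, eff, cls, converged = TRUE,
                    burst = NA_real_) {
  data.frame(chem_id = chem_id, endpoint_id = endpoint_id, ac50_uM = ac50,
             efficacy_pct = eff, curve_class = cls, converged = converged,
             burst_cutoff_uM = burst, stringsAsFactors = FALSE)
}

# Hit-call table from explicit active endpoint memberships.
hits_from_membership <- function(membership) {
  eps <- interference_endpoints()$endpoint_id
  do.call(rbind, lapply(names(membership), function(cid) {
    data.frame(chem_id = cid, endpoint_id = eps,
               active = eps %in% membership[[cid]],
               reasons = ifelse(eps %in% membership[[cid]], "", "class_fail"),
               stringsAsFactors = FALSE)
  }))
}
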