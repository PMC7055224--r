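#' Coordinated undersampling of the inactive class
#'
#' Builds the modeling subsets for the ensemble repetitions: every subset
#' keeps all actives and draws inactives without replacement so that
#' inactives make up `inactive_ratio` of the subset (default 70% inactive /
#' 30% active). Sampling is coordinated across repetitions: inactives are
#' consumed from one seeded shuffle until exhausted, then the pool is
#' refreshed, so that the union of the subsets covers the full inactive set
#' whenever enough repetitions are run.
#'
#' @param labels Named logical vector (`TRUE` = active), names = chem ids.
#' @param n_reps Number of repetitions (default 10).
#' @param inactive_ratio Target inactive share of each subset (default 0.7).
#' @param seed Integer seed.
#' @return List of length `n_reps`; each element a character vector of chem
#'   ids (all actives + that repetition's inactives).
#' @export
undersample <- function(labels, n_reps = 10L, inactive_ratio = 0.7, seed = 1L) {
  stopifnot(is.logical(labels), !is.null(names(labels)),
            inactive_ratio > 0, inactive_ratio < 1)
  actives <- names(labels)[labels]
  inactives <- names(labels)[!labels]
  if (length(actives) == 0L || length(inactives) == 0L) {
    stop("undersample requires both classes to be non-empty")
  }
  n_inact <- round(length(actives) * inactive_ratio / (1 - inactive_ratio))
  set.seed(derive_seed(seed, "undersample"))
  if (n_inact >= length(inactives)) {
    warning("fewer inactives than the target ratio requires; keeping all")
    return(replicate(n_reps, c(actives, inactives), simplify = FALSE))
  }
  pool <- sample(inactives)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    if (length(pool) < n_inact) {
      # refresh: reshuffle inactives not already drawn into this repetition
      pool <- c(pool, sample(setdiff(inactives, pool)))
    }
    out[[r]] <- c(actives, pool[seq_len(n_inact)])
    pool <- pool[-seq_len(n_inact)]
  }
  out
}
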