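#' Derive a stream-specific seed from a global seed
#'
#' Every stochastic operation in the package takes an explicit seed. When a
#' whole run is driven from one global seed, per-operation seeds are derived
#' by a stable string hash of `(seed, name)` so that adding or reordering
#' stages never perturbs the random stream of another stage.
#'
#' @param seed Integer global seed.
#' @param name Character scalar naming the consuming operation
#'   (e.g. `"simulate_titration"`).
#' @return An integer in `[1, 2^31 - 2]`, stable across platforms.
#' @examples
#' derive_seed(1L, "undersample")
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer(h %% (m - 2) + 1)
}
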