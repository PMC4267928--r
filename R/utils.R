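#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer mixing so that every simulated dataset, design draw
#' and fold plan has its own reproducible stream. All arithmetic stays below
#' 2^31 so the result is a valid \code{set.seed()} argument.
#'
#' @param seed master seed (integer).
#' @param ... integer stream indices (e.g. scenario group, stage, dataset).
#' @return a single integer seed.
#' @export
#' @examples
#' mixSeed(1L, 3L, 42L)
mixSeed <- function(seed, ...) {
  idx <- as.integer(c(...))
  x <- as.double(abs(as.integer(seed)) %% 2146319567)
  for (k in idx) {
    x <- (x * 1103 + (abs(k) %% 65011) * 7919 + 104729) %% 2146319567
  }
  as.integer(x + 1)
}

## stable small integer from a character key (used to tie scenario groups
## sharing base datasets to the same stream regardless of run order)
keyToInt <- function(key) {
  v <- utf8ToInt(key)
  as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 65011)
}

#' Trace of Pu %*% A without forming Pu
#'
#' \code{Pu = (I - J/n)/(n - 1)} is the centering operator whose quadratic
#' form gives the expected sample variance; \code{trace(Pu A)} reduces to
#' \code{(trace(A) - sum(A)/n)/(n - 1)}.
#'
#' @param A square matrix.
#' @return \code{trace(Pu A)}.
#' @keywords internal
puTrace <- function(A) {
  n <- nrow(A)
  (sum(diag(A)) - sum(A) / n) / (n - 1)
}

## symmetrize to guard against accumulated asymmetry in matrix products
symm <- function(A) (A + t(A)) / 2

## safe Pearson correlation: NA when either side is (numerically) constant
safeCor <- function(x, y) {
  if (length(x) < 3L || anyNA(x) || anyNA(y)) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx <= 0 || sy <= 0) return(NA_real_)
  stats::cor(x, y)
}
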