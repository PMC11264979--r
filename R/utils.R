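# Internal helpers shared across modules.

#' @importFrom stats pnorm qnorm dnorm rnorm runif cor optimize uniroot
#'   ecdf ks.test t.test setNames rlnorm rbeta
#' @importFrom utils head
NULL

# Derive a reproducible sub-seed from a top-level seed and a stream name, so
# that adding a sampling stage never perturbs the draws of earlier stages.
# Plain polynomial hash folded into the 31-bit signed-integer range.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the ambient RNG in charge.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_binary_matrix <- function(x) {
  is.matrix(x) && all(x %in% c(0, 1))
}

# Symmetrize and check a square matrix intended as a correlation matrix.
check_correlation_matrix <- function(R, name = "correlation matrix",
                                     require_pd = TRUE) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop_input(name, " must be a square matrix")
  }
  if (max(abs(R - t(R))) > 1e-8) stop_input(name, " must be symmetric")
  if (require_pd) {
    ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop_input(name, " is not positive definite (min eigenvalue ",
                 format(min(ev)), "); smooth it first")
    }
  }
  invisible(TRUE)
}

# Draw n rows from MVN(0, R) using a pre-computed upper Cholesky factor.
rmvn_chol <- function(n, chol_R) {
  J <- ncol(chol_R)
  matrix(rnorm(n * J), n, J) %*% chol_R
}

# Half-up rounding to the nearest integer (round() in R rounds half to even).
round_half_up <- function(x) floor(x + 0.5)
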