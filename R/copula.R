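#' Convert a Spearman rank correlation to the latent Pearson correlation
#'
#' For bivariate normal data the population Spearman correlation
#' \eqn{\phi} and Pearson correlation \eqn{r} are linked by
#' \eqn{r = 2\sin(\pi\phi/6)}; this is the conversion applied to every
#' tie-broken rank correlation before averaging in
#' [estimate_copula_correlation()].
#'
#' @param phi Spearman correlation(s) in \eqn{[-1, 1]}.
#' @return Pearson correlation(s) of the latent normal.
#' @export
spearman_to_pearson <- function(phi) {
  if (any(abs(phi) > 1)) stop_input("phi must lie in [-1, 1]")
  2 * sin(pi * phi / 6)
}

#' Estimate the Gaussian-copula correlation from relative abundances
#'
#' Computes the correlation matrix of the latent Gaussian copula from the
#' template relative abundances, treating zero cells as tied at the bottom.
#' All ties (zeros included) are broken by `K` independent random orderings;
#' for each ordering the Spearman rank correlation \eqn{\phi^{(k)}} is
#' converted to the Pearson correlation of the latent normal via
#' \deqn{r^{(k)} = 2 \sin(\pi \phi^{(k)} / 6),}
#' and the `K` matrices are averaged. The average is corrected to be
#' positive definite by raising eigenvalues below a small positive floor
#' and rescaling all eigenvalues so the trace is preserved (the diagonal is
#' *not* re-normalized to 1; trace preservation is the contract here).
#'
#' @param pi_mat An n x J matrix of relative abundances (zeros allowed).
#' @param K Number of random tie-break orderings (default 100).
#' @param seed Optional integer seed making the tie-breaking reproducible.
#' @param eig_floor Relative eigenvalue floor for the positive-definite
#'   correction (default 1e-10 times the largest eigenvalue).
#' @return A positive-definite J x J matrix `r_star` with attributes
#'   `K` and `n_floored`.
#' @export
estimate_copula_correlation <- function(pi_mat, K = 100L, seed = NULL,
                                        eig_floor = 1e-10) {
  if (nrow(pi_mat) < 3) stop_input("need at least 3 samples for rank correlation")
  if (K < 1) stop_input("K must be >= 1")
  J <- ncol(pi_mat)
  acc <- matrix(0, J, J)
  with_seed(seed, {
    for (k in seq_len(K)) {
      ranks <- apply(pi_mat, 2L, rank, ties.method = "random")
      acc <- acc + spearman_to_pearson(stats::cor(ranks))
    }
  })
  r_star <- acc / K
  dimnames(r_star) <- list(colnames(pi_mat), colnames(pi_mat))
  pd_correct_trace(r_star, eig_floor = eig_floor, K = K)
}

# Positive-definite correction preserving the trace: eigenvalues below the
# floor are raised to it, then all eigenvalues are rescaled so the total
# (trace) matches the input matrix.
pd_correct_trace <- function(R, eig_floor = 1e-10, K = NULL) {
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  floor_abs <- eig_floor * max(eig$values)
  n_floored <- sum(eig$values < floor_abs)
  lam <- pmax(eig$values, floor_abs)
  lam <- lam * sum(diag(R)) / sum(lam)
  out <- eig$vectors %*% (lam * t(eig$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(R)
  attr(out, "n_floored") <- n_floored
  if (!is.null(K)) attr(out, "K") <- as.integer(K)
  out
}

#' Fill present cells with empirical non-zero relative abundances
#'
#' For each taxon, draws \eqn{\widetilde m_j} values from the template's
#' non-zero relative abundances (`marginals[[j]]`): without replacement
#' when \eqn{\widetilde m_j \le m_j} (mimicking a permutation of the
#' template values), otherwise all \eqn{m_j} template values plus
#' \eqn{\widetilde m_j - m_j} extra draws with replacement. The drawn
#' values are then assigned to the present cells so that their ranking
#' matches the ranking of the Gaussian copula scores `W` among those cells
#' (ties in `W` broken by cell index).
#'
#' @param W n_sim x J matrix of Gaussian copula scores, drawn from
#'   MVN(0, r_star).
#' @param Z n_sim x J binary presence matrix.
#' @param marginals List of length J; element j holds taxon j's observed
#'   non-zero relative abundances.
#' @param m Length-J vector of template non-zero counts (lengths of
#'   `marginals`).
#' @param seed Optional integer seed.
#' @return An n_sim x J matrix of raw relative abundances (zero where
#'   `Z == 0`); rows are not yet normalized.
#' @export
assign_nonzero_abundances_empirical <- function(W, Z, marginals, m,
                                                seed = NULL) {
  stopifnot(all(dim(W) == dim(Z)))
  J <- ncol(Z)
  out <- matrix(0, nrow(Z), J, dimnames = dimnames(Z))
  with_seed(seed, {
    for (j in seq_len(J)) {
      idx <- which(Z[, j] == 1)
      mt <- length(idx)
      if (mt == 0L) next
      vals <- marginals[[j]]
      mj <- length(vals)
      if (mj == 0L) {
        stop_input("taxon ", j, " is present in the simulation but has no ",
                   "non-zero template values")
      }
      drawn <- if (mt <= mj) {
        vals[sample.int(mj, mt)]
      } else {
        c(vals, vals[sample.int(mj, mt - mj, replace = TRUE)])
      }
      out[idx[order(W[idx, j])], j] <- sort(drawn)
    }
  })
  out
}

#' Convert raw relative abundances to integer counts
#'
#' Multiplies each row of raw relative abundances by its target library
#' size; products strictly between 0 and 1 are rounded up to 1 (so the
#' presence-absence structure is preserved), all other products are rounded
#' to the nearest integer (half up). Realized library sizes are the row
#' sums of the rounded counts and the final relative abundances are
#' re-normalized by them.
#'
#' @param pi_raw n_sim x J matrix of non-negative raw relative abundances.
#' @param N Length-n_sim vector of positive target library sizes.
#' @return List with `counts` (integer matrix), `lib_sizes` (realized
#'   \eqn{\widetilde N_i}), and `rel_abund` (rows summing to 1; an all-zero
#'   row stays zero).
#' @export
relabund_to_counts <- function(pi_raw, N) {
  if (any(N <= 0)) stop_input("library sizes must be positive")
  if (any(pi_raw < 0)) stop_input("relative abundances must be non-negative")
  stopifnot(length(N) == nrow(pi_raw))
  raw <- pi_raw * N
  counts <- round_half_up(raw)
  counts[raw > 0 & raw < 1] <- 1
  lib <- rowSums(counts)
  rel <- counts / ifelse(lib > 0, lib, 1)
  list(counts = counts, lib_sizes = lib, rel_abund = rel)
}

#' Power-adjust a taxon's non-zero abundances toward a target mean
#'
#' Finds the exponent \eqn{\alpha} such that the transformed values
#' \eqn{v^\alpha} have a given mean. For values in (0,1) the mean of
#' \eqn{v^\alpha} is strictly decreasing in \eqn{\alpha}, so the root is
#' unique; it is found by bracketed root finding.
#'
#' @param values Non-empty vector of non-zero relative abundances in (0,1).
#' @param target_mean Target mean in (0,1).
#' @return List with `alpha` and `values` (the transformed vector).
#' @export
power_adjust_marginal <- function(values, target_mean) {
  if (!length(values) || any(values <= 0 | values >= 1)) {
    stop_input("values must be non-empty and lie strictly in (0, 1)")
  }
  if (target_mean <= 0 || target_mean >= 1) {
    stop_input("target_mean must lie strictly in (0, 1)")
  }
  cur <- mean(values)
  if (abs(cur - target_mean) < 1e-15) {
    return(list(alpha = 1, values = values))
  }
  f <- function(a) mean(values^a) - target_mean
  root <- uniroot(f, c(1e-8, 1), extendInt = "downX", tol = 1e-12)$root
  list(alpha = root, values = values^root)
}
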