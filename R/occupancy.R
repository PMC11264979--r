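#' Fit the probit occupancy model to presence-absence margins
#'
#' Solves for taxon effects \eqn{\theta_j} and sample effects \eqn{\eta_i}
#' of the latent-threshold model \eqn{Z_{ij} = I(D_{ij} > 0)},
#' \eqn{D_{ij} \sim N(\theta_j + \eta_i, 1)}, so that the expected margins
#' match the observed non-zero cell counts:
#' \deqn{\sum_i \Phi(\theta_j + \eta_i) = m_j, \qquad
#'       \sum_j \Phi(\theta_j + \eta_i) = n_i.}
#' The two margin equations are iterated alternately from
#' \eqn{\eta_i = 0}, \eqn{\theta_j = \Phi^{-1}(m_j/n)}; each coordinate
#' update is a strictly monotone scalar equation solved by safeguarded
#' Newton with a bisection fallback.
#'
#' Margin targets are clipped into `[0.5, n - 0.5]` (resp. `[0.5, J - 0.5]`)
#' before solving, because a margin of exactly 0 or n forces an infinite
#' effect. If, after clipping, the two margin totals disagree (only possible
#' for user-modified margins; both totals must equal the same grand total),
#' the sample targets are rescaled to restore consistency.
#'
#' @param m Length-J vector of per-taxon non-zero counts \eqn{m_j}.
#' @param n_counts Length-n vector of per-sample non-zero counts \eqn{n_i}.
#' @param tol Outer-loop tolerance on the maximum absolute margin residual
#'   (default 1e-6).
#' @param max_iter Maximum number of outer iterations (default 500).
#' @return List with `theta`, `eta`, `converged`, `residual` (max absolute
#'   margin error against the clipped targets), `iterations`, and the
#'   clipped targets `m_target`, `n_target`.
#' @export
fit_occupancy_probit <- function(m, n_counts, tol = 1e-6, max_iter = 500L) {
  J <- length(m)
  n <- length(n_counts)
  if (any(m < 0) || any(m > n)) stop_input("m_j must lie in [0, n]")
  if (any(n_counts < 0) || any(n_counts > J)) {
    stop_input("n_i must lie in [0, J]")
  }
  m_t <- pmin(pmax(m, 0.5), n - 0.5)
  n_t <- pmin(pmax(n_counts, 0.5), J - 0.5)
  if (abs(sum(m_t) - sum(n_t)) > 1e-9) {
    n_t <- n_t * sum(m_t) / sum(n_t)
  }

  eta <- rep(0, n)
  theta <- qnorm(m_t / n)

  # Solve sum_k Phi(x + off_k) = target for each row of a target vector,
  # vectorized safeguarded Newton: project into a per-element bracket and
  # bisect whenever the Newton step leaves it.
  solve_margin <- function(x, off, target, inner_tol = 1e-8) {
    lo <- rep(-12 - max(abs(off)), length(x))
    hi <- rep(12 + max(abs(off)), length(x))
    for (iter in 1:100) {
      P <- pnorm(outer(x, off, "+"))
      f <- rowSums(P) - target
      if (max(abs(f)) < inner_tol) break
      lo[f < 0] <- pmax(lo[f < 0], x[f < 0])
      hi[f > 0] <- pmin(hi[f > 0], x[f > 0])
      grad <- rowSums(dnorm(outer(x, off, "+")))
      step <- ifelse(grad > 1e-12, f / grad, sign(f))
      x_new <- x - step
      out <- x_new <= lo | x_new >= hi
      x_new[out] <- (lo[out] + hi[out]) / 2
      x <- x_new
    }
    x
  }

  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    theta <- solve_margin(theta, eta, m_t)
    eta <- solve_margin(eta, theta, n_t)
    P <- pnorm(outer(eta, theta, "+"))
    residual <- max(max(abs(colSums(P) - m_t)), max(abs(rowSums(P) - n_t)))
    if (residual < tol) break
  }
  converged <- residual < tol
  if (!converged) {
    warning("occupancy margin fit did not converge: residual ",
            format(residual), " after ", iter, " iterations")
  }
  list(theta = setNames(theta, names(m)), eta = setNames(eta, names(n_counts)),
       converged = converged, residual = residual, iterations = iter,
       m_target = m_t, n_target = n_t)
}

#' Pairwise tetrachoric correlation of a binary matrix
#'
#' For each pair of columns, estimates the latent bivariate-normal
#' correlation whose dichotomization at the margin-implied thresholds
#' maximizes the likelihood of the observed 2x2 table (pairwise maximum
#' likelihood, thresholds fixed at \eqn{\Phi^{-1}} of the column means).
#' Perfectly concordant pairs (both off-diagonal cells empty) return 1 and
#' perfectly discordant pairs return -1; otherwise empty cells receive a
#' +0.5 continuity correction before the likelihood is evaluated.
#' Degenerate pairs (a constant column) return 0.
#'
#' @param Z An n x J binary matrix.
#' @return A symmetric J x J matrix of tetrachoric correlations with unit
#'   diagonal (generally not positive definite; see
#'   [smooth_to_pd_correlation()]).
#' @export
estimate_tetrachoric <- function(Z) {
  if (!is_binary_matrix(Z)) stop_input("Z must be a binary matrix")
  n <- nrow(Z)
  J <- ncol(Z)
  p <- colMeans(Z)
  tau <- qnorm(1 - p)  # latent X > tau  <=>  Z = 1
  zeta <- diag(1, J)
  dimnames(zeta) <- list(colnames(Z), colnames(Z))
  if (J < 2L) return(zeta)
  cross <- crossprod(Z)  # a: 1-1 counts
  ones <- colSums(Z)
  for (j in 1:(J - 1L)) {
    for (l in (j + 1L):J) {
      a <- cross[j, l]
      b <- ones[j] - a
      cc <- ones[l] - a
      d <- n - a - b - cc
      zeta[j, l] <- zeta[l, j] <-
        tetrachoric_pair(a, b, cc, d, tau[j], tau[l])
    }
  }
  zeta
}

# ML estimate of the latent correlation for one 2x2 table with fixed
# thresholds. Cells: a = both present, b = first only, c = second only,
# d = both absent.
tetrachoric_pair <- function(a, b, cc, d, tau1, tau2) {
  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) {
    return(0)  # degenerate: a constant column
  }
  if (b == 0 && cc == 0) return(1)
  if (a == 0 && d == 0) return(-1)
  counts <- c(a, b, cc, d)
  counts[counts == 0] <- 0.5  # continuity correction on empty cells
  negll <- function(rho) {
    p11 <- mvtnorm::pmvnorm(lower = c(tau1, tau2), upper = c(Inf, Inf),
                            corr = matrix(c(1, rho, rho, 1), 2))[1]
    p1_ <- pnorm(tau1, lower.tail = FALSE)
    p_1 <- pnorm(tau2, lower.tail = FALSE)
    pr <- c(p11, p1_ - p11, p_1 - p11, 1 - p1_ - p_1 + p11)
    pr <- pmax(pr, 1e-12)
    -sum(counts * log(pr))
  }
  optimize(negll, c(-0.999, 0.999), tol = 1e-4)$minimum
}

#' Smooth a symmetric matrix to a positive-definite correlation matrix
#'
#' Eigenvalues below `eig_floor` (relative to the largest eigenvalue) are
#' raised to the floor, the matrix is reconstructed, and it is rescaled to
#' unit diagonal so the result is a valid correlation matrix. Matrices that
#' are already positive definite with unit diagonal are returned unchanged.
#'
#' @param zeta Symmetric J x J matrix (e.g. a raw tetrachoric matrix).
#' @param eig_floor Relative eigenvalue floor (default 1e-6 times the
#'   largest eigenvalue).
#' @return A positive-definite correlation matrix with unit diagonal. The
#'   number of floored eigenvalues is attached as attribute `n_floored`.
#' @export
smooth_to_pd_correlation <- function(zeta, eig_floor = 1e-6) {
  check_correlation_matrix(zeta, "zeta", require_pd = FALSE)
  eig <- eigen((zeta + t(zeta)) / 2, symmetric = TRUE)
  floor_abs <- eig_floor * max(eig$values)
  n_floored <- sum(eig$values < floor_abs)
  if (n_floored == 0L && max(abs(diag(zeta) - 1)) < 1e-12) {
    attr(zeta, "n_floored") <- 0L
    return(zeta)
  }
  lam <- pmax(eig$values, floor_abs)
  R <- eig$vectors %*% (lam * t(eig$vectors))
  s <- 1 / sqrt(diag(R))
  R <- R * tcrossprod(s)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- dimnames(zeta)
  attr(R, "n_floored") <- n_floored
  R
}

#' Sample presence-absence matrices from the fitted occupancy model
#'
#' `sample_presence_nonparametric()` draws latent rows
#' \eqn{D_i \sim MVN(\theta + \eta_i, \rho)} and sets
#' \eqn{Z_{ij} = I(D_{ij} > 0)}. When `n_sim` differs from the template
#' size, sample effects are taken from `eta_pool` by resampling (with
#' replacement when `n_sim` exceeds the pool, without when smaller).
#' Alternatively supply `eta` directly (e.g. to keep sample effects aligned
#' with resampled library sizes).
#'
#' @param theta Length-J taxon effects.
#' @param eta_pool Length-n pool of sample effects.
#' @param rho Positive-definite J x J correlation matrix.
#' @param n_sim Number of samples to draw.
#' @param seed Optional integer seed.
#' @param eta Optional explicit length-`n_sim` vector of sample effects
#'   overriding the pool-resampling rule.
#' @return An `n_sim` x J binary matrix.
#' @export
sample_presence_nonparametric <- function(theta, eta_pool, rho, n_sim,
                                          seed = NULL, eta = NULL) {
  check_correlation_matrix(rho, "rho")
  if (n_sim < 1) stop_input("n_sim must be >= 1")
  with_seed(seed, {
    if (is.null(eta)) {
      eta <- if (n_sim == length(eta_pool)) {
        eta_pool
      } else {
        sample(eta_pool, n_sim, replace = n_sim > length(eta_pool))
      }
    }
    stopifnot(length(eta) == n_sim)
    D <- rmvn_chol(n_sim, chol(rho)) +
      outer(eta, theta, "+")
    (D > 0) * 1
  })
}

#' @rdname sample_presence_nonparametric
#' @param prob_nonzero An `n_sim` x J matrix of marginal non-zero
#'   probabilities (in parametric mode, \eqn{F_j(N_i)}). Latent rows are
#'   drawn as \eqn{D_i \sim MVN(0, \rho)} and thresholded at
#'   \eqn{\Phi^{-1}(1 - prob)}, so each cell's marginal presence
#'   probability equals its entry.
#' @export
sample_presence_parametric <- function(prob_nonzero, rho, seed = NULL) {
  check_correlation_matrix(rho, "rho")
  if (any(prob_nonzero < 0 | prob_nonzero > 1)) {
    stop_input("prob_nonzero entries must lie in [0, 1]")
  }
  with_seed(seed, {
    D <- rmvn_chol(nrow(prob_nonzero), chol(rho))
    (D > qnorm(1 - prob_nonzero)) * 1
  })
}
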