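test_that("constant margins give exchangeable solution with exact fit", {
  n <- 12; J <- 4; m_per <- 6
  fit <- fit_occupancy_probit(rep(m_per, J), rep(m_per * J / J, n) * J / n)
  # all m_j equal and all n_i equal: eta all equal, fitted probs m/n
  expect_lt(diff(range(fit$eta)), 1e-6)
  P <- pnorm(outer(fit$eta, fit$theta, "+"))
  expect_equal(unname(P[1, 1]), m_per / n, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("margin equations hold to tolerance and match an independent solver", {
  rm <- random_margins(7)
  fit <- fit_occupancy_probit(rm$m, rm$n_i, tol = 1e-7)
  P <- pnorm(outer(fit$eta, fit$theta, "+"))
  expect_lt(max(abs(colSums(P) - fit$m_target)), 1e-6)
  expect_lt(max(abs(rowSums(P) - fit$n_target)), 1e-6)

  # independent general-purpose solver on the same system (gauge fixed by
  # eta_1 = 0 is unnecessary: compare fitted cell probabilities)
  n <- length(rm$n_i); J <- length(rm$m)
  obj <- function(par) {
    th <- par[1:J]; et <- par[J + (1:n)]
    Pm <- pnorm(outer(et, th, "+"))
    sum((colSums(Pm) - fit$m_target)^2) + sum((rowSums(Pm) - fit$n_target)^2)
  }
  opt <- optim(c(fit$theta * 0, fit$eta * 0), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  P2 <- pnorm(outer(opt$par[J + (1:n)], opt$par[1:J], "+"))
  expect_lt(max(abs(P2 - P)), 1e-2)
})

test_that("boundary margins are clipped to finite effects", {
  n <- 10
  m <- c(10, 5, 3)   # first taxon always present
  Z_n <- c(rep(2, 8), c(1, 1))
  fit <- fit_occupancy_probit(m, Z_n)
  expect_true(all(is.finite(fit$theta)))
  P <- pnorm(outer(fit$eta, fit$theta, "+"))
  expect_equal(unname(colSums(P)[1]), n - 0.5, tolerance = 1e-5)
})

test_that("tetrachoric estimator handles perfect, simulated, and independent pairs", {
  withr::with_seed(11, {
    z <- rbinom(40, 1, 0.5)
    z[1] <- 1; z[2] <- 0
    expect_equal(estimate_tetrachoric(cbind(z, z))[1, 2], 1)
    expect_equal(estimate_tetrachoric(cbind(z, 1 - z))[1, 2], -1)

    # dichotomized bivariate normal with latent correlation 0.5
    n <- 50000
    x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
    Z <- cbind(as.integer(x > 0), as.integer(y > 0))
    expect_equal(estimate_tetrachoric(Z)[1, 2], 0.5, tolerance = 0.03)

    # independent fair coins
    Zi <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    expect_lt(abs(estimate_tetrachoric(Zi)[1, 2]), 0.05)

    # constant column is degenerate: correlation 0
    expect_equal(estimate_tetrachoric(cbind(z, rep(1, 40)))[1, 2], 0)
  })
})

test_that("tetrachoric estimate is symmetric and sign-preserving under relabeling", {
  rm <- random_margins(5, n = 80, J = 4)
  zeta <- estimate_tetrachoric(rm$Z)
  expect_equal(zeta, t(zeta))
  # relabeling 0<->1 in both columns of a pair preserves the correlation
  Z2 <- rm$Z
  Z2[, 1:2] <- 1 - Z2[, 1:2]
  zeta2 <- estimate_tetrachoric(Z2)
  expect_equal(zeta2[1, 2], zeta[1, 2], tolerance = 1e-6)
})

test_that("smooth_to_pd_correlation floors eigenvalues and preserves PD input", {
  R <- diag(3)
  expect_equal(smooth_to_pd_correlation(R), R, ignore_attr = TRUE)

  ok <- matrix(c(1, .3, .1, .3, 1, .2, .1, .2, 1), 3)
  expect_equal(smooth_to_pd_correlation(ok), ok, ignore_attr = TRUE,
               tolerance = 1e-12)

  bad <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3)  # indefinite
  sm <- smooth_to_pd_correlation(bad, eig_floor = 1e-6)
  ev <- eigen(sm, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)
  expect_equal(diag(sm), rep(1, 3))
  expect_gt(attr(sm, "n_floored"), 0)
})

test_that("nonparametric presence sampling is calibrated and deterministic", {
  withr::with_seed(21, {
    # rho = identity, theta + eta = 0: independent Bernoulli(1/2) cells
    Z <- sample_presence_nonparametric(rep(0, 5), rep(0, 4), diag(5),
                                       n_sim = 10000, seed = 9)
    expect_equal(unname(colMeans(Z)), rep(0.5, 5), tolerance = 0.02)

    # expected column sums track the fitted margins
    rm <- random_margins(13)
    fit <- fit_occupancy_probit(rm$m, rm$n_i)
    R <- 50
    csum <- matrix(0, R, length(rm$m))
    for (r in seq_len(R)) {
      Zs <- sample_presence_nonparametric(fit$theta, fit$eta, diag(10),
                                          n_sim = 20, seed = 1000 + r)
      csum[r, ] <- colSums(Zs)
    }
    se <- apply(csum, 2, sd) / sqrt(R)
    expect_true(all(abs(colMeans(csum) - rm$m) <= 3 * pmax(se, 0.05)))
  })
  Z1 <- sample_presence_nonparametric(rep(0, 3), rep(0, 2), diag(3), 5, seed = 4)
  Z2 <- sample_presence_nonparametric(rep(0, 3), rep(0, 2), diag(3), 5, seed = 4)
  expect_identical(Z1, Z2)
})

test_that("parametric presence sampling honours per-cell probabilities", {
  P1 <- matrix(1, 20, 3)
  expect_true(all(sample_presence_parametric(P1, diag(3), seed = 1) == 1))

  P <- matrix(0.3, 2000, 5)
  Z <- sample_presence_parametric(P, diag(5), seed = 2)
  expect_equal(mean(Z), 0.3, tolerance = 0.015)

  # column-sum expectation equals the summed probabilities
  withr::with_seed(31, {
    Pv <- matrix(runif(50 * 4), 50, 4)
    R <- 50
    csum <- matrix(0, R, 4)
    for (r in seq_len(R)) {
      csum[r, ] <- colSums(sample_presence_parametric(Pv, diag(4),
                                                      seed = 2000 + r))
    }
    se <- apply(csum, 2, sd) / sqrt(R)
    expect_true(all(abs(colMeans(csum) - colSums(Pv)) <= 3 * se))
  })
  expect_error(sample_presence_parametric(matrix(0.5, 2, 2),
                                          matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("permuting taxa permutes the fit and samples coherently", {
  rm <- random_margins(17, n = 15, J = 6)
  fit <- fit_occupancy_probit(rm$m, rm$n_i)
  perm <- c(3, 1, 6, 2, 5, 4)
  fit_p <- fit_occupancy_probit(rm$m[perm], rm$n_i)
  expect_equal(unname(fit_p$theta), unname(fit$theta[perm]), tolerance = 1e-5)
  # the tetrachoric matrix permutes coherently too
  zeta <- estimate_tetrachoric(rm$Z)
  zeta_p <- estimate_tetrachoric(rm$Z[, perm])
  expect_equal(unname(zeta_p), unname(zeta[perm, perm]), tolerance = 1e-6)
})
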