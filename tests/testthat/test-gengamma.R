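test_that("CDF matches lognormal and exponential special cases", {
  # Q = 0 is lognormal: median at t = exp(-mu)
  expect_equal(gengamma_cdf(1, mu = 0, sigma = 1, Q = 0), 0.5)
  expect_equal(gengamma_cdf(exp(2), mu = -2, sigma = 1.5, Q = 0), 0.5)
  tg <- c(0.2, 1, 5)
  expect_equal(gengamma_cdf(tg, mu = 0.7, sigma = 1.2, Q = 0),
               plnorm(tg, meanlog = -0.7, sdlog = 1.2), tolerance = 1e-12)
  # Q = 1, sigma = 1, mu = 0 is Exp(1)
  expect_equal(gengamma_cdf(1, 0, 1, 1), 1 - exp(-1), tolerance = 1e-10)
  expect_error(gengamma_cdf(-1, 0, 1, 0), "positive")
})

test_that("CDF agrees with Monte-Carlo draws for non-zero shapes", {
  withr::with_seed(2, {
    for (Q in c(-0.25, 0.25)) {
      t <- flexsurv::rgengamma(1e5, mu = -0.4, sigma = 0.8, Q = Q)  # our mu = 0.4
      ks <- max(abs(ecdf(t)(t) - gengamma_cdf(t, 0.4, 0.8, Q)))
      expect_lt(ks, 0.01)
    }
  })
})

test_that("quantile/CDF round trip and continuity at Q = 0", {
  grid <- expand.grid(mu = c(-2, 0, 3), sigma = c(0.4, 1.3),
                      Q = c(-1, -1e-5, 0, 1e-5, 0.7))
  p <- c(1e-6, 0.01, 0.5, 0.99, 1 - 1e-6)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    q <- gengamma_quantile(p, g$mu, g$sigma, g$Q)
    expect_equal(gengamma_cdf(q, g$mu, g$sigma, g$Q), p, tolerance = 1e-10)
  }
  tg <- exp(seq(-4, 4, length.out = 30))
  for (Qeps in c(-1e-5, 1e-5)) {
    expect_lt(max(abs(gengamma_cdf(tg, 0.3, 0.9, Qeps) -
                        gengamma_cdf(tg, 0.3, 0.9, 0))), 1e-3)
  }
})

test_that("moment formula matches closed forms and Monte Carlo", {
  # lognormal closed form
  expect_equal(gengamma_moment(-1, 0, 1, 0), exp(0.5), tolerance = 1e-12)
  # hand-derived value: Q=0.5, sigma=0.5, mu=0, r=-1 -> 4/3
  expect_equal(gengamma_moment(-1, 0, 0.5, 0.5), 4 / 3, tolerance = 1e-12)
  # nonexistent moment errors with the constraint named
  expect_error(gengamma_moment(-1, 0, 1, 1), "does not exist")

  withr::with_seed(4, {
    cases <- list(c(0.5, 0.8, -0.6, -1), c(-1, 0.6, 0.4, -2),
                  c(0, 1, 0, -1), c(1, 0.5, 0.9, 1))
    for (cs in cases) {
      mu <- cs[1]; sig <- cs[2]; Q <- cs[3]; r <- cs[4]
      t <- flexsurv::rgengamma(2e5, mu = -mu, sigma = sig, Q = Q)
      mc <- t^r
      se <- sd(mc) / sqrt(length(mc))
      expect_lt(abs(gengamma_moment(r, mu, sig, Q) - mean(mc)), 3 * se)
    }
  })
})

test_that("moment fit recovers parameters under genuine censoring", {
  # a rare-taxon regime: ~13% of survival times exceed the library size
  withr::with_seed(6, {
    truth <- c(mu = -8.5, sigma = 0.8, Q = 0.5)
    t <- flexsurv::rgengamma(5000, mu = 8.5, sigma = 0.8, Q = 0.5)
    N <- rep(1e4, 5000)
    pi_col <- ifelse(t > N, 0, 1 / t)
    expect_gt(mean(pi_col == 0), 0.05)
    fit <- fit_gengamma_moments(pi_col, N)
    expect_equal(fit$mu, truth[["mu"]], tolerance = 0.1 * abs(truth[["mu"]]))
    expect_equal(fit$sigma, truth[["sigma"]], tolerance = 0.1 * truth[["sigma"]])
    expect_equal(fit$Q, truth[["Q"]], tolerance = 0.35)
  })
})

test_that("fitted model matches the empirical first moment by construction", {
  withr::with_seed(7, {
    t <- flexsurv::rgengamma(2000, mu = 9, sigma = 1.1, Q = -0.3)
    N <- round(runif(2000, 5e3, 5e4))
    pi_col <- ifelse(t > N, 0, 1 / t)
    fit <- suppressWarnings(fit_gengamma_moments(pi_col, N))
    implied <- gengamma_moment(-1, fit$mu, fit$sigma, fit$Q)
    expect_equal(implied, mean(pi_col), tolerance = 1e-8)
    expect_lt(abs(fit$moment_resid[["m1"]]), 1e-8)
  })
  expect_error(fit_gengamma_moments(rep(0.2, 10), rep(100, 10)),
               "coefficient of variation")
  expect_error(fit_gengamma_moments(rep(0, 5), rep(100, 5)), "non-zero")
})

test_that("predicted prevalence tracks observed non-zero counts across the
           abundance spectrum", {
  syn <- make_synthetic_template(n_samples = 400, n_taxa = 50, n_dominant = 4,
                                 zero_fraction = 0.6, seed = 17)
  ct <- filter_template(syn$ct, 0, 4)
  s <- summarize_template(ct)
  fits <- suppressWarnings(
    lapply(seq_along(ct$taxon_ids),
           function(j) fit_gengamma_moments(s$rel_abund[, j], s$lib_sizes)))
  pred <- vapply(fits, function(f) sum(prob_nonzero(s$lib_sizes, f)),
                 numeric(1))
  obs <- s$taxon_nonzero_counts
  ord <- order(obs)
  sel <- unique(c(head(ord, 10), utils::tail(ord, 10)))
  rel <- abs(pred[sel] - obs[sel]) / obs[sel]
  expect_lt(stats::median(rel), 0.15)
})

test_that("prob_nonzero is a monotone CDF limit", {
  f <- list(mu = -7, sigma = 1, Q = 0.4)
  expect_equal(prob_nonzero(1e12, f), 1, tolerance = 1e-6)
  Ns <- c(100, 1e3, 1e4, 1e5)
  p <- prob_nonzero(Ns, f)
  expect_true(all(diff(p) >= 0))
  expect_true(all(prob_nonzero(2 * Ns, f) >= p))
  # lognormal median identity: mu with median t = N gives 1/2
  Nq <- 5000
  expect_equal(prob_nonzero(Nq, list(mu = -log(Nq), sigma = 0.7, Q = 0)), 0.5)
})

test_that("truncated sampling matches the truncated CDF and inverts exactly", {
  f <- list(mu = -7.5, sigma = 0.9, Q = 0.3)
  N <- 1e4
  # u -> 1 approaches the truncation boundary pi = 1/N
  expect_equal(sample_truncated_abundance(f, N, 1 - 1e-12), 1 / N,
               tolerance = 1e-6)
  # inverse round trip at a known t0
  t0 <- 2500
  u0 <- gengamma_cdf(t0, f$mu, f$sigma, f$Q) / prob_nonzero(N, f)
  expect_equal(sample_truncated_abundance(f, N, u0), 1 / t0, tolerance = 1e-8)
  # all draws respect the truncation bound
  withr::with_seed(9, {
    u <- runif(1e5)
    pi_s <- sample_truncated_abundance(f, N, u)
    expect_true(all(pi_s >= 1 / N))
    t_s <- 1 / pi_s
    FN <- prob_nonzero(N, f)
    ks <- max(abs(ecdf(t_s)(t_s) -
                    gengamma_cdf(t_s, f$mu, f$sigma, f$Q) / FN))
    expect_lt(ks, 0.01)
  })
  expect_error(sample_truncated_abundance(f, N, 1.5), "strictly in")
})
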