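test_that("compositional covariate effect matches the worked example and the simplex", {
  p0 <- c(0.5, 0.3, 0.2)
  # null covariates reproduce the baseline exactly
  expect_equal(covariate_effect_relabund(p0, 0, 0, 1, 1, 1, 2), p0)
  expect_equal(covariate_effect_relabund(p0, 1, 1, 0, 0, 1, 2), p0)

  p <- covariate_effect_relabund(p0, X1 = 1, X2 = 0, beta1 = 1, beta2 = 1,
                                 M1 = 1, M2 = 3)
  expect_equal(p[1], 0.5 * exp(1) / (0.5 * exp(1) + 0.5), tolerance = 1e-12)
  expect_equal(p[2], 0.3 / (0.5 * exp(1) + 0.5), tolerance = 1e-4)
  expect_equal(p[3], 0.2 / (0.5 * exp(1) + 0.5), tolerance = 1e-4)
  expect_equal(sum(p), 1)

  # simplex preserved for arbitrary effects and groups
  withr::with_seed(3, {
    for (rep in 1:10) {
      J <- sample(5:30, 1)
      p0r <- prop.table(runif(J))
      pr <- covariate_effect_relabund(p0r, sample(0:1, 1), sample(0:1, 1),
                                      rnorm(1), rnorm(1),
                                      sample(J, 3), sample(J, 4))
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr > 0))
    }
  })
})

test_that("benchmark design builds four equal groups with the configured overlap", {
  withr::with_seed(5, {
    p0 <- prop.table(rgamma(120, 0.5))
  })
  d <- build_da_design(200, p0, n_causal_1 = 10, n_causal_2 = 10,
                       overlap = 5, beta1 = 1.5, top_pool = 100, seed = 9)
  tab <- table(d$X1, d$X2)
  expect_true(all(tab == 50))
  expect_equal(length(intersect(d$M1, d$M2)), 5)
  pool <- order(p0, decreasing = TRUE)[1:100]
  expect_true(all(c(d$M1, d$M2) %in% pool))
  d2 <- build_da_design(200, p0, overlap = 5, beta1 = 1.5, seed = 9)
  expect_identical(d, d2)
  expect_error(build_da_design(200, p0, n_causal_1 = 4, overlap = 5, seed = 1),
               "overlap")
  expect_error(build_da_design(201, p0, seed = 1), "divisible by 4")
})

test_that("parametric mean targets shift locations log-linearly and round-trip", {
  ct <- small_template(seed = 44, n = 80, J = 20)
  mod <- suppressWarnings(micosim_fit(ct, "parametric", K = 20, seed = 1))
  p_cur <- vapply(mod$gengamma,
                  function(f) gengamma_moment(-1, f$mu, f$sigma, f$Q),
                  numeric(1))
  # round trip: targeting the implied mean leaves mu unchanged
  same <- apply_parametric_modifications(
    mod, modification_spec(new_mean_rel_abund = unname(p_cur)))
  expect_equal(vapply(same$gengamma, `[[`, numeric(1), "mu"),
               vapply(mod$gengamma, `[[`, numeric(1), "mu"),
               tolerance = 1e-8)
  # scaling every target by c shifts every mu by exactly log(c)
  up <- apply_parametric_modifications(
    mod, modification_spec(new_mean_rel_abund = unname(pmin(p_cur * 1.7, 0.99))))
  shift <- vapply(up$gengamma, `[[`, numeric(1), "mu") -
    vapply(mod$gengamma, `[[`, numeric(1), "mu")
  expect_equal(unname(shift[p_cur * 1.7 < 0.99]),
               rep(log(1.7), sum(p_cur * 1.7 < 0.99)), tolerance = 1e-8)
  # doubled library sizes never decrease any presence probability
  N <- summarize_template(ct)$lib_sizes
  for (f in mod$gengamma) {
    expect_true(all(prob_nonzero(2 * N, f) >= prob_nonzero(N, f)))
  }
  expect_error(apply_parametric_modifications(
    mod, modification_spec(new_prop_nonzero = rep(0.5, 20))),
    "nonparametric-mode")
})

test_that("nonparametric modifications rescale margins and power-adjust values", {
  ct <- small_template(seed = 45, n = 80, J = 20)
  mod <- micosim_fit(ct, "nonparametric", K = 20, seed = 1)

  # an empty spec is the identity
  expect_identical(apply_nonparametric_modifications(mod, modification_spec()),
                   mod)

  s <- mod$summary
  # halve delta with p fixed: the non-zero mean doubles, so alpha < 1 on
  # taxa where that doubled mean stays attainable (< 1)
  delta <- s$prop_nonzero
  p <- s$mean_rel_abund
  delta_new <- pmax(delta / 2, 0.01)
  p_new <- pmin(p, 0.9 * delta_new)
  sel <- p_new == p & delta_new == delta / 2
  expect_gt(sum(sel), 0)
  spec <- modification_spec(new_prop_nonzero = unname(delta_new),
                            new_mean_rel_abund = unname(p_new))
  mod2 <- suppressWarnings(apply_nonparametric_modifications(mod, spec))
  expect_true(all(mod2$alpha[sel] < 1))
  # margins refitted to the new targets
  n <- length(s$sample_ids)
  P <- pnorm(outer(mod2$occupancy$eta, mod2$occupancy$theta, "+"))
  m_new <- pmin(pmax(round(n * delta_new), 0.5), n - 0.5)
  expect_equal(unname(colSums(P)), unname(m_new), tolerance = 0.02)

  # changing library sizes demands explicit margins
  expect_error(apply_nonparametric_modifications(
    mod, modification_spec(new_lib_sizes = rep(5e3, n))),
    "new_taxon_margins")

  # doubling the sample count alone still simulates
  mod3 <- apply_nonparametric_modifications(
    mod, modification_spec(new_n_samples = 2 * n))
  sim <- micosim_simulate(mod3, seed = 4)
  expect_equal(nrow(sim$counts), 2 * n)
})

test_that("covariate designs leave the null group at baseline in simulation", {
  ct <- small_template(seed = 46, n = 60, J = 30)
  mod <- suppressWarnings(micosim_fit(ct, "parametric", K = 20, seed = 1))
  d <- build_da_design(80, mod, n_causal_1 = 5, n_causal_2 = 5, overlap = 2,
                       beta1 = 2, top_pool = 20, seed = 3)
  mod_d <- apply_parametric_modifications(mod, d)
  expect_equal(nrow(mod_d$mu_shift), 80)
  # null group rows have zero location shift (kappa(0,0) is a no-op)
  null_rows <- which(d$X1 == 0 & d$X2 == 0)
  expect_true(all(mod_d$mu_shift[null_rows, ] == 0))
  # causal taxa get beta1 minus the compositional normalizer in X1-only rows
  x1_rows <- which(d$X1 == 1 & d$X2 == 0)
  p1 <- covariate_effect_relabund(d$p0 / sum(d$p0), 1, 0, d$beta1, d$beta2,
                                  d$M1, d$M2)
  expect_equal(unname(mod_d$mu_shift[x1_rows[1], ]),
               unname(log(p1 / (d$p0 / sum(d$p0)))), tolerance = 1e-12)
  sim <- micosim_simulate(mod_d, seed = 8)
  expect_equal(nrow(sim$counts), 80)
  expect_equal(sim$metadata$X1, d$X1)
})
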