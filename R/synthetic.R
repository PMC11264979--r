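#' Generate a synthetic template count table with known structure
#'
#' Builds a count table from a fully specified generative model so that
#' every stage of the simulator can be tested against ground truth without
#' external data: latent Gaussian scores with a chosen taxon-taxon
#' correlation (exchangeable or block), per-taxon generalized-gamma
#' marginals on the inverse-abundance scale, log-normal library sizes, and
#' censoring of any abundance below one read (the same mechanism that
#' creates zeros in real sequencing data). Counts are rounded with the same
#' rules as [relabund_to_counts()].
#'
#' The community has the two-tier structure typical of real templates: a
#' small set of dominant taxa (`n_dominant`) with modest dispersion
#' (`dominant_sigma`) that are present in essentially every sample and
#' carry most of the read mass, plus a sparse remainder. Remainder taxa get
#' target prevalences drawn from a Beta distribution whose mean is set so
#' the overall expected zero fraction matches `zero_fraction`; each
#' taxon's location parameter is then pinned so its detection probability
#' at the reference library size equals its target prevalence. The
#' dominant taxa share whatever expected mass the remainder does not use,
#' so expected relative abundances sum to one and realized library sizes
#' track the drawn log-normal sizes.
#'
#' @param n_samples,n_taxa Table dimensions (defaults 150 x 100).
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters
#'   (defaults 9.2 and 0.5).
#' @param correlation `"block"` (default) or `"exchangeable"`.
#' @param cor_strength Within-block (or common) latent correlation
#'   (default 0.4).
#' @param n_blocks Number of equally sized blocks for `"block"`
#'   (default 5).
#' @param zero_fraction Target overall zero fraction in (0, 1)
#'   (default 0.85).
#' @param n_dominant Number of dominant mass-carrying taxa (default 5).
#' @param sigma_range Scale-parameter range for the sparse remainder
#'   (default \eqn{[1.5, 2.5]}; large dispersions are what give real rare
#'   taxa their intermittent detection).
#' @param dominant_sigma Scale-parameter range for dominant taxa
#'   (default \eqn{[0.3, 0.6]}).
#' @param q_range Shape-parameter range (uniform draw, default
#'   \eqn{[-0.5, 1]}; for `Q > 0`, `sigma` is capped below `0.95/(2Q)` so
#'   fitted moments exist).
#' @param prevalence_shape Beta concentration for remainder prevalences
#'   (default 2; smaller means more very rare taxa).
#' @param seed Optional integer seed; the same seed yields an identical
#'   table.
#' @return A list with `ct` (a [count_table]) and `truth` (list with
#'   `Sigma`, `mu`, `sigma`, `Q`, `p_target` (expected mean relative
#'   abundances), `delta_target` (target prevalences), `lib_sizes`,
#'   `taxon_ids`, `dominant` (index set)).
#' @export
make_synthetic_template <- function(n_samples = 150, n_taxa = 100,
                                    lib_meanlog = 9.2, lib_sdlog = 0.5,
                                    correlation = c("block", "exchangeable"),
                                    cor_strength = 0.4, n_blocks = 5,
                                    zero_fraction = 0.85,
                                    n_dominant = 5,
                                    sigma_range = c(1.5, 2.5),
                                    dominant_sigma = c(0.3, 0.6),
                                    q_range = c(-0.5, 1),
                                    prevalence_shape = 2,
                                    seed = NULL) {
  correlation <- match.arg(correlation)
  if (zero_fraction <= 0 || zero_fraction >= 1) {
    stop_input("zero_fraction must lie in (0, 1)")
  }
  if (n_dominant >= n_taxa) stop_input("n_dominant must be < n_taxa")
  J <- n_taxa
  n_rest <- J - n_dominant
  # overall mean prevalence 1 - zero_fraction; dominants are always present
  delta_rest_mean <- ((1 - zero_fraction) * J - n_dominant) / n_rest
  if (delta_rest_mean <= 0.01 || delta_rest_mean >= 0.95) {
    stop_input("infeasible zero_fraction (", zero_fraction, ") for ",
               n_dominant, " always-present dominant taxa among ", J,
               ": implied remainder prevalence ", signif(delta_rest_mean, 3))
  }
  Sigma <- synth_correlation(J, correlation, cor_strength, n_blocks)
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop_input("correlation settings do not yield a positive-definite matrix")
  }
  with_seed(seed, {
    N <- round_half_up(rlnorm(n_samples, lib_meanlog, lib_sdlog))
    N <- pmax(N, 100)
    N_ref <- exp(lib_meanlog)
    dom <- seq_len(n_dominant)
    rest <- setdiff(seq_len(J), dom)

    sigma <- Q <- mu <- numeric(J)
    sigma[dom] <- runif(n_dominant, dominant_sigma[1L], dominant_sigma[2L])
    Q[dom] <- runif(n_dominant, -0.3, 0.3)
    sigma[rest] <- runif(n_rest, sigma_range[1L], sigma_range[2L])
    Q[rest] <- runif(n_rest, q_range[1L], q_range[2L])
    sigma <- pmin(sigma, ifelse(Q > 0.05, 0.95 / (2 * Q), Inf))

    delta <- rep(1, J)
    delta[rest] <- rbeta(n_rest, prevalence_shape * delta_rest_mean,
                         prevalence_shape * (1 - delta_rest_mean))
    delta[rest] <- pmin(pmax(delta[rest], 0.01), 0.95)

    log_h <- vapply(seq_len(J), function(j) {
      log(gengamma_moment(-1, 0, sigma[j], Q[j]))
    }, numeric(1))
    # pin each remainder taxon's detection probability at N_ref
    mu[rest] <- vapply(rest, function(j) {
      q0 <- gengamma_quantile(delta[j], mu = 0, sigma = sigma[j], Q = Q[j])
      log(q0 / N_ref)
    }, numeric(1))
    mass_rest <- sum(exp(mu[rest] + log_h[rest]))
    if (mass_rest > 0.8) {
      # rare taxa would out-mass the community; scale them back and let
      # prevalence drift slightly below target
      mu[rest] <- mu[rest] + log(0.8 / mass_rest)
      mass_rest <- 0.8
    }
    mu[dom] <- log((1 - mass_rest) / n_dominant) - log_h[dom]

    W <- rmvn_chol(n_samples, chol(Sigma))
    U <- pmin(pmax(pnorm(W), 1e-12), 1 - 1e-12)
    pi_raw <- matrix(0, n_samples, J)
    for (j in seq_len(J)) {
      t_ij <- gengamma_quantile(U[, j], mu[j], sigma[j], Q[j])
      obs <- t_ij <= N  # censored (zero count) when t exceeds library size
      pi_raw[obs, j] <- 1 / t_ij[obs]
    }
    out <- relabund_to_counts(pi_raw, N)
    taxon_ids <- sprintf("taxon%03d", seq_len(J))
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
    dimnames(out$counts) <- list(sample_ids, taxon_ids)
    keep <- rowSums(out$counts) > 0
    ct <- count_table(out$counts[keep, , drop = FALSE])
    list(ct = ct,
         truth = list(Sigma = Sigma, mu = mu, sigma = sigma, Q = Q,
                      p_target = exp(mu + log_h),
                      delta_target = delta,
                      lib_sizes = N[keep], taxon_ids = taxon_ids,
                      dominant = dom))
  })
}

synth_correlation <- function(J, type, strength, n_blocks) {
  if (abs(strength) >= 1) stop_input("cor_strength must lie in (-1, 1)")
  if (type == "exchangeable") {
    S <- matrix(strength, J, J)
  } else {
    block <- rep(seq_len(n_blocks), length.out = J)
    block <- sort(block)
    S <- outer(block, block, function(a, b) ifelse(a == b, strength, 0))
  }
  diag(S) <- 1
  S
}
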