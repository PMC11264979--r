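#' Specify controlled changes to a fitted simulator model
#'
#' Collects the user-controllable deviations from the template: new library
#' sizes, new per-taxon mean relative abundances \eqn{p_j}, new per-taxon
#' non-zero proportions \eqn{\delta_j} (nonparametric mode only), a new
#' number of samples, and (nonparametric mode with changed library sizes)
#' explicit margin overrides \eqn{m_j}, \eqn{n_i}.
#'
#' @param new_lib_sizes Optional vector of positive library sizes.
#' @param new_mean_rel_abund Optional length-J vector of target \eqn{p_j}
#'   in (0, 1).
#' @param new_prop_nonzero Optional length-J vector of target \eqn{\delta_j}
#'   in (0, 1].
#' @param new_n_samples Optional integer.
#' @param new_taxon_margins,new_sample_margins Optional explicit \eqn{m_j} /
#'   \eqn{n_i} targets for the occupancy refit.
#' @return An object of class `modification_spec`.
#' @export
modification_spec <- function(new_lib_sizes = NULL, new_mean_rel_abund = NULL,
                              new_prop_nonzero = NULL, new_n_samples = NULL,
                              new_taxon_margins = NULL,
                              new_sample_margins = NULL) {
  if (!is.null(new_lib_sizes) && any(new_lib_sizes <= 0)) {
    stop_input("new_lib_sizes must be positive")
  }
  if (!is.null(new_mean_rel_abund) &&
      any(new_mean_rel_abund <= 0 | new_mean_rel_abund >= 1)) {
    stop_input("new_mean_rel_abund targets must lie strictly in (0, 1)")
  }
  if (!is.null(new_prop_nonzero) &&
      any(new_prop_nonzero <= 0 | new_prop_nonzero > 1)) {
    stop_input("new_prop_nonzero targets must lie in (0, 1]")
  }
  if (!is.null(new_n_samples) && new_n_samples < 1) {
    stop_input("new_n_samples must be >= 1")
  }
  structure(list(new_lib_sizes = new_lib_sizes,
                 new_mean_rel_abund = new_mean_rel_abund,
                 new_prop_nonzero = new_prop_nonzero,
                 new_n_samples = if (is.null(new_n_samples)) NULL
                                 else as.integer(new_n_samples),
                 new_taxon_margins = new_taxon_margins,
                 new_sample_margins = new_sample_margins),
            class = "modification_spec")
}

is_empty_spec <- function(spec) all(vapply(unclass(spec), is.null, logical(1)))

#' Covariate-shifted mean relative abundances under the compositional model
#'
#' Applies a log-linear effect of two binary covariates to selected "causal"
#' taxa and renormalizes to the simplex:
#' \deqn{p_j = \frac{\exp\{X_1\beta_1 I(j \in M_1) + X_2\beta_2 I(j \in M_2)\}\, p^0_j}
#'   {\sum_{j'} \exp\{\cdot\}\, p^0_{j'}}.}
#' Renormalization means every taxon's mean shifts, not only the causal
#' ones (the compositional null hypothesis); the log of the normalizer is
#' the location offset \eqn{\kappa(X_1, X_2)} applied to all taxa in
#' parametric mode.
#'
#' @param p0 Baseline mean relative abundances (length J, summing to 1).
#' @param X1,X2 Scalar 0/1 covariate values for the group.
#' @param beta1,beta2 Scalar log-scale effect sizes.
#' @param M1,M2 Integer index sets of causal taxa.
#' @return Length-J vector of group mean relative abundances (sums to 1).
#' @export
covariate_effect_relabund <- function(p0, X1, X2, beta1, beta2, M1, M2) {
  if (abs(sum(p0) - 1) > 1e-8) stop_input("p0 must sum to 1")
  lin <- numeric(length(p0))
  lin[M1] <- lin[M1] + X1 * beta1
  lin[M2] <- lin[M2] + X2 * beta2
  w <- exp(lin) * p0
  w / sum(w)
}

#' Build a two-covariate differential-abundance benchmark design
#'
#' Generates the standard benchmark layout: two balanced binary covariates
#' dividing `n_sim` samples into four equal groups, a set `M1` of causal
#' taxa for the first covariate and a set `M2` for the second, both drawn
#' from the `top_pool` most abundant taxa with a fixed overlap.
#'
#' @param n_sim Number of samples (must be divisible by 4).
#' @param model A fitted `micosim_model` (source of mean relative
#'   abundances), or a plain vector of mean relative abundances.
#' @param n_causal_1 Number of taxa affected by X1 (10 or 20 in the
#'   standard benchmark).
#' @param n_causal_2 Number of taxa affected by X2 (default 10).
#' @param overlap Number of taxa affected by both (default 5).
#' @param beta1 Effect size for X1 (standard grid: 0.5, 1, 1.5, 2).
#' @param beta2 Effect size for X2 (default 1, treated as a confounder).
#' @param top_pool Size of the high-abundance pool to draw causal taxa
#'   from (default 100).
#' @param seed Optional integer seed; the design is reproducible from it.
#' @return An object of class `covariate_design`: list with `X1`, `X2`
#'   (length `n_sim` binary vectors), `M1`, `M2`, `beta1`, `beta2`, and
#'   `p0` (the baseline means).
#' @export
build_da_design <- function(n_sim, model, n_causal_1 = 10, n_causal_2 = 10,
                            overlap = 5, beta1 = 1, beta2 = 1,
                            top_pool = 100, seed = NULL) {
  p0 <- if (inherits(model, "micosim_model")) {
    model$summary$mean_rel_abund
  } else {
    model
  }
  J <- length(p0)
  if (n_sim %% 4 != 0) stop_input("n_sim must be divisible by 4")
  if (J < top_pool) stop_input("model has fewer taxa than top_pool")
  if (overlap > min(n_causal_1, n_causal_2)) {
    stop_input("overlap cannot exceed the smaller causal set")
  }
  pool <- order(p0, decreasing = TRUE)[seq_len(top_pool)]
  with_seed(seed, {
    M1 <- sort(sample(pool, n_causal_1))
    shared <- sample(M1, overlap)
    M2 <- sort(c(shared, sample(setdiff(pool, M1), n_causal_2 - overlap)))
    g <- rep(1:4, each = n_sim / 4)
    structure(list(
      X1 = as.integer(g %in% c(2, 4)),
      X2 = as.integer(g %in% c(3, 4)),
      M1 = M1, M2 = M2, beta1 = beta1, beta2 = beta2,
      p0 = unname(p0)
    ), class = "covariate_design")
  })
}

#' @export
print.covariate_design <- function(x, ...) {
  cat("<covariate_design> n =", length(x$X1), "in 4 groups;",
      length(x$M1), "+", length(x$M2), "causal taxa, overlap",
      length(intersect(x$M1, x$M2)), "\n")
  invisible(x)
}

#' Apply controlled modifications to a parametric model
#'
#' New target mean relative abundances are converted to new location
#' parameters with \eqn{(\sigma_j, Q_j)} held fixed: the mean on the
#' abundance scale is log-linear in \eqn{\mu_j}
#' (\eqn{E[\pi] \propto e^{\mu}}), so \eqn{\mu_j} shifts by
#' \eqn{\ln(p_j^{new}/p_j^{cur})}. New library sizes propagate through the
#' fitted CDF to per-cell presence probabilities at simulation time. A
#' `covariate_design` is accepted in place of a spec: the design's group
#' mean-abundance vectors are applied per group and the group library
#' sizes are resampled from the template.
#'
#' @param model A `micosim_model` fitted with `mode = "parametric"`.
#' @param spec A [modification_spec()] or a [build_da_design()] object.
#' @return A modified `micosim_model` (for a covariate design, the model
#'   gains a `design` field and per-sample location offsets used by
#'   [micosim_simulate()]).
#' @export
apply_parametric_modifications <- function(model, spec) {
  stopifnot(inherits(model, "micosim_model"))
  if (model$mode != "parametric") {
    stop_input("model was not fitted in parametric mode")
  }
  if (inherits(spec, "covariate_design")) {
    return(apply_da_design_parametric(model, spec))
  }
  stopifnot(inherits(spec, "modification_spec"))
  if (!is.null(spec$new_prop_nonzero)) {
    stop_input("new_prop_nonzero is a nonparametric-mode control; in ",
               "parametric mode zero proportions follow the fitted CDF")
  }
  if (!is.null(spec$new_mean_rel_abund)) {
    p_new <- spec$new_mean_rel_abund
    if (length(p_new) != length(model$gengamma)) {
      stop_input("new_mean_rel_abund must have one entry per taxon")
    }
    for (j in seq_along(model$gengamma)) {
      fit <- model$gengamma[[j]]
      p_cur <- gengamma_moment(-1, fit$mu, fit$sigma, fit$Q)
      model$gengamma[[j]]$mu <- fit$mu + log(p_new[j] / p_cur)
    }
  }
  if (!is.null(spec$new_lib_sizes)) model$target_lib_sizes <- spec$new_lib_sizes
  if (!is.null(spec$new_n_samples)) model$target_n <- spec$new_n_samples
  model
}

apply_da_design_parametric <- function(model, design) {
  p0_implied <- vapply(model$gengamma, function(f) {
    gengamma_moment(-1, f$mu, f$sigma, f$Q)
  }, numeric(1))
  # per-group target means under the compositional covariate model,
  # scaled to the model's implied total so only the *relative* pattern of
  # the template is shifted
  groups <- design$X1 + 2L * design$X2  # 0..3
  J <- length(p0_implied)
  mu_shift <- matrix(0, length(design$X1), J)
  p_base <- design$p0 / sum(design$p0)
  for (g in 0:3) {
    idx <- which(groups == g)
    if (!length(idx)) next
    X1 <- as.integer(g %% 2L == 1L)
    X2 <- as.integer(g >= 2L)
    p_g <- covariate_effect_relabund(p_base, X1, X2, design$beta1,
                                     design$beta2, design$M1, design$M2)
    mu_shift[idx, ] <- matrix(log(p_g / p_base), length(idx), J, byrow = TRUE)
  }
  model$design <- design
  model$mu_shift <- mu_shift
  model$target_n <- length(design$X1)
  model
}

#' Apply controlled modifications to a nonparametric model
#'
#' Target non-zero proportions \eqn{\delta_j} become new taxon margins
#' \eqn{m_j = round(n \cdot \delta_j)} for the occupancy refit (sample
#' margins are rescaled proportionally to keep the two margin totals
#' consistent). Target mean relative abundances \eqn{p_j} are converted to
#' non-zero-cell means \eqn{p_j^{(1)} = p_j/\delta_j} and each taxon's
#' empirical values are power-adjusted toward that mean. Changing library
#' sizes requires explicit `new_taxon_margins` and `new_sample_margins`,
#' because the number of zero cells in a sample depends on its library size
#' in a way the empirical model cannot predict.
#'
#' @param model A `micosim_model` fitted with `mode = "nonparametric"`.
#' @param spec A [modification_spec()].
#' @return A modified `micosim_model` (occupancy parameters refitted when
#'   margins changed).
#' @export
apply_nonparametric_modifications <- function(model, spec) {
  stopifnot(inherits(model, "micosim_model"),
            inherits(spec, "modification_spec"))
  if (model$mode != "nonparametric") {
    stop_input("model was not fitted in nonparametric mode")
  }
  if (is_empty_spec(spec)) return(model)
  if (!is.null(spec$new_lib_sizes) &&
      (is.null(spec$new_taxon_margins) || is.null(spec$new_sample_margins))) {
    stop_input("changing library sizes in nonparametric mode requires ",
               "explicit new_taxon_margins (m_j) and new_sample_margins ",
               "(n_i): the empirical model cannot predict how the zero ",
               "pattern responds to library size")
  }

  n <- length(model$summary$sample_ids)
  delta <- model$summary$prop_nonzero
  m_new <- spec$new_taxon_margins
  n_new <- spec$new_sample_margins
  if (!is.null(spec$new_prop_nonzero)) {
    delta <- spec$new_prop_nonzero
    m_new <- round_half_up(n * delta)
  }
  if (!is.null(m_new) || !is.null(n_new)) {
    m_new <- m_new %||% model$summary$taxon_nonzero_counts
    n_new <- n_new %||% model$summary$sample_nonzero_counts
    occ <- fit_occupancy_probit(m_new, n_new)
    model$occupancy$theta <- occ$theta
    model$occupancy$eta <- occ$eta
    model$occupancy$converged <- occ$converged
    model$occupancy$residual <- occ$residual
  }
  if (!is.null(spec$new_mean_rel_abund)) {
    p_new <- spec$new_mean_rel_abund
    if (length(p_new) != length(model$marginals)) {
      stop_input("new_mean_rel_abund must have one entry per taxon")
    }
    alphas <- numeric(length(p_new))
    for (j in seq_along(p_new)) {
      p1 <- p_new[j] / delta[j]
      if (p1 >= 1) {
        stop_input("taxon ", j, ": target p/delta = ", signif(p1, 4),
                   " is not attainable (must be < 1)")
      }
      adj <- power_adjust_marginal(model$marginals[[j]], p1)
      alphas[j] <- adj$alpha
      model$marginals[[j]] <- sort(adj$values)
    }
    model$alpha <- alphas
  }
  if (!is.null(spec$new_lib_sizes)) model$target_lib_sizes <- spec$new_lib_sizes
  if (!is.null(spec$new_n_samples)) model$target_n <- spec$new_n_samples
  model
}
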