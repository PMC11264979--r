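#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for fitted simulator models
#'
#' `tidy()` returns one row per taxon: the template margins
#' (\eqn{p_j}, \eqn{\delta_j}, \eqn{m_j}) plus the mode-specific
#' parameters (occupancy effect \eqn{\theta_j} in nonparametric mode;
#' \eqn{\mu_j, \sigma_j, Q_j} and the predicted non-zero count
#' \eqn{\sum_i F_j(N_i)} in parametric mode). `glance()` returns a one-row
#' model overview.
#'
#' @param x A `micosim_model` (or `template_summary` for its method).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy micosim_model
#' @export
tidy.micosim_model <- function(x, ...) {
  base <- tidy(x$summary)
  if (x$mode == "nonparametric") {
    dplyr::mutate(base, theta = unname(x$occupancy$theta))
  } else {
    pred <- vapply(x$gengamma, function(f) {
      sum(prob_nonzero(x$summary$lib_sizes, f))
    }, numeric(1))
    dplyr::mutate(base,
                  mu = vapply(x$gengamma, `[[`, numeric(1), "mu"),
                  sigma = vapply(x$gengamma, `[[`, numeric(1), "sigma"),
                  Q = vapply(x$gengamma, `[[`, numeric(1), "Q"),
                  predicted_nonzero = unname(pred))
  }
}

#' @rdname tidy.micosim_model
#' @method glance micosim_model
#' @export
glance.micosim_model <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_samples = x$provenance$n,
    n_taxa = x$provenance$J,
    zero_fraction = x$summary$zero_fraction,
    occupancy_residual = if (x$mode == "nonparametric")
      x$occupancy$residual else NA_real_,
    rho_eigen_floored = as.integer(attr(x$rho, "n_floored") %||% NA),
    r_star_eigen_floored = as.integer(attr(x$r_star, "n_floored") %||% NA),
    K = x$K
  )
}

#' @rdname tidy.micosim_model
#' @method tidy micosim_sim
#' @export
tidy.micosim_sim <- function(x, ...) {
  tibble::tibble(
    taxon_id = x$taxon_ids,
    mean_rel_abund = unname(colMeans(x$rel_abund)),
    prop_nonzero = unname(colMeans(x$presence)),
    n_nonzero = unname(colSums(x$presence))
  )
}

#' @rdname tidy.micosim_model
#' @method glance micosim_sim
#' @export
glance.micosim_sim <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$counts),
    n_taxa = ncol(x$counts),
    zero_fraction = mean(x$counts == 0),
    median_lib_size = stats::median(x$lib_sizes)
  )
}

#' Diagnostic plots for simulated data
#'
#' `autoplot.micosim_sim()` compares per-taxon margins of a simulation
#' against its fitted model's template: mean relative abundance and
#' non-zero proportion, simulated versus template, on a scatter with the
#' identity line. `autoplot.micosim_report()` shows the fidelity report's
#' p-values per check.
#'
#' @param object A `micosim_sim` or `micosim_report`.
#' @param model The `micosim_model` the simulation came from (required for
#'   the sim method).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot micosim_sim
#' @export
autoplot.micosim_sim <- function(object, model, ...) {
  stopifnot(inherits(model, "micosim_model"))
  tpl <- tidy(model$summary)
  sim <- tidy(object)
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "mean relative abundance",
                   template = tpl$mean_rel_abund,
                   simulated = sim$mean_rel_abund),
    tibble::tibble(panel = "proportion non-zero",
                   template = tpl$prop_nonzero,
                   simulated = sim$prop_nonzero)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$template, .data$simulated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "template", y = "simulated",
                  title = "Per-taxon margin calibration") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.micosim_sim
#' @method autoplot micosim_report
#' @export
autoplot.micosim_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = paste(df$check, df$metric),
                                   y = .data$p_value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2, colour = "red") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "p-value",
                  title = "Template-vs-simulated fidelity checks") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
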