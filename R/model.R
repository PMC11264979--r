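#' Fit the two-step copula simulator to a template count table
#'
#' Step one fits the presence-absence layer: the probit occupancy model
#' ([fit_occupancy_probit()]) for the marginal zero pattern and the smoothed
#' tetrachoric correlation ([estimate_tetrachoric()],
#' [smooth_to_pd_correlation()]) for its dependence. Step two fits the
#' relative-abundance layer: the Gaussian-copula correlation with random
#' tie-breaking ([estimate_copula_correlation()]) and, per taxon, either the
#' empirical non-zero abundance distribution (`mode = "nonparametric"`) or
#' a generalized gamma distribution on the inverse-abundance scale
#' (`mode = "parametric"`, [fit_gengamma_moments()]). In parametric mode the
#' occupancy margins follow the fitted CDFs, so \eqn{\theta}/\eqn{\eta} are
#' not needed.
#'
#' @param ct A filtered [count_table] (see [filter_template()]).
#' @param mode `"nonparametric"` (default) or `"parametric"`.
#' @param K Number of tie-break orderings for the copula correlation
#'   (default 100).
#' @param seed Optional integer seed (controls tie-breaking).
#' @return An object of class `micosim_model`.
#' @seealso [micosim_simulate()], [apply_parametric_modifications()],
#'   [apply_nonparametric_modifications()]
#' @examples
#' ct <- make_synthetic_template(n_samples = 40, n_taxa = 12, seed = 1)$ct
#' mod <- micosim_fit(filter_template(ct, 0, 1), seed = 1)
#' sim <- micosim_simulate(mod, seed = 2)
#' sim$counts[1:3, 1:4]
#' @export
micosim_fit <- function(ct, mode = c("nonparametric", "parametric"),
                        K = 100L, seed = NULL) {
  stopifnot(inherits(ct, "count_table"))
  mode <- match.arg(mode)
  if (any(colSums(ct$counts > 0) == 0)) {
    stop_input("template contains all-zero taxa; run filter_template() first")
  }
  summ <- summarize_template(ct)
  zeta <- estimate_tetrachoric(summ$presence)
  rho <- smooth_to_pd_correlation(zeta)
  r_star <- estimate_copula_correlation(
    summ$rel_abund, K = K,
    seed = if (is.null(seed)) NULL else substream_seed(seed, "tiebreak"))

  model <- list(mode = mode, summary = summ, rho = rho, r_star = r_star,
                K = as.integer(K), seed = seed,
                provenance = list(n = nrow(ct$counts), J = ncol(ct$counts),
                                  fitted_at = format(Sys.time(), "%Y-%m-%d"),
                                  version = "0.1.0"))
  if (mode == "nonparametric") {
    occ <- fit_occupancy_probit(summ$taxon_nonzero_counts,
                                summ$sample_nonzero_counts)
    model$occupancy <- occ[c("theta", "eta", "converged", "residual")]
    model$marginals <- lapply(seq_along(summ$taxon_ids), function(j) {
      sort(summ$rel_abund[summ$rel_abund[, j] > 0, j])
    })
    names(model$marginals) <- summ$taxon_ids
  } else {
    model$gengamma <- lapply(seq_along(summ$taxon_ids), function(j) {
      fit_gengamma_moments(summ$rel_abund[, j], summ$lib_sizes)
    })
    names(model$gengamma) <- summ$taxon_ids
  }
  class(model) <- "micosim_model"
  model
}

#' @export
print.micosim_model <- function(x, ...) {
  cat("<micosim_model> mode:", x$mode, "\n")
  cat("  template:", x$provenance$n, "samples x", x$provenance$J, "taxa,",
      "zero fraction", signif(x$summary$zero_fraction, 4), "\n")
  if (x$mode == "nonparametric") {
    cat("  occupancy fit residual:", format(x$occupancy$residual), "\n")
  }
  cat("  correlation smoothing: ", attr(x$rho, "n_floored"),
      " (presence), ", attr(x$r_star, "n_floored"),
      " (abundance) eigenvalues floored\n", sep = "")
  invisible(x)
}

#' Simulate a new dataset from a fitted model
#'
#' Draws presence-absence from step one (latent MVN thresholding), fills
#' present cells from step two (Gaussian copula scores
#' \eqn{W \sim MVN(0, r^*)} mapped through the empirical or truncated
#' generalized-gamma marginals), and converts to counts with
#' [relabund_to_counts()]. The top-level seed spawns named substreams per
#' stage (library sizes, presence, copula, marginal filling), so the same
#' seed always reproduces the same dataset.
#'
#' @param model A `micosim_model`, possibly modified.
#' @param n_sim Number of samples (default: the modified target if set,
#'   else the template size). When it differs from the template size,
#'   template samples (library size and, nonparametrically, sample effect)
#'   are resampled jointly, with replacement when `n_sim` exceeds the
#'   template.
#' @param seed Optional integer seed.
#' @return An object of class `micosim_sim`: list with `counts`,
#'   `rel_abund`, `presence`, `lib_sizes`, `sample_ids`, `taxon_ids`,
#'   `seed`, and (for covariate designs) `metadata` (tibble with X1, X2).
#' @export
micosim_simulate <- function(model, n_sim = NULL, seed = NULL) {
  stopifnot(inherits(model, "micosim_model"))
  n_tpl <- length(model$summary$sample_ids)
  n_sim <- n_sim %||% model$target_n %||% n_tpl
  if (n_sim < 1) stop_input("n_sim must be >= 1")
  J <- length(model$summary$taxon_ids)
  sub <- function(name) if (is.null(seed)) NULL else substream_seed(seed, name)

  # Template rows are resampled jointly so library size stays paired with
  # the sample effect; explicit target library sizes override. Under a
  # covariate design, each group's library sizes are drawn with replacement
  # from the template pool on a dedicated seed stream.
  idx <- with_seed(sub("rows"), {
    if (n_sim == n_tpl) seq_len(n_tpl)
    else sample.int(n_tpl, n_sim, replace = n_sim > n_tpl)
  })
  if (!is.null(model$design)) {
    if (length(model$design$X1) != n_sim) {
      stop_input("covariate design has ", length(model$design$X1),
                 " samples but n_sim = ", n_sim)
    }
    groups <- model$design$X1 + 2L * model$design$X2
    N <- numeric(n_sim)
    for (g in 0:3) {
      members <- which(groups == g)
      N[members] <- with_seed(sub(paste0("libsize", g)), {
        sample(unname(model$summary$lib_sizes), length(members),
               replace = TRUE)
      })
    }
  } else {
    N <- model$target_lib_sizes %||% unname(model$summary$lib_sizes[idx])
  }
  if (length(N) != n_sim) {
    stop_input("target library sizes have length ", length(N),
               " but n_sim = ", n_sim)
  }

  if (model$mode == "nonparametric") {
    Z <- sample_presence_nonparametric(
      model$occupancy$theta, model$occupancy$eta, model$rho, n_sim,
      seed = sub("presence"), eta = unname(model$occupancy$eta[idx]))
  } else {
    P <- vapply(model$gengamma, function(f) prob_nonzero(N, f), numeric(n_sim))
    P <- matrix(P, n_sim, J)
    if (!is.null(model$mu_shift)) {
      # covariate shifts move the whole location-scale family, so the
      # presence probability is the shifted CDF at the library size
      for (j in seq_len(J)) {
        f <- model$gengamma[[j]]
        for (sh in setdiff(unique(model$mu_shift[, j]), 0)) {
          rows <- which(model$mu_shift[, j] == sh)
          P[rows, j] <- gengamma_cdf(N[rows], f$mu + sh, f$sigma, f$Q)
        }
      }
    }
    Z <- sample_presence_parametric(P, model$rho, seed = sub("presence"))
  }

  W <- with_seed(sub("copula"), rmvn_chol(n_sim, chol(model$r_star)))

  if (model$mode == "nonparametric") {
    pi_raw <- assign_nonzero_abundances_empirical(
      W, Z, model$marginals, lengths(model$marginals),
      seed = sub("marginals"))
  } else {
    pi_raw <- matrix(0, n_sim, J)
    U <- pnorm(W)
    U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
    for (j in seq_len(J)) {
      pres <- which(Z[, j] == 1)
      if (!length(pres)) next
      fit <- model$gengamma[[j]]
      if (!is.null(model$mu_shift)) {
        # per-sample location offsets from a covariate design: one
        # truncated draw per distinct offset value in this taxon
        for (sh in unique(model$mu_shift[pres, j])) {
          rows <- pres[model$mu_shift[pres, j] == sh]
          fi <- fit
          fi$mu <- fit$mu + sh
          pi_raw[rows, j] <- sample_truncated_abundance(fi, N[rows],
                                                        U[rows, j])
        }
      } else {
        pi_raw[pres, j] <- sample_truncated_abundance(fit, N[pres], U[pres, j])
      }
    }
  }

  out <- relabund_to_counts(pi_raw, N)
  sample_ids <- sprintf("sim%0*d", nchar(n_sim), seq_len(n_sim))
  dimnames(out$counts) <- dimnames(out$rel_abund) <- dimnames(Z) <-
    list(sample_ids, model$summary$taxon_ids)
  res <- list(counts = out$counts, rel_abund = out$rel_abund,
              presence = Z, lib_sizes = setNames(out$lib_sizes, sample_ids),
              sample_ids = sample_ids,
              taxon_ids = model$summary$taxon_ids, seed = seed)
  if (!is.null(model$design)) {
    res$metadata <- tibble::tibble(sample_id = sample_ids,
                                   X1 = model$design$X1,
                                   X2 = model$design$X2)
  }
  class(res) <- "micosim_sim"
  res
}

#' @export
print.micosim_sim <- function(x, ...) {
  cat("<micosim_sim> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa; zero fraction ", signif(mean(x$counts == 0), 4), "\n", sep = "")
  invisible(x)
}

#' Convert a simulation result to a count table
#' @param sim A `micosim_sim`.
#' @return A [count_table].
#' @export
as_count_table <- function(sim) {
  stopifnot(inherits(sim, "micosim_sim"))
  count_table(sim$counts)
}

#' Write simulated data as TSV tables
#'
#' Writes three tab-separated tables sharing sample and taxon IDs:
#' `<prefix>.counts.tsv`, `<prefix>.relabund.tsv`, `<prefix>.presence.tsv`
#' (plus `<prefix>.metadata.tsv` when a covariate design is attached).
#'
#' @param sim A `micosim_sim`.
#' @param prefix Output path prefix.
#' @return The paths written, invisibly.
#' @export
write_simulated_data <- function(sim, prefix) {
  stopifnot(inherits(sim, "micosim_sim"))
  paths <- character(0)
  for (what in c("counts", "rel_abund", "presence")) {
    path <- paste0(prefix, ".", sub("rel_abund", "relabund", what), ".tsv")
    df <- data.frame(sample_id = sim$sample_ids, sim[[what]],
                     check.names = FALSE, row.names = NULL)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  if (!is.null(sim$metadata)) {
    path <- paste0(prefix, ".metadata.tsv")
    utils::write.table(sim$metadata, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Serialize a fitted model to JSON
#'
#' Writes every numeric component (margins, correlation matrices, empirical
#' marginals or generalized-gamma parameter table) at full precision so that
#' write -> read -> simulate reproduces in-memory simulation exactly under
#' the same seed.
#'
#' @param model A `micosim_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "micosim_model"))
  payload <- unclass(model)
  payload$summary <- unclass(payload$summary)
  payload$rho_n_floored <- attr(model$rho, "n_floored")
  payload$r_star_n_floored <- attr(model$r_star, "n_floored")
  attributes(payload$rho) <- list(dim = dim(model$rho))
  attributes(payload$r_star) <- list(dim = dim(model$r_star))
  if (!is.null(payload$gengamma)) {
    payload$gengamma <- lapply(payload$gengamma, unclass)
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) as.numeric(v)
  s <- x$summary
  n <- length(s$sample_ids); J <- length(s$taxon_ids)
  # jsonlite stores matrices row-major; simplifyVector usually rebuilds them
  restore_mat <- function(v, nr, nc, rn, cn) {
    m <- if (is.matrix(v)) v else matrix(num(unlist(v)), nr, nc, byrow = TRUE)
    storage.mode(m) <- "double"
    dimnames(m) <- list(rn, cn)
    m
  }
  summ <- structure(list(
    rel_abund = restore_mat(s$rel_abund, n, J, s$sample_ids, s$taxon_ids),
    presence = restore_mat(s$presence, n, J, s$sample_ids, s$taxon_ids),
    mean_rel_abund = setNames(num(s$mean_rel_abund), s$taxon_ids),
    prop_nonzero = setNames(num(s$prop_nonzero), s$taxon_ids),
    taxon_nonzero_counts = setNames(num(s$taxon_nonzero_counts), s$taxon_ids),
    sample_nonzero_counts = setNames(num(s$sample_nonzero_counts), s$sample_ids),
    zero_fraction = num(s$zero_fraction),
    lib_sizes = setNames(num(s$lib_sizes), s$sample_ids),
    sample_ids = s$sample_ids, taxon_ids = s$taxon_ids
  ), class = "template_summary")
  model <- list(mode = x$mode, summary = summ,
                rho = restore_mat(x$rho, J, J, s$taxon_ids, s$taxon_ids),
                r_star = restore_mat(x$r_star, J, J, s$taxon_ids, s$taxon_ids),
                K = as.integer(x$K), seed = x$seed,
                provenance = x$provenance)
  attr(model$rho, "n_floored") <- x$rho_n_floored
  attr(model$r_star, "n_floored") <- x$r_star_n_floored
  if (!is.null(x$occupancy)) {
    model$occupancy <- list(
      theta = setNames(num(x$occupancy$theta), s$taxon_ids),
      eta = setNames(num(x$occupancy$eta), s$sample_ids),
      converged = x$occupancy$converged,
      residual = num(x$occupancy$residual))
  }
  if (!is.null(x$marginals)) {
    model$marginals <- lapply(x$marginals, num)
    names(model$marginals) <- s$taxon_ids
  }
  if (!is.null(x$gengamma)) {
    model$gengamma <- lapply(x$gengamma, function(g) {
      structure(list(mu = num(g$mu), sigma = num(g$sigma), Q = num(g$Q),
                     logLik = num(g$logLik),
                     moment_resid = num(unlist(g$moment_resid)),
                     n = g$n, m = g$m, fallback = isTRUE(g$fallback)),
                class = "gengamma_fit")
    })
    names(model$gengamma) <- s$taxon_ids
  }
  for (fld in c("target_lib_sizes", "target_n", "alpha")) {
    if (!is.null(x[[fld]])) model[[fld]] <- num(x[[fld]])
  }
  if (!is.null(x$design)) {
    model$design <- structure(list(
      X1 = as.integer(x$design$X1), X2 = as.integer(x$design$X2),
      M1 = as.integer(x$design$M1), M2 = as.integer(x$design$M2),
      beta1 = num(x$design$beta1), beta2 = num(x$design$beta2),
      p0 = num(x$design$p0)), class = "covariate_design")
    model$mu_shift <- restore_mat(x$mu_shift, length(model$design$X1), J,
                                  NULL, NULL)
  }
  class(model) <- "micosim_model"
  model
}
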