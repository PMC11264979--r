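#' Per-sample alpha diversity
#'
#' Richness (number of taxa present) and the Shannon index
#' \eqn{-\sum p \ln p} (natural log) over each sample's non-zero
#' proportions. An all-zero sample has richness 0 and Shannon 0 by
#' convention.
#'
#' @param x A [count_table], `micosim_sim`, matrix, or data frame of
#'   non-negative abundances (samples in rows).
#' @return A tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  m <- abundance_matrix(x)
  rs <- rowSums(m)
  prop <- m / ifelse(rs > 0, rs, 1)
  tibble::tibble(
    sample_id = rownames(m) %||% paste0("sample", seq_len(nrow(m))),
    richness = unname(rowSums(m > 0)),
    shannon = unname(vegan::diversity(prop, index = "shannon"))
  )
}

# Coerce the various containers to a plain samples x taxa matrix.
abundance_matrix <- function(x, relative = FALSE) {
  m <- if (inherits(x, "count_table")) {
    x$counts
  } else if (inherits(x, "micosim_sim")) {
    if (relative) x$rel_abund else x$counts
  } else if (is.data.frame(x)) {
    as.matrix(tibble::column_to_rownames(x, var = names(x)[1L]))
  } else {
    as.matrix(x)
  }
  if (relative && !inherits(x, "micosim_sim")) {
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
  }
  m
}

#' Beta-diversity distance matrix
#'
#' Jaccard dissimilarity `(b + c)/(a + b + c)` on presence-absence, or
#' Bray-Curtis \eqn{\sum |x - y| / \sum (x + y)} on relative abundances
#' (counts are closed to proportions first). Distances involving two
#' all-zero samples are set to 0 with a warning.
#'
#' @param x As in [alpha_diversity()].
#' @param metric `"jaccard"` or `"bray-curtis"`.
#' @return A `dist` object with attributes `metric` and `Labels`.
#' @export
beta_distance <- function(x, metric = c("jaccard", "bray-curtis")) {
  metric <- match.arg(metric)
  m <- abundance_matrix(x, relative = metric == "bray-curtis")
  d <- if (metric == "jaccard") {
    vegan::vegdist((m > 0) * 1, method = "jaccard", binary = TRUE)
  } else {
    vegan::vegdist(m, method = "bray")
  }
  if (anyNA(d)) {
    warning("distances between all-zero samples set to 0")
    d[is.na(d)] <- 0
  }
  attr(d, "metric") <- metric
  d
}

#' Distance from each sample to its group centroid
#'
#' Embeds the distance matrix by principal coordinates (eigendecomposition
#' of the doubly-centred \eqn{-\tfrac12 D^2} matrix) and measures each
#' sample's distance to its group centroid, subtracting the
#' imaginary-axis contribution arising from negative eigenvalues and
#' flooring squared distances at zero before the square root (the standard
#' beta-dispersion convention; delegates to [vegan::betadisper()]).
#'
#' @param D A `dist` object (e.g. from [beta_distance()]).
#' @param groups Factor-like group labels, one per sample; every group
#'   must have at least 2 samples.
#' @return A tibble with columns `sample_id`, `group`, `dist_to_centroid`.
#' @export
dist_to_centroid <- function(D, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) {
    stop_input("every group needs at least 2 samples")
  }
  if (max(D) == 0) {  # all samples identical: centroid distance is zero
    return(tibble::tibble(
      sample_id = attr(D, "Labels") %||% as.character(seq_along(groups)),
      group = as.character(groups),
      dist_to_centroid = rep(0, length(groups))))
  }
  bd <- vegan::betadisper(D, groups, type = "centroid")
  tibble::tibble(
    sample_id = attr(D, "Labels") %||% as.character(seq_along(groups)),
    group = as.character(groups),
    dist_to_centroid = unname(bd$distances)
  )
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: a pseudo-F statistic
#' from the within/between partition of squared distances, with a
#' permutation p-value \eqn{(1 + \#\{F_{perm} \ge F\})/(1 + n_{perm})}.
#' Sample labels are permuted freely (no strata); delegates to
#' [vegan::adonis2()].
#'
#' @param D A `dist` object.
#' @param groups Group labels (at least 2 groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `pseudo_F`, `p_value`, `df`, `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop_input("n_perm must be >= 1")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop_input("need at least 2 groups")
  dat <- data.frame(group = groups)
  fit <- with_seed(seed,
    vegan::adonis2(D ~ group, data = dat, permutations = n_perm))
  tibble::tibble(pseudo_F = fit$F[1L], p_value = fit$`Pr(>F)`[1L],
                 df = fit$Df[1L], n_perm = as.integer(n_perm))
}

#' Template-versus-simulated fidelity report
#'
#' Pools the template and one simulated dataset (same taxon set) and runs
#' the standard fidelity checks: PERMANOVA on Jaccard and Bray-Curtis
#' distances with template/simulated labels; Welch t and two-sample
#' Kolmogorov-Smirnov tests on richness and Shannon diversity; and
#' Kolmogorov-Smirnov tests comparing the distance-to-centroid
#' distributions of the two groups under each metric. Large p-values mean
#' the simulation is indistinguishable from its template by that check.
#'
#' @param template A [count_table].
#' @param simulated A `micosim_sim` or [count_table] over the same taxa.
#' @param n_perm Permutations for PERMANOVA (default 999).
#' @param seed Optional integer seed.
#' @return An object of class `micosim_report`: a tibble with columns
#'   `check`, `metric`, `statistic`, `p_value`.
#' @export
compare_report <- function(template, simulated, n_perm = 999, seed = NULL) {
  mt <- abundance_matrix(template)
  ms <- abundance_matrix(simulated)
  if (ncol(mt) != ncol(ms) ||
      !identical(colnames(mt), colnames(ms))) {
    stop_input("template and simulated data must share the same taxon set")
  }
  rownames(ms) <- paste0("sim_", seq_len(nrow(ms)))
  rownames(mt) <- paste0("tpl_", seq_len(nrow(mt)))
  pooled <- rbind(mt, ms)
  labels <- rep(c("template", "simulated"), c(nrow(mt), nrow(ms)))

  rows <- list()
  for (metric in c("jaccard", "bray-curtis")) {
    D <- beta_distance(pooled, metric)
    pm <- permanova(D, labels, n_perm = n_perm,
                    seed = if (is.null(seed)) NULL
                           else substream_seed(seed, metric))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      check = "permanova", metric = metric,
      statistic = pm$pseudo_F, p_value = pm$p_value)
    dc <- dist_to_centroid(D, labels)
    ks <- suppressWarnings(ks.test(
      dc$dist_to_centroid[labels == "template"],
      dc$dist_to_centroid[labels == "simulated"]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      check = "dispersion_ks", metric = metric,
      statistic = unname(ks$statistic), p_value = ks$p.value)
  }

  at <- alpha_diversity(mt)
  as_ <- alpha_diversity(ms)
  for (what in c("richness", "shannon")) {
    tt <- t.test(at[[what]], as_[[what]])
    ks <- suppressWarnings(ks.test(at[[what]], as_[[what]]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      check = paste0(what, "_welch_t"), metric = "alpha",
      statistic = unname(tt$statistic), p_value = tt$p.value)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      check = paste0(what, "_ks"), metric = "alpha",
      statistic = unname(ks$statistic), p_value = ks$p.value)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("micosim_report", class(out))
  out
}

#' @export
print.micosim_report <- function(x, ...) {
  cat("Template-vs-simulated fidelity report\n")
  NextMethod()
}
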