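# Shared fixtures, built in code.

# A tiny deterministic count table.
tiny_ct <- function() {
  count_table(matrix(c(2L, 1L,
                       0L, 1L), 2, 2,
                     dimnames = list(c("s1", "s2"), c("tA", "tB"))))
}

# A small random count table with no degenerate taxa.
small_template <- function(seed = 101, n = 60, J = 25) {
  syn <- make_synthetic_template(n_samples = n, n_taxa = J,
                                 n_dominant = max(1L, J %/% 8L),
                                 zero_fraction = 0.55,
                                 seed = seed)
  filter_template(syn$ct, min_lib_size = 0, min_taxon_prevalence = 4)
}

# Random presence-absence margins that are jointly feasible (taken from a
# realized binary matrix).
random_margins <- function(seed, n = 20, J = 10) {
  withr::with_seed(seed, {
    p <- runif(J, 0.2, 0.8)
    Z <- matrix(rbinom(n * J, 1, rep(p, each = n)), n, J)
    list(Z = Z, m = colSums(Z), n_i = rowSums(Z))
  })
}
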