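#' Construct a count table
#'
#' A `count_table` is the package's container for a samples x taxa matrix of
#' non-negative integer read counts, together with sample/taxon identifiers
#' and per-sample library sizes (row sums). It is the required input for
#' [micosim_fit()] and the output of [make_synthetic_template()].
#'
#' @param counts A samples x taxa matrix of non-negative integers, or a
#'   data.frame/tibble whose first column holds sample IDs (as written by
#'   [write_count_table()]).
#' @param sample_ids,taxon_ids Optional character vectors of identifiers;
#'   default to the dimnames of `counts`, or `sample1..n` / `taxon1..J`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix with dimnames), `sample_ids`, `taxon_ids`, and
#'   `lib_sizes` (row sums, named by sample).
#' @examples
#' ct <- count_table(matrix(c(5L, 0L, 2L, 3L), 2, 2))
#' ct$lib_sizes
#' @export
count_table <- function(counts, sample_ids = NULL, taxon_ids = NULL) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1L]])
    counts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(counts) <- ids
    storage.mode(counts) <- "double"
  }
  if (!is.matrix(counts)) stop_input("`counts` must be a matrix or data frame")
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(counts))
    stop_input("counts must be non-negative integers; offending cell: row ",
               ij[1L], " (sample '", rownames(counts)[ij[1L]] %||% ij[1L],
               "'), column ", ij[2L], " (taxon '",
               colnames(counts)[ij[2L]] %||% ij[2L], "') = ",
               counts[bad[1L]])
  }
  sample_ids <- as.character(sample_ids %||% rownames(counts) %||%
                               paste0("sample", seq_len(nrow(counts))))
  taxon_ids <- as.character(taxon_ids %||% colnames(counts) %||%
                              paste0("taxon", seq_len(ncol(counts))))
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts)) {
    stop_input("ID lengths do not match the count matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) {
    stop_input("duplicated sample IDs: ",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(taxon_ids)) {
    stop_input("duplicated taxon IDs: ",
               paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(
    list(counts = counts, sample_ids = sample_ids, taxon_ids = taxon_ids,
         lib_sizes = rowSums(counts)),
    class = "count_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa\n", sep = "")
  cat("  library sizes: ", paste(range(x$lib_sizes), collapse = " - "),
      " (median ", stats::median(x$lib_sizes), ")\n", sep = "")
  cat("  zero fraction: ",
      signif(mean(x$counts == 0), 4), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table from a TSV (or BIOM) file
#'
#' The expected TSV dialect is tab-separated with a header row: in
#' `samples-by-taxa` orientation the header holds taxon IDs and the first
#' column holds sample IDs; `taxa-by-samples` is the transpose. The
#' orientation is an explicit flag rather than a guess, because silent
#' transposition is the classic microbiome-IO bug. A path ending in
#' `.biom` is read through the `biomformat` package instead (BIOM fixes
#' the orientation itself: observations are taxa).
#'
#' @param path Path to a TSV (or BIOM) file.
#' @param orientation `"samples-by-taxa"` (default) or `"taxa-by-samples"`;
#'   ignored for BIOM input.
#' @return A [count_table] in samples-by-taxa orientation.
#' @export
read_count_table <- function(path,
                             orientation = c("samples-by-taxa",
                                             "taxa-by-samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop_input("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations (taxa) x samples
    return(count_table(t(m)))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m))
    ij <- if (length(bad)) arrayInd(bad[1L], dim(m)) else c(NA, NA)
    stop_input("non-numeric entry in ", path, " at data row ", ij[1L],
               ", column '", colnames(m)[ij[2L]], "'")
  }
  rownames(m) <- ids
  if (orientation == "taxa-by-samples") m <- t(m)
  count_table(m)
}

#' Write a count table to a TSV file
#'
#' Inverse of [read_count_table()] (samples-by-taxa orientation, sample IDs
#' in the first column, taxon IDs in the header). Round-trips bit-exactly.
#'
#' @param ct A [count_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  df <- data.frame(sample_id = ct$sample_ids, ct$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a template count table
#'
#' Applies the standard template-preparation filters in a fixed order: an
#' optional explicit sample subset (`keep_samples`, e.g. first-visit samples
#' of a longitudinal study), then removal of samples whose library size is
#' below `min_lib_size`, then removal of taxa present in fewer than
#' `min_taxon_prevalence` of the remaining samples. The sample filter uses
#' library sizes computed *before* any taxon removal.
#'
#' @param ct A [count_table].
#' @param min_lib_size Minimum library size for a sample to be kept
#'   (default 3000).
#' @param min_taxon_prevalence Minimum number of samples in which a taxon
#'   must be present (default 4).
#' @param keep_samples Optional character vector of sample IDs applied first.
#' @return The filtered [count_table].
#' @export
filter_template <- function(ct, min_lib_size = 3000,
                            min_taxon_prevalence = 4, keep_samples = NULL) {
  stopifnot(inherits(ct, "count_table"))
  if (min_lib_size < 0 || min_taxon_prevalence < 0) {
    stop_input("filter thresholds must be non-negative")
  }
  counts <- ct$counts
  if (!is.null(keep_samples)) {
    missing <- setdiff(keep_samples, rownames(counts))
    if (length(missing)) {
      stop_input("keep_samples IDs not in table: ",
                 paste(head(missing, 5), collapse = ", "))
    }
    counts <- counts[rownames(counts) %in% keep_samples, , drop = FALSE]
  }
  keep_s <- rowSums(counts) >= min_lib_size
  if (!any(keep_s)) stop_input("all samples removed by the library-size filter")
  counts <- counts[keep_s, , drop = FALSE]
  prevalence <- colSums(counts > 0)
  keep_t <- prevalence >= max(min_taxon_prevalence, 1L)
  if (!any(keep_t)) stop_input("all taxa removed by the prevalence filter")
  counts <- counts[, keep_t, drop = FALSE]
  count_table(counts)
}

#' Summarize a template count table
#'
#' Computes the per-cell and marginal statistics the simulator is fitted to:
#' relative abundances \eqn{\pi_{ij} = C_{ij}/N_i}, presence indicators
#' \eqn{Z_{ij} = I(C_{ij} > 0)}, per-taxon mean relative abundances
#' \eqn{p_j}, non-zero proportions \eqn{\delta_j = m_j/n}, and the non-zero
#' cell counts per taxon (\eqn{m_j}) and per sample (\eqn{n_i}).
#'
#' @param ct A [count_table].
#' @return An object of class `template_summary`: list with `rel_abund`,
#'   `presence`, `mean_rel_abund`, `prop_nonzero`, `taxon_nonzero_counts`,
#'   `sample_nonzero_counts`, `zero_fraction`, `lib_sizes`, `sample_ids`,
#'   `taxon_ids`.
#' @export
summarize_template <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  if (any(ct$lib_sizes <= 0)) {
    stop_input("samples with zero library size cannot be summarized; filter first")
  }
  pi_mat <- ct$counts / ct$lib_sizes
  Z <- (ct$counts > 0) * 1
  m <- colSums(Z)
  n_i <- rowSums(Z)
  n <- nrow(ct$counts)
  structure(
    list(rel_abund = pi_mat,
         presence = Z,
         mean_rel_abund = colMeans(pi_mat),
         prop_nonzero = m / n,
         taxon_nonzero_counts = m,
         sample_nonzero_counts = n_i,
         zero_fraction = 1 - sum(m) / (n * ncol(Z)),
         lib_sizes = ct$lib_sizes,
         sample_ids = ct$sample_ids,
         taxon_ids = ct$taxon_ids),
    class = "template_summary"
  )
}

#' @export
print.template_summary <- function(x, ...) {
  cat("<template_summary> ", length(x$sample_ids), " samples x ",
      length(x$taxon_ids), " taxa; zero fraction ",
      signif(x$zero_fraction, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.micosim_model
#' @method tidy template_summary
#' @export
tidy.template_summary <- function(x, ...) {
  tibble::tibble(
    taxon_id = x$taxon_ids,
    mean_rel_abund = unname(x$mean_rel_abund),
    prop_nonzero = unname(x$prop_nonzero),
    n_nonzero = unname(x$taxon_nonzero_counts)
  )
}
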