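#' Generate a taxon count table with known proportions
#'
#' Draws each sample's reads multinomially at its sequencing depth from its
#' true taxon proportions — the generating model under which rarefaction and
#' relative-abundance estimates can be checked for bias.
#'
#' @param true_proportions Numeric matrix (taxa x samples) of per-sample
#'   taxon probabilities, each column summing to 1; a vector is treated as a
#'   single shared profile across all samples.
#' @param depths Integer vector of reads per sample (recycled to the number
#'   of samples). Zero depth yields an all-zero sample.
#' @param taxa,samples Optional names; defaults `taxon_1...`, `sample_1...`.
#' @param seed Integer seed.
#' @return A count table: tibble with a `taxon` character column followed by
#'   one integer column per sample. This wide taxa-by-samples layout is the
#'   `AbundanceTable` convention used by [rarefy()], [relative_abundance()]
#'   and [track_succession()].
#' @examples
#' generate_count_table(c(0.5, 0.3, 0.2), depths = c(100, 200), seed = 1)
#' @export
generate_count_table <- function(true_proportions, depths,
                                 taxa = NULL, samples = NULL, seed = NULL) {
  p <- true_proportions
  if (is.vector(p)) p <- matrix(p, ncol = length(depths), nrow = length(p))
  abort_if(any(p < 0), "Proportions must be non-negative.")
  abort_if(any(abs(colSums(p) - 1) > 1e-8),
           "Each sample's proportions must sum to 1.")
  n_samp <- ncol(p)
  depths <- as.integer(rep_len(depths, n_samp))
  abort_if(any(depths < 0), "`depths` must be non-negative integers.")
  taxa <- taxa %||% paste0("taxon_", seq_len(nrow(p)))
  samples <- samples %||% paste0("sample_", seq_len(n_samp))
  abort_if(anyDuplicated(taxa) > 0 || anyDuplicated(samples) > 0,
           "Taxon and sample names must be unique.")

  counts <- with_seed_or_not(seed, {
    vapply(seq_len(n_samp), function(j) {
      if (depths[j] == 0L) integer(nrow(p))
      else as.integer(stats::rmultinom(1L, size = depths[j], prob = p[, j]))
    }, integer(nrow(p)))
  })
  counts <- matrix(counts, nrow = nrow(p), dimnames = list(NULL, samples))
  dplyr::bind_cols(tibble::tibble(taxon = taxa), tibble::as_tibble(counts))
}

# Split a wide count table into its taxon names and integer count matrix.
count_matrix <- function(table) {
  abort_if(!is.data.frame(table) || !"taxon" %in% names(table),
           "A count table must be a data frame with a `taxon` column.")
  abort_if(anyDuplicated(table$taxon) > 0, "Taxon names must be unique.")
  m <- as.matrix(table[setdiff(names(table), "taxon")])
  abort_if(!is.numeric(m) || any(m < 0) || anyNA(m),
           "Counts must be non-negative numbers.")
  rownames(m) <- table$taxon
  m
}
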