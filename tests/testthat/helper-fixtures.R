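# small in-code fixtures shared across test files

# a tiny methylation matrix built from explicit count tables
tiny_meth <- function(pos = c(100L, 250L, 400L, 1000L),
                      n_samples = 3, beta = NULL, coverage = NULL,
                      chrom = "chr1") {
  n <- length(pos)
  if (!is.null(beta)) n_samples <- ncol(beta)
  else if (!is.null(coverage)) n_samples <- ncol(coverage)
  if (is.null(coverage)) {
    coverage <- matrix(10L, n, n_samples)
  }
  if (is.null(beta)) beta <- matrix(0.5, n, n_samples)
  colnames(beta) <- colnames(coverage) <- paste0("S", seq_len(n_samples))
  MethylationMatrix(beta, coverage, data.frame(chrom = chrom, pos = pos))
}

tiny_expr <- function(tpm) {
  tpm <- as.matrix(tpm)
  counts <- round(tpm * 10)
  storage.mode(counts) <- "integer"
  ExpressionMatrix(counts, tpm)
}

# the standard small coupled cohort used by several tests
small_cohort_config <- function(seed = 1, n_planted_links = 3, ...) {
  simulation_config(n_patients = 10, samples_per_patient = 4,
                    n_genes = 120, n_regions = 150,
                    n_planted_links = n_planted_links,
                    link_effect = 0.8, seed = seed, ...)
}
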