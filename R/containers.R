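#' Methylation matrix container
#'
#' Bundles per-site, per-sample beta values and read coverage together with
#' the site coordinates.  Sites are indexed by (chrom, 0-based position);
#' beta is defined only where coverage > 0 and is `NA` elsewhere.
#'
#' @param beta numeric matrix, sites x samples, values in \[0,1\] or `NA`.
#' @param coverage integer matrix of the same shape, non-negative; `NA`
#'   marks a site absent from a sample.
#' @param sites data.frame with columns `chrom` and `pos` (0-based,
#'   forward strand), one row per row of `beta`.
#' @return An object of class `MethylationMatrix`: a list with elements
#'   `beta`, `coverage`, `sites`.
#' @export
MethylationMatrix <- function(beta, coverage, sites) {
  beta <- as.matrix(beta)
  coverage <- as.matrix(coverage)
  stopifnot(
    nrow(beta) == nrow(sites),
    all(dim(beta) == dim(coverage)),
    all(c("chrom", "pos") %in% names(sites))
  )
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) stop("beta values must lie in [0,1]")
  if (any(!is.na(coverage) & coverage < 0)) {
    stop("coverage must be non-negative")
  }
  rn <- if (nrow(sites)) paste0(sites$chrom, ":", sites$pos) else character()
  rownames(beta) <- rn
  rownames(coverage) <- rn
  structure(
    list(beta = beta, coverage = coverage,
         sites = data.frame(chrom = as.character(sites$chrom),
                            pos = as.integer(sites$pos))),
    class = "MethylationMatrix"
  )
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat("MethylationMatrix:", nrow(x$beta), "CpG sites x",
      ncol(x$beta), "samples\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cov_ok <- mean(!is.na(x$coverage) & x$coverage >= 5)
  cat(sprintf("  fraction of cells with coverage >= 5: %.3f\n", cov_ok))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$beta)

#' Expression matrix container
#'
#' Raw counts and TPM for the same genes x samples grid.  No normalisation
#' is applied at construction; readers preserve gene and sample order.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param tpm non-negative numeric matrix with identical dimnames.
#' @return An object of class `ExpressionMatrix` with elements `counts`,
#'   `tpm`.
#' @export
ExpressionMatrix <- function(counts, tpm) {
  counts <- as.matrix(counts)
  tpm <- as.matrix(tpm)
  if (!identical(dim(counts), dim(tpm))) {
    stop("counts and TPM dimensions differ")
  }
  if (!identical(dimnames(counts), dimnames(tpm))) {
    stop("counts and TPM dimnames differ")
  }
  if (any(counts < 0, na.rm = TRUE) || any(tpm < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative")
  }
  structure(list(counts = counts, tpm = tpm), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Log-scale expression used throughout the pipeline
#'
#' Correlation screens, z-scores and the mean +/- SD extremes all operate on
#' `log2(TPM + 1)`; this helper centralises the transform.
#'
#' @param expr an [ExpressionMatrix] or a TPM matrix.
#' @return numeric matrix of log2(TPM+1) values.
#' @export
log_tpm <- function(expr) {
  m <- if (inherits(expr, "ExpressionMatrix")) expr$tpm else as.matrix(expr)
  log2(m + 1)
}

# ---- internal helpers -------------------------------------------------

# 0-based half-open interval -> GRanges (1-based closed)
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand)
}

# Pearson r and two-sided p (t transform, n-2 df) for paired rows of two
# matrices: r between x[i, ] and y[i, ] for each i.  Rows with zero
# variance yield NA.
row_cor_test <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  n <- ncol(x)
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- rowSums(xc^2)
  sy <- rowSums(yc^2)
  r <- rowSums(xc * yc) / sqrt(sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.na(r) & abs(r) == 1] <- 0
  data.frame(r = r, p = p, n = n)
}
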