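#' Cross-sample z-scores for a set of genes
#'
#' For each gene, `(x - mean) / sd` across samples on the log2(TPM+1)
#' scale, with the sample (n-1) standard deviation.  A constant gene has
#' z = 0 everywhere.  Genes absent from the matrix are dropped with a
#' warning and recorded in the `dropped` attribute.
#'
#' @param expr an [ExpressionMatrix] or a numeric matrix already on the
#'   desired scale.
#' @param genes character vector of gene ids (default: all genes).
#' @return genes x samples matrix of z-scores.
#' @export
gene_zscores <- function(expr, genes = NULL) {
  m <- if (inherits(expr, "ExpressionMatrix")) log_tpm(expr) else
    as.matrix(expr)
  if (ncol(m) < 2) stop("z-scores need >= 2 samples")
  if (is.null(genes)) genes <- rownames(m)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    warning("genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  genes <- intersect(genes, rownames(m))
  sub <- m[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  attr(z, "dropped") <- missing
  z
}

#' Single-sample rank-based enrichment score
#'
#' A signed Kolmogorov-Smirnov-style statistic: within each sample, genes
#' are ranked by decreasing expression and a running sum steps up by
#' 1/|signature| at signature genes and down by 1/(N - |signature|)
#' elsewhere; the score is the maximum positive deviation plus the minimum
#' negative deviation, in (-1, 1).  Positive scores mean the signature
#' genes concentrate at the top of the sample's ranking.  Being rank
#' based, the score is invariant under any strictly monotone transform of
#' a sample's expression values.  This is a self-contained single-sample
#' statistic with the same monotonicity contract as gene-set
#' variance-analysis scores; only its sign is consumed by the subtype
#' classifier.
#'
#' @param expr an [ExpressionMatrix] or expression matrix.
#' @param signature character vector of signature gene ids.
#' @return named numeric vector, one score per sample.
#' @export
enrichment_score <- function(expr, signature) {
  m <- if (inherits(expr, "ExpressionMatrix")) log_tpm(expr) else
    as.matrix(expr)
  sig <- intersect(unique(signature), rownames(m))
  if (length(sig) == 0) stop("no signature gene present in the matrix")
  n <- nrow(m)
  if (length(sig) == n) {                 # degenerate: signature = universe
    return(setNames(rep(0, ncol(m)), colnames(m)))
  }
  in_sig <- rownames(m) %in% sig
  step_hit <- 1 / length(sig)
  step_miss <- -1 / (n - length(sig))
  apply(m, 2, function(x) {
    ord <- order(-x, rownames(m))         # decreasing; ties by gene id
    walk <- cumsum(ifelse(in_sig[ord], step_hit, step_miss))
    max(walk, 0) + min(walk, 0)
  })
}

#' Classify a sample into the five AR/NE molecular subtypes
#'
#' Decision rules (all thresholds configurable, strictness as stated):
#' a sample is AR-negative iff its AR enrichment score is < 0 AND the sum
#' of the AR and KLK3 expression z-scores is < 0; otherwise it is AR+ when
#' the AR-signature z-score sum is > 3.5 and AR-low when <= 3.5.  It is
#' NE+ iff the NE1 z-score sum is > 0.  The combined label is one of
#' AR+/NE-, AR-low/NE-, AR-/NE-, AR-/NE+, AR+/NE+ (AR-low is reported as
#' "AR-low" regardless of NE status; AR-low/NE+ is labelled accordingly).
#'
#' @param ar_score AR signature enrichment score(s).
#' @param ar_klk3_zsum sum of AR and KLK3 z-scores.
#' @param ar_sig_zsum AR-signature z-score sum.
#' @param ne1_zsum NE1 z-score sum.
#' @param ar_plus_threshold AR-signature z-sum cut for AR+ (strict >).
#' @param ne_threshold NE1 z-sum cut for NE+ (strict >).
#' @param ar_neg_score_threshold,ar_neg_zsum_threshold AR-negative cuts
#'   (both strict <, conjunctive).
#' @return character vector of labels; vectorised over the inputs.
#' @export
classify_subtype <- function(ar_score, ar_klk3_zsum, ar_sig_zsum, ne1_zsum,
                             ar_plus_threshold = 3.5, ne_threshold = 0,
                             ar_neg_score_threshold = 0,
                             ar_neg_zsum_threshold = 0) {
  if (any(!is.finite(c(ar_score, ar_klk3_zsum, ar_sig_zsum, ne1_zsum)))) {
    stop("all classifier inputs must be finite")
  }
  ar_negative <- ar_score < ar_neg_score_threshold &
    ar_klk3_zsum < ar_neg_zsum_threshold
  ar_label <- ifelse(ar_negative, "AR-",
                     ifelse(ar_sig_zsum > ar_plus_threshold, "AR+", "AR-low"))
  ne_label <- ifelse(ne1_zsum > ne_threshold, "NE+", "NE-")
  paste0(ar_label, "/", ne_label)
}

#' Subtype calls for a whole cohort
#'
#' Runs the full classification path: AR enrichment score, AR+KLK3 z-sum,
#' AR-signature z-sum and NE1 z-sum per sample, then the threshold rules
#' of [classify_subtype()].
#'
#' @param expr an [ExpressionMatrix].
#' @param signatures named list with character vectors `ar_signature` and
#'   `ne1` (see [default_signatures()]); AR/KLK3 genes via `ar_genes`.
#' @param ar_genes the two genes whose z-sum defines AR negativity.
#' @param ... thresholds forwarded to [classify_subtype()].
#' @return data.frame of class `SubtypeCall` with per-sample scores,
#'   z-sums and `label`.
#' @export
call_subtypes <- function(expr, signatures = default_signatures(),
                          ar_genes = c("AR", "KLK3"), ...) {
  ar_score <- enrichment_score(expr, signatures$ar_signature)
  ne_score <- enrichment_score(expr, signatures$ne1)
  z_ar2 <- gene_zscores(expr, ar_genes)
  z_arsig <- gene_zscores(expr, signatures$ar_signature)
  z_ne1 <- gene_zscores(expr, signatures$ne1)
  out <- data.frame(
    sample_id = colnames(expr$tpm),
    ar_score = unname(ar_score),
    ne_score = unname(ne_score),
    ar_klk3_zsum = unname(colSums(z_ar2)),
    ar_sig_zsum = unname(colSums(z_arsig)),
    ne1_zsum = unname(colSums(z_ne1)),
    stringsAsFactors = FALSE
  )
  out$label <- classify_subtype(out$ar_score, out$ar_klk3_zsum,
                                out$ar_sig_zsum, out$ne1_zsum, ...)
  class(out) <- c("SubtypeCall", "data.frame")
  out
}

#' Bundled signature gene sets
#'
#' Editable TSVs under `inst/extdata/signatures/`.  The BMP4 and FGF
#' pathway sets are the eight-gene sets used for pathway z-sum scores
#' ("SMAD8" is kept under that name; it is an alias of SMAD9).  The AR
#' and NE1 membership lists are curator-entered defaults anchored on the
#' canonical program genes; substitute your own lists for real analyses.
#'
#' @param dir directory of signature TSVs (columns `set`, `gene`).
#' @return named list of character vectors
#'   (`ar_signature`, `ne1`, `bmp4`, `fgf`).
#' @export
default_signatures <- function(dir = system.file("extdata", "signatures",
                                                 package = "methlink")) {
  df <- utils::read.delim(file.path(dir, "signatures.tsv"),
                          stringsAsFactors = FALSE)
  split(df$gene, df$set)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centering plus eigendecomposition (Torgerson MDS) of a
#' symmetric, zero-diagonal, non-negative distance matrix.  Axes
#' corresponding to negative eigenvalues are dropped with a warning, and
#' each retained axis is oriented so that its largest-magnitude loading is
#' positive, making the embedding deterministic.
#'
#' @param d distance matrix (or `dist`).
#' @param dims number of requested dimensions.
#' @return list with `points` (samples x <= dims), `eig` (all
#'   eigenvalues).
#' @export
classical_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be non-negative")
  fit <- stats::cmdscale(stats::as.dist(d), k = min(dims, nrow(d) - 1),
                         eig = TRUE)
  pts <- fit$points
  pos <- sum(fit$eig > 1e-9)
  if (pos < dims) {
    warning("only ", pos, " positive-eigenvalue axes available; returning ",
            min(pos, ncol(pts)))
    pts <- pts[, seq_len(min(pos, ncol(pts))), drop = FALSE]
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  list(points = pts, eig = fit$eig)
}
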