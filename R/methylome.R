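#' Keep CpG sites with adequate coverage in every sample
#'
#' Retains sites whose read coverage is at least `min_coverage` in all
#' samples (default 5, the usual RRBS completeness filter).  Site order is
#' preserved.
#'
#' @param m a [MethylationMatrix].
#' @param min_coverage minimum per-sample coverage (>= 1).
#' @return A filtered [MethylationMatrix]; a warning is raised when no
#'   site survives.
#' @export
filter_complete_sites <- function(m, min_coverage = 5) {
  stopifnot(inherits(m, "MethylationMatrix"), min_coverage >= 1)
  keep <- rowSums(!is.na(m$coverage) & m$coverage >= min_coverage) ==
    ncol(m$coverage)
  if (!any(keep)) {
    warning("no CpG site has coverage >= ", min_coverage, " in all samples")
  }
  MethylationMatrix(m$beta[keep, , drop = FALSE],
                    m$coverage[keep, , drop = FALSE],
                    m$sites[keep, , drop = FALSE])
}

#' Select the most variable features
#'
#' Orders features (rows) by descending variance across samples and keeps
#' the top `k` (all, if fewer exist).  Ties are broken by original row
#' order, i.e. genomic order for site matrices, so the selection is
#' deterministic and invariant under sample permutation.
#'
#' @param x numeric matrix (features x samples) or a [MethylationMatrix]
#'   (uses beta values).
#' @param k number of features to keep.
#' @return integer vector of row indices into `x`, ordered by descending
#'   variance.
#' @export
top_variance_features <- function(x, k) {
  m <- if (inherits(x, "MethylationMatrix")) x$beta else as.matrix(x)
  stopifnot(k >= 1)
  if (ncol(m) < 2) stop("variance needs at least 2 samples")
  v <- apply(m, 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  ord <- order(-v, seq_along(v))    # ties -> genomic order
  head(ord, min(k, nrow(m)))
}

#' Sample-sample Pearson correlation matrix
#'
#' Pearson correlation between sample columns over the supplied features,
#' using pairwise-complete observations (per-patient reselection can
#' reintroduce missing values).  A sample with zero variance across
#' features has undefined correlations, recorded as `NA` with a warning.
#'
#' @param x numeric matrix (features x samples) or [MethylationMatrix].
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation <- function(x) {
  m <- if (inherits(x, "MethylationMatrix")) x$beta else as.matrix(x)
  if (nrow(m) < 2) stop("need >= 2 features for sample correlation")
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  degen <- apply(m, 2, function(col) stats::var(col, na.rm = TRUE) == 0)
  degen[is.na(degen)] <- TRUE
  if (any(degen)) {
    warning("sample(s) with zero variance: ",
            paste(colnames(m)[degen], collapse = ", "))
  }
  diag(r) <- 1
  r
}

#' Intra- versus inter-patient correlation comparison
#'
#' Partitions all unordered sample pairs into intra-patient (same patient)
#' and inter-patient pairs, and compares their correlation values with a
#' two-sided Wilcoxon rank-sum test.  The exact distribution is used when
#' both groups have at most 25 values and there are no ties; otherwise the
#' normal approximation with tie correction.  Optionally restricts the
#' inter-patient set to pairs sharing an anatomic site.
#'
#' @param corr symmetric sample correlation matrix (dimnames = sample ids).
#' @param metadata data.frame with `sample_id`, `patient_id` and optionally
#'   `anatomic_site`.
#' @param stratify_site restrict inter-patient pairs to same anatomic site.
#' @return list of class `CorrelationReport`: `pairs` (data.frame with
#'   `sample_a`, `sample_b`, `type`, `r`), counts `n_intra`/`n_inter`,
#'   group medians, and `statistic`/`p_value` of the two-sided Wilcoxon
#'   test (`NA` when a group is empty).
#' @export
intra_inter_comparison <- function(corr, metadata, stratify_site = FALSE) {
  samples <- colnames(corr)
  if (!all(samples %in% metadata$sample_id)) {
    stop("every sample in the correlation matrix needs metadata")
  }
  patient <- metadata$patient_id[match(samples, metadata$sample_id)]
  site <- if ("anatomic_site" %in% names(metadata)) {
    metadata$anatomic_site[match(samples, metadata$sample_id)]
  } else rep(NA_character_, length(samples))

  idx <- which(upper.tri(corr), arr.ind = TRUE)
  pairs <- data.frame(
    sample_a = samples[idx[, 1]],
    sample_b = samples[idx[, 2]],
    type = ifelse(patient[idx[, 1]] == patient[idx[, 2]], "intra", "inter"),
    r = corr[idx],
    stringsAsFactors = FALSE
  )
  if (stratify_site) {
    same_site <- site[idx[, 1]] == site[idx[, 2]]
    pairs <- pairs[pairs$type == "intra" | same_site, , drop = FALSE]
  }
  intra <- pairs$r[pairs$type == "intra"]
  inter <- pairs$r[pairs$type == "inter"]

  stat <- p <- NA_real_
  if (length(intra) > 0 && length(inter) > 0) {
    exact <- length(intra) <= 25 && length(inter) <= 25 &&
      !anyDuplicated(c(intra, inter))
    wt <- stats::wilcox.test(intra, inter, exact = exact, correct = TRUE)
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(
    list(pairs = pairs,
         n_intra = length(intra), n_inter = length(inter),
         median_intra = stats::median(intra),
         median_inter = stats::median(inter),
         statistic = stat, p_value = p),
    class = "CorrelationReport"
  )
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat("CorrelationReport:", x$n_intra, "intra-patient /", x$n_inter,
      "inter-patient pairs\n")
  cat(sprintf("  median r: intra %.3f, inter %.3f; Wilcoxon two-sided p = %g\n",
              x$median_intra, x$median_inter, x$p_value))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering with distance 1 - Pearson r (average linkage
#' by default), matching the correlation-centric view of methylome
#' similarity.  Accepts either a feature matrix (correlation computed
#' internally) or an already-computed correlation matrix.
#'
#' @param x features x samples matrix, [MethylationMatrix], or a symmetric
#'   correlation matrix (detected by `is_correlation`).
#' @param method linkage passed to [stats::hclust()].
#' @param is_correlation treat `x` as a correlation matrix.
#' @return list with the `hclust` object (`tree`) and the leaf sample
#'   order (`order`, character).
#' @export
hierarchical_cluster <- function(x, method = "average",
                                 is_correlation = FALSE) {
  r <- if (is_correlation) as.matrix(x) else sample_correlation(x)
  if (ncol(r) < 2) stop("need >= 2 samples to cluster")
  d <- 1 - r
  if (anyNA(d)) stop("missing distances; cannot cluster")
  hc <- stats::hclust(stats::as.dist(d), method = method)
  list(tree = hc, order = colnames(r)[hc$order])
}

#' Per-patient methylation clustering
#'
#' For one patient's samples, reselects the top `k` most variable CpGs
#' within that patient and clusters the samples, the per-case view used to
#' dissect intra-individual heterogeneity.
#'
#' @param m a [MethylationMatrix] (already coverage-filtered).
#' @param metadata sample metadata.
#' @param patient patient id.
#' @param k number of CpGs to reselect within the patient.
#' @inheritParams hierarchical_cluster
#' @return as [hierarchical_cluster()].
#' @export
cluster_patient_samples <- function(m, metadata, patient, k = 10000,
                                    method = "average") {
  samples <- metadata$sample_id[metadata$patient_id == patient]
  samples <- intersect(samples, colnames(m$beta))
  if (length(samples) < 2) stop("patient ", patient, " has < 2 samples")
  sub <- m$beta[, samples, drop = FALSE]
  idx <- top_variance_features(sub, k)
  hierarchical_cluster(sub[idx, , drop = FALSE], method = method)
}

#' Serialise a dendrogram as newick
#'
#' @param tree an `hclust` object (e.g. `hierarchical_cluster(x)$tree`).
#' @return single newick string.
#' @export
dendrogram_newick <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("newick export needs the 'ape' package")
  }
  ape::write.tree(ape::as.phylo(tree))
}

#' Mean methylation in fixed genome bins per sample group
#'
#' Divides each chromosome into consecutive `bin_size` windows (bin b
#' covers `[b*size, (b+1)*size)`), averages beta over the member CpGs of a
#' bin within each sample, then averages samples within each group.  Bins
#' with no covered CpG in a group are `NA`.
#'
#' @param m a [MethylationMatrix].
#' @param groups named character vector: sample id -> group label (e.g.
#'   molecular subtype).
#' @param bin_size bin width in bp (default 100,000).
#' @return data.frame with `chrom`, `bin`, `start`, `end` and one mean-beta
#'   column per group.
#' @export
bin_genome_means <- function(m, groups, bin_size = 100000) {
  stopifnot(bin_size > 0)
  samples <- intersect(colnames(m$beta), names(groups))
  if (length(samples) == 0) stop("no sample overlaps the group labels")
  bin <- m$sites$pos %/% bin_size
  key <- paste0(m$sites$chrom, ":", bin)
  ukey <- unique(key)
  out <- data.frame(
    chrom = sub(":[^:]*$", "", ukey),
    bin = as.integer(sub("^.*:", "", ukey))
  )
  out$start <- out$bin * bin_size
  out$end <- out$start + bin_size
  for (g in unique(groups[samples])) {
    gs <- samples[groups[samples] == g]
    # mean over member sites within each sample, then over samples
    per_sample <- vapply(gs, function(s) {
      tapply(m$beta[, s], key, mean, na.rm = TRUE)[ukey]
    }, numeric(length(ukey)))
    per_sample[is.nan(per_sample)] <- NA_real_
    out[[g]] <- rowMeans(as.matrix(per_sample), na.rm = TRUE)
    out[[g]][is.nan(out[[g]])] <- NA_real_
  }
  out[order(out$chrom, out$bin), , drop = FALSE]
}
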