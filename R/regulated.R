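#' Median-of-ratios size-factor normalisation
#'
#' Size factor per sample = median of that sample's ratios to the
#' per-gene geometric mean, over genes with a nonzero geometric mean;
#' normalised counts = counts / size factor.  A single sample gets size
#' factor 1 by convention.
#'
#' @param counts non-negative genes x samples count matrix.
#' @return list with `normalized` (matrix) and `size_factors`.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) == 1) {
    return(list(normalized = counts, size_factors = setNames(1, colnames(counts))))
  }
  log_geo <- rowMeans(log(counts))          # -Inf when any zero
  usable <- is.finite(log_geo)
  sf <- apply(counts, 2, function(col) {
    ratios <- log(col[usable]) - log_geo[usable]
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) == 0) {
      stop("a sample shares no nonzero gene with the geometric-mean reference")
    }
    exp(stats::median(ratios))
  })
  list(normalized = sweep(counts, 2, sf, "/"),
       size_factors = sf)
}

#' Keep genes expressed anywhere in the cohort
#'
#' Drops genes with TPM < 1 in every sample (TPM >= 1 in at least one
#' sample retains the gene).
#'
#' @param expr an [ExpressionMatrix] or TPM matrix.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(expr) {
  tpm <- if (inherits(expr, "ExpressionMatrix")) expr$tpm else as.matrix(expr)
  rownames(tpm)[apply(tpm, 1, max) >= 1]
}

#' Two-group differential expression
#'
#' A self-contained differential test: median-of-ratios normalisation,
#' log2 fold change of group means with a pseudocount, per-gene two-sided
#' Welch t-test on log2(normalised + 1), BH adjustment, and the DEG flag
#' |log2FC| > `lfc_threshold` with adjusted p <= `padj_threshold`.
#' Gene-level p-values are a package substitute for a negative-binomial
#' model; an externally produced DE table can be passed to
#' [nominate_regulated()] instead.
#'
#' @param counts genes x samples count matrix (or [ExpressionMatrix]).
#' @param group_a,group_b disjoint sample id vectors (each >= 2).
#' @param lfc_threshold DEG |log2FC| cut (strict >; default 1).
#' @param padj_threshold DEG BH-adjusted p cut (<=; default 0.05).
#' @param pseudocount added to normalised group means before log2.
#' @return data.frame: `gene`, `mean_a`, `mean_b`, `log2_fold_change`,
#'   `p`, `padj`, `deg`.
#' @export
differential_expression <- function(counts, group_a, group_b,
                                    lfc_threshold = 1, padj_threshold = 0.05,
                                    pseudocount = 1) {
  if (inherits(counts, "ExpressionMatrix")) counts <- counts$counts
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs >= 2 samples")
  }
  stopifnot(all(c(group_a, group_b) %in% colnames(counts)))
  norm <- normalize_counts(counts[, c(group_a, group_b), drop = FALSE])$normalized
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  la <- log2(a + 1); lb <- log2(b + 1)
  p <- vapply(seq_len(nrow(norm)), function(i) {
    if (stats::sd(la[i, ]) == 0 && stats::sd(lb[i, ]) == 0) {
      return(if (mean(la[i, ]) == mean(lb[i, ])) 1 else 0)
    }
    tryCatch(stats::t.test(la[i, ], lb[i, ])$p.value,
             error = function(e) NA_real_)
  }, 0)
  out <- data.frame(
    gene = rownames(norm),
    mean_a = rowMeans(a), mean_b = rowMeans(b),
    log2_fold_change = log2((rowMeans(a) + pseudocount) /
                              (rowMeans(b) + pseudocount)),
    p = p,
    stringsAsFactors = FALSE
  )
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$deg <- !is.na(out$padj) &
    abs(out$log2_fold_change) > lfc_threshold & out$padj <= padj_threshold
  rownames(out) <- NULL
  out
}

#' Single-sample contrast against a reference group
#'
#' For patients contributing a single sample of the phenotype of
#' interest: log2 fold change of that sample versus the reference-group
#' mean on normalised counts (shared pseudocount policy), flagged as DEG
#' when |log2FC| strictly exceeds `lfc_threshold` (default 2).  No
#' p-value exists in this mode.
#'
#' @param counts genes x samples count matrix (or [ExpressionMatrix]).
#' @param sample the single sample id.
#' @param reference reference sample ids (>= 2).
#' @param lfc_threshold |log2FC| cut (strict >).
#' @param pseudocount added before log2.
#' @return data.frame: `gene`, `log2_fold_change`, `deg` (plus `p`,
#'   `padj` columns of `NA` so the table is interchangeable with
#'   [differential_expression()] output).
#' @export
single_sample_contrast <- function(counts, sample, reference,
                                   lfc_threshold = 2, pseudocount = 1) {
  if (inherits(counts, "ExpressionMatrix")) counts <- counts$counts
  if (length(reference) < 2) stop("reference needs >= 2 samples")
  stopifnot(sample %in% colnames(counts), all(reference %in% colnames(counts)))
  norm <- normalize_counts(counts[, c(sample, reference), drop = FALSE])$normalized
  lfc <- log2((norm[, sample] + pseudocount) /
                (rowMeans(norm[, reference, drop = FALSE]) + pseudocount))
  data.frame(gene = rownames(norm), log2_fold_change = lfc,
             p = NA_real_, padj = NA_real_,
             deg = abs(lfc) > lfc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Nomination thresholds for methylation-regulated genes
#'
#' @param lfc_threshold DEG |log2FC| cut (1 for two-group mode, 2 in
#'   single-sample mode).
#' @param padj_threshold DEG adjusted-p cut.
#' @param meth_diff_threshold minimum absolute group difference in region
#'   mean beta (strict >; default 0.10).
#' @param extreme_sd multiplier of the cohort SD for the mean +/- SD
#'   expression extremes.
#' @return list of class `NominationConfig`.
#' @export
nomination_config <- function(lfc_threshold = 1, padj_threshold = 0.05,
                              meth_diff_threshold = 0.10, extreme_sd = 1) {
  stopifnot(lfc_threshold > 0, meth_diff_threshold > 0, extreme_sd > 0)
  structure(list(lfc_threshold = lfc_threshold,
                 padj_threshold = padj_threshold,
                 meth_diff_threshold = meth_diff_threshold,
                 extreme_sd = extreme_sd),
            class = "NominationConfig")
}

#' Nominate DNA-methylation-regulated genes
#'
#' A gene is nominated iff all four conditions hold: (a) it is a DEG
#' between the group of interest and the reference group; (b) it appears
#' in at least one significant region-gene link; (c) at least one linked
#' region's mean beta differs by more than the methylation-difference
#' threshold between the two groups (genes whose linked regions are all
#' unevaluable are excluded with reason); and (d) on log2(TPM+1) the
#' group-of-interest mean lies above the cohort mean + SD (upregulated)
#' or below the cohort mean - SD (downregulated), computed across all
#' cohort samples.  Removing any condition can only enlarge the set.
#'
#' @param degs DE table with columns `gene`, `log2_fold_change`, `deg`
#'   ([differential_expression()] or [single_sample_contrast()] output,
#'   or an externally produced equivalent).
#' @param links significant region-gene links.
#' @param rbeta regions x samples region-beta matrix.
#' @param expr the cohort [ExpressionMatrix] (all samples).
#' @param group_samples samples of the group of interest.
#' @param reference_samples reference-group samples.
#' @param config a [nomination_config()].
#' @return list with `up` and `down` (character vectors of nominated
#'   genes) and `table`: per candidate gene the four condition outcomes,
#'   supporting regions, and the exclusion reason if any.
#' @export
nominate_regulated <- function(degs, links, rbeta, expr, group_samples,
                               reference_samples,
                               config = nomination_config()) {
  le <- log_tpm(expr)
  stopifnot(all(group_samples %in% colnames(le)),
            all(reference_samples %in% colnames(le)))
  deg_genes <- degs$gene[degs$deg]
  candidates <- unique(links$gene)
  all_genes <- union(deg_genes, candidates)
  if (length(all_genes) == 0) {
    return(list(up = character(), down = character(),
                table = data.frame()))
  }
  mu <- rowMeans(le)
  sdv <- apply(le, 1, stats::sd)
  thr_up <- mu + config$extreme_sd * sdv
  thr_dn <- mu - config$extreme_sd * sdv

  rows <- lapply(all_genes, function(g) {
    is_deg <- g %in% deg_genes
    glinks <- links[links$gene == g, , drop = FALSE]
    has_link <- nrow(glinks) > 0
    meth_ok <- FALSE; meth_regions <- character(); reason <- ""
    if (has_link) {
      rids <- intersect(glinks$region_id, rownames(rbeta))
      diffs <- vapply(rids, function(rid) {
        gb <- rbeta[rid, group_samples]
        rb <- rbeta[rid, reference_samples]
        if (all(is.na(gb)) || all(is.na(rb))) return(NA_real_)
        abs(mean(gb, na.rm = TRUE) - mean(rb, na.rm = TRUE))
      }, 0)
      if (length(diffs) == 0 || all(is.na(diffs))) {
        reason <- "methylation unevaluable"
      } else {
        meth_ok <- any(diffs > config$meth_diff_threshold, na.rm = TRUE)
        meth_regions <- rids[!is.na(diffs) &
                               diffs > config$meth_diff_threshold]
      }
    }
    in_matrix <- g %in% rownames(le)
    gmean <- if (in_matrix) mean(le[g, group_samples]) else NA_real_
    extreme <- if (!in_matrix) "none" else if (gmean > thr_up[g]) "up" else
      if (gmean < thr_dn[g]) "down" else "none"
    data.frame(gene = g, deg = is_deg, linked = has_link,
               meth_diff = meth_ok,
               regions = paste(meth_regions, collapse = ";"),
               extreme = extreme, reason = reason,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$nominated <- tab$deg & tab$linked & tab$meth_diff & tab$extreme != "none"
  list(up = tab$gene[tab$nominated & tab$extreme == "up"],
       down = tab$gene[tab$nominated & tab$extreme == "down"],
       table = tab)
}

#' Pathway signature score (z-score sum)
#'
#' Per-sample sum of cross-sample z-scores of the member genes, on
#' log2(TPM+1): the score used for the eight-gene BMP4 and FGF pathway
#' signatures.  Missing member genes are dropped with a warning; scores
#' sum to zero across samples by the centering identity.
#'
#' @param expr an [ExpressionMatrix] or expression matrix.
#' @param signature character vector of member genes.
#' @return named numeric vector, one score per sample.
#' @export
signature_score <- function(expr, signature) {
  z <- gene_zscores(expr, signature)
  if (nrow(z) == 0) stop("no signature gene present")
  colSums(z)
}

#' Gene-set over-representation (one-sided Fisher)
#'
#' Hypergeometric upper-tail p per set (equivalently a one-sided
#' Fisher's exact test on the 2x2 table), BH-adjusted across sets.  Sets
#' disjoint from the universe are skipped with a warning.  No gene-set
#' database is bundled; sets are user inputs.
#'
#' @param selected selected genes (subset of `universe`).
#' @param universe background gene ids.
#' @param gene_sets named list of character vectors.
#' @return data.frame: `set`, `set_size` (in universe), `overlap`, `p`,
#'   `padj`.
#' @export
overrepresentation <- function(selected, universe, gene_sets) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe)) stop("selected genes must be in universe")
  if (any(lengths(gene_sets) == 0)) stop("gene sets must be non-empty")
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    if (length(set) == 0) {
      warning("set '", nm, "' shares no gene with the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(set, selected))
    # upper tail: P(X >= k)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(selected), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), padj = numeric()))
  }
  out$padj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
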