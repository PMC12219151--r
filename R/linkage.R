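#' Build CpG regions by single-linkage chaining
#'
#' Groups CpG sites whose consecutive genomic distance is at most
#' `max_gap` (200 bp by default) into clusters and keeps clusters with at
#' least `min_cpgs` members (3 by default).  Region coordinates span the
#' member CpGs (0-based half-open; `end` = last member position + 1).
#' Chaining on consecutive distances is order-independent; unsorted input
#' is sorted internally with a message.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based) or a
#'   [MethylationMatrix].
#' @param max_gap maximum distance between consecutive member CpGs.
#' @param min_cpgs minimum cluster size.
#' @return data.frame with `region_id`, `chrom`, `start`, `end`,
#'   `n_cpgs`; attribute `members` holds, per region, the integer indices
#'   of member sites into the input site table.
#' @export
build_cpg_regions <- function(sites, max_gap = 200, min_cpgs = 3) {
  if (inherits(sites, "MethylationMatrix")) sites <- sites$sites
  stopifnot(max_gap > 0, min_cpgs >= 1)
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    message("sites were not sorted; sorting by (chrom, pos)")
  }
  chrom <- sites$chrom[ord]
  pos <- sites$pos[ord]
  new_cluster <- c(TRUE, diff(pos) > max_gap | chrom[-1] != chrom[-length(chrom)])
  cl <- cumsum(new_cluster)
  sizes <- tabulate(cl)
  keep_cl <- which(sizes >= min_cpgs)
  members <- lapply(keep_cl, function(k) ord[cl == k])
  regions <- data.frame(
    chrom = vapply(members, function(i) sites$chrom[i[1]], ""),
    start = vapply(members, function(i) min(sites$pos[i]), 0),
    end = vapply(members, function(i) max(sites$pos[i]) + 1, 0),
    n_cpgs = lengths(members)
  )
  regions$region_id <- if (nrow(regions)) {
    paste0(regions$chrom, ":", regions$start, "-", regions$end)
  } else character()
  regions <- regions[, c("region_id", "chrom", "start", "end", "n_cpgs")]
  names(members) <- regions$region_id
  attr(regions, "members") <- members
  regions
}

#' Per-sample region methylation
#'
#' Region beta = mean beta of member CpGs per sample (unweighted by
#' default; `weighted = TRUE` weights by coverage).  Samples where no
#' member CpG is covered yield `NA`.
#'
#' @param regions output of [build_cpg_regions()] (carrying `members`).
#' @param m the [MethylationMatrix] the regions were built from.
#' @param weighted coverage-weighted mean instead of unweighted.
#' @return regions x samples matrix of region beta values.
#' @export
region_beta <- function(regions, m, weighted = FALSE) {
  members <- attr(regions, "members")
  if (is.null(members)) stop("regions carry no member index; rebuild them")
  out <- t(vapply(members, function(idx) {
    b <- m$beta[idx, , drop = FALSE]
    if (!weighted) {
      colMeans(b, na.rm = TRUE)
    } else {
      w <- m$coverage[idx, , drop = FALSE]
      colSums(b * w, na.rm = TRUE) / colSums(w * !is.na(b), na.rm = TRUE)
    }
  }, numeric(ncol(m$beta))))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- regions$region_id
  out
}

#' Union peak set across samples
#'
#' Merges overlapping per-sample peak calls of one histone mark into a
#' union peak set, counts in how many samples each union peak was
#' detected (>= 1 overlapping call), and drops union peaks detected in
#' fewer than `min_samples` samples.
#'
#' @param peak_list named list of per-sample peak data.frames (`chrom`,
#'   `start`, `end`, 0-based half-open), e.g. from [read_peaks()].
#' @param mark histone mark label attached to the result.
#' @param min_samples minimum number of detecting samples (default 2).
#' @return data.frame `peak_id`, `chrom`, `start`, `end`, `mark`,
#'   `detected_in`.
#' @export
union_peaks <- function(peak_list, mark = attr(peak_list, "mark"),
                        min_samples = 2) {
  nonempty <- Filter(function(p) nrow(p) > 0, peak_list)
  if (length(nonempty) == 0) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mark = character(), detected_in = integer()))
  }
  all_df <- do.call(rbind, lapply(names(nonempty), function(s) {
    cbind(nonempty[[s]][, c("chrom", "start", "end")], sample = s)
  }))
  gr <- gr0(all_df$chrom, all_df$start, all_df$end)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  detected <- vapply(seq_along(merged), function(i) {
    length(unique(all_df$sample[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]))
  }, 0L)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,    # back to 0-based
    end = GenomicRanges::end(merged),
    mark = if (is.null(mark)) NA_character_ else mark,
    detected_in = detected
  )
  out <- out[out$detected_in >= min_samples, , drop = FALSE]
  out$peak_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  rownames(out) <- NULL
  out[, c("peak_id", "chrom", "start", "end", "mark", "detected_in")]
}

#' Normalise a peak fragment-count matrix
#'
#' Scales counts-in-peak by per-sample totals (counts per million within
#' the peak set) and applies `log(1 + x)` as a variance-stabilising
#' monotone transform.  Downstream only Pearson correlations are
#' consumed, which are insensitive to the precise monotone rescaling.
#'
#' @param counts peaks x samples non-negative matrix.
#' @return normalised matrix of the same shape.
#' @export
normalize_peak_signal <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log1p(t(t(counts) / tot) * 1e6)
}

#' Correlate histone peak signal with nearby gene expression
#'
#' Candidate pairs are (peak, gene) with the gene's TSS within
#' `window` bp of the peak (distance from TSS to the nearest peak edge;
#' TSS inside the peak counts as 0).  Pearson r and its two-sided p (t
#' transform, n-2 df) are computed per pair over the shared samples,
#' p-values are BH-adjusted across all tested pairs of the mark, and
#' pairs are retained when `fdr < fdr_threshold` AND the sign matches the
#' mark convention: positive for H3K27ac, negative for H3K27me3.
#'
#' @param peaks union peak data.frame from [union_peaks()].
#' @param signal peaks x samples normalised signal matrix (rownames =
#'   `peak_id`).
#' @param expr an [ExpressionMatrix] (correlations use log2(TPM+1)).
#' @param genes gene model table ([read_gene_models()]).
#' @param window TSS window in bp (default 500,000).
#' @param fdr_threshold significance cut (default 0.01).
#' @param keep_all also return non-significant tested pairs (flagged).
#' @return data.frame of peak-gene links: `peak_id`, coordinates, `mark`,
#'   `gene`, `distance`, `r`, `p`, `fdr`, `significant`.  Only
#'   significant rows unless `keep_all`.
#' @export
peak_gene_links <- function(peaks, signal, expr, genes, window = 500000,
                            fdr_threshold = 0.01, keep_all = FALSE) {
  if (nrow(peaks) == 0) {
    return(empty_peak_links())
  }
  mark <- peaks$mark[1]
  le <- log_tpm(expr)
  common <- intersect(colnames(signal), colnames(le))
  if (length(common) < 3) stop("need >= 3 samples shared by signal and expression")
  missing_sig <- setdiff(peaks$peak_id, rownames(signal))
  if (length(missing_sig)) {
    stop("signal matrix lacks peaks: ", paste(head(missing_sig), collapse = ", "))
  }
  pk_gr <- gr0(peaks$chrom, peaks$start, peaks$end)
  tss_gr <- gr0(genes$chrom, genes$tss, genes$tss + 1)
  hits <- GenomicRanges::findOverlaps(
    pk_gr, GenomicRanges::resize(tss_gr, width = 2 * window + 1, fix = "center")
  )
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(pk_gr[pi], tss_gr[gi])
  keep <- !is.na(dist) & dist <= window
  pi <- pi[keep]; gi <- gi[keep]; dist <- dist[keep]
  if (length(pi) == 0) return(empty_peak_links())

  x <- signal[peaks$peak_id[pi], common, drop = FALSE]
  gene_ids <- genes$gene_id[gi]
  present <- gene_ids %in% rownames(le)
  x <- x[present, , drop = FALSE]
  pi <- pi[present]; gi <- gi[present]; dist <- dist[present]
  y <- le[genes$gene_id[gi], common, drop = FALSE]
  ct <- row_cor_test(x, y)
  out <- data.frame(
    peak_id = peaks$peak_id[pi],
    chrom = peaks$chrom[pi], start = peaks$start[pi], end = peaks$end[pi],
    mark = mark, gene = genes$gene_id[gi], distance = dist,
    r = ct$r, p = ct$p
  )
  tested <- !is.na(out$r)
  out <- out[tested, , drop = FALSE]
  if (any(!tested)) {
    warning(sum(!tested), " peak-gene pair(s) skipped (constant values)")
  }
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  sign_ok <- if (identical(mark, "H3K27me3")) out$r < 0 else out$r > 0
  out$significant <- out$fdr < fdr_threshold & sign_ok
  rownames(out) <- NULL
  if (keep_all) out else out[out$significant, , drop = FALSE]
}

empty_peak_links <- function() {
  data.frame(peak_id = character(), chrom = character(), start = integer(),
             end = integer(), mark = character(), gene = character(),
             distance = integer(), r = numeric(), p = numeric(),
             fdr = numeric(), significant = logical())
}

#' Merge nearby significant peaks linked to the same gene
#'
#' Within each (gene, mark), peaks whose intervals are within `merge_gap`
#' bp of each other (gap of exactly `merge_gap` merges; inclusive
#' semantics) are merged into one interval.  The merged peak's r and p are
#' recomputed on the mean normalised signal of its constituents; its FDR
#' is carried as the minimum constituent FDR (the BH family is not re-run
#' after merging).
#'
#' @param links significant peak-gene links from [peak_gene_links()].
#' @param signal the same peaks x samples signal matrix.
#' @param expr the [ExpressionMatrix] used for the screen.
#' @return data.frame like `links` with merged coordinates and an
#'   `n_merged` column.
#' @export
merge_linked_peaks <- function(links, signal, expr, merge_gap = 1000) {
  if (nrow(links) == 0) {
    links$n_merged <- integer()
    return(links)
  }
  le <- log_tpm(expr)
  common <- intersect(colnames(signal), colnames(le))
  pieces <- split(links, paste(links$gene, links$mark, sep = "\r"))
  merged <- lapply(pieces, function(lk) {
    gr <- gr0(lk$chrom, lk$start, lk$end)
    # reduce() merges gaps < min.gapwidth; gap <= merge_gap must merge
    red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1)
    hit <- GenomicRanges::findOverlaps(
      gr, red + merge_gap, select = "first")
    do.call(rbind, lapply(seq_along(red), function(i) {
      rows <- lk[hit == i, , drop = FALSE]
      sig <- colMeans(signal[rows$peak_id, common, drop = FALSE])
      y <- le[rows$gene[1], common]
      ct <- row_cor_test(matrix(sig, 1), matrix(y, 1))
      data.frame(
        peak_id = paste0(rows$chrom[1], ":",
                         GenomicRanges::start(red)[i] - 1L, "-",
                         GenomicRanges::end(red)[i]),
        chrom = rows$chrom[1],
        start = GenomicRanges::start(red)[i] - 1L,
        end = GenomicRanges::end(red)[i],
        mark = rows$mark[1], gene = rows$gene[1],
        distance = min(rows$distance),
        r = ct$r, p = ct$p, fdr = min(rows$fdr),
        significant = TRUE, n_merged = nrow(rows)
      )
    }))
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Categorize CpG regions by histone and genic context
#'
#' Multi-label assignment of candidate (region, category, gene) tuples:
#' \itemize{
#'   \item `H3K27ac-associated` / `H3K27me3-associated`: region within
#'     `flank` bp (inclusive of touching) of a significantly
#'     expression-linked peak of that mark; the peak's linked gene(s)
#'     become the region's candidate genes.  These regions are further
#'     annotated by the first matching genic feature in the hierarchy
#'     promoter > 5'UTR > 3'UTR > gene body, else `intergenic`.
#'   \item `promoter`: region overlapping the strand-aware
#'     `promoter_upstream` bp window upstream of a TSS, gene = that gene.
#'   \item `gene body`: region overlapping the TSS-TES span, gene = the
#'     containing gene.  Overlapping genes each contribute a tuple.
#' }
#' A region may appear under several categories (and genes); regions
#' matching nothing are omitted.
#'
#' @param regions region table from [build_cpg_regions()].
#' @param ac_links,me3_links significant (optionally merged) peak-gene
#'   links for each mark; pass an empty data.frame when unavailable.
#' @param genes gene model table.
#' @param flank histone association distance in bp (default 1000).
#' @param promoter_upstream promoter window upstream of TSS (default 1500).
#' @return data.frame with `region_id`, `chrom`, `start`, `end`,
#'   `category`, `annotation`, `gene`.
#' @export
categorize_regions <- function(regions, ac_links, me3_links, genes,
                               flank = 1000, promoter_upstream = 1500) {
  rg <- gr0(regions$chrom, regions$start, regions$end)
  res <- list()

  histone_tuples <- function(links, label) {
    if (is.null(links) || nrow(links) == 0) return(NULL)
    pk <- gr0(links$chrom, links$start, links$end)
    hits <- GenomicRanges::findOverlaps(rg, pk + flank)
    if (length(hits) == 0) return(NULL)
    ri <- S4Vectors::queryHits(hits)
    li <- S4Vectors::subjectHits(hits)
    data.frame(region_idx = ri, category = label, gene = links$gene[li])
  }
  res$ac <- histone_tuples(ac_links, "H3K27ac-associated")
  res$me3 <- histone_tuples(me3_links, "H3K27me3-associated")

  # strand-aware promoter windows, 0-based half-open
  prom_start <- ifelse(genes$strand == "+",
                       pmax(genes$tss - promoter_upstream, 0), genes$tss + 1)
  prom_end <- ifelse(genes$strand == "+",
                     genes$tss, genes$tss + 1 + promoter_upstream)
  prom <- gr0(genes$chrom, prom_start, prom_end)
  ph <- GenomicRanges::findOverlaps(rg, prom)
  if (length(ph)) {
    res$prom <- data.frame(region_idx = S4Vectors::queryHits(ph),
                           category = "promoter",
                           gene = genes$gene_id[S4Vectors::subjectHits(ph)])
  }
  body <- gr0(genes$chrom, pmin(genes$tss, genes$tes),
              pmax(genes$tss, genes$tes) + 1)
  bh <- GenomicRanges::findOverlaps(rg, body)
  if (length(bh)) {
    res$body <- data.frame(region_idx = S4Vectors::queryHits(bh),
                           category = "gene body",
                           gene = genes$gene_id[S4Vectors::subjectHits(bh)])
  }
  tuples <- do.call(rbind, res)
  if (is.null(tuples) || nrow(tuples) == 0) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      category = character(), annotation = character(),
                      gene = character()))
  }
  tuples <- unique(tuples)
  ann <- annotate_regions(rg, genes, promoter_upstream)
  out <- data.frame(
    region_id = regions$region_id[tuples$region_idx],
    chrom = regions$chrom[tuples$region_idx],
    start = regions$start[tuples$region_idx],
    end = regions$end[tuples$region_idx],
    category = tuples$category,
    annotation = ifelse(tuples$category %in% c("promoter", "gene body"),
                        tuples$category, ann[tuples$region_idx]),
    gene = tuples$gene,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$region_id, out$category, out$gene), , drop = FALSE]
}

# first matching feature in the hierarchy promoter > 5'UTR > 3'UTR >
# gene body, else intergenic
annotate_regions <- function(rg, genes, promoter_upstream = 1500) {
  ann <- rep("intergenic", length(rg))
  overlap_any <- function(feature_gr) {
    GenomicRanges::countOverlaps(rg, feature_gr) > 0
  }
  utr_gr <- function(col) {
    ivs <- lapply(genes[[col]], parse_intervals)
    n <- vapply(ivs, nrow, 0L)
    if (sum(n) == 0) return(GenomicRanges::GRanges())
    df <- do.call(rbind, ivs)
    gr0(rep(genes$chrom, n), df$start, df$end)
  }
  prom_start <- ifelse(genes$strand == "+",
                       pmax(genes$tss - promoter_upstream, 0), genes$tss + 1)
  prom_end <- ifelse(genes$strand == "+",
                     genes$tss, genes$tss + 1 + promoter_upstream)
  feats <- list(
    promoter = gr0(genes$chrom, prom_start, prom_end),
    `5'UTR` = utr_gr("utr5"),
    `3'UTR` = utr_gr("utr3"),
    `gene body` = gr0(genes$chrom, pmin(genes$tss, genes$tes),
                      pmax(genes$tss, genes$tes) + 1)
  )
  for (nm in rev(names(feats))) {          # apply in reverse priority
    hit <- overlap_any(feats[[nm]])
    ann[hit] <- nm
  }
  ann
}

#' Region-gene methylation-expression links
#'
#' For every candidate (region, gene, category) tuple, Pearson r between
#' region beta and log2(TPM+1) expression over shared samples, two-sided
#' p (t transform), BH adjustment within each category family, and
#' retention at `fdr < fdr_threshold`.  Both correlation signs are
#' permitted; the sign is recorded.
#'
#' @param candidates tuples from [categorize_regions()].
#' @param rbeta regions x samples matrix from [region_beta()].
#' @param expr an [ExpressionMatrix].
#' @param fdr_threshold significance cut (default 0.01).
#' @param keep_all also return non-significant tested tuples.
#' @return link data.frame: candidate columns plus `r`, `p`, `fdr`,
#'   `sign`, `significant`, `validated` (NA until [validate_links()]).
#' @export
region_gene_links <- function(candidates, rbeta, expr, fdr_threshold = 0.01,
                              keep_all = FALSE) {
  if (nrow(candidates) == 0) {
    out <- cbind(candidates,
                 data.frame(r = numeric(), p = numeric(), fdr = numeric(),
                            sign = character(), significant = logical(),
                            validated = logical()))
    return(out)
  }
  le <- log_tpm(expr)
  common <- intersect(colnames(rbeta), colnames(le))
  if (length(common) < 3) stop("need >= 3 shared samples")
  ok_gene <- candidates$gene %in% rownames(le)
  ok_region <- candidates$region_id %in% rownames(rbeta)
  cand <- candidates[ok_gene & ok_region, , drop = FALSE]
  x <- rbeta[cand$region_id, common, drop = FALSE]
  y <- le[cand$gene, common, drop = FALSE]
  # pairwise-complete: region beta may be NA in some samples
  ct <- vapply(seq_len(nrow(cand)), function(i) {
    xi <- x[i, ]; yi <- y[i, ]
    use <- !is.na(xi) & !is.na(yi)
    if (sum(use) < 3) return(c(NA_real_, NA_real_))
    res <- row_cor_test(matrix(xi[use], 1), matrix(yi[use], 1))
    c(res$r, res$p)
  }, numeric(2))
  cand$r <- ct[1, ]
  cand$p <- ct[2, ]
  tested <- !is.na(cand$r)
  cand <- cand[tested, , drop = FALSE]
  cand$fdr <- NA_real_
  for (cat in unique(cand$category)) {
    i <- cand$category == cat
    cand$fdr[i] <- stats::p.adjust(cand$p[i], method = "BH")
  }
  cand$sign <- ifelse(cand$r < 0, "negative", "positive")
  cand$significant <- cand$fdr < fdr_threshold
  cand$validated <- NA
  rownames(cand) <- NULL
  if (keep_all) cand else cand[cand$significant, , drop = FALSE]
}

#' Validate links in a replication cohort
#'
#' Recomputes each link's correlation in an independent cohort: region
#' beta is re-derived from the replication CpGs falling inside the
#' region's coordinates, correlated with the replication expression of
#' the linked gene.  A link is validated when the replication correlation
#' has the same sign and p < `p_threshold` (this package's criterion).
#' Links that cannot be looked up are marked not-validated with a reason.
#'
#' @param links link data.frame from [region_gene_links()].
#' @param repl_meth replication [MethylationMatrix].
#' @param repl_expr replication [ExpressionMatrix].
#' @param p_threshold replication significance cut (default 0.05).
#' @return `links` with `validated` filled in and a
#'   `validation_reason` column (`"ok"`, `"uncovered"`, `"gene_missing"`,
#'   `"sign_mismatch"`, `"not_significant"`).
#' @export
validate_links <- function(links, repl_meth, repl_expr, p_threshold = 0.05) {
  if (ncol(repl_meth$beta) == 0) stop("empty replication cohort")
  le <- log_tpm(repl_expr)
  common <- intersect(colnames(repl_meth$beta), colnames(le))
  if (length(common) < 3) stop("replication cohort needs >= 3 samples")
  links$validated <- FALSE
  links$validation_reason <- "uncovered"
  site_gr <- gr0(repl_meth$sites$chrom, repl_meth$sites$pos,
                 repl_meth$sites$pos + 1)
  reg_gr <- gr0(links$chrom, links$start, links$end)
  hits <- GenomicRanges::findOverlaps(reg_gr, site_gr)
  member <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (i in seq_len(nrow(links))) {
    idx <- member[[as.character(i)]]
    if (is.null(idx)) next
    if (!(links$gene[i] %in% rownames(le))) {
      links$validation_reason[i] <- "gene_missing"
      next
    }
    b <- colMeans(repl_meth$beta[idx, common, drop = FALSE], na.rm = TRUE)
    y <- le[links$gene[i], common]
    use <- !is.nan(b) & !is.na(b)
    if (sum(use) < 3) next
    ct <- row_cor_test(matrix(b[use], 1), matrix(y[use], 1))
    if (is.na(ct$r)) next
    if (sign(ct$r) != sign(links$r[i])) {
      links$validation_reason[i] <- "sign_mismatch"
    } else if (ct$p >= p_threshold) {
      links$validation_reason[i] <- "not_significant"
    } else {
      links$validated[i] <- TRUE
      links$validation_reason[i] <- "ok"
    }
  }
  links
}

#' Per-category link directionality summary
#'
#' For each category, counts distinct genes whose links are
#' majority-negative versus majority-positive (ties count as positive in
#' neither; they are reported separately).
#'
#' @param links link data.frame.
#' @return data.frame with `category`, `n_genes`, `negative`, `positive`,
#'   `tied`.
#' @export
summarize_link_directionality <- function(links) {
  if (nrow(links) == 0) {
    return(data.frame(category = character(), n_genes = integer(),
                      negative = integer(), positive = integer(),
                      tied = integer()))
  }
  do.call(rbind, lapply(split(links, links$category), function(lk) {
    per_gene <- tapply(lk$r < 0, lk$gene, function(neg) {
      nneg <- sum(neg); npos <- sum(!neg)
      if (nneg > npos) "negative" else if (npos > nneg) "positive" else "tied"
    })
    data.frame(category = lk$category[1],
               n_genes = length(per_gene),
               negative = sum(per_gene == "negative"),
               positive = sum(per_gene == "positive"),
               tied = sum(per_gene == "tied"),
               row.names = NULL)
  }))
}

#' Run the full linkage pipeline on a cohort bundle
#'
#' Convenience wrapper chaining coverage filtering, region construction,
#' peak union + screening + merging, categorization and region-gene link
#' inference with the standard defaults.
#'
#' @param cohort a cohort bundle ([simulate_cohort()] or assembled from
#'   the readers: elements `meth`, `expr`, `peak_calls`, `peak_signal`,
#'   `genes`).
#' @param min_coverage coverage completeness filter.
#' @param fdr_threshold FDR cut for both screens.
#' @param window,max_gap,min_cpgs,flank,promoter_upstream,merge_gap
#'   pipeline parameters (documented on the individual steps).
#' @return list with `links`, `candidates`, `regions`, `rbeta`,
#'   `ac_links`, `me3_links`, `n_tested` (tuples entering the region
#'   screen).
#' @export
run_linkage <- function(cohort, min_coverage = 5, fdr_threshold = 0.01,
                        window = 500000, max_gap = 200, min_cpgs = 3,
                        flank = 1000, promoter_upstream = 1500,
                        merge_gap = 1000) {
  meth <- filter_complete_sites(cohort$meth, min_coverage)
  regions <- build_cpg_regions(meth, max_gap = max_gap, min_cpgs = min_cpgs)
  rbeta <- region_beta(regions, meth)
  screen_mark <- function(mark) {
    calls <- cohort$peak_calls[[mark]]
    if (is.null(calls)) return(empty_peak_links())
    pk <- union_peaks(calls, mark = mark)
    sig <- cohort$peak_signal[[mark]]
    pk <- pk[pk$peak_id %in% rownames(sig), , drop = FALSE]
    lk <- peak_gene_links(pk, sig, cohort$expr, cohort$genes,
                          window = window, fdr_threshold = fdr_threshold)
    merge_linked_peaks(lk, sig, cohort$expr, merge_gap = merge_gap)
  }
  ac <- screen_mark("H3K27ac")
  me3 <- screen_mark("H3K27me3")
  cand <- categorize_regions(regions, ac, me3, cohort$genes,
                             flank = flank,
                             promoter_upstream = promoter_upstream)
  links <- region_gene_links(cand, rbeta, cohort$expr,
                             fdr_threshold = fdr_threshold)
  list(links = links, candidates = cand, regions = regions, rbeta = rbeta,
       ac_links = ac, me3_links = me3, n_tested = nrow(cand))
}
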