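test_that("CpG region chaining handles the worked example", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 250L, 400L, 1000L))
  regs <- build_cpg_regions(sites, max_gap = 200, min_cpgs = 3)
  # gaps 150, 150, 600: one 3-CpG region spanning 100-400; 1000 dropped
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start, 100)
  expect_equal(regs$end, 401)
  expect_equal(regs$n_cpgs, 3L)
  # two CpGs only: below min_cpgs
  expect_equal(nrow(build_cpg_regions(
    data.frame(chrom = "chr1", pos = c(10L, 20L)))), 0)
})

test_that("region chaining equals the brute-force transitive closure", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(3:50, 1)
    pos <- sort(sample(1:5000, n))
    gap <- sample(c(50, 100, 200, 400), 1)
    mc <- sample(2:4, 1)
    regs <- build_cpg_regions(data.frame(chrom = "chrX", pos = pos),
                              max_gap = gap, min_cpgs = mc)
    oracle <- oracle_chain_regions(pos, gap, mc)
    oracle_spans <- vapply(oracle, function(x) {
      paste0(min(x), "-", max(x) + 1)
    }, "")
    got_spans <- if (nrow(regs)) paste0(regs$start, "-", regs$end) else
      character(0)
    expect_setequal(got_spans, oracle_spans)
    expect_equal(sum(regs$n_cpgs), sum(lengths(oracle)))
  }
})

test_that("region beta is the mean of member CpG betas", {
  beta <- matrix(c(0.2, 0.4, 0.6, 0.9), 4, 1)
  m <- tiny_meth(pos = c(100L, 150L, 200L, 5000L), n_samples = 1,
                 beta = beta, coverage = matrix(10L, 4, 1))
  regs <- build_cpg_regions(m)
  rb <- region_beta(regs, m)
  expect_equal(unname(rb[1, 1]), 0.4)
  # coverage-weighted variant
  m2 <- tiny_meth(pos = c(100L, 150L, 200L), n_samples = 1,
                  beta = matrix(c(0.2, 0.4, 0.6), 3, 1),
                  coverage = matrix(c(10L, 10L, 20L), 3, 1))
  regs2 <- build_cpg_regions(m2)
  rbw <- region_beta(regs2, m2, weighted = TRUE)
  expect_equal(unname(rbw[1, 1]), (0.2 * 10 + 0.4 * 10 + 0.6 * 20) / 40)
})

test_that("peak unions merge overlaps and apply the detection filter", {
  calls <- list(
    A = data.frame(chrom = "chr1", start = 100L, end = 200L, signal = 1),
    B = data.frame(chrom = "chr1", start = 150L, end = 300L, signal = 1),
    C = data.frame(chrom = "chr1", start = 5000L, end = 5100L, signal = 1)
  )
  pk <- union_peaks(calls, mark = "H3K27ac")
  # A+B overlap -> union [100,300) detected in 2 and retained;
  # C's peak is single-sample and excluded
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 300L)
  expect_equal(pk$detected_in, 2L)
  # disjoint peaks in >= 2 samples stay separate
  calls2 <- list(
    A = data.frame(chrom = "chr1", start = c(0L, 1000L),
                   end = c(10L, 1100L), signal = 1),
    B = data.frame(chrom = "chr1", start = c(0L, 1000L),
                   end = c(10L, 1100L), signal = 1)
  )
  expect_equal(nrow(union_peaks(calls2, mark = "H3K27me3")), 2)
})

test_that("interval union matches the all-pairs merge oracle", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    start <- sample(0:2000, n, replace = TRUE)
    iv <- cbind(start, start + sample(10:300, n, replace = TRUE))
    calls <- list(
      A = data.frame(chrom = "chr9", start = iv[, 1], end = iv[, 2],
                     signal = 1),
      B = data.frame(chrom = "chr9", start = iv[, 1], end = iv[, 2],
                     signal = 1)
    )
    pk <- union_peaks(calls, mark = "H3K27ac")
    oracle <- oracle_merge_intervals(iv)
    expect_equal(pk$start, unname(oracle[, 1]))
    expect_equal(pk$end, unname(oracle[, 2]))
  }
})

test_that("peak-gene screening enforces the window, FDR and sign rules", {
  set.seed(17)
  n <- 30
  samples <- paste0("S", 1:n)
  genes <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                      strand = "+", tss = c(1000L, 400000L, 900000L),
                      tes = c(5000L, 405000L, 905000L),
                      utr5 = "", utr3 = "")
  peaks <- data.frame(peak_id = "chr1:2000-2500", chrom = "chr1",
                      start = 2000L, end = 2500L, mark = "H3K27ac",
                      detected_in = 5L)
  e <- matrix(rnorm(3 * n, 5, 1), 3, n,
              dimnames = list(genes$gene_id, samples))
  sig <- matrix(e["G1", ] + rnorm(n, 0, 0.1), 1, n,
                dimnames = list("chr1:2000-2500", samples))
  expr <- tiny_expr(2^e - 1)
  links <- peak_gene_links(peaks, sig, expr, genes, window = 500000,
                           keep_all = TRUE)
  # G3's TSS is 897,500 bp from the peak edge: beyond the window;
  # G1 and G2 are the candidates
  expect_setequal(links$gene, c("G1", "G2"))
  expect_true(links$significant[links$gene == "G1"])
  expect_false(any(links$significant[links$gene != "G1"]))

  # H3K27me3 peak positively tracking expression is never significant
  peaks$mark <- "H3K27me3"
  links2 <- peak_gene_links(peaks, sig, expr, genes, keep_all = TRUE)
  expect_false(any(links2$significant[links2$r > 0]))
})

test_that("a distant TSS is excluded by the +-0.5 Mb window", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      tss = 600000L, tes = 605000L, utr5 = "", utr3 = "")
  peaks <- data.frame(peak_id = "chr1:0-100", chrom = "chr1", start = 0L,
                      end = 100L, mark = "H3K27ac", detected_in = 2L)
  sig <- matrix(rnorm(10), 1, 10,
                dimnames = list("chr1:0-100", paste0("S", 1:10)))
  tpm <- matrix(rexp(10), 1, 10,
                dimnames = list("G1", paste0("S", 1:10)))
  links <- peak_gene_links(peaks, sig, tiny_expr(tpm), genes,
                           keep_all = TRUE)
  expect_equal(nrow(links), 0)    # 599,900 > 500,000
})

test_that("a 20-pair screen equals a brute-force r/p/BH oracle loop", {
  set.seed(23)
  n <- 24
  samples <- paste0("S", 1:n)
  ngene <- 20
  genes <- data.frame(gene_id = paste0("G", 1:ngene), chrom = "chr1",
                      strand = "+",
                      tss = seq(1000L, by = 10000L, length.out = ngene),
                      tes = seq(6000L, by = 10000L, length.out = ngene),
                      utr5 = "", utr3 = "")
  peaks <- data.frame(peak_id = "chr1:50000-50500", chrom = "chr1",
                      start = 50000L, end = 50500L, mark = "H3K27ac",
                      detected_in = 3L)
  e <- matrix(rnorm(ngene * n, 4, 1), ngene, n,
              dimnames = list(genes$gene_id, samples))
  sigv <- rnorm(n)
  e[3, ] <- 4 + sigv * 2 + rnorm(n, 0, 0.4)      # one coupled gene
  e <- pmax(e, 0.01)                             # keep TPM non-negative
  sig <- matrix(sigv, 1, n, dimnames = list(peaks$peak_id, samples))
  expr <- tiny_expr(2^e - 1)
  links <- peak_gene_links(peaks, sig, expr, genes, keep_all = TRUE)
  # oracle: per-pair r, p from t transform, BH by hand formula
  le <- log2(expr$tpm + 1)
  or <- vapply(links$gene, function(g) {
    r <- cor(sigv, le[g, ])
    t <- r * sqrt((n - 2) / (1 - r^2))
    c(r = r, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
  }, numeric(2))
  expect_equal(links$r, unname(or["r", ]), tolerance = 1e-12)
  expect_equal(links$p, unname(or["p", ]), tolerance = 1e-12)
  expect_equal(links$fdr, oracle_bh(links$p), tolerance = 1e-12)
  expect_equal(links$significant,
               oracle_bh(links$p) < 0.01 & links$r > 0)
})

test_that("BH adjustment matches the hand example and its invariants", {
  p <- c(0.001, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.003, 0.03, 0.04))
  expect_equal(oracle_bh(p), c(0.003, 0.03, 0.04))
  set.seed(3)
  for (rep in 1:25) {
    p <- runif(sample(2:50, 1))
    adj <- p.adjust(p, "BH")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone
  }
})

test_that("linked peaks merge by gap with inclusive boundary semantics", {
  n <- 12
  samples <- paste0("S", 1:n)
  e <- rnorm(n)
  mk_links <- function(starts, ends, genes) {
    data.frame(peak_id = paste0("chr1:", starts, "-", ends), chrom = "chr1",
               start = starts, end = ends, mark = "H3K27ac", gene = genes,
               distance = 0L, r = 0.9, p = 1e-6, fdr = 1e-5,
               significant = TRUE)
  }
  sig <- matrix(rep(e, each = 4) + rnorm(4 * n, 0, 0.1), 4, n)
  rownames(sig) <- c("chr1:1000-1500", "chr1:2000-2400",
                     "chr1:3400-3500", "chr1:9000-9100")
  colnames(sig) <- samples
  expr <- tiny_expr(matrix(2^e, 1, n, dimnames = list("G", samples)))

  # gap 500 -> merge; gap exactly 1000 -> merge (inclusive); gap 5500 -> not
  links <- mk_links(c(1000L, 2000L, 3400L, 9000L),
                    c(1500L, 2400L, 3500L, 9100L), "G")
  merged <- merge_linked_peaks(links, sig, expr, merge_gap = 1000)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start[1], 1000L)
  expect_equal(merged$end[1], 3500L)
  expect_equal(merged$n_merged, c(3L, 1L))
  # same peaks on different genes do not merge
  links2 <- mk_links(c(1000L, 2000L), c(1500L, 2400L), c("G", "G2"))
  sig2 <- sig[1:2, ]; rownames(sig2) <- links2$peak_id
  expr2 <- tiny_expr(matrix(2^rbind(e, e), 2, n,
                            dimnames = list(c("G", "G2"), samples)))
  expect_equal(nrow(merge_linked_peaks(links2, sig2, expr2)), 2)
})

test_that("region categorization follows the promoter/flank/hierarchy rules", {
  genes <- data.frame(
    gene_id = c("G", "H"), chrom = "chr1", strand = c("+", "+"),
    tss = c(10000L, 30000L), tes = c(20000L, 40000L),
    utr5 = c("10000-10200", "30000-30200"),
    utr3 = c("19700-20000", "39700-40000"))
  regions <- data.frame(
    region_id = c("R1", "R2", "R3"), chrom = "chr1",
    start = c(9200L, 31000L, 25000L),
    end = c(9300L, 31100L, 25100L), n_cpgs = 3L)
  # an H3K27ac peak linked to G sits 900 bp from R2
  ac <- data.frame(peak_id = "chr1:32000-32500", chrom = "chr1",
                   start = 32000L, end = 32500L, mark = "H3K27ac",
                   gene = "G", distance = 0L, r = 0.9, p = 1e-7,
                   fdr = 1e-6, significant = TRUE)
  none <- ac[0, ]
  tup <- categorize_regions(regions, ac, none, genes)
  # R1 at TSS-800..-700: promoter of G
  expect_true(any(tup$region_id == "R1" & tup$category == "promoter" &
                    tup$gene == "G"))
  # R2: within 1 kb of the G-linked peak AND inside H's gene body
  expect_true(any(tup$region_id == "R2" &
                    tup$category == "H3K27ac-associated" & tup$gene == "G"))
  expect_true(any(tup$region_id == "R2" & tup$category == "gene body" &
                    tup$gene == "H"))
  # the histone tuple carries the hierarchy annotation (inside H's body)
  expect_equal(unique(tup$annotation[tup$region_id == "R2" &
                                       tup$category == "H3K27ac-associated"]),
               "gene body")
  # R3 is intergenic and > 1 kb from any peak: no tuples
  expect_false("R3" %in% tup$region_id)
})

test_that("region flank proximity matches a naive all-pairs distance oracle", {
  set.seed(41)
  for (rep in 1:20) {
    nr <- sample(5:40, 1)
    rs <- sort(sample(seq(0, 200000, by = 100), nr))
    regions <- data.frame(region_id = paste0("R", seq_len(nr)),
                          chrom = "chr2", start = rs, end = rs + 150,
                          n_cpgs = 3L)
    np <- sample(2:10, 1)
    ps <- sample(seq(0, 200000, by = 100), np)
    ac <- data.frame(peak_id = paste0("P", seq_len(np)), chrom = "chr2",
                     start = ps, end = ps + 400, mark = "H3K27ac",
                     gene = paste0("LG", seq_len(np)), distance = 0L,
                     r = 0.9, p = 1e-7, fdr = 1e-6, significant = TRUE)
    genes <- data.frame(gene_id = "FAR", chrom = "chr2", strand = "+",
                        tss = 900000L, tes = 905000L, utr5 = "", utr3 = "")
    tup <- categorize_regions(regions, ac, ac[0, ], genes, flank = 1000)
    # oracle: region within 1 kb of peak <=> expanded intervals overlap
    for (i in seq_len(nr)) for (j in seq_len(np)) {
      expected <- oracle_overlaps(regions$start[i], regions$end[i],
                                  ac$start[j] - 1000, ac$end[j] + 1000)
      got <- any(tup$region_id == regions$region_id[i] &
                   tup$gene == ac$gene[j])
      expect_equal(got, expected)
    }
  }
})

test_that("region-gene links honor FDR families and record both signs", {
  set.seed(47)
  n <- 30
  samples <- paste0("S", 1:n)
  nr <- 15
  rb <- matrix(runif(nr * n, 0.2, 0.8), nr, n,
               dimnames = list(paste0("R", 1:nr), samples))
  e <- matrix(rnorm(nr * n, 4, 1), nr, n,
              dimnames = list(paste0("G", 1:nr), samples))
  e[1, ] <- 8 - 6 * rb[1, ] + rnorm(n, 0, 0.2)    # strong negative
  e[2, ] <- 2 + 6 * rb[2, ] + rnorm(n, 0, 0.2)    # strong positive
  cand <- data.frame(region_id = paste0("R", 1:nr), chrom = "chr1",
                     start = 1:nr * 1000L, end = 1:nr * 1000L + 100L,
                     category = rep(c("promoter", "gene body"),
                                    length.out = nr),
                     annotation = "promoter", gene = paste0("G", 1:nr))
  expr <- tiny_expr(2^e - 1)
  links <- region_gene_links(cand, rb, expr, keep_all = TRUE)
  # oracle loop per category family
  le <- log2(expr$tpm + 1)
  for (cat in unique(cand$category)) {
    rows <- which(links$category == cat)
    pr <- vapply(rows, function(i) {
      r <- cor(rb[links$region_id[i], ], le[links$gene[i], ])
      t <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(abs(t), n - 2, lower.tail = FALSE)
    }, 0)
    expect_equal(links$fdr[rows], oracle_bh(pr), tolerance = 1e-10)
  }
  sig <- links[links$significant, ]
  expect_true(all(c("G1", "G2") %in% sig$gene))
  expect_equal(sig$sign[sig$gene == "G1"], "negative")
  expect_equal(sig$sign[sig$gene == "G2"], "positive")
  # a perfectly anti-tracking pair is retained with r = -1
  rb2 <- matrix(seq(0.1, 0.9, length.out = 6), 1, 6,
                dimnames = list("R1", paste0("S", 1:6)))
  e2 <- matrix(10 - seq(0.1, 0.9, length.out = 6), 1, 6,
               dimnames = list("G1", paste0("S", 1:6)))
  l2 <- region_gene_links(cand[1, ], rb2, tiny_expr(2^e2 - 1))
  expect_equal(l2$r, -1)
  expect_true(l2$significant)
})

test_that("validation flags replication support and uncovered regions", {
  co <- simulate_cohort(small_cohort_config(seed = 5))
  res <- run_linkage(co)
  expect_gt(nrow(res$links), 0)
  # replication identical to discovery: everything validates
  v <- validate_links(res$links, co$meth, co$expr)
  expect_true(all(v$validated))
  # a region outside replication coverage is flagged "uncovered"
  shifted <- res$links[1, ]
  shifted$start <- 9e7; shifted$end <- 9e7 + 100
  v2 <- validate_links(shifted, co$meth, co$expr)
  expect_false(v2$validated)
  expect_equal(v2$validation_reason, "uncovered")
})

test_that("label-shuffled replication collapses the validation rate", {
  co <- simulate_cohort(small_cohort_config(seed = 8))
  res <- run_linkage(co)
  planted <- res$links[paste(res$links$region_id, res$links$gene) %in%
                         paste(co$truth$planted_links$region_id,
                               co$truth$planted_links$gene), ]
  set.seed(99)
  rates <- vapply(1:10, function(i) {
    perm <- sample(ncol(co$meth$beta))
    shuf <- co$meth
    colnames(shuf$beta) <- colnames(shuf$beta)[perm]
    colnames(shuf$coverage) <- colnames(shuf$beta)
    mean(validate_links(planted, shuf, co$expr)$validated)
  }, 0)
  expect_lt(mean(rates), 0.15)
})

test_that("directionality summary tallies majority signs per gene", {
  links <- data.frame(
    category = c(rep("H3K27ac-associated", 4), rep("promoter", 2)),
    gene = c("A", "A", "B", "C", "D", "D"),
    r = c(-0.5, -0.6, 0.4, -0.9, -0.3, 0.3))
  s <- summarize_link_directionality(links)
  ac <- s[s$category == "H3K27ac-associated", ]
  expect_equal(ac$n_genes, 3)
  expect_equal(ac$negative, 2)   # A (2 neg), C (1 neg)
  expect_equal(ac$positive, 1)   # B
  expect_equal(s[s$category == "promoter", "tied"], 1)   # D: 1 neg, 1 pos
  # all-negative input: 100% negative per category
  all_neg <- data.frame(category = "promoter", gene = c("X", "Y"),
                        r = c(-0.2, -0.8))
  sn <- summarize_link_directionality(all_neg)
  expect_equal(sn$negative, sn$n_genes)
})
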