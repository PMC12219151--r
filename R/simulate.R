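#' Configuration for the cohort simulator
#'
#' Defines the statistical structure of a simulated multi-patient,
#' multi-site cohort: patient-specific methylation baselines shared across
#' a patient's metastases, subtype-specific AR/NE expression programs, and
#' planted sign-constrained methylation-expression-histone couplings.
#'
#' @param n_patients number of patients.
#' @param samples_per_patient `NULL` (draw 1-8 sites per patient, median
#'   ~4), a single integer, or a vector of per-patient sample counts.
#' @param n_genes number of genes (must exceed the signature genes plus
#'   planted/regulated genes).
#' @param n_regions number of CpG regions laid out on the genome.
#' @param n_cpg_sites optional total CpG count; extra sites beyond the
#'   region members are scattered as singletons/pairs that the >= 3-CpG
#'   region filter must discard.
#' @param n_planted_links planted region-gene links per category: a
#'   single count applied to each of the four categories, or a named
#'   vector over `"H3K27ac-associated"`, `"H3K27me3-associated"`,
#'   `"promoter"`, `"gene body"`.
#' @param link_effect target |Pearson r| between region beta and linked
#'   gene expression in the emitted matrices (0 < r < 1).
#' @param patient_baseline_sd SD of per-site patient-level beta logit
#'   offsets; > 0 makes intra-patient methylation correlation exceed
#'   inter-patient correlation.
#' @param subtype_assignment `NULL` (random per patient), a character
#'   vector of one label per patient, or a list of per-sample label
#'   vectors (allowing heterogeneous patients).
#' @param subtype_probs label probabilities for random assignment, in the
#'   order AR+/NE-, AR-low/NE-, AR-/NE-, AR-/NE+, AR+/NE+.
#' @param coverage_mean,coverage_dispersion negative-binomial read
#'   coverage model (mean / size).
#' @param noise_sd residual SD of log2 expression.
#' @param n_regulated_genes when > 0, patient 1 becomes a two-subtype
#'   "heterogeneous" case (4 reference + 4 double-negative samples) with
#'   this many planted methylation-regulated genes (half up, half down in
#'   the DN samples), each also carrying a promoter region-gene link.
#' @param n_background_peaks uncoupled histone peaks per mark.
#' @param seed integer seed; a fixed seed gives byte-identical cohorts.
#' @return validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_patients = 12, samples_per_patient = NULL,
                              n_genes = 300, n_regions = 500,
                              n_cpg_sites = NULL, n_planted_links = 5,
                              link_effect = 0.7, patient_baseline_sd = 0.6,
                              subtype_assignment = NULL,
                              subtype_probs = c(0.34, 0.15, 0.08, 0.39, 0.04),
                              coverage_mean = 40, coverage_dispersion = 20,
                              noise_sd = 0.5, n_regulated_genes = 0,
                              n_background_peaks = 30, seed = 1) {
  categories <- c("H3K27ac-associated", "H3K27me3-associated",
                  "promoter", "gene body")
  if (length(n_planted_links) == 1 && is.null(names(n_planted_links))) {
    n_planted_links <- setNames(rep(n_planted_links, 4), categories)
  } else {
    stopifnot(all(names(n_planted_links) %in% categories))
    full <- setNames(rep(0L, 4), categories)
    full[names(n_planted_links)] <- n_planted_links
    n_planted_links <- full
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    samples_per_patient = samples_per_patient,
    n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
    n_cpg_sites = n_cpg_sites, n_planted_links = n_planted_links,
    link_effect = link_effect, patient_baseline_sd = patient_baseline_sd,
    subtype_assignment = subtype_assignment, subtype_probs = subtype_probs,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    noise_sd = noise_sd, n_regulated_genes = as.integer(n_regulated_genes),
    n_background_peaks = as.integer(n_background_peaks),
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_patients > 0, cfg$n_genes > 0, cfg$n_regions > 0,
            all(cfg$n_planted_links >= 0),
            cfg$link_effect > 0, cfg$link_effect < 1,
            cfg$patient_baseline_sd >= 0, cfg$coverage_mean > 0,
            cfg$coverage_dispersion > 0, cfg$noise_sd >= 0,
            cfg$n_regulated_genes >= 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

SUBTYPE_LABELS <- c("AR+/NE-", "AR-low/NE-", "AR-/NE-", "AR-/NE+", "AR+/NE+")

# latent-correlation inflation offsetting attenuation from the logit
# transform, binomial count noise and patient offsets (see methods
# vignette for the variance accounting)
LINK_EFFECT_INFLATION <- 1.10

#' Simulate a coupled multi-omic cohort with planted ground truth
#'
#' Generates beta values on the logit scale (global site level + per-site
#' patient offset + planted coupling + noise, then inverse logit), read
#' coverage from a negative binomial with binomially sampled methylated
#' counts, subtype-shifted expression programs for the AR/NE signature
#' genes, and H3K27ac/H3K27me3 peaks whose signal tracks (positively /
#' negatively) their target gene's expression.  Planted region-gene links
#' share a latent per-sample factor between region methylation and gene
#' expression, with the sign set by category convention (negative for
#' H3K27ac-associated and promoter links, positive for
#' H3K27me3-associated, alternating for gene bodies).
#'
#' All randomness flows from `config$seed` through a single generator in
#' a fixed draw order, so a fixed config is byte-identical across runs.
#'
#' @param config a [simulation_config()].
#' @return list of class `MethCohort`: `meth` ([MethylationMatrix]),
#'   `expr` ([ExpressionMatrix]), `peak_calls` (mark -> per-sample peak
#'   data.frames), `peak_signal` (mark -> peaks x samples matrix),
#'   `genes` (gene model table), `metadata`, `truth` (class
#'   `GroundTruth`: `planted_links`, `subtype_labels`, `patient_map`,
#'   `regulated_genes`, `dn_samples`, `reference_samples`, plus the
#'   region/gene namespaces), and `config`.
#' @export
simulate_cohort <- function(config) {
  build_cohort(config, couple = TRUE)
}

#' Simulate an uncoupled (null) cohort
#'
#' Identical layout and marginal distributions to [simulate_cohort()] but
#' with every coupling removed: methylation, expression and histone
#' signal are mutually independent given the patient baselines, no
#' subtype expression shifts are applied, and `truth$planted_links` is
#' empty.  Used to calibrate the FDR of the link screens.
#'
#' @inheritParams simulate_cohort
#' @return as [simulate_cohort()].
#' @export
simulate_null <- function(config) {
  build_cohort(config, couple = FALSE)
}

build_cohort <- function(config, couple = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  categories <- names(config$n_planted_links)

  ## --- samples & patients (draw 1) ---------------------------------
  spp <- config$samples_per_patient
  if (is.null(spp)) {
    spp <- sample(1:8, config$n_patients, replace = TRUE,
                  prob = c(0.08, 0.12, 0.17, 0.25, 0.15, 0.10, 0.08, 0.05))
  } else if (length(spp) == 1) {
    spp <- rep(as.integer(spp), config$n_patients)
  }
  stopifnot(length(spp) == config$n_patients, all(spp > 0))
  regulated_mode <- config$n_regulated_genes > 0
  if (regulated_mode) spp[1] <- 8L   # heterogeneous case: 4 + 4
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  patient_of <- rep(patients, spp)
  samples <- unlist(lapply(seq_along(patients), function(i) {
    sprintf("%s_S%d", patients[i], seq_len(spp[i]))
  }))
  n_samples <- length(samples)

  ## --- subtype labels (draw 2) -------------------------------------
  sa <- config$subtype_assignment
  if (is.null(sa)) {
    # largest-remainder allocation keeps every simulated cohort close to
    # the target subtype composition; patient order is randomised
    quota <- config$subtype_probs * config$n_patients
    n_lab <- floor(quota)
    short <- config$n_patients - sum(n_lab)
    if (short > 0) {
      bump <- order(quota - n_lab, decreasing = TRUE)[seq_len(short)]
      n_lab[bump] <- n_lab[bump] + 1
    }
    per_patient <- sample(rep(SUBTYPE_LABELS, n_lab))
    labels <- rep(per_patient, spp)
  } else if (is.list(sa)) {
    stopifnot(length(sa) == config$n_patients,
              all(lengths(sa) == spp))
    labels <- unlist(sa)
  } else {
    stopifnot(length(sa) == config$n_patients)
    labels <- rep(sa, spp)
  }
  if (regulated_mode) {
    labels[patient_of == patients[1]] <- rep(c("AR+/NE-", "AR-/NE-"),
                                             each = 4)
  }
  names(labels) <- samples
  dn_samples <- if (regulated_mode) {
    samples[patient_of == patients[1] & labels == "AR-/NE-"]
  } else character()
  ref_samples <- if (regulated_mode) {
    samples[patient_of == patients[1] & labels == "AR+/NE-"]
  } else character()

  ## --- gene layout (draw 3) ----------------------------------------
  sigs <- default_signatures()
  sig_genes <- unique(c("AR", "KLK3", sigs$ar_signature, sigs$ne1,
                        sigs$bmp4, sigs$fgf))
  n_filler <- config$n_genes - length(sig_genes)
  if (n_filler < 0) stop("n_genes must be >= ", length(sig_genes),
                         " to accommodate the signature genes")
  gene_ids <- c(sig_genes, sprintf("GENE%04d", seq_len(n_filler)))
  slot <- 50000L; span <- 10000L
  slot_start <- (seq_len(config$n_genes) - 1L) * slot + 10000L
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE,
                   prob = c(0.7, 0.3))
  tss <- ifelse(strand == "+", slot_start, slot_start + span)
  tes <- ifelse(strand == "+", slot_start + span, slot_start)
  utr5 <- ifelse(strand == "+",
                 paste0(tss, "-", tss + 200),
                 paste0(tss + 1 - 200, "-", tss + 1))
  utr3 <- ifelse(strand == "+",
                 paste0(tes - 300, "-", tes),
                 paste0(tes, "-", tes + 300))
  genes <- data.frame(gene_id = gene_ids, chrom = "chr1", strand = strand,
                      tss = as.integer(tss), tes = as.integer(tes),
                      utr5 = utr5, utr3 = utr3, stringsAsFactors = FALSE)
  gene_mu <- c(rep(1.5, length(sig_genes)),
               stats::rnorm(n_filler, 3.5, 0.8))
  names(gene_mu) <- gene_ids

  ## --- choose planted genes (fillers only) --------------------------
  filler_idx <- which(!(gene_ids %in% sig_genes))
  n_link_total <- sum(config$n_planted_links)
  need <- n_link_total + config$n_regulated_genes
  if (need > length(filler_idx)) {
    stop("planted regions cannot be placed without overlap: need ", need,
         " distinct non-signature genes, have ", length(filler_idx))
  }
  chosen <- sample(filler_idx, need)
  link_gene_idx <- if (n_link_total > 0) chosen[seq_len(n_link_total)] else
    integer()
  link_category <- rep(categories, config$n_planted_links)
  reg_gene_idx <- if (regulated_mode) tail(chosen, config$n_regulated_genes)
    else integer()
  reg_dir <- rep(c("up", "down"), length.out = config$n_regulated_genes)

  ## --- region layout (draw 4) --------------------------------------
  # per planted link / regulated gene: one region at a category-specific
  # offset inside the gene's slot; remaining regions fill promoters,
  # bodies and far-intergenic space of unclaimed genes.
  region_plan <- list()
  add_region <- function(gene_idx, kind, planted_category = NA,
                         planted_sign = NA, regulated = NA) {
    region_plan[[length(region_plan) + 1L]] <<- list(
      gene_idx = gene_idx, kind = kind, category = planted_category,
      sign = planted_sign, regulated = regulated)
  }
  sign_of <- function(cat, k) {
    switch(cat,
           "H3K27ac-associated" = -1,
           "promoter" = -1,
           "H3K27me3-associated" = +1,
           "gene body" = if (k %% 2 == 0) +1 else -1)
  }
  for (k in seq_along(link_gene_idx)) {
    cat <- link_category[k]
    kind <- switch(cat, "promoter" = "promoter", "gene body" = "body",
                   "H3K27ac-associated" = "ac", "H3K27me3-associated" = "me3")
    add_region(link_gene_idx[k], kind, cat, sign_of(cat, k))
  }
  for (k in seq_along(reg_gene_idx)) {
    add_region(reg_gene_idx[k], "promoter", "promoter", -1, reg_dir[k])
  }
  n_rest <- config$n_regions - length(region_plan)
  if (n_rest < 0) stop("n_regions too small for the planted links")
  unclaimed <- setdiff(seq_len(config$n_genes),
                       c(link_gene_idx, reg_gene_idx))
  rest_kinds <- rep(c("promoter", "body", "far"),
                    c(ceiling(n_rest * 0.5), ceiling(n_rest * 0.3),
                      n_rest - ceiling(n_rest * 0.5) - ceiling(n_rest * 0.3)))
  rest_genes <- rep_len(unclaimed, n_rest)
  for (k in seq_len(n_rest)) add_region(rest_genes[k], rest_kinds[k])
  # occurrence index per (gene, kind): repeated fillers shift anchors
  plan_key <- vapply(region_plan, function(r) {
    paste(r$gene_idx, r$kind)
  }, "")
  occurrence <- stats::ave(seq_along(plan_key), plan_key,
                           FUN = seq_along) - 1L

  region_anchor <- function(gene_idx, kind, occ = 0L) {
    s0 <- slot_start[gene_idx]
    if (kind == "promoter") {
      base <- if (strand[gene_idx] == "+") tss[gene_idx] - 1200 else
        tss[gene_idx] + 400
      base + 800 * occ
    } else {
      switch(kind,
             body = s0 + 3000 + 1500 * (gene_idx %% 2) + 800 * occ,
             ac = s0 + 15700,   # 100-850 bp from the ac peak edge
             me3 = s0 + 20700,
             far = s0 + 40000 + 800 * occ)
    }
  }
  n_regions <- length(region_plan)
  sizes <- sample(3:6, n_regions, replace = TRUE)
  site_list <- vector("list", n_regions)
  for (k in seq_len(n_regions)) {
    rp <- region_plan[[k]]
    anchor <- region_anchor(rp$gene_idx, rp$kind, occurrence[k])
    gaps <- sample(40:60, sizes[k] - 1, replace = TRUE)
    site_list[[k]] <- as.integer(anchor + cumsum(c(0, gaps)))
  }
  region_tab <- data.frame(
    region_id = vapply(site_list, function(p) {
      paste0("chr1:", min(p), "-", max(p) + 1)
    }, ""),
    gene = gene_ids[vapply(region_plan, `[[`, 0L, "gene_idx")],
    kind = vapply(region_plan, `[[`, "", "kind"),
    category = vapply(region_plan, function(r) as.character(r$category), ""),
    sign = vapply(region_plan, function(r) as.numeric(r$sign), 0),
    regulated = vapply(region_plan, function(r) as.character(r$regulated), ""),
    stringsAsFactors = FALSE
  )

  ## scattered sub-threshold CpGs (singletons / pairs)
  scatter <- integer()
  if (!is.null(config$n_cpg_sites)) {
    extra <- config$n_cpg_sites - sum(sizes)
    if (extra > 0) {
      zones <- slot_start[rep_len(seq_len(config$n_genes), extra)] + 30000L
      scatter <- as.integer(zones + sample(0:2000, extra, replace = TRUE) * 2L)
      scatter <- setdiff(scatter, unlist(site_list))
    }
  }
  pos <- c(unlist(site_list), scatter)
  site_region <- c(rep(seq_len(n_regions), sizes),
                   rep(NA_integer_, length(scatter)))
  ord <- order(pos)
  pos <- pos[ord]; site_region <- site_region[ord]
  n_sites <- length(pos)

  ## --- methylation latent structure (draws 5-8) ---------------------
  site_mu <- stats::rnorm(n_sites, 0, 1.2)
  pat_off <- matrix(stats::rnorm(n_sites * config$n_patients, 0,
                                 config$patient_baseline_sd),
                    n_sites, config$n_patients,
                    dimnames = list(NULL, patients))
  rho <- min(0.98, config$link_effect * LINK_EFFECT_INFLATION)
  latent <- matrix(stats::rnorm(n_regions * n_samples), n_regions, n_samples)
  eps_region <- matrix(stats::rnorm(n_regions * n_samples),
                       n_regions, n_samples)
  eps_expr_link <- matrix(stats::rnorm(n_regions * n_samples),
                          n_regions, n_samples)
  a_B <- 1.8; a_E <- 1.5

  logit_beta <- matrix(site_mu, n_sites, n_samples) +
    pat_off[, match(patient_of, patients)] +
    matrix(stats::rnorm(n_sites * n_samples, 0, 0.3), n_sites, n_samples)
  region_latent <- matrix(0, n_regions, n_samples)   # shared with expr
  if (couple) {
    # regulated genes derive their coupling from the group contrast
    # alone, keeping within-group variance at the residual level
    planted <- which(region_tab$category != "NA" & !is.na(region_tab$sign) &
                       region_tab$sign != 0 &
                       !(region_tab$regulated %in% c("up", "down")))
    for (k in planted) {
      shared <- sqrt(rho) * latent[k, ] + sqrt(1 - rho) * eps_region[k, ]
      region_latent[k, ] <- region_tab$sign[k] * a_B * shared
    }
    if (regulated_mode) {
      reg_rows <- which(region_tab$regulated %in% c("up", "down"))
      for (k in reg_rows) {
        shift <- if (region_tab$regulated[k] == "up") -2.5 else +2.5
        region_latent[k, samples %in% dn_samples] <-
          region_latent[k, samples %in% dn_samples] + shift
      }
    }
    has_region <- !is.na(site_region)
    logit_beta[has_region, ] <- logit_beta[has_region, ] +
      region_latent[site_region[has_region], ]
  }
  beta_true <- stats::plogis(logit_beta)
  coverage <- matrix(stats::rnbinom(n_sites * n_samples,
                                    size = config$coverage_dispersion,
                                    mu = config$coverage_mean),
                     n_sites, n_samples)
  met <- matrix(stats::rbinom(n_sites * n_samples, as.vector(coverage),
                              as.vector(beta_true)),
                n_sites, n_samples)
  beta <- ifelse(coverage > 0, met / coverage, NA_real_)
  colnames(beta) <- colnames(coverage) <- samples
  meth <- MethylationMatrix(beta, coverage,
                            data.frame(chrom = "chr1", pos = pos))

  ## --- expression (draw 9) ------------------------------------------
  logx <- matrix(gene_mu, config$n_genes, n_samples,
                 dimnames = list(gene_ids, samples)) +
    matrix(stats::rnorm(config$n_genes * n_samples, 0, config$noise_sd),
           config$n_genes, n_samples)
  if (couple) {
    ar_prog <- unique(c("AR", "KLK3", sigs$ar_signature))
    shift_for <- function(lbl) {
      ar <- sub("/.*", "", lbl); ne <- sub(".*/", "", lbl)
      c(ar_plus = if (ar == "AR+") 5 else if (ar == "AR-low") 2.5 else 0,
        ne_plus = if (ne == "NE+") 4 else 0)
    }
    sh <- vapply(labels, shift_for, numeric(2))
    logx[ar_prog, ] <- logx[ar_prog, ] +
      matrix(sh["ar_plus", ], length(ar_prog), n_samples, byrow = TRUE)
    logx[sigs$ne1, ] <- logx[sigs$ne1, ] +
      matrix(sh["ne_plus", ], length(sigs$ne1), n_samples, byrow = TRUE)
    is_dn <- labels == "AR-/NE-"
    if (any(is_dn)) {        # pathway programs active in double negatives
      logx[sigs$bmp4, is_dn] <- logx[sigs$bmp4, is_dn] + 3
      logx[sigs$fgf, is_dn] <- logx[sigs$fgf, is_dn] + 2
    }
    for (k in planted) {
      shared <- sqrt(rho) * latent[k, ] + sqrt(1 - rho) * eps_expr_link[k, ]
      logx[region_tab$gene[k], ] <- logx[region_tab$gene[k], ] + a_E * shared
    }
    if (regulated_mode) {
      for (k in which(region_tab$regulated %in% c("up", "down"))) {
        delta <- if (region_tab$regulated[k] == "up") 3.5 else -3.5
        logx[region_tab$gene[k], samples %in% dn_samples] <-
          logx[region_tab$gene[k], samples %in% dn_samples] + delta
      }
    }
  }
  tpm <- pmax(2^logx - 1, 0)
  depth <- exp(stats::rnorm(n_samples, log(20), 0.2))
  counts <- matrix(stats::rpois(length(tpm),
                                as.vector(t(t(tpm) * depth))),
                   nrow(tpm), ncol(tpm), dimnames = dimnames(tpm))
  expr <- ExpressionMatrix(counts, tpm)

  ## --- histone peaks (draw 10) --------------------------------------
  peak_bundle <- simulate_peaks(config, region_tab, slot_start, gene_ids,
                                logx, samples, couple)

  ## --- metadata (draw 11) -------------------------------------------
  metadata <- data.frame(
    sample_id = samples, patient_id = patient_of,
    anatomic_site = sample(c("lymph_node", "liver", "lung", "bone",
                             "prostate", "brain", "other"),
                           n_samples, replace = TRUE,
                           prob = c(0.26, 0.25, 0.09, 0.07, 0.08, 0.09, 0.16)),
    morphology = ifelse(grepl("NE\\+$", labels), "NEPC", "adenocarcinoma"),
    stringsAsFactors = FALSE
  )

  planted_links <- region_tab[!is.na(region_tab$sign) &
                                region_tab$sign != 0 & couple,
                              c("region_id", "gene", "category", "sign")]
  planted_links$sign <- ifelse(planted_links$sign < 0, "negative", "positive")
  rownames(planted_links) <- NULL
  truth <- structure(
    list(planted_links = planted_links,
         subtype_labels = labels,
         patient_map = setNames(patient_of, samples),
         regulated_genes = if (regulated_mode && couple) {
           data.frame(gene = region_tab$gene[region_tab$regulated %in%
                                               c("up", "down")],
                      direction = region_tab$regulated[
                        region_tab$regulated %in% c("up", "down")],
                      region_id = region_tab$region_id[
                        region_tab$regulated %in% c("up", "down")],
                      stringsAsFactors = FALSE)
         } else data.frame(gene = character(), direction = character(),
                           region_id = character()),
         dn_samples = dn_samples, reference_samples = ref_samples,
         gene_universe = gene_ids,
         region_universe = region_tab$region_id),
    class = "GroundTruth")

  structure(
    list(meth = meth, expr = expr,
         peak_calls = peak_bundle$calls, peak_signal = peak_bundle$signal,
         genes = genes, metadata = metadata, truth = truth, config = config),
    class = "MethCohort")
}

# planted peaks (one per H3K27ac/H3K27me3 planted link) + background
# peaks; per-sample calls equal the union interval where detected
simulate_peaks <- function(config, region_tab, slot_start, gene_ids,
                           logx, samples, couple) {
  n_samples <- length(samples)
  mk <- function(mark) {
    kind <- if (mark == "H3K27ac") "ac" else "me3"
    off <- if (mark == "H3K27ac") 15000L else 20000L
    rows <- which(region_tab$kind == kind)
    gene_idx <- match(region_tab$gene[rows], gene_ids)
    planted <- data.frame(
      chrom = rep("chr1", length(rows)),
      start = as.integer(slot_start[gene_idx] + off),
      end = as.integer(slot_start[gene_idx] + off + 600L),
      gene = region_tab$gene[rows])
    bg_slots <- sample(seq_along(slot_start), config$n_background_peaks,
                       replace = TRUE)
    bg <- data.frame(
      chrom = "chr1",
      start = as.integer(slot_start[bg_slots] + 30000L +
                           sample(0:40, config$n_background_peaks,
                                  replace = TRUE) * 100L),
      end = 0L, gene = NA_character_)
    bg$end <- bg$start + 400L
    peaks <- unique(rbind(planted, bg))
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    # keep a strict gap between peaks so the union preserves intervals
    keep <- c(TRUE, peaks$start[-1] > head(peaks$end, -1))
    peaks <- peaks[keep, , drop = FALSE]
    peak_id <- paste0("chr1:", peaks$start, "-", peaks$end)

    sig <- matrix(stats::rnorm(nrow(peaks) * n_samples, 2, 1),
                  nrow(peaks), n_samples,
                  dimnames = list(peak_id, samples))
    if (couple) {
      for (i in which(!is.na(peaks$gene))) {
        e <- logx[peaks$gene[i], ]
        ez <- (e - mean(e)) / max(stats::sd(e), 1e-8)
        dir <- if (mark == "H3K27ac") 1 else -1
        sig[i, ] <- 2 + dir * 0.95 * ez +
          stats::rnorm(n_samples, 0, 0.3)
      }
    }
    detected <- matrix(stats::runif(nrow(peaks) * n_samples) < 0.9,
                       nrow(peaks), n_samples)
    few <- rowSums(detected) < 2
    detected[few, 1:2] <- TRUE
    # a couple of single-sample peaks exercise the detected_in filter
    if (nrow(peaks) > 2) {
      solo_start <- max(peaks$end) + c(5000L, 9000L)
      solo <- data.frame(chrom = "chr1", start = solo_start,
                         end = solo_start + 300L, gene = NA_character_)
      solo_det <- matrix(FALSE, 2, n_samples)
      solo_det[, 1] <- TRUE
      peaks <- rbind(peaks, solo)
      detected <- rbind(detected, solo_det)
      sig <- rbind(sig, matrix(stats::rnorm(2 * n_samples, 2, 1), 2,
                               n_samples))
      rownames(sig) <- paste0("chr1:", peaks$start, "-", peaks$end)
    }
    calls <- lapply(seq_len(n_samples), function(s) {
      i <- detected[, s]
      data.frame(chrom = peaks$chrom[i], start = peaks$start[i],
                 end = peaks$end[i],
                 signal = round(pmax(sig[i, s], 0), 3))
    })
    names(calls) <- samples
    attr(calls, "mark") <- mark
    list(calls = calls, signal = sig)
  }
  ac <- mk("H3K27ac"); me3 <- mk("H3K27me3")
  list(calls = list(H3K27ac = ac$calls, H3K27me3 = me3$calls),
       signal = list(H3K27ac = ac$signal, H3K27me3 = me3$signal))
}

#' @export
print.MethCohort <- function(x, ...) {
  cat("MethCohort:", ncol(x$meth$beta), "samples,",
      nrow(x$meth$beta), "CpG sites,", nrow(x$expr$counts), "genes,",
      nrow(x$truth$planted_links), "planted links\n")
  invisible(x)
}

#' Score inferred links against the planted ground truth
#'
#' @param links inferred link data.frame (significant rows of
#'   [region_gene_links()]).
#' @param truth the `GroundTruth` element of a simulated cohort.
#' @return list: `sensitivity` (recovered / planted), `sign_accuracy`
#'   (over recovered links only, `NaN` when none), `false_links` (count
#'   of inferred links not planted), `recovered` (logical per planted
#'   link), plus `n_planted` and `n_inferred`.
#' @export
evaluate_recovery <- function(links, truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (nrow(links) > 0) {
    if (!all(links$gene %in% truth$gene_universe)) {
      stop("link and truth gene namespaces do not match")
    }
  }
  key <- function(df) paste(df$region_id, df$gene, df$category, sep = "\r")
  planted <- truth$planted_links
  pk <- key(planted)
  ik <- if (nrow(links)) key(links) else character()
  recovered <- pk %in% ik
  sign_ok <- rep(NA, nrow(planted))
  if (any(recovered)) {
    m <- match(pk[recovered], ik)
    sign_ok[recovered] <- links$sign[m] == planted$sign[recovered]
  }
  list(
    sensitivity = if (nrow(planted)) mean(recovered) else NaN,
    sign_accuracy = if (any(recovered)) mean(sign_ok[recovered]) else NaN,
    false_links = sum(!(ik %in% pk)),
    recovered = recovered,
    n_planted = nrow(planted), n_inferred = length(ik)
  )
}
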