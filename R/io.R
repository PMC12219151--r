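#' Read per-sample CpG methylation tables
#'
#' Accepts the Bismark coverage dialect (chrom, start, end, percent
#' methylation, methylated count, unmethylated count; 1-based positions) or
#' a plain 4-column dialect (chrom, position, methylated, unmethylated).
#' Positions are converted to 0-based forward-strand coordinates on read.
#' With `collapse_strands = TRUE`, a record at position p+1 is treated as
#' the reverse-strand half of the CpG at p and is merged into it by summing
#' counts, mirroring how methylation callers collapse CpGs to the forward
#' strand.
#'
#' @param paths character vector of file paths, one per sample; names are
#'   used as sample ids (defaulting to the file base names).
#' @param collapse_strands merge records at adjacent positions p, p+1.
#' @param dialect `"auto"` (by column count), `"bismark"` or `"plain"`.
#' @return A [MethylationMatrix] with sites aligned across samples; a site
#'   absent from a sample has `NA` beta and `NA` coverage there.
#' @export
read_methylation <- function(paths, collapse_strands = FALSE,
                             dialect = c("auto", "bismark", "plain")) {
  dialect <- match.arg(dialect)
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  per_sample <- lapply(seq_along(paths), function(i) {
    path <- paths[[i]]
    df <- tryCatch(
      utils::read.delim(path, header = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e))
    )
    nc <- ncol(df)
    d <- if (dialect == "auto") {
      if (nc >= 6) "bismark" else if (nc == 4) "plain" else {
        stop(path, ": cannot infer methylation dialect from ", nc, " columns")
      }
    } else dialect
    tab <- suppressWarnings(if (d == "bismark") {
      if (nc < 6) stop(path, ": bismark coverage dialect needs 6 columns")
      data.frame(chrom = as.character(df[[1]]),
                 pos = as.integer(df[[2]]) - 1L,   # 1-based -> 0-based
                 met = as.integer(df[[5]]),
                 unmet = as.integer(df[[6]]))
    } else {
      if (nc != 4) stop(path, ": plain dialect needs 4 columns")
      data.frame(chrom = as.character(df[[1]]),
                 pos = as.integer(df[[2]]) - 1L,
                 met = as.integer(df[[3]]),
                 unmet = as.integer(df[[4]]))
    })   # non-numeric fields surface as the malformed-record error below
    if (anyNA(tab$pos) || anyNA(tab$met) || anyNA(tab$unmet)) {
      bad <- which(is.na(tab$pos) | is.na(tab$met) | is.na(tab$unmet))[1]
      stop(path, ": malformed record at line ", bad)
    }
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
    if (collapse_strands) tab <- collapse_cpg_strands(tab)
    key <- paste0(tab$chrom, ":", tab$pos)
    if (anyDuplicated(key)) {
      stop(path, ": duplicate site ", key[duplicated(key)][1])
    }
    tab
  })
  names(per_sample) <- names(paths)

  keys <- lapply(per_sample, function(t) paste0(t$chrom, ":", t$pos))
  all_keys <- unique(unlist(keys))
  first <- do.call(rbind, per_sample)[!duplicated(unlist(keys)), ]
  ord <- order(first$chrom, first$pos)
  all_keys <- all_keys[ord]
  sites <- first[ord, c("chrom", "pos")]

  met <- unmet <- matrix(NA_integer_, length(all_keys), length(paths),
                         dimnames = list(all_keys, names(paths)))
  for (i in seq_along(per_sample)) {
    idx <- match(keys[[i]], all_keys)
    met[idx, i] <- per_sample[[i]]$met
    unmet[idx, i] <- per_sample[[i]]$unmet
  }
  coverage <- met + unmet
  beta <- ifelse(!is.na(coverage) & coverage > 0, met / coverage, NA_real_)
  MethylationMatrix(beta, coverage, sites)
}

# merge (p, p+1) record pairs within one sample by summing counts onto p
collapse_cpg_strands <- function(tab) {
  out <- vector("list", length(unique(tab$chrom)))
  i <- 0L
  for (chr in unique(tab$chrom)) {
    t <- tab[tab$chrom == chr, , drop = FALSE]
    follows <- c(FALSE, diff(t$pos) == 1L)
    # a record flagged `follows` is absorbed into its predecessor unless the
    # predecessor was itself absorbed (runs of 3+ positions pair greedily)
    absorb <- logical(nrow(t))
    for (k in which(follows)) absorb[k] <- !absorb[k - 1L]
    keep <- which(!absorb)
    t$met[keep] <- t$met[keep] +
      ifelse(keep + 1L <= nrow(t) & absorb[pmin(keep + 1L, nrow(t))],
             t$met[pmin(keep + 1L, nrow(t))], 0L)
    t$unmet[keep] <- t$unmet[keep] +
      ifelse(keep + 1L <= nrow(t) & absorb[pmin(keep + 1L, nrow(t))],
             t$unmet[pmin(keep + 1L, nrow(t))], 0L)
    i <- i + 1L
    out[[i]] <- t[keep, , drop = FALSE]
  }
  do.call(rbind, out)
}

#' Write per-sample methylation tables
#'
#' Inverse of [read_methylation()]; one file per sample in the chosen
#' dialect, skipping sites absent (NA coverage) in a sample.
#'
#' @param m a [MethylationMatrix].
#' @param dir output directory (created if needed).
#' @param dialect `"bismark"` or `"plain"`.
#' @return named character vector of written paths, invisibly.
#' @export
write_methylation <- function(m, dir, dialect = c("bismark", "plain")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- colnames(m$beta)
  ext <- if (dialect == "bismark") ".cov" else ".meth.tsv"
  paths <- setNames(file.path(dir, paste0(samples, ext)), samples)
  for (s in samples) {
    cov <- m$coverage[, s]
    present <- !is.na(cov)
    met <- as.integer(round(m$beta[present, s] * cov[present]))
    met[is.na(met)] <- 0L
    unmet <- as.integer(cov[present]) - met
    pos1 <- m$sites$pos[present] + 1L           # back to 1-based
    df <- if (dialect == "bismark") {
      data.frame(m$sites$chrom[present], pos1, pos1,
                 ifelse(cov[present] > 0, 100 * met / cov[present], 0),
                 met, unmet)
    } else {
      data.frame(m$sites$chrom[present], pos1, met, unmet)
    }
    utils::write.table(df, paths[[s]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read a gene expression matrix (counts + TPM)
#'
#' Both files are genes x samples TSVs with a gene id column followed by
#' one column per sample.  No normalisation is applied; after upstream gene
#' filtering TPM columns need not sum to 1e6.
#'
#' @param counts_path,tpm_path file paths.
#' @return An [ExpressionMatrix].
#' @export
read_expression <- function(counts_path, tpm_path) {
  read_mat <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  counts <- read_mat(counts_path)
  tpm <- read_mat(tpm_path)
  if (!identical(dim(counts), dim(tpm)) ||
      !identical(rownames(counts), rownames(tpm)) ||
      !identical(colnames(counts), colnames(tpm))) {
    stop("counts and TPM files disagree in genes or samples")
  }
  storage.mode(counts) <- "integer"
  ExpressionMatrix(counts, tpm)
}

#' Write an expression matrix as counts + TPM TSVs
#' @param expr an [ExpressionMatrix].
#' @param counts_path,tpm_path output paths.
#' @export
write_expression <- function(expr, counts_path, tpm_path) {
  wr <- function(m, p) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(expr$counts, counts_path)
  wr(expr$tpm, tpm_path)
  invisible(NULL)
}

#' Read per-sample histone peak calls
#'
#' narrowPeak (10 columns, H3K27ac) or broadPeak (9 columns, H3K27me3) BED
#' dialects; intervals are kept 0-based half-open as in BED.  An empty file
#' is a valid sample with no called peaks.
#'
#' @param paths character vector of files, one per sample (names = sample
#'   ids).
#' @param mark `"H3K27ac"` (narrowPeak) or `"H3K27me3"` (broadPeak).
#' @return named list of data.frames with columns `chrom`, `start`, `end`,
#'   `signal`; attribute `mark` records the modification.
#' @export
read_peaks <- function(paths, mark = c("H3K27ac", "H3K27me3")) {
  mark <- match.arg(mark)
  want <- if (mark == "H3K27ac") 10L else 9L
  dialect <- if (mark == "H3K27ac") "narrowPeak" else "broadPeak"
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  out <- lapply(paths, function(p) {
    info <- file.info(p)
    if (is.na(info$size)) stop("missing peak file: ", p)
    if (info$size == 0) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), signal = numeric()))
    }
    df <- utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) != want) {
      stop(p, ": expected ", want, " columns for ", dialect,
           " (", mark, "), found ", ncol(df))
    }
    data.frame(chrom = as.character(df[[1]]),
               start = as.integer(df[[2]]),
               end = as.integer(df[[3]]),
               signal = as.numeric(df[[7]]))
  })
  attr(out, "mark") <- mark
  out
}

#' Write per-sample peak calls in narrowPeak/broadPeak dialect
#' @param peaks named list of data.frames as returned by [read_peaks()].
#' @param dir output directory.
#' @param mark histone mark; decides the dialect.
#' @export
write_peaks <- function(peaks, dir, mark = c("H3K27ac", "H3K27me3")) {
  mark <- match.arg(mark)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (mark == "H3K27ac") ".narrowPeak" else ".broadPeak"
  paths <- setNames(file.path(dir, paste0(names(peaks), ext)), names(peaks))
  for (s in names(peaks)) {
    pk <- peaks[[s]]
    if (nrow(pk) == 0) { file.create(paths[[s]]); next }
    base <- data.frame(pk$chrom, pk$start, pk$end,
                       paste0("peak_", seq_len(nrow(pk))), 0L, ".",
                       pk$signal, -1, -1)
    if (mark == "H3K27ac") base$summit <- -1L
    utils::write.table(base, paths[[s]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read a gene model table
#'
#' Flat TSV with columns `gene_id`, `chrom`, `strand`, `tss`, `tes`,
#' `utr5`, `utr3`.  `tss`/`tes` are 0-based positions; UTR columns hold
#' semicolon-separated `start-end` half-open intervals (may be empty).
#' Only TSS/TES/UTR/strand are consumed downstream, so a full GTF parser is
#' deliberately not provided.
#'
#' @param path file path.
#' @return data.frame with the columns above (`tss`, `tes` integer).
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(utr5 = "character",
                                         utr3 = "character"))
  need <- c("gene_id", "chrom", "strand", "tss", "tes", "utr5", "utr3")
  if (!all(need %in% names(df))) {
    stop("gene model table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  ok <- ifelse(df$strand == "+", df$tss <= df$tes, df$tss >= df$tes)
  if (!all(ok)) stop("TSS must be upstream of TES in transcription direction")
  df$utr5[is.na(df$utr5)] <- ""
  df$utr3[is.na(df$utr3)] <- ""
  df
}

#' @rdname read_gene_models
#' @param genes gene model data.frame to write.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# parse "a-b;c-d" UTR interval strings -> data.frame(start, end)
parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(start = integer(), end = integer()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(parts, `[`, "", 1)),
             end = as.integer(vapply(parts, `[`, "", 2)))
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `patient_id`, `anatomic_site`,
#' `morphology`.  Sample ids must be unique; each sample belongs to exactly
#' one patient.
#'
#' @param path file path.
#' @return data.frame of metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id")
  if (!all(need %in% names(df))) {
    stop("metadata needs columns sample_id, patient_id")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}

#' @rdname read_metadata
#' @param metadata metadata data.frame to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write and read region-gene link tables
#'
#' Links round-trip losslessly through a TSV with region coordinates,
#' category, annotation, gene, correlation (serialised at full precision),
#' p, FDR and validation status.
#'
#' @param links a link data.frame as produced by [region_gene_links()].
#' @param path file path.
#' @export
write_links <- function(links, path) {
  cols <- c("region_id", "chrom", "start", "end", "category", "annotation",
            "gene", "r", "p", "fdr", "validated")
  out <- links[, intersect(cols, names(links)), drop = FALSE]
  for (col in c("r", "p", "fdr")) {
    if (col %in% names(out)) out[[col]] <- format(out[[col]], digits = 15)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_links
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("r", "p", "fdr")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if ("validated" %in% names(df)) df$validated <- as.logical(df$validated)
  df
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits per-sample Bismark-style coverage files, expression counts/TPM
#' TSVs, per-sample narrowPeak/broadPeak calls plus peak-signal matrices,
#' the gene-model table and sample metadata, so that a simulated cohort can
#' be re-read through the standard readers.
#'
#' @param cohort a cohort bundle from [simulate_cohort()].
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation(cohort$meth, file.path(dir, "methylation"))
  write_expression(cohort$expr, file.path(dir, "counts.tsv"),
                   file.path(dir, "tpm.tsv"))
  for (mark in names(cohort$peak_calls)) {
    write_peaks(cohort$peak_calls[[mark]],
                file.path(dir, paste0("peaks_", mark)), mark)
    sig <- cohort$peak_signal[[mark]]
    utils::write.table(
      data.frame(peak_id = rownames(sig), sig, check.names = FALSE),
      file.path(dir, paste0("signal_", mark, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gene_models(cohort$genes, file.path(dir, "genes.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
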