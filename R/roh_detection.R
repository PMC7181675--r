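#' Total autosomal extent of the BovineHD map, in kilobases
#'
#' The published map constant for the Illumina BovineHD beadchip: the total
#' length of autosome covered by the assay's SNPs, interpreted in kb (the
#' bovine autosomal genome is ~2.51 Gb). Available for comparison output;
#' [detect_roh()] computes the denominator from the dataset map instead.
#' @export
BOVINE_HD_L_AUTO_KB <- 2510611

#' ROH detection parameters
#'
#' Per-run constraints in the Golden-Helix-SVS style, with BovineHD-scale
#' defaults: minimum length 500 kb, minimum 25 SNPs, at most one
#' heterozygote and five missing calls per run, and no inter-SNP gap above
#' 100 kb. The heterozygote allowance absorbs isolated genotyping errors.
#'
#' @param min_length_bp minimum run length (end_bp - start_bp).
#' @param min_snps minimum number of markers spanned by the run.
#' @param max_het maximum heterozygous calls inside a run.
#' @param max_missing maximum missing calls inside a run.
#' @param max_gap_bp maximum distance between consecutive markers in a run.
#' @return a `roh_params` list.
#' @export
roh_params <- function(min_length_bp = 500000, min_snps = 25L,
                       max_het = 1L, max_missing = 5L,
                       max_gap_bp = 100000) {
  stopifnot(min_length_bp >= 0, min_snps >= 0, max_het >= 0,
    max_missing >= 0, max_gap_bp >= 0)
  structure(list(min_length_bp = min_length_bp, min_snps = as.integer(min_snps),
    max_het = as.integer(max_het), max_missing = as.integer(max_missing),
    max_gap_bp = max_gap_bp), class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Scans each sample and autosomal chromosome left to right for maximal runs
#' satisfying every [roh_params()] constraint. Runs start and end on
#' homozygous non-missing SNPs (a permitted heterozygote or missing call may
#' only be interior, preventing length inflation by non-informative edges).
#' Maximality: a run cannot be extended by one adjacent SNP without
#' violating a constraint; overlapping candidates are resolved to the
#' leftmost maximal non-overlapping set.
#'
#' @param dataset a [genotype_dataset()]; non-autosomal markers are dropped.
#' @param params a [roh_params()].
#' @return a `roh_set`: list with `records` (data.frame: sample_id,
#'   chromosome, start_bp, end_bp, length_bp, n_snps, n_het, n_missing),
#'   `params`, and `l_auto_bp` (sum over autosomes of last - first mapped
#'   position, the F_ROH denominator).
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  ds <- autosomal(dataset)
  mk <- ds$markers
  ord <- order(chromosome_order(mk$chromosome), mk$position_bp)
  if (!identical(ord, seq_len(nrow(mk))))
    stop("precondition error: marker map must be sorted by (chromosome, position)")
  g <- ds$genotypes
  g[is.na(g)] <- -1L
  storage.mode(g) <- "integer"

  recs <- list()
  l_auto <- 0
  for (ch in unique(mk$chromosome)) {
    idx <- which(mk$chromosome == ch)
    pos <- mk$position_bp[idx]
    if (length(idx) >= 2L) l_auto <- l_auto + (max(pos) - min(pos))
    df <- .scan_roh_chrom(g[, idx, drop = FALSE], pos,
      params$min_length_bp, params$min_snps,
      params$max_het, params$max_missing, params$max_gap_bp)
    if (nrow(df)) {
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = ds$samples$sample_id[df$sample],
        chromosome = ch,
        start_bp = pos[df$start_idx],
        end_bp = pos[df$end_idx],
        length_bp = pos[df$end_idx] - pos[df$start_idx],
        n_snps = df$n_snps,
        n_het = df$n_het,
        n_missing = df$n_missing,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else data.frame(
    sample_id = character(0), chromosome = character(0),
    start_bp = integer(0), end_bp = integer(0), length_bp = integer(0),
    n_snps = integer(0), n_het = integer(0), n_missing = integer(0),
    stringsAsFactors = FALSE)
  records <- records[order(chromosome_order(records$chromosome),
    records$start_bp, records$sample_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, params = params, l_auto_bp = l_auto,
    sample_ids = ds$samples$sample_id),
    class = "roh_set")
}

#' @export
print.roh_set <- function(x, ...) {
  cat("roh_set:", nrow(x$records), "runs in", length(x$sample_ids),
    "samples; L_auto =", x$l_auto_bp, "bp\n")
  invisible(x)
}

#' Summarize ROH in cumulative length bins
#'
#' Bins are open lower bounds in Mb as conventionally printed: a 3 Mb run
#' counts in both the >0.5 and >2 bins. Values are means over the
#' individuals of each group (samples with no runs contribute zeros).
#'
#' @param rohset a `roh_set` from [detect_roh()].
#' @param bins_mb numeric lower bin bounds in Mb.
#' @param group_labels per-sample labels aligned with `rohset$sample_ids`
#'   (default: one group, "all").
#' @return data.frame: group, bin_mb, mean_count, mean_total_mb, n_samples.
#' @export
summarize_roh_bins <- function(rohset, bins_mb = c(0.5, 2, 4, 8, 16),
                               group_labels = NULL) {
  ids <- rohset$sample_ids
  if (is.null(group_labels)) group_labels <- rep("all", length(ids))
  stopifnot(length(group_labels) == length(ids))
  rec <- rohset$records
  len_mb <- rec$length_bp / 1e6
  out <- list()
  for (grp in unique(group_labels)) {
    members <- ids[group_labels == grp]
    if (length(members) == 0L) {
      warning("empty group '", grp, "': means reported as 0")
      out[[grp]] <- data.frame(group = grp, bin_mb = bins_mb,
        mean_count = 0, mean_total_mb = 0, n_samples = 0L)
      next
    }
    sub <- rec[rec$sample_id %in% members, , drop = FALSE]
    sub_len <- len_mb[rec$sample_id %in% members]
    rows <- lapply(bins_mb, function(b) {
      inbin <- sub_len > b
      counts <- table(factor(sub$sample_id[inbin], levels = members))
      totals <- tapply(sub_len[inbin],
        factor(sub$sample_id[inbin], levels = members), sum)
      totals[is.na(totals)] <- 0
      data.frame(group = grp, bin_mb = b,
        mean_count = mean(as.numeric(counts)),
        mean_total_mb = mean(as.numeric(totals)),
        n_samples = length(members))
    })
    out[[grp]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-SNP ROH incidence
#'
#' For each autosomal marker, the number of ROH records whose interval
#' contains its position — the basis for identifying the most commonly
#' homozygous stretches of genome.
#'
#' @param rohset a `roh_set`.
#' @param markers a MarkerMap data.frame (same dataset the runs came from).
#' @return integer vector of counts aligned to the autosomal rows of `markers`
#'   (non-autosomal markers get NA), with the map as attributes.
#' @export
snp_incidence <- function(rohset, markers) {
  counts <- rep(NA_integer_, nrow(markers))
  auto <- is_autosome(markers$chromosome)
  counts[auto] <- 0L
  rec <- rohset$records
  for (ch in unique(rec$chromosome)) {
    mi <- which(markers$chromosome == ch & auto)
    if (!length(mi)) next
    pos <- markers$position_bp[mi]
    sub <- rec[rec$chromosome == ch, , drop = FALSE]
    # difference-array accumulation over position-sorted markers
    dd <- integer(length(mi) + 1L)
    lo <- findInterval(sub$start_bp - 1L, pos) + 1L  # first marker >= start
    hi <- findInterval(sub$end_bp, pos)              # last marker <= end
    ok <- lo <= hi
    for (k in which(ok)) {
      dd[lo[k]] <- dd[lo[k]] + 1L
      dd[hi[k] + 1L] <- dd[hi[k] + 1L] - 1L
    }
    counts[mi] <- cumsum(dd[-length(dd)])
  }
  counts
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH = (sum of run lengths at or above the length threshold) / L_AUTO,
#' per sample, with L_AUTO the total mapped autosomal extent of the dataset.
#' Computed at 0.5 and 10 Mb thresholds by default, mirroring the customary
#' F_ROH0.5 / F_ROH10 pair.
#'
#' @param rohset a `roh_set`.
#' @param min_length_mb length threshold(s) in Mb.
#' @return data.frame: sample_id plus one `f_roh_<threshold>` column per
#'   threshold, values in [0, 1].
#' @export
compute_f_roh <- function(rohset, min_length_mb = c(0.5, 10)) {
  stopifnot(rohset$l_auto_bp > 0)
  ids <- rohset$sample_ids
  rec <- rohset$records
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (thr in min_length_mb) {
    keep <- rec$length_bp >= thr * 1e6
    sums <- tapply(rec$length_bp[keep],
      factor(rec$sample_id[keep], levels = ids), sum)
    sums[is.na(sums)] <- 0
    out[[sprintf("f_roh_%g", thr)]] <- as.numeric(sums) / rohset$l_auto_bp
  }
  out
}

#' Write ROH records as a BED-style table
#' @param rohset a `roh_set`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_roh <- function(rohset, path) {
  utils::write.table(rohset$records, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
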