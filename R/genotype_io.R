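#' Read a binary genotype fileset (bed/bim/fam dialect)
#'
#' Reads the de-facto standard trio: a variant-major 2-bit binary genotype
#' matrix (`.bed`), a text marker map (`.bim`: chromosome, marker_id,
#' genetic-distance placeholder, position_bp, allele1, allele2) and a text
#' sample table (`.fam`). Genotypes are decoded to alternate-allele counts
#' with heterozygotes as 1 and missing preserved as `NA`.
#'
#' @param fileset_path path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(fileset_path) {
  paths <- paste0(fileset_path, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("fileset error: missing file(s): ", paste(missing, collapse = ", "))

  bim_cols <- c("chromosome", "marker_id", "cm", "position_bp", "allele1", "allele2")
  bim <- if (file.size(paths[2]) == 0) {
    stats::setNames(data.frame(character(0), character(0), numeric(0),
      integer(0), character(0), character(0), stringsAsFactors = FALSE), bim_cols)
  } else utils::read.table(paths[2], header = FALSE, sep = "\t",
    colClasses = c("character", "character", "numeric", "integer",
      "character", "character"), col.names = bim_cols)
  fam_cols <- c("family_id", "sample_id", "father", "mother", "sex_code", "phenotype")
  fam <- if (file.size(paths[3]) == 0) {
    stats::setNames(as.data.frame(replicate(6, character(0), simplify = FALSE),
      stringsAsFactors = FALSE), fam_cols)
  } else utils::read.table(paths[3], header = FALSE, sep = "\t",
    colClasses = "character", col.names = fam_cols)
  m <- nrow(bim)
  n <- nrow(fam)

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error: not a bed file (bad magic number)")
  if (raw[3] != as.raw(0x01))
    stop("format error: only variant-major bed files are supported")
  bytes_per_marker <- ceiling(n / 4)
  expected <- 3L + bytes_per_marker * m
  if (length(raw) != expected)
    stop("format error: bed payload has ", length(raw) - 3L,
      " bytes, expected ", expected - 3L,
      " for ", n, " samples x ", m, " markers")

  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  if (m > 0L && n > 0L) {
    body <- raw[-(1:3)]
    # unpack 2-bit codes: 00 -> 0 (hom allele1), 10 -> 1 (het),
    # 11 -> 2 (hom allele2), 01 -> NA (missing)
    ints <- as.integer(body)
    codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                   (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
    dim(codes) <- c(4L * bytes_per_marker, m)
    codes <- codes[seq_len(n), , drop = FALSE]
    lut <- c(0L, NA_integer_, 1L, 2L)  # index by code + 1
    geno <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  }

  sex <- c("1" = "male", "2" = "female")[fam$sex_code]
  sex[is.na(sex)] <- "unknown"
  by <- suppressWarnings(as.integer(fam$phenotype))
  by[!is.na(by) & by %in% c(-9L, 0L)] <- NA_integer_
  samples <- data.frame(
    sample_id = fam$sample_id,
    population = fam$family_id,
    sex = unname(sex),
    birth_year = by,
    stringsAsFactors = FALSE)
  markers <- bim[, c("marker_id", "chromosome", "position_bp", "allele1", "allele2")]
  genotype_dataset(geno, markers, samples)
}

#' Write a binary genotype fileset (bed/bim/fam dialect)
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(x, p))`
#' reproduces `x` bit-for-bit in genotype content. The population label is
#' stored in the fam family-id column and birth year in the phenotype column.
#'
#' @param dataset a [genotype_dataset()].
#' @param fileset_path path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return invisibly, the three file paths.
#' @export
write_genotypes <- function(dataset, fileset_path) {
  validate_genotype_dataset(dataset)
  dir <- dirname(fileset_path)
  if (!dir.exists(dir))
    stop("I/O error: directory does not exist: ", dir)
  paths <- paste0(fileset_path, c(".bed", ".bim", ".fam"))

  mk <- dataset$markers
  utils::write.table(
    data.frame(mk$chromosome, mk$marker_id, 0, mk$position_bp,
      mk$allele1, mk$allele2),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  sm <- dataset$samples
  sex_code <- c(male = "1", female = "2", unknown = "0")[sm$sex]
  sex_code[is.na(sex_code)] <- "0"
  pheno <- ifelse(is.na(sm$birth_year), "-9", as.character(sm$birth_year))
  zero <- rep("0", nrow(sm))
  utils::write.table(
    data.frame(sm$population, sm$sample_id, zero, zero, unname(sex_code), pheno),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  n <- n_samples(dataset)
  m <- n_markers(dataset)
  bytes_per_marker <- ceiling(n / 4)
  con <- file(paths[1], "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0L && n > 0L) {
    # genotype value -> 2-bit code
    code <- matrix(1L, nrow = 4L * bytes_per_marker, ncol = m)  # pad = missing code 01
    g <- dataset$genotypes
    lut <- c(0L, 2L, 3L)  # genotype 0/1/2 -> bed code; NA -> 1 (missing)
    enc <- matrix(lut[g + 1L], nrow = n)
    enc[is.na(enc)] <- 1L
    code[seq_len(n), ] <- enc
    dim(code) <- c(4L, bytes_per_marker * m)
    packed <- code[1L, ] + 4L * code[2L, ] + 16L * code[3L, ] + 64L * code[4L, ]
    writeBin(as.raw(packed), con)
  }
  invisible(paths)
}

#' Quality control for a genotype dataset
#'
#' Applies the standard SNP-array QC ledger: (1) samples below the call-rate
#' floor are dropped (call rate computed over all input markers); (2) markers
#' failing the call-rate or minor-allele-frequency floors on the retained
#' samples are dropped; (3) unmapped then sex-chromosome markers are dropped
#' from the survivors; (4) near-duplicate samples (pairwise method-of-moments
#' IBD pi-hat at or above `ibd_dup_threshold` on the retained markers) are
#' resolved by dropping the lower-call-rate member of each offending pair.
#' The defaults reproduce the published BovineHD-style ledger
#' (>95\% call rates, >5\% MAF, IBD < 0.75).
#'
#' @param dataset a [genotype_dataset()].
#' @param marker_call_rate_min retain markers with call rate strictly above this.
#' @param maf_min retain markers with MAF strictly above this.
#' @param sample_call_rate_min retain samples with call rate strictly above this.
#' @param ibd_dup_threshold pi-hat at/above which a pair is deduplicated.
#' @param drop_unmapped,drop_sex drop unmapped / sex-linked markers.
#' @return list with elements `dataset` (filtered [genotype_dataset()]) and
#'   `report` (a `qc_report` of the removal tallies).
#' @export
apply_qc <- function(dataset,
                     marker_call_rate_min = 0.95,
                     maf_min = 0.05,
                     sample_call_rate_min = 0.95,
                     ibd_dup_threshold = 0.75,
                     drop_unmapped = TRUE,
                     drop_sex = TRUE) {
  if (n_samples(dataset) == 0L || n_markers(dataset) == 0L)
    stop("apply_qc requires a nonempty dataset")
  n_markers_input <- n_markers(dataset)
  n_samples_input <- n_samples(dataset)

  # 1. sample call rate on all input markers
  scr <- sample_call_rate(dataset)
  keep_s <- scr > sample_call_rate_min
  n_samples_removed_callrate <- sum(!keep_s)
  ds <- subset_dataset(dataset, samples = which(keep_s))

  # 2. marker call rate / MAF on post-sample-filter set
  if (n_samples(ds) == 0L) {
    warning("all samples removed by call-rate filter; returning empty result")
    rep <- qc_report(n_markers_input, n_markers_input, 0L, 0L,
      n_samples_input, n_samples_removed_callrate, 0L)
    return(list(dataset = ds, report = rep))
  }
  mcr <- marker_call_rate(ds)
  p <- allele_freqs(ds)
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0
  pass_cm <- mcr > marker_call_rate_min & maf > maf_min
  n_fail_callrate_or_maf <- sum(!pass_cm)

  # 3. unmapped, then sex-linked, among survivors
  unm <- is_unmapped_marker(ds$markers) & pass_cm
  n_unmapped_removed <- if (drop_unmapped) sum(unm) else 0L
  pass_u <- pass_cm & (!drop_unmapped | !unm)
  sexm <- is_sex_marker(ds$markers) & pass_u
  n_sex_removed <- if (drop_sex) sum(sexm) else 0L
  keep_m <- pass_u & (!drop_sex | !sexm)
  if (!any(keep_m))
    warning("all markers removed by QC; returning empty result")
  ds <- subset_dataset(ds, markers = which(keep_m))

  # 4. IBD dedup on the filtered markers
  n_samples_removed_dup <- 0L
  if (n_samples(ds) >= 2L && n_markers(ds) >= 1L && is.finite(ibd_dup_threshold)) {
    auto <- autosomal(ds)
    if (n_markers(auto) >= 2L) {
      ibd <- ibd_matrix(auto)
      ph <- ibd$pi_hat
      scr2 <- sample_call_rate(ds)
      pairs <- which(upper.tri(ph) & ph >= ibd_dup_threshold, arr.ind = TRUE)
      if (nrow(pairs)) {
        ord <- order(-ph[pairs])
        pairs <- pairs[ord, , drop = FALSE]
        drop <- rep(FALSE, n_samples(ds))
        for (k in seq_len(nrow(pairs))) {
          i <- pairs[k, 1]; j <- pairs[k, 2]
          if (drop[i] || drop[j]) next
          # drop the lower-call-rate member; tie -> the later sample
          victim <- if (scr2[i] < scr2[j]) i else j
          drop[victim] <- TRUE
        }
        n_samples_removed_dup <- sum(drop)
        ds <- subset_dataset(ds, samples = which(!drop))
      }
    }
  }

  rep <- qc_report(n_markers_input, n_fail_callrate_or_maf,
    n_unmapped_removed, n_sex_removed,
    n_samples_input, n_samples_removed_callrate, n_samples_removed_dup)
  list(dataset = ds, report = rep)
}

qc_report <- function(n_markers_input, n_fail_callrate_or_maf,
                      n_unmapped_removed, n_sex_removed,
                      n_samples_input, n_samples_removed_callrate,
                      n_samples_removed_dup) {
  x <- list(
    n_markers_input = as.integer(n_markers_input),
    n_fail_callrate_or_maf = as.integer(n_fail_callrate_or_maf),
    n_unmapped_removed = as.integer(n_unmapped_removed),
    n_sex_removed = as.integer(n_sex_removed),
    n_markers_retained = as.integer(n_markers_input - n_fail_callrate_or_maf -
      n_unmapped_removed - n_sex_removed),
    n_samples_input = as.integer(n_samples_input),
    n_samples_removed_callrate = as.integer(n_samples_removed_callrate),
    n_samples_removed_dup = as.integer(n_samples_removed_dup),
    n_samples_retained = as.integer(n_samples_input -
      n_samples_removed_callrate - n_samples_removed_dup),
    filter_order = "samples, marker call rate/MAF, unmapped, sex, IBD dedup")
  stopifnot(all(unlist(x[1:9]) >= 0L))
  structure(x, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (order:", x$filter_order, ")\n")
  cat(sprintf("  markers: %d input; %d fail call-rate/MAF; %d unmapped; %d sex-linked; %d retained\n",
    x$n_markers_input, x$n_fail_callrate_or_maf, x$n_unmapped_removed,
    x$n_sex_removed, x$n_markers_retained))
  cat(sprintf("  samples: %d input; %d low call rate; %d IBD duplicates; %d retained\n",
    x$n_samples_input, x$n_samples_removed_callrate,
    x$n_samples_removed_dup, x$n_samples_retained))
  invisible(x)
}

#' Serialize a QC report as a flat key-value text file
#' @param report a `qc_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  keys <- setdiff(names(report), "filter_order")
  writeLines(c(paste0(keys, "\t", unlist(report[keys])),
               paste0("filter_order\t", report$filter_order)), path)
  invisible(path)
}

#' LD pruning by sliding-window pairwise r-squared
#'
#' Greedy window pruning of markers in high linkage disequilibrium, in the
#' `indep-pairwise` style: within each `window_snps`-marker window (advanced
#' `step_snps` markers at a time along each chromosome), every retained pair
#' with squared Pearson correlation of 0/1/2 dosages at or above `r2_max`
#' is resolved by removing the later-positioned marker. Monomorphic markers
#' have undefined r-squared and are treated as r2 = 0 (never pruned for LD).
#' The defaults are the customary window 50, step 5, r2 >= 0.5.
#'
#' @param dataset a [genotype_dataset()] sorted by map order.
#' @param window_snps window width in markers.
#' @param step_snps window advance in markers.
#' @param r2_max prune one of each pair with r-squared at/above this.
#' @return integer vector of retained marker indices (into `dataset$markers`).
#' @export
ld_prune <- function(dataset, window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  m <- n_markers(dataset)
  if (m == 0L) return(integer(0))
  keep <- rep(TRUE, m)
  g <- dataset$genotypes
  chrom <- dataset$markers$chromosome
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    mc <- length(idx)
    if (mc < 2L) next
    starts <- seq(1L, mc, by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, mc)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      r2 <- suppressWarnings(stats::cor(g[, win, drop = FALSE],
        use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0  # monomorphic / all-missing pairs
      for (b in 2:length(win)) {
        if (!keep[win[b]]) next
        for (a in 1:(b - 1L)) {
          if (keep[win[a]] && r2[a, b] >= r2_max) {
            keep[win[b]] <- FALSE  # later-positioned marker removed
            break
          }
        }
      }
    }
  }
  which(keep)
}
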