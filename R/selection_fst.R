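# Weir & Cockerham (1984) variance components for one or more markers and
# two or more subpopulations, from genotype counts (uses observed
# heterozygosity; sample-size weighted). Returns per-marker a, b, c.
.wc_components <- function(geno, group_idx) {
  r <- length(group_idx)
  m <- ncol(geno)
  n_i <- matrix(0, r, m)   # non-missing sample counts
  p_i <- matrix(0, r, m)   # allele-2 frequencies
  h_i <- matrix(0, r, m)   # observed heterozygote proportions
  for (i in seq_len(r)) {
    gi <- geno[group_idx[[i]], , drop = FALSE]
    n_i[i, ] <- colSums(!is.na(gi))
    p_i[i, ] <- colMeans(gi, na.rm = TRUE) / 2
    h_i[i, ] <- colMeans(gi == 1L, na.rm = TRUE)
  }
  ok <- colSums(n_i >= 2) == r          # every group informative
  nbar <- colMeans(n_i)
  nsum <- colSums(n_i)
  nc <- (nsum - colSums(n_i^2) / nsum) / (r - 1)
  pbar <- colSums(n_i * p_i) / nsum
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / nsum

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  list(a = a, b = b, c = cc, informative = ok)
}

#' Per-marker Weir-Cockerham F_ST profile
#'
#' Computes the Weir & Cockerham (1984) theta estimator for each biallelic
#' marker between two groups, from genotype counts. Negative per-marker
#' estimates are clamped to 0 so the profile lies in [0, 1]; markers with no
#' variance component (monomorphic across both groups, or uninformative
#' group counts) get theta = 0 and are tallied in `n_zero_variance`. The
#' genome-wide mean (mu_hat) and standard deviation (sigma_hat) are
#' computed over all markers after clamping, including the invariant ones.
#'
#' @param dataset a [genotype_dataset()].
#' @param group_labels two-level labels, one per sample.
#' @return an `fst_profile`: list with `theta` (per marker), `mu_hat`,
#'   `sigma_hat`, `n_zero_variance`, `markers`, `groups`.
#' @export
marker_fst <- function(dataset, group_labels) {
  lv <- unique(group_labels)
  if (length(lv) != 2L)
    stop("precondition error: exactly two groups required")
  idx <- lapply(lv, function(l) which(group_labels == l))
  if (any(lengths(idx) < 2L))
    stop("precondition error: each group needs at least 2 samples")
  wc <- .wc_components(dataset$genotypes, idx)
  denom <- wc$a + wc$b + wc$c
  zero <- !(denom > 0) | !wc$informative
  theta <- ifelse(zero, 0, wc$a / denom)
  theta <- pmin(1, pmax(0, theta))
  structure(list(theta = theta,
    mu_hat = mean(theta), sigma_hat = stats::sd(theta),
    n_zero_variance = sum(zero),
    markers = dataset$markers, groups = lv), class = "fst_profile")
}

#' @export
print.fst_profile <- function(x, ...) {
  cat(sprintf("fst_profile: %d markers, %s vs %s; mu_hat = %.4f, sigma_hat = %.4f, %d invariant\n",
    length(x$theta), x$groups[1], x$groups[2], x$mu_hat, x$sigma_hat,
    x$n_zero_variance))
  invisible(x)
}

# Shared sigma-threshold region caller. Seeds are values strictly above
# mean + seed_mult * sd. An isolated seed (both immediate flanks at or
# below mean + ext_mult * sd) yields a window of +/- pad_bp centered on the
# seed. Otherwise the contiguous run of markers above the extension
# threshold containing the seed is taken and pad_bp is added at each end
# (strict_pad doubles the padding, the alternative reading of "an
# additional Mb at each end"). Overlapping regions are merged per
# chromosome and clipped below at 1 bp (and above at chrom_sizes if given).
sigma_threshold_regions <- function(values, chrom, pos, seed_mult = 7,
                                    ext_mult = 5, pad_bp = 500000,
                                    strict_pad = FALSE, chrom_sizes = NULL) {
  empty <- data.frame(chromosome = character(0), start_bp = numeric(0),
    end_bp = numeric(0), n_seeds = integer(0), n_consecutive_extreme = integer(0),
    seed_snp_idx = I(list()), stringsAsFactors = FALSE)
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (!is.finite(sigma) || sigma == 0) return(empty)
  seed_thr <- mu + seed_mult * sigma
  ext_thr <- mu + ext_mult * sigma
  pad_ext <- if (strict_pad) 2 * pad_bp else pad_bp
  regions <- list()
  for (ch in unique(chrom)) {
    ci <- which(chrom == ch)
    v <- values[ci]; p <- pos[ci]
    seeds <- which(v > seed_thr)
    if (!length(seeds)) next
    above <- v > ext_thr
    for (s in seeds) {
      flank_lo <- s == 1L || !above[s - 1L]
      flank_hi <- s == length(v) || !above[s + 1L]
      if (flank_lo && flank_hi) {
        reg <- c(p[s] - pad_bp, p[s] + pad_bp)
        nseg <- 1L
        i0 <- j0 <- s
      } else {
        i0 <- s; while (i0 > 1L && above[i0 - 1L]) i0 <- i0 - 1L
        j0 <- s; while (j0 < length(v) && above[j0 + 1L]) j0 <- j0 + 1L
        reg <- c(p[i0] - pad_ext, p[j0] + pad_ext)
        nseg <- j0 - i0 + 1L
      }
      regions[[length(regions) + 1L]] <- data.frame(
        chromosome = ch, start_bp = reg[1], end_bp = reg[2],
        seed_idx = ci[s], n_consecutive_extreme = nseg,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) return(empty)
  rg <- do.call(rbind, regions)
  out <- list()
  for (ch in unique(rg$chromosome)) {
    sub <- rg[rg$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$start_bp), , drop = FALSE]
    cur <- sub[1, ]; seeds <- list(cur$seed_idx); next_i <- 1L
    flush <- function(cur, seeds) {
      lo <- max(1, cur$start_bp)
      hi <- cur$end_bp
      if (!is.null(chrom_sizes) && !is.null(chrom_sizes[[cur$chromosome]]))
        hi <- min(hi, chrom_sizes[[cur$chromosome]])
      df <- data.frame(chromosome = cur$chromosome, start_bp = lo, end_bp = hi,
        n_seeds = length(unlist(seeds)),
        n_consecutive_extreme = cur$n_consecutive_extreme,
        stringsAsFactors = FALSE)
      df$seed_snp_idx <- I(list(sort(unique(unlist(seeds)))))
      df
    }
    if (nrow(sub) > 1) {
      for (k in 2:nrow(sub)) {
        if (sub$start_bp[k] <= cur$end_bp) {
          cur$end_bp <- max(cur$end_bp, sub$end_bp[k])
          cur$n_consecutive_extreme <- max(cur$n_consecutive_extreme,
            sub$n_consecutive_extreme[k])
          seeds[[length(seeds) + 1L]] <- sub$seed_idx[k]
        } else {
          out[[length(out) + 1L]] <- flush(cur, seeds)
          cur <- sub[k, ]; seeds <- list(cur$seed_idx)
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cur, seeds)
  }
  res <- do.call(rbind, out)
  res <- res[order(chromosome_order(res$chromosome), res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call candidate selection regions from an F_ST profile
#'
#' The sigma-threshold rule: SNPs with theta above mu_hat + `seed_mult` *
#' sigma_hat seed regions. An isolated seed whose immediate flanks are at or
#' below the mu_hat + `ext_mult` * sigma_hat extension threshold yields a
#' window centered on the seed (half-width `pad_bp`, i.e. a 1 Mb window by
#' default); otherwise the contiguous segment of supra-extension-threshold
#' SNPs containing the seed is padded by `pad_bp` at each end (`strict_pad`
#' doubles this). Overlapping regions are merged.
#'
#' @param profile an `fst_profile` from [marker_fst()].
#' @param markers MarkerMap data.frame aligned with the profile (defaults to
#'   the profile's own map).
#' @param seed_mult,ext_mult sigma multipliers.
#' @param pad_bp padding in bp (default 500 kb).
#' @param strict_pad use the alternative reading of the padding rule
#'   (+2 * `pad_bp` per end on extended segments).
#' @param chrom_sizes optional named list of chromosome lengths for clipping.
#' @return data.frame: chromosome, start_bp, end_bp, n_seeds,
#'   n_consecutive_extreme, seed_snp_ids.
#' @export
call_regions <- function(profile, markers = profile$markers, seed_mult = 7,
                         ext_mult = 5, pad_bp = 500000, strict_pad = FALSE,
                         chrom_sizes = NULL) {
  res <- sigma_threshold_regions(profile$theta, markers$chromosome,
    markers$position_bp, seed_mult = seed_mult, ext_mult = ext_mult,
    pad_bp = pad_bp, strict_pad = strict_pad, chrom_sizes = chrom_sizes)
  res$seed_snp_ids <- I(lapply(res$seed_snp_idx, function(i) markers$marker_id[i]))
  res
}

#' Multilocus pairwise fixation indices between populations
#'
#' For every pair of groups, the multilocus Weir-Cockerham theta is the
#' ratio of the summed variance components over markers (ratio of sums, not
#' mean of per-marker ratios), clamped into [0, 1].
#'
#' @param dataset a [genotype_dataset()].
#' @param group_labels labels with at least two levels, each with at least
#'   two samples.
#' @return symmetric numeric matrix of fixation indices with zero diagonal.
#' @export
pairwise_population_fst <- function(dataset, group_labels) {
  lv <- unique(group_labels)
  if (length(lv) < 2L)
    stop("precondition error: at least two groups required")
  sizes <- table(factor(group_labels, levels = lv))
  if (any(sizes < 2L))
    stop("precondition error: each group needs at least 2 samples")
  out <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    idx <- list(which(group_labels == lv[i]), which(group_labels == lv[j]))
    wc <- .wc_components(dataset$genotypes, idx)
    denom <- sum(wc$a + wc$b + wc$c)
    theta <- if (denom > 0) sum(wc$a) / denom else 0
    out[i, j] <- out[j, i] <- min(1, max(0, theta))
  }
  out
}
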