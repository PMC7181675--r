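#' Find ROH clusters shared across individuals
#'
#' Sweeps each chromosome's ROH coverage profile for regions where at least
#' `min_members` distinct samples carry a run. Each cluster is seeded at the
#' leftmost qualifying local coverage maximum; its members are all runs
#' overlapping the seed point; the consensus interval runs from the maximum
#' of the member start positions to the minimum of the member end positions
#' (nonempty because every member contains the seed). Member runs are
#' removed before the sweep continues, so clusters never share a seed.
#'
#' @param rohset a `roh_set` from [detect_roh()].
#' @param markers MarkerMap data.frame of the same dataset (for the first-SNP
#'   anchor and SNP counts).
#' @param min_members minimum number of distinct carriers.
#' @return data.frame of clusters: chromosome, consensus_start_bp,
#'   consensus_end_bp, first_snp_id, n_members, n_snps_in_cluster, plus a
#'   `members` list-column of sample ids.
#' @export
find_clusters <- function(rohset, markers, min_members = 5L) {
  rec <- rohset$records
  clusters <- list()
  for (ch in unique(rec$chromosome)) {
    sub <- rec[rec$chromosome == ch, , drop = FALSE]
    repeat {
      if (nrow(sub) < min_members) break
      seed <- .leftmost_coverage_peak(sub$start_bp, sub$end_bp, min_members)
      if (is.na(seed)) break
      mem <- which(sub$start_bp <= seed & sub$end_bp >= seed)
      cs <- max(sub$start_bp[mem])
      ce <- min(sub$end_bp[mem])
      mi <- which(markers$chromosome == ch & markers$position_bp >= cs)
      first_id <- if (length(mi)) markers$marker_id[mi[which.min(markers$position_bp[mi])]]
                  else NA_character_
      nsnp <- sum(markers$chromosome == ch & markers$position_bp >= cs &
                  markers$position_bp <= ce)
      clusters[[length(clusters) + 1L]] <- data.frame(
        chromosome = ch, consensus_start_bp = cs, consensus_end_bp = ce,
        first_snp_id = first_id, n_members = length(mem),
        n_snps_in_cluster = nsnp, stringsAsFactors = FALSE)
      clusters[[length(clusters)]]$members <- list(sort(sub$sample_id[mem]))
      sub <- sub[-mem, , drop = FALSE]
    }
  }
  if (!length(clusters)) {
    out <- data.frame(chromosome = character(0), consensus_start_bp = integer(0),
      consensus_end_bp = integer(0), first_snp_id = character(0),
      n_members = integer(0), n_snps_in_cluster = integer(0),
      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  out <- do.call(rbind, clusters)
  out <- out[order(chromosome_order(out$chromosome), out$consensus_start_bp), ,
    drop = FALSE]
  rownames(out) <- NULL
  out
}

# Leftmost position at which interval coverage is a local maximum of at
# least min_cov. Coverage is piecewise constant between breakpoints; a
# plateau qualifies when its coverage exceeds both neighbours' (chromosome
# ends count as zero coverage). Returns the plateau's left edge, or NA.
.leftmost_coverage_peak <- function(starts, ends, min_cov) {
  ev_pos <- c(starts, ends + 1L)
  ev_val <- c(rep(1L, length(starts)), rep(-1L, length(ends)))
  ord <- order(ev_pos)
  pos <- ev_pos[ord]
  dv <- ev_val[ord]
  upos <- unique(pos)
  cov <- cumsum(tapply(dv, factor(pos, levels = upos), sum))
  cov <- as.integer(cov)
  ext <- c(0L, cov, 0L)
  for (i in seq_along(cov)) {
    if (cov[i] >= min_cov && cov[i] > ext[i] &&
        (i == length(cov) || cov[i] >= cov[i + 1])) {
      # plateau [upos[i], next breakpoint); require a strict drop afterwards
      j <- i
      while (j < length(cov) && cov[j + 1] == cov[i]) j <- j + 1
      if (j == length(cov) || cov[j + 1] < cov[i]) return(upos[i])
    }
  }
  NA_integer_
}

#' Cluster membership matrix
#'
#' Binary sample x cluster matrix: entry 1 iff the sample has an ROH whose
#' interval contains the position of the cluster's first SNP. This mirrors
#' the reduction of the genome-wide homozygosity test to one test per
#' cluster anchored at its first marker.
#'
#' @param rohset a `roh_set`.
#' @param clusters data.frame from [find_clusters()].
#' @param markers MarkerMap data.frame (to resolve first-SNP positions).
#' @return integer matrix, rows = samples, columns = clusters.
#' @export
membership_matrix <- function(rohset, clusters, markers) {
  ids <- rohset$sample_ids
  M <- matrix(0L, length(ids), nrow(clusters),
    dimnames = list(ids, clusters$first_snp_id))
  rec <- rohset$records
  for (k in seq_len(nrow(clusters))) {
    midx <- match(clusters$first_snp_id[k], markers$marker_id)
    anchor <- markers$position_bp[midx]
    ch <- markers$chromosome[midx]
    hit <- rec$chromosome == ch & rec$start_bp <= anchor & rec$end_bp >= anchor
    M[unique(rec$sample_id[hit]), k] <- 1L
  }
  M
}

#' Homozygosity association between two groups
#'
#' For each cluster, tests the 2x2 table of group by ROH membership.
#' The primary p-value is the two-sided Fisher exact test (exact control at
#' small sample sizes); a chi-square statistic without continuity correction
#' is reported alongside. Bonferroni uses the number of clusters as the test
#' count; Benjamini-Hochberg q-values are also reported. Degenerate tables
#' (membership constant across all samples) get p = 1.
#'
#' @param membership binary matrix from [membership_matrix()].
#' @param group_labels two-level labels, one per row of `membership`.
#' @return data.frame: cluster, carriers and sizes per group, odds_ratio,
#'   enriched group, p_value (Fisher), chisq_stat, chisq_p, bonferroni_p,
#'   bh_fdr_q; attribute `test_count`.
#' @export
homozygosity_association <- function(membership, group_labels) {
  lv <- unique(group_labels)
  if (length(lv) != 2L)
    stop("precondition error: exactly two groups required, got ", length(lv))
  ia <- group_labels == lv[1]
  ib <- group_labels == lv[2]
  nA <- sum(ia); nB <- sum(ib)
  if (nA == 0L || nB == 0L)
    stop("precondition error: both groups must be nonempty")
  K <- ncol(membership)
  kA <- colSums(membership[ia, , drop = FALSE])
  kB <- colSums(membership[ib, , drop = FALSE])
  p <- numeric(K); chi <- numeric(K); chi_p <- numeric(K)
  for (j in seq_len(K)) {
    p[j] <- fisher_exact_p(kA[j], kB[j], nA, nB)
    cs <- .chisq_2x2(kA[j], nA - kA[j], kB[j], nB - kB[j])
    chi[j] <- cs[1]; chi_p[j] <- cs[2]
  }
  or <- (kA * (nB - kB)) / ((nA - kA) * kB)
  propA <- kA / nA; propB <- kB / nB
  enriched <- ifelse(propA > propB, lv[1], ifelse(propB > propA, lv[2], "none"))
  out <- data.frame(
    cluster = if (is.null(colnames(membership))) seq_len(K) else colnames(membership),
    carriers_a = as.integer(kA), n_a = nA,
    carriers_b = as.integer(kB), n_b = nB,
    odds_ratio = or, enriched = enriched,
    p_value = p, chisq_stat = chi, chisq_p = chi_p,
    bonferroni_p = pmin(1, p * K),
    bh_fdr_q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  attr(out, "test_count") <- K
  attr(out, "groups") <- lv
  out
}

# chi-square statistic for a 2x2 table, no continuity correction;
# zero margin -> statistic 0, p 1.
.chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(c(0, 1))
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  c(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# memoized two-sided Fisher exact p for a 2x2 table with margins
# (carriers kA of nA, kB of nB); the sum of hypergeometric point
# probabilities no greater than the observed one (the fisher.test rule).
.fisher_cache <- new.env(parent = emptyenv())

fisher_exact_p <- function(kA, kB, nA, nB) {
  m <- kA + kB
  if (m == 0L || m == nA + nB) return(1)
  key <- paste(kA, m, nA, nB, sep = "_")
  hit <- .fisher_cache[[key]]
  if (!is.null(hit)) return(hit)
  lo <- max(0L, m - nB)
  hi <- min(m, nA)
  d <- stats::dhyper(lo:hi, nA, nB, m)
  obs <- d[kA - lo + 1L]
  p <- min(1, sum(d[d <= obs * (1 + 1e-7)]))
  .fisher_cache[[key]] <- p
  p
}

#' Call commonly homozygous regions from per-SNP ROH incidence
#'
#' Applies the same sigma-threshold region logic as [call_regions()] to the
#' per-SNP incidence counts: seeds are SNPs whose count exceeds
#' mean + `seed_mult` * sd, extended through consecutive SNPs above
#' mean + `ext_mult` * sd.
#'
#' @param incidence per-SNP counts from [snp_incidence()], aligned to `markers`.
#' @param markers MarkerMap data.frame.
#' @param seed_mult,ext_mult sigma multipliers for seeding / extension.
#' @param pad_bp padding added to each region end (and the half-width of the
#'   centered window for isolated seeds).
#' @return data.frame of regions as from [call_regions()].
#' @export
call_incidence_regions <- function(incidence, markers, seed_mult = 7,
                                   ext_mult = 5, pad_bp = 500000) {
  ok <- !is.na(incidence)
  sigma_threshold_regions(as.numeric(incidence[ok]),
    markers$chromosome[ok], markers$position_bp[ok],
    seed_mult = seed_mult, ext_mult = ext_mult, pad_bp = pad_bp)
}
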