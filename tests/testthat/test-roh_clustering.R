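# convenience: wrap a records data.frame into a roh_set
as_rohset <- function(records, sample_ids) {
  structure(list(records = records, params = roh_params(), l_auto_bp = 1,
    sample_ids = sample_ids), class = "roh_set")
}

mk_map <- function(pos, chrom = "1") data.frame(
  marker_id = sprintf("mk_%s_%07d", chrom, seq_along(pos)),
  chromosome = chrom, position_bp = as.integer(pos),
  allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)

roh_df <- function(ids, starts, ends, chrom = "1") data.frame(
  sample_id = ids, chromosome = chrom, start_bp = starts, end_bp = ends,
  length_bp = ends - starts, n_snps = 10L, n_het = 0L, n_missing = 0L,
  stringsAsFactors = FALSE)

test_that("find_clusters applies the max-start/min-end consensus rule", {
  mk <- mk_map(seq(5e5, 30e6, by = 1e5))
  ids <- sprintf("s%03d", 1:5)
  # five identical runs
  rs <- as_rohset(roh_df(ids, rep(10e6, 5), rep(20e6, 5)), ids)
  cl <- find_clusters(rs, mk)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$consensus_start_bp, 10e6)
  expect_equal(cl$consensus_end_bp, 20e6)
  expect_equal(cl$n_members, 5L)
  expect_equal(cl$first_snp_id, mk$marker_id[which(mk$position_bp >= 10e6)[1]])
  # staggered runs: starts 1..5 Mb, ends 11..15 Mb -> consensus [5, 11] Mb
  rs2 <- as_rohset(roh_df(ids, (1:5) * 1e6, (11:15) * 1e6), ids)
  cl2 <- find_clusters(rs2, mk)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$consensus_start_bp, 5e6)
  expect_equal(cl2$consensus_end_bp, 11e6)
  # four carriers only -> below the floor, no cluster
  rs3 <- as_rohset(roh_df(ids[1:4], rep(10e6, 4), rep(20e6, 4)), ids[1:4])
  expect_equal(nrow(find_clusters(rs3, mk)), 0L)
})

test_that("every consensus interval is contained in every member's run", {
  set.seed(404)
  mk <- mk_map(seq(1e5, 60e6, by = 5e4))
  for (rep in 1:5) {
    ids <- sprintf("s%03d", 1:20)
    n <- 60
    starts <- sample(seq(1e6, 50e6, by = 1e5), n, TRUE)
    lens <- sample(seq(1e6, 12e6, by = 1e5), n, TRUE)
    recs <- roh_df(sample(ids, n, TRUE), starts, starts + lens)
    # de-overlap within sample: keep first of each overlapping pair
    recs <- recs[order(recs$sample_id, recs$start_bp), ]
    keep <- rep(TRUE, nrow(recs))
    last_end <- -1; last_id <- ""
    for (i in seq_len(nrow(recs))) {
      if (recs$sample_id[i] == last_id && recs$start_bp[i] <= last_end) {
        keep[i] <- FALSE
      } else { last_id <- recs$sample_id[i]; last_end <- recs$end_bp[i] }
    }
    recs <- recs[keep, ]
    rs <- as_rohset(recs, ids)
    cl <- find_clusters(rs, mk, min_members = 5)
    for (k in seq_len(nrow(cl))) {
      mem <- cl$members[[k]]
      expect_gte(length(mem), 5)
      for (s in mem) {
        sub <- recs[recs$sample_id == s, ]
        expect_true(any(sub$start_bp <= cl$consensus_start_bp[k] &
                        sub$end_bp >= cl$consensus_end_bp[k]))
      }
    }
  }
})

test_that("membership_matrix equals the point-in-interval oracle", {
  set.seed(17)
  mk <- mk_map(seq(1e5, 40e6, by = 1e5))
  ids <- sprintf("s%03d", 1:15)
  starts <- sample(seq(1e6, 30e6, by = 5e5), 40, TRUE)
  recs <- roh_df(sample(ids, 40, TRUE), starts, starts + 5e6)
  recs <- recs[!duplicated(recs[c("sample_id", "start_bp")]), ]
  rs <- as_rohset(recs, ids)
  cl <- find_clusters(rs, mk, min_members = 4)
  M <- membership_matrix(rs, cl, mk)
  expect_equal(dim(M), c(length(ids), nrow(cl)))
  for (k in seq_len(nrow(cl))) {
    anchor <- mk$position_bp[match(cl$first_snp_id[k], mk$marker_id)]
    for (s in ids) {
      sub <- recs[recs$sample_id == s, ]
      expect_equal(unname(M[s, k]),
        as.integer(any(sub$start_bp <= anchor & sub$end_bp >= anchor)))
    }
    expect_true(all(M[cl$members[[k]], k] == 1L))
  }
  # a sample with no runs has an all-zero row
  expect_true(any(rowSums(M) == 0) || all(ids %in% recs$sample_id))
})

test_that("fisher_exact_p agrees with stats::fisher.test", {
  set.seed(88)
  for (i in 1:60) {
    nA <- sample(3:50, 1); nB <- sample(3:50, 1)
    kA <- sample(0:nA, 1); kB <- sample(0:nB, 1)
    expect_equal(fisher_exact_p(kA, kB, nA, nB),
      stats::fisher.test(matrix(c(kA, nA - kA, kB, nB - kB), 2))$p.value,
      tolerance = 1e-10, info = sprintf("%d/%d vs %d/%d", kA, nA, kB, nB))
  }
})

test_that("homozygosity_association handles extreme and degenerate tables", {
  ids <- sprintf("s%03d", 1:40)
  grp <- rep(c("A", "B"), each = 20)
  # cluster carried by all of A, none of B: p = 2 / C(40, 20)
  M <- cbind(all_vs_none = c(rep(1L, 20), rep(0L, 20)),
             everyone = rep(1L, 40),
             balanced = rep(c(1L, 0L), 20))
  rownames(M) <- ids
  res <- homozygosity_association(M, grp)
  expect_equal(res$p_value[1], 2 / choose(40, 20), tolerance = 1e-12)
  expect_equal(res$enriched[1], "A")
  expect_equal(res$p_value[2], 1)     # degenerate: everyone a carrier
  expect_equal(res$p_value[3], 1)     # identical proportions, balanced
  expect_equal(res$bonferroni_p, pmin(1, res$p_value * 3))
  expect_true(all(diff(sort(res$bh_fdr_q)) >= 0))
  expect_error(homozygosity_association(M, rep("A", 40)), "two groups")
})

test_that("fisher and chi-square rank tables almost identically", {
  set.seed(3141)
  nA <- 30; nB <- 25
  kA <- rbinom(200, nA, runif(200, 0.15, 0.85))
  kB <- rbinom(200, nB, runif(200, 0.15, 0.85))
  M <- matrix(0L, nA + nB, 200)
  for (j in 1:200) M[c(seq_len(kA[j]), nA + seq_len(kB[j])), j] <- 1L
  rownames(M) <- sprintf("s%03d", 1:(nA + nB))
  res <- homozygosity_association(M, rep(c("A", "B"), c(nA, nB)))
  nondeg <- res$p_value < 1 & res$chisq_p < 1
  expect_gt(suppressWarnings(cor(res$p_value[nondeg], res$chisq_p[nondeg],
    method = "spearman")), 0.99)
})

test_that("association p-values are valid under label permutation", {
  # super-uniformity: P(p <= alpha) <= alpha (+ Monte-Carlo slack) for the
  # discrete conservative Fisher test; literal KS uniformity cannot hold
  set.seed(2024)
  n <- 40
  memb <- matrix(rbinom(n, 1, 0.3), n, 1)
  rownames(memb) <- sprintf("s%03d", 1:n)
  B <- 1000
  ps <- replicate(B, {
    homozygosity_association(memb, sample(rep(c("A", "B"), each = n / 2)))$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(alpha * (1 - alpha) / B)
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
})

test_that("call_incidence_regions shares the sigma-threshold logic", {
  mk <- mk_map(seq(1e6, 60e6, by = 1e5))
  inc <- rep(5, nrow(mk))
  # flat profile -> no regions
  expect_equal(nrow(call_incidence_regions(inc, mk)), 0L)
  # single spike -> exactly one interval containing the spike
  set.seed(5)
  inc <- rpois(nrow(mk), 2)
  spike <- 300
  inc[spike] <- 200
  reg <- call_incidence_regions(inc, mk)
  expect_equal(nrow(reg), 1L)
  expect_true(reg$start_bp <= mk$position_bp[spike] &&
              reg$end_bp >= mk$position_bp[spike])
  # identical numeric vector through the generic caller gives the same call
  reg2 <- sigma_threshold_regions(as.numeric(inc), mk$chromosome, mk$position_bp)
  expect_equal(reg$start_bp, reg2$start_bp)
  expect_equal(reg$end_bp, reg2$end_bp)
})
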