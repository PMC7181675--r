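test_that("a clean homozygous stretch yields exactly one maximal run", {
  # 30 homozygous SNPs spanning 600 kb inside a heterozygous background
  pos <- c(seq(1e5, by = 2e4, length.out = 10),
           seq(1e6, by = 600000 / 29, length.out = 30),
           seq(2e6, by = 2e4, length.out = 10))
  g <- c(rep(1L, 10), rep(2L, 30), rep(1L, 10))
  ds <- make_dataset(matrix(g, 1), pos = round(pos))
  rec <- detect_roh(ds, roh_params())$records
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_snps, 30L)
  expect_equal(rec$start_bp, 1000000L)
  expect_gte(rec$length_bp, 500000)
  expect_equal(rec$n_het, 0L)
})

test_that("two well-spaced interior heterozygotes kill a marginal field", {
  # 30-SNP homozygous field barely over the floors; 2 hets split it into
  # fragments that individually fail min_snps -> no qualifying run
  pos <- round(seq(1e6, by = 600000 / 29, length.out = 30))
  g <- rep(0L, 30)
  g[c(10, 20)] <- 1L
  ds <- make_dataset(matrix(g, 1), pos = pos)
  rec <- detect_roh(ds, roh_params())$records
  expect_equal(nrow(rec), 0L)
  ora <- oracle_roh_vector(g, pos, roh_params())
  expect_equal(nrow(ora), 0L)
  # with the hets removed the same field qualifies
  g2 <- rep(0L, 30)
  expect_equal(nrow(detect_roh(make_dataset(matrix(g2, 1), pos = pos),
    roh_params())$records), 1L)
})

test_that("detect_roh matches the brute-force oracle on random instances", {
  set.seed(314)
  for (i in 1:40) {
    m <- sample(150:900, 1)
    pos <- cumsum(sample(500:6000, m, TRUE))
    prm <- roh_params(
      min_length_bp = sample(c(2e4, 5e4, 1e5), 1),
      min_snps = sample(5:20, 1),
      max_het = sample(0:2, 1),
      max_missing = sample(0:4, 1),
      max_gap_bp = sample(c(1e4, 3e4, 1e5), 1))
    n <- sample(1:6, 1)
    g <- replicate(n, random_roh_genotypes(m))
    ds <- make_dataset(t(g), pos = pos)
    det <- detect_roh(ds, prm)$records
    for (s in seq_len(n)) {
      ora <- oracle_roh_vector(g[, s], pos, prm)
      sub <- det[det$sample_id == sprintf("s%03d", s), , drop = FALSE]
      expect_equal(match(sub$start_bp, pos), ora$start_idx, info = paste("case", i, s))
      expect_equal(match(sub$end_bp, pos), ora$end_idx)
      expect_equal(sub$n_snps, ora$n_snps)
      expect_equal(sub$n_het, ora$n_het)
      expect_equal(sub$n_missing, ora$n_missing)
    }
  }
})

test_that("roh records satisfy their own invariants", {
  set.seed(99)
  m <- 2000
  pos <- cumsum(sample(1000:6000, m, TRUE))
  g <- t(replicate(8, random_roh_genotypes(m, p_het = 0.08)))
  prm <- roh_params(min_length_bp = 5e4, min_snps = 10)
  rs <- detect_roh(make_dataset(g, pos = pos), prm)
  rec <- rs$records
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$n_het <= prm$max_het))
  expect_true(all(rec$n_missing <= prm$max_missing))
  expect_true(all(rec$n_snps >= prm$min_snps))
  expect_true(all(rec$length_bp >= prm$min_length_bp))
  expect_equal(rec$length_bp, rec$end_bp - rec$start_bp)
  # non-overlap within sample
  for (s in unique(rec$sample_id)) {
    sub <- rec[rec$sample_id == s, ]
    sub <- sub[order(sub$start_bp), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start_bp[-1] > sub$end_bp[-nrow(sub)]))
  }
})

test_that("relaxing any single constraint only grows the candidate run set", {
  # The emitted leftmost-maximal non-overlapping runs are NOT monotone under
  # relaxation (a newly qualifying short run can preempt a longer overlapping
  # one), but the underlying set of qualifying intervals is: every run found
  # under the strict parameters must still be reachable — contained in a
  # qualifying candidate with the same start — under the relaxed ones.
  set.seed(271)
  m <- 1500
  pos <- cumsum(sample(1000:6000, m, TRUE))
  gv <- random_roh_genotypes(m, p_het = 0.1)
  ds <- make_dataset(matrix(gv, 1), pos = pos)
  base <- roh_params(min_length_bp = 1e5, min_snps = 15, max_het = 1,
    max_missing = 2, max_gap_bp = 3e4)
  strict <- detect_roh(ds, base)$records
  expect_gt(nrow(strict), 0)
  relaxed <- list(
    modifyList(base, list(min_length_bp = 5e4)),
    modifyList(base, list(min_snps = 8L)),
    modifyList(base, list(max_het = 2L)),
    modifyList(base, list(max_missing = 4L)),
    modifyList(base, list(max_gap_bp = 6e4)))
  for (prm in relaxed) {
    class(prm) <- "roh_params"
    # candidate reachability via the per-start maximal-end oracle
    for (k in seq_len(nrow(strict))) {
      s <- match(strict$start_bp[k], pos)
      e <- match(strict$end_bp[k], pos)
      ora <- oracle_roh_vector(gv, pos, prm)
      # a qualifying oracle run must cover the strict run's interval
      expect_true(any(ora$start_idx <= s & ora$end_idx >= e) ||
        # or the strict run is preempted by an earlier overlapping run whose
        # end reaches at least into the strict run
        any(ora$start_idx < s & ora$end_idx >= s),
        info = sprintf("param relaxation lost run %d", k))
    }
  }
})

test_that("summarize_roh_bins uses open cumulative bins", {
  rs <- structure(list(
    records = data.frame(sample_id = "s001", chromosome = "1",
      start_bp = c(1e6, 10e6, 40e6), end_bp = c(2e6, 13e6, 60e6),
      length_bp = c(1e6, 3e6, 20e6), n_snps = c(100L, 300L, 2000L),
      n_het = 0L, n_missing = 0L, stringsAsFactors = FALSE),
    params = roh_params(), l_auto_bp = 6e7, sample_ids = "s001"),
    class = "roh_set")
  b <- summarize_roh_bins(rs)
  expect_equal(b$mean_count, c(3, 2, 1, 1, 1))
  expect_equal(b$mean_total_mb, c(24, 23, 20, 20, 20))
  # empty set -> zeros with a warning for the empty group
  rs$records <- rs$records[0, ]
  expect_equal(summarize_roh_bins(rs)$mean_count, rep(0, 5))
})

test_that("snp_incidence matches the point-in-interval oracle and conserves counts", {
  set.seed(55)
  m <- 400
  mk <- data.frame(marker_id = sprintf("m%04d", 1:m),
    chromosome = rep(c("1", "2"), each = m / 2),
    position_bp = rep(cumsum(sample(1000:4000, m / 2, TRUE)), 2),
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    ch <- sample(c("1", "2"), 1)
    pos <- mk$position_bp[mk$chromosome == ch]
    a <- sort(sample(pos, 2))
    data.frame(sample_id = sprintf("s%03d", sample(1:10, 1)), chromosome = ch,
      start_bp = a[1], end_bp = a[2], length_bp = a[2] - a[1],
      n_snps = sum(pos >= a[1] & pos <= a[2]), n_het = 0L, n_missing = 0L,
      stringsAsFactors = FALSE)
  }))
  rs <- structure(list(records = recs, params = roh_params(), l_auto_bp = 1,
    sample_ids = sprintf("s%03d", 1:10)), class = "roh_set")
  inc <- snp_incidence(rs, mk)
  expect_equal(inc, oracle_incidence(recs, mk))
  expect_equal(sum(inc), sum(recs$n_snps))  # conservation
})

test_that("shared and disjoint runs produce the obvious incidence profile", {
  mk <- data.frame(marker_id = sprintf("m%02d", 1:50), chromosome = "1",
    position_bp = seq(1e5, by = 1e4, length.out = 50),
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  recs <- data.frame(sample_id = sprintf("s%03d", 1:10), chromosome = "1",
    start_bp = mk$position_bp[5], end_bp = mk$position_bp[40],
    length_bp = mk$position_bp[40] - mk$position_bp[5],
    n_snps = 36L, n_het = 0L, n_missing = 0L, stringsAsFactors = FALSE)
  rs <- structure(list(records = recs, params = roh_params(), l_auto_bp = 1,
    sample_ids = recs$sample_id), class = "roh_set")
  inc <- snp_incidence(rs, mk)
  expect_equal(inc[5:40], rep(10L, 36))
  expect_equal(inc[c(1:4, 41:50)], rep(0L, 14))
})

test_that("compute_f_roh spans [0, 1] and is monotone in the length floor", {
  mk_pos <- seq(1e6, 51e6, by = 1e5)
  rs <- structure(list(
    records = data.frame(sample_id = "s001", chromosome = "1",
      start_bp = 1e6, end_bp = 51e6, length_bp = 5e7, n_snps = 500L,
      n_het = 0L, n_missing = 0L, stringsAsFactors = FALSE),
    params = roh_params(), l_auto_bp = 5e7, sample_ids = c("s001", "s002")),
    class = "roh_set")
  fr <- compute_f_roh(rs)
  expect_equal(fr$f_roh_0.5, c(1, 0))   # whole autosome / no runs
  expect_equal(fr$f_roh_10, c(1, 0))
  # monotone: larger floor never increases F_ROH
  set.seed(21)
  recs <- data.frame(sample_id = "s001", chromosome = "1",
    start_bp = seq(1e6, 40e6, by = 4e6))
  recs$end_bp <- recs$start_bp + sample(c(6e5, 2e6, 12e6), nrow(recs), TRUE)
  recs$length_bp <- recs$end_bp - recs$start_bp
  recs$n_snps <- 100L; recs$n_het <- 0L; recs$n_missing <- 0L
  rs$records <- recs
  fr2 <- compute_f_roh(rs, min_length_mb = c(0.5, 2, 10))
  expect_true(fr2$f_roh_0.5[1] >= fr2$f_roh_2[1])
  expect_true(fr2$f_roh_2[1] >= fr2$f_roh_10[1])
})
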