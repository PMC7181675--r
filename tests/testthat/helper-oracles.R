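# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as direct transcriptions of definitions
# (per-start enumeration, scalar formulas, point-in-interval counting) and
# never share code with the package implementations they check.

# quick dataset builder: g is samples x markers, pos per marker
make_dataset <- function(g, pos = NULL, chrom = NULL, pop = NULL,
                         birth_year = NA_integer_, sex = "unknown") {
  g <- as.matrix(g)
  m <- ncol(g)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = m)
  if (is.null(chrom)) chrom <- rep("1", m)
  pop <- rep_len(if (is.null(pop)) "POP1" else pop, nrow(g))
  sex <- rep_len(sex, nrow(g))
  birth_year <- rep_len(birth_year, nrow(g))
  genotype_dataset(
    g,
    data.frame(marker_id = sprintf("m%05d", seq_len(m)),
      chromosome = as.character(chrom), position_bp = as.integer(pos),
      allele1 = "A", allele2 = "B", stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%03d", seq_len(nrow(g))),
      population = pop, sex = sex, birth_year = birth_year,
      stringsAsFactors = FALSE))
}

# Brute-force ROH oracle for one genotype vector on one chromosome.
# For every homozygous start SNP s, walks right to the maximal end E(s)
# under the window constraints (het/missing budgets, gap cap, homozygous
# endpoint); an interval qualifies iff [s, E(s)] meets the min_snps and
# min_length floors (both are maximized at E(s), so sub-ends need no
# separate check). Runs are then selected greedily left to right
# (smallest qualifying start, maximal end, non-overlapping).
oracle_roh_vector <- function(g, pos, params) {
  m <- length(g)
  is_hom <- !is.na(g) & g != 1L
  max_end <- rep(NA_integer_, m)
  for (s in seq_len(m)) {
    if (!is_hom[s]) next
    het <- 0L; miss <- 0L; j <- s; best <- s
    while (j < m) {
      if (pos[j + 1L] - pos[j] > params$max_gap_bp) break
      gn <- g[j + 1L]
      if (is.na(gn)) {
        miss <- miss + 1L
        if (miss > params$max_missing) break
      } else if (gn == 1L) {
        het <- het + 1L
        if (het > params$max_het) break
      }
      j <- j + 1L
      if (is_hom[j]) best <- j
    }
    max_end[s] <- best
  }
  qualifies <- function(s) {
    e <- max_end[s]
    !is.na(e) && (e - s + 1L) >= params$min_snps &&
      (pos[e] - pos[s]) >= params$min_length_bp
  }
  out <- list()
  cursor <- 1L
  repeat {
    cand <- NA_integer_
    for (s in cursor:m) {
      if (is_hom[s] && qualifies(s)) { cand <- s; break }
      if (s == m) break
    }
    if (is.na(cand)) break
    e <- max_end[cand]
    gg <- g[cand:e]
    out[[length(out) + 1L]] <- data.frame(start_idx = cand, end_idx = e,
      n_snps = e - cand + 1L,
      n_het = sum(!is.na(gg) & gg == 1L), n_missing = sum(is.na(gg)))
    cursor <- e + 1L
    if (cursor > m) break
  }
  if (!length(out)) return(data.frame(start_idx = integer(0),
    end_idx = integer(0), n_snps = integer(0), n_het = integer(0),
    n_missing = integer(0)))
  do.call(rbind, out)
}

# genotype vector generator biased towards homozygous stretches so ROH
# logic is actually exercised
random_roh_genotypes <- function(m, p_het = 0.12, p_miss = 0.03) {
  u <- runif(m)
  g <- ifelse(u < p_het, 1L, ifelse(u < p_het + (1 - p_het) / 2, 0L, 2L))
  g[runif(m) < p_miss] <- NA_integer_
  g
}

# scalar Weir & Cockerham (1984) theta for one marker, two populations,
# transcribed directly from the variance-component definitions
oracle_wc_theta <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  r <- 2
  n1 <- length(gA); n2 <- length(gB)
  p1 <- mean(gA) / 2; p2 <- mean(gB) / 2
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
    (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
    theta = if (a + b + cc > 0) a / (a + b + cc) else 0)
}

# point-in-interval incidence oracle: O(records x markers)
oracle_incidence <- function(records, markers) {
  counts <- rep(NA_integer_, nrow(markers))
  auto <- is_autosome(markers$chromosome)
  counts[auto] <- 0L
  for (k in seq_len(nrow(records))) {
    hit <- auto & markers$chromosome == records$chromosome[k] &
      markers$position_bp >= records$start_bp[k] &
      markers$position_bp <= records$end_bp[k]
    counts[hit] <- counts[hit] + 1L
  }
  counts
}
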