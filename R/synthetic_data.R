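#' Simulation configuration
#'
#' Describes a synthetic SNP-array cohort: K subpopulations diverged from a
#' common ancestral gene pool under the Balding-Nichols model, with optional
#' within-individual inbreeding, planted autozygous (ROH) tracts, fixed
#' relationship constructions (one duplicate pair and one parent-offspring
#' pair) and uniform genotype missingness. Defaults emulate a BovineHD-style
#' design: ~1 SNP per 3.5 kb, ancestral frequencies in (0.05, 0.95) so the
#' default MAF filter rarely fires, and 0.5\% missing calls (typical for
#' post-QC array data).
#'
#' @param n_pops number of subpopulations.
#' @param n_per_pop integer vector (recycled) of diploid sample counts.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param snp_spacing_mean_bp mean exponential inter-SNP spacing.
#' @param divergence_F Balding-Nichols divergence, scalar or one per population.
#' @param within_inbreeding_Fis within-individual inbreeding coefficient,
#'   scalar or one per population (recycled): P(het) = 2p(1-p)(1-Fis).
#' @param missing_rate uniform independent genotype missingness.
#' @param maf_range range of the uniform ancestral allele frequency draw.
#' @param planted_roh NULL or data.frame with columns `pop` (population label
#'   or "all"), `chromosome`, `start_bp`, `end_bp`, `carrier_fraction`.
#' @param add_relationships plant one duplicate and one parent-offspring pair
#'   in population 1 (requires at least 4 samples there).
#' @param decade_range birth years drawn uniformly from this range.
#' @param pop_labels population labels (default POP1..POPK).
#' @param seed RNG seed; identical seeds reproduce identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pops = 2L,
                       n_per_pop = 25L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 50e6,
                       snp_spacing_mean_bp = 3500L,
                       divergence_F = 0.1,
                       within_inbreeding_Fis = 0,
                       missing_rate = 0.005,
                       maf_range = c(0.05, 0.95),
                       planted_roh = NULL,
                       add_relationships = FALSE,
                       decade_range = c(1960L, 2009L),
                       pop_labels = NULL,
                       seed = 1L) {
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  divergence_F <- rep_len(divergence_F, n_pops)
  within_inbreeding_Fis <- rep_len(within_inbreeding_Fis, n_pops)
  if (is.null(pop_labels)) pop_labels <- paste0("POP", seq_len(n_pops))
  stopifnot(n_pops >= 1L, all(n_per_pop >= 1L),
    all(divergence_F >= 0), all(divergence_F < 1),
    all(within_inbreeding_Fis >= 0), all(within_inbreeding_Fis < 1),
    missing_rate >= 0, missing_rate < 1,
    length(pop_labels) == n_pops)
  if (!is.null(planted_roh)) {
    planted_roh <- as.data.frame(planted_roh, stringsAsFactors = FALSE)
    need <- c("pop", "chromosome", "start_bp", "end_bp", "carrier_fraction")
    if (!all(need %in% names(planted_roh)))
      stop("config error: planted_roh needs columns ", paste(need, collapse = ", "))
    if (any(planted_roh$start_bp < 1 | planted_roh$end_bp > chrom_length_bp |
            planted_roh$start_bp >= planted_roh$end_bp))
      stop("config error: planted interval outside chromosome bounds")
    if (any(planted_roh$carrier_fraction < 0 | planted_roh$carrier_fraction > 1))
      stop("config error: carrier_fraction must be in [0, 1]")
    if (any(!as.integer(planted_roh$chromosome) %in% seq_len(n_chromosomes)))
      stop("config error: planted chromosome outside the simulated genome")
  }
  structure(list(
    n_pops = as.integer(n_pops), n_per_pop = n_per_pop,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    snp_spacing_mean_bp = as.numeric(snp_spacing_mean_bp),
    divergence_F = divergence_F,
    within_inbreeding_Fis = within_inbreeding_Fis,
    missing_rate = missing_rate,
    maf_range = maf_range,
    planted_roh = planted_roh,
    add_relationships = isTRUE(add_relationships),
    decade_range = as.integer(decade_range),
    pop_labels = pop_labels,
    seed = as.integer(seed)), class = "sim_config")
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws one frequency per population from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so that across populations
#' E(freq) = p and Var(freq) = F p (1-p). F = 0 returns the ancestral
#' frequency for every population (the degenerate limit).
#'
#' @param ancestral_p ancestral allele frequency (vectorized over markers).
#' @param F divergence parameter in [0, 1).
#' @param n_pops number of populations to draw.
#' @return matrix of frequencies, `length(ancestral_p)` rows x `n_pops` columns.
#' @export
balding_nichols_freqs <- function(ancestral_p, F, n_pops = 1L) {
  stopifnot(all(ancestral_p > 0), all(ancestral_p < 1), F >= 0, F < 1)
  m <- length(ancestral_p)
  if (F == 0)
    return(matrix(rep(ancestral_p, n_pops), nrow = m))
  shape1 <- ancestral_p * (1 - F) / F
  shape2 <- (1 - ancestral_p) * (1 - F) / F
  matrix(stats::rbeta(m * n_pops, shape1, shape2), nrow = m)
}

#' Simulate a genotype dataset with ground truth
#'
#' Generates markers with exponential spacing, ancestral frequencies uniform
#' on `maf_range`, per-population frequencies under the Balding-Nichols
#' model, and genotypes under inbreeding-adjusted Hardy-Weinberg proportions.
#' Sites are independent (no background LD) except inside planted ROH, where
#' one haplotype's alleles are drawn from the population frequency and copied
#' to both chromosomes so the tract is fully homozygous. When
#' `add_relationships` is set, the last sample of population 1 becomes a
#' genotype-identical duplicate of the first (expected pi-hat ~ 1) and the
#' second-to-last an offspring of the first (one allele per site inherited;
#' expected pi-hat ~ 0.5); both are constructed after planting and are
#' excluded from ROH carrier selection. Missingness is injected last, after
#' truth recording.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [genotype_dataset()]) and `truth`
#'   (a `sim_truth`: `ancestral_freqs`, `pop_freqs`, `true_roh`,
#'   `relationship_pairs`, `divergence_F`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_pops
  n_tot <- sum(config$n_per_pop)

  # marker map: exponential spacings, one chromosome at a time
  chrom <- integer(0); pos <- numeric(0)
  for (ch in seq_len(config$n_chromosomes)) {
    p <- cumsum(1 + round(stats::rexp(
      ceiling(1.4 * config$chrom_length_bp / config$snp_spacing_mean_bp) + 20,
      rate = 1 / config$snp_spacing_mean_bp)))
    p <- p[p <= config$chrom_length_bp]
    chrom <- c(chrom, rep(ch, length(p)))
    pos <- c(pos, p)
  }
  m <- length(pos)
  markers <- data.frame(
    marker_id = sprintf("mk%02d_%07d", chrom, seq_len(m)),
    chromosome = as.character(chrom),
    position_bp = as.integer(pos),
    allele1 = "A", allele2 = "B",
    stringsAsFactors = FALSE)

  anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pop_freqs <- matrix(NA_real_, m, K, dimnames = list(NULL, config$pop_labels))
  for (k in seq_len(K))
    pop_freqs[, k] <- balding_nichols_freqs(anc, config$divergence_F[k], 1L)

  # genotypes under inbreeding-adjusted HWE
  geno <- matrix(NA_integer_, n_tot, m)
  pop_of <- rep(config$pop_labels, config$n_per_pop)
  row0 <- 0L
  for (k in seq_len(K)) {
    nk <- config$n_per_pop[k]
    fis <- config$within_inbreeding_Fis[k]
    p <- pop_freqs[, k]; q <- 1 - p
    p_het <- 2 * p * q * (1 - fis)
    p_hom2 <- p^2 + fis * p * q
    u <- matrix(stats::runif(nk * m), nk, m)
    g <- matrix(0L, nk, m)
    het_thr <- matrix(p_het, nk, m, byrow = TRUE)
    hom_thr <- matrix(p_het + p_hom2, nk, m, byrow = TRUE)
    g[u < hom_thr] <- 2L
    g[u < het_thr] <- 1L
    geno[row0 + seq_len(nk), ] <- g
    row0 <- row0 + nk
  }

  # plant autozygous tracts (before relationship copies, after base draw)
  true_roh <- data.frame(sample_id = character(0), chromosome = character(0),
    start_bp = integer(0), end_bp = integer(0), stringsAsFactors = FALSE)
  sample_ids <- sprintf("%s_%03d", pop_of, unlist(lapply(config$n_per_pop, seq_len)))
  dup_src <- dup_tgt <- off_tgt <- NA_integer_
  if (config$add_relationships) {
    if (config$n_per_pop[1] < 4L)
      stop("config error: add_relationships requires >= 4 samples in population 1")
    dup_src <- 1L
    off_tgt <- config$n_per_pop[1] - 1L
    dup_tgt <- config$n_per_pop[1]
  }
  if (!is.null(config$planted_roh)) {
    for (r in seq_len(nrow(config$planted_roh))) {
      pr <- config$planted_roh[r, ]
      rows <- if (identical(pr$pop, "all")) seq_len(n_tot)
              else which(pop_of == pr$pop)
      rows <- setdiff(rows, c(dup_tgt, off_tgt))
      ncar <- round(pr$carrier_fraction * length(rows))
      if (ncar == 0L) next
      carriers <- sort(sample(rows, ncar))
      snp_idx <- which(chrom == as.integer(pr$chromosome) &
        pos >= pr$start_bp & pos <= pr$end_bp)
      if (length(snp_idx) == 0L) next
      for (s in carriers) {
        pk <- pop_freqs[snp_idx, match(pop_of[s], config$pop_labels)]
        hap <- as.integer(stats::runif(length(snp_idx)) < pk)
        geno[s, snp_idx] <- 2L * hap
      }
      true_roh <- rbind(true_roh, data.frame(
        sample_id = sample_ids[carriers],
        chromosome = as.character(pr$chromosome),
        start_bp = as.integer(pr$start_bp), end_bp = as.integer(pr$end_bp),
        stringsAsFactors = FALSE))
    }
  }

  relationship_pairs <- data.frame(sample_a = character(0), sample_b = character(0),
    expected_pi_hat = numeric(0), relationship = character(0),
    stringsAsFactors = FALSE)
  if (config$add_relationships) {
    geno[dup_tgt, ] <- geno[dup_src, ]
    # duplicate inherits any planted tract of its source
    src_rows <- true_roh$sample_id == sample_ids[dup_src]
    if (any(src_rows)) {
      dup_rows <- true_roh[src_rows, ]
      dup_rows$sample_id <- sample_ids[dup_tgt]
      true_roh <- rbind(true_roh, dup_rows)
    }
    # offspring: one allele transmitted by the parent, one from the population
    gp <- geno[dup_src, ]
    transmitted <- ifelse(gp == 2L, 1L,
      ifelse(gp == 0L, 0L, as.integer(stats::runif(m) < 0.5)))
    other <- as.integer(stats::runif(m) < pop_freqs[, 1])
    geno[off_tgt, ] <- transmitted + other
    relationship_pairs <- data.frame(
      sample_a = sample_ids[c(dup_src, dup_src)],
      sample_b = sample_ids[c(dup_tgt, off_tgt)],
      expected_pi_hat = c(1, 0.5),
      relationship = c("duplicate", "parent_offspring"),
      stringsAsFactors = FALSE)
  }

  # missingness injected last, after truth recording
  if (config$missing_rate > 0) {
    drop <- stats::runif(n_tot * m) < config$missing_rate
    geno[matrix(drop, n_tot, m)] <- NA_integer_
  }

  samples <- data.frame(
    sample_id = sample_ids,
    population = pop_of,
    sex = sample(c("male", "female"), n_tot, replace = TRUE),
    birth_year = sample(seq(config$decade_range[1], config$decade_range[2]),
      n_tot, replace = TRUE),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    ancestral_freqs = anc,
    pop_freqs = pop_freqs,
    true_roh = true_roh,
    relationship_pairs = relationship_pairs,
    divergence_F = config$divergence_F), class = "sim_truth")
  list(dataset = genotype_dataset(geno, markers, samples), truth = truth)
}

#' Write simulation truth tables
#'
#' Emits the planted-ROH truth as a tab-separated table
#' (sample_id, chromosome, start_bp, end_bp) and a JSON summary of the
#' configured divergence and relationship pairs.
#'
#' @param truth a `sim_truth` from [simulate_dataset()].
#' @param path_prefix output prefix; `.roh_truth.tsv` / `.truth.json` appended.
#' @return invisibly, the two paths.
#' @export
write_sim_truth <- function(truth, path_prefix) {
  p1 <- paste0(path_prefix, ".roh_truth.tsv")
  p2 <- paste0(path_prefix, ".truth.json")
  utils::write.table(truth$true_roh, p1, sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(
    divergence_F = truth$divergence_F,
    relationship_pairs = truth$relationship_pairs,
    n_markers = length(truth$ancestral_freqs)),
    p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
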