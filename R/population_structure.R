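#' Pairwise identity-by-descent by method of moments
#'
#' PLINK-style moments estimator: observed identity-by-state (IBS) sharing
#' counts for every pair are compared with their expectations under IBD
#' states Z = 0, 1, 2, computed from sample allele frequencies with the
#' without-replacement (small-sample) correction. Raw state probabilities
#' are bounded into [0, 1] and renormalized; pi-hat = P(Z=1)/2 + P(Z=2).
#' An LD-pruned marker set is recommended (the estimator assumes
#' quasi-independent loci). Monomorphic and fully missing markers are
#' uninformative and excluded.
#'
#' @param dataset a [genotype_dataset()] with at least 50 markers.
#' @param min_joint_markers pairs with fewer jointly non-missing markers are
#'   flagged unreliable.
#' @return list of symmetric matrices `z0`, `z1`, `z2`, `pi_hat` (diagonal
#'   pi-hat = 1), `n_joint` (joint non-missing marker counts) and `reliable`
#'   (logical).
#' @export
ibd_matrix <- function(dataset, min_joint_markers = 50L) {
  g <- dataset$genotypes
  n <- nrow(g)
  if (n < 2L) stop("ibd_matrix needs at least two samples")
  called <- colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  use <- called >= 2L & p > 0 & p < 1
  if (sum(use) < 2L) stop("ibd_matrix: no informative (polymorphic) markers")
  g <- g[, use, drop = FALSE]
  Tn <- 2 * called[use]              # sampled allele counts per locus
  cA <- colSums(g, na.rm = TRUE)     # allele-2 counts
  cB <- Tn - cA

  # expected IBS-state probabilities per locus, drawing alleles without
  # replacement from the observed pool (Purcell et al. 2007 moments scheme)
  d4 <- Tn * (Tn - 1) * (Tn - 2) * (Tn - 3)
  d3 <- Tn * (Tn - 1) * (Tn - 2)
  e00 <- 2 * cA * (cA - 1) * cB * (cB - 1) / d4
  e10 <- (4 * cA * (cA - 1) * (cA - 2) * cB +
          4 * cA * cB * (cB - 1) * (cB - 2)) / d4
  e20 <- 1 - e00 - e10
  e11 <- (2 * cA * (cA - 1) * cB + 2 * cA * cB * (cB - 1)) / d3
  e21 <- 1 - e11
  keep <- is.finite(e00) & is.finite(e11)
  g <- g[, keep, drop = FALSE]
  L <- ncol(g)
  S00 <- sum(e00[keep]); S10 <- sum(e10[keep]); S20 <- sum(e20[keep])
  S11 <- sum(e11[keep]); S21 <- sum(e21[keep])

  # observed IBS counts for all pairs via indicator cross-products
  H0 <- (!is.na(g)) & g == 0L; H0[is.na(H0)] <- FALSE
  H1 <- (!is.na(g)) & g == 1L; H1[is.na(H1)] <- FALSE
  H2 <- (!is.na(g)) & g == 2L; H2[is.na(H2)] <- FALSE
  storage.mode(H0) <- storage.mode(H1) <- storage.mode(H2) <- "double"
  M <- H0 + H1 + H2                  # non-missing indicator
  obs0 <- H0 %*% t(H2); obs0 <- obs0 + t(obs0)
  obs2 <- tcrossprod(H0) + tcrossprod(H1) + tcrossprod(H2)
  njoint <- tcrossprod(M)
  obs1 <- njoint - obs0 - obs2

  f <- njoint / L                    # missingness scaling of expectations
  z0 <- obs0 / (S00 * f)
  z1 <- (obs1 - z0 * S10 * f) / (S11 * f)
  z2 <- (obs2 - z0 * S20 * f - z1 * S21 * f) / njoint
  z0 <- pmin(pmax(z0, 0), 1); z1 <- pmin(pmax(z1, 0), 1); z2 <- pmin(pmax(z2, 0), 1)
  tot <- z0 + z1 + z2
  z0 <- z0 / tot; z1 <- z1 / tot; z2 <- z2 / tot
  pi_hat <- z1 / 2 + z2
  diag(pi_hat) <- 1; diag(z2) <- 1; diag(z1) <- 0; diag(z0) <- 0
  ids <- dataset$samples$sample_id
  dimnames(pi_hat) <- dimnames(z0) <- dimnames(z1) <- dimnames(z2) <-
    dimnames(njoint) <- list(ids, ids)
  list(z0 = z0, z1 = z1, z2 = z2, pi_hat = pi_hat,
    n_joint = njoint, reliable = njoint >= min_joint_markers)
}

#' Per-individual inbreeding coefficient f (F_IS analogue)
#'
#' Excess-homozygosity estimator: f = (O_hom - E_hom) / (L - E_hom) over
#' each sample's non-missing polymorphic markers, with the expected
#' homozygosity E_hom = sum over markers of 1 - 2*p*q * 2n/(2n - 1) (the
#' unbiased expected heterozygosity). f is 0 under exact Hardy-Weinberg
#' expectation, -1 at complete heterozygote excess, +1 at complete
#' homozygosity.
#'
#' @param dataset a [genotype_dataset()].
#' @param freqs optional external allele frequencies (per marker); defaults
#'   to the pooled sample estimate.
#' @return an `inbreeding_table` data.frame: sample_id, f, observed_hom,
#'   expected_hom, n_used, population, birth_year.
#' @export
inbreeding_f <- function(dataset, freqs = NULL) {
  g <- dataset$genotypes
  called <- colSums(!is.na(g))
  p <- if (is.null(freqs)) colMeans(g, na.rm = TRUE) / 2 else freqs
  use <- called >= 2L & p > 0 & p < 1
  if (!any(use))
    stop("inbreeding_f: no polymorphic markers; f undefined")
  g <- g[, use, drop = FALSE]
  p <- p[use]
  nall <- 2 * called[use]
  ehet <- 2 * p * (1 - p) * nall / (nall - 1)
  e_hom_l <- 1 - ehet
  nonmiss <- !is.na(g)
  O <- rowSums(g == 0L | g == 2L, na.rm = TRUE)
  E <- as.numeric(nonmiss %*% e_hom_l)
  Lrow <- rowSums(nonmiss)
  f <- (O - E) / (Lrow - E)
  out <- data.frame(
    sample_id = dataset$samples$sample_id,
    f = f, observed_hom = O, expected_hom = E, n_used = Lrow,
    population = dataset$samples$population,
    birth_year = dataset$samples$birth_year,
    stringsAsFactors = FALSE)
  class(out) <- c("inbreeding_table", "data.frame")
  out
}

#' Mean inbreeding per group and birth decade
#'
#' Decade = floor(birth_year / 10) * 10. Samples without a birth year are
#' excluded and tallied in the `n_missing_birth_year` attribute.
#'
#' @param table an `inbreeding_table` from [inbreeding_f()].
#' @return data.frame: population, decade, mean_f, n.
#' @export
decade_means <- function(table) {
  has <- !is.na(table$birth_year)
  dec <- floor(table$birth_year[has] / 10) * 10
  sub <- table[has, , drop = FALSE]
  key <- interaction(sub$population, dec, drop = TRUE)
  out <- data.frame(
    population = tapply(sub$population, key, `[`, 1),
    decade = as.integer(tapply(dec, key, `[`, 1)),
    mean_f = as.numeric(tapply(sub$f, key, mean)),
    n = as.integer(tapply(sub$f, key, length)),
    stringsAsFactors = FALSE)
  out <- out[order(out$population, out$decade), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_birth_year") <- sum(!has)
  out
}

#' Compare mean inbreeding between two groups (Welch t-test)
#'
#' Two-sided Welch (unequal-variance) t-test on per-sample f. Groups with
#' zero variance and equal means return p = 1.
#'
#' @param table an `inbreeding_table`.
#' @param groupA,groupB population labels to compare.
#' @return list: t_statistic, p_value, mean_a, mean_b, n_a, n_b.
#' @export
compare_groups_f <- function(table, groupA, groupB) {
  fa <- table$f[table$population == groupA]
  fb <- table$f[table$population == groupB]
  if (length(fa) < 2L || length(fb) < 2L)
    stop("precondition error: both groups need at least 2 samples")
  if (stats::var(fa) == 0 && stats::var(fb) == 0) {
    eq <- isTRUE(all.equal(mean(fa), mean(fb)))
    return(list(t_statistic = if (eq) 0 else Inf,
      p_value = if (eq) 1 else 0,
      mean_a = mean(fa), mean_b = mean(fb),
      n_a = length(fa), n_b = length(fb)))
  }
  tt <- stats::t.test(fa, fb, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
    mean_a = mean(fa), mean_b = mean(fb),
    n_a = length(fa), n_b = length(fb))
}

#' PCA of genotypes with Hardy-Weinberg normalization
#'
#' EIGENSTRAT-style decomposition: each polymorphic marker column is
#' centered by twice its allele frequency and scaled by its theoretical
#' standard deviation under Hardy-Weinberg equilibrium, sqrt(2p(1-p));
#' missing entries are mean-imputed (zero after centering). Components come
#' from the eigen-decomposition of the sample-by-sample covariance of the
#' normalized matrix.
#'
#' @param dataset a [genotype_dataset()].
#' @param n_components number of component scores to return (clipped with a
#'   warning if above min(samples, markers)).
#' @return a `pca_result`: `scores` (samples x components, the projections
#'   U * D), `eigenvalues` (all, nonincreasing), `n_markers_used`.
#' @export
pca_genotypes <- function(dataset, n_components = 10L) {
  g <- dataset$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("pca_genotypes: no polymorphic markers")
  g <- g[, use, drop = FALSE]
  p <- p[use]
  X <- sweep(g, 2L, 2 * p, `-`)
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), `/`)
  X[is.na(X)] <- 0
  n <- nrow(X); m <- ncol(X)
  kmax <- min(n, m)
  if (n_components > kmax) {
    warning("n_components clipped to ", kmax)
    n_components <- kmax
  }
  K <- tcrossprod(X)
  eg <- eigen(K, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  scores <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_components)]), n_components)
  rownames(scores) <- dataset$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, eigenvalues = vals, n_markers_used = m),
    class = "pca_result")
}

#' Tabulate hemizygous haplotypes
#'
#' For hemizygous markers (e.g. Y-linked SNPs in males) each sample's
#' haplotype is its ordered allele string. Heterozygous calls are genotyping
#' anomalies: the sample is excluded and flagged. Samples with any missing
#' call are grouped separately. Pairwise Hamming distances between distinct
#' complete haplotypes are reported.
#'
#' @param hemizygous_calls sample x marker matrix of genotype codes (0/2, or
#'   1 for an anomalous heterozygote, NA missing), with sample row names.
#' @return list: `counts` (data.frame haplotype, count), `incomplete`
#'   (sample ids with missing calls), `anomalies` (sample ids with
#'   heterozygous calls), `hamming` (distance matrix between haplotypes).
#' @export
tabulate_haplotypes <- function(hemizygous_calls) {
  g <- as.matrix(hemizygous_calls)
  ids <- rownames(g)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(g)))
  het <- apply(g, 1L, function(r) any(!is.na(r) & r == 1L))
  miss <- apply(g, 1L, function(r) any(is.na(r)))
  complete <- !het & !miss
  hap <- apply(g[complete, , drop = FALSE], 1L, paste, collapse = "")
  tab <- table(hap)
  counts <- data.frame(haplotype = names(tab), count = as.integer(tab),
    stringsAsFactors = FALSE)
  counts <- counts[order(-counts$count, counts$haplotype), , drop = FALSE]
  rownames(counts) <- NULL
  uh <- counts$haplotype
  hm <- matrix(0L, length(uh), length(uh), dimnames = list(uh, uh))
  if (length(uh) > 1) {
    sp <- strsplit(uh, "")
    for (i in seq_along(uh)) for (j in seq_along(uh))
      hm[i, j] <- sum(sp[[i]] != sp[[j]])
  }
  list(counts = counts,
    incomplete = ids[miss & !het],
    anomalies = ids[het],
    hamming = hm)
}
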