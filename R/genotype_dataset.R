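#' Construct a genotype dataset
#'
#' The central container of rohscan: a sample x marker matrix of
#' alternate-allele counts (0 = homozygous for allele 1, 1 = heterozygous,
#' 2 = homozygous for allele 2, `NA` = missing) together with a physical
#' marker map and a sample table. Heterozygotes are always coded 1, so every
#' homozygosity-based statistic is free of allele labelling.
#'
#' @param genotypes integer matrix, samples in rows, markers in columns,
#'   entries in \{0, 1, 2, NA\}.
#' @param markers data.frame with columns `marker_id`, `chromosome`
#'   (autosome number as character, or "X", "Y", "MT", "0"), `position_bp`
#'   (1-based physical coordinate) and `allele1`, `allele2`.
#' @param samples data.frame with columns `sample_id`, `population`, `sex`
#'   ("male", "female" or "unknown") and `birth_year` (integer or NA).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, markers, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_m <- c("marker_id", "chromosome", "position_bp", "allele1", "allele2")
  if (!all(need_m %in% names(markers)))
    stop("markers must have columns: ", paste(need_m, collapse = ", "))
  need_s <- c("sample_id", "population", "sex", "birth_year")
  for (col in setdiff(need_s, names(samples))) {
    samples[[col]] <- switch(col,
      population = "POP1", sex = "unknown", birth_year = NA_integer_,
      stop("samples must have a sample_id column"))
  }
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.integer(markers$position_bp)
  x <- structure(
    list(genotypes = genotypes, markers = markers, samples = samples),
    class = "genotype_dataset")
  validate_genotype_dataset(x)
  x
}

validate_genotype_dataset <- function(x) {
  g <- x$genotypes
  if (nrow(g) != nrow(x$samples))
    stop("format error: genotype rows (", nrow(g), ") != samples (", nrow(x$samples), ")")
  if (ncol(g) != nrow(x$markers))
    stop("format error: genotype columns (", ncol(g), ") != markers (", nrow(x$markers), ")")
  if (anyDuplicated(x$markers$marker_id))
    stop("marker_id values must be unique")
  if (anyDuplicated(x$samples$sample_id))
    stop("sample_id values must be unique")
  bad <- g[!is.na(g)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be 0, 1, 2 or NA")
  ord <- order(chromosome_order(x$markers$chromosome), x$markers$position_bp)
  if (is.unsorted(ord) && !identical(ord, seq_len(nrow(x$markers))))
    stop("markers must be sorted by (chromosome, position_bp)")
  invisible(x)
}

# Deterministic chromosome sort key: autosomes numerically, then X, Y, MT,
# then unmapped ("0"/NA) last.
chromosome_order <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.integer(chrom))
  key <- ifelse(!is.na(num) & num > 0L, num,
    ifelse(chrom == "X", 1000L,
      ifelse(chrom == "Y", 1001L,
        ifelse(chrom == "MT", 1002L, 2000L))))
  key
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x", nrow(x$markers), "markers\n")
  cat("  chromosomes:", paste(unique(x$markers$chromosome), collapse = " "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  cat("  populations:", paste(names(table(x$samples$population)), collapse = " "), "\n")
  invisible(x)
}

#' Number of samples / markers
#' @param dataset a `genotype_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$samples)

#' @rdname n_samples
#' @export
n_markers <- function(dataset) nrow(dataset$markers)

#' Is a chromosome label autosomal?
#'
#' "X", "Y", "MT" are sex/non-autosomal; "0", "", NA are unmapped.
#' @param chrom character vector of chromosome labels.
#' @return logical vector.
#' @export
is_autosome <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.integer(chrom))
  !is.na(num) & num > 0L
}

is_unmapped_marker <- function(markers) {
  chrom <- as.character(markers$chromosome)
  pos <- markers$position_bp
  is.na(chrom) | chrom == "0" | chrom == "" | is.na(pos) | pos <= 0L
}

is_sex_marker <- function(markers) {
  as.character(markers$chromosome) %in% c("X", "Y", "MT")
}

#' Subset a genotype dataset
#'
#' @param dataset a `genotype_dataset`.
#' @param samples,markers integer or logical index vectors (default: keep all).
#' @return a `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, markers = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(dataset))
  if (is.null(markers)) markers <- seq_len(n_markers(dataset))
  genotype_dataset(
    dataset$genotypes[samples, markers, drop = FALSE],
    dataset$markers[markers, , drop = FALSE],
    dataset$samples[samples, , drop = FALSE])
}

#' Restrict a dataset to mapped autosomal markers
#' @param dataset a `genotype_dataset`.
#' @return a `genotype_dataset` containing only autosomal mapped markers.
#' @export
autosomal <- function(dataset) {
  keep <- is_autosome(dataset$markers$chromosome) & !is_unmapped_marker(dataset$markers)
  subset_dataset(dataset, markers = which(keep))
}

#' Sample allele frequencies of allele 2
#' @param dataset a `genotype_dataset`.
#' @return numeric vector, one frequency per marker (NaN if fully missing).
#' @export
allele_freqs <- function(dataset) {
  colMeans(dataset$genotypes, na.rm = TRUE) / 2
}

#' Per-marker and per-sample call rates
#' @param dataset a `genotype_dataset`.
#' @return numeric vector of non-missing fractions.
#' @export
marker_call_rate <- function(dataset) {
  1 - colMeans(is.na(dataset$genotypes))
}

#' @rdname marker_call_rate
#' @export
sample_call_rate <- function(dataset) {
  1 - rowMeans(is.na(dataset$genotypes))
}
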