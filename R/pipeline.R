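#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]: exactly one of a
#' binary genotype fileset prefix or a [sim_config()] as the input source,
#' a two-group assignment for the association and selection scans, and the
#' module parameter blocks. Every default equals the headline analysis
#' parameters (QC >95\%/>5\%, ROH 500 kb/25 SNPs/1 het/5 missing/100 kb,
#' clusters of >= 5 carriers, 7-sigma seeds with 5-sigma extension, LD
#' pruning 50/5/0.5, 10 principal components).
#'
#' @param fileset path prefix of a bed/bim/fam trio, or NULL.
#' @param sim a [sim_config()], or NULL.
#' @param group_column samples column holding the two-group labels.
#' @param groups optional character vector of exactly two labels to compare
#'   (default: the two most frequent levels of `group_column`).
#' @param qc named list overriding [apply_qc()] defaults.
#' @param roh a [roh_params()].
#' @param min_members cluster membership floor.
#' @param seed_mult,ext_mult,pad_bp sigma-region parameters.
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters.
#' @param n_components principal components to report.
#' @param out_dir output directory (created if absent).
#' @param seed global seed fanned out to stage child seeds by fixed offsets.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(fileset = NULL, sim = NULL,
                            group_column = "population", groups = NULL,
                            qc = list(), roh = roh_params(),
                            min_members = 5L,
                            seed_mult = 7, ext_mult = 5, pad_bp = 500000,
                            ld_window = 50L, ld_step = 5L, ld_r2 = 0.5,
                            n_components = 10L,
                            out_dir = tempfile("rohscan_run_"),
                            seed = 1L) {
  if (is.null(fileset) == is.null(sim))
    stop("config error: exactly one of `fileset` or `sim` must be given")
  structure(list(fileset = fileset, sim = sim, group_column = group_column,
    groups = groups, qc = qc, roh = roh, min_members = as.integer(min_members),
    seed_mult = seed_mult, ext_mult = ext_mult, pad_bp = pad_bp,
    ld_window = as.integer(ld_window), ld_step = as.integer(ld_step),
    ld_r2 = ld_r2, n_components = as.integer(n_components),
    out_dir = out_dir, seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: load or simulate genotypes; QC;
#' LD pruning; population structure (PCA, pairwise IBD, inbreeding f,
#' decade means, group comparison); ROH detection, length bins, per-SNP
#' incidence and F_ROH; ROH clustering, membership and homozygosity
#' association; per-marker F_ST with sigma-threshold regions; and the
#' multilocus pairwise fixation-index matrix. Every stage's tables are
#' written to the output directory with a JSON manifest of parameters and
#' seed; re-running an identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_bundle` list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rec <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(rec, file.path(config$out_dir, "error.json"),
        auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })
  }
  tsv <- function(x, name) utils::write.table(x,
    file.path(config$out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  bundle <- list(config = config)
  raw <- stage("input", {
    if (!is.null(config$sim)) {
      sc <- config$sim
      sc$seed <- config$seed + 101L   # stage child seed, recorded in manifest
      sim <- simulate_dataset(sc)
      bundle$truth <- sim$truth
      sim$dataset
    } else read_genotypes(config$fileset)
  })
  bundle$truth <- bundle$truth

  qcres <- stage("qc", do.call(apply_qc, c(list(raw), config$qc)))
  ds <- qcres$dataset
  bundle$qc_report <- qcres$report
  write_qc_report(qcres$report, file.path(config$out_dir, "qc_report.txt"))

  groups <- config$groups
  labels <- ds$samples[[config$group_column]]
  if (is.null(groups)) {
    groups <- names(sort(table(labels), decreasing = TRUE))[1:2]
  }
  missing_g <- setdiff(groups, unique(labels))
  if (length(missing_g))
    stage("groups", stop("config error: unknown group label(s): ",
      paste(missing_g, collapse = ", ")))
  two <- labels %in% groups
  ds2 <- subset_dataset(ds, samples = which(two))
  lab2 <- ds2$samples[[config$group_column]]

  auto <- autosomal(ds)
  pruned_idx <- stage("ld_prune",
    ld_prune(auto, config$ld_window, config$ld_step, config$ld_r2))
  pruned <- subset_dataset(auto, markers = pruned_idx)
  bundle$pruned_markers <- pruned$markers$marker_id

  bundle$pca <- stage("pca", pca_genotypes(auto, config$n_components))
  tsv(data.frame(sample_id = rownames(bundle$pca$scores), bundle$pca$scores),
    "pca_scores.tsv")
  bundle$ibd <- stage("ibd", ibd_matrix(pruned))
  utils::write.table(bundle$ibd$pi_hat, file.path(config$out_dir, "pi_hat.tsv"),
    sep = "\t", quote = FALSE)
  bundle$inbreeding <- stage("inbreeding", inbreeding_f(pruned))
  tsv(bundle$inbreeding, "inbreeding_f.tsv")
  bundle$decades <- stage("decades", decade_means(bundle$inbreeding))
  tsv(bundle$decades, "decade_means.tsv")
  bundle$group_f_test <- stage("group_f_test", {
    sub <- bundle$inbreeding[bundle$inbreeding$population %in% groups, ]
    if (all(table(factor(sub$population, levels = groups)) >= 2))
      compare_groups_f(sub, groups[1], groups[2]) else NULL
  })

  bundle$roh <- stage("roh", detect_roh(ds, config$roh))
  write_roh(bundle$roh, file.path(config$out_dir, "roh.tsv"))
  bundle$f_roh <- stage("f_roh", compute_f_roh(bundle$roh))
  tsv(bundle$f_roh, "f_roh.tsv")
  bundle$bins <- stage("bins", summarize_roh_bins(bundle$roh,
    group_labels = ds$samples$population))
  tsv(bundle$bins, "roh_bins.tsv")
  bundle$incidence <- stage("incidence", snp_incidence(bundle$roh, auto$markers))
  bundle$incidence_regions <- stage("incidence_regions",
    call_incidence_regions(bundle$incidence, auto$markers,
      config$seed_mult, config$ext_mult, config$pad_bp))

  bundle$clusters <- stage("clusters",
    find_clusters(bundle$roh, auto$markers, config$min_members))
  tsv(bundle$clusters[, setdiff(names(bundle$clusters), "members")],
    "roh_clusters.tsv")
  roh2 <- stage("roh_groups", {
    x <- bundle$roh
    keep <- x$records$sample_id %in% ds2$samples$sample_id
    x$records <- x$records[keep, , drop = FALSE]
    x$sample_ids <- ds2$samples$sample_id
    x
  })
  bundle$membership <- stage("membership",
    membership_matrix(roh2, bundle$clusters, auto$markers))
  bundle$association <- stage("association", {
    if (nrow(bundle$clusters))
      homozygosity_association(bundle$membership, lab2) else NULL
  })
  if (!is.null(bundle$association)) tsv(bundle$association, "association.tsv")

  bundle$fst <- stage("fst", marker_fst(subset_dataset(autosomal(ds2)), lab2))
  tsv(data.frame(marker_id = bundle$fst$markers$marker_id,
    chromosome = bundle$fst$markers$chromosome,
    position_bp = bundle$fst$markers$position_bp,
    theta = bundle$fst$theta), "fst_profile.tsv")
  bundle$fst_regions <- stage("fst_regions", call_regions(bundle$fst,
    seed_mult = config$seed_mult, ext_mult = config$ext_mult,
    pad_bp = config$pad_bp))
  tsv(bundle$fst_regions[, setdiff(names(bundle$fst_regions),
    c("seed_snp_idx", "seed_snp_ids"))], "fst_regions.tsv")
  bundle$pairwise_fst <- stage("pairwise_fst", {
    sizes <- table(ds$samples$population)
    use <- ds$samples$population %in% names(sizes)[sizes >= 2]
    pairwise_population_fst(subset_dataset(autosomal(ds), samples = which(use)),
      ds$samples$population[use])
  })
  utils::write.table(bundle$pairwise_fst,
    file.path(config$out_dir, "pairwise_fst.tsv"), sep = "\t", quote = FALSE)

  manifest <- list(seed = config$seed, stage_seed_offsets = list(sim = 101L),
    groups = groups, qc = config$qc, roh = unclass(config$roh),
    min_members = config$min_members, seed_mult = config$seed_mult,
    ext_mult = config$ext_mult, pad_bp = config$pad_bp,
    ld = list(window = config$ld_window, step = config$ld_step, r2 = config$ld_r2),
    n_components = config$n_components)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Human-readable pipeline report
#'
#' Renders the bundle as text tables mirroring the customary reporting
#' shapes: a cluster listing (Chr, Start SNP, Position Start, End Position,
#' Length, # SNPs, P-value, Population), per-group ROH length-bin means,
#' the pairwise fixation-index matrix, and the per-group inbreeding summary
#' (mean f and F_ROH). Missing sections are flagged rather than fatal.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param file optional path; when given the report is also written there.
#' @return character vector of report lines, invisibly when `file` is given.
#' @export
generate_report <- function(bundle, file = NULL) {
  out <- c("rohscan pipeline report", strrep("=", 23), "")

  out <- c(out, "ROH cluster association (Table style)",
    paste("Chr", "Start SNP", "Position Start (bp)", "End Position (bp)",
      "Length (bp)", "# SNPs", "P-value", "Population", sep = "\t"))
  if (!is.null(bundle$association) && nrow(bundle$association)) {
    cl <- bundle$clusters
    as_ <- bundle$association
    for (i in seq_len(nrow(cl))) {
      out <- c(out, paste(cl$chromosome[i], cl$first_snp_id[i],
        cl$consensus_start_bp[i], cl$consensus_end_bp[i],
        cl$consensus_end_bp[i] - cl$consensus_start_bp[i],
        cl$n_snps_in_cluster[i],
        signif(as_$p_value[i], 6), as_$enriched[i], sep = "\t"))
    }
  } else out <- c(out, "(no clusters)")
  out <- c(out, "")

  out <- c(out, "Mean ROH per individual by length bin")
  if (!is.null(bundle$bins) && nrow(bundle$bins)) {
    out <- c(out, paste("group", "bin(>Mb)", "mean_count", "mean_total_Mb", sep = "\t"))
    b <- bundle$bins
    out <- c(out, paste(b$group, b$bin_mb, signif(b$mean_count, 4),
      signif(b$mean_total_mb, 4), sep = "\t"))
  } else out <- c(out, "(missing)")
  out <- c(out, "")

  out <- c(out, "Pairwise fixation index (F_ST)")
  if (!is.null(bundle$pairwise_fst)) {
    pf <- bundle$pairwise_fst
    out <- c(out, paste(c("", colnames(pf)), collapse = "\t"))
    for (i in seq_len(nrow(pf)))
      out <- c(out, paste(c(rownames(pf)[i], signif(pf[i, ], 4)), collapse = "\t"))
  } else out <- c(out, "(missing)")
  out <- c(out, "")

  out <- c(out, "Inbreeding summary (mean f and F_ROH per population)")
  if (!is.null(bundle$inbreeding) && !is.null(bundle$f_roh)) {
    inb <- bundle$inbreeding
    fr <- bundle$f_roh
    frcols <- grep("^f_roh_", names(fr), value = TRUE)
    pops <- sort(unique(inb$population))
    hdr <- paste(c("population", "n", "mean_f", frcols), collapse = "\t")
    out <- c(out, hdr)
    full <- bundle$roh$sample_ids
    for (pp in pops) {
      rows <- inb$population == pp
      ids <- inb$sample_id[rows]
      frv <- vapply(frcols, function(cn)
        mean(fr[[cn]][fr$sample_id %in% ids]), numeric(1))
      out <- c(out, paste(c(pp, sum(rows), signif(mean(inb$f[rows]), 4),
        signif(frv, 4)), collapse = "\t"))
    }
  } else out <- c(out, "(missing)")

  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
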