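#' Simulate a sorted-cell reference experiment with planted DMR blocks
#'
#' Emulates a cell-sorting experiment measured at CpG resolution: for every
#' cell type, blocks of consecutive CpGs are planted in which that type is
#' clearly unmethylated while all others are methylated (hypo blocks) and
#' vice versa (hyper blocks); additional consensus blocks are uniformly
#' unmethylated or methylated across every type. Background CpGs between
#' blocks sit at an intermediate level in all types. Replicate measurements
#' add i.i.d. normal noise (clipped to \[0, 1\]).
#'
#' @param K cell types (default 6; whole-blood leukocyte names).
#' @param reps replicates per cell type (default 6).
#' @param blocks_per_contrast planted hypo and hyper blocks per type
#'   (default 2).
#' @param n_consensus consensus blocks per state (default 3).
#' @param block_size CpGs per planted block (default 5).
#' @param n_background background CpGs between blocks (default 3).
#' @param spacing base pairs between consecutive CpGs (default 100).
#' @param noise_sd replicate noise standard deviation (default 0.05).
#' @param low,high,background mean beta of the unmethylated, methylated and
#'   background levels.
#' @param cell_types optional type names.
#' @param seed RNG seed.
#' @return A [reference_sample_set()]; attribute `"blocks"` is a data.frame
#'   of the planted truth (`start`, `end` 0-based half-open, `target`,
#'   `kind` in hypo/hyper/consensus_low/consensus_high, `first_idx`,
#'   `last_idx`).
#' @export
simulate_reference_set <- function(K = 6L, reps = 6L, blocks_per_contrast = 2L,
                                   n_consensus = 3L, block_size = 5L,
                                   n_background = 3L, spacing = 100L,
                                   noise_sd = 0.05, low = 0.1, high = 0.9,
                                   background = 0.5, cell_types = NULL,
                                   seed = 1L) {
  if (is.null(cell_types)) {
    cell_types <- if (K == 6) c("Gran", "CD4T", "CD8T", "Bcell", "Mono", "NK")
                  else sprintf("celltype_%d", seq_len(K))
  }
  specs <- list()
  for (k in seq_len(K)) {
    for (b in seq_len(blocks_per_contrast)) {
      specs[[length(specs) + 1L]] <- list(target = cell_types[k], kind = "hypo")
      specs[[length(specs) + 1L]] <- list(target = cell_types[k], kind = "hyper")
    }
  }
  for (b in seq_len(n_consensus)) {
    specs[[length(specs) + 1L]] <- list(target = NA, kind = "consensus_low")
    specs[[length(specs) + 1L]] <- list(target = NA, kind = "consensus_high")
  }

  mean_rows <- list()
  block_rows <- list()
  idx <- 0L
  add_cpgs <- function(n, means) {
    for (j in seq_len(n)) mean_rows[[length(mean_rows) + 1L]] <<- means
    idx <<- idx + n
  }
  add_cpgs(n_background, rep(background, K))
  for (sp in specs) {
    means <- switch(sp$kind,
      hypo = {m <- rep(high, K); m[cell_types == sp$target] <- low; m},
      hyper = {m <- rep(low, K); m[cell_types == sp$target] <- high; m},
      consensus_low = rep(low, K),
      consensus_high = rep(high, K))
    first <- idx + 1L
    add_cpgs(block_size, means)
    block_rows[[length(block_rows) + 1L]] <-
      data.frame(target = sp$target, kind = sp$kind,
                 first_idx = first, last_idx = idx,
                 stringsAsFactors = FALSE)
    add_cpgs(n_background, rep(background, K))
  }
  M <- do.call(rbind, mean_rows)       # J x K mean betas
  J <- nrow(M)
  pos <- (seq_len(J) - 1L) * spacing + 1000L
  blocks <- do.call(rbind, block_rows)
  blocks$start <- pos[blocks$first_idx]
  blocks$end <- pos[blocks$last_idx] + 1L
  blocks$chrom <- "chrSim"

  set.seed(seed)
  labels <- rep(cell_types, each = reps)
  betas <- matrix(NA_real_, J, length(labels))
  for (m in seq_along(labels)) {
    mu <- M[, cell_types == labels[m]]
    betas[, m] <- pmin(pmax(mu + stats::rnorm(J, 0, noise_sd), 0), 1)
  }
  colnames(betas) <- sprintf("%s_rep%d", labels,
                             stats::ave(seq_along(labels), labels,
                                        FUN = seq_along))
  ref <- reference_sample_set(betas, labels, chrom = rep("chrSim", J),
                              pos = pos)
  attr(ref, "blocks") <- blocks
  ref
}

#' Assemble a reference sample set from measurement tables and labels
#'
#' @param tables list of array-style `CpGMeasurementTable` sharing one CpG
#'   grid (e.g. from [read_beta_table()]).
#' @param labels named character vector or data.frame (`sample_id`,
#'   `cell_type`) assigning each table's sample to a cell type.
#' @return A [reference_sample_set()].
#' @export
reference_from_tables <- function(tables, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$cell_type),
                              labels$sample_id)
  }
  ids <- vapply(tables, function(x) x$sample_id, character(1))
  missing <- setdiff(ids, names(labels))
  .stop_if(length(missing) > 0, "no cell-type label for sample(s): ",
           paste(missing, collapse = ", "))
  base <- tables[[1]]$data
  betas <- vapply(tables, function(tb) {
    .stop_if(!identical(tb$data$cpg_id, base$cpg_id),
             "reference samples must share one CpG grid")
    tb$data$level
  }, numeric(nrow(base)))
  colnames(betas) <- ids
  ord <- order(base$chrom, base$pos)
  reference_sample_set(betas[ord, , drop = FALSE], labels[ids],
                       chrom = base$chrom[ord], pos = base$pos[ord])
}

#' Expand region-level methylation to CpG-level measurement tables
#'
#' Assigns each region's level to every CpG position inside it (a convenient
#' way to materialize CpG-level fixtures from the region-level generative
#' model). Sequencing-style output converts levels to read counts at a fixed
#' depth.
#'
#' @param rmm a [region_methylation_matrix()].
#' @param cpgs_per_region CpGs placed uniformly inside each region
#'   (default 3).
#' @param style `"array"` (betas) or `"sequencing"` (counts).
#' @param depth total reads per CpG for sequencing output (default 20).
#' @return named list of `CpGMeasurementTable` objects, one per sample.
#' @export
expand_to_cpgs <- function(rmm, cpgs_per_region = 3L,
                           style = c("array", "sequencing"), depth = 20L) {
  style <- match.arg(style)
  reg <- rmm$regions
  pos <- unlist(lapply(seq_len(nrow(reg)), function(r) {
    w <- reg$end[r] - reg$start[r]
    reg$start[r] + floor(w * (seq_len(cpgs_per_region) - 0.5) /
                           cpgs_per_region)
  }))
  chrom <- rep(reg$chrom, each = cpgs_per_region)
  lev <- rmm$Y[rep(seq_len(nrow(reg)), each = cpgs_per_region), , drop = FALSE]
  out <- lapply(seq_along(rmm$sample_ids), function(i) {
    if (style == "array") {
      keep <- !is.na(lev[, i])
      cpg_measurement_table(rmm$sample_ids[i], chrom[keep], pos[keep],
                            beta = lev[keep, i], platform = "array")
    } else {
      keep <- !is.na(lev[, i])
      meth <- round(lev[keep, i] * depth)
      cpg_measurement_table(rmm$sample_ids[i], chrom[keep], pos[keep],
                            meth = meth, unmeth = depth - meth,
                            platform = "sequencing")
    }
  })
  stats::setNames(out, rmm$sample_ids)
}

#' Write a self-contained set of example fixture files
#'
#' Generates a synthetic sorted-cell reference, builds the region-state
#' matrix from it, simulates a small heterogeneous cohort on the default
#' array platform, and writes everything in the package's file formats:
#' `regions.bed` (BED + state columns), `reference_betas.tsv` +
#' `reference_labels.tsv`, `mixture_betas.tsv` (CpG-level beta table),
#' `mixture_sample1.cov` (Bismark coverage), and `true_composition.tsv`.
#'
#' @param dir output directory (created if needed).
#' @param N mixture samples (default 3).
#' @param seed RNG seed.
#' @return named character vector of file paths (invisibly).
#' @export
write_example_fixtures <- function(dir, N = 3L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference_set(seed = seed)
  rsm <- build_z_matrix(ref)
  paths <- c(regions = file.path(dir, "regions.bed"))
  write_regions(rsm, paths["regions"])

  ref_tables <- lapply(seq_len(ncol(ref$betas)), function(m) {
    cpg_measurement_table(colnames(ref$betas)[m], ref$chrom, ref$pos,
                          beta = ref$betas[, m], platform = "array")
  })
  paths["reference_betas"] <- file.path(dir, "reference_betas.tsv")
  write_beta_table(ref_tables, paths["reference_betas"])
  paths["reference_labels"] <- file.path(dir, "reference_labels.tsv")
  utils::write.table(
    data.frame(sample_id = colnames(ref$betas), cell_type = ref$labels),
    paths["reference_labels"], sep = "\t", quote = FALSE, row.names = FALSE)

  config <- simulation_config(N = N, K = length(rsm$cell_types), Z = rsm,
                              pi_dirichlet_alpha = rep(2, length(rsm$cell_types)),
                              n_sims = 1L, seed = seed)
  ds <- simulate_mixtures(config)
  tables <- expand_to_cpgs(ds$Y[[1]])
  paths["mixture_betas"] <- file.path(dir, "mixture_betas.tsv")
  write_beta_table(tables, paths["mixture_betas"])
  cov_tables <- expand_to_cpgs(ds$Y[[1]], style = "sequencing")
  paths["mixture_coverage"] <- file.path(dir, "mixture_sample1.cov")
  write_bismark_coverage(cov_tables[[1]], paths["mixture_coverage"])
  paths["true_composition"] <- file.path(dir, "true_composition.tsv")
  utils::write.table(
    data.frame(sample_id = rownames(ds$pi_true), ds$pi_true,
               check.names = FALSE),
    paths["true_composition"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
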