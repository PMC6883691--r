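#' Sorted-cell reference sample set
#'
#' CpG-level beta values for purified (sorted) cell populations, used to
#' discover cell-type-specific differentially methylated regions (DMRs) and
#' assemble the binary region-state matrix Z.
#'
#' @param betas J x M numeric matrix of beta values in \[0, 1\] (CpGs x
#'   replicate samples).
#' @param labels length-M cell-type assignment for each replicate; every
#'   cell type needs at least 2 replicates.
#' @param chrom,pos length-J CpG coordinates (`pos` 0-based), sorted by
#'   position within each chromosome.
#'
#' @return An object of class `ReferenceSampleSet`.
#' @export
reference_sample_set <- function(betas, labels, chrom, pos) {
  betas <- as.matrix(betas)
  labels <- as.character(labels)
  .stop_if(ncol(betas) != length(labels), "one label per reference column required")
  .stop_if(length(chrom) != nrow(betas) || length(pos) != nrow(betas),
           "chrom/pos must have one entry per CpG row")
  .stop_if(min(betas) < -1e-9 || max(betas) > 1 + 1e-9,
           "reference betas must lie in [0, 1]")
  tab <- table(labels)
  .stop_if(any(tab < 2), "each cell type needs >= 2 replicates; short: ",
           paste(names(tab)[tab < 2], collapse = ", "))
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    .stop_if(is.unsorted(p, strictly = TRUE),
             "CpG positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(betas = pmin(pmax(betas, 0), 1), labels = labels,
                 chrom = as.character(chrom), pos = pos,
                 cell_types = sort(unique(labels))),
            class = "ReferenceSampleSet")
}

#' @export
print.ReferenceSampleSet <- function(x, ...) {
  cat("ReferenceSampleSet:", nrow(x$betas), "CpGs x", ncol(x$betas),
      "replicates;", length(x$cell_types), "cell types\n")
  invisible(x)
}

#' Region-calling criteria for DMR discovery
#'
#' @param effect_cutoff minimum per-CpG |mean difference| (target vs rest)
#'   for a CpG to enter a candidate region; in (0, 1).
#' @param min_cpgs preferred minimum CpGs per region (soft: single-CpG
#'   candidates are kept when a contrast yields nothing longer, or when
#'   `include_single_cpgs` is set).
#' @param max_gap maximum base-pair gap between consecutive CpGs of one
#'   region (> 0).
#' @param max_regions_per_contrast cap on selected regions per (cell type,
#'   direction) contrast.
#' @param include_single_cpgs keep single-CpG candidates unconditionally.
#'
#' @return An object of class `DMRCriteria`.
#' @export
dmr_criteria <- function(effect_cutoff = 0.3, min_cpgs = 2L, max_gap = 500L,
                         max_regions_per_contrast = 20L,
                         include_single_cpgs = FALSE) {
  .stop_if(effect_cutoff <= 0 || effect_cutoff >= 1,
           "effect_cutoff must be in (0, 1)")
  .stop_if(max_gap <= 0, "max_gap must be > 0")
  structure(list(effect_cutoff = effect_cutoff, min_cpgs = as.integer(min_cpgs),
                 max_gap = as.integer(max_gap),
                 max_regions_per_contrast = as.integer(max_regions_per_contrast),
                 include_single_cpgs = isTRUE(include_single_cpgs)),
            class = "DMRCriteria")
}

#' Per-CpG one-vs-rest differential methylation effects
#'
#' Fits, at every CpG, the two-group linear model contrasting the target
#' cell type against all other cell types pooled. For a two-group design the
#' least-squares slope equals the difference of group means, so the effect
#' is computed directly as `mean(target) - mean(rest)`; a pooled-variance
#' t-like score accompanies it.
#'
#' @param ref a [reference_sample_set()].
#' @param target_cell_type the cell type contrasted against the rest.
#' @return data.frame with one row per CpG: `chrom`, `pos`, `effect`,
#'   `tstat`.
#' @export
fit_per_cpg_contrast <- function(ref, target_cell_type) {
  .stop_if(!target_cell_type %in% ref$labels,
           "cell type not present in reference labels: ", target_cell_type)
  in_t <- ref$labels == target_cell_type
  n1 <- sum(in_t); n2 <- sum(!in_t)
  .stop_if(n1 < 2 || n2 < 2, "both groups need >= 2 replicates")
  m1 <- rowMeans(ref$betas[, in_t, drop = FALSE])
  m2 <- rowMeans(ref$betas[, !in_t, drop = FALSE])
  v1 <- apply(ref$betas[, in_t, drop = FALSE], 1, stats::var)
  v2 <- apply(ref$betas[, !in_t, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  effect <- m1 - m2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, sign(effect) * Inf))
  data.frame(chrom = ref$chrom, pos = ref$pos, effect = effect, tstat = tstat,
             stringsAsFactors = FALSE)
}

#' Call candidate regions from per-CpG effects
#'
#' Finds maximal runs of consecutive CpGs (same chromosome) whose effects
#' all exceed `effect_cutoff` in absolute value with a common sign, with
#' inter-CpG gaps at most `max_gap`. Candidates are ranked by CpG count,
#' then mean |effect|, descending. Single-CpG candidates are kept only if
#' `include_single_cpgs` is set or the contrast yields no multi-CpG
#' candidate (regions with more than one CpG are prioritized whenever
#' possible).
#'
#' @param effects data.frame from [fit_per_cpg_contrast()] (columns `chrom`,
#'   `pos`, `effect`), positions sorted within chromosome.
#' @param criteria a [dmr_criteria()].
#' @return data.frame of candidates: `chrom`, `start`, `end` (0-based
#'   half-open, covering first to last CpG), `n_cpgs`, `mean_abs_effect`,
#'   `direction` (+1 hypermethylated in target, -1 hypomethylated),
#'   `first_idx`, `last_idx` (row indices into `effects`), ordered by rank.
#' @export
call_regions <- function(effects, criteria = dmr_criteria()) {
  ok <- abs(effects$effect) >= criteria$effect_cutoff
  sgn <- sign(effects$effect)
  n <- nrow(effects)
  # break runs at: below-cutoff CpGs, sign changes, chromosome changes, gaps
  new_run <- ok & (seq_len(n) == 1L |
                   !c(FALSE, ok[-n]) |
                   c(TRUE, sgn[-1] != sgn[-n]) |
                   c(TRUE, effects$chrom[-1] != effects$chrom[-n]) |
                   c(TRUE, (effects$pos[-1] - effects$pos[-n]) > criteria$max_gap))
  run_id <- cumsum(new_run)
  run_id[!ok] <- NA_integer_
  idx <- which(ok)
  if (length(idx) == 0) {
    warning("no candidate regions at effect_cutoff = ", criteria$effect_cutoff,
            call. = FALSE)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), mean_abs_effect = numeric(),
                      direction = integer(), first_idx = integer(),
                      last_idx = integer()))
  }
  sp <- split(idx, run_id[idx])
  cand <- do.call(rbind, lapply(sp, function(ii) {
    data.frame(chrom = effects$chrom[ii[1]],
               start = effects$pos[ii[1]],
               end = effects$pos[ii[length(ii)]] + 1L,
               n_cpgs = length(ii),
               mean_abs_effect = mean(abs(effects$effect[ii])),
               direction = as.integer(sgn[ii[1]]),
               first_idx = ii[1], last_idx = ii[length(ii)],
               stringsAsFactors = FALSE)
  }))
  rownames(cand) <- NULL
  if (!criteria$include_single_cpgs && any(cand$n_cpgs > 1)) {
    cand <- cand[cand$n_cpgs > 1, , drop = FALSE]
  }
  cand[order(-cand$n_cpgs, -cand$mean_abs_effect,
             cand$chrom, cand$start), , drop = FALSE]
}

# Consensus runs where all cell-type means are above hi (state 1 everywhere)
# or below lo (state 0 everywhere); used so Z contains all-zero/all-one rows
# for initialization of the latent-state model.
.call_consensus_regions <- function(type_means, chrom, pos, criteria,
                                    lo = 0.2, hi = 0.8) {
  out <- list()
  for (mode in c("low", "high")) {
    flag <- if (mode == "low") apply(type_means < lo, 1, all) else
      apply(type_means > hi, 1, all)
    pseudo <- data.frame(chrom = chrom, pos = pos,
                         effect = ifelse(flag, 1, 0))
    crit <- criteria
    crit$effect_cutoff <- 0.5
    cand <- suppressWarnings(call_regions(pseudo, crit))
    if (nrow(cand)) cand$consensus <- mode
    out[[mode]] <- cand
  }
  do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
}

#' Build the region-state matrix Z from sorted-cell reference data
#'
#' Runs one-vs-rest contrasts for every cell type in both directions
#' (target hypo- and hypermethylated relative to the rest), ranks candidate
#' regions within each contrast, and greedily selects non-overlapping
#' regions round-robin across contrasts up to `max_regions_per_contrast`
#' each. Optionally adds consensus regions that are uniformly methylated or
#' unmethylated across all cell types, which gives Z the all-zero and
#' all-one rows used to initialize the latent-state model. Each selected
#' region's state `Z[r, k]` is 1 when the mean reference beta of cell type k
#' across the region's CpGs exceeds `methylated_threshold`.
#'
#' @param ref a [reference_sample_set()].
#' @param criteria a [dmr_criteria()].
#' @param methylated_threshold dichotomization threshold on the mean
#'   reference beta (default 0.5).
#' @param include_consensus also search for all-methylated/all-unmethylated
#'   consensus regions (default TRUE).
#' @param max_consensus_per_state cap on consensus regions per state.
#'
#' @return A [region_state_matrix()]; attribute `"contrast_counts"` reports
#'   selected region counts per contrast.
#' @export
build_z_matrix <- function(ref, criteria = dmr_criteria(),
                           methylated_threshold = 0.5,
                           include_consensus = TRUE,
                           max_consensus_per_state = 10L) {
  K <- length(ref$cell_types)
  type_means <- vapply(ref$cell_types, function(ct) {
    rowMeans(ref$betas[, ref$labels == ct, drop = FALSE])
  }, numeric(nrow(ref$betas)))

  cand_by_contrast <- list()
  for (ct in ref$cell_types) {
    eff <- fit_per_cpg_contrast(ref, ct)
    cand <- suppressWarnings(call_regions(eff, criteria))
    for (dir in c(-1L, 1L)) {
      key <- paste0(ct, ifelse(dir < 0, "_hypo", "_hyper"))
      cand_by_contrast[[key]] <- cand[cand$direction == dir, , drop = FALSE]
    }
  }
  if (include_consensus) {
    cons <- .call_consensus_regions(type_means, ref$chrom, ref$pos, criteria)
    if (!is.null(cons) && nrow(cons)) {
      for (mode in unique(cons$consensus)) {
        cc <- cons[cons$consensus == mode, , drop = FALSE]
        cc$consensus <- NULL
        cand_by_contrast[[paste0("consensus_", mode)]] <-
          utils::head(cc, max_consensus_per_state)
      }
    }
  }

  # round-robin greedy selection of non-overlapping regions across contrasts
  selected <- list()
  taken <- data.frame(chrom = character(), start = integer(), end = integer())
  counts <- stats::setNames(integer(length(cand_by_contrast)),
                            names(cand_by_contrast))
  cursors <- stats::setNames(rep(1L, length(cand_by_contrast)),
                             names(cand_by_contrast))
  caps <- ifelse(grepl("^consensus_", names(cand_by_contrast)),
                 max_consensus_per_state, criteria$max_regions_per_contrast)
  names(caps) <- names(cand_by_contrast)
  overlaps_any <- function(cand_row) {
    same <- taken$chrom == cand_row$chrom
    any(same & taken$start < cand_row$end & cand_row$start < taken$end)
  }
  repeat {
    progressed <- FALSE
    for (key in names(cand_by_contrast)) {
      if (counts[key] >= caps[key]) next
      cand <- cand_by_contrast[[key]]
      while (cursors[key] <= nrow(cand)) {
        row <- cand[cursors[key], , drop = FALSE]
        cursors[key] <- cursors[key] + 1L
        if (!overlaps_any(row)) {
          selected[[length(selected) + 1L]] <- row
          taken <- rbind(taken, row[, c("chrom", "start", "end")])
          counts[key] <- counts[key] + 1L
          progressed <- TRUE
          break
        }
      }
    }
    if (!progressed) break
  }
  .stop_if(length(selected) == 0,
           "no differential regions found; relax the criteria ",
           "(lower effect_cutoff, raise max_gap, or include_single_cpgs)")
  reg <- do.call(rbind, selected)
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  reg$region_id <- sprintf("%s:%d-%d", reg$chrom, reg$start, reg$end)

  # state assignment from mean reference beta per cell type over region CpGs
  Z <- matrix(0, nrow(reg), K, dimnames = list(reg$region_id, ref$cell_types))
  for (r in seq_len(nrow(reg))) {
    in_reg <- ref$chrom == reg$chrom[r] & ref$pos >= reg$start[r] &
      ref$pos < reg$end[r]
    mb <- colMeans(type_means[in_reg, , drop = FALSE])
    Z[r, ] <- as.numeric(mb > methylated_threshold)
  }
  rsm <- tryCatch(
    region_state_matrix(reg[, c("chrom", "start", "end", "region_id")], Z),
    error = function(e) {
      stop("region-state matrix failed validation: ", conditionMessage(e),
           " Consider relaxing the DMR criteria.", call. = FALSE)
    })
  attr(rsm, "contrast_counts") <- counts
  rsm
}
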