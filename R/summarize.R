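#' Summarize CpG-level measurements over regions
#'
#' Collapses each sample's CpG-level methylation to one value per region,
#' producing the regions x samples matrix the deconvolution model is fitted
#' to. A CpG overlaps a region when `start <= pos < end` (0-based half-open
#' on both sides). Two summaries are available: the unweighted arithmetic
#' mean of per-CpG levels, and the coverage-weighted summary
#' `sum(meth) / sum(meth + unmeth)` for sequencing input. With
#' `weighting = "auto"` each sample uses the summary matching how its
#' platform quantifies methylation: unweighted for arrays, coverage-weighted
#' for sequencing counts.
#'
#' @param cpgs a `CpGMeasurementTable` or a list of them (one per sample).
#' @param regions a [region_state_matrix()] or a region data.frame.
#' @param weighting `"auto"`, `"unweighted"` or `"coverage"`.
#' @param min_sample_coverage minimum fraction of regions that must be
#'   non-missing for each sample (default 0.8); samples below it are an
#'   error so the downstream likelihood stays well conditioned. Set to 0 to
#'   disable.
#' @param warn_sparse_frac warn about regions missing in more than this
#'   fraction of samples (default 0.5).
#' @param drop_sparse_regions drop those sparse regions instead of warning
#'   only.
#'
#' @return A [region_methylation_matrix()]; the attribute `"cpg_counts"`
#'   holds the per-region, per-sample count of contributing CpGs.
#' @export
summarize_regions <- function(cpgs, regions,
                              weighting = c("auto", "unweighted", "coverage"),
                              min_sample_coverage = 0.8,
                              warn_sparse_frac = 0.5,
                              drop_sparse_regions = FALSE) {
  weighting <- match.arg(weighting)
  if (inherits(cpgs, "CpGMeasurementTable")) cpgs <- list(cpgs)
  .stop_if(length(cpgs) == 0, "no samples supplied")
  reg_df <- if (inherits(regions, "RegionStateMatrix")) regions$regions else
    as.data.frame(regions)
  R <- nrow(reg_df)
  reg_gr <- GenomicRanges::GRanges(
    seqnames = reg_df$chrom,
    ranges = IRanges::IRanges(start = reg_df$start + 1L, end = reg_df$end))

  sample_ids <- vapply(cpgs, function(x) x$sample_id, character(1))
  N <- length(cpgs)
  Y <- matrix(NA_real_, R, N)
  counts <- matrix(0L, R, N)

  for (i in seq_len(N)) {
    tb <- cpgs[[i]]
    d <- tb$data
    w <- if (weighting == "auto") {
      if (tb$type == "sequencing") "coverage" else "unweighted"
    } else weighting
    .stop_if(w == "coverage" && tb$type != "sequencing",
             "coverage weighting needs read counts; sample ", tb$sample_id,
             " is array-style")
    cpg_gr <- GenomicRanges::GRanges(
      seqnames = d$chrom, ranges = IRanges::IRanges(d$pos + 1L, d$pos + 1L))
    hits <- GenomicRanges::findOverlaps(cpg_gr, reg_gr)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(si) == 0) {
      stop("sample ", tb$sample_id, " has no CpGs overlapping any region",
           call. = FALSE)
    }
    if (w == "coverage") {
      tot <- d$meth[qi] + d$unmeth[qi]
      keep <- tot > 0
      msum <- tapply(d$meth[qi][keep], si[keep], sum)
      tsum <- tapply(tot[keep], si[keep], sum)
      idx <- as.integer(names(msum))
      Y[idx, i] <- as.numeric(msum) / as.numeric(tsum)
      cnt <- table(si[keep])
    } else {
      keep <- !is.na(d$level[qi])
      lv <- tapply(d$level[qi][keep], si[keep], mean)
      idx <- as.integer(names(lv))
      Y[idx, i] <- as.numeric(lv)
      cnt <- table(si[keep])
    }
    counts[as.integer(names(cnt)), i] <- as.integer(cnt)
    if (all(is.na(Y[, i]))) {
      stop("sample ", tb$sample_id, " covers zero regions", call. = FALSE)
    }
  }

  cover_frac <- colMeans(!is.na(Y))
  if (min_sample_coverage > 0 && any(cover_frac < min_sample_coverage)) {
    bad <- sample_ids[cover_frac < min_sample_coverage]
    stop("sample(s) with < ", round(100 * min_sample_coverage),
         "% non-missing regions: ", paste(bad, collapse = ", "),
         " (lower min_sample_coverage to override)", call. = FALSE)
  }
  sparse <- rowMeans(is.na(Y)) > warn_sparse_frac
  if (any(sparse)) {
    if (drop_sparse_regions) {
      warning(sum(sparse), " region(s) missing in > ",
              round(100 * warn_sparse_frac), "% of samples; dropped",
              call. = FALSE)
      Y <- Y[!sparse, , drop = FALSE]
      counts <- counts[!sparse, , drop = FALSE]
      reg_df <- reg_df[!sparse, , drop = FALSE]
    } else {
      warning(sum(sparse), " region(s) missing in > ",
              round(100 * warn_sparse_frac), "% of samples", call. = FALSE)
    }
  }
  out <- region_methylation_matrix(reg_df, Y, sample_ids)
  attr(out, "cpg_counts") <- counts
  out
}
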