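#' Domain containers for region-level methylation deconvolution
#'
#' The package works with a small set of validated containers:
#' a binary region-state matrix `Z` (regions x cell types), CpG-level
#' measurement tables per sample, region-level methylation matrices
#' `Y` (regions x samples), CpG-level cell-type reference profiles, and
#' composition estimates (samples x cell types, on or near the probability
#' simplex). All genomic coordinates are 0-based, half-open (BED convention).
#'
#' @name methylcomp-classes
NULL

.stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Construct a validated region-state matrix
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `region_id` (0-based half-open coordinates).
#' @param Z numeric matrix, R regions x K cell types, entries in \{0, 1\};
#'   column names give the cell types (or supply `cell_types`).
#' @param cell_types optional character vector of K cell-type names.
#'
#' @details `Z[r, k] = 1` means region r is methylated in cell type k.
#'   Identifiability of the cell proportions requires `Z` to have full
#'   column rank; this is checked on construction and a rank-deficient
#'   matrix is rejected with the dependent columns named. Regions must be
#'   pairwise non-overlapping within a chromosome so that region-level
#'   summaries can be treated as independent observations.
#'
#' @return An object of class `RegionStateMatrix` with elements `regions`,
#'   `cell_types`, `Z`.
#' @export
region_state_matrix <- function(regions, Z, cell_types = colnames(Z)) {
  regions <- as.data.frame(regions)
  .stop_if(!all(c("chrom", "start", "end") %in% names(regions)),
           "regions must have columns chrom, start, end")
  if (is.null(regions$region_id)) {
    regions$region_id <- sprintf("region_%d", seq_len(nrow(regions)))
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  .stop_if(anyNA(regions$start) || anyNA(regions$end),
           "malformed region coordinates (non-integer start/end)")
  .stop_if(any(regions$start >= regions$end),
           "region coordinates must satisfy start < end (0-based half-open)")
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  .stop_if(nrow(Z) != nrow(regions), "Z must have one row per region")
  .stop_if(is.null(cell_types), "cell types must be named (colnames(Z) or cell_types=)")
  .stop_if(length(cell_types) != ncol(Z), "cell_types length must match ncol(Z)")
  .stop_if(!all(Z %in% c(0, 1)), "Z entries must all be 0 or 1")
  .check_no_overlap(regions)
  dimnames(Z) <- list(regions$region_id, cell_types)
  .check_full_rank(Z)
  structure(list(regions = regions, cell_types = as.character(cell_types), Z = Z),
            class = "RegionStateMatrix")
}

.check_no_overlap <- function(regions) {
  sp <- split(regions, regions$chrom)
  for (df in sp) {
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
      stop("regions overlap on chromosome ", df$chrom[1], call. = FALSE)
    }
  }
  invisible(TRUE)
}

.check_full_rank <- function(Z) {
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    dep <- colnames(Z)[qrz$pivot[(qrz$rank + 1L):ncol(Z)]]
    stop("region-state matrix is rank-deficient (rank ", qrz$rank, " < K = ",
         ncol(Z), "); cell proportions are not identifiable. ",
         "Linearly dependent column(s): ", paste(dep, collapse = ", "),
         ". Relax the region-calling criteria or add regions.", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.RegionStateMatrix <- function(x, ...) {
  cat("RegionStateMatrix: R =", nrow(x$Z), "regions x K =", ncol(x$Z),
      "cell types\n  cell types:", paste(x$cell_types, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a CpG-level measurement table for one sample
#'
#' Array-style input carries a beta value per CpG; sequencing-style input
#' carries methylated/unmethylated read counts, from which the methylation
#' level is `meth / (meth + unmeth)` (missing when total coverage is zero).
#'
#' @param sample_id sample identifier.
#' @param chrom,pos CpG coordinates (`pos` 0-based).
#' @param beta per-CpG methylation fractions in \[0, 1\] (array input).
#' @param meth,unmeth non-negative read counts (sequencing input).
#' @param cpg_id optional CpG identifiers; defaults to `chrom:pos`.
#' @param platform free-text platform tag.
#' @param clamp clip betas slightly outside \[0, 1\] back to the boundary
#'   instead of erroring.
#' @param tol tolerance beyond which an out-of-range beta is an error even
#'   with `clamp = FALSE`.
#'
#' @return An object of class `CpGMeasurementTable` with a `data` data.frame
#'   (`cpg_id`, `chrom`, `pos`, `level`, and for sequencing input `meth`,
#'   `unmeth`) plus `sample_id`, `platform` and `type` ("array" or
#'   "sequencing").
#' @export
cpg_measurement_table <- function(sample_id, chrom, pos, beta = NULL,
                                  meth = NULL, unmeth = NULL, cpg_id = NULL,
                                  platform = "unknown", clamp = FALSE,
                                  tol = 1e-9) {
  pos <- as.integer(pos)
  .stop_if(anyNA(pos), "CpG positions must be integers")
  .stop_if(anyDuplicated(paste(chrom, pos)) > 0,
           "duplicate CpG positions in sample ", sample_id)
  if (is.null(cpg_id)) cpg_id <- paste0(chrom, ":", pos)
  if (!is.null(beta)) {
    beta <- as.numeric(beta)
    bad <- !is.na(beta) & (beta < -tol | beta > 1 + tol)
    if (clamp) {
      beta <- pmin(pmax(beta, 0), 1)
    } else {
      .stop_if(any(bad), "beta values outside [0, 1] (max deviation ",
               format(max(abs(pmax(beta - 1, -beta)), na.rm = TRUE)),
               ") in sample ", sample_id, "; use clamp = TRUE to clip")
      beta <- pmin(pmax(beta, 0), 1)  # snap within-tolerance excursions
    }
    data <- data.frame(cpg_id = cpg_id, chrom = as.character(chrom), pos = pos,
                       level = beta, stringsAsFactors = FALSE)
    type <- "array"
  } else {
    .stop_if(is.null(meth) || is.null(unmeth),
             "supply either beta or meth/unmeth counts")
    meth <- as.integer(meth); unmeth <- as.integer(unmeth)
    .stop_if(any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE),
             "read counts must be non-negative")
    total <- meth + unmeth
    level <- ifelse(total > 0, meth / total, NA_real_)
    data <- data.frame(cpg_id = cpg_id, chrom = as.character(chrom), pos = pos,
                       level = level, meth = meth, unmeth = unmeth,
                       stringsAsFactors = FALSE)
    type <- "sequencing"
  }
  structure(list(sample_id = as.character(sample_id),
                 platform = as.character(platform), type = type, data = data),
            class = "CpGMeasurementTable")
}

#' @export
print.CpGMeasurementTable <- function(x, ...) {
  cat("CpGMeasurementTable:", x$sample_id, "(", x$type, ",", x$platform, "),",
      nrow(x$data), "CpGs\n")
  invisible(x)
}

#' Construct a region-level methylation matrix
#'
#' @param regions region data.frame (as in [region_state_matrix()]).
#' @param Y numeric matrix, R regions x N samples; `NA` marks a region with
#'   no usable CpG coverage in that sample. Non-missing entries must be
#'   methylation fractions in \[0, 1\].
#' @param sample_ids character vector of N sample names.
#'
#' @return An object of class `RegionMethylationMatrix`.
#' @export
region_methylation_matrix <- function(regions, Y, sample_ids = colnames(Y)) {
  regions <- as.data.frame(regions)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  .stop_if(nrow(Y) != nrow(regions), "Y must have one row per region")
  .stop_if(is.null(sample_ids), "sample ids required (colnames(Y) or sample_ids=)")
  .stop_if(length(sample_ids) != ncol(Y), "sample_ids length must match ncol(Y)")
  v <- Y[!is.na(Y)]
  .stop_if(length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9),
           "non-missing region methylation levels must lie in [0, 1]")
  if (is.null(regions$region_id)) {
    regions$region_id <- sprintf("region_%d", seq_len(nrow(regions)))
  }
  dimnames(Y) <- list(regions$region_id, sample_ids)
  structure(list(regions = regions, sample_ids = as.character(sample_ids), Y = Y),
            class = "RegionMethylationMatrix")
}

#' @export
print.RegionMethylationMatrix <- function(x, ...) {
  cat("RegionMethylationMatrix: R =", nrow(x$Y), "regions x N =", ncol(x$Y),
      "samples;", sum(is.na(x$Y)), "missing entries\n")
  invisible(x)
}

#' Construct a CpG-level cell-type reference profile
#'
#' @param cpg_ids character vector of J CpG identifiers.
#' @param X numeric J x K matrix of reference methylation fractions in
#'   \[0, 1\]; no missing values allowed.
#' @param cell_types K cell-type names (defaults to `colnames(X)`).
#'
#' @return An object of class `CellTypeReferenceProfile`.
#' @export
cell_type_reference_profile <- function(cpg_ids, X, cell_types = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  .stop_if(length(cpg_ids) != nrow(X), "cpg_ids must match nrow(X)")
  .stop_if(is.null(cell_types), "cell types must be named")
  .stop_if(anyNA(X), "reference profile must not contain missing values")
  .stop_if(min(X) < -1e-9 || max(X) > 1 + 1e-9,
           "reference profile entries must lie in [0, 1]")
  dimnames(X) <- list(cpg_ids, cell_types)
  structure(list(cpg_ids = as.character(cpg_ids),
                 cell_types = as.character(cell_types), X = X),
            class = "CellTypeReferenceProfile")
}

#' Construct a composition estimate
#'
#' @param pi numeric N x K matrix of estimated proportions.
#' @param sample_ids,cell_types row/column labels.
#' @param sum_constrained whether rows were constrained to sum to one (then
#'   each row must sum to 1 within 1e-8).
#'
#' @return An object of class `CompositionEstimate`.
#' @export
composition_estimate <- function(pi, sample_ids = rownames(pi),
                                 cell_types = colnames(pi),
                                 sum_constrained = TRUE) {
  pi <- as.matrix(pi)
  .stop_if(is.null(sample_ids) || is.null(cell_types),
           "sample and cell-type labels required")
  .stop_if(any(pi < -1e-10), "proportion estimates below -1e-10")
  if (sum_constrained) {
    .stop_if(any(abs(rowSums(pi) - 1) > 1e-8),
             "sum-constrained proportions must sum to 1 within 1e-8 per sample")
  }
  dimnames(pi) <- list(sample_ids, cell_types)
  structure(list(sample_ids = as.character(sample_ids),
                 cell_types = as.character(cell_types), pi = pi,
                 sum_constrained = sum_constrained),
            class = "CompositionEstimate")
}

#' @export
print.CompositionEstimate <- function(x, ...) {
  cat("CompositionEstimate: N =", nrow(x$pi), "samples x K =", ncol(x$pi),
      "cell types", if (x$sum_constrained) "(rows sum to 1)" else "", "\n")
  print(utils::head(round(x$pi, 4)))
  invisible(x)
}

#' Construct the model parameter vector
#'
#' Parameters of the region-level latent-state model: `alpha0`/`alpha1` are
#' the mean methylation levels of the unmethylated/methylated states,
#' `sigma0_sq`/`sigma1_sq` the region-to-region variances of the
#' platform-dependent random effects, and `tau_sq` the measurement-error
#' variance. All are unitless (methylation-fraction scale).
#'
#' @param alpha0,alpha1,sigma0_sq,sigma1_sq,tau_sq scalar parameters.
#' @return An object of class `ModelParams`.
#' @export
model_params <- function(alpha0, alpha1, sigma0_sq, sigma1_sq, tau_sq) {
  .stop_if(sigma0_sq < 0 || sigma1_sq < 0, "state variances must be >= 0")
  .stop_if(tau_sq <= 0, "measurement-error variance tau_sq must be > 0")
  if (!(alpha0 >= 0 && alpha0 <= alpha1 && alpha1 <= 1)) {
    warning("expected 0 <= alpha0 <= alpha1 <= 1; got alpha0 = ",
            format(alpha0), ", alpha1 = ", format(alpha1), call. = FALSE)
  }
  structure(list(alpha0 = alpha0, alpha1 = alpha1, sigma0_sq = sigma0_sq,
                 sigma1_sq = sigma1_sq, tau_sq = tau_sq),
            class = "ModelParams")
}

#' @export
print.ModelParams <- function(x, ...) {
  cat(sprintf(
    "ModelParams: alpha0 = %.4f, alpha1 = %.4f, sigma0^2 = %.3g, sigma1^2 = %.3g, tau^2 = %.3g\n",
    x$alpha0, x$alpha1, x$sigma0_sq, x$sigma1_sq, x$tau_sq))
  invisible(x)
}

# Accept either a RegionMethylationMatrix or a plain matrix for Y.
.y_matrix <- function(Y) {
  if (inherits(Y, "RegionMethylationMatrix")) Y$Y else as.matrix(Y)
}

.z_matrix <- function(Z) {
  if (inherits(Z, "RegionStateMatrix")) Z$Z else as.matrix(Z)
}
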