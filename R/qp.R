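#' Solve the simplex-constrained quadratic program for cell proportions
#'
#' Minimizes `0.5 * t(p) %*% Q %*% p + sum(a * p)` subject (optionally) to
#' `sum(p) == 1` and `p >= 0`. This is the constrained least-squares problem
#' `argmin ||y - X p||^2` written with `Q = t(X) %*% X` and
#' `a = -t(X) %*% y`. The backend is the dual active-set method of
#' `quadprog::solve.QP()`; if `Q` is numerically singular a symmetric ridge
#' of `1e-10 * trace(Q) / K` is added (escalated up to 1e-6 relative) until
#' the solver accepts it.
#'
#' @param Q K x K symmetric positive-semidefinite matrix (symmetry checked
#'   to 1e-10 relative tolerance).
#' @param a K-vector (linear term).
#' @param equality_sum_constraint impose `sum(p) == 1`.
#' @param lower_bound_zero impose `p >= 0`.
#' @return The minimizing K-vector.
#' @export
solve_simplex_qp <- function(Q, a, equality_sum_constraint = TRUE,
                             lower_bound_zero = TRUE) {
  Q <- as.matrix(Q)
  K <- ncol(Q)
  .stop_if(length(a) != K, "a must have length ncol(Q)")
  scale <- max(abs(Q), 1)
  .stop_if(max(abs(Q - t(Q))) > 1e-10 * scale, "Q must be symmetric")
  Q <- (Q + t(Q)) / 2

  if (!equality_sum_constraint && !lower_bound_zero) {
    return(as.numeric(solve(Q, -a)))
  }
  Amat <- NULL
  bvec <- NULL
  meq <- 0L
  if (equality_sum_constraint) {
    Amat <- cbind(Amat, rep(1, K))
    bvec <- c(bvec, 1)
    meq <- 1L
  }
  if (lower_bound_zero) {
    Amat <- cbind(Amat, diag(K))
    bvec <- c(bvec, rep(0, K))
  }
  ridge_rel <- c(0, 1e-10, 1e-8, 1e-6)
  trK <- sum(diag(Q)) / K
  if (trK <= 0) trK <- 1
  last_err <- NULL
  for (rr in ridge_rel) {
    Qr <- Q + diag(rr * trK, K)
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = Qr, dvec = -a, Amat = Amat, bvec = bvec,
                         meq = meq)$solution,
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(sol)) return(as.numeric(sol))
  }
  stop("quadratic program could not be solved: ", conditionMessage(last_err),
       call. = FALSE)
}

#' Estimate cell proportions given a region-level design matrix
#'
#' Per-sample constrained least squares of the observed region methylation
#' on the design `X` (regions x cell types): for sample i the QP uses
#' `Q = t(X) %*% X` and `a = -t(X) %*% Y[, i]` restricted to that sample's
#' non-missing regions.
#'
#' @param Y a [region_methylation_matrix()] or plain R x N matrix (NA =
#'   missing).
#' @param X R x K design matrix; must have full column rank on each sample's
#'   non-missing rows.
#' @param sum_to_one constrain each sample's proportions to sum to 1.
#' @param nonneg constrain proportions to be non-negative (default TRUE).
#' @param cell_types optional cell-type names (defaults to `colnames(X)`).
#' @return A [composition_estimate()] (N x K).
#' @export
estimate_pi_given_X <- function(Y, X, sum_to_one = TRUE, nonneg = TRUE,
                                cell_types = colnames(X)) {
  Ym <- .y_matrix(Y)
  X <- as.matrix(X)
  K <- ncol(X)
  .stop_if(nrow(X) != nrow(Ym), "X and Y must have the same regions")
  if (is.null(cell_types)) cell_types <- sprintf("celltype_%d", seq_len(K))
  sample_ids <- colnames(Ym)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(ncol(Ym)))
  N <- ncol(Ym)
  pi_hat <- matrix(NA_real_, N, K)
  for (i in seq_len(N)) {
    obs <- which(!is.na(Ym[, i]))
    if (length(obs) < K) {
      stop("sample ", sample_ids[i], " has ", length(obs),
           " non-missing regions (< K = ", K, ")", call. = FALSE)
    }
    Xo <- X[obs, , drop = FALSE]
    if (qr(Xo)$rank < K) {
      stop("design matrix is rank-deficient on the non-missing regions of ",
           "sample ", sample_ids[i], call. = FALSE)
    }
    pi_hat[i, ] <- solve_simplex_qp(crossprod(Xo), -crossprod(Xo, Ym[obs, i]),
                                    equality_sum_constraint = sum_to_one,
                                    lower_bound_zero = nonneg)
  }
  composition_estimate(pi_hat, sample_ids, cell_types,
                       sum_constrained = sum_to_one)
}

#' Reference-based composition estimate (constrained least squares on CpGs)
#'
#' The classical reference-based estimator: each heterogeneous sample's
#' CpG-level methylation is regressed on measured cell-type-specific
#' reference profiles over the CpGs shared between sample and reference,
#' with non-negativity constraints. By default the proportions are NOT
#' rescaled to sum to one, leaving room for unaccounted cell types; set
#' `sum_to_one = TRUE` for the fully simplex-constrained fit.
#'
#' @param samples a `CpGMeasurementTable` or list of them.
#' @param reference a [cell_type_reference_profile()].
#' @param sum_to_one impose the sum-to-one constraint (default FALSE).
#' @return A [composition_estimate()]; attribute `"n_cpgs_used"` reports the
#'   per-sample size of the CpG intersection.
#' @export
houseman_estimate <- function(samples, reference, sum_to_one = FALSE) {
  if (inherits(samples, "CpGMeasurementTable")) samples <- list(samples)
  K <- length(reference$cell_types)
  N <- length(samples)
  pi_hat <- matrix(NA_real_, N, K)
  n_used <- integer(N)
  sample_ids <- vapply(samples, function(x) x$sample_id, character(1))
  for (i in seq_len(N)) {
    d <- samples[[i]]$data
    d <- d[!is.na(d$level), , drop = FALSE]
    m <- match(reference$cpg_ids, d$cpg_id)
    keep <- which(!is.na(m))
    n_used[i] <- length(keep)
    if (length(keep) < K) {
      stop("sample ", sample_ids[i], " shares only ", length(keep),
           " CpGs with the reference profile (need >= K = ", K, ")",
           call. = FALSE)
    }
    Xo <- reference$X[keep, , drop = FALSE]
    yo <- d$level[m[keep]]
    pi_hat[i, ] <- solve_simplex_qp(crossprod(Xo), -crossprod(Xo, yo),
                                    equality_sum_constraint = sum_to_one,
                                    lower_bound_zero = TRUE)
  }
  out <- composition_estimate(pi_hat, sample_ids, reference$cell_types,
                              sum_constrained = sum_to_one)
  attr(out, "n_cpgs_used") <- stats::setNames(n_used, sample_ids)
  out
}
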