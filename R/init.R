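#' Initialize model parameters and proportions (EM step t = 0)
#'
#' Moment-based starting values for the latent-state model. Rows of Z that
#' are unmethylated in every cell type (all-zero rows, the R0 set) have
#' expectation `alpha0` regardless of the mixing proportions, so `alpha0`
#' starts at the grand mean of Y over those rows (per-sample means averaged
#' over samples) and `sigma0_sq` at the average per-sample variance across
#' those rows (denominator `R0 - 1`); this variance is a Jensen upper bound
#' that also absorbs the measurement error, which is assumed small at this
#' stage. The all-one rows (R1 set) give `alpha1` and `sigma1_sq`
#' symmetrically. Proportions start from the simplex-constrained fit to the
#' binarized design `X0 = (1 - Z) * alpha0 + Z * alpha1`, and `tau_sq` from
#' the mean squared residual of that fit.
#'
#' If Z has fewer than 2 all-zero (all-one) rows, the rows with the smallest
#' (largest) row sums stand in as pseudo-R0 (pseudo-R1) sets, with a
#' warning.
#'
#' @param Y a [region_methylation_matrix()] or R x N matrix.
#' @param Z a [region_state_matrix()] or R x K binary matrix.
#' @param min_extreme_rows minimum number of rows per extreme set (default 2).
#' @return list with elements `theta` ([model_params()]) and `pi`
#'   ([composition_estimate()]).
#' @export
init_params <- function(Y, Z, min_extreme_rows = 2L) {
  Ym <- .y_matrix(Y)
  Zm <- .z_matrix(Z)
  .stop_if(nrow(Ym) != nrow(Zm), "Y and Z must have the same regions")
  K <- ncol(Zm)
  rs <- rowSums(Zm)
  r0 <- which(rs == 0)
  r1 <- which(rs == K)
  if (length(r0) < min_extreme_rows) {
    ord <- order(rs)
    r0 <- ord[seq_len(min(min_extreme_rows, nrow(Zm)))]
    warning("Z has fewer than ", min_extreme_rows, " all-zero rows; using the ",
            length(r0), " rows with smallest state sums as a pseudo-R0 set",
            call. = FALSE)
  }
  if (length(r1) < min_extreme_rows) {
    ord <- order(rs, decreasing = TRUE)
    r1 <- ord[seq_len(min(min_extreme_rows, nrow(Zm)))]
    warning("Z has fewer than ", min_extreme_rows, " all-one rows; using the ",
            length(r1), " rows with largest state sums as a pseudo-R1 set",
            call. = FALSE)
  }
  mom <- function(rows) {
    sub <- Ym[rows, , drop = FALSE]
    means <- colMeans(sub, na.rm = TRUE)
    vars <- apply(sub, 2, function(y) {
      y <- y[!is.na(y)]
      if (length(y) >= 2) stats::var(y) else NA_real_
    })
    list(alpha = mean(means, na.rm = TRUE), sigma_sq = mean(vars, na.rm = TRUE))
  }
  m0 <- mom(r0)
  m1 <- mom(r1)
  .stop_if(!is.finite(m0$alpha) || !is.finite(m1$alpha),
           "could not initialize: extreme-state rows are entirely missing")
  s0 <- if (is.finite(m0$sigma_sq)) m0$sigma_sq else 0
  s1 <- if (is.finite(m1$sigma_sq)) m1$sigma_sq else 0

  X0 <- (1 - Zm) * m0$alpha + Zm * m1$alpha
  pi0 <- estimate_pi_given_X(Ym, X0, sum_to_one = TRUE,
                             cell_types = colnames(Zm))
  fitted <- X0 %*% t(pi0$pi)
  res2 <- (Ym - fitted)^2
  tau_sq <- mean(res2[!is.na(res2)])
  theta <- suppressWarnings(model_params(m0$alpha, m1$alpha, s0, s1,
                                         max(tau_sq, 1e-12)))
  list(theta = theta, pi = pi0)
}
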