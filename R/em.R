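#' Region weights of the unmethylated/methylated states
#'
#' For sample i and region r, `W0[r, i] = sum_k pi[i, k] * (1 - Z[r, k])` is
#' the mixture weight on the unmethylated state and
#' `W1[r, i] = sum_k pi[i, k] * Z[r, k]` on the methylated state. When the
#' proportions lie on the simplex, `W0 + W1 == 1` elementwise.
#'
#' @param pi a [composition_estimate()] or N x K matrix.
#' @param Z a [region_state_matrix()] or R x K binary matrix.
#' @return list with R x N matrices `W0` and `W1`.
#' @export
region_weights <- function(pi, Z) {
  pim <- if (inherits(pi, "CompositionEstimate")) pi$pi else as.matrix(pi)
  Zm <- .z_matrix(Z)
  .stop_if(ncol(pim) != ncol(Zm), "pi and Z must agree on K")
  list(W0 = (1 - Zm) %*% t(pim), W1 = Zm %*% t(pim))
}

# Internal: per-region Woodbury pieces shared by e_step and observed_loglik.
# For region r the observed samples have covariance
#   C_r = tau^2 I + sigma0^2 w0 w0' + sigma1^2 w1 w1'
# (w0, w1 the rows of W0, W1 restricted to observed samples). With
# U = [w0, w1], D = diag(sigma0^2, sigma1^2), the Woodbury identity gives
#   u' C^{-1} v = (u'v - (u'U) M^{-1} (U'v) / tau^2) / tau^2,
#   M = D^{-1} + U'U / tau^2,
# so only the 2x2 statistics s0 = w0'w0, s01 = w0'w1, s1 = w1'w1 and the
# projections b0 = w0'e, b1 = w1'e are needed; everything vectorizes over
# regions. Zero state variances are floored at 1e-12 to keep D invertible
# (the correction terms then vanish to the same order).
.region_blocks <- function(Ym, Zm, theta, pim) {
  mu_x <- (1 - Zm) * theta$alpha0 + Zm * theta$alpha1  # R x K
  W <- region_weights(pim, Zm)
  E <- Ym - mu_x %*% t(pim)
  obs <- !is.na(Ym)
  E[!obs] <- 0
  W0o <- W$W0 * obs
  W1o <- W$W1 * obs
  s0 <- rowSums(W0o * W0o)
  s1 <- rowSums(W1o * W1o)
  s01 <- rowSums(W0o * W1o)
  b0 <- rowSums(W0o * E)
  b1 <- rowSums(W1o * E)
  t2 <- theta$tau_sq
  v0 <- max(theta$sigma0_sq, 1e-12)
  v1 <- max(theta$sigma1_sq, 1e-12)
  M11 <- 1 / v0 + s0 / t2
  M22 <- 1 / v1 + s1 / t2
  M12 <- s01 / t2
  detM <- M11 * M22 - M12^2
  # u'C^{-1}v given a = u'U (2 cols) and c = U'v (2 cols), uv = u'v
  ucv <- function(a1, a2, c1, c2, uv) {
    (uv - (a1 * (M22 * c1 - M12 * c2) + a2 * (M11 * c2 - M12 * c1)) /
       (detM * t2)) / t2
  }
  list(E = E, obs = obs, s0 = s0, s01 = s01, s1 = s1, b0 = b0, b1 = b1,
       t2 = t2, v0 = v0, v1 = v1, M11 = M11, M22 = M22, M12 = M12,
       detM = detM, ucv = ucv, n_obs = rowSums(obs))
}

#' E-step: conditional moments of the state random effects given Y
#'
#' Computes, for every region r, the posterior mean and variance of the
#' unmethylated-state effect `delta0[r]` and methylated-state effect
#' `delta1[r]` given ALL observed samples. Because region effects and noise
#' are independent across regions, the joint normal conditioning reduces to
#' independent per-region blocks; each block is handled through the rank-2
#' Woodbury identity rather than materializing the full (RN + R)-dimensional
#' joint covariance. Regions with no observed samples fall back to the prior
#' moments.
#'
#' @param Y a [region_methylation_matrix()] or R x N matrix (NA = missing).
#' @param Z a [region_state_matrix()] or R x K binary matrix.
#' @param theta a [model_params()].
#' @param pi a [composition_estimate()] or N x K matrix with rows on the
#'   simplex.
#' @return list with elements `moments` (fields `mean_delta0`, `mean_delta1`,
#'   `var_delta0`, `var_delta1`, each length R) and `stats` (sufficient
#'   statistics `T1`..`T5`: sums over regions of posterior first/second
#'   moments of `delta0`/`delta1`, and the posterior-mean residual sum of
#'   squares).
#' @export
e_step <- function(Y, Z, theta, pi) {
  Ym <- .y_matrix(Y)
  Zm <- .z_matrix(Z)
  pim <- if (inherits(pi, "CompositionEstimate")) pi$pi else as.matrix(pi)
  .stop_if(theta$tau_sq <= 0, "tau_sq must be > 0 in the E-step")
  bl <- .region_blocks(Ym, Zm, theta, pim)

  g0e <- bl$ucv(bl$s0, bl$s01, bl$b0, bl$b1, bl$b0)   # w0' C^-1 e
  g1e <- bl$ucv(bl$s01, bl$s1, bl$b0, bl$b1, bl$b1)   # w1' C^-1 e
  g00 <- bl$ucv(bl$s0, bl$s01, bl$s0, bl$s01, bl$s0)  # w0' C^-1 w0
  g11 <- bl$ucv(bl$s01, bl$s1, bl$s01, bl$s1, bl$s1)  # w1' C^-1 w1

  m0 <- theta$alpha0 + bl$v0 * g0e
  m1 <- theta$alpha1 + bl$v1 * g1e
  vd0 <- bl$v0 - bl$v0^2 * g00
  vd1 <- bl$v1 - bl$v1^2 * g11
  if (any(!is.finite(c(m0, m1, vd0, vd1)))) {
    bad <- which(!is.finite(m0 + m1 + vd0 + vd1))[1]
    stop("non-finite posterior moments at region index ", bad, call. = FALSE)
  }
  vd0 <- pmin(pmax(vd0, 0), bl$v0)
  vd1 <- pmin(pmax(vd1, 0), bl$v1)
  moments <- list(mean_delta0 = m0, mean_delta1 = m1,
                  var_delta0 = vd0, var_delta1 = vd1)

  # posterior-mean residuals for T5
  Xpost <- (1 - Zm) * m0 + Zm * m1
  U <- Ym - Xpost %*% t(pim)
  stats <- list(T1 = sum(m0), T2 = sum(m1),
                T3 = sum(m0^2 + vd0), T4 = sum(m1^2 + vd1),
                T5 = sum(U[bl$obs]^2))
  list(moments = moments, stats = stats)
}

#' M-step: closed-form parameter updates and QP update of the proportions
#'
#' Updates the state means and variances from the E-step sufficient
#' statistics (`alpha0 = T1 / R`, `sigma0_sq = T3 / R - alpha0^2`, and
#' symmetrically for the methylated state), rebuilds the working design from
#' the posterior means, `X[r, k] = (1 - Z[r, k]) * mean_delta0[r] +
#' Z[r, k] * mean_delta1[r]`, re-solves the simplex-constrained QP for the
#' proportions, and sets `tau_sq` to the mean squared residual over observed
#' entries. Variances are floored at 1e-12 (with a warning for `tau_sq`) to
#' keep the per-region covariance blocks positive definite.
#'
#' @param stats,moments output of [e_step()].
#' @param Y,Z data and region states as in [e_step()].
#' @return list with `theta` ([model_params()]), `pi`
#'   ([composition_estimate()]), and the working design `X`.
#' @export
m_step <- function(stats, moments, Y, Z) {
  Ym <- .y_matrix(Y)
  Zm <- .z_matrix(Z)
  R <- nrow(Zm)
  alpha0 <- stats$T1 / R
  alpha1 <- stats$T2 / R
  sigma0_sq <- max(stats$T3 / R - alpha0^2, 1e-12)
  sigma1_sq <- max(stats$T4 / R - alpha1^2, 1e-12)
  X <- (1 - Zm) * moments$mean_delta0 + Zm * moments$mean_delta1
  pi_new <- estimate_pi_given_X(Ym, X, sum_to_one = TRUE,
                                cell_types = colnames(Zm))
  res2 <- (Ym - X %*% t(pi_new$pi))^2
  tau_sq <- mean(res2[!is.na(res2)])
  if (tau_sq < 1e-12) {
    warning("residual variance hit zero; floored at 1e-12", call. = FALSE)
    tau_sq <- 1e-12
  }
  theta <- suppressWarnings(model_params(alpha0, alpha1, sigma0_sq, sigma1_sq,
                                         tau_sq))
  list(theta = theta, pi = pi_new, X = X)
}

#' Observed-data log-likelihood of the latent-state model
#'
#' The marginal density of Y factorizes over regions (region effects and
#' noise are independent across regions); each region contributes a
#' multivariate normal over its observed samples with mean `(X pi')[r, ]`
#' and covariance `tau^2 I + sigma0^2 w0 w0' + sigma1^2 w1 w1'`. Computed
#' with Woodbury determinant/inverse identities; all-missing regions
#' contribute zero.
#'
#' @inheritParams e_step
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(Y, Z, theta, pi) {
  Ym <- .y_matrix(Y)
  Zm <- .z_matrix(Z)
  pim <- if (inherits(pi, "CompositionEstimate")) pi$pi else as.matrix(pi)
  .stop_if(theta$tau_sq <= 0, "tau_sq must be > 0")
  bl <- .region_blocks(Ym, Zm, theta, pim)
  t2 <- bl$t2
  # log det C = n_obs log tau^2 + log det(I2 + D U'U / tau^2)
  det2 <- (1 + bl$v0 * bl$s0 / t2) * (1 + bl$v1 * bl$s1 / t2) -
    bl$v0 * bl$v1 * bl$s01^2 / t2^2
  logdet <- bl$n_obs * log(t2) + log(det2)
  ee <- rowSums(bl$E^2)
  quad <- bl$ucv(bl$b0, bl$b1, bl$b0, bl$b1, ee)  # e' C^-1 e
  ll <- -0.5 * (bl$n_obs * log(2 * base::pi) + logdet + quad)
  sum(ll[bl$n_obs > 0])
}

#' Fit the latent-state cell-composition model by EM
#'
#' Alternates the conditional-moment E-step ([e_step()]) and the closed-form
#' plus QP M-step ([m_step()]) from the moment-based initialization
#' ([init_params()]) until the maximum relative change across the five model
#' parameters and the maximum absolute change across all proportions both
#' fall below `tol`, or `max_iter` is reached. The proportion update plugs
#' posterior means of the state effects into the least-squares criterion, so
#' a strict likelihood ascent is not guaranteed; decreases of the observed
#' log-likelihood beyond 1e-6 are reported as warnings, not errors. The fit
#' contains no randomness: repeated calls on the same input are identical.
#'
#' @param Y a [region_methylation_matrix()] or R x N matrix (NA = missing).
#' @param Z a [region_state_matrix()] or R x K binary matrix with full
#'   column rank; R must exceed K.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence tolerance (default 1e-4).
#' @param init_override optional list(theta, pi) replacing [init_params()].
#' @param verbose print per-iteration parameters and log-likelihood.
#' @return An object of class `FitResult`: `pi` ([composition_estimate()]),
#'   `theta` ([model_params()]), `loglik_trace`, `n_iter`, `converged`.
#' @export
fit_methylcc <- function(Y, Z, max_iter = 100L, tol = 1e-4,
                         init_override = NULL, verbose = FALSE) {
  Ym <- .y_matrix(Y)
  Zm <- .z_matrix(Z)
  K <- ncol(Zm)
  .stop_if(nrow(Zm) <= K, "need more regions than cell types (R > K)")
  .check_full_rank(Zm)
  init <- if (is.null(init_override)) init_params(Ym, Zm) else init_override
  theta <- init$theta
  pi_cur <- init$pi
  loglik_trace <- observed_loglik(Ym, Zm, theta, pi_cur)
  converged <- FALSE
  iter <- 0L
  theta_vec <- function(th) c(th$alpha0, th$alpha1, th$sigma0_sq,
                              th$sigma1_sq, th$tau_sq)
  while (iter < max_iter) {
    iter <- iter + 1L
    es <- e_step(Ym, Zm, theta, pi_cur)
    ms <- m_step(es$stats, es$moments, Ym, Zm)
    ll <- observed_loglik(Ym, Zm, ms$theta, ms$pi)
    loglik_trace <- c(loglik_trace, ll)
    d_theta <- max(abs(theta_vec(ms$theta) - theta_vec(theta)) /
                     pmax(abs(theta_vec(theta)), 1e-8))
    d_pi <- max(abs(ms$pi$pi - pi_cur$pi))
    theta <- ms$theta
    pi_cur <- ms$pi
    if (verbose) {
      message(sprintf(
        "iter %3d  ll %.4f  a0 %.4f a1 %.4f s0 %.2e s1 %.2e t2 %.2e",
        iter, ll, theta$alpha0, theta$alpha1, theta$sigma0_sq,
        theta$sigma1_sq, theta$tau_sq))
    }
    if (max(d_theta, d_pi) < tol) {
      converged <- TRUE
      break
    }
  }
  drops <- diff(loglik_trace) < -1e-6
  if (any(drops)) {
    warning(sprintf(
      "observed log-likelihood decreased at %d of %d iterations (max %.3g); the proportion update plugs in posterior means and is not a strict EM ascent step",
      sum(drops), iter, max(-diff(loglik_trace))), call. = FALSE)
  }
  structure(list(pi = pi_cur, theta = theta, loglik_trace = loglik_trace,
                 n_iter = iter, converged = converged),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult:", x$n_iter, "EM iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(final loglik %.3f)\n", utils::tail(x$loglik_trace, 1)))
  print(x$theta)
  print(x$pi)
  invisible(x)
}

#' Serialize a fit: proportions as TSV, parameters and trace as JSON
#'
#' @param fit a `FitResult`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the files written (invisibly).
#' @export
write_fit_result <- function(fit, dir, prefix = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pi_path <- file.path(dir, paste0(prefix, "_composition.tsv"))
  meta_path <- file.path(dir, paste0(prefix, "_model.json"))
  write_composition(fit$pi, pi_path)
  jsonlite::write_json(
    list(theta = fit$theta[c("alpha0", "alpha1", "sigma0_sq", "sigma1_sq",
                             "tau_sq")],
         loglik_trace = fit$loglik_trace, n_iter = fit$n_iter,
         converged = fit$converged),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(pi_path, meta_path))
}
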