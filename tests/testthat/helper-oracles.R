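# Independent oracles used across the test suite. These deliberately take
# the slow, literal route (dense joint-normal conditioning, exhaustive grid
# search) so they share no code with the package's structured
# implementations.

# Dense joint-normal E-step oracle: builds the full (RN + R) x (RN + R)
# covariance of (Y, delta_l) entry by entry from the model definition and
# applies the textbook conditional-normal formula. Only usable for tiny
# problems. Y, Z, pi plain matrices; theta a list.
dense_estep_oracle <- function(Y, Z, theta, pi) {
  R <- nrow(Z)
  N <- ncol(Y)
  W0 <- (1 - Z) %*% t(pi)
  W1 <- Z %*% t(pi)
  X <- (1 - Z) * theta$alpha0 + Z * theta$alpha1
  mu_y <- as.vector(X %*% t(pi))          # column-major: (r, i) -> (i-1)*R + r
  idx <- function(r, i) (i - 1L) * R + r
  RN <- R * N
  S11 <- matrix(0, RN, RN)
  for (r in seq_len(R)) {
    for (i in seq_len(N)) {
      for (ip in seq_len(N)) {
        S11[idx(r, i), idx(r, ip)] <-
          W0[r, i] * W0[r, ip] * theta$sigma0_sq +
          W1[r, i] * W1[r, ip] * theta$sigma1_sq +
          (i == ip) * theta$tau_sq
      }
    }
  }
  cond <- function(W, s2, alpha) {
    S12 <- matrix(0, RN, R)
    for (r in seq_len(R)) {
      for (i in seq_len(N)) S12[idx(r, i), r] <- W[r, i] * s2
    }
    S22 <- diag(s2, R)
    Si <- solve(S11)
    m <- alpha + t(S12) %*% Si %*% (as.vector(Y) - mu_y)
    V <- S22 - t(S12) %*% Si %*% S12
    list(mean = as.numeric(m), var = diag(V))
  }
  c0 <- cond(W0, theta$sigma0_sq, theta$alpha0)
  c1 <- cond(W1, theta$sigma1_sq, theta$alpha1)
  list(mean_delta0 = c0$mean, var_delta0 = c0$var,
       mean_delta1 = c1$mean, var_delta1 = c1$var,
       S11 = S11, mu_y = mu_y)
}

# Dense observed-data log-likelihood oracle via mvtnorm on the stacked Y.
dense_loglik_oracle <- function(Y, Z, theta, pi) {
  or <- dense_estep_oracle(Y, Z, theta, pi)
  mvtnorm::dmvnorm(as.vector(Y), mean = or$mu_y, sigma = or$S11, log = TRUE)
}

# Exhaustive grid search over the probability simplex (K = 2 or 3) for
# min 0.5 p'Qp + a'p. Returns the best grid point.
grid_simplex_qp <- function(Q, a, step = 0.001) {
  K <- ncol(Q)
  stopifnot(K %in% c(2L, 3L))
  if (K == 2L) {
    s <- seq(0, 1, by = step)
    P <- cbind(s, 1 - s)
  } else {
    if (is.null(.grid_cache$P) || .grid_cache$step != step) {
      s <- seq(0, 1, by = step)
      g <- expand.grid(p1 = s, p2 = s)
      g <- g[g$p1 + g$p2 <= 1 + 1e-12, , drop = FALSE]
      .grid_cache$P <- cbind(g$p1, g$p2, 1 - g$p1 - g$p2)
      .grid_cache$step <- step
    }
    P <- .grid_cache$P
  }
  obj <- 0.5 * rowSums((P %*% Q) * P) + as.numeric(P %*% a)
  as.numeric(P[which.min(obj), ])
}
.grid_cache <- new.env()

# Random strictly convex QP instance (bounded-below eigenvalues so the grid
# argmin is within O(step) of the true minimizer).
random_qp_instance <- function(K = 3L, ridge = 0.05) {
  A <- matrix(stats::rnorm(K * K), K)
  list(Q = crossprod(A) + diag(ridge, K), a = stats::rnorm(K))
}

# Small random model instance for E-step / likelihood oracle suites.
random_model_instance <- function(R = 4L, N = 3L, K = 2L) {
  Z <- matrix(stats::rbinom(R * K, 1, 0.5), R, K)
  while (qr(Z)$rank < K) Z <- matrix(stats::rbinom(R * K, 1, 0.5), R, K)
  pi <- t(apply(matrix(stats::rgamma(N * K, 2), N, K), 1,
                function(x) x / sum(x)))
  if (K == 1) pi <- matrix(1, N, 1)
  theta <- list(alpha0 = stats::runif(1, 0.05, 0.3),
                alpha1 = stats::runif(1, 0.7, 0.95),
                sigma0_sq = stats::runif(1, 1e-4, 0.01),
                sigma1_sq = stats::runif(1, 1e-4, 0.01),
                tau_sq = stats::runif(1, 1e-4, 0.01))
  X <- (1 - Z) * theta$alpha0 + Z * theta$alpha1
  Y <- X %*% t(pi) + matrix(stats::rnorm(R * N, 0, sqrt(theta$tau_sq)), R, N)
  list(Y = Y, Z = Z, theta = theta, pi = pi)
}

theta_as_params <- function(theta) {
  suppressWarnings(model_params(theta$alpha0, theta$alpha1, theta$sigma0_sq,
                                theta$sigma1_sq, theta$tau_sq))
}
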