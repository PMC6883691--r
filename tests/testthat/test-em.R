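toy_Z <- function() {
  Z <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  colnames(Z) <- c("A", "B")
  Z
}

test_that("region weights implement the state mixture weights and sum to one", {
  Z <- matrix(c(1, 0), 1, 2)
  w <- region_weights(matrix(c(1, 0), 1, 2), Z)
  expect_equal(w$W0[1, 1], 0)
  expect_equal(w$W1[1, 1], 1)
  w2 <- region_weights(matrix(c(0.5, 0.5), 1, 2), Z)
  expect_equal(w2$W0[1, 1], 0.5)
  expect_equal(w2$W1[1, 1], 0.5)

  set.seed(11)
  for (i in 1:5) {
    inst <- random_model_instance(R = 6, N = 4, K = 3)
    w <- region_weights(inst$pi, inst$Z)
    expect_equal(w$W0 + w$W1, matrix(1, 6, 4), tolerance = 1e-12)
  }
})

test_that("E-step degenerates to the prior when state variances vanish", {
  Z <- toy_Z()
  theta <- model_params(0.2, 0.8, 0, 0, 0.01)
  pi <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE)
  Y <- matrix(runif(8), 4, 2)
  es <- e_step(Y, Z, theta, pi)
  expect_equal(es$moments$mean_delta0, rep(0.2, 4), tolerance = 1e-9)
  expect_equal(es$moments$var_delta0, rep(0, 4), tolerance = 1e-9)
  expect_equal(es$stats$T1, 4 * 0.2, tolerance = 1e-8)
  expect_equal(es$stats$T3, 4 * 0.04, tolerance = 1e-8)
})

test_that("structured E-step equals dense joint-normal conditioning", {
  set.seed(12)
  inst <- random_model_instance(R = 4, N = 3, K = 2)
  es <- e_step(inst$Y, inst$Z, theta_as_params(inst$theta), inst$pi)
  or <- dense_estep_oracle(inst$Y, inst$Z, inst$theta, inst$pi)
  expect_equal(es$moments$mean_delta0, or$mean_delta0, tolerance = 1e-8)
  expect_equal(es$moments$var_delta0, or$var_delta0, tolerance = 1e-8)
  expect_equal(es$moments$mean_delta1, or$mean_delta1, tolerance = 1e-8)
  expect_equal(es$moments$var_delta1, or$var_delta1, tolerance = 1e-8)
  # sufficient statistics match the same moments
  expect_equal(es$stats$T1, sum(or$mean_delta0), tolerance = 1e-8)
  expect_equal(es$stats$T3, sum(or$mean_delta0^2 + or$var_delta0),
               tolerance = 1e-8)
})

test_that("an uninformative likelihood returns the prior moments", {
  Z <- toy_Z()
  theta <- model_params(0.2, 0.8, 0.01, 0.01, 1e8)
  pi <- matrix(c(0.5, 0.5), 1, 2)
  es <- e_step(matrix(runif(4), 4, 1), Z, theta, pi)
  expect_equal(es$moments$mean_delta0, rep(0.2, 4), tolerance = 1e-4)
  expect_equal(es$moments$var_delta0, rep(0.01, 4), tolerance = 1e-4)
})

test_that("posterior variances never exceed prior variances", {
  set.seed(13)
  for (i in 1:10) {
    inst <- random_model_instance(R = 6, N = 4, K = 3)
    es <- e_step(inst$Y, inst$Z, theta_as_params(inst$theta), inst$pi)
    expect_true(all(es$moments$var_delta0 <= inst$theta$sigma0_sq + 1e-12))
    expect_true(all(es$moments$var_delta1 <= inst$theta$sigma1_sq + 1e-12))
    expect_true(all(es$moments$var_delta0 >= -1e-12))
    expect_true(all(es$moments$var_delta1 >= -1e-12))
  }
})

test_that("M-step applies the closed-form MLE updates and the QP proportion update", {
  R <- 10
  stats <- list(T1 = 0.3 * R, T2 = 0.8 * R, T3 = 0.09 * R, T4 = 0.65 * R)
  Z <- rbind(toy_Z(), toy_Z(), c(1, 0), c(0, 1))
  colnames(Z) <- c("A", "B")
  moments <- list(mean_delta0 = rep(0.3, R), mean_delta1 = rep(0.8, R),
                  var_delta0 = rep(0, R), var_delta1 = rep(0, R))
  pi_true <- c(0.6, 0.4)
  X <- (1 - Z) * 0.3 + Z * 0.8
  Y <- X %*% pi_true
  ms <- suppressWarnings(m_step(stats, moments, Y, Z))
  expect_equal(ms$theta$alpha0, 0.3)
  expect_equal(ms$theta$alpha1, 0.8)
  expect_equal(ms$theta$sigma0_sq, 1e-12)  # T3/R - alpha0^2 = 0, floored
  expect_equal(ms$theta$sigma1_sq, 0.65 - 0.64, tolerance = 1e-12)
  expect_equal(unname(ms$pi$pi[1, ]), pi_true, tolerance = 1e-8)
  # exact fit: residual variance hits the floor with a warning
  expect_warning(m_step(stats, moments, Y, Z), "floored")
})

test_that("one full EM iteration matches a hand-rolled formula oracle", {
  set.seed(14)
  inst <- random_model_instance(R = 4, N = 3, K = 2)
  or <- dense_estep_oracle(inst$Y, inst$Z, inst$theta, inst$pi)
  R <- 4
  # oracle M-step from the oracle E-step moments
  a0 <- sum(or$mean_delta0) / R
  a1 <- sum(or$mean_delta1) / R
  s0 <- sum(or$mean_delta0^2 + or$var_delta0) / R - a0^2
  s1 <- sum(or$mean_delta1^2 + or$var_delta1) / R - a1^2
  Xo <- (1 - inst$Z) * or$mean_delta0 + inst$Z * or$mean_delta1
  pi_o <- t(vapply(1:3, function(i) {
    grid_simplex_qp(crossprod(Xo), -crossprod(Xo, inst$Y[, i]), step = 0.001)
  }, numeric(2)))
  tau_o <- mean((inst$Y - Xo %*% t(pi_o))^2)

  es <- e_step(inst$Y, inst$Z, theta_as_params(inst$theta), inst$pi)
  ms <- m_step(es$stats, es$moments, inst$Y, inst$Z)
  expect_equal(ms$theta$alpha0, a0, tolerance = 1e-10)
  expect_equal(ms$theta$alpha1, a1, tolerance = 1e-10)
  expect_equal(ms$theta$sigma0_sq, s0, tolerance = 1e-10)
  expect_equal(ms$theta$sigma1_sq, s1, tolerance = 1e-10)
  expect_equal(unname(ms$pi$pi), unname(pi_o), tolerance = 2e-3)
  expect_equal(ms$theta$tau_sq, tau_o, tolerance = 1e-4)
})

test_that("observed log-likelihood matches closed forms and the dense oracle", {
  # R = N = 1 with degenerate state variances: univariate normal density
  Z1 <- matrix(1, 1, 1, dimnames = list(NULL, "A"))
  theta <- model_params(0.2, 0.8, 0, 0, 0.04)
  y <- matrix(0.7, 1, 1)
  ll <- observed_loglik(y, Z1, theta, matrix(1, 1, 1))
  expect_equal(ll, dnorm(0.7, 0.8, 0.2, log = TRUE), tolerance = 1e-8)

  set.seed(15)
  inst <- random_model_instance(R = 4, N = 3, K = 2)
  ll2 <- observed_loglik(inst$Y, inst$Z, theta_as_params(inst$theta), inst$pi)
  expect_equal(ll2, dense_loglik_oracle(inst$Y, inst$Z, inst$theta, inst$pi),
               tolerance = 1e-8)

  # an all-missing region contributes nothing
  Y_aug <- rbind(inst$Y, NA)
  Z_aug <- rbind(inst$Z, c(1, 0))
  expect_equal(observed_loglik(Y_aug, Z_aug, theta_as_params(inst$theta),
                               inst$pi), ll2, tolerance = 1e-12)
})

test_that("EM recovers proportions exactly from noiseless data", {
  Z <- simulate_z_matrix(30, 3, cell_types = c("A", "B", "C"), seed = 16)
  set.seed(16)
  pi_true <- t(apply(matrix(rgamma(5 * 3, 2), 5, 3), 1, function(x) x / sum(x)))
  X <- (1 - Z$Z) * 0.1 + Z$Z * 0.9
  Y <- X %*% t(pi_true)
  fit <- suppressWarnings(fit_methylcc(Y, Z))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$pi$pi - pi_true)), 1e-6)
})

test_that("the fit is deterministic and permutation-equivariant", {
  cfg <- simulation_config(N = 4, K = 2, Z = simulate_z_matrix(24, 2,
                                                               cell_types = c("A", "B"),
                                                               seed = 17),
                           pi_dirichlet_alpha = c(2, 2), n_sims = 1, seed = 17)
  ds <- simulate_mixtures(cfg)
  f1 <- suppressWarnings(fit_methylcc(ds$Y$array, cfg$Z))
  f2 <- suppressWarnings(fit_methylcc(ds$Y$array, cfg$Z))
  expect_identical(f1$pi$pi, f2$pi$pi)
  expect_identical(f1$loglik_trace, f2$loglik_trace)

  # relabeling cell types permutes the estimated proportions exactly
  Zp <- cfg$Z
  Zp$Z <- Zp$Z[, c(2, 1)]
  Zp$cell_types <- Zp$cell_types[c(2, 1)]
  fp <- suppressWarnings(fit_methylcc(ds$Y$array, Zp))
  expect_equal(unname(fp$pi$pi), unname(f1$pi$pi[, c(2, 1)]),
               tolerance = 1e-8)

  # constraints hold on every fitted row
  expect_true(all(abs(rowSums(f1$pi$pi) - 1) <= 1e-8))
  expect_true(all(f1$pi$pi >= -1e-10))
})

test_that("non-convergence is reported, not thrown, and R <= K is rejected", {
  cfg <- simulation_config(N = 3, K = 2, Z = simulate_z_matrix(24, 2,
                                                               cell_types = c("A", "B"),
                                                               seed = 18),
                           pi_dirichlet_alpha = c(2, 2), n_sims = 1, seed = 18)
  ds <- simulate_mixtures(cfg)
  fit <- suppressWarnings(fit_methylcc(ds$Y$array, cfg$Z, max_iter = 1))
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 1L)

  Zsmall <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(fit_methylcc(matrix(0.5, 2, 3), Zsmall), "R > K")
})

test_that("missing entries are excluded blockwise without breaking the fit", {
  cfg <- simulation_config(N = 6, K = 2, Z = simulate_z_matrix(30, 2,
                                                               cell_types = c("A", "B"),
                                                               seed = 19),
                           pi_dirichlet_alpha = c(2, 2), tau = 0.02,
                           n_sims = 1, seed = 19)
  ds <- simulate_mixtures(cfg)
  Y <- ds$Y$array$Y
  set.seed(19)
  Y[sample(length(Y), 15)] <- NA
  fit <- suppressWarnings(fit_methylcc(Y, cfg$Z))
  expect_true(all(abs(rowSums(fit$pi$pi) - 1) <= 1e-8))
  expect_lt(mean(rmse_by_cell_type(fit$pi, ds$pi_true)), 0.1)
})
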