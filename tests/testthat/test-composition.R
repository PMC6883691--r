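test_that("simplex QP solves the printed examples and projection cases", {
  # unconstrained minimizer already on the simplex
  expect_equal(solve_simplex_qp(diag(2), c(-0.3, -0.7)), c(0.3, 0.7),
               tolerance = 1e-10)
  # projections onto the simplex, verified against exhaustive grid search
  for (a in list(c(0.2, -1.2), c(-0.9, -0.9))) {
    qp <- solve_simplex_qp(diag(2), a)
    grid <- grid_simplex_qp(diag(2), a)
    expect_equal(qp, grid, tolerance = 1e-3)
  }
  expect_equal(solve_simplex_qp(diag(2), c(0.2, -1.2)), c(0, 1),
               tolerance = 1e-8)
  expect_equal(solve_simplex_qp(diag(2), c(-0.9, -0.9)), c(0.5, 0.5),
               tolerance = 1e-8)
  expect_error(solve_simplex_qp(matrix(c(1, 0.5, 0, 1), 2, 2), c(0, 0)),
               "symmetric")
  # without constraints it is the plain linear solve
  expect_equal(solve_simplex_qp(diag(2), c(-2, 3), FALSE, FALSE), c(2, -3))
})

test_that("QP agrees with the simplex grid oracle on random convex instances", {
  set.seed(2)
  for (i in 1:25) {
    inst <- random_qp_instance(K = 3)
    qp <- solve_simplex_qp(inst$Q, inst$a)
    expect_equal(sum(qp), 1, tolerance = 1e-8)
    expect_true(all(qp >= -1e-10))
    grid <- grid_simplex_qp(inst$Q, inst$a)
    expect_lt(max(abs(qp - grid)), 1e-3 + 1e-9)
  }
})

test_that("nonnegative-only QP matches the Lawson-Hanson NNLS solver", {
  skip_if_not_installed("pracma")
  set.seed(4)
  for (i in 1:10) {
    X <- matrix(runif(30), 10, 3)
    y <- runif(10)
    qp <- solve_simplex_qp(crossprod(X), -crossprod(X, y),
                           equality_sum_constraint = FALSE)
    nnls <- pracma::lsqnonneg(X, y)$x
    expect_equal(qp, nnls, tolerance = 1e-6)
  }
})

test_that("estimate_pi_given_X recovers noiseless mixtures and flags degeneracy", {
  set.seed(5)
  X <- matrix(runif(40), 20, 2)
  pi_true <- c(0.2, 0.8)
  Y <- X %*% pi_true
  est <- estimate_pi_given_X(Y, X, sum_to_one = TRUE)
  expect_equal(unname(est$pi[1, ]), pi_true, tolerance = 1e-8)

  # constant (rank-1) design is rejected
  expect_error(estimate_pi_given_X(Y, cbind(rep(1, 20), rep(1, 20))),
               "rank-deficient")
  # fewer non-missing regions than K is rejected
  Yna <- Y; Yna[2:20] <- NA
  expect_error(estimate_pi_given_X(Yna, X), "non-missing")
})

test_that("estimate_pi_given_X matches the grid oracle under noise and is permutation-equivariant", {
  set.seed(6)
  X <- matrix(runif(60), 20, 3)
  pi_true <- c(0.5, 0.3, 0.2)
  Y <- X %*% pi_true + rnorm(20, 0, 0.02)
  est <- estimate_pi_given_X(Y, X, sum_to_one = TRUE)
  grid <- grid_simplex_qp(crossprod(X), -crossprod(X, Y))
  expect_lt(max(abs(est$pi[1, ] - grid)), 1e-3 + 1e-9)

  perm <- c(3, 1, 2)
  est_p <- estimate_pi_given_X(Y, X[, perm], sum_to_one = TRUE)
  expect_equal(unname(est_p$pi[, ]), unname(est$pi[1, perm]),
               tolerance = 1e-8)
})

test_that("reference-based CpG estimator recovers exact mixtures and reports CpG loss", {
  set.seed(7)
  J <- 30
  ref <- cell_type_reference_profile(
    sprintf("cg%02d", 1:J), matrix(runif(J * 2), J, 2,
                                   dimnames = list(NULL, c("A", "B"))))
  y <- ref$X %*% c(0.2, 0.8)
  tb <- cpg_measurement_table("s1", "chr1", seq_len(J) * 100L, beta = y,
                              cpg_id = ref$cpg_ids)
  est <- houseman_estimate(tb, ref)
  expect_equal(unname(est$pi[1, ]), c(0.2, 0.8), tolerance = 1e-8)
  expect_equal(unname(attr(est, "n_cpgs_used")["s1"]), 30L)
  expect_false(est$sum_constrained)

  # sample measuring only K - 1 reference CpGs: error names the count
  tb_short <- cpg_measurement_table("s2", "chr1", 100L, beta = y[1],
                                    cpg_id = ref$cpg_ids[1])
  expect_error(houseman_estimate(tb_short, ref), "only 1")

  # sum-to-one variant coincides with the region-level constrained fit
  est_sum <- houseman_estimate(tb, ref, sum_to_one = TRUE)
  est_reg <- estimate_pi_given_X(y, ref$X, sum_to_one = TRUE)
  expect_equal(est_sum$pi[1, ], est_reg$pi[1, ], tolerance = 1e-10)
})

test_that("a mismatched reference biases the unscaled estimator in the direction of the platform shift", {
  set.seed(8)
  Z <- simulate_z_matrix(40, 3, cell_types = c("A", "B", "C"), seed = 8)
  pi_true <- matrix(rep(1 / 3, 3), 1)
  # data platform attenuated (0.15/0.85); references: matched, wider, narrower
  X_data <- (1 - Z$Z) * 0.15 + Z$Z * 0.85
  Y <- X_data %*% t(pi_true)
  X_wide <- (1 - Z$Z) * 0.05 + Z$Z * 0.95
  X_narrow <- (1 - Z$Z) * 0.25 + Z$Z * 0.75
  tot <- function(X) sum(estimate_pi_given_X(Y, X, sum_to_one = FALSE)$pi)
  expect_equal(tot(X_data), 1, tolerance = 1e-6)
  expect_lt(tot(X_wide), 0.99)    # wider reference spread -> shrunken totals
  expect_gt(tot(X_narrow), 1.01)  # narrower spread -> inflated totals
})

test_that("initialization reproduces the moment formulas on constructed data", {
  Z <- rbind(matrix(0, 2, 2), matrix(1, 2, 2), diag(2), 1 - diag(2))
  colnames(Z) <- c("A", "B")
  R <- nrow(Z)
  # constant Y on the all-zero rows: alpha0 = 0.1, sigma0 = 0
  Y <- matrix(0.5, R, 2)
  Y[1:2, ] <- 0.1
  Y[3:4, ] <- 0.9
  init <- init_params(Y, Z)
  expect_equal(init$theta$alpha0, 0.1)
  expect_equal(init$theta$sigma0_sq, 0)
  expect_equal(init$theta$alpha1, 0.9)

  # two-point R0 values {0.0, 0.2}: per-sample variance 0.02 (denominator 1)
  Y2 <- Y
  Y2[1, ] <- 0.0
  Y2[2, ] <- 0.2
  init2 <- init_params(Y2, Z)
  expect_equal(init2$theta$alpha0, 0.1)
  expect_equal(init2$theta$sigma0_sq, 0.02)
  expect_equal(sum(init2$pi$pi), 2, tolerance = 1e-8)  # rows on the simplex

  # missing all-one rows: pseudo-R1 set with a warning
  Zno <- rbind(matrix(0, 2, 2), diag(2), 1 - diag(2))
  colnames(Zno) <- c("A", "B")
  Yno <- matrix(c(0.1, 0.1, 0.5, 0.5, 0.5, 0.5), 6, 2)
  expect_warning(init_no <- init_params(Yno, Zno), "pseudo")
  expect_equal(init_no$theta$alpha0, 0.1)
})

test_that("initial state-mean estimates are consistent under the generative model", {
  # Monte Carlo: with tau = 0 the R0-row variance is exactly the state
  # variance, and alpha0-hat concentrates at alpha0 (3 SE band over seeds)
  errs <- numeric(10)
  vars <- numeric(10)
  s0sq <- 0.0025
  for (s in 1:10) {
    cfg <- simulation_config(N = 20, K = 3, Z = simulate_z_matrix(90, 3, seed = 2),
                             pi_dirichlet_alpha = rep(2, 3), tau = 1e-8,
                             platforms = list(platform_params("p", 0.15, 0.85,
                                                              s0sq, s0sq)),
                             n_sims = 1, seed = 100 + s)
    ds <- simulate_mixtures(cfg)
    init <- init_params(ds$Y$p, cfg$Z)
    errs[s] <- init$theta$alpha0 - 0.15
    vars[s] <- init$theta$sigma0_sq
  }
  n_r0 <- sum(rowSums(simulate_z_matrix(90, 3, seed = 2)$Z) == 0)
  se <- sqrt(s0sq / n_r0) # SE of one replicate's alpha0-hat
  expect_lt(mean(abs(errs) < 3 * se), 1.01)
  expect_gte(mean(abs(errs) < 3 * se), 0.8)
  # Jensen bound is tight at tau = 0: mean variance estimate near sigma0^2
  expect_equal(mean(vars), s0sq, tolerance = 0.35)
})
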