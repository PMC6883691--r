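#' Platform parameters for the two-platform simulation
#'
#' Each platform measures the same underlying binary region states, but its
#' random effects sit at platform-specific means and variances: arrays
#' attenuate methylation levels away from 0 and 1, while bisulfite
#' sequencing yields values closer to the extremes.
#'
#' @param name platform label.
#' @param alpha0_star,alpha1_star platform means of the unmethylated /
#'   methylated state (0 <= alpha0_star < alpha1_star <= 1).
#' @param sigma0_sq_star,sigma1_sq_star platform variances of the state
#'   random effects.
#' @return An object of class `PlatformParams`.
#' @export
platform_params <- function(name, alpha0_star, alpha1_star,
                            sigma0_sq_star = 0.0025,
                            sigma1_sq_star = 0.0025) {
  .stop_if(!(alpha0_star >= 0 && alpha0_star < alpha1_star && alpha1_star <= 1),
           "platform means must satisfy 0 <= alpha0_star < alpha1_star <= 1")
  .stop_if(sigma0_sq_star < 0 || sigma1_sq_star < 0,
           "platform variances must be >= 0")
  structure(list(name = name, alpha0_star = alpha0_star,
                 alpha1_star = alpha1_star, sigma0_sq_star = sigma0_sq_star,
                 sigma1_sq_star = sigma1_sq_star),
            class = "PlatformParams")
}

#' Default array-like and sequencing-like platforms
#'
#' Array-like: states at 0.15 / 0.85 (attenuated away from the edges);
#' sequencing-like: states at 0.05 / 0.95 (close to 0 and 1). Both use state
#' variance 0.0025 (sd 0.05).
#'
#' @return named list of two [platform_params()] objects (`array`,
#'   `sequencing`).
#' @export
default_platforms <- function() {
  list(array = platform_params("array", 0.15, 0.85),
       sequencing = platform_params("sequencing", 0.05, 0.95))
}

#' Generate a synthetic full-rank region-state matrix
#'
#' Builds an R x K binary Z with the structure the model expects: a block of
#' all-zero rows (unmethylated in every cell type) and all-one rows
#' (methylated in every cell type) for initialization, one
#' uniquely-methylated and one uniquely-unmethylated row per cell type
#' (guaranteeing full column rank), and Bernoulli(0.5) rows for the rest.
#' Regions are laid out as non-overlapping 500-bp intervals on one synthetic
#' chromosome.
#'
#' @param R number of regions (default 210).
#' @param K number of cell types (default 6).
#' @param cell_types cell-type names; defaults to the six major leukocyte
#'   types of whole blood.
#' @param prop_extreme fraction of rows reserved for each of the all-zero
#'   and all-one blocks (default 0.1).
#' @param seed RNG seed for the Bernoulli rows.
#' @return A [region_state_matrix()].
#' @export
simulate_z_matrix <- function(R = 210L, K = 6L,
                              cell_types = NULL,
                              prop_extreme = 0.1, seed = 1L) {
  if (is.null(cell_types)) {
    cell_types <- if (K == 6) c("Gran", "CD4T", "CD8T", "Bcell", "Mono", "NK")
                  else sprintf("celltype_%d", seq_len(K))
  }
  .stop_if(length(cell_types) != K, "cell_types must have length K")
  n_ext <- max(2L, round(prop_extreme * R))
  .stop_if(R < 2 * n_ext + 2 * K + 1, "R too small for the structured blocks")
  rows <- list(matrix(0, n_ext, K), matrix(1, n_ext, K), diag(K), 1 - diag(K))
  n_struct <- 2L * n_ext + 2L * K
  set.seed(seed)
  rand <- matrix(stats::rbinom((R - n_struct) * K, 1L, 0.5), ncol = K)
  Z <- do.call(rbind, c(rows, list(rand)))
  regions <- data.frame(chrom = "chrSim",
                        start = (seq_len(R) - 1L) * 1000L,
                        end = (seq_len(R) - 1L) * 1000L + 500L,
                        region_id = sprintf("sim_region_%d", seq_len(R)))
  region_state_matrix(regions, Z, cell_types = cell_types)
}

#' Simulation configuration
#'
#' Defines the study conditions for the two-platform Monte Carlo experiment:
#' N heterogeneous samples, true proportions drawn from a Dirichlet, and
#' per-platform cell-type profiles assembled from the shared binary states
#' and platform-dependent random effects.
#'
#' @param N samples per replicate (default 200).
#' @param K cell types (default 6).
#' @param Z a [region_state_matrix()]; defaults to
#'   `simulate_z_matrix(210, K)`.
#' @param pi_dirichlet_alpha Dirichlet concentration for the true
#'   proportions (default `rep(2, K)`).
#' @param tau measurement-error standard deviation (default 0.03).
#' @param platforms list of [platform_params()] (default
#'   [default_platforms()]).
#' @param n_sims number of Monte Carlo replicates (default 100).
#' @param seed base seed; replicate s uses `seed + s`.
#' @param share_noise reuse the same measurement error across platforms
#'   within a replicate (the two platform equations share one error term);
#'   set FALSE to redraw per platform.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(N = 200L, K = 6L, Z = NULL,
                              pi_dirichlet_alpha = NULL, tau = 0.03,
                              platforms = default_platforms(),
                              n_sims = 100L, seed = 1L, share_noise = TRUE) {
  .stop_if(N < 1, "N must be >= 1")
  .stop_if(n_sims < 1, "n_sims must be >= 1")
  if (is.null(Z)) Z <- simulate_z_matrix(210L, K, seed = seed)
  .stop_if(ncol(Z$Z) != K, "Z must have K columns")
  if (is.null(pi_dirichlet_alpha)) pi_dirichlet_alpha <- rep(2, K)
  .stop_if(length(pi_dirichlet_alpha) != K || any(pi_dirichlet_alpha <= 0),
           "pi_dirichlet_alpha must be K positive values")
  for (p in platforms) .stop_if(!inherits(p, "PlatformParams"),
                                "platforms must be platform_params() objects")
  structure(list(N = as.integer(N), K = as.integer(K), Z = Z,
                 pi_dirichlet_alpha = pi_dirichlet_alpha, tau = tau,
                 platforms = platforms, n_sims = as.integer(n_sims),
                 seed = as.integer(seed), share_noise = isTRUE(share_noise)),
            class = "SimulationConfig")
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate one platform's cell-type profile matrix X*
#'
#' Draws the platform's state random effects `delta0* ~ N(alpha0*,
#' sigma0*^2)` and `delta1* ~ N(alpha1*, sigma1*^2)` (one value per region,
#' shared by all cell types, clipped to \[0, 1\]) and assembles
#' `X*[r, k] = (1 - Z[r, k]) * delta0*[r] + Z[r, k] * delta1*[r]`.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param Z a [region_state_matrix()] or R x K binary matrix.
#' @param platform a [platform_params()].
#' @return R x K numeric matrix; attributes `"delta0"`/`"delta1"` hold the
#'   drawn effects.
#' @export
simulate_platform_profiles <- function(Z, platform) {
  Zm <- .z_matrix(Z)
  R <- nrow(Zm)
  d0 <- pmin(pmax(stats::rnorm(R, platform$alpha0_star,
                               sqrt(platform$sigma0_sq_star)), 0), 1)
  d1 <- pmin(pmax(stats::rnorm(R, platform$alpha1_star,
                               sqrt(platform$sigma1_sq_star)), 0), 1)
  X <- (1 - Zm) * d0 + Zm * d1
  attr(X, "delta0") <- d0
  attr(X, "delta1") <- d1
  X
}

#' Simulate heterogeneous mixture samples on every platform
#'
#' One replicate of the generative model: true proportions
#' `pi_i ~ Dirichlet(alpha)`, measurement error `eps ~ N(0, tau^2)` i.i.d.
#' per region and sample, and per-platform profiles from
#' [simulate_platform_profiles()]. The same proportions (and, by default,
#' the same error draws) feed every platform, so platform differences come
#' only from the state random effects. Observed values are clipped to
#' \[0, 1\] and clip events counted. Bit-exactly reproducible from
#' `(config, config$seed)`.
#'
#' @param config a [simulation_config()].
#' @return An object of class `SimulatedDataset`: list with `Y` (named list
#'   of [region_methylation_matrix()] per platform), `X_star` (named list of
#'   R x K profile matrices), `pi_true` (N x K), `theta_true` (the platform
#'   parameter objects), `clip_count` (per platform), `config`.
#' @export
simulate_mixtures <- function(config) {
  set.seed(config$seed)
  N <- config$N
  Zm <- config$Z$Z
  R <- nrow(Zm)
  pi_true <- .rdirichlet(N, config$pi_dirichlet_alpha)
  colnames(pi_true) <- config$Z$cell_types
  rownames(pi_true) <- sprintf("sample_%d", seq_len(N))
  eps <- matrix(stats::rnorm(R * N, 0, config$tau), R, N)
  Ys <- list()
  Xs <- list()
  clip <- integer(0)
  for (p in config$platforms) {
    Xp <- simulate_platform_profiles(config$Z, p)
    e <- if (config$share_noise) eps else
      matrix(stats::rnorm(R * N, 0, config$tau), R, N)
    Yp <- Xp %*% t(pi_true) + e
    n_clip <- sum(Yp < 0 | Yp > 1)
    Yp <- pmin(pmax(Yp, 0), 1)
    colnames(Yp) <- rownames(pi_true)
    Ys[[p$name]] <- region_methylation_matrix(config$Z$regions, Yp)
    Xs[[p$name]] <- Xp
    clip[p$name] <- n_clip
  }
  structure(list(Y = Ys, X_star = Xs, pi_true = pi_true,
                 theta_true = stats::setNames(config$platforms,
                                              vapply(config$platforms,
                                                     `[[`, "", "name")),
                 clip_count = clip, config = config),
            class = "SimulatedDataset")
}

#' Cell-type-specific RMSE of composition estimates
#'
#' `RMSE_k = sqrt(mean over samples of (pi_hat[, k] - pi_true[, k])^2)`.
#' The mean over cell types of this vector is the "mean RMSE" used to score
#' a method in the simulation study.
#'
#' @param pi_hat estimated N x K matrix (or [composition_estimate()]).
#' @param pi_true true N x K matrix.
#' @return named K-vector of per-cell-type RMSE.
#' @export
rmse_by_cell_type <- function(pi_hat, pi_true) {
  ph <- if (inherits(pi_hat, "CompositionEstimate")) pi_hat$pi else
    as.matrix(pi_hat)
  pt <- as.matrix(pi_true)
  .stop_if(!all(dim(ph) == dim(pt)), "pi_hat and pi_true shapes differ")
  sqrt(colMeans((ph - pt)^2))
}

#' Run the two-platform simulation study
#'
#' For each replicate: draw fresh proportions, platform profiles and noise;
#' run the requested estimators on the target platform's data; record each
#' estimator's mean RMSE against the true proportions. The reference-based
#' estimator is handed the REFERENCE platform's profile matrix, so setting
#' `target_platform != reference_platform` reproduces the cross-platform
#' mismatch scenario, while equal platforms give the matched-reference
#' scenario. The latent-state estimator only ever sees Z.
#'
#' @param config a [simulation_config()].
#' @param methods subset of `c("houseman", "methylcc")`.
#' @param reference_platform,target_platform platform names from
#'   `config$platforms` (default: reference is the first platform, target
#'   the last).
#' @param houseman_sum_to_one sum-to-one flag for the reference-based
#'   estimator (default FALSE, unscaled).
#' @param max_iter,tol EM controls for the latent-state fits.
#' @return list with `per_replicate` (data.frame: replicate, method,
#'   mean_rmse, and for methylcc the absolute errors of the fitted state
#'   means vs the target platform's), `summary` (median and IQR of mean RMSE
#'   per method), `failures` (count per method).
#' @export
run_simulation_study <- function(config, methods = c("houseman", "methylcc"),
                                 reference_platform = NULL,
                                 target_platform = NULL,
                                 houseman_sum_to_one = FALSE,
                                 max_iter = 100L, tol = 1e-4) {
  .stop_if(!all(methods %in% c("houseman", "methylcc")),
           "methods must be a subset of houseman, methylcc")
  pnames <- unname(vapply(config$platforms, `[[`, "", "name"))
  if (is.null(reference_platform)) reference_platform <- pnames[1]
  if (is.null(target_platform)) target_platform <- pnames[length(pnames)]
  .stop_if(!reference_platform %in% pnames, "unknown reference platform")
  .stop_if(!target_platform %in% pnames, "unknown target platform")
  rows <- list()
  failures <- stats::setNames(integer(length(methods)), methods)
  target_theta <- config$platforms[[which(pnames == target_platform)]]
  for (s in seq_len(config$n_sims)) {
    rep_config <- config
    rep_config$seed <- config$seed + s
    ds <- simulate_mixtures(rep_config)
    Yt <- ds$Y[[target_platform]]
    Xref <- ds$X_star[[reference_platform]]
    for (m in methods) {
      res <- tryCatch({
        if (m == "houseman") {
          est <- estimate_pi_given_X(Yt, Xref,
                                     sum_to_one = houseman_sum_to_one,
                                     cell_types = config$Z$cell_types)
          data.frame(replicate = s, method = m,
                     mean_rmse = mean(rmse_by_cell_type(est, ds$pi_true)),
                     alpha0_abs_err = NA_real_, alpha1_abs_err = NA_real_)
        } else {
          fit <- fit_methylcc(Yt, config$Z, max_iter = max_iter, tol = tol)
          data.frame(replicate = s, method = m,
                     mean_rmse = mean(rmse_by_cell_type(fit$pi, ds$pi_true)),
                     alpha0_abs_err = abs(fit$theta$alpha0 -
                                            target_theta$alpha0_star),
                     alpha1_abs_err = abs(fit$theta$alpha1 -
                                            target_theta$alpha1_star))
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[m] <- failures[m] + 1L
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  per_replicate <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicate = integer(), method = character(),
               mean_rmse = numeric(), alpha0_abs_err = numeric(),
               alpha1_abs_err = numeric())
  summary <- do.call(rbind, lapply(unique(per_replicate$method), function(m) {
    x <- per_replicate$mean_rmse[per_replicate$method == m]
    data.frame(method = m, n = length(x), median_mean_rmse = stats::median(x),
               iqr_mean_rmse = stats::IQR(x))
  }))
  list(per_replicate = per_replicate, summary = summary, failures = failures,
       reference_platform = reference_platform,
       target_platform = target_platform)
}
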