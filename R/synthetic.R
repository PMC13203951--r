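#' Monte Carlo simulation configuration
#'
#' Bundles the design of the parameter-recovery study: requirement maps and
#' learner profiles drawn from a discretized Gaussian over the ordered
#' levels (mean 2, variance 3 by default), slip/guess from a four-parameter
#' beta on \[0.1, 0.4\], and Bernoulli responses.  Defaults are the study
#' design; `U` and `reps` are routinely reduced for desk-scale runs.
#'
#' @param E,K,U exercises, concepts, learners (defaults 20, 5, 20000).
#' @param L_max maximum level (default 6).
#' @param level_mean,level_var Gaussian mean/variance for requirement-map
#'   levels (defaults 2 and 3).
#' @param profile_mean,profile_var same for learner profiles (default: same
#'   as the requirement distribution).
#' @param sg_range support of slip/guess draws (default `c(0.1, 0.4)`).
#' @param sg_shapes beta shape pair (default `c(2, 2)`; `c(1, 1)` gives the
#'   uniform special case).
#' @param reps number of replications (default 100).
#' @param seed master seed; per-rep seeds are derived with [rep_seeds()].
#' @param prior_mode,tol_param,tol_loglik,max_iter forwarded to [fit_em()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(E = 20L, K = 5L, U = 20000L, L_max = 6L,
                       level_mean = 2, level_var = 3,
                       profile_mean = level_mean, profile_var = level_var,
                       sg_range = c(0.1, 0.4), sg_shapes = c(2, 2),
                       reps = 100L, seed = 1L,
                       prior_mode = "empirical", tol_param = 1e-4,
                       tol_loglik = 1e-6, max_iter = 1000L) {
  stopifnot(level_var > 0, profile_var > 0, reps >= 1,
            length(sg_range) == 2, sg_range[1] < sg_range[2],
            sg_range[1] > 0, sg_range[2] < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Deterministic per-replication seeds
#'
#' Draws `reps` integer seeds from the master seed so any replication can be
#' re-run in isolation.
#'
#' @param seed master seed.
#' @param reps number of replications.
#' @return integer vector of length `reps`.
#' @export
rep_seeds <- function(seed, reps) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, reps))
}

#' Sample ordered levels from a discretized Gaussian
#'
#' Independent `Normal(mean, var)` draws rounded to the nearest integer and
#' clipped into `[0, L_max]`; used for both requirement maps and learner
#' profiles.
#'
#' @param rows,cols matrix dimensions.
#' @param mean,var Gaussian mean and variance.
#' @param L_max maximum level.
#' @param seed optional seed (RNG state restored afterwards).
#' @return integer matrix.
#' @export
sample_levels <- function(rows, cols, mean = 2, var = 3, L_max = 6L,
                          seed = NULL) {
  stopifnot(var >= 0)
  with_seed(seed, {
    x <- round(rnorm(rows * cols, mean, sqrt(var)))
    matrix(as.integer(pmin(pmax(x, 0), L_max)), rows, cols)
  })
}

#' Sample slip/guess parameters from a four-parameter beta
#'
#' `a + (b - a) * Beta(shape1, shape2)` on the interval `sg_range = c(a, b)`.
#'
#' @param E number of exercises.
#' @param sg_range support interval (default `c(0.1, 0.4)`).
#' @param shapes beta shape pair (default `c(2, 2)`).
#' @param seed optional seed.
#' @return an [item_params()] with `s` and `g` in `sg_range`.
#' @export
sample_item_params <- function(E, sg_range = c(0.1, 0.4), shapes = c(2, 2),
                               seed = NULL) {
  with_seed(seed, {
    s <- sg_range[1] + diff(sg_range) * rbeta(E, shapes[1], shapes[2])
    g <- sg_range[1] + diff(sg_range) * rbeta(E, shapes[1], shapes[2])
    item_params(s, g)
  })
}

#' Generate one complete ground-truth dataset
#'
#' Draws, in order: the requirement map (all-zero exercise rows resampled so
#' every exercise tests something), learner profiles, item parameters, and
#' Bernoulli responses.
#'
#' @param config a [sim_config()].
#' @param seed seed for this draw (default `config$seed`).
#' @return list of class `sim_truth` with `req`, `profiles`, `params`,
#'   `responses`.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  with_seed(seed, {
    a <- sample_levels(config$E, config$K, config$level_mean,
                       config$level_var, config$L_max)
    while (any(rowSums(a) == 0L)) {
      zero <- rowSums(a) == 0L
      a[zero, ] <- sample_levels(sum(zero), config$K, config$level_mean,
                                 config$level_var, config$L_max)
    }
    req <- requirement_map(a, L_max = config$L_max)
    profiles <- sample_levels(config$U, config$K, config$profile_mean,
                              config$profile_var, config$L_max)
    params <- sample_item_params(config$E, config$sg_range, config$sg_shapes)
    responses <- simulate_responses(req, profiles, params)
    structure(list(req = req, profiles = profiles, params = params,
                   responses = responses, config = config, seed = seed),
              class = "sim_truth")
  })
}

#' Bernoulli responses from ground truth
#'
#' Each learner answers each exercise correctly with probability
#' `(1 - s_e)` if their ideal response is correct and `g_e` otherwise.
#'
#' @param req a [requirement_map()].
#' @param profiles integer `U x K` matrix of true levels.
#' @param params an [item_params()].
#' @param seed optional seed.
#' @return binary `U x E` matrix with the map's exercise ids as column
#'   names.
#' @export
simulate_responses <- function(req, profiles, params, seed = NULL) {
  with_seed(seed, {
    pi_u <- ideal_response_rows(req, profiles)
    U <- nrow(profiles)
    P <- pi_u * rep(1 - params$s, each = U) +
      (1 - pi_u) * rep(params$g, each = U)
    R <- matrix(rbinom(length(P), 1L, P), U, req$E)
    colnames(R) <- req$exercise_ids
    R
  })
}

#' Recovery metrics for one replication
#'
#' Parameter accuracy as mean absolute error and mean squared error
#' (reported separately for slip and guess, and pooled over all `2E`
#' parameters), and profile accuracy as the pattern match ratio (share of
#' learners with all `K` levels exactly recovered) and average attribute
#' match ratio (share of correctly recovered learner-concept cells).
#'
#' @param truth a [simulate_truth()] result (or any list with `params` and
#'   `profiles`).
#' @param est_params fitted [item_params()] (or a data.frame with `slip` and
#'   `guess` columns).
#' @param est_levels inferred integer `U x K` reported levels.
#' @return list with `mae_s`, `mae_g`, `mae`, `mse_s`, `mse_g`, `mse`,
#'   `pmr`, `aamr`.
#' @export
recovery_metrics <- function(truth, est_params, est_levels) {
  if (is.data.frame(est_params)) {
    est_params <- item_params(est_params$slip, est_params$guess)
  }
  ds <- est_params$s - truth$params$s
  dg <- est_params$g - truth$params$g
  if (!identical(dim(est_levels), dim(truth$profiles))) {
    stop("inferred level matrix does not match the true profile matrix")
  }
  hit <- est_levels == truth$profiles
  list(mae_s = mean(abs(ds)), mae_g = mean(abs(dg)),
       mae = mean(abs(c(ds, dg))),
       mse_s = mean(ds^2), mse_g = mean(dg^2), mse = mean(c(ds, dg)^2),
       pmr = mean(rowSums(hit) == ncol(hit)), aamr = mean(hit))
}

#' Run the Monte Carlo parameter-recovery study
#'
#' For each replication: draw ground truth, fit the EM, infer reported
#' levels, and score recovery; then average across replications.
#'
#' @param config a [sim_config()].
#' @param progress print one line per replication.
#' @return list of class `sim_result` with `summary` (across-rep means),
#'   `per_rep` (data.frame, one row per replication including its seed), and
#'   `last_rep` (true vs estimated slip/guess table of the final
#'   replication).  Failed replications are recorded and excluded with a
#'   warning.
#' @export
run_monte_carlo <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- rep_seeds(config$seed, config$reps)
  rows <- vector("list", config$reps)
  last_rep <- NULL
  for (r in seq_len(config$reps)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      truth <- simulate_truth(config, seeds[r])
      keep <- filter_invalid_exercises(truth$responses)
      if (length(keep$removed) > 0) {
        stop("degenerate exercises in simulated data: ",
             paste(keep$removed, collapse = ", "))
      }
      fit <- fit_em(truth$responses, truth$req,
                    prior_mode = config$prior_mode,
                    tol_param = config$tol_param,
                    tol_loglik = config$tol_loglik,
                    max_iter = config$max_iter, store_posterior = "never")
      diag <- diagnose(truth$responses, truth$req, fit = fit,
                       compute_ci = FALSE)
      m <- recovery_metrics(truth, fit$item_params, diag$reported)
      last_rep <- data.frame(exercise_id = truth$req$exercise_ids,
                              slip_true = truth$params$s,
                              slip_est = fit$item_params$slip,
                              guess_true = truth$params$g,
                              guess_est = fit$item_params$guess)
      c(list(rep = r, seed = seeds[r], ok = TRUE,
             n_iter = fit$n_iter, converged = fit$converged), m)
    }, error = function(e) {
      warning("replication ", r, " failed: ", conditionMessage(e))
      list(rep = r, seed = seeds[r], ok = FALSE, n_iter = NA, converged = NA,
           mae_s = NA, mae_g = NA, mae = NA, mse_s = NA, mse_g = NA,
           mse = NA, pmr = NA, aamr = NA)
    })
    res$elapsed <- proc.time()[["elapsed"]] - t0
    rows[[r]] <- as.data.frame(res)
    if (progress) {
      message(sprintf("rep %d/%d: PMR %.3f AAMR %.3f MAE(s) %.3f MAE(g) %.3f [%.1fs]",
                      r, config$reps, res$pmr, res$aamr, res$mae_s,
                      res$mae_g, res$elapsed))
    }
  }
  per_rep <- do.call(rbind, rows)
  ok <- per_rep$ok
  if (!any(ok)) stop("every replication failed")
  metric_cols <- c("mae_s", "mae_g", "mae", "mse_s", "mse_g", "mse",
                   "pmr", "aamr")
  summary <- as.list(colMeans(per_rep[ok, metric_cols, drop = FALSE]))
  summary$n_ok <- sum(ok)
  structure(list(summary = summary, per_rep = per_rep, last_rep = last_rep,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Monte Carlo recovery over %d replication(s) (E = %d, K = %d, U = %d):\n",
    s$n_ok, x$config$E, x$config$K, x$config$U))
  cat(sprintf("  MAE  slip %.4f | guess %.4f | pooled %.4f\n",
              s$mae_s, s$mae_g, s$mae))
  cat(sprintf("  MSE  slip %.4f | guess %.4f | pooled %.4f\n",
              s$mse_s, s$mse_g, s$mse))
  cat(sprintf("  PMR %.3f | AAMR %.3f\n", s$pmr, s$aamr))
  invisible(x)
}
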