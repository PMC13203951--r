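#' Item slip/guess parameter container
#'
#' @param s,g numeric vectors of per-exercise slip and guess probabilities.
#' @return Object of class `item_params` (list with `s` and `g`).
#' @export
item_params <- function(s, g) {
  if (length(s) != length(g)) stop("slip and guess vectors differ in length")
  if (any(is.infinite(s)) || any(is.infinite(g))) {
    stop("non-finite item parameters")
  }
  structure(list(s = as.numeric(s), g = as.numeric(g)), class = "item_params")
}

# Clip probabilities into [clip, 1 - clip], warning when anything moved.
clip_probs <- function(x, clip = 1e-6, what = "probabilities") {
  if (any(x < clip) || any(x > 1 - clip)) {
    if (any(x < 0) || any(x > 1)) {
      warning(what, " outside (0,1); clipped to [", clip, ", ", 1 - clip, "]")
    }
    x <- pmin(pmax(x, clip), 1 - clip)
  }
  x
}

#' Correct-response probability for every profile and exercise
#'
#' `P_e(beta_n) = g_e^(1 - pi_ne) * (1 - s_e)^(pi_ne)`: a profile whose ideal
#' response is correct succeeds unless it slips; otherwise it succeeds only
#' by guessing.
#'
#' @param params an [item_params()].
#' @param pi_mat binary `N x E` ideal-response matrix
#'   ([ideal_response_matrix()]).
#' @param clip probability floor; out-of-range parameters are clipped with a
#'   warning.
#' @return `N x E` probability matrix.
#' @export
response_probability <- function(params, pi_mat, clip = 1e-6) {
  stopifnot(inherits(params, "item_params"))
  if (length(params$s) != ncol(pi_mat)) {
    stop("parameter vectors and ideal-response matrix disagree on E")
  }
  s <- clip_probs(params$s, clip, "slip parameters")
  g <- clip_probs(params$g, clip, "guess parameters")
  N <- nrow(pi_mat)
  pi_mat * rep(1 - s, each = N) + (1 - pi_mat) * rep(g, each = N)
}

#' Per-learner, per-profile response log-likelihood
#'
#' Entry `(u, n)` is `sum_e R_ue log P_e(beta_n) + (1 - R_ue) log(1 -
#' P_e(beta_n))`, the log-probability of learner `u`'s full response vector
#' under profile `n`, using conditional independence across exercises.
#' Computed in log space throughout.
#'
#' @param responses binary `U x E` matrix.
#' @param P `N x E` correct-response probability matrix
#'   ([response_probability()]).
#' @param clip probability floor applied to `P` before taking logs.
#' @return `U x N` log-likelihood matrix.
#' @export
log_likelihood_matrix <- function(responses, P, clip = 1e-6) {
  responses <- validate_responses(responses)
  if (ncol(responses) != ncol(P)) {
    stop("responses and probability matrix disagree on E")
  }
  P <- clip_probs(P, clip, "response probabilities")
  lp1 <- log(P)
  lp0 <- log(1 - P)
  U <- nrow(responses)
  responses %*% t(lp1 - lp0) +
    matrix(rowSums(lp0), U, nrow(P), byrow = TRUE)
}

# Normalize and validate a prior vector over profiles.
validate_prior <- function(prior, N) {
  if (length(prior) != N) stop("prior has length ", length(prior), ", expected ", N)
  if (any(prior < 0)) stop("prior probabilities must be nonnegative")
  s <- sum(prior)
  if (abs(s - 1) > 1e-12) {
    if (s <= 0) stop("prior sums to zero")
    prior <- prior / s
  }
  prior
}

#' E step: posterior over profiles for every learner
#'
#' Row `u` is proportional to `exp(loglik[u, ]) * prior`, normalized with the
#' log-sum-exp trick.
#'
#' @param loglik `U x N` matrix from [log_likelihood_matrix()].
#' @param prior length-`N` prior over profiles (normalized internally).
#' @return `U x N` posterior matrix; rows sum to 1.
#' @export
e_step <- function(loglik, prior) {
  prior <- validate_prior(prior, ncol(loglik))
  lp <- loglik + matrix(log(prior), nrow(loglik), ncol(loglik), byrow = TRUE)
  mx <- apply(lp, 1, max)
  if (any(!is.finite(mx))) {
    stop("posterior undefined (all profiles have zero likelihood) for learner(s) ",
         paste(which(!is.finite(mx)), collapse = ", "))
  }
  w <- exp(lp - mx)
  w / rowSums(w)
}

#' M step: closed-form slip/guess update from expected counts
#'
#' Splits, for each exercise, the expected posterior mass between profiles
#' whose ideal response is 0 (`Z0`) and 1 (`Z1`), together with the expected
#' number of correct responders within each part (`F0`, `F1`); then
#' `g_e = F0/Z0` (correct among non-masters) and `s_e = (Z1 - F1)/Z1`
#' (incorrect among masters).
#'
#' @param responses binary `U x E` matrix.
#' @param post `U x N` posterior from [e_step()].
#' @param pi_mat binary `N x E` ideal-response matrix.
#' @param prev_params optional [item_params()] retained for exercises whose
#'   `Z0` or `Z1` is numerically zero (degenerate for the current posterior).
#' @return list with `params` ([item_params()]) and `counts` (list `Z0`,
#'   `Z1`, `F0`, `F1` per exercise and `Z_n` per profile).
#' @export
m_step <- function(responses, post, pi_mat, prev_params = NULL) {
  responses <- validate_responses(responses)
  U <- nrow(responses)
  Z_n <- colSums(post)
  W <- crossprod(post, responses)            # N x E expected correct
  F1 <- colSums(pi_mat * W)
  Z1 <- as.vector(crossprod(pi_mat, Z_n))
  F0 <- colSums(W) - F1
  Z0 <- U - Z1
  g <- F0 / Z0
  s <- (Z1 - F1) / Z1
  deg0 <- Z0 <= 1e-10
  deg1 <- Z1 <= 1e-10
  if (any(deg0) || any(deg1)) {
    warning("degenerate expected counts for exercise(s) ",
            paste(which(deg0 | deg1), collapse = ", "),
            "; parameter kept at previous value")
    if (is.null(prev_params)) {
      g[deg0] <- NA_real_
      s[deg1] <- NA_real_
    } else {
      g[deg0] <- prev_params$g[deg0]
      s[deg1] <- prev_params$s[deg1]
    }
  }
  list(params = item_params(s, g),
       counts = list(Z0 = Z0, Z1 = Z1, F0 = F0, F1 = F1, Z_n = Z_n))
}

#' Marginal log-likelihood of the observed responses
#'
#' `sum_u log sum_n exp(loglik[u, n]) * prior[n]`, stabilized via
#' log-sum-exp.
#'
#' @inheritParams e_step
#' @return scalar log-likelihood.
#' @export
marginal_log_likelihood <- function(loglik, prior) {
  prior <- validate_prior(prior, ncol(loglik))
  lp <- loglik + matrix(log(prior), nrow(loglik), ncol(loglik), byrow = TRUE)
  mx <- apply(lp, 1, max)
  sum(mx + log(rowSums(exp(lp - mx))))
}

#' Information criteria for model comparison
#'
#' @param loglik marginal log-likelihood at the fitted parameters.
#' @param n_params number of free parameters (`2E` with a fixed profile
#'   prior; `2E + N - 1` when the prior is estimated).
#' @param U number of learners.
#' @return list with `AIC` and `BIC`.
#' @export
information_criteria <- function(loglik, n_params, U) {
  stopifnot(n_params >= 0, U >= 1)
  list(AIC = -2 * loglik + 2 * n_params,
       BIC = -2 * loglik + n_params * log(U))
}

# ---------------------------------------------------------------------------
# Reduced representation: ideal-response equivalence classes of profiles.
#
# For concept k only the thresholds that actually occur as requirement levels
# matter: two levels falling between the same consecutive thresholds yield
# identical indicators for every exercise.  Profiles therefore collapse into
# boxes (products of per-concept threshold intervals) within which the
# likelihood -- and hence the posterior, under any prior constant within
# boxes -- is constant.  All EM and inference quantities over the full
# profile space are recovered exactly from the class level.

class_structure <- function(req) {
  K <- req$K
  L_max <- req$L_max
  thr <- lapply(seq_len(K), function(k) sort(unique(req$a[, k][req$a[, k] > 0L])))
  nk <- vapply(thr, length, 0L) + 1L
  M <- prod(nk)
  G <- matrix(0L, M, K)
  idx <- 0:(M - 1)
  for (k in K:1) {
    G[, k] <- as.integer(idx %% nk[k])
    idx <- idx %/% nk[k]
  }
  intervals <- lapply(seq_len(K), function(k) {
    bnd <- c(0L, thr[[k]], L_max + 1L)
    lapply(seq_len(nk[k]), function(i) bnd[i]:(bnd[i + 1] - 1L))
  })
  size_k <- lapply(intervals, function(iv) vapply(iv, length, 0L))
  mean_k <- lapply(intervals, function(iv) vapply(iv, mean, 0))
  lo_k <- lapply(intervals, function(iv) vapply(iv, min, 0L))
  csize <- Reduce(`*`, lapply(seq_len(K), function(k) size_k[[k]][G[, k] + 1]))
  cmean <- vapply(seq_len(K), function(k) mean_k[[k]][G[, k] + 1], numeric(M))
  clo <- vapply(seq_len(K), function(k) lo_k[[k]][G[, k] + 1], integer(M))
  cmean <- matrix(cmean, M, K)
  clo <- matrix(clo, M, K)
  PIc <- matrix(1, M, req$E)
  for (e in seq_len(req$E)) {
    for (k in seq_len(K)) {
      if (req$a[e, k] > 0L) PIc[, e] <- PIc[, e] * (clo[, k] >= req$a[e, k])
    }
  }
  # marginal spread matrix: S[c, (k-1)*(L+1) + l + 1] = P(beta_k = l | class c)
  S <- matrix(0, M, K * (L_max + 1))
  for (k in seq_len(K)) {
    for (i in seq_len(nk[k])) {
      rows <- G[, k] == i - 1L
      lv <- intervals[[k]][[i]]
      S[rows, (k - 1) * (L_max + 1) + lv + 1] <- 1 / length(lv)
    }
  }

  # Second exact reduction: boxes whose ideal-response rows coincide on every
  # exercise are indistinguishable by the likelihood, and any prior that
  # starts uniform over profiles keeps their masses proportional to their
  # sizes throughout EM.  They are merged with a size-weighted uniform
  # conditional; all summaries aggregate accordingly.
  key <- apply(PIc, 1, paste, collapse = "")
  first <- !duplicated(key)
  merged <- match(key, key[first])
  Mm <- sum(first)
  agg <- function(x) {
    out <- rowsum(x * csize, merged)
    out / as.vector(rowsum(csize, merged))
  }
  # representative corner: lowest-index box corner within each merged class
  corner_index <- as.vector(clo %*% (L_max + 1)^((K - 1):0))
  ord <- order(merged, corner_index)
  firsts <- ord[!duplicated(merged[ord])]
  corner <- clo[firsts, , drop = FALSE]
  list(thr = thr, nk = nk, M = Mm, box_count = M, box_class = merged,
       csize = as.vector(rowsum(csize, merged)),
       cmean = agg(cmean), clo = corner, PIc = PIc[first, , drop = FALSE],
       S = agg(S), K = K, L_max = L_max, N = (L_max + 1)^K)
}

# Merged-class index (1-based) of each profile row; used to expand
# class-level quantities back to the full space on small problems.
class_of_profiles <- function(cls, profiles) {
  K <- cls$K
  idx <- rep(0, nrow(profiles))
  for (k in seq_len(K)) {
    ck <- findInterval(profiles[, k], cls$thr[[k]])  # 0-based box digit
    idx <- idx * cls$nk[k] + ck
  }
  cls$box_class[as.integer(idx + 1)]
}

collapse_patterns <- function(responses) {
  key <- apply(responses, 1, paste, collapse = "")
  first <- !duplicated(key)
  Rp <- responses[first, , drop = FALSE]
  idx <- match(key, key[first])
  list(Rp = Rp, w = tabulate(idx, sum(first)), idx = idx)
}

#' Fit slip/guess parameters by marginal maximum likelihood (EM)
#'
#' Alternates the E step (posterior over ordered profiles given current
#' parameters) and the closed-form M step until the largest parameter change
#' drops below `tol_param` or the marginal log-likelihood change drops below
#' `tol_loglik`.  By default the profile prior is re-estimated each M step as
#' the expected profile frequencies (`empirical`, the standard latent-class
#' mixture EM); `prior_mode = "uniform"` keeps it fixed at uniform over all
#' `(L_max+1)^K` profiles.  The empirical mode is the default because a fixed
#' uniform prior is severely misspecified for realistic, centered level
#' populations and biases the slip estimates (see the methods vignette).
#'
#' Internally the fit runs on an exactly reduced problem: learners are
#' collapsed to distinct response patterns with multiplicities, and profiles
#' to ideal-response equivalence classes; see the methods vignette.
#'
#' @param responses binary `U x E` learner response matrix (column names, if
#'   present, are matched against the map's exercise ids); pre-filter with
#'   [filter_invalid_exercises()].
#' @param req a [requirement_map()].
#' @param prior_mode `"empirical"` (default) or `"uniform"`.
#' @param s_init,g_init initial parameter values (default 0.2), or set
#'   `init = "random"` for a seeded uniform draw on \[0.05, 0.3\].
#' @param init `"fixed"` or `"random"`.
#' @param tol_param,tol_loglik,max_iter convergence controls.
#' @param clip probability floor for all likelihood work.
#' @param seed seed used when `init = "random"`.
#' @param cap profile-space cap forwarded from [enumerate_profiles()]
#'   semantics: the fit refuses `(L_max+1)^K > cap` unless raised.
#' @param store_posterior `"auto"` (materialize the full `U x N` posterior
#'   only when `U * N <= 2e7`), `"always"`, or `"never"`.  The reduced
#'   posterior used by [diagnose()] is always kept.
#' @param block number of response patterns per block in the E step.
#' @return Object of class `ekc_fit`; see Details.  Key fields:
#'   `item_params` (data.frame with `exercise_id`, `slip`, `guess`),
#'   `loglik`, `loglik_trace`, `AIC`, `BIC`, `n_params`, `converged`,
#'   `n_iter`, `prior_mode`, and optionally `posterior` (`U x N`).
#' @examples
#' truth <- simulate_truth(sim_config(E = 6, K = 2, U = 300, reps = 1,
#'                                    seed = 1))
#' fit <- fit_em(truth$responses, truth$req)
#' fit$item_params
#' @export
fit_em <- function(responses, req, prior_mode = c("empirical", "uniform"),
                   s_init = 0.2, g_init = 0.2, init = c("fixed", "random"),
                   tol_param = 1e-4, tol_loglik = 1e-6, max_iter = 1000,
                   clip = 1e-6, seed = NULL, cap = 1e7,
                   store_posterior = c("auto", "always", "never"),
                   block = 2048L) {
  prior_mode <- match.arg(prior_mode)
  init <- match.arg(init)
  store_posterior <- match.arg(store_posterior)
  stopifnot(inherits(req, "requirement_map"))
  responses <- validate_responses(responses)
  req <- align_requirements(responses, req)
  E <- req$E
  U <- nrow(responses)
  N <- (req$L_max + 1)^req$K
  if (N > cap) {
    stop(sprintf("profile space too large: (L_max+1)^K = %.4g exceeds cap %.4g",
                 N, cap))
  }
  cm <- colMeans(responses)
  if (any(cm == 0 | cm == 1)) {
    stop("responses contain exercises with no variation; run filter_invalid_exercises() first")
  }

  cls <- class_structure(req)
  pat <- collapse_patterns(responses)
  if (init == "random") {
    s0 <- with_seed(seed, stats::runif(E, 0.05, 0.3))
    g0 <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                    stats::runif(E, 0.05, 0.3))
  } else {
    s0 <- rep(s_init, length.out = E)
    g0 <- rep(g_init, length.out = E)
  }
  log_prior0 <- log(cls$csize / N)   # uniform over profiles, at class level
  res <- .em_engine_cpp(pat$Rp, pat$w, cls$PIc, log_prior0, s0, g0,
                        prior_mode == "empirical", tol_param, tol_loglik,
                        as.integer(max_iter), clip, as.integer(block))
  if (!res$converged) {
    warning("EM did not converge in ", max_iter, " iterations")
  }
  if (res$n_degenerate > 0) {
    warning("degenerate expected counts encountered in ", res$n_degenerate,
            " M-step update(s); affected parameters kept at previous values")
  }
  s <- as.numeric(res$s)
  g <- as.numeric(res$g)
  # posterior and marginal log-likelihood at the final parameter values
  pe <- .posterior_engine_cpp(pat$Rp, cls$PIc, res$log_prior, s, g, clip)
  loglik <- sum(pat$w * as.numeric(pe$loglik))
  sg_warn <- s + g >= 1
  if (any(sg_warn)) {
    warning("slip + guess >= 1 for exercise(s) ",
            paste(req$exercise_ids[sg_warn], collapse = ", "),
            " (monitored, not enforced)")
  }
  n_params <- if (prior_mode == "empirical") 2 * E + (N - 1) else 2 * E
  ic <- information_criteria(loglik, n_params, U)
  posterior <- NULL
  if (store_posterior == "always" ||
      (store_posterior == "auto" && U * N <= 2e7)) {
    posterior <- expand_posterior(pe$post, pat$idx, cls)
  }
  structure(list(
    item_params = data.frame(exercise_id = req$exercise_ids, slip = s,
                             guess = g, sg_warn = sg_warn,
                             stringsAsFactors = FALSE),
    prior_mode = prior_mode,
    prior_class_mass = exp(as.numeric(res$log_prior)),
    loglik = loglik,
    loglik_trace = as.numeric(res$loglik_trace),
    delta_trace = as.numeric(res$delta_trace),
    n_iter = res$n_iter, converged = res$converged,
    n_params = n_params, AIC = ic$AIC, BIC = ic$BIC,
    U = U, E = E, K = req$K, L_max = req$L_max, N = N,
    posterior = posterior,
    req = req,
    reduced = list(cls = cls, patterns = pat, post = pe$post,
                   loglik_pattern = as.numeric(pe$loglik),
                   log_prior = as.numeric(res$log_prior)),
    config = list(prior_mode = prior_mode, tol_param = tol_param,
                  tol_loglik = tol_loglik, max_iter = max_iter, clip = clip,
                  init = init, s_init = s_init, g_init = g_init, seed = seed,
                  block = block)
  ), class = "ekc_fit")
}

# Expand a pattern x class posterior to the full learner x profile matrix
# (small problems only): each profile in a class shares the class posterior
# split uniformly over the class (uniform-within-class priors).
expand_posterior <- function(post_red, idx, cls) {
  sp_profiles <- enumerate_profiles(cls$K, cls$L_max)$profiles
  ci <- class_of_profiles(cls, sp_profiles)
  full <- post_red[, ci, drop = FALSE] /
    rep(cls$csize[ci], each = nrow(post_red))
  full[idx, , drop = FALSE]
}

# Reorder the requirement map to match the response matrix columns.
align_requirements <- function(responses, req) {
  ids <- colnames(responses)
  if (is.null(ids)) {
    if (ncol(responses) != req$E) {
      stop("responses have ", ncol(responses), " columns but the map has E = ", req$E)
    }
    return(req)
  }
  if (!all(ids %in% req$exercise_ids)) {
    stop("unknown exercise id(s) in responses: ",
         paste(setdiff(ids, req$exercise_ids), collapse = ", "))
  }
  if (identical(ids, req$exercise_ids)) return(req)
  requirement_map(req$a[ids, , drop = FALSE], exercise_ids = ids,
                  concept_ids = req$concept_ids, L_max = req$L_max)
}

#' @export
print.ekc_fit <- function(x, ...) {
  cat(sprintf(
    "EM fit: U = %d learners, E = %d exercises, K = %d concepts (N = %s profiles)\n",
    x$U, x$E, x$K, format(x$N, big.mark = ",")))
  cat(sprintf("  prior: %s | iterations: %d (%s)\n", x$prior_mode, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  loglik = %.2f | AIC = %.1f | BIC = %.1f (n_params = %d)\n",
              x$loglik, x$AIC, x$BIC, x$n_params))
  cat(sprintf("  slip  in [%.3f, %.3f], guess in [%.3f, %.3f]\n",
              min(x$item_params$slip), max(x$item_params$slip),
              min(x$item_params$guess), max(x$item_params$guess)))
  invisible(x)
}
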