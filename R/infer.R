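#' MAP candidate set of a posterior row
#'
#' All profiles whose posterior is within a relative tolerance of the row
#' maximum.  Exact ties arise systematically whenever the requirement map
#' leaves some levels indistinguishable (profiles with identical ideal
#' responses have identical likelihood), so the candidate set rather than a
#' single argmax is the faithful point summary.
#'
#' @param post_row normalized posterior vector of length `N`.
#' @param space matching [enumerate_profiles()] object.
#' @param tol relative tie tolerance (default `1e-9`).
#' @return integer vector of profile indices attaining the maximum.
#' @export
map_candidates <- function(post_row, space, tol = 1e-9) {
  stopifnot(inherits(space, "profile_space"), length(post_row) == space$N)
  mx <- max(post_row)
  which(post_row >= mx * (1 - tol))
}

#' Point levels from a candidate set
#'
#' The expected level per concept is the unweighted mean over the tied
#' candidates; the reported level rounds it half-up and clips into
#' `[0, L_max]`.
#'
#' @param candidates integer profile indices ([map_candidates()]).
#' @param space matching [enumerate_profiles()] object.
#' @return list with `expected_levels` (numeric) and `reported_levels`
#'   (integer), both length `K`.
#' @export
reported_levels <- function(candidates, space) {
  stopifnot(length(candidates) >= 1)
  prof <- space$profiles[candidates, , drop = FALSE]
  expected <- colMeans(prof)
  reported <- as.integer(pmin(pmax(floor(expected + 0.5), 0), space$L_max))
  list(expected_levels = expected, reported_levels = reported)
}

#' Marginal posterior over the ordered levels of one concept
#'
#' `p_k(l) = sum over profiles with beta_k = l of the posterior`.
#'
#' @inheritParams map_candidates
#' @param k concept index.
#' @return numeric vector of length `L_max + 1` (levels `0:L_max`), sums
#'   to 1.
#' @export
marginal_level_posterior <- function(post_row, space, k) {
  stopifnot(k >= 1, k <= space$K)
  lev <- space$profiles[, k]
  vapply(0:space$L_max, function(l) sum(post_row[lev == l]), 0)
}

#' Mode-anchored credible interval on an ordinal marginal
#'
#' Smallest contiguous level interval that contains the marginal mode and
#' holds at least `mass` posterior probability, built by greedily extending
#' toward the neighbor with more mass (ties extend downward).
#'
#' @param marginal normalized vector over levels `0:(length(marginal)-1)`.
#' @param mass target coverage (default 0.95).
#' @return integer `c(lo, hi)` in level units.
#' @examples
#' credible_interval(c(0.02, 0.03, 0.50, 0.40, 0.05, 0, 0))  # [2, 4]
#' @export
credible_interval <- function(marginal, mass = 0.95) {
  L <- length(marginal) - 1
  lo <- hi <- which.max(marginal) - 1L
  got <- marginal[lo + 1]
  while (got < mass && (lo > 0 || hi < L)) {
    left <- if (lo > 0) marginal[lo] else -Inf
    right <- if (hi < L) marginal[hi + 2] else -Inf
    if (right > left) {
      hi <- hi + 1L
      got <- got + marginal[hi + 1]
    } else {
      lo <- lo - 1L
      got <- got + marginal[lo + 1]
    }
  }
  c(lo, hi)
}

#' Boundary-item identifiability gate for a concept
#'
#' Distinguishing adjacent levels `c` and `c+1` for a concept requires items
#' that pin each side of the boundary.  The gate counts the items requiring
#' the concept at exactly each queried level and is `"Strong"` when every
#' count is at least 2.
#'
#' @param req a [requirement_map()].
#' @param k concept index.
#' @param levels the queried levels (default `c(2, 3)`,
#'   Understanding/Applying).
#' @return list with `gate` (`"Strong"`/`"Weak"`) and `nq` (named counts).
#' @export
identifiability_gate <- function(req, k, levels = c(2, 3)) {
  stopifnot(inherits(req, "requirement_map"), k >= 1, k <= req$K)
  nq <- vapply(levels, function(c) sum(req$a[, k] == c), 0L)
  names(nq) <- paste0("nq", levels)
  list(gate = if (all(nq >= 2)) "Strong" else "Weak", nq = nq)
}

#' Adjacent-level separability diagnostics for one concept
#'
#' Restricts to learners whose reported level for concept `k` lies in
#' `levels` and summarizes how well the posterior separates the two levels:
#' the share whose credible interval spans both (`indet_rate`), the median
#' absolute log-odds `|log(p(l1)/p(l2))|`, and the share with
#' `|p(l1) - p(l2)| < delta`.
#'
#' @param diagnosis an `ekc_diagnosis` from [diagnose()], or a list with
#'   elements `reported` (`U x K`), `marginals` (`U x K x (L_max+1)`), and
#'   `ci` (`U x K x 2`).
#' @param req a [requirement_map()].
#' @param k concept index.
#' @param levels adjacent level pair (default `c(2, 3)`).
#' @param delta near-tie threshold on the marginal probability difference
#'   (strict inequality; default 0.10).
#' @return one-row data.frame with columns `concept_id`, `gate`, `nq<l1>`,
#'   `nq<l2>`, `n_pair`, `indet_rate`, `median_abs_log_odds`,
#'   `p_delta_small`.  With no eligible learners the rates are `NA` and
#'   `n_pair = 0`.
#' @export
separability_diagnostics <- function(diagnosis, req, k, levels = c(2, 3),
                                     delta = 0.10) {
  gate <- identifiability_gate(req, k, levels)
  rep_k <- diagnosis$reported[, k]
  sel <- rep_k %in% levels
  n_pair <- sum(sel)
  if (n_pair == 0) {
    out <- data.frame(concept_id = req$concept_ids[k], gate = gate$gate,
                      n_pair = 0L, indet_rate = NA_real_,
                      median_abs_log_odds = NA_real_,
                      p_delta_small = NA_real_, stringsAsFactors = FALSE)
  } else {
    p1 <- pmax(diagnosis$marginals[sel, k, levels[1] + 1], 1e-300)
    p2 <- pmax(diagnosis$marginals[sel, k, levels[2] + 1], 1e-300)
    lo <- diagnosis$ci[sel, k, 1]
    hi <- diagnosis$ci[sel, k, 2]
    out <- data.frame(
      concept_id = req$concept_ids[k], gate = gate$gate, n_pair = n_pair,
      indet_rate = mean(lo <= levels[1] & hi >= levels[2]),
      median_abs_log_odds = stats::median(abs(log(p1 / p2))),
      p_delta_small = mean(abs(p1 - p2) < delta), stringsAsFactors = FALSE)
  }
  out[[names(gate$nq)[1]]] <- gate$nq[[1]]
  out[[names(gate$nq)[2]]] <- gate$nq[[2]]
  out[, c("concept_id", "gate", names(gate$nq), "n_pair", "indet_rate",
          "median_abs_log_odds", "p_delta_small")]
}

#' Diagnose learner knowledge-cognition profiles
#'
#' Full inference pipeline: fits the slip/guess parameters by EM (unless a
#' fit is supplied), computes every learner's posterior over ordered
#' profiles, and summarizes it as MAP candidate sets, expectation-rounded
#' reported levels, per-concept marginal level posteriors, credible
#' intervals, and per-concept separability diagnostics.
#'
#' @inheritParams fit_em
#' @param fit optional pre-computed [fit_em()] result for these responses.
#' @param ci_mass credible-interval coverage (default 0.95).
#' @param sep_levels adjacent level pair for the separability report.
#' @param compute_ci set `FALSE` to skip credible intervals and the
#'   separability report (faster for large simulation sweeps).
#' @param ... further arguments passed to [fit_em()].
#' @return Object of class `ekc_diagnosis`: list with `reported` and
#'   `expected` (`U x K` matrices), `marginals` (`U x K x (L_max+1)` array),
#'   `ci` (`U x K x 2` array), `n_candidates`, `map_profile` (`U x K`
#'   lowest-index representative), `separability` (data.frame, one row per
#'   concept), and `fit`.
#' @export
diagnose <- function(responses, req, fit = NULL, ci_mass = 0.95,
                     sep_levels = c(2, 3), compute_ci = TRUE, ...) {
  if (is.null(fit)) fit <- fit_em(responses, req, ...)
  req <- fit$req
  cls <- fit$reduced$cls
  pat <- fit$reduced$patterns
  post <- fit$reduced$post                 # D x M class posterior
  L1 <- cls$L_max + 1
  D <- nrow(post)
  K <- cls$K

  # per-profile posterior within each class is post/csize (uniform split)
  pp <- post / rep(cls$csize, each = D)
  mi <- max.col(pp, ties.method = "first")
  mx <- pp[cbind(seq_len(D), mi)]
  cand <- pp >= mx * (1 - 1e-9)
  cand_n <- as.vector(cand %*% cls$csize)            # number of tied profiles
  expected <- (cand %*% (cls$cmean * cls$csize)) / cand_n
  reported <- matrix(as.integer(pmin(pmax(floor(expected + 0.5), 0), cls$L_max)),
                     D, K)
  # lowest-index representative: box lower corner of the first tied class
  first_cand <- max.col(cand, ties.method = "first")
  map_profile <- cls$clo[first_cand, , drop = FALSE]
  marg <- post %*% cls$S                              # D x K*(L_max+1)

  ci <- NULL
  if (compute_ci) {
    ci <- array(NA_integer_, c(D, K, 2))
    for (k in seq_len(K)) {
      mk <- marg[, (k - 1) * L1 + seq_len(L1), drop = FALSE]
      for (d in seq_len(D)) {
        ci[d, k, ] <- credible_interval(mk[d, ], ci_mass)
      }
    }
  }

  # expand patterns back to learners; marg columns are concept-major blocks
  idx <- pat$idx
  marg_arr <- aperm(array(marg[idx, , drop = FALSE],
                          c(length(idx), L1, K)), c(1, 3, 2))
  out <- list(
    learner_ids = if (!is.null(responses)) rownames(responses) else NULL,
    reported = reported[idx, , drop = FALSE],
    expected = expected[idx, , drop = FALSE],
    marginals = marg_arr,
    ci = if (compute_ci) ci[idx, , , drop = FALSE] else NULL,
    n_candidates = cand_n[idx],
    map_profile = map_profile[idx, , drop = FALSE],
    concept_ids = req$concept_ids,
    fit = fit
  )
  dimnames(out$marginals) <- list(NULL, req$concept_ids, 0:cls$L_max)
  colnames(out$reported) <- colnames(out$expected) <-
    colnames(out$map_profile) <- req$concept_ids
  class(out) <- "ekc_diagnosis"
  if (compute_ci && max(sep_levels) <= cls$L_max) {
    out$separability <- do.call(rbind, lapply(seq_len(K), function(k) {
      separability_diagnostics(out, req, k, sep_levels)
    }))
  }
  out
}

#' @export
print.ekc_diagnosis <- function(x, ...) {
  U <- nrow(x$reported)
  cat(sprintf("Diagnosis of %d learners on %d concepts (levels 0..%d)\n",
              U, ncol(x$reported), x$fit$L_max))
  cat("Reported level distribution per concept:\n")
  print(apply(x$reported, 2, function(v) table(factor(v, 0:x$fit$L_max))))
  if (!is.null(x$separability)) {
    cat("Adjacent-level separability:\n")
    print(x$separability, row.names = FALSE)
  }
  invisible(x)
}
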