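#' Krippendorff's alpha for ordinal (or interval) ratings
#'
#' Chance-corrected agreement via the coincidence-matrix formulation,
#' `alpha = 1 - D_o / D_e`, supporting missing ratings natively (units with
#' fewer than two ratings drop out).  The ordinal distance between
#' categories `c < k` is the squared sum of intervening coincidence
#' marginals, `(sum_{g=c}^{k} n_g - (n_c + n_k)/2)^2`; the interval metric
#' `(c - k)^2` is kept as a hand-checkable cross-check.
#'
#' @param ratings items x raters matrix of ordinal levels; `NA` = missing.
#' @param metric `"ordinal"` (default) or `"interval"`.
#' @return numeric alpha.  When the ratings show no variation the expected
#'   disagreement is zero and the coefficient is degenerate: `NA` is
#'   returned with attribute `degenerate = TRUE`.
#' @export
krippendorff_alpha <- function(ratings, metric = c("ordinal", "interval")) {
  metric <- match.arg(metric)
  ratings <- as.matrix(ratings)
  cats <- sort(unique(as.vector(ratings[!is.na(ratings)])))
  C <- length(cats)
  o <- matrix(0, C, C)
  for (u in seq_len(nrow(ratings))) {
    v <- ratings[u, ]
    v <- v[!is.na(v)]
    m <- length(v)
    if (m < 2) next
    ci <- match(v, cats)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) o[ci[i], ci[j]] <- o[ci[i], ci[j]] + 1 / (m - 1)
      }
    }
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  if (n < 2) stop("need at least 2 pairable ratings")
  delta2 <- matrix(0, C, C)
  for (a in seq_len(C)) {
    for (b in seq_len(C)) {
      if (a == b) next
      delta2[a, b] <- if (metric == "interval") {
        (cats[a] - cats[b])^2
      } else {
        lo <- min(a, b); hi <- max(a, b)
        (sum(n_c[lo:hi]) - (n_c[a] + n_c[b]) / 2)^2
      }
    }
  }
  D_o <- sum(o * delta2) / n
  D_e <- sum(outer(n_c, n_c) * delta2) / (n * (n - 1))
  if (D_e == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  1 - D_o / D_e
}

#' Quadratic weighted kappa between two raters
#'
#' `kappa_w = 1 - sum(w * O) / sum(w * E)` with weights
#' `w_ij = (i - j)^2 / (C - 1)^2`, observed cell proportions `O` and
#' expected proportions `E` from the marginal products.
#'
#' @param r1,r2 equal-length ordinal rating vectors (pairs with missing
#'   values are dropped).
#' @param categories ordered category set (default `0:6`).
#' @return numeric kappa in `[-1, 1]`.  If both raters are constant and
#'   equal, returns 1 with attribute `degenerate = TRUE`.
#' @export
quadratic_weighted_kappa <- function(r1, r2, categories = 0:6) {
  if (length(r1) != length(r2)) stop("rating vectors differ in length")
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- r1[keep]; r2 <- r2[keep]
  if (!all(c(r1, r2) %in% categories)) {
    stop("ratings outside the declared category set")
  }
  C <- length(categories)
  O <- table(factor(r1, categories), factor(r2, categories)) / length(r1)
  p1 <- rowSums(O); p2 <- colSums(O)
  Emat <- outer(p1, p2)
  w <- outer(seq_len(C), seq_len(C), function(i, j) (i - j)^2 / (C - 1)^2)
  den <- sum(w * Emat)
  if (den == 0) {
    return(structure(if (all(r1 == r2)) 1 else NA_real_, degenerate = TRUE))
  }
  1 - sum(w * O) / den
}

#' Exact and within-one-level agreement rates
#'
#' @param ratings complete items x raters matrix.
#' @return list with `exact_all` (share of items where all raters coincide)
#'   and `within_one` (share where the rating range is at most one level).
#' @export
agreement_rates <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("agreement rates require complete ratings")
  rng <- apply(ratings, 1, function(v) max(v) - min(v))
  list(exact_all = mean(rng == 0), within_one = mean(rng <= 1))
}

#' Nonparametric bootstrap confidence interval over items
#'
#' Items (the rated exercise-knowledge units) are the sampled population;
#' raters are fixed.  Resamples item rows with replacement, recomputes the
#' statistic, and returns the percentile interval.  Resamples on which the
#' statistic is undefined (`NA`) are redrawn and counted.
#'
#' @param statistic function mapping a ratings matrix to a scalar.
#' @param ratings items x raters matrix.
#' @param n_boot number of resamples (default 1000).
#' @param level coverage (default 0.95).
#' @param seed optional seed.
#' @return numeric `c(lo, hi)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(statistic, ratings, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  with_seed(seed, {
    vals <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      v <- NA_real_
      tries <- 0L
      while (is.na(v) && tries < 100L) {
        v <- suppressWarnings(
          statistic(ratings[sample.int(n, n, replace = TRUE), , drop = FALSE]))
        tries <- tries + 1L
      }
      redrawn <- redrawn + tries - 1L
      vals[b] <- v
    }
    ci <- unname(quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE))
    structure(ci, n_redrawn = redrawn)
  })
}

#' Inter-rater reliability report for ordinal annotations
#'
#' The pre-adjudication reliability battery for level-tagged item banks:
#' ordinal Krippendorff's alpha with bootstrap CI, all pairwise quadratic
#' weighted kappas with CIs (per pair and on their mean), and exact /
#' within-one-level agreement.
#'
#' @param ratings items x raters matrix (column names identify raters).
#' @param categories ordered category set (default `0:6`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level CI coverage (default 0.95).
#' @param seed seed for the bootstrap.
#' @return list of class `irr_report`.
#' @export
irr_report <- function(ratings, categories = 0:6, n_boot = 1000,
                       level = 0.95, seed = 1L) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2) stop("need at least 2 raters")
  raters <- colnames(ratings) %||% paste0("R", seq_len(ncol(ratings)))
  alpha <- krippendorff_alpha(ratings)
  alpha_ci <- bootstrap_ci(function(x) krippendorff_alpha(x), ratings,
                           n_boot, level, seed)
  pairs <- utils::combn(ncol(ratings), 2)
  qwk <- data.frame(pair = apply(pairs, 2, function(p)
    paste(raters[p], collapse = "-")), kappa = NA_real_,
    ci_lo = NA_real_, ci_hi = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    p <- pairs[, j]
    qwk$kappa[j] <- quadratic_weighted_kappa(ratings[, p[1]], ratings[, p[2]],
                                             categories)
    ci <- bootstrap_ci(function(x)
      quadratic_weighted_kappa(x[, 1], x[, 2], categories),
      ratings[, p, drop = FALSE], n_boot, level, seed + j)
    qwk$ci_lo[j] <- ci[1]; qwk$ci_hi[j] <- ci[2]
  }
  mean_ci <- bootstrap_ci(function(x) {
    mean(apply(pairs, 2, function(p)
      quadratic_weighted_kappa(x[, p[1]], x[, p[2]], categories)))
  }, ratings, n_boot, level, seed + ncol(pairs) + 1L)
  agr <- if (any(is.na(ratings))) {
    list(exact_all = NA_real_, within_one = NA_real_)
  } else {
    agreement_rates(ratings)
  }
  structure(list(alpha = as.numeric(alpha), alpha_ci = as.numeric(alpha_ci),
                 pairwise_qwk = qwk, qwk_mean = mean(qwk$kappa),
                 qwk_mean_ci = as.numeric(mean_ci),
                 exact_agreement_all = agr$exact_all,
                 within_one_agreement = agr$within_one,
                 n_items = nrow(ratings), n_raters = ncol(ratings),
                 n_boot = n_boot, level = level, seed = seed),
            class = "irr_report")
}

#' @export
print.irr_report <- function(x, ...) {
  cat(sprintf("Inter-rater reliability (%d items, %d raters):\n",
              x$n_items, x$n_raters))
  cat(sprintf("  ordinal Krippendorff alpha = %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$alpha, 100 * x$level, x$alpha_ci[1], x$alpha_ci[2]))
  for (j in seq_len(nrow(x$pairwise_qwk))) {
    cat(sprintf("  QWK %s = %.3f (CI %.3f-%.3f)\n", x$pairwise_qwk$pair[j],
                x$pairwise_qwk$kappa[j], x$pairwise_qwk$ci_lo[j],
                x$pairwise_qwk$ci_hi[j]))
  }
  cat(sprintf("  QWK mean = %.3f (CI %.3f-%.3f)\n", x$qwk_mean,
              x$qwk_mean_ci[1], x$qwk_mean_ci[2]))
  cat(sprintf("  exact agreement (all raters) = %.3f; within +/-1 level = %.3f\n",
              x$exact_agreement_all, x$within_one_agreement))
  invisible(x)
}
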