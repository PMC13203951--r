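#' Item-level maximum required cognitive level
#'
#' `c_max` summarizes an item's intended cognitive demand as the maximum
#' required level over all concepts it involves; items requiring nothing get
#' 0 and are flagged.
#'
#' @param req a [requirement_map()].
#' @return integer vector of length `E` with attribute `all_zero` marking
#'   rows without requirements.
#' @export
item_cmax <- function(req) {
  stopifnot(inherits(req, "requirement_map"))
  cmax <- apply(req$a, 1, max)
  structure(as.integer(cmax), names = req$exercise_ids,
            all_zero = which(cmax == 0))
}

#' Crosswalk from ordered cognitive levels to broad cognitive domains
#'
#' Levels 1-2 map to Knowing, 3-4 to Applying, 5-6 to Reasoning; level 0
#' (nothing required) has no domain and is returned as `NA` with a warning.
#'
#' @param level integer vector of levels in `0:6`.
#' @return factor with levels `Knowing < Applying < Reasoning` (ordered).
#' @export
bloom_to_timss <- function(level) {
  if (any(!level %in% 0:6)) stop("levels must be integers in 0..6")
  if (any(level == 0)) warning("level 0 has no domain; returned as NA")
  out <- cut(ifelse(level == 0, NA_real_, as.numeric(level)), c(0, 2, 4, 6),
             labels = c("Knowing", "Applying", "Reasoning"))
  factor(out, levels = c("Knowing", "Applying", "Reasoning"), ordered = TRUE)
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Mid-rank H statistic with the tie correction
#' `H = H_raw / (1 - sum(t^3 - t) / (n^3 - n))` and a chi-squared p-value on
#' `k - 1` degrees of freedom (delegated to [stats::kruskal.test()], which
#' implements exactly this form).
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `H`, `p`, `df`, `n`, `k`, and `degenerate` (TRUE when
#'   all values are tied everywhere, where H is undefined).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1) {
    return(list(H = NA_real_, p = NA_real_, df = nlevels(groups) - 1L,
                n = length(values), k = nlevels(groups), degenerate = TRUE))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter), n = length(values), k = nlevels(groups),
       degenerate = FALSE)
}

#' Rank epsilon-squared effect size
#'
#' The nonparametric effect-size index `(H - k + 1) / (n - k)` for a
#' Kruskal-Wallis statistic `H` over `k` groups and `n` observations.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n total observations.
#' @param k number of groups.
#' @return numeric effect size.
#' @examples
#' epsilon_squared(15.017, 19, 3)  # 0.814
#' @export
epsilon_squared <- function(H, n, k) {
  if (n <= k) stop("epsilon-squared undefined for n <= k")
  (H - k + 1) / (n - k)
}

#' Tie-aware Spearman trend test
#'
#' Spearman's rho as the Pearson correlation of mid-ranks, with a two-sided
#' p-value from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom.  For `|rho| = 1` the t statistic diverges and
#' the p-value is reported at the double floor with `p_floored = TRUE`; zero
#' variance in either vector yields an undefined flag.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list with `rho`, `p`, `n`, `p_floored`, `degenerate`.
#' @export
spearman_trend <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("vectors differ in length")
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, p_floored = FALSE,
                degenerate = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    return(list(rho = sign(rho), p = .Machine$double.xmin, n = n,
                p_floored = TRUE, degenerate = FALSE))
  }
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), n - 2), n = n, p_floored = FALSE,
       degenerate = FALSE)
}

#' Construct-validity report against external cognitive-domain labels
#'
#' Checks whether the ordered requirement levels encode the intended
#' cognitive demand: per-domain distributions of `c_max` (median and IQR,
#' linear-interpolation quartiles) and mean proportion-correct, a
#' tie-corrected Kruskal-Wallis omnibus test with rank epsilon-squared, a
#' Spearman trend of the ordered domain index (Knowing = 1, Applying = 2,
#' Reasoning = 3) against `c_max`, the crosswalk concordance between
#' [bloom_to_timss()]`(c_max)` and the given labels, and (when
#' proportion-correct is supplied) the difficulty checks: Spearman of
#' `c_max` vs proportion-correct and Kruskal-Wallis of proportion-correct
#' across domains.
#'
#' @param req a [requirement_map()].
#' @param domains per-exercise labels in
#'   `c("Knowing", "Applying", "Reasoning")`.
#' @param p_correct optional per-exercise proportion-correct in `[0, 1]`.
#' @return list of class `validity_report`.
#' @export
validity_report <- function(req, domains, p_correct = NULL) {
  cmax <- as.integer(item_cmax(req))
  domains <- factor(domains, levels = c("Knowing", "Applying", "Reasoning"))
  if (any(is.na(domains))) stop("every exercise needs a valid domain label")
  if (length(domains) != req$E) stop("one domain label per exercise required")
  if (!is.null(p_correct)) {
    stopifnot(length(p_correct) == req$E, all(p_correct >= 0 & p_correct <= 1))
  }
  by_domain <- do.call(rbind, lapply(levels(domains), function(d) {
    sel <- domains == d
    if (!any(sel)) {
      return(data.frame(domain = d, n_items = 0L, cmax_median = NA_real_,
                        cmax_q1 = NA_real_, cmax_q3 = NA_real_,
                        p_correct_mean = NA_real_))
    }
    q <- quantile(cmax[sel], c(0.25, 0.5, 0.75), type = 7)
    data.frame(domain = d, n_items = sum(sel), cmax_median = unname(q[2]),
               cmax_q1 = unname(q[1]), cmax_q3 = unname(q[3]),
               p_correct_mean = if (is.null(p_correct)) NA_real_
                                else mean(p_correct[sel]))
  }))
  present <- droplevels(domains)
  single_domain <- nlevels(present) < 2
  kw <- eps2 <- trend <- NULL
  if (!single_domain) {
    kw <- kruskal_wallis(cmax, present)
    eps2 <- if (!kw$degenerate) epsilon_squared(kw$H, kw$n, kw$k) else NA_real_
    trend <- spearman_trend(as.integer(domains), cmax)
  }
  crosswalk <- bloom_to_timss(pmax(cmax, 1L))
  concordance <- table(mapped = crosswalk, labeled = domains)
  difficulty <- NULL
  if (!is.null(p_correct)) {
    difficulty <- list(
      cmax_vs_p = spearman_trend(cmax, p_correct),
      p_across_domains = if (!single_domain)
        kruskal_wallis(p_correct, present) else NULL)
  }
  structure(list(by_domain = by_domain, kruskal = kw, epsilon_sq = eps2,
                 trend = trend, concordance = concordance,
                 concordance_rate = mean(as.character(crosswalk) ==
                                           as.character(domains)),
                 difficulty = difficulty, single_domain = single_domain,
                 cmax = cmax, domains = domains, p_correct = p_correct),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Construct validity of ordered requirement levels\n")
  print(x$by_domain, row.names = FALSE)
  if (!x$single_domain) {
    cat(sprintf("  Kruskal-Wallis H = %.3f, p = %.3g, epsilon^2 = %.3f\n",
                x$kruskal$H, x$kruskal$p, x$epsilon_sq))
    cat(sprintf("  Spearman trend rho = %.3f, p = %.3g%s\n", x$trend$rho,
                x$trend$p, if (x$trend$p_floored) " (p at floor)" else ""))
  } else {
    cat("  single domain present: trend tests skipped\n")
  }
  cat(sprintf("  crosswalk concordance = %.3f\n", x$concordance_rate))
  if (!is.null(x$difficulty)) {
    d <- x$difficulty$cmax_vs_p
    cat(sprintf("  c_max vs proportion-correct: rho = %.3f, p = %.3g\n",
                d$rho, d$p))
  }
  invisible(x)
}
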