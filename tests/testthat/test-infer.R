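test_that("MAP candidate sets collect all tied maxima", {
  sp <- enumerate_profiles(1, 2)
  expect_equal(map_candidates(c(0, 1, 0), sp), 2L)
  expect_equal(map_candidates(c(0.5, 0.5, 0), sp), c(1L, 2L))
  expect_equal(map_candidates(c(0.165, 0.742, 0.093), sp), 2L)
  # every candidate beats every non-candidate
  set.seed(41)
  sp2 <- enumerate_profiles(2, 2)
  for (i in 1:10) {
    p <- runif(sp2$N)
    p <- p / sum(p)
    cand <- map_candidates(p, sp2)
    if (length(cand) < sp2$N) {
      expect_true(min(p[cand]) >= max(p[-cand]))
    }
  }
})

test_that("expectation rounding over candidates uses half-up on the mean", {
  sp <- enumerate_profiles(2, 6)
  one <- reported_levels(profile_to_index(sp, c(2, 3)), sp)
  expect_equal(one$reported_levels, c(2L, 3L))

  two <- reported_levels(c(profile_to_index(sp, c(2, 3)),
                           profile_to_index(sp, c(3, 3))), sp)
  expect_equal(two$expected_levels, c(2.5, 3))
  expect_equal(two$reported_levels, c(3L, 3L))

  far <- reported_levels(c(profile_to_index(sp, c(0, 6)),
                           profile_to_index(sp, c(6, 0))), sp)
  expect_equal(far$expected_levels, c(3, 3))
  expect_equal(far$reported_levels, c(3L, 3L))
})

test_that("marginal level posteriors group the full posterior correctly", {
  sp <- enumerate_profiles(2, 6)
  point <- numeric(sp$N)
  point[profile_to_index(sp, c(4, 1))] <- 1
  expect_equal(marginal_level_posterior(point, sp, 1),
               c(0, 0, 0, 0, 1, 0, 0))
  expect_equal(marginal_level_posterior(point, sp, 2),
               c(0, 1, 0, 0, 0, 0, 0))

  unif <- rep(1 / sp$N, sp$N)
  for (k in 1:2) {
    expect_equal(marginal_level_posterior(unif, sp, k), rep(1 / 7, 7))
  }

  set.seed(43)
  p <- runif(sp$N)
  p <- p / sum(p)
  for (k in 1:2) {
    naive <- vapply(0:6, function(l)
      sum(p[sp$profiles[, k] == l]), 0)
    m <- marginal_level_posterior(p, sp, k)
    expect_equal(m, naive, tolerance = 1e-12)
    expect_equal(sum(m), 1, tolerance = 1e-10)
  }
})

test_that("credible intervals are mode-anchored, greedy, and cover the mass", {
  expect_equal(credible_interval(c(0, 0, 0, 1, 0, 0, 0)), c(3, 3))
  expect_equal(credible_interval(c(0.02, 0.03, 0.50, 0.40, 0.05, 0, 0)),
               c(2, 4))
  expect_equal(credible_interval(rep(1 / 7, 7)), c(0, 6))
  set.seed(47)
  for (i in 1:20) {
    m <- runif(7)
    m <- m / sum(m)
    ci <- credible_interval(m)
    mode <- which.max(m) - 1
    expect_true(ci[1] <= mode && mode <= ci[2])
    expect_gte(sum(m[(ci[1] + 1):(ci[2] + 1)]), 0.95 - 1e-12)
  }
})

test_that("the identifiability gate counts boundary items", {
  a <- matrix(0L, 7, 2)
  a[, 1] <- c(2L, 2L, 2L, 3L, 3L, 3L, 1L)
  req <- requirement_map(a)
  g1 <- identifiability_gate(req, 1)
  expect_equal(g1$gate, "Strong")
  expect_equal(unname(g1$nq), c(3L, 3L))
  a2 <- matrix(c(rep(2L, 6), 3L), 7, 1)
  g2 <- identifiability_gate(requirement_map(a2), 1)
  expect_equal(g2$gate, "Weak")
  expect_equal(unname(g2$nq), c(6L, 1L))
  g3 <- identifiability_gate(req, 2)
  expect_equal(g3$gate, "Weak")
  expect_equal(unname(g3$nq), c(0L, 0L))
})

test_that("separability diagnostics summarize closed-form cohorts correctly", {
  req <- requirement_map(matrix(c(2L, 2L, 3L, 3L), 4, 1))
  mk_diag <- function(p2, p3, lo, hi, rep_level, n = 10) {
    marg <- array(0, c(n, 1, 7))
    marg[, 1, 3] <- p2
    marg[, 1, 4] <- p3
    marg[, 1, 1] <- 1 - p2 - p3
    ci <- array(NA_integer_, c(n, 1, 2))
    ci[, 1, 1] <- lo
    ci[, 1, 2] <- hi
    list(reported = matrix(rep_level, n, 1), marginals = marg, ci = ci)
  }
  confident <- separability_diagnostics(mk_diag(0.99, 0.01, 2, 2, 2L), req, 1)
  expect_equal(confident$gate, "Strong")
  expect_equal(confident$indet_rate, 0)
  expect_equal(confident$median_abs_log_odds, log(99), tolerance = 1e-12)
  expect_equal(confident$p_delta_small, 0)

  torn <- separability_diagnostics(mk_diag(0.5, 0.5, 2, 3, 3L), req, 1)
  expect_equal(torn$indet_rate, 1)
  expect_equal(torn$median_abs_log_odds, 0)
  expect_equal(torn$p_delta_small, 1)

  empty <- separability_diagnostics(mk_diag(0.9, 0.05, 0, 0, 0L), req, 1)
  expect_equal(empty$n_pair, 0L)
  expect_true(is.na(empty$indet_rate))

  # per-learner loop oracle on a mixed synthetic cohort
  set.seed(51)
  n <- 40
  p2 <- runif(n, 0, 0.6)
  p3 <- runif(n, 0, 1 - p2 - 0.01)
  lo <- sample(0:2, n, replace = TRUE)
  hi <- lo + sample(0:3, n, replace = TRUE)
  rep_level <- sample(1:4, n, replace = TRUE)
  d <- mk_diag(p2, p3, lo, hi, rep_level, n)
  out <- separability_diagnostics(d, req, 1)
  sel <- rep_level %in% c(2, 3)
  expect_equal(out$n_pair, sum(sel))
  expect_equal(out$indet_rate, mean(lo[sel] <= 2 & hi[sel] >= 3))
  expect_equal(out$median_abs_log_odds, median(abs(log(p2[sel] / p3[sel]))))
  expect_equal(out$p_delta_small, mean(abs(p2[sel] - p3[sel]) < 0.10))
})

test_that("diagnosis matches the full-space R path on a small instance", {
  inst <- random_instance(1100, U = 25, E = 5, K = 2, L_max = 2)
  fit <- suppressWarnings(fit_em(inst$R, inst$req, max_iter = 50,
                                 store_posterior = "always"))
  d <- diagnose(inst$R, inst$req, fit = fit)
  sp <- enumerate_profiles(2, inst$L_max)
  for (u in seq_len(nrow(inst$R))) {
    cand <- map_candidates(fit$posterior[u, ], sp)
    lv <- reported_levels(cand, sp)
    expect_equal(d$reported[u, ], lv$reported_levels,
                 ignore_attr = TRUE)
    expect_equal(d$expected[u, ], lv$expected_levels,
                 ignore_attr = TRUE, tolerance = 1e-9)
    for (k in 1:2) {
      expect_equal(d$marginals[u, k, 1:(inst$L_max + 1)],
                   marginal_level_posterior(fit$posterior[u, ], sp, k),
                   ignore_attr = TRUE, tolerance = 1e-9)
      expect_equal(
        d$ci[u, k, ],
        credible_interval(marginal_level_posterior(fit$posterior[u, ], sp, k)),
        ignore_attr = TRUE)
    }
  }
})

test_that("noiseless data recover identified profiles exactly", {
  # items pin every level boundary of both concepts, so all levels identified
  a <- as.matrix(expand.grid(1:3, 1:3))
  a <- rbind(cbind(1:3, 0L), cbind(0L, 1:3))
  req <- requirement_map(a, L_max = 3)
  sp <- enumerate_profiles(2, 3)
  profiles <- sp$profiles[rep(seq_len(sp$N), 4), ]
  R <- ideal_response_rows(req <- req, profiles)
  storage.mode(R) <- "integer"
  colnames(R) <- req$exercise_ids
  fit <- suppressWarnings(fit_em(R, req, s_init = 0.01, g_init = 0.01,
                                 max_iter = 200, store_posterior = "never"))
  d <- diagnose(R, req, fit = fit)
  expect_equal(unname(d$reported), unname(profiles))
  expect_lt(max(fit$item_params$slip), 0.01)
  expect_lt(max(fit$item_params$guess), 0.01)
})

test_that("binary requirements yield binary levels matching DINA MAP classification", {
  set.seed(61)
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1))
  alpha <- matrix(rbinom(200 * 2, 1, 0.5), 200, 2)
  eta <- t(apply(alpha, 1, function(al)
    apply(Q, 1, function(q) as.integer(all(al >= q)))))
  P <- t(apply(eta, 1, function(ee) ifelse(ee == 1, 0.9, 0.1)))
  R <- matrix(rbinom(length(P), 1, P), nrow(P), ncol(P))
  req <- requirement_map_from_q_matrix(Q)
  d <- suppressWarnings(diagnose(R, req, max_iter = 40))
  expect_true(all(d$reported %in% 0:1))
  # the independent DINA oracle must agree on unambiguous learners
  ora <- oracle_dina_em(R, Q, update_prior = TRUE, n_iter = 40)
  map_ora <- ora$B[max.col(ora$post, ties.method = "first"), ]
  unambiguous <- apply(ora$post, 1, max) > 0.6
  expect_true(mean(d$reported[unambiguous, ] ==
                     map_ora[unambiguous, ]) > 0.99)
})
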