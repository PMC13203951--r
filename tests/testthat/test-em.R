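# Small fixed instance used across several blocks: one concept, two
# exercises requiring levels 1 and 2, s = 0.1, g = 0.2, response (1, 0).
# Hand enumeration over the three profiles gives per-profile likelihoods
# 0.16, 0.72, 0.09.
k1_instance <- function() {
  req <- requirement_map(matrix(c(1L, 2L), 2, 1), L_max = 2)
  sp <- enumerate_profiles(1, 2)
  pim <- ideal_response_matrix(req, sp)
  params <- item_params(s = c(0.1, 0.1), g = c(0.2, 0.2))
  R <- matrix(c(1L, 0L), 1, 2)
  list(req = req, sp = sp, pim = pim, params = params, R = R)
}

test_that("response probabilities follow the slip/guess rule", {
  p <- response_probability(item_params(0.2, 0.3), matrix(1, 1, 1))
  expect_equal(p[1, 1], 0.8)
  p <- response_probability(item_params(0.2, 0.1), matrix(0, 1, 1))
  expect_equal(p[1, 1], 0.1)
  # noiseless limit: probabilities equal the ideal responses up to the floor
  pim <- rbind(c(1, 0), c(0, 1))
  p <- suppressWarnings(response_probability(item_params(c(0, 0), c(0, 0)), pim))
  expect_equal(p, pmin(pmax(pim, 1e-6), 1 - 1e-6))
})

test_that("log-likelihood matrix matches hand enumeration and the oracle", {
  inst <- k1_instance()
  P <- response_probability(inst$params, inst$pim)
  ll <- log_likelihood_matrix(inst$R, P)
  expect_equal(exp(ll[1, ]), c(0.16, 0.72, 0.09), tolerance = 1e-10)

  # all-correct responses at P = 0.5 give E * log 0.5 everywhere
  ll2 <- log_likelihood_matrix(matrix(1L, 2, 3), matrix(0.5, 4, 3))
  expect_true(all(abs(ll2 - 3 * log(0.5)) < 1e-12))

  set.seed(7)
  for (i in 1:5) {
    inst2 <- random_instance(200 + i, U = 3, E = 4)
    ora <- oracle_loglik(inst2$R, inst2$a, inst2$s, inst2$g, inst2$L_max)
    sp <- enumerate_profiles(2, inst2$L_max)
    P <- response_probability(item_params(inst2$s, inst2$g),
                              ideal_response_matrix(inst2$req, sp))
    expect_equal(unname(log_likelihood_matrix(inst2$R, P)), unname(ora),
                 tolerance = 1e-12)
  }
})

test_that("E step normalizes posteriors and matches the naive oracle", {
  inst <- k1_instance()
  P <- response_probability(inst$params, inst$pim)
  ll <- log_likelihood_matrix(inst$R, P)
  post <- e_step(ll, rep(1 / 3, 3))
  expect_equal(post[1, ], c(0.16, 0.72, 0.09) / 0.97, tolerance = 1e-10)

  # uniform likelihoods with uniform prior stay uniform
  expect_equal(e_step(matrix(0, 2, 4), rep(0.25, 4)),
               matrix(0.25, 2, 4))
  # a point-mass prior forces a point-mass posterior
  expect_equal(e_step(matrix(0, 1, 3), c(0, 1, 0))[1, ], c(0, 1, 0))

  set.seed(9)
  for (i in 1:5) {
    inst2 <- random_instance(300 + i, U = 6)
    ll <- oracle_loglik(inst2$R, inst2$a, inst2$s, inst2$g, inst2$L_max)
    prior <- runif(ncol(ll))
    prior <- prior / sum(prior)
    post <- e_step(ll, prior)
    expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-10)
    expect_equal(post, oracle_estep(ll, prior), tolerance = 1e-10)
  }
})

test_that("M step reduces to counting under a hard posterior and matches the oracle", {
  # two learners assigned with certainty to a profile with ideal response 0:
  # one answered correctly, so the guess estimate is 1/2
  pim <- matrix(c(0, 1), 2, 1)
  post <- matrix(c(1, 1, 0, 0), 2, 2)
  R <- matrix(c(1L, 0L), 2, 1)
  expect_warning(up <- m_step(R, post, pim), "degenerate")
  expect_equal(up$params$g, 0.5)

  # all mass on the ideal-response-1 profile and all correct: no slips
  post2 <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_warning(
    up2 <- m_step(matrix(1L, 2, 1), post2, pim,
                  prev_params = item_params(0.2, 0.2)),
    "degenerate")
  expect_equal(up2$params$s, 0)

  set.seed(13)
  for (i in 1:5) {
    inst <- random_instance(400 + i, U = 4)
    sp <- enumerate_profiles(2, inst$L_max)
    pim <- ideal_response_matrix(inst$req, sp)
    ll <- oracle_loglik(inst$R, inst$a, inst$s, inst$g, inst$L_max)
    post <- oracle_estep(ll, rep(1 / sp$N, sp$N))
    up <- m_step(inst$R, post, pim)
    ora <- oracle_mstep(inst$R, post, pim)
    expect_equal(up$params$s, ora$s, tolerance = 1e-10)
    expect_equal(up$params$g, ora$g, tolerance = 1e-10)
    expect_equal(up$counts$Z0 + up$counts$Z1, rep(nrow(inst$R), ncol(inst$R)),
                 tolerance = 1e-8)
  }
})

test_that("marginal log-likelihood is log-sum-exp stable and symmetric in learners", {
  inst <- k1_instance()
  P <- response_probability(inst$params, inst$pim)
  ll <- log_likelihood_matrix(inst$R, P)
  expect_equal(marginal_log_likelihood(ll, rep(1 / 3, 3)), log(0.97 / 3),
               tolerance = 1e-12)

  set.seed(17)
  inst2 <- random_instance(500, U = 6)
  ll <- oracle_loglik(inst2$R, inst2$a, inst2$s, inst2$g, inst2$L_max)
  prior <- rep(1 / ncol(ll), ncol(ll))
  expect_equal(marginal_log_likelihood(ll, prior),
               marginal_log_likelihood(ll[sample(6), ], prior))
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, 10, round(exp(2)))
  expect_equal(ic$AIC, 220)
  expect_equal(ic$BIC, -2 * -100 + 10 * log(round(exp(2))))
  ic0 <- information_criteria(-50, 0, 10)
  expect_equal(ic0$AIC, 100)
  expect_equal(ic0$BIC, 100)
  # BIC - AIC identity
  ic2 <- information_criteria(-123.4, 7, 55)
  expect_equal(ic2$BIC - ic2$AIC, 7 * (log(55) - 2))
})

test_that("one EM sweep of the compiled engine equals the composed R operations", {
  set.seed(21)
  inst <- random_instance(600, U = 10, E = 5)
  sp <- enumerate_profiles(2, inst$L_max)
  pim <- ideal_response_matrix(inst$req, sp)
  # one iteration via the exported R-surface operations
  params <- item_params(rep(0.2, 5), rep(0.2, 5))
  P <- response_probability(params, pim)
  ll <- log_likelihood_matrix(inst$R, P)
  post <- e_step(ll, rep(1 / sp$N, sp$N))
  up <- m_step(inst$R, post, pim)
  # one iteration via fit_em's engine
  fit <- suppressWarnings(fit_em(inst$R, inst$req, prior_mode = "uniform",
                                 max_iter = 1, store_posterior = "never"))
  expect_equal(fit$item_params$slip, up$params$s, tolerance = 1e-12)
  expect_equal(fit$item_params$guess, up$params$g, tolerance = 1e-12)
  expect_equal(fit$loglik_trace[1],
               marginal_log_likelihood(ll, rep(1 / sp$N, sp$N)),
               tolerance = 1e-8)
})

test_that("the EM log-likelihood trace is non-decreasing", {
  for (i in 1:6) {
    inst <- random_instance(700 + i, U = 30, E = 6)
    for (mode in c("uniform", "empirical")) {
      fit <- suppressWarnings(fit_em(inst$R, inst$req, prior_mode = mode,
                                     max_iter = 60, store_posterior = "never"))
      expect_true(all(diff(fit$loglik_trace) > -1e-8))
    }
  }
})

test_that("binary requirement maps reproduce an independent textbook DINA EM", {
  set.seed(31)
  Q <- matrix(rbinom(8, 1, 0.7), 4, 2)
  Q[rowSums(Q) == 0, 1] <- 1L
  alpha <- matrix(rbinom(120 * 2, 1, 0.5), 120, 2)
  eta <- t(apply(alpha, 1, function(al)
    apply(Q, 1, function(q) as.integer(all(al >= q)))))
  P <- t(apply(eta, 1, function(ee) ifelse(ee == 1, 0.85, 0.15)))
  R <- matrix(rbinom(length(P), 1, P), nrow(P), ncol(P))
  for (e in seq_len(ncol(R))) {
    if (all(R[, e] == R[1, e])) R[1, e] <- 1L - R[1, e]
  }
  req <- requirement_map_from_q_matrix(Q)
  for (mode in c("uniform", "empirical")) {
    ora <- oracle_dina_em(R, Q, update_prior = mode == "empirical",
                          n_iter = 40)
    fit <- suppressWarnings(fit_em(R, req, prior_mode = mode, max_iter = 40,
                                   tol_param = 0, tol_loglik = 0,
                                   store_posterior = "always"))
    expect_equal(fit$item_params$slip, ora$s, tolerance = 1e-6)
    expect_equal(fit$item_params$guess, ora$g, tolerance = 1e-6)
  }
})

test_that("parameters are recovered on simulated data and improve with sample size", {
  cfg_small <- sim_config(E = 20, K = 3, U = 400, reps = 1, seed = 77)
  cfg_big <- sim_config(E = 20, K = 3, U = 4000, reps = 1, seed = 77)
  maes <- vapply(list(cfg_small, cfg_big), function(cfg) {
    truth <- simulate_truth(cfg, seed = 99)
    keep <- filter_invalid_exercises(truth$responses)
    fit <- suppressWarnings(fit_em(keep$responses, truth$req,
                                   store_posterior = "never"))
    mean(abs(c(fit$item_params$slip - truth$params$s,
               fit$item_params$guess - truth$params$g)))
  }, 0)
  expect_lt(maes[2], 0.05)   # recovery at the larger sample
  expect_lt(maes[2], maes[1])  # error shrinks as U grows
})

test_that("posterior rows sum to one on random instances", {
  for (i in 1:5) {
    inst <- random_instance(800 + i, U = 12)
    fit <- suppressWarnings(fit_em(inst$R, inst$req, max_iter = 25,
                                   store_posterior = "always"))
    expect_equal(rowSums(fit$posterior), rep(1, nrow(inst$R)),
                 tolerance = 1e-10)
    expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  }
})

test_that("non-convergence returns a flagged result with a warning", {
  inst <- random_instance(900, U = 20, E = 5)
  expect_warning(
    fit <- fit_em(inst$R, inst$req, max_iter = 2, tol_param = 0,
                  tol_loglik = 0, store_posterior = "never"),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2)
})
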