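# Independent brute-force oracles: plain double loops over the full profile
# space, written against the model definitions only.  They deliberately share
# no code with the package internals.

oracle_ideal <- function(a, beta) {
  E <- nrow(a)
  out <- integer(E)
  for (e in seq_len(E)) {
    ok <- TRUE
    for (k in seq_len(ncol(a))) {
      if (a[e, k] > 0 && beta[k] < a[e, k]) ok <- FALSE
    }
    out[e] <- as.integer(ok)
  }
  out
}

oracle_profiles <- function(K, L_max) {
  as.matrix(rev(expand.grid(rev(replicate(K, 0:L_max, simplify = FALSE)))))
}

# Per-learner, per-profile likelihood by elementwise products.
oracle_loglik <- function(R, a, s, g, L_max) {
  B <- oracle_profiles(ncol(a), L_max)
  U <- nrow(R); N <- nrow(B); E <- nrow(a)
  out <- matrix(0, U, N)
  for (u in seq_len(U)) {
    for (n in seq_len(N)) {
      pi_n <- oracle_ideal(a, B[n, ])
      ll <- 0
      for (e in seq_len(E)) {
        p <- if (pi_n[e] == 1) 1 - s[e] else g[e]
        p <- min(max(p, 1e-6), 1 - 1e-6)
        ll <- ll + if (R[u, e] == 1) log(p) else log(1 - p)
      }
      out[u, n] <- ll
    }
  }
  out
}

oracle_estep <- function(loglik, prior) {
  post <- matrix(0, nrow(loglik), ncol(loglik))
  for (u in seq_len(nrow(loglik))) {
    w <- exp(loglik[u, ]) * prior
    post[u, ] <- w / sum(w)
  }
  post
}

oracle_mstep <- function(R, post, pi_mat) {
  E <- ncol(R); N <- nrow(pi_mat)
  s <- g <- numeric(E)
  for (e in seq_len(E)) {
    Z0 <- Z1 <- F0 <- F1 <- 0
    for (u in seq_len(nrow(R))) {
      for (n in seq_len(N)) {
        if (pi_mat[n, e] == 1) {
          Z1 <- Z1 + post[u, n]
          if (R[u, e] == 1) F1 <- F1 + post[u, n]
        } else {
          Z0 <- Z0 + post[u, n]
          if (R[u, e] == 1) F0 <- F0 + post[u, n]
        }
      }
    }
    g[e] <- F0 / Z0
    s[e] <- (Z1 - F1) / Z1
  }
  list(s = s, g = g)
}

# Textbook DINA EM on a binary Q-matrix: full 2^K latent class enumeration,
# likelihood by loops, optional mixing-proportion update.
oracle_dina_em <- function(R, Q, update_prior = TRUE, n_iter = 40,
                           s0 = 0.2, g0 = 0.2) {
  K <- ncol(Q); E <- nrow(Q); U <- nrow(R)
  B <- oracle_profiles(K, 1)
  N <- nrow(B)
  eta <- matrix(0L, N, E)
  for (n in seq_len(N)) eta[n, ] <- oracle_ideal(Q, B[n, ])
  s <- rep(s0, E); g <- rep(g0, E)
  prior <- rep(1 / N, N)
  for (it in seq_len(n_iter)) {
    ll <- matrix(0, U, N)
    for (u in seq_len(U)) {
      for (n in seq_len(N)) {
        acc <- 0
        for (e in seq_len(E)) {
          p <- if (eta[n, e] == 1) 1 - s[e] else g[e]
          p <- min(max(p, 1e-6), 1 - 1e-6)
          acc <- acc + if (R[u, e] == 1) log(p) else log(1 - p)
        }
        ll[u, n] <- acc
      }
    }
    post <- oracle_estep(ll, prior)
    upd <- oracle_mstep(R, post, eta)
    s <- pmin(pmax(upd$s, 1e-6), 1 - 1e-6)
    g <- pmin(pmax(upd$g, 1e-6), 1 - 1e-6)
    if (update_prior) prior <- colSums(post) / U
  }
  list(s = s, g = g, prior = prior, post = post, eta = eta, B = B)
}

# Small random model instance for property tests.
random_instance <- function(seed, U = 8, E = 4, K = 2, L_max = 2) {
  set.seed(seed)
  repeat {
    a <- matrix(sample(0:L_max, E * K, replace = TRUE,
                       prob = c(0.3, rep(0.7 / L_max, L_max))), E, K)
    if (all(rowSums(a) > 0)) break
  }
  profiles <- matrix(sample(0:L_max, U * K, replace = TRUE), U, K)
  s <- runif(E, 0.05, 0.3)
  g <- runif(E, 0.05, 0.3)
  pi_u <- t(apply(profiles, 1, function(b) oracle_ideal(a, b)))
  P <- t(apply(pi_u, 1, function(pi) ifelse(pi == 1, 1 - s, g)))
  R <- matrix(rbinom(U * E, 1, P), U, E)
  # guarantee column variation so fit_em accepts the matrix
  for (e in seq_len(E)) {
    if (all(R[, e] == R[1, e])) R[sample(U, 1), e] <- 1L - R[1, e]
  }
  list(a = a, req = requirement_map(a, L_max = L_max), profiles = profiles,
       s = s, g = g, R = R, L_max = L_max)
}
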