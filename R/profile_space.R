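#' Enumerate the space of ordered knowledge-cognition profiles
#'
#' A profile assigns each of the `K` concepts an ordered level in
#' `0:L_max`, so there are `(L_max + 1)^K` profiles (`7^K` at the default
#' `L_max = 6`).  Profiles are ordered mixed-radix in base `L_max + 1` with
#' the *last* concept as the fastest-changing digit, which makes the
#' index/vector bijection deterministic and trivially invertible.
#'
#' @param K number of knowledge concepts (>= 1).
#' @param L_max maximum level (default 6).
#' @param cap refuse to enumerate more than this many profiles (default
#'   `1e7`); pass a larger value to override explicitly.
#' @return Object of class `profile_space`: list with `K`, `L_max`, `N` and
#'   `profiles`, an `N x K` integer matrix whose row `n` is the profile with
#'   index `n`.
#' @examples
#' sp <- enumerate_profiles(2, 1)
#' sp$profiles  # (0,0), (0,1), (1,0), (1,1)
#' @export
enumerate_profiles <- function(K, L_max = 6L, cap = 1e7) {
  stopifnot(K >= 1, L_max >= 1)
  base <- L_max + 1
  N <- base^K
  if (N > cap) {
    stop(sprintf(
      "profile space too large: (%d+1)^%d = %.3g profiles exceeds the cap of %.3g; raise `cap` to override",
      as.integer(L_max), as.integer(K), N, cap))
  }
  N <- as.integer(N)
  profiles <- matrix(0L, N, K)
  idx <- 0:(N - 1)
  for (k in K:1) {
    profiles[, k] <- as.integer(idx %% base)
    idx <- idx %/% base
  }
  structure(list(K = as.integer(K), L_max = as.integer(L_max), N = N,
                 profiles = profiles),
            class = "profile_space")
}

#' @export
print.profile_space <- function(x, ...) {
  cat(sprintf("Profile space: K = %d, levels 0..%d, N = %d profiles\n",
              x$K, x$L_max, x$N))
  invisible(x)
}

#' Profile index from level vector
#'
#' @param space a [enumerate_profiles()] object.
#' @param beta integer vector of length `K` with entries in `0:L_max`.
#' @return 1-based profile index.
#' @export
profile_to_index <- function(space, beta) {
  stopifnot(inherits(space, "profile_space"))
  if (length(beta) != space$K) {
    stop("profile has length ", length(beta), " but the space has K = ", space$K)
  }
  if (any(beta < 0) || any(beta > space$L_max) || any(beta != round(beta))) {
    stop("profile entries must be integers in [0, L_max]")
  }
  base <- space$L_max + 1
  as.integer(sum(beta * base^((space$K - 1):0)) + 1)
}

#' Level vector from profile index
#'
#' @inheritParams profile_to_index
#' @param n 1-based profile index.
#' @return integer level vector of length `K`.
#' @export
index_to_profile <- function(space, n) {
  stopifnot(inherits(space, "profile_space"))
  if (n < 1 || n > space$N) stop("profile index out of range")
  space$profiles[n, ]
}
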