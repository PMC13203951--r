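#' Ideal response of a profile to every exercise
#'
#' Under the deterministic part of the model a learner answers exercise `e`
#' correctly iff their level meets or exceeds the required level on *every*
#' concept the exercise requires: `pi_e = prod_k 1(a[e,k] <= beta_k)`,
#' where concepts with `a[e,k] = 0` never fail the indicator.  Slip and guess
#' perturb this deterministic outcome.
#'
#' @param req a [requirement_map()].
#' @param beta integer profile vector of length `K`.
#' @return binary vector of length `E`.
#' @examples
#' req <- requirement_map(rbind(c(2, 4), c(0, 2)))
#' ideal_response(req, c(2, 4))  # 1, 1
#' ideal_response(req, c(2, 3))  # 0, 1
#' @export
ideal_response <- function(req, beta) {
  stopifnot(inherits(req, "requirement_map"))
  if (length(beta) != req$K) {
    stop("profile has length ", length(beta), " but the map has K = ", req$K)
  }
  as.integer(apply(req$a, 1, function(a_e) all(a_e <= beta | a_e == 0L)))
}

#' Ideal-response matrix over a whole profile space
#'
#' Row `n` is [ideal_response()] of profile `n`; computed vectorised per
#' concept so large spaces stay cheap.
#'
#' @param req a [requirement_map()].
#' @param space a [enumerate_profiles()] object with matching `K`.
#' @return binary `N x E` matrix.
#' @export
ideal_response_matrix <- function(req, space) {
  stopifnot(inherits(req, "requirement_map"), inherits(space, "profile_space"))
  if (req$K != space$K) stop("requirement map and profile space disagree on K")
  pi_mat <- matrix(1, space$N, req$E)
  for (e in seq_len(req$E)) {
    for (k in seq_len(req$K)) {
      if (req$a[e, k] > 0L) {
        pi_mat[, e] <- pi_mat[, e] * (space$profiles[, k] >= req$a[e, k])
      }
    }
  }
  colnames(pi_mat) <- req$exercise_ids
  pi_mat
}

# Ideal responses for arbitrary profile rows (internal; used by the
# simulator, where profiles are learners rather than the enumerated space).
ideal_response_rows <- function(req, profiles) {
  pi_mat <- matrix(1, nrow(profiles), req$E)
  for (e in seq_len(req$E)) {
    for (k in seq_len(req$K)) {
      if (req$a[e, k] > 0L) {
        pi_mat[, e] <- pi_mat[, e] * (profiles[, k] >= req$a[e, k])
      }
    }
  }
  pi_mat
}

#' Remove exercises with no response variation
#'
#' Columns answered correctly by everyone or by no one carry no information
#' about slip/guess or profiles and are removed before fitting.
#'
#' @param responses binary learner x exercise matrix.
#' @return list with `responses` (columns in original order) and
#'   `removed` (character ids, or column indices when unnamed).
#' @export
filter_invalid_exercises <- function(responses) {
  responses <- validate_responses(responses)
  cm <- colMeans(responses)
  bad <- cm == 0 | cm == 1
  ids <- colnames(responses) %||% as.character(seq_len(ncol(responses)))
  if (all(bad)) {
    stop("all exercises are answered uniformly; nothing left to fit")
  }
  list(responses = responses[, !bad, drop = FALSE], removed = ids[bad])
}

# Validate a binary response matrix; preserves dimnames.
validate_responses <- function(responses) {
  responses <- as.matrix(responses)
  if (any(is.na(responses))) {
    stop("missing responses are not supported; the model assumes a complete binary matrix")
  }
  if (!all(responses %in% c(0, 1))) {
    stop("responses must be binary 0/1")
  }
  storage.mode(responses) <- "integer"
  responses
}
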