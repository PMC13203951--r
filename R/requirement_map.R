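#' Ordered requirement map
#'
#' The requirement map is the central item-attribute structure of the model:
#' an integer matrix `a` with one row per exercise and one column per
#' knowledge concept, where `a[e, k] = c > 0` says that exercise `e` requires
#' concept `k` at ordered cognitive level `c` (1--`L_max`, revised Bloom
#' taxonomy: Remember ... Create) and `a[e, k] = 0` says the concept is not
#' required.  It generalises the binary Q-matrix, which is recovered when all
#' entries lie in `{0, 1}`.
#'
#' @param a integer matrix (exercises x concepts) with entries in
#'   `0:L_max`.
#' @param exercise_ids,concept_ids unique identifiers; default taken from
#'   `dimnames(a)` or generated (`E1..`, `KC1..`).
#' @param L_max maximum cognitive level (default 6).
#' @return An object of class `requirement_map`: a list with elements `a`,
#'   `exercise_ids`, `concept_ids`, `L_max`, `E`, `K`.
#' @examples
#' req <- requirement_map(rbind(c(2, 4), c(0, 2)))
#' req$a
#' @export
requirement_map <- function(a, exercise_ids = NULL, concept_ids = NULL,
                            L_max = 6L) {
  a <- as.matrix(a)
  if (!is.numeric(a) || any(is.na(a))) {
    stop("requirement map must be a numeric matrix without missing values")
  }
  if (any(a != round(a)) || any(a < 0) || any(a > L_max)) {
    stop("requirement levels must be integers in [0, ", L_max, "]")
  }
  storage.mode(a) <- "integer"
  exercise_ids <- exercise_ids %||% rownames(a) %||% paste0("E", seq_len(nrow(a)))
  concept_ids <- concept_ids %||% colnames(a) %||% paste0("KC", seq_len(ncol(a)))
  if (anyDuplicated(exercise_ids)) stop("duplicated exercise ids")
  if (anyDuplicated(concept_ids)) stop("duplicated concept ids")
  if (length(exercise_ids) != nrow(a) || length(concept_ids) != ncol(a)) {
    stop("id lengths do not match requirement-map dimensions")
  }
  dimnames(a) <- list(exercise_ids, concept_ids)
  if (any(rowSums(a) == 0)) {
    warning("exercise(s) requiring no concept: ",
            paste(exercise_ids[rowSums(a) == 0], collapse = ", "),
            " (ideal response is always 1; only the slip parameter is informed)")
  }
  structure(
    list(a = a, exercise_ids = as.character(exercise_ids),
         concept_ids = as.character(concept_ids), L_max = as.integer(L_max),
         E = nrow(a), K = ncol(a)),
    class = "requirement_map"
  )
}

#' @export
print.requirement_map <- function(x, ...) {
  cat("Ordered requirement map:", x$E, "exercises x", x$K,
      "concepts, levels 0..", x$L_max, "\n", sep = " ")
  print(x$a)
  invisible(x)
}

#' Exercise-knowledge-cognition tensor
#'
#' A binary indicator array over (exercise, concept, level) triples in which
#' at most one level per exercise-concept pair is positive.  The tensor is the
#' raw form produced by level-tagging an item bank; [requirement_map_from_tensor()]
#' collapses it to the ordered requirement map used everywhere else.
#'
#' @param entries binary array with `dim = c(E, K, C)`.
#' @return Object of class `ekc_tensor`.
#' @export
ekc_tensor <- function(entries) {
  entries <- as.array(entries)
  if (length(dim(entries)) != 3) stop("EKC tensor must have dimensions E x K x C")
  if (any(is.na(entries)) || !all(entries %in% c(0, 1))) {
    stop("EKC tensor entries must be binary")
  }
  per_pair <- apply(entries, c(1, 2), sum)
  if (any(per_pair > 1)) {
    bad <- which(per_pair > 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid EKC tensor: exercise %d, concept %d has %d positive levels (at most one allowed)",
      bad[1], bad[2], per_pair[bad[1], bad[2]]))
  }
  structure(list(entries = entries, E = dim(entries)[1], K = dim(entries)[2],
                 C = dim(entries)[3]), class = "ekc_tensor")
}

#' Collapse an EKC tensor to its ordered requirement map
#'
#' Each exercise-concept pair carries at most one positive level `c`; the map
#' stores that level, or 0 when no level is flagged.
#'
#' @param tensor an [ekc_tensor()] (or a raw binary E x K x C array).
#' @param L_max maximum level of the resulting map; defaults to the tensor's
#'   third dimension.
#' @return A [requirement_map()].
#' @examples
#' tn <- array(0, c(2, 2, 6)); tn[1, 2, 4] <- 1
#' requirement_map_from_tensor(tn)$a
#' @export
requirement_map_from_tensor <- function(tensor, L_max = NULL) {
  if (!inherits(tensor, "ekc_tensor")) tensor <- ekc_tensor(tensor)
  lev <- apply(tensor$entries, c(1, 2), function(v) {
    p <- which(v == 1)
    if (length(p)) p else 0L
  })
  requirement_map(lev, L_max = L_max %||% tensor$C)
}

#' Requirement map from a binary Q-matrix
#'
#' Lifts a classical binary Q-matrix into the ordered framework by reading
#' every required concept as "required at level 1".  With such a map the model
#' is exactly the DINA model, which is how the binary baseline is run.
#'
#' @param Q binary exercises x concepts matrix.
#' @inheritParams requirement_map
#' @return A [requirement_map()] with levels in `{0, 1}` (`L_max = 1` unless
#'   overridden).
#' @export
requirement_map_from_q_matrix <- function(Q, L_max = 1L) {
  Q <- as.matrix(Q)
  if (any(is.na(Q)) || !all(Q %in% c(0, 1))) {
    stop("Q-matrix entries must be binary 0/1")
  }
  requirement_map(Q, L_max = L_max)
}
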