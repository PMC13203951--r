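#' Read an ordered requirement map from CSV or JSON
#'
#' Long CSV: header `exercise_id,concept_id,level`; pairs not listed are 0.
#' Wide CSV: one row per exercise (`exercise_id` column), one column per
#' concept.  JSON: nested `{exercise: {concept: level}}` (the serialized
#' tensor form).  Format is sniffed from the extension and header unless
#' given.
#'
#' @param path file path.
#' @param format `"auto"`, `"long"`, `"wide"`, or `"json"`.
#' @param L_max maximum level (default 6).
#' @return a [requirement_map()].
#' @export
read_requirement_map <- function(path, format = c("auto", "long", "wide", "json"),
                                 L_max = 6L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      "json"
    } else {
      hdr <- names(read.csv(path, nrows = 1, check.names = FALSE))
      if (identical(hdr[1:3], c("exercise_id", "concept_id", "level")))
        "long" else "wide"
    }
  }
  if (format == "json") {
    nested <- jsonlite::read_json(path, simplifyVector = TRUE)
    ex <- names(nested)
    kc <- sort(unique(unlist(lapply(nested, names))))
    a <- matrix(0L, length(ex), length(kc), dimnames = list(ex, kc))
    for (e in ex) {
      lv <- unlist(nested[[e]])
      a[e, names(lv)] <- as.integer(lv)
    }
    return(requirement_map(a, L_max = L_max))
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "long") {
    need <- c("exercise_id", "concept_id", "level")
    if (!all(need %in% names(df))) {
      stop("long requirement CSV needs columns: ", paste(need, collapse = ", "))
    }
    ex <- unique(df$exercise_id)
    kc <- unique(df$concept_id)
    a <- matrix(0L, length(ex), length(kc), dimnames = list(ex, kc))
    a[cbind(match(df$exercise_id, ex), match(df$concept_id, kc))] <-
      as.integer(df$level)
    requirement_map(a, L_max = L_max)
  } else {
    if (names(df)[1] != "exercise_id") {
      stop("wide requirement CSV needs a leading exercise_id column")
    }
    a <- as.matrix(df[, -1, drop = FALSE])
    rownames(a) <- df$exercise_id
    requirement_map(a, L_max = L_max)
  }
}

#' Write a requirement map as long CSV
#'
#' Only nonzero pairs are written (absent pairs mean level 0).
#'
#' @param req a [requirement_map()].
#' @param path output path.
#' @export
write_requirement_map <- function(req, path) {
  nz <- which(req$a > 0, arr.ind = TRUE)
  df <- data.frame(exercise_id = req$exercise_ids[nz[, 1]],
                   concept_id = req$concept_ids[nz[, 2]],
                   level = req$a[nz])
  df <- df[order(match(df$exercise_id, req$exercise_ids),
                 match(df$concept_id, req$concept_ids)), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary response matrix from CSV
#'
#' Header `learner_id,<exercise_id>,...`, cells 0/1; missing cells are an
#' error (the model assumes complete data).
#'
#' @param path file path.
#' @return binary integer matrix with learner ids as row names and exercise
#'   ids as column names.
#' @export
read_response_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "learner_id") {
    stop("response CSV needs a leading learner_id column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing response at row %d, column '%s'", bad[1],
                 colnames(m)[bad[2]]))
  }
  if (!all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    stop(sprintf("non-binary response value '%s' at cell %d", m[bad], bad))
  }
  rownames(m) <- df$learner_id
  storage.mode(m) <- "integer"
  m
}

#' Write a response matrix as CSV
#'
#' @param responses binary matrix with learner row names.
#' @param path output path.
#' @export
write_response_matrix <- function(responses, path) {
  df <- data.frame(learner_id = rownames(responses) %||%
                     seq_len(nrow(responses)), responses,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an items x raters ordinal rating table from CSV
#'
#' Header `item_id,<rater_id>,...`; blank cells are missing.
#'
#' @param path file path.
#' @return numeric matrix with item ids as row names.
#' @export
read_rating_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "item_id") stop("rating CSV needs a leading item_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df$item_id
  m
}

# --- structured output writers used by the command-line tool ---------------

write_fit_outputs <- function(fit, out_dir, stem = "fit") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params_csv <- file.path(out_dir, paste0(stem, "_params.csv"))
  write.csv(fit$item_params[, c("exercise_id", "slip", "guess")], params_csv,
            row.names = FALSE, quote = FALSE)
  report <- list(loglik = fit$loglik, AIC = fit$AIC, BIC = fit$BIC,
                 n_params = fit$n_params, n_iter = fit$n_iter,
                 converged = fit$converged, U = fit$U, E = fit$E, K = fit$K,
                 L_max = fit$L_max, N = fit$N, config = fit$config)
  report_json <- file.path(out_dir, paste0(stem, "_report.json"))
  jsonlite::write_json(report, report_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  chart <- list(type = "line", x = fit$item_params$exercise_id,
                series = list(slip = fit$item_params$slip,
                              guess = fit$item_params$guess))
  chart_json <- file.path(out_dir, paste0(stem, "_chart.json"))
  jsonlite::write_json(chart, chart_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(params_csv, report_json, chart_json)
}

write_diagnosis_outputs <- function(diag, out_dir, stem = "diagnosis") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  K <- ncol(diag$reported)
  kc <- diag$concept_ids
  prof <- data.frame(learner_id = diag$learner_ids %||%
                       seq_len(nrow(diag$reported)))
  for (k in seq_len(K)) {
    prof[[paste0(kc[k], "_level")]] <- diag$reported[, k]
    prof[[paste0(kc[k], "_ci_lo")]] <- diag$ci[, k, 1]
    prof[[paste0(kc[k], "_ci_hi")]] <- diag$ci[, k, 2]
  }
  profiles_csv <- file.path(out_dir, paste0(stem, "_profiles.csv"))
  write.csv(prof, profiles_csv, row.names = FALSE, quote = FALSE)
  marg_json <- file.path(out_dir, paste0(stem, "_marginals.json"))
  jsonlite::write_json(
    list(concepts = kc, levels = 0:diag$fit$L_max,
         marginals = diag$marginals),
    marg_json, digits = NA, auto_unbox = TRUE)
  sep_csv <- file.path(out_dir, paste0(stem, "_separability.csv"))
  write.csv(diag$separability, sep_csv, row.names = FALSE, quote = FALSE)
  radar <- list(type = "radar", axes = kc,
                max_level = diag$fit$L_max,
                learners = diag$learner_ids %||% seq_len(nrow(diag$reported)),
                levels = diag$reported)
  radar_json <- file.path(out_dir, paste0(stem, "_radar_chart.json"))
  jsonlite::write_json(radar, radar_json, digits = NA, auto_unbox = TRUE)
  c(profiles_csv, marg_json, sep_csv, radar_json)
}

write_simulation_outputs <- function(sim, out_dir, stem = "simulation") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_rep_csv <- file.path(out_dir, paste0(stem, "_per_rep.csv"))
  write.csv(sim$per_rep, per_rep_csv, row.names = FALSE, quote = FALSE)
  summary_csv <- file.path(out_dir, paste0(stem, "_summary.csv"))
  write.csv(sim$last_rep, summary_csv, row.names = FALSE, quote = FALSE)
  js <- file.path(out_dir, paste0(stem, "_summary.json"))
  cfg <- unclass(sim$config)
  cfg$rep_seeds <- rep_seeds(sim$config$seed, sim$config$reps)
  jsonlite::write_json(list(summary = sim$summary, config = cfg), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(per_rep_csv, summary_csv, js)
}
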