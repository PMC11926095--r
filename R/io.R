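#' File formats: ratings, rosters, edge lists, fitted models, run configs
#'
#' All tabular inputs and outputs are plain CSV. Ratings: `user_id,
#' task_id, score`. Roster: `classroom_id, student_id, age, gender`. Edge
#' lists: `classroom_id, layer, source_id, target_id`. Fitted models are
#' serialized as JSON. Validation errors name the offending row.
#'
#' @name io_formats
NULL

#' Read a ratings CSV
#'
#' @param path CSV with header `user_id, task_id, score`.
#' @return A [ratings_table()].
#' @export
read_ratings <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "task_id", "score")
  if (!all(need %in% names(d))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(d$score) | d$score != as.integer(d$score) |
                 !(d$score %in% SCORES))
  if (length(bad)) stopf("%s: invalid score at row %s", path, paste(bad, collapse = ", "))
  key <- paste(d$user_id, d$task_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) stopf("%s: duplicate (user, task) at row %s", path, paste(dup, collapse = ", "))
  ratings_table(d)
}

#' Write a ratings table to CSV
#'
#' @param ratings a [ratings_table()].
#' @param path output path.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(as.data.frame(ratings), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert raw task performances to quintile scores
#'
#' Per task, raw values are converted to percentile ranks over the full
#' sample (ties receive average ranks) and binned into quintiles 1..5 at cut
#' points 20/40/60/80; values exactly on a boundary go to the lower
#' quintile.
#'
#' @param raw_scores data.frame with columns `user_id`, `task_id`, `value`.
#' @return data.frame `user_id, task_id, score` plus attribute
#'   `degenerate_tasks` naming tasks with fewer than 5 distinct values.
#' @export
scores_to_quintiles <- function(raw_scores) {
  stopifnot(all(c("user_id", "task_id", "value") %in% names(raw_scores)))
  res <- lapply(split(raw_scores, raw_scores$task_id), function(d) {
    pct <- 100 * rank(d$value, ties.method = "average") / nrow(d)
    q <- 1L + (pct > 20) + (pct > 40) + (pct > 60) + (pct > 80)
    data.frame(user_id = d$user_id, task_id = d$task_id, score = as.integer(q))
  })
  degenerate <- names(which(vapply(
    split(raw_scores$value, raw_scores$task_id),
    function(v) length(unique(v)) < 5, logical(1)
  )))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "degenerate_tasks") <- degenerate
  out
}

#' Read a roster CSV into classrooms
#'
#' @param path CSV with header `classroom_id, student_id, age, gender`.
#' @return Named list of [classroom()] objects.
#' @export
read_roster <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("classroom_id", "student_id", "age", "gender")
  if (!all(need %in% names(d))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  rooms <- lapply(split(d, d$classroom_id), function(g) {
    classroom(g$classroom_id[1], g$age[1],
              data.frame(student_id = g$student_id, gender = g$gender))
  })
  rooms[order(names(rooms))]
}

#' Read multilayer sociograms from edge-list and roster CSVs
#'
#' Rejects, naming the row: endpoints outside the source classroom,
#' self-loops, duplicate nominations, and more than three nominations by one
#' student in one layer.
#'
#' @param edges_path CSV with header `classroom_id, layer, source_id,
#'   target_id`.
#' @param roster_path roster CSV, see [read_roster()].
#' @return List of elements with `classroom` and `sociogram`
#'   (a [multilayer_sociogram()]), one per classroom.
#' @export
read_sociograms <- function(edges_path, roster_path) {
  rooms <- read_roster(roster_path)
  e <- read.csv(edges_path, stringsAsFactors = FALSE)
  need <- c("classroom_id", "layer", "source_id", "target_id")
  if (!all(need %in% names(e))) {
    stopf("%s: expected columns %s", edges_path, paste(need, collapse = ", "))
  }
  e$row <- seq_len(nrow(e))
  bad_layer <- which(!(e$layer %in% LAYER_LABELS))
  if (length(bad_layer)) stopf("unknown layer at row %d", bad_layer[1])
  lapply(rooms, function(cls) {
    roster <- cls$students$student_id
    sub <- e[e$classroom_id == cls$classroom_id, , drop = FALSE]
    out_row <- which(!(sub$source_id %in% roster) | !(sub$target_id %in% roster))
    if (length(out_row)) stopf("cross-classroom edge at row %d", sub$row[out_row[1]])
    self_row <- which(sub$source_id == sub$target_id)
    if (length(self_row)) stopf("self-loop at row %d", sub$row[self_row[1]])
    dup <- which(duplicated(paste(sub$layer, sub$source_id, sub$target_id, sep = "\r")))
    if (length(dup)) stopf("duplicate nomination at row %d", sub$row[dup[1]])
    layers <- lapply(intersect(LAYER_LABELS, unique(sub$layer)), function(lab) {
      sl <- sub[sub$layer == lab, , drop = FALSE]
      if (nrow(sl) && max(table(sl$source_id)) > 3L) {
        over <- names(which.max(table(sl$source_id)))
        stopf("student %s has more than 3 nominations in layer %s (row %d)",
              over, lab, max(sl$row[sl$source_id == over]))
      }
      sociogram_layer(lab, data.frame(source = sl$source_id, target = sl$target_id),
                      roster)
    })
    list(classroom = cls, sociogram = multilayer_sociogram(cls, layers))
  })
}

#' Write multilayer sociograms and roster to CSV
#'
#' @param dataset list as returned by [make_age_series()] or
#'   [read_sociograms()].
#' @param edges_path,roster_path output paths.
#' @export
write_sociograms <- function(dataset, edges_path, roster_path) {
  edges <- do.call(rbind, lapply(dataset, function(el) {
    do.call(rbind, lapply(el$sociogram$layers, function(ly) {
      if (nrow(ly$edges) == 0L) return(NULL)
      data.frame(classroom_id = el$classroom$classroom_id, layer = ly$label,
                 source_id = ly$edges$source, target_id = ly$edges$target)
    }))
  }))
  roster <- do.call(rbind, lapply(dataset, function(el) {
    data.frame(classroom_id = el$classroom$classroom_id,
               student_id = el$classroom$students$student_id,
               age = el$classroom$age,
               gender = el$classroom$students$gender)
  }))
  write.csv(edges, edges_path, row.names = FALSE, quote = FALSE)
  write.csv(roster, roster_path, row.names = FALSE, quote = FALSE)
  invisible(list(edges = edges_path, roster = roster_path))
}

#' Serialize a fitted model to JSON
#'
#' @param fit an `mmsbm_fit` or `mmsbm_params` object.
#' @param path output path.
#' @export
write_model <- function(fit, path) {
  params <- if (inherits(fit, "mmsbm_fit")) fit$params else fit
  meta <- if (inherits(fit, "mmsbm_fit")) {
    list(seed = fit$seed, n_iter = fit$n_iter, converged = fit$converged,
         best_restart = fit$best_restart, loglik = max(fit$restart_logliks))
  }
  obj <- list(
    theta = unname(params$theta), eta = unname(params$eta),
    p = params$p, users = params$users, tasks = params$tasks,
    K = ncol(params$theta), L = ncol(params$eta), metadata = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_model()].
#' @return An `mmsbm_params` object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- array(obj$p, dim = c(obj$K, obj$L, length(SCORES)))
  mmsbm_params(obj$theta, obj$eta, p, users = obj$users, tasks = obj$tasks)
}

#' Default run configuration
#'
#' A single top-level seed is fanned out to every stochastic stage by
#' hashing stage names, so whole runs are reproducible while stages stay
#' independent.
#'
#' @param ... overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    model = list(K = 3L, L = 3L, tol = 1e-6, max_iter = 500L, n_restarts = 10L),
    nulls = list(n_shuffles = 1000L, n_rewire_samples = 1000L, swap_multiplier = 10),
    distance = "euclidean",
    alpha = 0.05
  )
  over <- list(...)
  structure(modifyList(cfg, over), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path a YAML file with any subset of the [run_config()] fields.
#' @return A `run_config` list (missing fields at defaults).
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
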