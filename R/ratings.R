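#' Ratings table: observed links of the bipartite student-task graph
#'
#' A `ratings_table` holds one row per observed (student, task) pair with its
#' quintile score in 1..5. The user and task indices (the full sets of ids the
#' table may reference) are kept as attributes so that holdout splits, which
#' drop links, still know about all students and tasks.
#'
#' @param links data.frame with columns `user_id`, `task_id`, `score`.
#' @param users,tasks optional character vectors of all user/task ids; default
#'   to the ids present in `links`.
#' @return A `ratings_table` object (a validated data.frame).
#' @export
ratings_table <- function(links, users = NULL, tasks = NULL) {
  stopifnot(is.data.frame(links))
  need <- c("user_id", "task_id", "score")
  if (!all(need %in% names(links))) {
    stopf("ratings need columns %s", paste(need, collapse = ", "))
  }
  links <- as.data.frame(links)[need]
  links$user_id <- as.character(links$user_id)
  links$task_id <- as.character(links$task_id)
  bad <- which(!(links$score %in% SCORES))
  if (length(bad)) {
    stopf("score outside 1..5 at row %s", paste(bad, collapse = ", "))
  }
  key <- paste(links$user_id, links$task_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("duplicate (user, task) pair at row %s", paste(dup, collapse = ", "))
  }
  users <- as.character(users %||% unique(links$user_id))
  tasks <- as.character(tasks %||% unique(links$task_id))
  if (!all(links$user_id %in% users)) stopf("link references user absent from index")
  if (!all(links$task_id %in% tasks)) stopf("link references task absent from index")
  structure(links,
    users = users, tasks = tasks,
    class = c("ratings_table", "data.frame")
  )
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf(
    "ratings_table: %d links, %d users, %d tasks\n",
    nrow(x), length(attr(x, "users")), length(attr(x, "tasks"))
  ))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

# Integer (user, task) indices of each link against the table's index.
link_indices <- function(ratings) {
  list(
    u = match(ratings$user_id, attr(ratings, "users")),
    t = match(ratings$task_id, attr(ratings, "tasks")),
    s = as.integer(ratings$score)
  )
}

# Rebuild a ratings_table from a subset of rows, keeping the full index.
subset_ratings <- function(ratings, idx) {
  ratings_table(as.data.frame(ratings)[idx, , drop = FALSE],
    users = attr(ratings, "users"), tasks = attr(ratings, "tasks")
  )
}
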