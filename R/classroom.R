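#' Classroom roster
#'
#' @param classroom_id identifier.
#' @param age integer age in years (6-15 in the study population).
#' @param students data.frame with columns `student_id`, `gender`
#'   (one of "boy", "girl", "no-answer", "other").
#' @return A `classroom` object.
#' @export
classroom <- function(classroom_id, age, students) {
  stopifnot(is.data.frame(students), all(c("student_id", "gender") %in% names(students)))
  students$student_id <- as.character(students$student_id)
  if (anyDuplicated(students$student_id)) stopf("duplicate student ids in classroom %s", classroom_id)
  ok <- students$gender %in% c("boy", "girl", "no-answer", "other")
  if (!all(ok)) stopf("unknown gender label: %s", students$gender[!ok][1])
  structure(
    list(classroom_id = as.character(classroom_id), age = as.integer(age),
         students = students[c("student_id", "gender")]),
    class = "classroom"
  )
}

#' @export
print.classroom <- function(x, ...) {
  cat(sprintf("classroom %s: age %d, %d students\n",
              x$classroom_id, x$age, nrow(x$students)))
  invisible(x)
}

LAYER_LABELS <- c("work+", "work-", "play+", "play-", "friend")

#' One directed nomination layer of a classroom sociogram
#'
#' Each child names up to `max_out` classmates; responses are directed edges
#' nominator -> nominee within one classroom. Self-loops and duplicate
#' nominations are invalid.
#'
#' @param label layer label, one of `work+`, `work-`, `play+`, `play-`, `friend`.
#' @param edges data.frame with columns `source`, `target` (student ids).
#' @param roster character vector of all student ids in the classroom.
#' @param max_out per-child nomination cap (3 in the questionnaire design).
#' @return A `sociogram_layer` object.
#' @export
sociogram_layer <- function(label, edges, roster, max_out = 3L) {
  if (!label %in% LAYER_LABELS) stopf("unknown layer label '%s'", label)
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(0), target = character(0))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  roster <- as.character(roster)
  if (!all(edges$source %in% roster) || !all(edges$target %in% roster)) {
    stopf("layer '%s': edge endpoint outside the classroom roster", label)
  }
  if (any(edges$source == edges$target)) stopf("layer '%s': self-nomination", label)
  if (anyDuplicated(paste(edges$source, edges$target, sep = "\r"))) {
    stopf("layer '%s': duplicate nomination", label)
  }
  if (nrow(edges) && max(table(edges$source)) > max_out) {
    stopf("layer '%s': a student exceeds %d nominations", label, max_out)
  }
  structure(
    list(label = label, edges = edges[c("source", "target")], roster = roster),
    class = "sociogram_layer"
  )
}

#' @export
print.sociogram_layer <- function(x, ...) {
  cat(sprintf("sociogram_layer '%s': %d edges over %d students\n",
              x$label, nrow(x$edges), length(x$roster)))
  invisible(x)
}

edge_keys <- function(layer) paste(layer$edges$source, layer$edges$target, sep = "\r")

#' Multilayer sociogram of one classroom
#'
#' @param classroom a [classroom()] object.
#' @param layers named list of [sociogram_layer()] objects sharing the
#'   classroom's roster.
#' @return A `multilayer_sociogram` object.
#' @export
multilayer_sociogram <- function(classroom, layers) {
  stopifnot(inherits(classroom, "classroom"), is.list(layers))
  roster <- classroom$students$student_id
  for (ly in layers) {
    if (!setequal(ly$roster, roster)) stopf("layer '%s' roster differs from classroom roster", ly$label)
  }
  names(layers) <- vapply(layers, `[[`, character(1), "label")
  structure(list(classroom = classroom, layers = layers),
            class = "multilayer_sociogram")
}

#' @export
print.multilayer_sociogram <- function(x, ...) {
  cat(sprintf("multilayer_sociogram: classroom %s (age %d), layers: %s\n",
              x$classroom$classroom_id, x$classroom$age,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}
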