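#' Cognitive assortativity and social status in sociograms
#'
#' Two estimators join fitted cognitive profiles to the nomination networks.
#' Assortativity: within a classroom, the mean profile distance over
#' connected pairs (d_connected) is compared with the mean over all
#' within-class pairs (d_all) as log(d_connected / d_all); negative values
#' mean connected students are cognitively closer than chance. Its null
#' shuffles the profile vectors among students, keeping edges fixed. Status:
#' PageRank on the directed nomination graph (receiving nominations raises
#' status) is rank-correlated with membership in the high- or
#' low-achievement group; its null shuffles membership vectors.
#'
#' @name interplay
NULL

#' Distance between two cognitive profiles
#'
#' @param theta_u,theta_v equal-length membership vectors.
#' @param metric `"euclidean"` (default), `"l1"` or `"cosine"`.
#' @return Nonnegative distance; zero iff the profiles are equal
#'   (for cosine, iff proportional).
#' @export
cognitive_distance <- function(theta_u, theta_v,
                               metric = c("euclidean", "l1", "cosine")) {
  metric <- match.arg(metric)
  if (length(theta_u) != length(theta_v)) stopf("profile length mismatch")
  switch(metric,
    euclidean = sqrt(sum((theta_u - theta_v)^2)),
    l1 = sum(abs(theta_u - theta_v)),
    cosine = 1 - sum(theta_u * theta_v) /
      sqrt(sum(theta_u^2) * sum(theta_v^2))
  )
}

profile_matrix <- function(profiles, roster) {
  if (is.matrix(profiles)) {
    missing <- setdiff(roster, rownames(profiles))
    if (length(missing)) stopf("no profile for student %s", missing[1])
    return(profiles[roster, , drop = FALSE])
  }
  stopf("profiles must be a matrix with student ids as rownames")
}

distance_matrix <- function(theta, metric) {
  n <- nrow(theta)
  switch(metric,
    euclidean = as.matrix(stats::dist(theta)),
    l1 = as.matrix(stats::dist(theta, method = "manhattan")),
    cosine = {
      nrm <- sqrt(rowSums(theta^2))
      1 - (theta %*% t(theta)) / outer(nrm, nrm)
    }
  )
}

log_ratio_from_dist <- function(D, si, ti) {
  n <- nrow(D)
  d_conn <- mean(D[cbind(si, ti)])
  d_all <- sum(D[upper.tri(D)]) / (n * (n - 1) / 2)
  if (d_all <= 0 || d_conn <= 0) {
    return(structure(NA_real_, d_connected = d_conn, d_all = d_all, flagged = TRUE))
  }
  structure(log(d_conn / d_all), d_connected = d_conn, d_all = d_all, flagged = FALSE)
}

#' Cognitive-distance assortativity log-ratio of one layer
#'
#' @param layer a [sociogram_layer()] with at least one edge.
#' @param profiles matrix of membership vectors, rownames = student ids.
#' @param metric distance metric, see [cognitive_distance()].
#' @return log(d_connected / d_all); NA with attribute `flagged = TRUE` when
#'   either mean distance is zero (degenerate classroom). Attributes
#'   `d_connected` and `d_all` carry the two means.
#' @export
assortativity_log_ratio <- function(layer, profiles, metric = "euclidean") {
  if (nrow(layer$edges) == 0L || length(layer$roster) < 2L) {
    return(structure(NA_real_, flagged = TRUE, d_connected = NA_real_, d_all = NA_real_))
  }
  theta <- profile_matrix(profiles, layer$roster)
  D <- distance_matrix(theta, metric)
  si <- match(layer$edges$source, layer$roster)
  ti <- match(layer$edges$target, layer$roster)
  log_ratio_from_dist(D, si, ti)
}

#' Profile-shuffling null for the assortativity log-ratio
#'
#' Cognitive vectors are permuted uniformly among the classroom's students;
#' the edge structure is untouched.
#'
#' @inheritParams assortativity_log_ratio
#' @param n_shuffles number of permutations (>= 2).
#' @param seed integer seed.
#' @return List with `mean`, `sd` and `samples` (flagged shuffles yield NA
#'   and are excluded from the summaries).
#' @export
assortativity_null <- function(layer, profiles, n_shuffles = 1000L, seed = 1L,
                               metric = "euclidean") {
  stopifnot(n_shuffles >= 2)
  theta <- profile_matrix(profiles, layer$roster)
  D <- distance_matrix(theta, metric)
  si <- match(layer$edges$source, layer$roster)
  ti <- match(layer$edges$target, layer$roster)
  n <- length(layer$roster)
  samples <- withr::with_seed(derive_seed(seed, "assort-null"), {
    vapply(seq_len(n_shuffles), function(i) {
      perm <- sample.int(n)
      as.numeric(log_ratio_from_dist(D[perm, perm, drop = FALSE], si, ti))
    }, numeric(1))
  })
  list(mean = mean(samples, na.rm = TRUE), sd = sd(samples, na.rm = TRUE),
       samples = samples)
}

#' PageRank social status within one layer
#'
#' PageRank on the directed nomination graph (edges nominator -> nominee, so
#' receiving nominations raises status), over the full classroom roster;
#' isolated students receive teleport mass only. Scores sum to 1.
#'
#' @param layer a [sociogram_layer()].
#' @param damping damping factor in (0, 1).
#' @return Named numeric vector of PageRank scores, one per roster student.
#' @export
pagerank_status <- function(layer, damping = 0.85) {
  stopifnot(damping > 0, damping < 1)
  if (length(layer$roster) == 0L) stopf("empty roster")
  gr <- igraph::graph_from_data_frame(layer$edges, directed = TRUE,
                                      vertices = data.frame(name = layer$roster))
  pr <- igraph::page_rank(gr, damping = damping)$vector
  pr[layer$roster]
}

#' Spearman correlation between PageRank status and achievement membership
#'
#' @param layer a [sociogram_layer()].
#' @param profiles membership matrix (rownames = student ids); column 1 is
#'   the high-achievement group, column 2 the low-achievement group.
#' @param group `"high"` or `"low"`.
#' @param damping PageRank damping factor.
#' @return Spearman rho; NA with attribute `flagged = TRUE` when PageRank or
#'   the membership column is constant across the classroom.
#' @export
status_profile_correlation <- function(layer, profiles, group = c("high", "low"),
                                       damping = 0.85) {
  group <- match.arg(group)
  theta <- profile_matrix(profiles, layer$roster)
  pr <- pagerank_status(layer, damping)
  memb <- theta[, if (group == "high") 1L else 2L]
  if (sd(pr) == 0 || sd(memb) == 0) {
    return(structure(NA_real_, flagged = TRUE))
  }
  structure(cor(pr, memb, method = "spearman"), flagged = FALSE)
}

#' Membership-shuffling null for the status correlation
#'
#' @inheritParams status_profile_correlation
#' @param n_shuffles number of permutations (>= 2).
#' @param seed integer seed.
#' @return List with `mean`, `sd` and `samples`.
#' @export
status_null <- function(layer, profiles, group = c("high", "low"),
                        n_shuffles = 1000L, seed = 1L, damping = 0.85) {
  group <- match.arg(group)
  stopifnot(n_shuffles >= 2)
  theta <- profile_matrix(profiles, layer$roster)
  pr <- pagerank_status(layer, damping)
  memb <- theta[, if (group == "high") 1L else 2L]
  if (sd(pr) == 0 || sd(memb) == 0) {
    return(list(mean = NA_real_, sd = NA_real_, samples = rep(NA_real_, n_shuffles)))
  }
  pr_rank <- rank(pr)
  samples <- withr::with_seed(derive_seed(seed, "status-null"), {
    vapply(seq_len(n_shuffles), function(i) {
      cor(pr_rank, rank(sample(memb)), method = "spearman")
    }, numeric(1))
  })
  list(mean = mean(samples), sd = sd(samples), samples = samples)
}

#' Average per-classroom statistics within age
#'
#' Flagged or undefined (NA) classrooms are excluded from the averages and
#' counted.
#'
#' @param per_classroom_values numeric vector, one value per classroom.
#' @param ages integer vector of classroom ages, same length.
#' @return data.frame with `age`, `mean`, `n`, `n_excluded`.
#' @export
aggregate_by_age <- function(per_classroom_values, ages) {
  stopifnot(length(per_classroom_values) == length(ages))
  d <- data.frame(value = as.numeric(per_classroom_values), age = ages)
  out <- do.call(rbind, lapply(split(d, d$age), function(g) {
    ok <- !is.na(g$value)
    data.frame(age = g$age[1],
               mean = if (any(ok)) mean(g$value[ok]) else NA_real_,
               n = sum(ok), n_excluded = sum(!ok))
  }))
  out[order(out$age), ]
}
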