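#' Edge overlap between sociogram layers and its rewiring null
#'
#' Overlap between two nomination layers of the same classroom is the
#' Jaccard index of their directed edge sets, |A int B| / |A un B|. The null
#' model randomizes each layer by directed double-edge swaps, which preserve
#' every student's in- and out-degree exactly, and recomputes the overlap;
#' observed overlaps are compared with the distribution of these null
#' overlaps.
#'
#' @name sociogram_overlap
NULL

#' Jaccard index of two layers' directed edge sets
#'
#' @param A,B [sociogram_layer()] objects over the same roster.
#' @return |A int B| / |A un B|; 0 when both layers are empty.
#' @export
jaccard_overlap <- function(A, B) {
  if (!setequal(A$roster, B$roster)) stopf("layers are over different rosters")
  ka <- edge_keys(A); kb <- edge_keys(B)
  if (length(ka) == 0L && length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Degree-preserving randomization of a nomination layer
#'
#' Performs directed double-edge swaps: two edges (a -> b), (c -> d) are
#' replaced by (a -> d), (c -> b) unless that would create a self-loop or a
#' duplicate edge. Every node's in- and out-degree is unchanged exactly.
#' Layers where no swap is feasible are returned unchanged with attribute
#' `no_swap = TRUE`.
#'
#' @param layer a [sociogram_layer()] with >= 2 edges for any swap to occur.
#' @param n_swap_multiplier attempted swaps = multiplier x number of edges.
#' @param seed integer seed.
#' @return A rewired [sociogram_layer()].
#' @export
rewire_preserving_degrees <- function(layer, n_swap_multiplier = 10, seed = 1L) {
  m <- nrow(layer$edges)
  if (m < 2L) {
    out <- layer
    attr(out, "no_swap") <- TRUE
    return(out)
  }
  n <- length(layer$roster)
  src <- match(layer$edges$source, layer$roster)
  tgt <- match(layer$edges$target, layer$roster)
  present <- logical(n * n)  # edge (i -> j) at slot (i - 1) * n + j
  present[(src - 1L) * n + tgt] <- TRUE
  attempts <- ceiling(n_swap_multiplier * m)
  accepted <- 0L
  withr::with_seed(seed, {
    e1 <- sample.int(m, attempts, replace = TRUE)
    e2 <- sample.int(m, attempts, replace = TRUE)
    for (i in seq_len(attempts)) {
      a <- e1[i]; b <- e2[i]
      if (a == b) next
      sa <- src[a]; ta <- tgt[a]; sb <- src[b]; tb <- tgt[b]
      if (sa == tb || sb == ta) next            # would create a self-loop
      if (present[(sa - 1L) * n + tb] || present[(sb - 1L) * n + ta]) next
      present[(sa - 1L) * n + ta] <- FALSE
      present[(sb - 1L) * n + tb] <- FALSE
      present[(sa - 1L) * n + tb] <- TRUE
      present[(sb - 1L) * n + ta] <- TRUE
      tgt[a] <- tb; tgt[b] <- ta
      accepted <- accepted + 1L
    }
  })
  out <- sociogram_layer(
    layer$label,
    data.frame(source = layer$roster[src], target = layer$roster[tgt]),
    layer$roster,
    max_out = max(3L, max(tabulate(src, n)))
  )
  attr(out, "no_swap") <- accepted == 0L
  attr(out, "n_accepted") <- accepted
  out
}

#' Null distribution of the overlap between two layers
#'
#' Both layers are rewired independently per sample and the Jaccard index of
#' the rewired pair recorded.
#'
#' @param A,B [sociogram_layer()] objects over the same roster.
#' @param n_samples number of null samples (>= 2).
#' @param seed integer seed.
#' @param n_swap_multiplier passed to [rewire_preserving_degrees()].
#' @return List with `mean`, `sd` and `samples`.
#' @export
null_overlap <- function(A, B, n_samples = 1000L, seed = 1L,
                         n_swap_multiplier = 10) {
  stopifnot(n_samples >= 2)
  samples <- vapply(seq_len(n_samples), function(i) {
    jaccard_overlap(
      rewire_preserving_degrees(A, n_swap_multiplier, seed = derive_seed(seed, paste0("A", i))),
      rewire_preserving_degrees(B, n_swap_multiplier, seed = derive_seed(seed, paste0("B", i)))
    )
  }, numeric(1))
  list(mean = mean(samples), sd = sd(samples), samples = samples)
}

#' Per-age average overlap between two layers, with its null
#'
#' Computes the observed Jaccard overlap for every classroom, averages
#' within age (SEM = sd / sqrt(n)), and summarizes the rewiring null the
#' same way: the age-level null mean averages the per-classroom null means,
#' and the age-level null sd is the sd of the age average under independent
#' classroom nulls, sqrt(sum sigma_c^2) / n.
#'
#' @param dataset list of elements each holding `classroom` and `sociogram`
#'   (as returned by [make_age_series()] or [read_sociograms()]).
#' @param layer_pair character vector of two layer labels.
#' @param n_samples null samples per classroom.
#' @param seed integer seed.
#' @return data.frame with one row per age: `age`, `n_classrooms`, `mean`,
#'   `sem`, `null_mean`, `null_sd`.
#' @export
overlap_by_age <- function(dataset, layer_pair = c("work+", "play+"),
                           n_samples = 200L, seed = 1L) {
  stopifnot(length(layer_pair) == 2)
  rows <- lapply(seq_along(dataset), function(i) {
    el <- dataset[[i]]
    A <- el$sociogram$layers[[layer_pair[1]]]
    B <- el$sociogram$layers[[layer_pair[2]]]
    if (is.null(A) || is.null(B)) stopf("classroom %s lacks a requested layer", el$classroom$classroom_id)
    nl <- null_overlap(A, B, n_samples, seed = derive_seed(seed, paste0("class", i)))
    data.frame(age = el$classroom$age, observed = jaccard_overlap(A, B),
               null_mean = nl$mean, null_sd = nl$sd)
  })
  per_class <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(per_class, per_class$age), function(d) {
    n <- nrow(d)
    data.frame(
      age = d$age[1], n_classrooms = n,
      mean = mean(d$observed),
      sem = if (n > 1) sd(d$observed) / sqrt(n) else NA_real_,
      null_mean = mean(d$null_mean),
      null_sd = sqrt(sum(d$null_sd^2)) / n
    )
  }))
  out[order(out$age), ]
}

#' Same-gender edge fraction with a label-shuffling null
#'
#' Edges with an endpoint whose gender is "no-answer" or "other" are
#' excluded from both numerator and denominator. The null shuffles gender
#' labels among the classroom's students and recomputes the fraction.
#'
#' @param layer a [sociogram_layer()].
#' @param roster data.frame with `student_id`, `gender` (the classroom's
#'   `students` table).
#' @param n_shuffles null shuffles.
#' @param seed integer seed.
#' @return List with `fraction` (NA and `flagged = TRUE` when no eligible
#'   edges), `null_mean`, `null_sd`, `n_eligible`.
#' @export
gender_homophily <- function(layer, roster, n_shuffles = 1000L, seed = 1L) {
  g <- setNames(roster$gender, roster$student_id)
  frac_same <- function(gmap) {
    gs <- gmap[layer$edges$source]; gt <- gmap[layer$edges$target]
    ok <- gs %in% c("boy", "girl") & gt %in% c("boy", "girl")
    if (!any(ok)) return(NA_real_)
    mean(gs[ok] == gt[ok])
  }
  observed <- frac_same(g)
  null <- withr::with_seed(derive_seed(seed, "gender-null"), {
    vapply(seq_len(n_shuffles), function(i) {
      frac_same(setNames(sample(g), names(g)))
    }, numeric(1))
  })
  list(
    fraction = observed,
    flagged = is.na(observed),
    null_mean = mean(null, na.rm = TRUE),
    null_sd = sd(null, na.rm = TRUE),
    n_eligible = sum(g[layer$edges$source] %in% c("boy", "girl") &
                       g[layer$edges$target] %in% c("boy", "girl"))
  )
}
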