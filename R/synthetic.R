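#' Synthetic study populations with planted block structure
#'
#' The generator emulates the statistical structure of the study data:
#' classrooms of 20-30 students aged 6-15, 8-10 cognitive tasks scored in
#' quintiles 1-5, three latent achievement groups (I high, II low, III
#' average) with student memberships concentrated on the I-III and II-III
#' simplex edges, and five directed nomination layers per classroom with
#' tunable cognitive homophily, gender homophily and preference for
#' high-achieving nominees. Because the truth is planted, every downstream
#' estimator can be tested for recovery and null calibration without access
#' to school data.
#'
#' @name synthetic_data
NULL

GENDER_PROBS <- c(boy = 0.46, girl = 0.40, `no-answer` = 0.13, other = 0.01)

sample_genders <- function(n) {
  sample(names(GENDER_PROBS), n, replace = TRUE, prob = GENDER_PROBS)
}

# Student membership vectors on the (I, II, III) simplex following the
# observed pattern: mass on the I-III or II-III edges or pure group II,
# never mixing I (high) and II (low).
planted_thetas <- function(n) {
  type <- sample(c("pureII", "edgeII_III", "edgeI_III"), n,
                 replace = TRUE, prob = c(1, 1, 1) / 3)
  w <- runif(n)
  theta <- matrix(0, n, 3)
  theta[type == "pureII", 2] <- 1
  i <- type == "edgeII_III"
  theta[i, 2] <- w[i]; theta[i, 3] <- 1 - w[i]
  i <- type == "edgeI_III"
  theta[i, 1] <- w[i]; theta[i, 3] <- 1 - w[i]
  theta
}

# Score distributions stochastically ordered by achievement group: sharply
# peaked with exponential decay away from a group- and task-group-specific
# peak quintile. Within every task group the peaks are ordered I > III > II
# (high > average > low); across task groups the peak triples differ
# ((5,1,3), (4,1,2), (5,2,4)), so task groups are identifiable and carry
# predictive value. The decay scale is small (0.15): with ~10 observed
# tasks per student, a student's mixing weight on a simplex edge is only
# recoverable when single scores identify the emitting group, so the
# planted components must be close to disjoint (see the methods vignette
# for the information-floor argument).
planted_p <- function(L) {
  peaks <- rbind(c(5, 1, 3), c(4, 1, 2), c(5, 2, 4))  # columns: I, II, III
  tau <- 0.15 + runif(L, -0.01, 0.01)
  p <- array(0, dim = c(3, L, 5))
  for (l in seq_len(L)) {
    pk <- peaks[(l - 1L) %% 3L + 1L, ]
    for (k in 1:3) {
      w <- exp(-abs(SCORES - pk[k]) / tau[l])
      p[k, l, ] <- w / sum(w)
    }
  }
  p
}

# Partition n students into classrooms of size 20-30 (remainder folded into
# the last classroom when small), each with an age and self-reported genders.
make_roster <- function(n_students, ids, ages = 6:15) {
  sizes <- integer(0)
  left <- n_students
  while (left > 0) {
    sz <- min(left, sample(20:30, 1))
    sizes <- c(sizes, sz)
    left <- left - sz
  }
  if (length(sizes) > 1 && sizes[length(sizes)] < 10) {
    sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  start <- cumsum(c(1L, sizes[-length(sizes)]))
  lapply(seq_along(sizes), function(i) {
    idx <- start[i]:(start[i] + sizes[i] - 1L)
    classroom(
      classroom_id = sprintf("c%03d", i),
      age = sample(ages, 1),
      students = data.frame(student_id = ids[idx], gender = sample_genders(sizes[i]))
    )
  })
}

#' Generate planted model parameters and a classroom roster
#'
#' @param n_students,n_tasks population dimensions.
#' @param K,L numbers of student and task groups.
#' @param pattern `"paper"` (K = L = 3 only): student memberships on the
#'   I-III / II-III simplex edges or pure group II, near-pure task
#'   memberships, and score distributions ordered so group I is
#'   highest-achieving, II lowest, III intermediate. `"pure"`: one-hot
#'   memberships. `"uniform"`: flat Dirichlet rows.
#' @param seed integer seed.
#' @return A `planted_population`: `theta_true` (n_students x K),
#'   `eta_true` (n_tasks x L), `p_true` (K x L x 5), `roster` (list of
#'   [classroom()]), plus `users` and `tasks` id vectors.
#' @export
make_planted_params <- function(n_students, n_tasks, K = 3L, L = 3L,
                                pattern = c("paper", "pure", "uniform"),
                                seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(K >= 1, L >= 1, n_students >= 1, n_tasks >= 1)
  if (pattern == "paper" && (K != 3L || L != 3L)) {
    stopf("pattern 'paper' requires K = L = 3")
  }
  users <- sprintf("s%04d", seq_len(n_students))
  tasks <- sprintf("t%02d", seq_len(n_tasks))
  withr::with_seed(seed, {
    if (pattern == "paper") {
      theta <- planted_thetas(n_students)
      dominant <- rep_len(seq_len(L), n_tasks)
      mass <- runif(n_tasks, 0.92, 0.99)
      eta <- matrix((1 - mass) / (L - 1), n_tasks, L)
      eta[cbind(seq_len(n_tasks), dominant)] <- mass
      if (L == 1L) eta[] <- 1
      p <- planted_p(L)
    } else if (pattern == "pure") {
      theta <- diag(K)[sample(K, n_students, replace = TRUE), , drop = FALSE]
      eta <- diag(L)[sample(L, n_tasks, replace = TRUE), , drop = FALSE]
      # well-separated peaked score distributions (peaks spread over the
      # quintiles, decay scale cycling per task group) so the planted
      # single-group structure is identifiable from realistic link counts
      peaks <- round(seq(5, 1, length.out = K))
      tau <- rep_len(c(0.25, 0.35, 0.30), L)
      p <- array(0, dim = c(K, L, 5))
      for (l in seq_len(L)) for (k in seq_len(K)) {
        w <- exp(-abs(SCORES - peaks[k]) / tau[l])
        p[k, l, ] <- w / sum(w)
      }
    } else {
      theta <- rdirichlet_rows(n_students, K)
      eta <- rdirichlet_rows(n_tasks, L)
      p <- array(rdirichlet_rows(K * L, 5), dim = c(K, L, 5))
    }
    roster <- make_roster(n_students, users)
  })
  rownames(theta) <- users
  rownames(eta) <- tasks
  structure(
    list(theta_true = theta, eta_true = eta, p_true = p,
         roster = roster, users = users, tasks = tasks),
    class = "planted_population"
  )
}

#' @export
print.planted_population <- function(x, ...) {
  cat(sprintf(
    "planted_population: %d students (K=%d), %d tasks (L=%d), %d classrooms\n",
    nrow(x$theta_true), ncol(x$theta_true), nrow(x$eta_true), ncol(x$eta_true),
    length(x$roster)
  ))
  invisible(x)
}

#' Sample a ratings table from a planted population
#'
#' Each (student, task) pair is observed independently with probability
#' `coverage`; observed scores are drawn from the model's categorical law
#' `Pr(s) = sum_{k,l} theta_uk eta_tl p_kl(s)`.
#'
#' @param population a [make_planted_params()] result.
#' @param coverage observation probability in (0, 1].
#' @param seed integer seed.
#' @return A [ratings_table()].
#' @export
sample_ratings <- function(population, coverage = 1, seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1)
  U <- nrow(population$theta_true); T <- nrow(population$eta_true)
  params <- mmsbm_params(population$theta_true, population$eta_true,
                         population$p_true,
                         users = population$users, tasks = population$tasks)
  grid <- expand.grid(u = seq_len(U), t = seq_len(T))
  withr::with_seed(seed, {
    keep <- runif(nrow(grid)) < coverage
    grid <- grid[keep, , drop = FALSE]
    K <- ncol(params$theta); L <- ncol(params$eta)
    kcol <- rep(seq_len(K), times = L); lcol <- rep(seq_len(L), each = K)
    mix <- params$theta[grid$u, kcol, drop = FALSE] *
      params$eta[grid$t, lcol, drop = FALSE]
    prob <- mix %*% t(p_flat(params))
    scores <- sample_categorical_rows(prob)
  })
  ratings_table(
    data.frame(user_id = population$users[grid$u],
               task_id = population$tasks[grid$t],
               score = scores),
    users = population$users, tasks = population$tasks
  )
}

#' Specification of one nomination layer's generative weights
#'
#' Nominee v is chosen by nominator u with weight proportional to
#' `exp(-lambda_cog * d(u, v) + gamma_gender * same_gender + beta_status *
#' theta_v[high])`, where d is the Euclidean distance between cognitive
#' profiles. Negative-sign layers ("would not work/play with") flip the sign
#' of `lambda_cog`, making them cognitively disassortative.
#'
#' @param lambda_cog cognitive homophily strength (>= 0 attracts similar
#'   profiles in positive layers).
#' @param gamma_gender log-weight bonus for same-gender nominees.
#' @param beta_status log-weight per unit membership of the nominee in the
#'   high-achievement group.
#' @param sign `"positive"` or `"negative"`.
#' @param max_nominations per-child nomination cap (>= 1).
#' @return A `sociogram_spec` object.
#' @export
sociogram_spec <- function(lambda_cog = 0, gamma_gender = 0, beta_status = 0,
                           sign = c("positive", "negative"),
                           max_nominations = 3L) {
  sign <- match.arg(sign)
  if (max_nominations < 1L) stopf("max_nominations must be >= 1")
  structure(
    list(lambda_cog = lambda_cog, gamma_gender = gamma_gender,
         beta_status = beta_status, sign = sign,
         max_nominations = as.integer(max_nominations)),
    class = "sociogram_spec"
  )
}

# Core nomination sampler. Each student draws a nomination count uniformly
# from 1..max_nominations, then picks that many distinct classmates without
# replacement with the spec's softmax weights. If base_edges is given, each
# of the nominator's base nominees is retained with probability copy_prob
# (capped by the nomination count), planting edge overlap between layers.
sample_layer_edges <- function(ids, theta, genders, spec,
                               base_edges = NULL, copy_prob = 0) {
  n <- length(ids)
  lam <- if (spec$sign == "negative") -spec$lambda_cog else spec$lambda_cog
  d <- as.matrix(stats::dist(theta))
  w_base <- -lam * d +
    spec$gamma_gender * outer(genders, genders, "==") +
    matrix(spec$beta_status * theta[, 1], n, n, byrow = TRUE)
  src <- tgt <- character(0)
  for (i in seq_len(n)) {
    n_nom <- sample.int(spec$max_nominations, 1L)
    picked <- integer(0)
    if (!is.null(base_edges) && copy_prob > 0) {
      prev <- match(base_edges$target[base_edges$source == ids[i]], ids)
      kept <- prev[runif(length(prev)) < copy_prob]
      if (length(kept) > n_nom) kept <- sample(kept, n_nom)
      picked <- kept
    }
    free <- setdiff(seq_len(n)[-i], picked)
    n_more <- n_nom - length(picked)
    if (n_more > 0 && length(free) > 0) {
      w <- exp(w_base[i, free] - max(w_base[i, free]))
      picked <- c(picked, free[sample.int(length(free),
                                          min(n_more, length(free)),
                                          prob = w)])
    }
    src <- c(src, rep(ids[i], length(picked)))
    tgt <- c(tgt, ids[picked])
  }
  data.frame(source = src, target = tgt)
}

#' Sample one sociogram layer for a classroom
#'
#' @param classroom a [classroom()] object with at least
#'   `max_nominations + 1` students.
#' @param thetas matrix of cognitive profiles, one row per roster student (in
#'   roster order; column 1 is the high-achievement group).
#' @param genders character vector of genders in roster order (defaults to
#'   the roster's).
#' @param spec a [sociogram_spec()].
#' @param seed integer seed.
#' @param label layer label.
#' @return A [sociogram_layer()].
#' @export
sample_sociogram_layer <- function(classroom, thetas,
                                   genders = classroom$students$gender,
                                   spec = sociogram_spec(), seed = 1L,
                                   label = "work+") {
  ids <- classroom$students$student_id
  if (length(ids) < spec$max_nominations + 1L) {
    stopf("classroom %s too small for %d nominations",
          classroom$classroom_id, spec$max_nominations)
  }
  edges <- withr::with_seed(seed, sample_layer_edges(ids, thetas, genders, spec))
  sociogram_layer(label, edges, ids, max_out = spec$max_nominations)
}

#' Default age-series configuration
#'
#' One row per age 6-15: cognitive homophily `lambda_cog = 2` (a strong,
#' reliably detectable planted effect at classroom size ~25),
#' `gamma_gender = 1.3` (yields roughly 70-75% same-gender nominations under
#' the study's gender composition), `beta_status = 4.5` (a status preference
#' detectable beyond two null standard deviations in most classrooms of 25),
#' and a planted work/play overlap (`overlap_copy`) declining from 0.6 at
#' age 6 to 0.4 at age 15, emulating the age-related divergence of work and
#' play nominations.
#'
#' @param ages integer vector of ages.
#' @param n_classrooms classrooms per age.
#' @return data.frame consumed by [make_age_series()].
#' @export
default_age_config <- function(ages = 6:15, n_classrooms = 3L) {
  data.frame(age = ages, n_classrooms = n_classrooms,
             lambda_cog = 2, gamma_gender = 1.3, beta_status = 4.5,
             overlap_copy = seq(0.6, 0.4, length.out = length(ages)))
}

#' Generate a multi-age series of classrooms with full sociograms
#'
#' For each configured age, generates classrooms (sizes uniform on 20-30)
#' with planted cognitive profiles and all five nomination layers. The
#' `play+` layer copies each `work+` nomination with probability
#' `overlap_copy` before drawing its remaining nominations, so the planted
#' work/play edge overlap is controlled per age. Negative layers flip the
#' sign of the cognitive homophily (disassortative) and of the status
#' preference.
#'
#' @param config data.frame with columns `age`, `n_classrooms` and optional
#'   `lambda_cog`, `gamma_gender`, `beta_status`, `overlap_copy`.
#' @param seed integer seed; the same seed reproduces identical edge lists.
#' @return List with one element per classroom: `classroom`, `sociogram`
#'   (a [multilayer_sociogram()]) and `thetas` (planted profile matrix).
#' @export
make_age_series <- function(config = default_age_config(), seed = 1L) {
  stopifnot(is.data.frame(config), nrow(config) >= 1,
            all(c("age", "n_classrooms") %in% names(config)))
  defaults <- default_age_config()[1, setdiff(names(default_age_config()), c("age", "n_classrooms"))]
  for (nm in names(defaults)) if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]

  out <- list()
  idx <- 0L
  for (r in seq_len(nrow(config))) {
    for (ci in seq_len(config$n_classrooms[r])) {
      idx <- idx + 1L
      cseed <- derive_seed(seed, sprintf("age%d-class%d", config$age[r], ci))
      res <- withr::with_seed(cseed, {
        n <- sample(20:30, 1)
        ids <- sprintf("a%02dc%02ds%02d", config$age[r], ci, seq_len(n))
        cls <- classroom(sprintf("a%02dc%02d", config$age[r], ci),
                         age = config$age[r],
                         students = data.frame(student_id = ids,
                                               gender = sample_genders(n)))
        theta <- planted_thetas(n)
        rownames(theta) <- ids
        g <- cls$students$gender
        sp <- function(lam, gam, bet, sign = "positive") {
          sociogram_spec(lam, gam, bet, sign = sign)
        }
        with_cfg <- config[r, ]
        work_pos <- sample_layer_edges(ids, theta, g,
          sp(with_cfg$lambda_cog, with_cfg$gamma_gender, with_cfg$beta_status))
        play_pos <- sample_layer_edges(ids, theta, g,
          sp(with_cfg$lambda_cog, with_cfg$gamma_gender, 0),
          base_edges = work_pos, copy_prob = with_cfg$overlap_copy)
        friend <- sample_layer_edges(ids, theta, g,
          sp(with_cfg$lambda_cog, with_cfg$gamma_gender, 0))
        work_neg <- sample_layer_edges(ids, theta, g,
          sp(with_cfg$lambda_cog, 0, -with_cfg$beta_status, sign = "negative"))
        play_neg <- sample_layer_edges(ids, theta, g,
          sp(with_cfg$lambda_cog, 0, 0, sign = "negative"))
        layers <- list(
          sociogram_layer("work+", work_pos, ids),
          sociogram_layer("play+", play_pos, ids),
          sociogram_layer("friend", friend, ids),
          sociogram_layer("work-", work_neg, ids),
          sociogram_layer("play-", play_neg, ids)
        )
        list(classroom = cls, sociogram = multilayer_sociogram(cls, layers),
             thetas = theta)
      })
      out[[idx]] <- res
    }
  }
  out
}
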