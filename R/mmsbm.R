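#' Mixed-membership stochastic block model for bipartite ordinal scores
#'
#' The model: each student u carries a membership vector theta_u on the
#' K-simplex, each task t a membership vector eta_t on the L-simplex, and each
#' pair of latent groups (k, l) a probability distribution p_kl(s) over the
#' five quintile scores. The probability that student u obtains score s on
#' task t is
#'
#'   Pr(s_ut = s) = sum_{k,l} theta_uk * eta_tl * p_kl(s)
#'
#' and the observed links are independent given the parameters. Fitting is by
#' expectation-maximization on a variational lower bound: the E-step computes
#' per-link responsibilities omega_ut(k,l) proportional to
#' theta_uk * eta_tl * p_kl(s_ut), and the M-step re-estimates theta, eta and
#' p from responsibility sums, which never decreases the log-likelihood.
#'
#' @name mmsbm
NULL

#' Construct a parameter set for the mixed-membership block model
#'
#' @param theta U x K row-stochastic matrix of student memberships.
#' @param eta T x L row-stochastic matrix of task memberships.
#' @param p K x L x 5 array of score distributions, normalized over scores.
#' @param users,tasks optional id vectors labelling the rows of theta/eta.
#' @return An `mmsbm_params` object.
#' @export
mmsbm_params <- function(theta, eta, p, users = NULL, tasks = NULL) {
  theta <- as.matrix(theta); eta <- as.matrix(eta); p <- as.array(p)
  if (length(dim(p)) != 3L || dim(p)[3] != length(SCORES)) {
    stopf("p must be a K x L x %d array", length(SCORES))
  }
  K <- ncol(theta); L <- ncol(eta)
  if (dim(p)[1] != K || dim(p)[2] != L) stopf("p dimensions do not match theta/eta")
  chk_simplex(theta, "theta"); chk_simplex(eta, "eta")
  ps <- apply(p, c(1, 2), sum)
  if (any(abs(ps - 1) > 1e-8) || any(p < 0)) stopf("p slices must be distributions over scores")
  structure(
    list(theta = theta, eta = eta, p = p,
         users = users %||% rownames(theta), tasks = tasks %||% rownames(eta)),
    class = "mmsbm_params"
  )
}

chk_simplex <- function(m, what) {
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
    stopf("%s rows must be points on the probability simplex", what)
  }
  invisible(m)
}

#' @export
print.mmsbm_params <- function(x, ...) {
  cat(sprintf(
    "mmsbm_params: U=%d students (K=%d groups), T=%d tasks (L=%d groups)\n",
    nrow(x$theta), ncol(x$theta), nrow(x$eta), ncol(x$eta)
  ))
  invisible(x)
}

#' Random initial parameters
#'
#' Strictly positive random simplex rows (flat Dirichlet): zero entries are
#' absorbing under the multiplicative EM updates, so the initializer never
#' produces them.
#'
#' @param U,T numbers of students and tasks.
#' @param K,L numbers of student and task groups.
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return An `mmsbm_params` object.
#' @export
init_params <- function(U, T, K, L, seed = 1L) {
  if (any(c(U, T, K, L) < 1)) stopf("dimensions must be >= 1")
  withr::with_seed(seed, {
    theta <- rdirichlet_rows(U, K)
    eta <- rdirichlet_rows(T, L)
    p <- array(rdirichlet_rows(K * L, length(SCORES)), dim = c(K, L, length(SCORES)))
  })
  mmsbm_params(theta, eta, p)
}

# p as an S x (K*L) matrix, columns in column-major (k fastest) order.
p_flat <- function(params) {
  K <- ncol(params$theta); L <- ncol(params$eta)
  t(matrix(params$p, nrow = K * L, ncol = length(SCORES)))
}

# Unnormalized responsibilities: N x (K*L) matrix whose row sums are the
# per-link probabilities of Pr(s_ut = s).
omega_numerator <- function(params, idx) {
  K <- ncol(params$theta); L <- ncol(params$eta)
  kcol <- rep(seq_len(K), times = L)
  lcol <- rep(seq_len(L), each = K)
  params$theta[idx$u, kcol, drop = FALSE] *
    params$eta[idx$t, lcol, drop = FALSE] *
    p_flat(params)[idx$s, , drop = FALSE]
}

resolve_indices <- function(params, ratings) {
  users <- params$users; tasks <- params$tasks
  if (is.null(users) || is.null(tasks)) return(link_indices(ratings))
  u <- match(ratings$user_id, users); t <- match(ratings$task_id, tasks)
  if (anyNA(u)) stopf("unknown user id: %s", ratings$user_id[which(is.na(u))[1]])
  if (anyNA(t)) stopf("unknown task id: %s", ratings$task_id[which(is.na(t))[1]])
  list(u = u, t = t, s = as.integer(ratings$score))
}

#' Marginal score probability for one (student, task) pair
#'
#' @param params an `mmsbm_params` object.
#' @param u,t user and task identifiers (ids if the params carry them,
#'   otherwise row indices).
#' @param s score(s) in 1..5; default all five.
#' @return Numeric vector of probabilities, one per requested score.
#' @export
score_probability <- function(params, u, t, s = SCORES) {
  if (!all(s %in% SCORES)) stopf("score must be in 1..5")
  if (!is.null(params$users) && !all(as.character(u) %in% params$users)) {
    stopf("unknown user id: %s", setdiff(as.character(u), params$users)[1])
  }
  if (!is.null(params$tasks) && !all(as.character(t) %in% params$tasks)) {
    stopf("unknown task id: %s", setdiff(as.character(t), params$tasks)[1])
  }
  rt <- ratings_table(
    data.frame(user_id = u, task_id = t, score = s[1]),
    users = params$users %||% as.character(u),
    tasks = params$tasks %||% as.character(t)
  )
  idx <- resolve_indices(params, rt)
  pm <- p_flat(params)
  K <- ncol(params$theta); L <- ncol(params$eta)
  kcol <- rep(seq_len(K), times = L); lcol <- rep(seq_len(L), each = K)
  mix <- params$theta[idx$u, kcol] * params$eta[idx$t, lcol]
  as.numeric(pm[s, , drop = FALSE] %*% mix)
}

#' Log-likelihood of a ratings table
#'
#' Sum over observed links of the log marginal probability of the observed
#' score. Returns -Inf only if some link has probability exactly zero.
#'
#' @inheritParams score_probability
#' @param ratings a `ratings_table`.
#' @return A single number (0 for an empty table).
#' @export
log_likelihood <- function(params, ratings) {
  if (nrow(ratings) == 0L) return(0)
  idx <- resolve_indices(params, ratings)
  sum(log(rowSums(omega_numerator(params, idx))))
}

#' Variational E-step: per-link responsibilities
#'
#' For each observed link, omega_ut(k,l) is proportional to
#' theta_uk * eta_tl * p_kl(s_ut), normalized over all (k, l).
#'
#' @inheritParams log_likelihood
#' @return N x (K*L) matrix (columns in column-major (k,l) order, k fastest),
#'   each row summing to 1, with attribute `dims = c(K, L)`.
#' @export
e_step <- function(params, ratings) {
  idx <- resolve_indices(params, ratings)
  num <- omega_numerator(params, idx)
  z <- rowSums(num)
  if (any(z <= 0)) {
    stopf("degenerate parameters: link %d has zero probability", which(z <= 0)[1])
  }
  structure(num / z, dims = c(ncol(params$theta), ncol(params$eta)))
}

#' M-step: re-estimate parameters from responsibilities
#'
#' theta_uk averages the task-group-summed responsibilities over the links of
#' student u (dividing by the student's degree d_u); eta_tl does the same on
#' the task side; p_kl(s) is the share of (k,l) responsibility carried by
#' links with score s. Students or tasks without links, and (k,l) cells with
#' zero total responsibility, are set to uniform and flagged in the
#' `degenerate` attribute.
#'
#' @param omega responsibility matrix as returned by [e_step()].
#' @param ratings the `ratings_table` the responsibilities refer to.
#' @param U,T,K,L model dimensions.
#' @return An `mmsbm_params` object.
#' @export
m_step <- function(omega, ratings, U, T, K, L) {
  idx <- link_indices(ratings)
  S <- length(SCORES)
  kcol <- rep(seq_len(K), times = L); lcol <- rep(seq_len(L), each = K)

  sum_over_l <- t(rowsum(t(omega), kcol))  # N x K
  sum_over_k <- t(rowsum(t(omega), lcol))  # N x L

  acc_rows <- function(m, group, n_groups, width) {
    out <- matrix(0, n_groups, width)
    agg <- rowsum(m, group)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  theta_num <- acc_rows(sum_over_l, idx$u, U, K)
  eta_num <- acc_rows(sum_over_k, idx$t, T, L)

  d_u <- tabulate(idx$u, U); d_t <- tabulate(idx$t, T)
  zero_u <- d_u == 0; zero_t <- d_t == 0
  theta <- theta_num / pmax(d_u, 1)
  eta <- eta_num / pmax(d_t, 1)
  theta[zero_u, ] <- 1 / K
  eta[zero_t, ] <- 1 / L
  # guard against drift from accumulated floating error
  theta <- theta / rowSums(theta)
  eta <- eta / rowSums(eta)

  p_num <- acc_rows(omega, idx$s, S, K * L)  # S x (K*L)
  tot <- colSums(p_num)
  zero_kl <- tot <= 0
  pm <- sweep(p_num, 2L, pmax(tot, .Machine$double.xmin), "/")
  pm[, zero_kl] <- 1 / S
  p <- array(t(pm), dim = c(K, L, S))

  out <- mmsbm_params(theta, eta, p,
    users = attr(ratings, "users"), tasks = attr(ratings, "tasks")
  )
  attr(out, "degenerate") <- list(
    users = which(zero_u), tasks = which(zero_t),
    cells = which(zero_kl)
  )
  out
}

#' Fit the block model by expectation-maximization with restarts
#'
#' Alternates [e_step()] and [m_step()] until the largest absolute change in
#' any parameter drops below `tol` or `max_iter` is reached. Multiple random
#' restarts are run from independent seeded initializations and the run with
#' the highest final log-likelihood is returned.
#'
#' @param ratings a `ratings_table`.
#' @param K,L numbers of student and task groups.
#' @param seed integer seed; restart r uses a seed derived from it.
#' @param tol convergence threshold on the max absolute parameter change.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random restarts.
#' @return An `mmsbm_fit` object: `params`, `loglik_trace` (one value per
#'   iteration, non-decreasing), `n_iter`, `converged`, `seed`,
#'   `best_restart`, and `restart_logliks`.
#' @export
fit_em <- function(ratings, K, L, seed = 1L, tol = 1e-6, max_iter = 500L,
                   n_restarts = 10L) {
  stopifnot(max_iter >= 1, tol > 0, n_restarts >= 1)
  if (nrow(ratings) == 0L) stopf("cannot fit an empty ratings table")
  U <- length(attr(ratings, "users")); T <- length(attr(ratings, "tasks"))

  run_one <- function(r) {
    params <- init_params(U, T, K, L, seed = derive_seed(seed, paste0("restart", r)))
    params$users <- attr(ratings, "users"); params$tasks <- attr(ratings, "tasks")
    idx <- link_indices(ratings)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      num <- omega_numerator(params, idx)
      z <- rowSums(num)
      if (any(z <= 0)) stopf("degenerate parameters: a link has zero probability")
      trace[it] <- sum(log(z))
      omega <- num / z
      new <- m_step(omega, ratings, U, T, K, L)
      delta <- max(
        abs(new$theta - params$theta),
        abs(new$eta - params$eta),
        abs(new$p - params$p)
      )
      params <- new
      if (delta < tol) { converged <- TRUE; break }
    }
    list(params = params, trace = trace, converged = converged,
         final_ll = log_likelihood(params, ratings))
  }

  runs <- lapply(seq_len(n_restarts), run_one)
  lls <- vapply(runs, `[[`, numeric(1), "final_ll")
  best <- which.max(lls)
  structure(
    list(
      params = runs[[best]]$params,
      loglik_trace = runs[[best]]$trace,
      n_iter = length(runs[[best]]$trace),
      converged = runs[[best]]$converged,
      seed = seed,
      best_restart = best,
      restart_logliks = lls
    ),
    class = "mmsbm_fit"
  )
}

#' @export
print.mmsbm_fit <- function(x, ...) {
  cat(sprintf(
    "mmsbm_fit: K=%d, L=%d, %d iterations (%s), log-likelihood %.4f (best of %d restarts)\n",
    ncol(x$params$theta), ncol(x$params$eta), x$n_iter,
    if (x$converged) "converged" else "iteration cap", max(x$restart_logliks),
    length(x$restart_logliks)
  ))
  invisible(x)
}

#' Align group labels of a fitted model to a reference
#'
#' The model is identifiable only up to a relabeling of student groups and of
#' task groups. This permutes the candidate's labels to minimize the total L1
#' distance between the score tensors; exhaustive over all permutation pairs
#' for K, L <= 5, greedy matching otherwise.
#'
#' @param reference,candidate `mmsbm_params` with matching dimensions.
#' @return The candidate with permuted labels; attribute `perm` holds the
#'   applied permutations.
#' @export
align_labels <- function(reference, candidate) {
  K <- ncol(reference$theta); L <- ncol(reference$eta)
  if (ncol(candidate$theta) != K || ncol(candidate$eta) != L) {
    stopf("dimension mismatch between reference and candidate")
  }
  perms <- function(n) {
    if (n == 1L) return(list(1L))
    do.call(c, lapply(seq_len(n), function(i) {
      lapply(perms(n - 1L), function(p) c(i, setdiff(seq_len(n), i)[p]))
    }))
  }
  cost <- function(pk, pl) sum(abs(candidate$p[pk, pl, , drop = FALSE] - reference$p))
  if (K <= 5L && L <= 5L) {
    best <- NULL; best_cost <- Inf
    for (pk in perms(K)) for (pl in perms(L)) {
      cc <- cost(pk, pl)
      if (cc < best_cost) { best_cost <- cc; best <- list(pk = pk, pl = pl) }
    }
  } else {
    greedy_match <- function(n, pair_cost) {
      perm <- integer(n); left <- seq_len(n)
      for (i in seq_len(n)) {
        j <- left[which.min(vapply(left, pair_cost, numeric(1), i = i))]
        perm[i] <- j; left <- setdiff(left, j)
      }
      perm
    }
    pk <- greedy_match(K, function(j, i) sum(abs(candidate$p[j, , ] - reference$p[i, , ])))
    pl <- greedy_match(L, function(j, i) sum(abs(candidate$p[, j, ] - reference$p[, i, ])))
    best <- list(pk = pk, pl = pl)
  }
  out <- mmsbm_params(
    candidate$theta[, best$pk, drop = FALSE],
    candidate$eta[, best$pl, drop = FALSE],
    candidate$p[best$pk, best$pl, , drop = FALSE],
    users = candidate$users, tasks = candidate$tasks
  )
  attr(out, "perm") <- best
  out
}

#' Predict score distributions for (student, task) pairs
#'
#' @param params an `mmsbm_params` object carrying user/task ids.
#' @param pairs data.frame with columns `user_id`, `task_id`.
#' @return data.frame with the pair columns, `modal` (argmax score, ties
#'   broken toward the lower score) and columns `p1`..`p5`.
#' @export
predict_scores <- function(params, pairs) {
  stopifnot(all(c("user_id", "task_id") %in% names(pairs)))
  if (!is.null(params$users)) {
    bad <- setdiff(as.character(pairs$user_id), params$users)
    if (length(bad)) stopf("unknown user id: %s", bad[1])
    bad <- setdiff(as.character(pairs$task_id), params$tasks)
    if (length(bad)) stopf("unknown task id: %s", bad[1])
  }
  rt <- ratings_table(
    data.frame(user_id = pairs$user_id, task_id = pairs$task_id, score = 1L),
    users = params$users %||% unique(as.character(pairs$user_id)),
    tasks = params$tasks %||% unique(as.character(pairs$task_id))
  )
  idx <- resolve_indices(params, rt)
  K <- ncol(params$theta); L <- ncol(params$eta)
  kcol <- rep(seq_len(K), times = L); lcol <- rep(seq_len(L), each = K)
  mix <- params$theta[idx$u, kcol, drop = FALSE] * params$eta[idx$t, lcol, drop = FALSE]
  prob <- mix %*% t(p_flat(params))  # N x S
  colnames(prob) <- paste0("p", SCORES)
  modal <- max.col(prob, ties.method = "first")  # first = lower score on ties
  cbind(
    data.frame(user_id = pairs$user_id, task_id = pairs$task_id, modal = modal),
    as.data.frame(prob)
  )
}
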