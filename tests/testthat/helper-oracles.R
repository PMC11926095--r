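# Independent brute-force oracles and small fixture builders. These never
# call the implementation paths they are used to check.

# Marginal score probability by explicit enumeration over all (k, l).
oracle_score_prob <- function(theta_u, eta_t, p, s) {
  tot <- 0
  for (k in seq_along(theta_u)) for (l in seq_along(eta_t)) {
    tot <- tot + theta_u[k] * eta_t[l] * p[k, l, s]
  }
  tot
}

# Log-likelihood as a term-by-term sum of enumerated marginals.
oracle_loglik <- function(params, links) {
  tot <- 0
  for (i in seq_len(nrow(links))) {
    tot <- tot + log(oracle_score_prob(
      params$theta[links$u[i], ], params$eta[links$t[i], ],
      params$p, links$s[i]
    ))
  }
  tot
}

# Responsibilities by direct normalization of the enumerated numerator.
oracle_omega <- function(params, links) {
  K <- ncol(params$theta); L <- ncol(params$eta)
  out <- matrix(0, nrow(links), K * L)
  for (i in seq_len(nrow(links))) {
    num <- matrix(0, K, L)
    for (k in 1:K) for (l in 1:L) {
      num[k, l] <- params$theta[links$u[i], k] * params$eta[links$t[i], l] *
        params$p[k, l, links$s[i]]
    }
    out[i, ] <- as.vector(num) / sum(num)
  }
  out
}

# PageRank by plain power iteration with uniform teleport and dangling-node
# redistribution.
oracle_pagerank <- function(edges, roster, damping = 0.85, iters = 2000) {
  n <- length(roster)
  A <- matrix(0, n, n)
  si <- match(edges$source, roster); ti <- match(edges$target, roster)
  for (i in seq_along(si)) A[si[i], ti[i]] <- 1
  out_deg <- rowSums(A)
  pr <- rep(1 / n, n)
  for (it in seq_len(iters)) {
    new <- rep((1 - damping) / n, n)
    for (v in seq_len(n)) {
      if (out_deg[v] > 0) {
        new <- new + damping * pr[v] * A[v, ] / out_deg[v]
      } else {
        new <- new + damping * pr[v] / n
      }
    }
    if (max(abs(new - pr)) < 1e-14) { pr <- new; break }
    pr <- new
  }
  stats::setNames(pr, roster)
}

# Two-sided Mann-Whitney p-value by exhaustive enumeration of all
# assignments of the pooled tie-free sample to the two groups.
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">"))
  obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Small deterministic fixtures -----------------------------------------

tiny_ratings <- function() {
  ratings_table(data.frame(
    user_id = c("u1", "u1", "u2", "u2", "u3"),
    task_id = c("t1", "t2", "t1", "t2", "t1"),
    score = c(1L, 3L, 5L, 2L, 4L)
  ))
}

tiny_classroom <- function(n = 8, genders = NULL, id = "c1", age = 9) {
  ids <- sprintf("k%02d", seq_len(n))
  classroom(id, age, data.frame(
    student_id = ids,
    gender = genders %||% rep(c("boy", "girl"), length.out = n)
  ))
}

tiny_layer <- function(edges, n = 8, label = "work+") {
  cls <- tiny_classroom(n)
  sociogram_layer(label, edges, cls$students$student_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_params <- function(U, T, K, L, seed) {
  withr::with_seed(seed, {
    theta <- matrix(stats::rgamma(U * K, 1), U); theta <- theta / rowSums(theta)
    eta <- matrix(stats::rgamma(T * L, 1), T); eta <- eta / rowSums(eta)
    p <- array(stats::rgamma(K * L * 5, 1), c(K, L, 5))
    for (k in 1:K) for (l in 1:L) p[k, l, ] <- p[k, l, ] / sum(p[k, l, ])
    mmsbm_params(theta, eta, p)
  })
}

random_ratings <- function(U, T, seed, users = sprintf("u%d", 1:U),
                           tasks = sprintf("t%d", 1:T)) {
  grid <- expand.grid(user_id = users, task_id = tasks,
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    grid$score <- sample(1:5, nrow(grid), replace = TRUE)
  })
  ratings_table(grid, users = users, tasks = tasks)
}
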