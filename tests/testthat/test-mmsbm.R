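test_that("init_params produces valid, reproducible, strictly positive simplex rows", {
  p1 <- init_params(7, 4, 3, 2, seed = 42)
  p2 <- init_params(7, 4, 3, 2, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1$theta > 0) && all(p1$eta > 0) && all(p1$p > 0))
  expect_lt(max(abs(rowSums(p1$theta) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(p1$eta) - 1)), 1e-12)
  expect_lt(max(abs(apply(p1$p, c(1, 2), sum) - 1)), 1e-12)
  one <- init_params(3, 2, 1, 1, seed = 1)
  expect_equal(unname(one$theta), matrix(1, 3, 1))
  expect_equal(unname(one$eta), matrix(1, 2, 1))
  expect_error(init_params(0, 2, 1, 1), "dimensions")
})

test_that("score_probability collapses correctly and matches enumeration", {
  # single-group collapse: returns the p_11 row
  one <- init_params(2, 2, 1, 1, seed = 3)
  expect_equal(score_probability(one, 1, 1), as.numeric(one$p[1, 1, ]))
  # one-hot collapse picks out p_kl
  theta <- rbind(c(1, 0), c(0, 1)); eta <- rbind(c(0, 1), c(1, 0))
  p <- random_params(2, 2, 2, 2, seed = 9)$p
  ph <- mmsbm_params(theta, eta, p)
  expect_equal(score_probability(ph, 1, 1), as.numeric(p[1, 2, ]))
  # mixed membership equals the explicit 4-term sum
  pm <- mmsbm_params(rbind(c(0.3, 0.7), c(0.5, 0.5)),
                     rbind(c(0.6, 0.4), c(0.2, 0.8)), p)
  for (s in 1:5) {
    expect_equal(score_probability(pm, 1, 1, s),
                 oracle_score_prob(c(0.3, 0.7), c(0.6, 0.4), p, s),
                 tolerance = 1e-14)
  }
  expect_lt(abs(sum(score_probability(pm, 2, 1)) - 1), 1e-12)
  expect_error(score_probability(pm, 1, 1, 6), "score")
})

test_that("log_likelihood and e_step match brute-force enumeration to 1e-12", {
  for (seed in c(4, 5, 6)) {
    params <- random_params(5, 4, 2, 2, seed = seed)
    ratings <- random_ratings(5, 4, seed = seed + 100)
    links <- list(u = match(ratings$user_id, attr(ratings, "users")),
                  t = match(ratings$task_id, attr(ratings, "tasks")),
                  s = ratings$score)
    links <- as.data.frame(links)
    expect_equal(log_likelihood(params, ratings), oracle_loglik(params, links),
                 tolerance = 1e-12)
    om <- e_step(params, ratings)
    expect_lt(max(abs(om - oracle_omega(params, links))), 1e-12)
    expect_lt(max(abs(rowSums(om) - 1)), 1e-12)
  }
  expect_equal(log_likelihood(random_params(2, 2, 2, 2, 1),
                              ratings_table(data.frame(user_id = character(0),
                                                       task_id = character(0),
                                                       score = integer(0)),
                                            users = "u1", tasks = "t1")), 0)
})

test_that("e_step reduces to known closed forms", {
  one <- init_params(3, 3, 1, 1, seed = 2)
  r <- random_ratings(3, 3, seed = 7)
  expect_equal(unname(e_step(one, r)[, 1]), rep(1, nrow(r)))
  # constant p over (k,l): responsibilities factorize as theta_uk * eta_tl
  p <- array(rep(rep(0.2, 5), each = 4), c(2, 2, 5))
  params <- mmsbm_params(rbind(c(0.3, 0.7), c(0.6, 0.4), c(0.5, 0.5)),
                         rbind(c(0.1, 0.9), c(0.8, 0.2), c(0.25, 0.75)), p)
  om <- e_step(params, r)
  iu <- match(r$user_id, attr(r, "users")); it <- match(r$task_id, attr(r, "tasks"))
  expected <- cbind(params$theta[iu, 1] * params$eta[it, 1],
                    params$theta[iu, 2] * params$eta[it, 1],
                    params$theta[iu, 1] * params$eta[it, 2],
                    params$theta[iu, 2] * params$eta[it, 2])
  expect_lt(max(abs(om - expected)), 1e-12)
})

test_that("m_step reproduces hand-computed update sums", {
  # 3 users x 2 tasks, full bipartite, K = L = 2, hand-set responsibilities
  r <- ratings_table(data.frame(
    user_id = c("u1", "u1", "u2", "u2", "u3", "u3"),
    task_id = c("t1", "t2", "t1", "t2", "t1", "t2"),
    score = c(1L, 2L, 1L, 5L, 3L, 3L)
  ))
  om <- rbind(
    c(1, 0, 0, 0), c(0.5, 0.5, 0, 0), c(0.25, 0.25, 0.25, 0.25),
    c(0, 0, 1, 0), c(0.1, 0.2, 0.3, 0.4), c(0.7, 0.1, 0.1, 0.1)
  )
  out <- m_step(om, r, 3, 2, 2, 2)
  # theta_u1: links 1-2, sum over l of omega columns (k fastest): k=1 cols 1,3
  expect_equal(unname(out$theta[1, ]), c((1 + 0 + 0.5 + 0) / 2, (0 + 0 + 0.5 + 0) / 2))
  expect_equal(unname(out$theta[3, ]), c((0.1 + 0.3 + 0.7 + 0.1) / 2, (0.2 + 0.4 + 0.1 + 0.1) / 2))
  # eta_t1: links 1, 3, 5; l=1 is cols 1,2
  expect_equal(unname(out$eta[1, ]),
               c((1 + 0 + 0.25 + 0.25 + 0.1 + 0.2) / 3, (0 + 0 + 0.25 + 0.25 + 0.3 + 0.4) / 3))
  # p_kl(s): share of cell (1,1) mass on score 1 (links 1 and 3)
  cell11 <- om[, 1]
  expect_equal(out$p[1, 1, 1], sum(cell11[c(1, 3)]) / sum(cell11))
  expect_lt(max(abs(apply(out$p, c(1, 2), sum) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(out$theta) - 1)), 1e-12)
})

test_that("m_step point-mass responsibilities force one-hot memberships", {
  r <- random_ratings(4, 3, seed = 11)
  om <- matrix(0, nrow(r), 4); om[, 3] <- 1  # cell (k=1, l=2) in column-major
  out <- m_step(om, r, 4, 3, 2, 2)
  expect_equal(unname(out$theta[, 1]), rep(1, 4))
  expect_equal(unname(out$eta[, 2]), rep(1, 3))
  # uniform responsibilities give uniform memberships
  omu <- matrix(0.25, nrow(r), 4)
  outu <- m_step(omu, r, 4, 3, 2, 2)
  expect_equal(unname(outu$theta), matrix(0.5, 4, 2))
})

test_that("EM trace is monotone and invariants hold after every M-step", {
  for (seed in 1:10) {
    r <- random_ratings(8, 5, seed = seed)
    fit <- fit_em(r, 2, 2, seed = seed, max_iter = 60, n_restarts = 1)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  }
  # explicit invariant check along one trajectory
  r <- random_ratings(10, 6, seed = 77)
  params <- init_params(10, 6, 3, 2, seed = 1)
  params$users <- attr(r, "users"); params$tasks <- attr(r, "tasks")
  for (i in 1:25) {
    params <- m_step(e_step(params, r), r, 10, 6, 3, 2)
    expect_lt(max(abs(rowSums(params$theta) - 1)), 1e-12)
    expect_lt(max(abs(rowSums(params$eta) - 1)), 1e-12)
    expect_lt(max(abs(apply(params$p, c(1, 2), sum) - 1)), 1e-12)
  }
})

test_that("EM on single-score data collapses p to that score's point mass", {
  r <- ratings_table(data.frame(
    user_id = rep(sprintf("u%d", 1:6), each = 4),
    task_id = rep(sprintf("t%d", 1:4), times = 6),
    score = 3L
  ))
  fit <- fit_em(r, 2, 2, seed = 9, n_restarts = 1, max_iter = 100)
  expect_gt(min(fit$params$p[, , 3]), 1 - 1e-6)
})

test_that("fit_em recovers planted one-hot structure", {
  pop <- make_planted_params(300, 9, K = 3, L = 3, pattern = "pure", seed = 5)
  r <- sample_ratings(pop, coverage = 1, seed = 6)
  fit <- fit_em(r, 3, 3, seed = 7, n_restarts = 5, max_iter = 400)
  al <- align_labels(
    mmsbm_params(pop$theta_true, pop$eta_true, pop$p_true),
    fit$params
  )
  expect_lt(mean(abs(al$p - pop$p_true)), 0.05)
})

test_that("align_labels inverts a known permutation and matches exhaustive search", {
  ref <- random_params(6, 5, 3, 3, seed = 13)
  perm_k <- c(2, 3, 1); perm_l <- c(3, 1, 2)
  cand <- mmsbm_params(ref$theta[, perm_k], ref$eta[, perm_l],
                       ref$p[perm_k, perm_l, ])
  back <- align_labels(ref, cand)
  expect_equal(back$p, ref$p, tolerance = 1e-14)
  expect_equal(back$theta, ref$theta, tolerance = 1e-14)
  # identity case
  same <- align_labels(ref, ref)
  expect_equal(attr(same, "perm"), list(pk = 1:3, pl = 1:3))
  # random candidate: result must equal the exhaustive-minimum cost
  cand2 <- random_params(6, 5, 3, 3, seed = 14)
  out <- align_labels(ref, cand2)
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  costs <- sapply(perms(1:3), function(pk)
    sapply(perms(1:3), function(pl) sum(abs(cand2$p[pk, pl, ] - ref$p))))
  expect_equal(sum(abs(out$p - ref$p)), min(costs), tolerance = 1e-12)
  expect_error(align_labels(ref, random_params(6, 5, 2, 3, seed = 1)), "mismatch")
})

test_that("predict_scores returns normalized distributions and lower-tie modal scores", {
  p <- array(0, c(2, 2, 5)); p[, , 4] <- 1
  params <- mmsbm_params(rbind(c(0.5, 0.5), c(1, 0)), rbind(c(0.5, 0.5)), p,
                         users = c("u1", "u2"), tasks = "t1")
  out <- predict_scores(params, data.frame(user_id = c("u1", "u2"), task_id = "t1"))
  expect_equal(out$modal, c(4L, 4L))
  # tie between scores 2 and 5 resolves to the lower score
  p2 <- array(0, c(1, 1, 5)); p2[1, 1, c(2, 5)] <- 0.5
  params2 <- mmsbm_params(matrix(1), matrix(1), p2, users = "u1", tasks = "t1")
  expect_equal(predict_scores(params2, data.frame(user_id = "u1", task_id = "t1"))$modal, 2L)
  # distributions normalized and equal to the enumerated marginal
  pr <- random_params(4, 3, 2, 2, seed = 21)
  pr$users <- sprintf("u%d", 1:4); pr$tasks <- sprintf("t%d", 1:3)
  pairs <- data.frame(user_id = c("u2", "u4"), task_id = c("t1", "t3"))
  got <- predict_scores(pr, pairs)
  expect_lt(max(abs(rowSums(as.matrix(got[paste0("p", 1:5)])) - 1)), 1e-12)
  for (s in 1:5) {
    expect_equal(got[[paste0("p", s)]][2],
                 oracle_score_prob(pr$theta[4, ], pr$eta[3, ], pr$p, s),
                 tolerance = 1e-12)
  }
  expect_error(predict_scores(pr, data.frame(user_id = "nope", task_id = "t1")),
               "unknown user")
})

test_that("zero-degree users get uniform memberships with a degeneracy flag", {
  r <- ratings_table(data.frame(user_id = c("u1", "u2"), task_id = c("t1", "t1"),
                                score = c(2L, 4L)),
                     users = c("u1", "u2", "u3"), tasks = c("t1", "t2"))
  om <- e_step({
    p <- init_params(3, 2, 2, 2, seed = 1)
    p$users <- c("u1", "u2", "u3"); p$tasks <- c("t1", "t2"); p
  }, r)
  out <- m_step(om, r, 3, 2, 2, 2)
  expect_equal(unname(out$theta[3, ]), c(0.5, 0.5))
  expect_equal(attr(out, "degenerate")$users, 3L)
  expect_equal(attr(out, "degenerate")$tasks, 2L)
})
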