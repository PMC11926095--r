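test_that("layer constructor enforces roster, self-loop, duplicate and cap rules", {
  roster <- sprintf("k%02d", 1:8)
  expect_error(sociogram_layer("work+", data.frame(source = "k01", target = "k01"),
                               roster), "self")
  expect_error(sociogram_layer("work+",
                               data.frame(source = c("k01", "k01"),
                                          target = c("k02", "k02")), roster),
               "duplicate")
  expect_error(sociogram_layer("work+",
                               data.frame(source = rep("k01", 4),
                                          target = c("k02", "k03", "k04", "k05")),
                               roster), "nominations")
  expect_error(sociogram_layer("work+", data.frame(source = "k01", target = "zz"),
                               roster), "roster")
  expect_error(sociogram_layer("wat", data.frame(source = "k01", target = "k02"),
                               roster), "label")
})

test_that("jaccard_overlap enumerates edge sets as directed pairs", {
  A <- tiny_layer(data.frame(source = c("k01", "k02"), target = c("k02", "k03")))
  B <- tiny_layer(data.frame(source = c("k02", "k03"), target = c("k03", "k04")))
  expect_equal(jaccard_overlap(A, B), 1 / 3)
  expect_equal(jaccard_overlap(A, A), 1)
  C <- tiny_layer(data.frame(source = "k05", target = "k06"))
  expect_equal(jaccard_overlap(A, C), 0)
  # direction matters: the reversed edge is a different edge
  D <- tiny_layer(data.frame(source = "k02", target = "k01"))
  E <- tiny_layer(data.frame(source = "k01", target = "k02"))
  expect_equal(jaccard_overlap(D, E), 0)
  # symmetric; empty-empty defined as 0
  expect_equal(jaccard_overlap(B, A), jaccard_overlap(A, B))
  E0 <- tiny_layer(data.frame(source = character(0), target = character(0)))
  expect_equal(jaccard_overlap(E0, E0), 0)
  other <- sociogram_layer("work+", data.frame(source = "x1", target = "x2"),
                           c("x1", "x2"))
  expect_error(jaccard_overlap(A, other), "roster")
})

test_that("rewiring preserves in/out degree sequences exactly", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:25, 1)
    cls <- tiny_classroom(n, id = sprintf("r%02d", i))
    th <- matrix(1 / 3, n, 3); rownames(th) <- cls$students$student_id
    ly <- sample_sociogram_layer(cls, th, spec = sociogram_spec(1, 1, 1),
                                 seed = 600 + i)
    rw <- rewire_preserving_degrees(ly, seed = 700 + i)
    deg <- function(l) list(
      out = table(factor(l$edges$source, levels = l$roster)),
      `in` = table(factor(l$edges$target, levels = l$roster))
    )
    expect_equal(deg(rw), deg(ly))
    expect_false(any(rw$edges$source == rw$edges$target))
    expect_false(anyDuplicated(paste(rw$edges$source, rw$edges$target)) > 0)
  }
})

test_that("rewiring leaves unswappable layers unchanged but shuffles dense ones", {
  single <- tiny_layer(data.frame(source = "k01", target = "k02"))
  out <- rewire_preserving_degrees(single, seed = 1)
  expect_true(attr(out, "no_swap"))
  expect_equal(out$edges, single$edges)

  cls <- tiny_classroom(20)
  th <- matrix(1 / 3, 20, 3); rownames(th) <- cls$students$student_id
  dense <- sample_sociogram_layer(cls, th, seed = 5)
  rw <- rewire_preserving_degrees(dense, seed = 6)
  keys <- function(l) paste(l$edges$source, l$edges$target)
  expect_lt(length(intersect(keys(rw), keys(dense))) / nrow(dense$edges), 1)
})

test_that("null overlap brackets the chance expectation for unrelated layers", {
  # two independently generated neutral layers: E|A&B| ~ |A||B|/(n(n-1))
  set.seed(12)
  n <- 30
  cls <- tiny_classroom(n)
  th <- matrix(1 / 3, n, 3); rownames(th) <- cls$students$student_id
  A <- sample_sociogram_layer(cls, th, seed = 31)
  B <- sample_sociogram_layer(cls, th, seed = 32, label = "play+")
  nl <- null_overlap(A, B, n_samples = 200, seed = 33)
  ea <- nrow(A$edges); eb <- nrow(B$edges)
  # expected intersection under uniform random placement with fixed sizes,
  # converted to an approximate expected Jaccard
  exp_int <- ea * eb / (n * (n - 1))
  exp_j <- exp_int / (ea + eb - exp_int)
  expect_lt(abs(nl$mean - exp_j), 4 * nl$sd / sqrt(200) + 0.25 * exp_j)
  expect_length(nl$samples, 200)
  # identical dense layers rewired independently: null mean well below 1
  nid <- null_overlap(A, A, n_samples = 50, seed = 34)
  expect_lt(nid$mean, 1)
  # layers with no feasible swap: all samples equal the observed overlap
  s1 <- tiny_layer(data.frame(source = "k01", target = "k02"))
  s2 <- tiny_layer(data.frame(source = "k01", target = "k02"), label = "play+")
  ns <- null_overlap(s1, s2, n_samples = 2, seed = 35)
  expect_equal(ns$samples, c(1, 1))
})

test_that("per-age overlap aggregation averages classrooms within age", {
  series <- make_age_series(data.frame(age = c(8, 11), n_classrooms = 3),
                            seed = 41)
  tab <- overlap_by_age(series, c("work+", "play+"), n_samples = 20, seed = 42)
  expect_equal(tab$age, c(8, 11))
  expect_equal(tab$n_classrooms, c(3, 3))
  expect_true(all(is.finite(tab$mean)))
  expect_true(all(tab$sem >= 0))
  # duplicated classroom: SEM must be 0; single classroom: SEM missing
  one <- series[1]
  dup <- list(series[[1]], series[[1]])
  expect_equal(overlap_by_age(dup, c("work+", "play+"), n_samples = 5, seed = 2)$sem, 0)
  expect_true(is.na(overlap_by_age(one, c("work+", "play+"), n_samples = 5, seed = 2)$sem))
})

test_that("declining planted overlap shows up as declining per-age estimates", {
  cfg <- data.frame(age = c(7, 12, 15), n_classrooms = 4,
                    overlap_copy = c(0.8, 0.45, 0.1))
  series <- make_age_series(cfg, seed = 51)
  tab <- overlap_by_age(series, c("work+", "play+"), n_samples = 10, seed = 52)
  expect_true(tab$mean[1] > tab$mean[2] && tab$mean[2] > tab$mean[3])
})

test_that("gender homophily recovers planted preference against its shuffle null", {
  cls <- tiny_classroom(24)
  th <- matrix(1 / 3, 24, 3); rownames(th) <- cls$students$student_id
  hom <- sample_sociogram_layer(cls, th, spec = sociogram_spec(0, 3, 0), seed = 61)
  gh <- gender_homophily(hom, cls$students, n_shuffles = 300, seed = 62)
  expect_gt(gh$fraction, gh$null_mean + 2 * gh$null_sd)
  # all-boys classroom: fraction and null are both 1
  boys <- classroom("b", 9, data.frame(student_id = sprintf("b%02d", 1:10),
                                       gender = "boy"))
  thb <- matrix(1 / 3, 10, 3); rownames(thb) <- boys$students$student_id
  lyb <- sample_sociogram_layer(boys, thb, seed = 63)
  ghb <- gender_homophily(lyb, boys$students, n_shuffles = 20, seed = 64)
  expect_equal(ghb$fraction, 1)
  expect_equal(ghb$null_mean, 1)
  # undisclosed-gender students are excluded from the fraction
  mix <- classroom("m", 9, data.frame(
    student_id = c("m1", "m2", "m3", "m4"),
    gender = c("boy", "boy", "no-answer", "other")
  ))
  lym <- sociogram_layer("friend", data.frame(
    source = c("m1", "m3"), target = c("m2", "m4")
  ), mix$students$student_id)
  ghm <- gender_homophily(lym, mix$students, n_shuffles = 10, seed = 65)
  expect_equal(ghm$n_eligible, 1)
  expect_equal(ghm$fraction, 1)
})
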