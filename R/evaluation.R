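#' Holdout prediction experiments and model-dimension selection
#'
#' The predictive protocol hides a fraction of the observed (student, task)
#' links, fits the block model on the rest, and scores predictions on the
#' hidden links: exact accuracy (predicted modal quintile equals the observed
#' one) and one-off accuracy (within one quintile). A per-task mode predictor
#' provides the reference ordering.
#'
#' @name evaluation
NULL

#' Random train/test splits of a ratings table
#'
#' @param ratings a [ratings_table()].
#' @param hide_fraction fraction of links moved to the test set, in (0, 1).
#' @param n_splits number of independent splits (20 in the study protocol).
#' @param seed integer seed.
#' @return List of `holdout_split` objects, each with `train`, `test`,
#'   `hide_fraction`, `split` and `seed`.
#' @export
make_holdout_splits <- function(ratings, hide_fraction, n_splits = 20L, seed = 1L) {
  stopifnot(hide_fraction > 0, hide_fraction < 1, n_splits >= 1)
  n <- nrow(ratings)
  n_test <- round(n * hide_fraction)
  if (n_test >= n || n_test < 1) stopf("hide_fraction leaves an empty train or test set")
  lapply(seq_len(n_splits), function(i) {
    test_idx <- withr::with_seed(
      derive_seed(seed, paste0("split", i)),
      sample.int(n, n_test)
    )
    structure(
      list(train = subset_ratings(ratings, -test_idx),
           test = subset_ratings(ratings, test_idx),
           hide_fraction = hide_fraction, split = i, seed = seed),
      class = "holdout_split"
    )
  })
}

chk_aligned <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stopf("prediction/truth length mismatch")
  if (length(truth) == 0L) stopf("empty prediction set")
}

#' Exact prediction accuracy
#'
#' @param predictions,truth aligned integer score vectors.
#' @return Fraction of pairs with predicted score equal to the observed one.
#' @export
exact_accuracy <- function(predictions, truth) {
  chk_aligned(predictions, truth)
  mean(predictions == truth)
}

#' One-off prediction accuracy
#'
#' @inheritParams exact_accuracy
#' @return Fraction of pairs predicted within one quintile of the observed
#'   score.
#' @export
one_off_accuracy <- function(predictions, truth) {
  chk_aligned(predictions, truth)
  mean(abs(predictions - truth) <= 1)
}

#' Per-task mode baseline predictor
#'
#' Predicts, for any (student, task) pair, the most frequent training score
#' of that task (ties toward the lower score); tasks unseen in training fall
#' back to the global training mode.
#'
#' @param train a non-empty [ratings_table()].
#' @return A function mapping a data.frame with a `task_id` column to an
#'   integer score vector.
#' @export
baseline_mode_predictor <- function(train) {
  if (nrow(train) == 0L) stopf("empty training table")
  mode_of <- function(x) as.integer(names(which.max(table(factor(x, levels = SCORES)))))
  task_modes <- tapply(train$score, train$task_id, mode_of)
  global_mode <- mode_of(train$score)
  function(pairs) {
    m <- task_modes[as.character(pairs$task_id)]
    m[is.na(m)] <- global_mode
    as.integer(m)
  }
}

#' Grid search for the numbers of student and task groups
#'
#' Evaluates every (K, L) on the grid by mean exact accuracy over holdout
#' splits with 40% of links hidden, then applies a one-standard-error
#' parsimony rule: among all grid points whose mean accuracy is within one
#' standard error of the grid maximum, the one with the smallest K + L is
#' selected (ties broken by higher accuracy, then smaller K).
#'
#' @param ratings a [ratings_table()].
#' @param K_range,L_range integer candidate vectors.
#' @param seed integer seed.
#' @param n_splits holdout splits per grid point.
#' @param hide_fraction fraction hidden per split.
#' @param n_restarts,max_iter,tol EM settings used for the grid fits.
#' @return List with `K`, `L` and `table` (one row per grid point: K, L,
#'   mean exact accuracy, its standard error over splits).
#' @export
select_dimensions <- function(ratings, K_range = 1:5, L_range = 1:5, seed = 1L,
                              n_splits = 3L, hide_fraction = 0.4,
                              n_restarts = 2L, max_iter = 200L, tol = 1e-5) {
  stopifnot(length(K_range) >= 1, length(L_range) >= 1)
  splits <- make_holdout_splits(ratings, hide_fraction, n_splits,
                                seed = derive_seed(seed, "selection-splits"))
  grid <- expand.grid(K = K_range, L = L_range)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    acc <- vapply(splits, function(sp) {
      fit <- fit_em(sp$train, grid$K[g], grid$L[g],
                    seed = derive_seed(seed, sprintf("grid%d", g)),
                    tol = tol, max_iter = max_iter, n_restarts = n_restarts)
      pred <- predict_scores(fit$params, sp$test)
      exact_accuracy(pred$modal, sp$test$score)
    }, numeric(1))
    c(mean = mean(acc), se = sd(acc) / sqrt(length(acc)))
  })
  tab <- cbind(grid, do.call(rbind, res))
  best <- max(tab$mean)
  se_at_best <- tab$se[which.max(tab$mean)]
  ok <- tab$mean >= best - se_at_best
  cand <- tab[ok, , drop = FALSE]
  cand <- cand[order(cand$K + cand$L, -cand$mean, cand$K), , drop = FALSE]
  list(K = cand$K[1], L = cand$L[1], table = tab)
}

#' Per-student counts of high-discrepancy tasks
#'
#' For each student, counts the observed tasks where the observed score and
#' the model's modal prediction differ by at least `threshold` quintiles.
#' Also reports, among students with at least one such task, the fraction
#' with at most two.
#'
#' @param params fitted `mmsbm_params`.
#' @param ratings a [ratings_table()] of observed scores.
#' @param threshold discrepancy threshold in quintiles (>= 1; default 2).
#' @return List with `counts` (named per-student integer vector) and
#'   `frac_flagged_at_most_two`.
#' @export
discrepancy_profile <- function(params, ratings, threshold = 2L) {
  stopifnot(threshold >= 1)
  pred <- predict_scores(params, ratings)
  high <- abs(pred$modal - ratings$score) >= threshold
  tab <- tapply(high, factor(ratings$user_id, levels = attr(ratings, "users")), sum)
  counts <- setNames(as.integer(tab), names(tab))
  counts[is.na(counts)] <- 0L
  flagged <- counts[counts > 0]
  list(
    counts = counts,
    frac_flagged_at_most_two = if (length(flagged)) mean(flagged <= 2) else NA_real_
  )
}
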