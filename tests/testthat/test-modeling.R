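# small synthetic feature tables for protocol tests (no trace simulation)
toy_features <- function(n_per_class = c(novice = 6, intermediate = 6, expert = 6),
                         trials = 8, p = 5, sep = 0, idio = 0, seed = 1) {
  set.seed(seed)
  rows <- list(); pid <- 0
  for (cl in names(n_per_class)) {
    shift <- sep * (match(cl, names(n_per_class)) - 2)
    for (i in seq_len(n_per_class[[cl]])) {
      pid <- pid + 1
      off <- rnorm(p, 0, idio)
      x <- matrix(rnorm(trials * p) + rep(off, each = trials) + shift,
                  trials, p)
      colnames(x) <- paste0("f", seq_len(p))
      rows[[pid]] <- cbind(
        data.frame(trial_id = sprintf("P%02d_t%02d", pid, seq_len(trials)),
                   participant_id = sprintf("P%02d", pid), class_label = cl),
        as.data.frame(x))
    }
  }
  do.call(rbind, rows)
}

test_that("participant-wise splits never leak a participant across sides", {
  fm <- toy_features(c(novice = 12, intermediate = 10, expert = 13))
  for (s in 1:20) {
    plan <- participant_wise_split(fm, n_train = 8, n_eval = 2, seed = s)
    expect_length(intersect(plan$train_pid, plan$eval_pid), 0)
    expect_length(plan$train_pid, 24)
    expect_length(plan$eval_pid, 6)
    both <- fm$participant_id[plan$train_rows]
    expect_true(all(both %in% plan$train_pid))
  }
  # idle participants: 12/10/13 minus 10 used per class leaves 2 + 0 + 3
  plan <- participant_wise_split(fm, 8, 2, seed = 1)
  used <- c(plan$train_pid, plan$eval_pid)
  expect_equal(length(unique(fm$participant_id)) - length(used), 5)
  # deterministic under a fixed seed
  expect_identical(participant_wise_split(fm, 8, 2, seed = 3)$eval_pid,
                   participant_wise_split(fm, 8, 2, seed = 3)$eval_pid)
  expect_error(participant_wise_split(fm, 11, 2), "participants")
})

test_that("the ensemble separates separable data and degenerates sanely", {
  fm <- toy_features(trials = 10, sep = 4, seed = 2)
  fn <- paste0("f", 1:5)
  plan <- participant_wise_split(fm, n_train = 4, n_eval = 2, seed = 2)
  ens <- train_ensemble(as.matrix(fm[plan$train_rows, fn]),
                        fm$class_label[plan$train_rows], k = 5)
  res <- evaluate_leave_out(ens, fm, plan$eval_rows)
  expect_equal(res$accuracy, 1)
  expect_true(all(res$miss_rate == 0))
  # k = 1 reduces to a single direct fit
  x <- as.matrix(fm[plan$train_rows, fn])
  y <- fm$class_label[plan$train_rows]
  ens1 <- train_ensemble(x, y, k = 1)
  expect_length(ens1$models, 1)
  xs <- scale(x, ens1$center, ens1$scale)
  direct <- e1071::svm(xs, droplevels(factor(y)), kernel = "linear",
                       cost = 1, scale = FALSE)
  expect_identical(as.character(predict(ens1, fm[plan$eval_rows, fn])),
                   as.character(predict(direct,
                     scale(as.matrix(fm[plan$eval_rows, fn]),
                           ens1$center, ens1$scale))))
  expect_error(train_ensemble(x, rep("a", nrow(x)), k = 5), "2 classes")
  mixed <- c(1, 2, nrow(x))   # two classes, but fewer rows than folds
  expect_error(train_ensemble(x[mixed, ], y[mixed], k = 5), "folds")
})

test_that("feature importance ranks the separating feature first", {
  set.seed(4)
  x <- matrix(rnorm(1200), 300, 4)
  colnames(x) <- c("noise_a", "signal", "noise_b", "noise_c")
  y <- rep(c("A", "B"), each = 150)
  x[y == "B", "signal"] <- x[y == "B", "signal"] + 4
  ens <- train_ensemble(x, y, k = 5)
  imp <- feature_importance(ens)
  expect_identical(imp$feature[1], "signal")
  # duplicated columns tie and break by canonical name order
  x2 <- cbind(x, signal2 = x[, "signal"])
  ens2 <- train_ensemble(x2, y, k = 1)
  imp2 <- feature_importance(ens2)
  s <- imp2$importance[imp2$feature %in% c("signal", "signal2")]
  expect_lt(abs(diff(s)), 1e-6)
  expect_lt(match("signal", imp2$feature), match("signal2", imp2$feature))
})

test_that("the significance screen keeps shifted features and drops null ones", {
  set.seed(6)
  n <- 200
  x <- data.frame(
    shifted = c(rnorm(n), rnorm(n, 3)),          # 3 SD mean shift
    null_feature = rnorm(2 * n),                 # same distribution
    constant = rep(1, 2 * n))
  y <- rep(c("A", "B"), each = n)
  scr <- significance_screen(x, y, alpha = 0.011)
  expect_true("shifted" %in% scr$selected)
  expect_false("null_feature" %in% scr$selected)
  expect_false("constant" %in% scr$selected)
  expect_equal(scr$p_values$p_value[scr$p_values$feature == "constant"], 1)
  # type-I calibration: about an alpha fraction of pure-noise features kept
  xn <- as.data.frame(matrix(rnorm(400 * 400), 400, 400))
  yn <- rep(c("A", "B"), each = 200)
  frac <- length(significance_screen(xn, yn, alpha = 0.011)$selected) / 400
  expect_lt(frac, 0.04)
})

test_that("experiment runs are reproducible and regimes restrict features", {
  fm <- toy_features(trials = 10, sep = 1.5, seed = 7)
  r1 <- run_experiment(fm, "ALL", n_runs = 2, k = 3, n_train = 4, n_eval = 2,
                       seed = 11)
  r2 <- run_experiment(fm, "ALL", n_runs = 2, k = 3, n_train = 4, n_eval = 2,
                       seed = 11)
  expect_identical(run_metric(r1, "accuracy"), run_metric(r2, "accuracy"))
  expect_identical(r1[[1]]$top_features, r2[[1]]$top_features)
  expect_error(run_experiment(fm, "MFF", n_runs = 1), "mff_features")
  rm <- run_experiment(fm, "MFF", n_runs = 2, k = 3, n_train = 4, n_eval = 2,
                       mff_features = c("f1", "f2"), seed = 11)
  expect_identical(rm[[1]]$features_used, c("f1", "f2"))
  rs <- run_experiment(fm, "SF", n_runs = 2, k = 3, n_train = 4, n_eval = 2,
                       seed = 11)
  expect_true(all(rs[[1]]$features_used %in% paste0("f", 1:5)))
})

test_that("most frequent features counts per-run top rankings with tie rules", {
  mk <- function(tops) structure(lapply(tops, function(t) list(top_features = t)),
                                 class = "run_results")
  res <- mk(list(c("a", "b", "c"), c("a", "c", "d"), c("a", "b", "d")))
  expect_identical(most_frequent_features(res, top_m = 1), "a")
  expect_identical(most_frequent_features(res, top_m = 2), c("a", "b"))
  # single run: its own top-m
  res1 <- mk(list(c("x", "y", "z")))
  expect_identical(most_frequent_features(res1, top_m = 3), c("x", "y", "z"))
  # ties on count break by total rank, then name
  res2 <- mk(list(c("b", "a"), c("a", "b")))
  expect_identical(most_frequent_features(res2, top_m = 2), c("a", "b"))
})

test_that("the relabel control is deterministic and errors on tiny classes", {
  fm <- toy_features(c(expert = 8), trials = 6, idio = 0.3, seed = 9)
  a1 <- relabel_control(fm, n_iter = 1, k = 2, seed = 5)
  a2 <- relabel_control(fm, n_iter = 1, k = 2, seed = 5)
  expect_identical(a1, a2)
  fm2 <- toy_features(c(expert = 3), trials = 6, seed = 9)
  expect_error(relabel_control(fm2), "participants")
})
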