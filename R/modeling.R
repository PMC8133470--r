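# per-run seeds derived deterministically from the master seed; kept well
# below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

#' Participant-wise train/eval assignment
#'
#' All trials of a participant land on exactly one side of the split: per
#' class, `n_train` participants are drawn for training and `n_eval` of the
#' remaining participants for the leave-out evaluation. This prevents the
#' classifier from exploiting participant idiosyncrasy as a biometric
#' shortcut.
#'
#' @param features a [feature_matrix()] data.frame.
#' @param n_train,n_eval participants per class on each side.
#' @param seed optional seed.
#' @return list with `train_pid`, `eval_pid` (character vectors) and the
#'   row indices `train_rows`, `eval_rows`.
#' @export
participant_wise_split <- function(features, n_train = 8, n_eval = 2,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train_pid <- character(0); eval_pid <- character(0)
  for (cl in sort(unique(features$class_label))) {
    pids <- unique(features$participant_id[features$class_label == cl])
    if (length(pids) < n_train + n_eval) {
      stop(sprintf("class %s has %d participants; %d needed",
                   cl, length(pids), n_train + n_eval))
    }
    tr <- sample(pids, n_train)
    ev <- sample(setdiff(pids, tr), n_eval)
    train_pid <- c(train_pid, tr)
    eval_pid <- c(eval_pid, ev)
  }
  stopifnot(length(intersect(train_pid, eval_pid)) == 0)
  list(train_pid = train_pid, eval_pid = eval_pid,
       train_rows = which(features$participant_id %in% train_pid),
       eval_rows = which(features$participant_id %in% eval_pid))
}

#' Sample-wise (leaky) train/eval assignment
#'
#' Assigns trials to train/eval at random, ignoring participant identity —
#' the assignment scheme the participant-wise protocol exists to avoid.
#' Provided for demonstrating idiosyncrasy leakage; the evaluation fraction
#' per class mirrors the participant-wise eval share.
#'
#' @param features a [feature_matrix()] data.frame.
#' @param eval_fraction fraction of each class's trials placed in the
#'   evaluation set.
#' @param seed optional seed.
#' @return list with `train_rows`, `eval_rows`.
#' @export
sample_wise_split <- function(features, eval_fraction = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eval_rows <- integer(0)
  for (cl in sort(unique(features$class_label))) {
    rows <- which(features$class_label == cl)
    eval_rows <- c(eval_rows, sample(rows, max(1, round(eval_fraction * length(rows)))))
  }
  list(train_pid = NULL, eval_pid = NULL,
       train_rows = setdiff(seq_len(nrow(features)), eval_rows),
       eval_rows = sort(eval_rows))
}

# stratified fold assignment; every fold contains every class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

#' Train a k-fold ensemble of linear SVMs
#'
#' The i-th model is trained on the out-of-fold data of fold i and its
#' cross-validation accuracy measured on the in-fold data; the final
#' ensemble predicts by averaging the k models' per-class scores (signed
#' one-vs-one margins) and taking the arg-max. Features are standardized
#' with training-set statistics only. `k = 1` reduces to a single fit on all
#' training rows.
#'
#' @param x numeric matrix (trials x features).
#' @param y class labels (coerced to factor).
#' @param k number of folds / models (default 50).
#' @param cost SVM regularization constant.
#' @return an object of class `gaze_ensemble` with elements `models`,
#'   `center`, `scale`, `levels`, `features`, `cv_accuracy`.
#' @export
train_ensemble <- function(x, y, k = 50, cost = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data must contain at least 2 classes")
  if (nrow(x) < k) stop("fewer training rows than folds")
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center, scl)
  cv_acc <- rep(NA_real_, k)
  if (k == 1) {
    models <- list(e1071::svm(xs, y, kernel = "linear", cost = cost,
                              scale = FALSE))
  } else {
    fold <- stratified_folds(y, k)
    models <- vector("list", k)
    for (i in seq_len(k)) {
      out_rows <- which(fold != i)
      m <- e1071::svm(xs[out_rows, , drop = FALSE], y[out_rows],
                      kernel = "linear", cost = cost, scale = FALSE)
      in_rows <- which(fold == i)
      if (length(in_rows)) {
        cv_acc[i] <- mean(predict(m, xs[in_rows, , drop = FALSE]) == y[in_rows])
      }
      models[[i]] <- m
    }
  }
  structure(list(models = models, center = center, scale = scl,
                 levels = levels(y), features = colnames(x),
                 cv_accuracy = cv_acc),
            class = "gaze_ensemble")
}

# Per-class score from one-vs-one decision values (positive favors the first
# class of each pair). Margins are clipped to [-1, 1]: raw margins are
# unbounded, and a point far from one pairwise boundary would otherwise
# credit an uninvolved class with an arbitrarily large score (a middle-class
# bias); clipped margins make the score a continuous soft vote.
ovo_class_scores <- function(model, xs, lev) {
  dv <- attr(predict(model, xs, decision.values = TRUE), "decision.values")
  dv <- pmin(pmax(dv, -1), 1)
  scores <- matrix(0, nrow(xs), length(lev), dimnames = list(NULL, lev))
  for (p in colnames(dv)) {
    pair <- strsplit(p, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, p]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, p]
  }
  scores
}

#' Predict with a trained ensemble
#'
#' @param object a `gaze_ensemble`.
#' @param newdata matrix or data.frame carrying the ensemble's feature
#'   columns.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.gaze_ensemble <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  xs <- scale(x, object$center, object$scale)
  total <- matrix(0, nrow(xs), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in object$models) {
    total <- total + ovo_class_scores(m, xs, object$levels)
  }
  factor(object$levels[max.col(total, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.gaze_ensemble <- function(x, ...) {
  cat(sprintf("<gaze_ensemble> %d linear SVM folds, %d features, classes: %s\n",
              length(x$models), length(x$features),
              paste(x$levels, collapse = ", ")))
  if (any(!is.na(x$cv_accuracy))) {
    cat(sprintf("  mean in-fold CV accuracy: %.3f\n",
                mean(x$cv_accuracy, na.rm = TRUE)))
  }
  invisible(x)
}

# reconstruct the primal weight vectors of every one-vs-one pair from a
# linear libsvm fit (SVs are grouped by class in model$labels order; for the
# pair (i, j), i < j, class-i SVs contribute through dual-coef column j - 1
# and class-j SVs through column i)
svm_pair_weights <- function(m) {
  k <- length(m$labels)
  lev <- m$levels[m$labels]
  starts <- cumsum(c(1, m$nSV))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ri <- starts[i]:(starts[i] + m$nSV[i] - 1)
      rj <- starts[j]:(starts[j] + m$nSV[j] - 1)
      w <- colSums(m$coefs[ri, j - 1, drop = FALSE][, 1] * m$SV[ri, , drop = FALSE]) +
        colSums(m$coefs[rj, i, drop = FALSE][, 1] * m$SV[rj, , drop = FALSE])
      pairs[[paste(lev[i], lev[j], sep = "/")]] <- w
    }
  }
  do.call(rbind, pairs)
}

#' Rank features by importance in a trained ensemble
#'
#' For the linear kernel, a feature's importance is its mean absolute primal
#' weight across all one-vs-one pairs of all k fold models. Ties are broken
#' by canonical feature-name order.
#'
#' @param ensemble a `gaze_ensemble`.
#' @return data.frame with `feature` and `importance`, sorted decreasing.
#' @export
feature_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "gaze_ensemble"))
  acc <- 0
  for (m in ensemble$models) {
    acc <- acc + colMeans(abs(svm_pair_weights(m)))
  }
  imp <- acc / length(ensemble$models)
  ord <- order(-imp, ensemble$features)
  data.frame(feature = ensemble$features[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Screen features by rank-sum significance
#'
#' For every feature, Mann-Whitney-U (Wilcoxon rank-sum) tests between each
#' pair of classes; the feature's combined p-value is the minimum over the
#' pairwise tests (configurable to a Kruskal-Wallis omnibus test). Features
#' with a combined p-value below `alpha` are kept. Constant features get
#' p = 1.
#'
#' @param x numeric matrix or data.frame of features.
#' @param y class labels.
#' @param alpha significance threshold (default 0.011).
#' @param combine `"min"` (default) or `"kruskal"`.
#' @return list with `selected` (feature names), `p_values` (data.frame).
#' @export
significance_screen <- function(x, y, alpha = 0.011,
                                combine = c("min", "kruskal")) {
  combine <- match.arg(combine)
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  p <- vapply(x, function(v) {
    if (length(unique(v)) <= 1) return(1)
    if (combine == "kruskal") {
      return(stats::kruskal.test(v, y)$p.value)
    }
    pmin <- 1
    lev <- levels(y)
    for (i in seq_len(nlevels(y) - 1)) {
      for (j in (i + 1):nlevels(y)) {
        pv <- suppressWarnings(
          wilcox.test(v[y == lev[i]], v[y == lev[j]], exact = FALSE)$p.value)
        if (!is.na(pv)) pmin <- min(pmin, pv)
      }
    }
    pmin
  }, numeric(1))
  tab <- data.frame(feature = names(p), p_value = unname(p),
                    selected = unname(p < alpha), stringsAsFactors = FALSE)
  list(selected = tab$feature[tab$selected], p_values = tab)
}

#' Evaluate an ensemble on a leave-out set
#'
#' @param ensemble a `gaze_ensemble` trained on the plan's training side.
#' @param features the full feature data.frame.
#' @param eval_rows row indices of the leave-out set.
#' @return a `run_result`: confusion matrix, accuracy, per-class miss rate
#'   and recall, plus the predicted/true labels.
#' @export
evaluate_leave_out <- function(ensemble, features, eval_rows) {
  if (length(eval_rows) == 0) stop("empty evaluation set")
  truth <- factor(features$class_label[eval_rows], levels = ensemble$levels)
  pred <- predict(ensemble, features[eval_rows, ])
  metrics <- confusion_and_metrics(truth, pred)
  structure(c(metrics, list(n_eval = length(eval_rows))),
            class = "run_result")
}

#' Run the resampled classification experiment
#'
#' For each run a fresh split is drawn (participant-wise by default), the
#' feature regime is applied, a k-fold SVM ensemble is trained on the
#' training side only, and leave-out metrics are recorded. Per-run seeds are
#' derived deterministically from the master seed.
#'
#' Regimes: `"ALL"` uses all 46 features; `"SF"` re-screens features on the
#' training side of every run ([significance_screen()]); `"MFF"` restricts
#' to a supplied most-frequent-feature subset (see
#' [most_frequent_features()]).
#'
#' @param features a [feature_matrix()] data.frame.
#' @param regime `"ALL"`, `"SF"` or `"MFF"`.
#' @param n_runs number of resampling runs (the reference protocol uses
#'   1000).
#' @param k folds per ensemble.
#' @param cost SVM regularization constant.
#' @param n_train,n_eval participants per class on each side.
#' @param split `"participant"` (default) or `"sample"` (leaky; for the
#'   idiosyncrasy demonstration).
#' @param alpha screen threshold for the SF regime.
#' @param top_m how many top-ranked features to record per run.
#' @param mff_features feature subset for the MFF regime.
#' @param seed master seed.
#' @return list of class `run_results`; each element carries the run's
#'   metrics and its `top_features` ranking.
#' @export
run_experiment <- function(features, regime = c("ALL", "SF", "MFF"),
                           n_runs = 1000, k = 50, cost = 1,
                           n_train = 8, n_eval = 2,
                           split = c("participant", "sample"),
                           alpha = 0.011, top_m = 7,
                           mff_features = NULL, seed = 1L) {
  regime <- match.arg(regime)
  split <- match.arg(split)
  if (regime == "MFF" && is.null(mff_features)) {
    stop("regime 'MFF' needs mff_features (see most_frequent_features())")
  }
  fn <- setdiff(names(features),
                c("trial_id", "participant_id", "class_label"))
  results <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, r))
    plan <- if (split == "participant") {
      participant_wise_split(features, n_train, n_eval)
    } else {
      sample_wise_split(features, n_eval / (n_train + n_eval))
    }
    use <- fn
    if (regime == "SF") {
      scr <- significance_screen(features[plan$train_rows, fn],
                                 features$class_label[plan$train_rows],
                                 alpha = alpha)
      use <- scr$selected
      if (length(use) < 2) use <- fn   # degenerate screen: fall back
    } else if (regime == "MFF") {
      use <- intersect(fn, mff_features)
    }
    ens <- train_ensemble(as.matrix(features[plan$train_rows, use]),
                          features$class_label[plan$train_rows],
                          k = k, cost = cost)
    res <- evaluate_leave_out(ens, features, plan$eval_rows)
    res$run <- r
    res$regime <- regime
    res$features_used <- use
    res$top_features <- head(feature_importance(ens)$feature, top_m)
    res$cv_accuracy <- mean(ens$cv_accuracy, na.rm = TRUE)
    results[[r]] <- res
  }
  structure(results, class = "run_results")
}

#' Most frequent top-ranked features across runs
#'
#' Counts how often each feature appears in the per-run top-`m` importance
#' rankings and returns the `m` most frequent (ties broken by total rank
#' score, then by name).
#'
#' @param results a `run_results` list whose elements carry `top_features`.
#' @param top_m subset size (default 7).
#' @return character vector of feature names.
#' @export
most_frequent_features <- function(results, top_m = 7) {
  tops <- lapply(results, `[[`, "top_features")
  all_feats <- unique(unlist(tops))
  count <- sapply(all_feats, function(f) sum(vapply(tops, function(t) f %in% t, logical(1))))
  # total rank score: lower is better; absent counts as top_m + 1
  rank_score <- sapply(all_feats, function(f) {
    sum(vapply(tops, function(t) {
      i <- match(f, t)
      if (is.na(i)) top_m + 1 else i
    }, numeric(1)))
  })
  ord <- order(-count, rank_score, all_feats)
  head(all_feats[ord], top_m)
}

#' Expert half-relabeling control
#'
#' Tests whether within-class gaze variation is smaller than between-class
#' differences: in each iteration half of the expert participants are
#' relabeled as a pseudo-class and a binary participant-wise classification
#' of expert vs relabeled is run. For a homogeneous expert class the mean
#' accuracy should sit at (or below) the 50% chance level; genuinely bimodal
#' experts are detectable above chance when `subgroups` supplies the true
#' split.
#'
#' @param features a [feature_matrix()] data.frame.
#' @param class_label the class to split (default `"expert"`).
#' @param n_iter iterations (default 100).
#' @param k folds per ensemble.
#' @param cost SVM regularization constant.
#' @param n_eval evaluation participants per pseudo-class.
#' @param subgroups optional character vector of participant ids forming the
#'   relabeled half; when `NULL` the half is drawn at random each iteration.
#' @param seed master seed.
#' @return numeric vector of leave-out accuracies, one per iteration.
#' @export
relabel_control <- function(features, class_label = "expert", n_iter = 100,
                            k = 5, cost = 1, n_eval = 1, subgroups = NULL,
                            seed = 1L) {
  sub <- features[features$class_label == class_label, ]
  pids <- unique(sub$participant_id)
  if (length(pids) < 4) stop("need at least 4 participants for the control")
  fn <- setdiff(names(sub), c("trial_id", "participant_id", "class_label"))
  acc <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(seed, it))
    relab <- if (is.null(subgroups)) {
      sample(pids, floor(length(pids) / 2))
    } else {
      subgroups
    }
    dat <- sub
    dat$class_label <- ifelse(dat$participant_id %in% relab,
                              "relabeled", class_label)
    n_a <- length(setdiff(pids, relab)); n_b <- length(relab)
    n_train <- min(n_a, n_b) - n_eval
    if (n_train < 1) stop("too few participants per pseudo-class")
    plan <- participant_wise_split(dat, n_train = n_train, n_eval = n_eval)
    ens <- train_ensemble(as.matrix(dat[plan$train_rows, fn]),
                          dat$class_label[plan$train_rows],
                          k = k, cost = cost)
    acc[it] <- evaluate_leave_out(ens, dat, plan$eval_rows)$accuracy
  }
  acc
}
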