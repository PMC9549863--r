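# Transition-aware scoring, one-vs-rest metrics, nested leave-one-subject-out
# cross-validation, pooled confusion matrices and impairment correlations.

#' Transition-aware correctness of a window prediction
#'
#' A non-transition window is correct iff the prediction equals its mapped
#' majority label. A transition window between adjoining classes A and B is
#' correct iff the prediction equals (the task mapping of) either A or B —
#' the transition's direction is not encoded, so both ends count.
#'
#' @param window one row of a `labeled_windows` data frame.
#' @param predicted predicted task class.
#' @param task `"gait"` or `"gait_posture"`.
#' @return Logical.
#' @export
transition_aware_correct <- function(window, predicted,
                                     task = c("gait", "gait_posture")) {
  task <- match.arg(task)
  if (window$is_transition) {
    predicted %in% map_task_labels(c(window$pair_a, window$pair_b), task)
  } else {
    predicted == map_task_labels(window$majority_label, task)
  }
}

# vectorized correctness over a labeled_windows frame
scoring_correct <- function(windows, predictions, task) {
  correct <- logical(nrow(windows))
  tr <- windows$is_transition
  if (any(!tr))
    correct[!tr] <- predictions[!tr] ==
      map_task_labels(windows$majority_label[!tr], task)
  if (any(tr))
    correct[tr] <- predictions[tr] == map_task_labels(windows$pair_a[tr], task) |
      predictions[tr] == map_task_labels(windows$pair_b[tr], task)
  correct
}

# confusion-matrix truth assignment: non-transition windows use their mapped
# label; correctly scored transition windows are credited to the predicted
# class; incorrect ones to the first adjoining class (pair order fixed by the
# transition class name).
scoring_truth <- function(windows, predictions, correct, task) {
  truth <- character(nrow(windows))
  tr <- windows$is_transition
  truth[!tr] <- map_task_labels(windows$majority_label[!tr], task)
  truth[tr & correct] <- predictions[tr & correct]
  truth[tr & !correct] <- map_task_labels(windows$pair_a[tr & !correct], task)
  truth
}

#' Per-fold classification metrics
#'
#' One-vs-rest sensitivity, specificity and positive predictive value per
#' class, overall accuracy (fraction of transition-aware-correct windows),
#' per-class balanced accuracy `(sensitivity + specificity) / 2`, and overall
#' balanced accuracy as the unweighted mean of per-class balanced accuracies
#' (which reduces to `(sens + spec) / 2` of the positive class for a binary
#' task). All rates in percent. Transition windows are scored by the
#' either-adjoining-class rule and credited to the predicted class in the
#' confusion matrix when correct.
#'
#' @param windows `labeled_windows` data frame of the evaluated windows.
#' @param predictions character vector of predicted task classes.
#' @param task `"gait"` or `"gait_posture"`.
#' @return List with `per_class` (data frame), `accuracy`,
#'   `balanced_accuracy`, `confusion` (true class x predicted class counts)
#'   and `n_windows`.
#' @export
compute_metrics <- function(windows, predictions,
                            task = c("gait", "gait_posture")) {
  task <- match.arg(task)
  stopifnot(nrow(windows) == length(predictions))
  classes <- task_classes(task)
  stopifnot(all(predictions %in% classes))
  correct <- scoring_correct(windows, predictions, task)
  truth <- scoring_truth(windows, predictions, correct, task)
  confusion <- table(factor(truth, levels = classes),
                     factor(predictions, levels = classes))
  confusion <- unclass(confusion)
  total <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, 100 * tn / (tn + fp), NA_real_)
  ppv <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  balanced <- (sens + spec) / 2
  absent <- rowSums(confusion) == 0
  if (any(absent))
    warning("class absent from truth, excluded from aggregation: ",
            paste(classes[absent], collapse = ", "))
  list(per_class = data.frame(class = classes, sensitivity = sens,
                              specificity = spec, ppv = ppv,
                              balanced_accuracy = balanced,
                              row.names = NULL),
       accuracy = 100 * mean(correct),
       balanced_accuracy = mean(balanced[!absent], na.rm = TRUE),
       confusion = confusion,
       n_windows = nrow(windows))
}

# ---- dataset preparation ----------------------------------------------------

#' Prepare a windowed, standardized dataset from sessions
#'
#' Runs preprocessing, windowing and feature extraction for every session
#' under one sensor configuration and standardizes features per subject.
#'
#' @param sessions list of [recording_session()] objects.
#' @param config_id sensor configuration `"A"`..`"E"`.
#' @param params filter constants.
#' @return List with `features` (n x d standardized matrix), `windows`
#'   (stacked `labeled_windows`), `subjects`, `config_id`.
#' @export
prepare_dataset <- function(sessions, config_id = "A",
                            params = preprocess_defaults()) {
  wd <- window_defaults()
  win_list <- lapply(sessions, function(s)
    label_windows(s$label_track, s$subject_id, wd$length, wd$hop))
  fms <- mapply(function(s, w) extract_features(s, config_id, w, params),
                sessions, win_list, SIMPLIFY = FALSE)
  fm <- bind_features(fms)
  std <- standardize_per_subject(fm)
  windows <- do.call(rbind, win_list)
  class(windows) <- c("labeled_windows", "data.frame")
  list(features = std$matrix$values, windows = windows,
       subjects = vapply(sessions, `[[`, character(1), "subject_id"),
       config_id = config_id)
}

#' Permute window labels within each subject
#'
#' Destroys the label-feature association while preserving each subject's
#' label distribution; used for permutation-null checks of the evaluation
#' protocol.
#'
#' @param dataset a [prepare_dataset()] result.
#' @param seed RNG seed.
#' @return The dataset with permuted window labels (transition flags and
#'   adjoining pairs recomputed).
#' @export
permute_dataset_labels <- function(dataset, seed) {
  set.seed(seed)
  w <- dataset$windows
  for (s in unique(w$subject_id)) {
    rows <- which(w$subject_id == s)
    w$majority_label[rows] <- w$majority_label[sample(rows)]
  }
  w$is_transition <- w$majority_label %in% transition_classes()
  w$pair_a <- w$pair_b <- NA_character_
  if (any(w$is_transition)) {
    pairs <- vapply(w$majority_label[w$is_transition], transition_pair,
                    character(2))
    w$pair_a[w$is_transition] <- pairs[1, ]
    w$pair_b[w$is_transition] <- pairs[2, ]
  }
  dataset$windows <- w
  dataset
}

# ---- nested leave-one-subject-out -------------------------------------------

fit_on_subjects <- function(dataset, subjects, model_kind, params, task,
                            forbidden_subject = NULL) {
  rows <- which(dataset$windows$subject_id %in% subjects &
                  !dataset$windows$is_transition)
  if (!is.null(forbidden_subject) &&
      any(dataset$windows$subject_id[rows] == forbidden_subject))
    stop("leakage: held-out subject present in training rows")  # nocov
  y <- map_task_labels(dataset$windows$majority_label[rows], task)
  fit_classifier(model_kind, params, dataset$features[rows, , drop = FALSE],
                 y, class_set = task_classes(task))
}

predict_subject <- function(model, dataset, subject) {
  rows <- which(dataset$windows$subject_id == subject)
  list(rows = rows,
       windows = dataset$windows[rows, , drop = FALSE],
       predictions = predict(model,
                             dataset$features[rows, , drop = FALSE]))
}

#' Inner-loop hyperparameter selection
#'
#' Leave-one-subject-out over the outer training subjects: every grid point
#' is fitted on each inner training set (transitions removed) and scored by
#' balanced accuracy on the inner test subject (transitions included); the
#' point with the highest unweighted mean balanced accuracy across inner
#' folds wins, ties resolving to the earliest point in declared grid order.
#' A single-point grid is returned directly without fitting.
#'
#' @param dataset a [prepare_dataset()] result.
#' @param subjects outer-training subject ids (>= 2).
#' @param model_kind,grid classifier and its grid.
#' @param task classification task.
#' @return List with `params` (selected row, as a list) and `index` in the
#'   grid.
#' @export
inner_select <- function(dataset, subjects, model_kind, grid,
                         task = c("gait", "gait_posture")) {
  task <- match.arg(task)
  if (length(subjects) < 2) stop("inner selection needs >= 2 subjects")
  if (nrow(grid) == 1)
    return(list(params = as.list(grid[1, , drop = FALSE]), index = 1L))
  scores <- matrix(NA_real_, nrow(grid), length(subjects))
  for (j in seq_along(subjects)) {
    inner_test <- subjects[j]
    inner_train <- setdiff(subjects, inner_test)
    for (g in seq_len(nrow(grid))) {
      model <- fit_on_subjects(dataset, inner_train, model_kind,
                               as.list(grid[g, , drop = FALSE]), task,
                               forbidden_subject = inner_test)
      pred <- predict_subject(model, dataset, inner_test)
      scores[g, j] <- compute_metrics(pred$windows, pred$predictions,
                                      task)$balanced_accuracy
    }
  }
  mean_scores <- rowMeans(scores)
  best <- which.max(mean_scores)   # first maximum = earliest grid point
  list(params = as.list(grid[best, , drop = FALSE]), index = best,
       mean_scores = mean_scores)
}

#' Nested leave-one-subject-out evaluation
#'
#' Outer loop: each subject in turn is held out; the inner loop selects
#' hyperparameters by leave-one-subject-out over the remaining subjects; the
#' winning configuration is refitted on the whole outer training set
#' (transition windows removed) and scored on the held-out subject with
#' transition windows included. No window of the held-out subject enters any
#' fit (asserted at run time). Aggregates are unweighted means and SDs
#' across folds.
#'
#' @param sessions list of [recording_session()] objects (>= 3), or `NULL`
#'   if `dataset` is supplied.
#' @param task `"gait"` or `"gait_posture"`.
#' @param config_id sensor configuration `"A"`..`"E"`.
#' @param model_kind `"svm"`, `"lr"` or `"knn"`.
#' @param grid hyperparameter grid (default: the model's full grid).
#' @param dataset optionally a precomputed [prepare_dataset()] result (e.g.
#'   to reuse one extraction across tasks).
#' @return An object of class `evaluation_report`: task/config/model,
#'   per-fold results, aggregate mean/SD table, pooled row-normalized
#'   confusion matrix (%).
#' @export
nested_loso <- function(sessions = NULL, task = c("gait", "gait_posture"),
                        config_id = "A", model_kind = "svm", grid = NULL,
                        dataset = NULL) {
  task <- match.arg(task)
  if (is.null(grid)) grid <- hyperparameter_grid(model_kind)
  if (is.null(dataset)) dataset <- prepare_dataset(sessions, config_id)
  subjects <- unique(dataset$windows$subject_id)
  if (length(subjects) < 3) stop("nested LOSO needs >= 3 subjects")
  folds <- list()
  for (held_out in subjects) {
    outer_train <- setdiff(subjects, held_out)
    sel <- inner_select(dataset, outer_train, model_kind, grid, task)
    model <- fit_on_subjects(dataset, outer_train, model_kind, sel$params,
                             task, forbidden_subject = held_out)
    pred <- predict_subject(model, dataset, held_out)
    m <- withCallingHandlers(
      compute_metrics(pred$windows, pred$predictions, task),
      warning = function(w) invokeRestart("muffleWarning"))
    folds[[held_out]] <- list(held_out_subject = held_out,
                              selected_params = sel$params,
                              metrics = m,
                              predictions = pred$predictions,
                              window_rows = pred$rows)
  }
  fold_val <- function(f, what) f$metrics[[what]]
  acc <- vapply(folds, fold_val, numeric(1), "accuracy")
  bal <- vapply(folds, fold_val, numeric(1), "balanced_accuracy")
  aggregate <- data.frame(
    metric = c("accuracy", "balanced_accuracy"),
    mean = c(mean(acc), mean(bal)),
    sd = c(stats::sd(acc), stats::sd(bal)))
  structure(list(task = task, config_id = dataset$config_id,
                 model_kind = model_kind, folds = folds,
                 aggregate = aggregate,
                 pooled_confusion = pooled_confusion(folds)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> task=%s config=%s model=%s (%d folds)\n",
              x$task, x$config_id, x$model_kind, length(x$folds)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: %.1f%% (SD %.1f)\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  invisible(x)
}

#' Pooled row-normalized confusion matrix
#'
#' Sums confusion counts across folds, then normalizes each true-class row
#' to 100%. Rows with no windows are reported as `NA`, not 0.
#'
#' @param fold_results list of fold results from [nested_loso()] (or any
#'   list of elements carrying `metrics$confusion`).
#' @return Class x class matrix of percentages.
#' @export
pooled_confusion <- function(fold_results) {
  stopifnot(length(fold_results) >= 1)
  get_conf <- function(f) if (!is.null(f$metrics)) f$metrics$confusion else f$confusion
  total <- Reduce(`+`, lapply(fold_results, get_conf))
  rs <- rowSums(total)
  out <- 100 * total / ifelse(rs > 0, rs, NA_real_)
  out[rs == 0, ] <- NA_real_
  out
}

#' Null band of balanced accuracy under per-subject label permutation
#'
#' Repeatedly permutes the evaluated windows' labels within each subject and
#' recomputes balanced accuracy against fixed predictions, returning the
#' central interval of the permutation distribution.
#'
#' @param windows `labeled_windows` of the evaluated windows.
#' @param predictions fixed predicted task classes.
#' @param task classification task.
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed.
#' @param level central coverage (default 0.95).
#' @return Named vector `lower`/`upper` (percent) plus the permutation
#'   scores as an attribute.
#' @export
permutation_band <- function(windows, predictions, task, n_perm = 200,
                             seed = 1, level = 0.95) {
  set.seed(seed)
  scores <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    w <- windows
    for (s in unique(w$subject_id)) {
      rows <- which(w$subject_id == s)
      perm <- sample(rows)
      w$majority_label[rows] <- w$majority_label[perm]
      w$is_transition[rows] <- w$is_transition[perm]
      w$pair_a[rows] <- w$pair_a[perm]
      w$pair_b[rows] <- w$pair_b[perm]
    }
    m <- withCallingHandlers(compute_metrics(w, predictions, task),
                             warning = function(x) invokeRestart("muffleWarning"))
    scores[b] <- m$balanced_accuracy
  }
  alpha <- (1 - level) / 2
  band <- stats::quantile(scores, c(alpha, 1 - alpha), names = FALSE)
  structure(c(lower = band[1], upper = band[2]), scores = scores)
}

#' Correlate classification performance with clinical impairment
#'
#' Chooses Pearson correlation when both variables pass the Shapiro-Wilk
#' normality test at alpha = 0.05, Spearman otherwise; returns the
#' coefficient and a two-sided p-value. No multiple-testing correction is
#' applied.
#'
#' @param per_subject_scores numeric vector (e.g. per-fold balanced
#'   accuracies).
#' @param clinical_values paired numeric vector of a clinical score.
#' @return List with `coefficient`, `p_value`, `method`.
#' @export
correlate_performance_impairment <- function(per_subject_scores,
                                             clinical_values) {
  stopifnot(length(per_subject_scores) == length(clinical_values))
  if (length(per_subject_scores) < 3) stop("need at least 3 paired values")
  if (anyNA(per_subject_scores) || anyNA(clinical_values))
    stop("missing values not allowed")
  if (stats::sd(per_subject_scores) == 0 || stats::sd(clinical_values) == 0)
    stop("zero variance in one of the variables")
  normal <- stats::shapiro.test(per_subject_scores)$p.value > 0.05 &&
    stats::shapiro.test(clinical_values)$p.value > 0.05
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(per_subject_scores, clinical_values,
                                         method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       method = method)
}
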