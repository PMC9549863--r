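test_that("transition windows are scored correct when either adjoining class is predicted", {
  w <- windows_from_labels(c("trans_sit_stand", "walking"))
  expect_true(transition_aware_correct(w[1, ], "sitting", "gait_posture"))
  expect_true(transition_aware_correct(w[1, ], "standing", "gait_posture"))
  expect_false(transition_aware_correct(w[1, ], "walking", "gait_posture"))
  expect_false(transition_aware_correct(w[2, ], "standing", "gait_posture"))
  expect_true(transition_aware_correct(w[2, ], "walking", "gait_posture"))
  # under the gait task the sit/stand pair maps to (no_gait, no_gait)
  expect_true(transition_aware_correct(w[1, ], "no_gait", "gait"))
  expect_false(transition_aware_correct(w[1, ], "gait", "gait"))
  # ... and the stand/walk pair to (no_gait, gait): any prediction counts
  w2 <- windows_from_labels("trans_stand_walk")
  expect_true(transition_aware_correct(w2[1, ], "gait", "gait"))
  expect_true(transition_aware_correct(w2[1, ], "no_gait", "gait"))
})

test_that("metric formulas reproduce the definitional confusion-table rates", {
  # TP=9 FN=1 TN=8 FP=2 on the binary gait task ("gait" = positive class)
  truth <- c(rep("walking", 10), rep("sitting", 10))
  pred <- c(rep("gait", 9), "no_gait", rep("no_gait", 8), rep("gait", 2))
  m <- compute_metrics(windows_from_labels(truth), pred, "gait")
  g <- m$per_class[m$per_class$class == "gait", ]
  oracle <- oracle_binary_rates(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(g$sensitivity, oracle[["sens"]])   # 90
  expect_equal(g$specificity, oracle[["spec"]])   # 80
  expect_equal(g$balanced_accuracy, oracle[["bal"]])  # 85
  expect_equal(g$ppv, oracle[["ppv"]], tolerance = 1e-6)  # 81.82
  expect_equal(m$accuracy, 100 * 17 / 20)
  # binary macro mean equals the positive-class (sens+spec)/2
  expect_equal(m$balanced_accuracy, 85)
})

test_that("perfect and constant predictions bound the balanced accuracy", {
  truth <- rep(c("walking", "sitting"), each = 6)
  perfect <- map_task_labels(truth, "gait")
  m1 <- compute_metrics(windows_from_labels(truth), perfect, "gait")
  expect_equal(m1$accuracy, 100)
  expect_equal(m1$balanced_accuracy, 100)
  expect_true(all(m1$per_class$sensitivity == 100))
  m2 <- compute_metrics(windows_from_labels(truth),
                        rep("gait", 12), "gait")
  expect_equal(m2$balanced_accuracy, 50)
})

test_that("metrics agree with a brute-force confusion evaluation on random cases", {
  set.seed(31)
  for (case in 1:200) {
    n <- sample(10:60, 1)
    truth <- sample(c("lying", "sitting", "standing", "walking", "stairs",
                      "trans_sit_stand", "trans_stand_walk"),
                    n, replace = TRUE)
    pred <- sample(task_classes("gait_posture"), n, replace = TRUE)
    w <- windows_from_labels(truth)
    m <- suppressWarnings(compute_metrics(w, pred, "gait_posture"))
    # brute force: per-window correctness by the A-or-B rule
    correct <- vapply(seq_len(n), function(i)
      transition_aware_correct(w[i, ], pred[i], "gait_posture"), logical(1))
    expect_equal(m$accuracy, 100 * mean(correct))
    # brute-force confusion with the documented crediting convention
    classes <- task_classes("gait_posture")
    conf <- matrix(0, 5, 5, dimnames = list(classes, classes))
    for (i in seq_len(n)) {
      tr_cls <- if (!w$is_transition[i]) w$majority_label[i]
        else if (correct[i]) pred[i] else w$pair_a[i]
      conf[tr_cls, pred[i]] <- conf[tr_cls, pred[i]] + 1
    }
    expect_equal(unname(m$confusion), unname(conf))
    expect_equal(sum(m$confusion), n)
  }
})

test_that("pooled confusion normalizes summed counts row-wise to 100%", {
  c1 <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(c("gait", "no_gait"), c("gait", "no_gait")))
  c2 <- matrix(c(2, 0, 3, 7), 2, 2, byrow = TRUE,
               dimnames = dimnames(c1))
  pooled <- pooled_confusion(list(list(confusion = c1), list(confusion = c2)))
  expect_equal(pooled["gait", "gait"], 100 * 10 / 12)
  expect_equal(pooled["no_gait", "no_gait"], 100 * 16 / 20)
  expect_true(all(abs(rowSums(pooled) - 100) < 0.1))
  # an empty true-class row is undefined, not zero
  c3 <- matrix(c(0, 0, 1, 4), 2, 2, byrow = TRUE, dimnames = dimnames(c1))
  pooled3 <- pooled_confusion(list(list(confusion = c3)))
  expect_true(all(is.na(pooled3["gait", ])))
})

test_that("inner selection returns single points directly and breaks ties by grid order", {
  ds <- prepare_dataset(tiny_cohort(3, session_s = 120), "E")
  one <- hyperparameter_grid("svm", reduced = TRUE)
  sel <- inner_select(ds, unique(ds$windows$subject_id)[1:2], "svm", one, "gait")
  expect_equal(sel$index, 1L)
  expect_equal(sel$params$C, 0.01)
  # duplicate-entry grid forces an exact tie -> first point wins
  dup <- data.frame(n = c(4, 4), weights = c("uniform", "uniform"))
  sel2 <- inner_select(ds, unique(ds$windows$subject_id), "knn", dup, "gait")
  expect_equal(sel2$index, 1L)
  expect_equal(sel2$mean_scores[1], sel2$mean_scores[2])
  expect_error(inner_select(ds, "S01", "svm", hyperparameter_grid("svm"), "gait"),
               ">= 2 subjects")
})

test_that("nested LOSO refuses leakage and is deterministic", {
  ds <- prepare_dataset(tiny_cohort(3, session_s = 120), "E")
  subj <- unique(ds$windows$subject_id)
  expect_error(
    imugait:::fit_on_subjects(ds, subj, "svm", list(C = 0.01), "gait",
                              forbidden_subject = subj[1]),
    "leakage")
  grid <- hyperparameter_grid("knn", reduced = TRUE)
  r1 <- nested_loso(task = "gait", model_kind = "knn", grid = grid, dataset = ds)
  r2 <- nested_loso(task = "gait", model_kind = "knn", grid = grid, dataset = ds)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_identical(r1$pooled_confusion, r2$pooled_confusion)
  expect_length(r1$folds, 3)
  # confusion row sums equal each subject's evaluated window count
  for (f in r1$folds) {
    n_subj <- sum(ds$windows$subject_id == f$held_out_subject)
    expect_equal(sum(f$metrics$confusion), n_subj)
  }
})

test_that("separable synthetic subjects reach perfect fold scores", {
  # well-separated cohort: strong gait oscillation vs static postures
  # (C = 1 from the declared grid; small cohorts need less regularization)
  ds <- prepare_dataset(tiny_cohort(3, seed = 5, session_s = 150), "A")
  r <- nested_loso(task = "gait", model_kind = "svm",
                   grid = data.frame(C = 1), dataset = ds)
  for (f in r$folds) expect_gte(f$metrics$balanced_accuracy, 99)
})

test_that("normality-gated correlation picks the right method", {
  # strictly monotone, heavy-tailed scores -> Spearman, rho = 1
  x <- c(1, 2, 4, 8, 16, 32, 64, 1000, 1e4, 1e5)
  y <- seq_along(x)
  r <- correlate_performance_impairment(x, y)
  expect_identical(r$method, "spearman")
  expect_equal(r$coefficient, 1)
  # bivariate normal with correlation 0.8 -> Pearson near 0.8
  set.seed(8)
  n <- 200
  a <- stats::rnorm(n)
  b <- 0.8 * a + sqrt(1 - 0.64) * stats::rnorm(n)
  r2 <- correlate_performance_impairment(a, b)
  expect_identical(r2$method, "pearson")
  expect_lt(abs(r2$coefficient - 0.8), 0.1)
  expect_error(correlate_performance_impairment(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(correlate_performance_impairment(c(1, 2), c(1, 2)), "3")
})
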