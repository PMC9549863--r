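# Classifier wrappers: RBF support vector machine, elastic-net logistic
# regression, and k-nearest neighbours, each with its cross-validated
# hyperparameter grid and class-balanced weighting where applicable.

#' Hyperparameter search grids
#'
#' The per-model grids explored by the inner cross-validation loop:
#' SVM — cost `C` in \{0.01, 0.1, 1, 10\}, radial-basis kernel,
#' class-balanced weighting (4 points); logistic regression — `C` in
#' \{0.001, 0.01, 0.1\} crossed with `l1_ratio` in \{0.01, 0.1\},
#' elastic-net penalty, intercept, class-balanced weighting (6 points);
#' kNN — `n` in \{1, 2, 4, 8, 12, 16, 20, 24, 28, 32\} crossed with
#' uniform/distance vote weighting (20 points).
#'
#' @param model_kind `"svm"`, `"lr"` or `"knn"`.
#' @param reduced if `TRUE`, keep only the first entry of every parameter
#'   list (a single grid point, for quick runs).
#' @return Data frame with one row per grid point, in declared order.
#' @export
hyperparameter_grid <- function(model_kind = c("svm", "lr", "knn"),
                                reduced = FALSE) {
  model_kind <- match.arg(model_kind)
  g <- switch(model_kind,
    svm = data.frame(C = c(0.01, 0.1, 1, 10)),
    lr = {
      e <- expand.grid(l1_ratio = c(0.01, 0.1), C = c(0.001, 0.01, 0.1))
      data.frame(C = e$C, l1_ratio = e$l1_ratio)
    },
    knn = {
      e <- expand.grid(weights = c("uniform", "distance"),
                       n = c(1, 2, 4, 8, 12, 16, 20, 24, 28, 32),
                       stringsAsFactors = FALSE)
      data.frame(n = e$n, weights = e$weights, stringsAsFactors = FALSE)
    })
  if (reduced) g <- g[1, , drop = FALSE]
  attr(g, "model_kind") <- model_kind
  g
}

balanced_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

check_grid_point <- function(params, model_kind) {
  grid <- hyperparameter_grid(model_kind)
  for (i in seq_len(nrow(grid))) {
    ok <- TRUE
    for (nm in names(grid)) {
      gv <- grid[[nm]][i]; pv <- params[[nm]]
      ok <- !is.null(pv) && if (is.numeric(gv)) {
        isTRUE(all.equal(gv, as.numeric(pv)))
      } else identical(as.character(gv), as.character(pv))
      if (!ok) break
    }
    if (ok) return(invisible(TRUE))
  }
  stop("hyperparameters outside the declared grid")
}

#' Fit a classifier at one grid point
#'
#' Class-balanced weighting (weights proportional to inverse class
#' frequency, `n / (k * n_c)`) is applied for the SVM and logistic
#' regression. Feature matrices are expected to be standardized already; no
#' internal rescaling is performed.
#'
#' @param model_kind `"svm"`, `"lr"` or `"knn"`.
#' @param params one-row data frame or named list, a point of
#'   [hyperparameter_grid()].
#' @param X numeric matrix of standardized features (rows = windows).
#' @param y character vector of task labels (transition windows must be
#'   excluded).
#' @param class_set label set of the task, fixing class order.
#' @return An object of class `imugait_model` with a [predict] method
#'   returning class labels.
#' @export
fit_classifier <- function(model_kind = c("svm", "lr", "knn"), params, X, y,
                           class_set = sort(unique(y))) {
  model_kind <- match.arg(model_kind)
  params <- as.list(params)
  check_grid_point(params, model_kind)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2)
    stop("single-class training labels; cannot fit a classifier")
  if (nrow(X) < length(class_set)) stop("fewer rows than classes")
  yf <- factor(y, levels = class_set)
  fit <- switch(model_kind,
    svm = {
      w <- balanced_class_weights(yf)
      e1071::svm(x = X, y = yf, kernel = "radial", cost = params$C,
                 class.weights = w, scale = FALSE, cachesize = 256)
    },
    lr = {
      cw <- balanced_class_weights(yf)
      obs_w <- as.numeric(cw[as.character(yf)])
      fam <- if (length(class_set) == 2) "binomial" else "multinomial"
      lam <- 1 / (params$C * nrow(X))
      glmnet::glmnet(X, yf, family = fam, weights = obs_w,
                     alpha = params$l1_ratio, lambda = lam,
                     standardize = FALSE, intercept = TRUE)
    },
    knn = list(X = X, y = as.character(yf), k = params$n,
               weights = as.character(params$weights)))
  structure(list(model_kind = model_kind, params = params, fit = fit,
                 class_set = class_set),
            class = "imugait_model")
}

knn_predict <- function(model, newX) {
  Xtr <- model$fit$X
  d2 <- outer(rowSums(newX^2), rep(1, nrow(Xtr))) +
    outer(rep(1, nrow(newX)), rowSums(Xtr^2)) -
    2 * tcrossprod(newX, Xtr)
  d2[d2 < 0] <- 0
  k <- min(model$fit$k, nrow(Xtr))
  ytr <- model$fit$y
  classes <- model$class_set
  apply(d2, 1, function(drow) {
    nn <- order(drow)[seq_len(k)]
    w <- if (model$fit$weights == "distance") {
      1 / pmax(sqrt(drow[nn]), 1e-12)
    } else rep(1, k)
    votes <- vapply(classes, function(cl) sum(w[ytr[nn] == cl]), numeric(1))
    classes[which.max(votes)]   # ties -> first class in declared order
  })
}

#' @export
predict.imugait_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- switch(object$model_kind,
    svm = as.character(stats::predict(object$fit, newdata)),
    lr = {
      p <- stats::predict(object$fit, newx = newdata, type = "class",
                          s = object$fit$lambda[1])
      as.character(p[, 1])
    },
    knn = knn_predict(object, newdata))
  unname(out)
}
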