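# Sliding-window segmentation, majority labels, task label mapping and the
# transition-aware train/eval split.

#' Default windowing constants
#' @return List with `length` (samples per window) and `hop` (stride).
#' @export
window_defaults <- function() list(length = 128L, hop = 64L)

#' Sliding-window start indices
#'
#' Half-open, 0-based windows `[start, start + window)`; the trailing partial
#' window is discarded.
#'
#' @param n_samples number of samples available.
#' @param window window length in samples (default 128).
#' @param hop stride between window starts (default 64, i.e. 50% overlap).
#' @return Integer vector of start indices (possibly empty).
#' @export
segment <- function(n_samples, window = 128L, hop = 64L) {
  stopifnot(window > 0, hop > 0, hop <= window)
  if (n_samples < window) return(integer(0))
  as.integer(seq.int(0L, n_samples - window, by = hop))
}

#' Majority label of a window
#'
#' Returns the modal label; ties are broken towards the label whose first
#' occurrence in the window is earliest (deterministic and order-stable).
#'
#' @param window_labels character vector of per-sample labels.
#' @return Single label string.
#' @export
majority_label <- function(window_labels) {
  if (length(window_labels) == 0) stop("empty window")
  # factor levels in order of first occurrence => which.max's first-winner
  # tie-break is exactly the earliest-first-occurrence rule
  counts <- table(factor(window_labels, levels = unique(window_labels)))
  names(counts)[which.max(counts)]
}

#' Map an 8-class label into a classification task's label set
#'
#' The binary `gait` task aggregates walking and stair walking into "gait"
#' and the three postures into "no_gait"; the 5-class `gait_posture` task
#' keeps the activity classes. Transition labels keep their transition status
#' in both tasks; their adjoining pair is mapped through the same function.
#'
#' @param label a label from [label_vocabulary()].
#' @param task `"gait"` or `"gait_posture"`.
#' @return The task-level label (transition labels map to themselves).
#' @export
map_task_labels <- function(label, task = c("gait", "gait_posture")) {
  task <- match.arg(task)
  vocab <- label_vocabulary()
  if (!all(label %in% vocab)) stop("unknown label: ",
                                   paste(setdiff(label, vocab), collapse = ", "))
  if (task == "gait_posture") return(label)
  out <- label
  out[label %in% c("walking", "stairs")] <- "gait"
  out[label %in% c("lying", "sitting", "standing")] <- "no_gait"
  out
}

#' Class set of a task
#' @param task `"gait"` or `"gait_posture"`.
#' @return Character vector of the task's (non-transition) classes.
#' @export
task_classes <- function(task = c("gait", "gait_posture")) {
  task <- match.arg(task)
  if (task == "gait") c("gait", "no_gait") else activity_classes()
}

#' Segment a labeled session into majority-labeled windows
#'
#' @param labels per-sample label vector (or a [label_track()]).
#' @param subject_id subject the windows belong to.
#' @param window,hop windowing constants, see [window_defaults()].
#' @return Data frame of class `labeled_windows` with columns `start`
#'   (0-based), `length`, `majority_label`, `is_transition`, `pair_a`,
#'   `pair_b` (adjoining classes, `NA` for non-transition windows) and
#'   `subject_id`.
#' @export
label_windows <- function(labels, subject_id, window = 128L, hop = 64L) {
  if (inherits(labels, "label_track")) labels <- labels$labels
  starts <- segment(length(labels), window, hop)
  maj <- vapply(starts,
                function(s) majority_label(labels[(s + 1):(s + window)]),
                character(1))
  is_tr <- maj %in% transition_classes()
  pair_a <- pair_b <- rep(NA_character_, length(maj))
  if (any(is_tr)) {
    pairs <- vapply(maj[is_tr], transition_pair, character(2))
    pair_a[is_tr] <- pairs[1, ]
    pair_b[is_tr] <- pairs[2, ]
  }
  out <- data.frame(start = starts, length = window, majority_label = maj,
                    is_transition = is_tr, pair_a = pair_a, pair_b = pair_b,
                    subject_id = subject_id, stringsAsFactors = FALSE)
  class(out) <- c("labeled_windows", "data.frame")
  out
}

#' Split windows into training and evaluation sets
#'
#' Transition windows are removed from the training set but kept in the
#' evaluation set, so that models are trained on unambiguous windows yet
#' scored on everything a free-living recording contains.
#'
#' @param windows a `labeled_windows` data frame.
#' @return List with elements `train` (non-transition windows) and `eval`
#'   (all windows), both order-preserving.
#' @export
split_train_eval <- function(windows) {
  train <- windows[!windows$is_transition, , drop = FALSE]
  if (nrow(train) == 0) stop("no trainable windows: all windows are transitions")
  list(train = train, eval = windows)
}
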