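# Small in-code fixtures shared across test files.

# a tiny deterministic session with all five sensors
tiny_session <- function(subject_id = "T01", seconds = 30, seed = 42) {
  script <- activity_script(c("sitting", "standing"),
                            c(seconds / 2, seconds / 2))
  generate_session(subject_profile(subject_id), script, seed = seed)
}

# a small cohort with short sessions, for evaluation-protocol tests
tiny_cohort <- function(n = 3, seed = 11, session_s = 150) {
  default_cohort(n, seed = seed, session_s = session_s)
}

# windows data frame built directly from labels (one label per window)
windows_from_labels <- function(labels, subject_id = "S1") {
  is_tr <- labels %in% transition_classes()
  pair_a <- pair_b <- rep(NA_character_, length(labels))
  if (any(is_tr)) {
    pairs <- vapply(labels[is_tr], transition_pair, character(2))
    pair_a[is_tr] <- pairs[1, ]
    pair_b[is_tr] <- pairs[2, ]
  }
  out <- data.frame(start = seq_along(labels) - 1L,
                    length = rep(128L, length(labels)),
                    majority_label = labels, is_transition = is_tr,
                    pair_a = pair_a, pair_b = pair_b,
                    subject_id = rep(subject_id, length(labels)),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_windows", "data.frame")
  out
}

# brute-force confusion-table metrics used as the independent oracle
oracle_binary_rates <- function(tp, fn, tn, fp) {
  c(sens = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    bal = 50 * tp / (tp + fn) + 50 * tn / (tn + fp))
}
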