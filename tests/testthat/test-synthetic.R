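test_that("label bookkeeping carves transitions out of adjoining bouts", {
  script <- activity_script(c("sitting", "standing"), c(60, 60))
  sess <- generate_session(subject_profile("B1"), script, seed = 4)
  lab <- sess$label_track$labels
  expect_length(lab, 6000)                       # total time preserved
  n_trans <- sum(lab == "trans_sit_stand")
  expect_equal(n_trans, 135, tolerance = 2 / 135)  # 2.7 s x 50 Hz
  expect_equal(sum(lab == "sitting"), 3000 - n_trans / 2, tolerance = 0.001)
  expect_equal(sum(lab == "standing"), 3000 - n_trans / 2, tolerance = 0.001)
  # labels form contiguous ordered segments
  expect_identical(unique(lab), c("sitting", "trans_sit_stand", "standing"))
})

test_that("invalid adjacency chains are rejected", {
  expect_error(activity_script(c("lying", "walking"), c(30, 30)),
               "invalid adjacency")
  expect_error(activity_script(c("walking", "stairs"), c(30, 30)),
               "invalid adjacency")
})

test_that("stair bouts ramp the shared altitude by one rise per step", {
  prof <- subject_profile("ST1", step_time_stairs_s = 0.9, stair_rise_m = 0.17)
  # 16 steps of emitted stair time once the two transitions are carved
  stair_script_s <- 16 * 0.9 + 4.7
  script <- activity_script(c("standing", "stairs", "standing"),
                            c(30, stair_script_s, 30))
  sess <- generate_session(prof, script, seed = 6)
  lab <- sess$label_track$labels
  idx <- which(lab == "stairs")
  baro <- sess$streams$ankle_right$baro_alt
  net <- baro[max(idx)] - baro[min(idx)]
  expect_lt(abs(net - 16 * 0.17), 0.25)          # first stair bout ascends
  # altimeter output is quantized to 0.1 m
  expect_true(all(abs(baro * 10 - round(baro * 10)) < 1e-9))
})

test_that("identical profile, script and seed give bit-identical sessions", {
  prof <- subject_profile("D1")
  script <- build_daily_script(180)
  a <- generate_session(prof, script, seed = 12)
  b <- generate_session(prof, script, seed = 12)
  expect_identical(a, b)
  c2 <- generate_session(prof, script, seed = 13)
  expect_false(identical(a$streams$chest$accel, c2$streams$chest$accel))
  expect_identical(default_cohort(3, seed = 2, session_s = 120),
                   default_cohort(3, seed = 2, session_s = 120))
})

test_that("streams and label track always share one length", {
  for (seed in 1:3) {
    sess <- generate_session(subject_profile("L"),
                             build_daily_script(150, jitter_sd = 0.1),
                             seed = seed)
    n <- length(sess$label_track$labels)
    for (s in sess$streams) {
      expect_equal(nrow(s$accel), n)
      expect_equal(nrow(s$gyro), n)
      expect_length(s$baro_alt, n)
    }
  }
})

test_that("the default cohort reproduces the calibrated class-time shares", {
  cohort <- default_cohort(5, seed = 77, session_s = 240)
  for (sess in cohort) {
    sh <- label_shares(sess)
    expect_gt(sh[["lying"]], 3.8);    expect_lt(sh[["lying"]], 5.8)
    expect_gt(sh[["standing"]], 31.8); expect_lt(sh[["standing"]], 33.8)
    expect_gt(sh[["sitting"]], 19.2); expect_lt(sh[["sitting"]], 21.2)
    expect_gt(sh[["walking"]], 18.5); expect_lt(sh[["walking"]], 20.5)
    expect_gt(sh[["stairs"]], 5.5);   expect_lt(sh[["stairs"]], 7.5)
    # transitions take up the remainder (~16%)
    trans <- sum(sh[transition_classes()])
    expect_gt(trans, 13); expect_lt(trans, 19)
  }
  expect_error(default_cohort(2), "at least 3")
})

test_that("symmetric arm swing does not hurt wrists-only gait detection", {
  # cohorts identical except for the affected-side attenuation level;
  # balanced accuracy on configuration E must be non-decreasing as the
  # swing becomes symmetric (attenuation -> 1)
  cohort_at <- function(att) {
    lapply(1:4, function(i) {
      set.seed(300 + i)
      prof <- subject_profile(sprintf("P%d", i),
                              affected_side = c("left", "right")[1 + i %% 2],
                              cadence_hz = stats::runif(1, 0.65, 0.95),
                              affected_attenuation = att)
      generate_session(prof, build_daily_script(150, jitter_sd = 0.05),
                       seed = 500 + i)
    })
  }
  bal_at <- vapply(c(0.2, 0.6, 1.0), function(att) {
    ds <- prepare_dataset(cohort_at(att), "E")
    r <- nested_loso(task = "gait", model_kind = "svm",
                     grid = data.frame(C = 1), dataset = ds)
    r$aggregate$mean[r$aggregate$metric == "balanced_accuracy"]
  }, numeric(1))
  expect_true(all(diff(bal_at) >= -1e-9))
})

test_that("wrist gait amplitude increases with attenuation towards symmetric swing", {
  script <- activity_script(c("standing", "walking", "standing"),
                            c(20, 60, 20))
  amp_for <- function(att) {
    prof <- subject_profile("W", affected_side = "left",
                            affected_attenuation = att)
    sess <- generate_session(prof, script, seed = 3)
    idx <- which(sess$label_track$labels == "walking")
    stats::sd(sess$streams$wrist_left$gyro[idx, 1])
  }
  amps <- vapply(c(0.2, 0.5, 1), amp_for, numeric(1))
  expect_true(all(diff(amps) > 0))
  # unaffected wrist unaffected by the attenuation setting
  prof <- subject_profile("W", affected_side = "left",
                          affected_attenuation = 0.2)
  sess <- generate_session(prof, script, seed = 3)
  idx <- which(sess$label_track$labels == "walking")
  expect_gt(stats::sd(sess$streams$wrist_right$gyro[idx, 1]),
            stats::sd(sess$streams$wrist_left$gyro[idx, 1]))
})
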