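fs <- 50

# build a filtered_channels-like list directly (bypassing filters) so the
# statistics can be checked against independent formulas
raw_channels <- function(n = 128, seed = 1) {
  set.seed(seed)
  list(posture_acc = matrix(stats::rnorm(3 * n), n, 3),
       activity_acc = matrix(stats::rnorm(3 * n), n, 3),
       gyro_filt = matrix(stats::rnorm(3 * n, sd = 20), n, 3),
       baro_filt = cumsum(stats::rnorm(n, sd = 0.01)),
       sample_rate_hz = fs)
}

test_that("the per-sensor feature vector has exactly 134 named features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 134)
  expect_equal(sum(reg$channel == "baro"), 8)
  expect_equal(sum(reg$channel == "posture_acc"), 42)
  expect_false(any(duplicated(reg$name)))
  v <- extract_sensor_features(raw_channels(), fs)
  expect_length(v, 134)
  expect_identical(names(v), reg$name)
  expect_false(anyNA(v))
})

test_that("an all-zero window yields zero dispersion, slope and change features", {
  ch <- list(posture_acc = matrix(0, 128, 3), activity_acc = matrix(0, 128, 3),
             gyro_filt = matrix(0, 128, 3), baro_filt = numeric(128))
  v <- extract_sensor_features(ch, fs)
  expect_true(all(v == 0))
})

test_that("statistics agree with independent brute-force implementations", {
  ch <- raw_channels(seed = 99)
  v <- extract_sensor_features(ch, fs)
  x <- ch$posture_acc[, 1]
  n <- length(x)
  expect_equal(v[["posture_acc.x.mean"]], mean(x), tolerance = 1e-8)
  expect_equal(v[["posture_acc.x.var"]], stats::var(x), tolerance = 1e-8)
  expect_equal(v[["posture_acc.x.min"]], min(x))
  expect_equal(v[["posture_acc.x.max"]], max(x))
  expect_equal(v[["posture_acc.x.range"]], diff(range(x)))
  expect_equal(v[["posture_acc.x.median"]], stats::median(x), tolerance = 1e-8)
  expect_equal(v[["posture_acc.x.iqr"]], stats::IQR(x), tolerance = 1e-8)
  expect_equal(v[["posture_acc.x.rms"]], sqrt(mean(x^2)), tolerance = 1e-8)
  xc <- x - mean(x)
  expect_equal(v[["posture_acc.x.skewness"]],
               mean(xc^3) / mean(xc^2)^1.5, tolerance = 1e-8)
  expect_equal(v[["posture_acc.x.kurtosis"]],
               mean(xc^4) / mean(xc^2)^2 - 3, tolerance = 1e-8)
  # spectral oracle: Hann taper, magnitude spectrum, DC bin excluded
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  P <- Mod(stats::fft(x * h))[2:(n / 2 + 1)]^2
  expect_equal(v[["posture_acc.x.spec_energy"]], sum(P), tolerance = 1e-8)
  p <- P / sum(P)
  expect_equal(v[["posture_acc.x.spec_entropy"]], -sum(p * log(p)),
               tolerance = 1e-8)
  expect_equal(v[["posture_acc.x.dom_freq"]], which.max(P) * fs / n,
               tolerance = 1e-8)
  expect_equal(v[["gyro.xy.corr"]],
               stats::cor(ch$gyro_filt[, 1], ch$gyro_filt[, 2]),
               tolerance = 1e-8)
  # barometric block
  b <- ch$baro_filt
  t <- (0:(n - 1)) / fs
  fit <- stats::lm(b ~ t)
  expect_equal(v[["baro.slope"]], unname(stats::coef(fit)[2]), tolerance = 1e-8)
  expect_equal(v[["baro.net_change"]], b[n] - b[1], tolerance = 1e-10)
  expect_equal(v[["baro.diff_rms"]], sqrt(mean(diff(b)^2)), tolerance = 1e-10)
})

test_that("a barometric ramp yields its least-squares slope and net change", {
  ch <- raw_channels()
  ch$baro_filt <- seq(0, 0.5, length.out = 128)
  v <- extract_sensor_features(ch, fs)
  expect_equal(v[["baro.net_change"]], 0.5, tolerance = 1e-10)
  # slope of an exact line = rise/run in m/s
  expect_equal(v[["baro.slope"]], 0.5 / (127 / fs), tolerance = 1e-8)
})

test_that("a 2 Hz sinusoid's dominant frequency lands within one spectral bin", {
  ch <- raw_channels()
  t <- (0:127) / fs
  ch$activity_acc[, 1] <- sin(2 * pi * 2 * t)
  v <- extract_sensor_features(ch, fs)
  expect_lte(abs(v[["activity_acc.x.dom_freq"]] - 2), fs / 128 + 1e-9)
})

test_that("correlation with a constant axis is defined as zero", {
  ch <- raw_channels()
  ch$gyro_filt[, 2] <- 5
  v <- extract_sensor_features(ch, fs)
  expect_identical(unname(v[["gyro.xy.corr"]]), 0)
  expect_identical(unname(v[["gyro.yz.corr"]]), 0)
})

test_that("feature matrix dimensionality follows the sensor configuration", {
  sess <- tiny_session(seconds = 20)
  fmA <- extract_features(sess, "A")
  expect_equal(ncol(fmA$values), 670)
  fmE <- extract_features(sess, "E")
  expect_equal(ncol(fmE$values), 268)
  expect_false(anyNA(fmA$values))
  expect_false(any(duplicated(fmA$feature_names)))
  # zero windows -> 0 x d matrix with the full name list
  short <- windows_from_labels(character(0))
  fm0 <- extract_features(sess, "A", windows = short[0, ])
  expect_equal(dim(fm0$values), c(0, 670))
  expect_length(fm0$feature_names, 670)
})

test_that("per-subject standardization follows the population-variance formula", {
  fm <- structure(list(values = matrix(c(1, 2, 3), 3, 1),
                       feature_names = "f", subject_ids = rep("s1", 3)),
                  class = "feature_matrix")
  out <- standardize_per_subject(fm)
  expect_equal(as.numeric(out$matrix$values),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(out$stats$s1$mu, c(f = 2))
  expect_equal(out$stats$s1$sigma, c(f = sqrt(2 / 3)), tolerance = 1e-12)
})

test_that("degenerate features standardize to zero and subjects are centred independently", {
  vals <- cbind(c(1, 1, 1, 10, 10, 10),        # constant within each subject
                c(1, 2, 3, 101, 102, 103))     # same shape, shifted offset
  fm <- structure(list(values = vals, feature_names = c("f1", "f2"),
                       subject_ids = rep(c("a", "b"), each = 3)),
                  class = "feature_matrix")
  out <- standardize_per_subject(fm)$matrix$values
  expect_true(all(out[, 1] == 0))              # sigma = 0 guard
  expect_equal(out[1:3, 2], out[4:6, 2])       # offsets removed per subject
  expect_equal(mean(out[1:3, 2]), 0, tolerance = 1e-12)
  fm_small <- structure(list(values = matrix(1, 1, 1), feature_names = "f",
                             subject_ids = "solo"), class = "feature_matrix")
  expect_error(standardize_per_subject(fm_small), "solo")
})

test_that("standardization is idempotent and affine-invariant per subject", {
  set.seed(21)
  vals <- matrix(stats::rnorm(40 * 5), 40, 5)
  fm <- structure(list(values = vals, feature_names = paste0("f", 1:5),
                       subject_ids = rep(c("a", "b"), each = 20)),
                  class = "feature_matrix")
  once <- standardize_per_subject(fm)$matrix
  twice <- standardize_per_subject(once)$matrix
  expect_equal(twice$values, once$values, tolerance = 1e-9)
  for (rep_i in 1:5) {
    a <- stats::runif(1, 0.1, 10); b <- stats::rnorm(1, 0, 50)
    fm2 <- fm
    fm2$values <- a * fm$values + b
    expect_equal(standardize_per_subject(fm2)$matrix$values, once$values,
                 tolerance = 1e-9)
  }
})
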