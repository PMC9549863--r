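# Decomposition of raw sensor streams into the four filtered time-series
# used downstream: posture acceleration (gravity band), activity acceleration
# (movement band), low-passed gyroscope, and despiked/smoothed altitude.

#' Default filter constants
#'
#' Cutoffs of the preprocessing filter bank, Hz. `posture_cutoff` splits the
#' gravity/orientation band from body movement; `movement_cutoff` bounds the
#' band of voluntary human movement; barometric smoothing uses
#' `posture_cutoff` after a `baro_median_s`-second moving-median despiker
#' that removes the altimeter's 0.1 m quantization steps. All filters are
#' order-2 Butterworth applied forward-backward (zero phase).
#'
#' @return Named list of filter constants.
#' @export
preprocess_defaults <- function() {
  list(posture_cutoff_hz = 0.5, movement_cutoff_hz = 11,
       filter_order = 2, baro_median_s = 0.5)
}

# Zero-phase Butterworth filtering with odd (point-symmetric) edge extension,
# so ramps and DC pass through the boundaries without endpoint droop.
zero_phase <- function(x, filt, fs) {
  n <- length(x)
  pad <- min(n - 1, max(6 * round(fs), 12))
  if (pad < 3) stop("segment too short for stable filtering")
  # mean removal keeps constant signals exactly constant (no startup
  # transient); odd extension lets ramps pass the boundaries without droop
  m <- mean(x)
  xc <- x - m
  head_ext <- 2 * xc[1] - xc[(pad + 1):2]
  tail_ext <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(head_ext, xc, tail_ext))
  dc_gain <- (sum(filt$b) / sum(filt$a))^2   # forward + backward pass
  y[(pad + 1):(pad + n)] + m * dc_gain
}

zero_phase_cols <- function(m, filt, fs) {
  apply(m, 2, zero_phase, filt = filt, fs = fs)
}

check_filter_input <- function(n, order) {
  if (n < 4 * order * 3)  # forward-backward order-2 needs some support
    stop("segment too short")
}

#' Split raw acceleration into posture and activity components
#'
#' The posture (gravity/orientation) component is a zero-phase order-2
#' low-pass at `posture_cutoff_hz`; the activity (body-movement) component is
#' a zero-phase band-pass between `posture_cutoff_hz` and
#' `movement_cutoff_hz`. Both preserve the input length.
#'
#' @param accel N x 3 acceleration matrix, m/s^2.
#' @param fs sampling rate, Hz; must exceed twice the upper cutoff.
#' @param params filter constants, see [preprocess_defaults()].
#' @return List with elements `posture_acc` and `activity_acc` (N x 3 each).
#' @export
decompose_acceleration <- function(accel, fs, params = preprocess_defaults()) {
  accel <- as.matrix(accel)
  check_filter_input(nrow(accel), params$filter_order)
  stopifnot(fs > 2 * params$movement_cutoff_hz)
  nyq <- fs / 2
  lp <- signal::butter(params$filter_order, params$posture_cutoff_hz / nyq, "low")
  bp <- signal::butter(params$filter_order,
                       c(params$posture_cutoff_hz, params$movement_cutoff_hz) / nyq,
                       "pass")
  list(posture_acc = zero_phase_cols(accel, lp, fs),
       activity_acc = zero_phase_cols(accel, bp, fs))
}

#' Low-pass filter the gyroscope channels
#'
#' Zero-phase order-2 low-pass at `movement_cutoff_hz`, suppressing
#' super-movement-band noise while preserving angular rates below ~5 Hz.
#'
#' @inheritParams decompose_acceleration
#' @param gyro N x 3 angular-rate matrix, deg/s.
#' @return N x 3 filtered matrix.
#' @export
filter_gyro <- function(gyro, fs, params = preprocess_defaults()) {
  gyro <- as.matrix(gyro)
  check_filter_input(nrow(gyro), params$filter_order)
  lp <- signal::butter(params$filter_order,
                       params$movement_cutoff_hz / (fs / 2), "low")
  zero_phase_cols(gyro, lp, fs)
}

#' Despike and smooth the barometric altitude channel
#'
#' A moving median over `baro_median_s` seconds removes the 0.1 m
#' quantization steps of the altimeter, followed by a zero-phase order-2
#' low-pass at `posture_cutoff_hz`. Net altitude change across slow ramps
#' (stair walking) is preserved.
#'
#' @inheritParams decompose_acceleration
#' @param baro_alt length-N altitude vector, meters.
#' @return Length-N filtered vector.
#' @export
filter_baro <- function(baro_alt, fs, params = preprocess_defaults()) {
  baro_alt <- as.numeric(baro_alt)
  n <- length(baro_alt)
  if (n < 25) stop("segment too short")
  k <- round(params$baro_median_s * fs)
  if (k %% 2 == 0) k <- k + 1
  despiked <- stats::runmed(baro_alt, k, endrule = "median")
  lp <- signal::butter(params$filter_order,
                       params$posture_cutoff_hz / (fs / 2), "low")
  zero_phase(as.numeric(despiked), lp, fs)
}

#' Preprocess one sensor stream into its four filtered channels
#'
#' @param stream a [sensor_stream()].
#' @param params filter constants, see [preprocess_defaults()].
#' @return An object of class `filtered_channels`: list with `posture_acc`,
#'   `activity_acc`, `gyro_filt` (N x 3 each), `baro_filt` (length N),
#'   `sample_rate_hz`, and an `edge_samples` attribute marking the first/last
#'   second whose samples are influenced by boundary extension.
#' @export
preprocess_stream <- function(stream, params = preprocess_defaults()) {
  fs <- stream$sample_rate_hz
  acc <- decompose_acceleration(stream$accel, fs, params)
  out <- list(posture_acc = acc$posture_acc,
              activity_acc = acc$activity_acc,
              gyro_filt = filter_gyro(stream$gyro, fs, params),
              baro_filt = filter_baro(stream$baro_alt, fs, params),
              sample_rate_hz = fs)
  attr(out, "edge_samples") <- round(fs)
  class(out) <- "filtered_channels"
  out
}
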