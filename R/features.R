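# Per-window feature extraction (134 features per sensor) and per-subject
# standardization.
#
# Per tri-axial channel (posture acc, activity acc, gyro): 13 per-axis
# statistics x 3 axes + 3 inter-axis correlations = 42; three such channels
# give 126. The barometric channel contributes 8 (level, dispersion, trend
# and roughness statistics). Total 134 per sensor.

axis_feature_names <- function() {
  c("mean", "var", "min", "max", "range", "median", "iqr", "rms",
    "skewness", "kurtosis", "spec_energy", "spec_entropy", "dom_freq")
}

baro_feature_names <- function() {
  c("mean", "var", "min", "max", "range", "slope", "net_change", "diff_rms")
}

#' Feature registry
#'
#' Machine-readable table of the 134 per-sensor features in canonical column
#' order: for each tri-axial channel, 13 statistics per axis plus 3 pairwise
#' inter-axis correlations; 8 statistics for the barometric channel.
#'
#' @return Data frame with columns `name`, `channel`, `axis`, `feature`.
#' @export
feature_registry <- function() {
  rows <- list()
  for (ch in c("posture_acc", "activity_acc", "gyro")) {
    for (ax in c("x", "y", "z"))
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, axis = ax, feature = axis_feature_names())
    rows[[length(rows) + 1]] <- data.frame(
      channel = ch, axis = c("xy", "xz", "yz"), feature = "corr")
  }
  rows[[length(rows) + 1]] <- data.frame(
    channel = "baro", axis = "", feature = baro_feature_names())
  reg <- do.call(rbind, rows)
  reg$name <- ifelse(reg$axis == "",
                     paste(reg$channel, reg$feature, sep = "."),
                     paste(reg$channel, reg$axis, reg$feature, sep = "."))
  rownames(reg) <- NULL
  reg[, c("name", "channel", "axis", "feature")]
}

# ---- vectorized per-axis statistics (columns of X are windows) -------------

# 13 statistics for each column of a W x n matrix
axis_stats <- function(X, fs) {
  n <- nrow(X); k <- ncol(X)
  m <- colMeans(X)
  Xc <- X - matrix(m, n, k, byrow = TRUE)
  ss2 <- colMeans(Xc^2)                      # population 2nd moment
  v <- colSums(Xc^2) / max(n - 1, 1)         # sample variance
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  quart <- apply(X, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
                 names = FALSE)
  if (is.null(dim(quart))) quart <- matrix(quart, 3, k)
  rms <- sqrt(colMeans(X^2))
  sd_pop <- sqrt(ss2)
  skew <- ifelse(sd_pop > 0, colMeans(Xc^3) / sd_pop^3, 0)
  kurt <- ifelse(sd_pop > 0, colMeans(Xc^4) / ss2^2 - 3, 0)
  # magnitude spectrum of the Hann-tapered, unpadded window; DC bin excluded
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  F <- stats::mvfft(X * h)
  half <- 2:(floor(n / 2) + 1)
  P <- Mod(F[half, , drop = FALSE])^2
  energy <- colSums(P)
  entropy <- numeric(k); domf <- numeric(k)
  pos <- energy > 0
  if (any(pos)) {
    p <- P[, pos, drop = FALSE] /
      matrix(energy[pos], nrow(P), sum(pos), byrow = TRUE)
    plogp <- ifelse(p > 0, p * log(p), 0)
    entropy[pos] <- -colSums(plogp)
    domf[pos] <- apply(P[, pos, drop = FALSE], 2, which.max) * fs / n
  }
  rbind(mean = m, var = v, min = mins, max = maxs, range = maxs - mins,
        median = quart[2, ], iqr = quart[3, ] - quart[1, ], rms = rms,
        skewness = skew, kurtosis = kurt, spec_energy = energy,
        spec_entropy = entropy, dom_freq = domf)
}

# correlation of paired columns; 0 where either axis is constant
col_corr <- function(X, Y) {
  n <- nrow(X)
  Xc <- X - matrix(colMeans(X), n, ncol(X), byrow = TRUE)
  Yc <- Y - matrix(colMeans(Y), n, ncol(Y), byrow = TRUE)
  sx <- colSums(Xc^2); sy <- colSums(Yc^2)
  ifelse(sx > 0 & sy > 0, colSums(Xc * Yc) / sqrt(sx * sy), 0)
}

triaxial_features <- function(mat, starts, window, fs) {
  idx <- outer(seq_len(window), starts, `+`)   # starts are 0-based
  axes <- lapply(1:3, function(a) matrix(mat[, a][idx], window, length(starts)))
  per_axis <- lapply(axes, axis_stats, fs = fs)
  corr <- rbind(col_corr(axes[[1]], axes[[2]]),
                col_corr(axes[[1]], axes[[3]]),
                col_corr(axes[[2]], axes[[3]]))
  rbind(per_axis[[1]], per_axis[[2]], per_axis[[3]], corr)
}

baro_features <- function(vec, starts, window, fs) {
  idx <- outer(seq_len(window), starts, `+`)
  X <- matrix(vec[idx], window, length(starts))
  n <- nrow(X)
  m <- colMeans(X)
  Xc <- X - matrix(m, n, ncol(X), byrow = TRUE)
  v <- colSums(Xc^2) / max(n - 1, 1)
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  t <- (0:(n - 1)) / fs
  tc <- t - mean(t)
  slope <- colSums(X * tc) / sum(tc^2)        # least-squares trend, m/s
  net <- X[n, ] - X[1, ]
  diff_rms <- sqrt(colMeans(apply(X, 2, diff)^2))
  rbind(mean = m, var = v, min = mins, max = maxs, range = maxs - mins,
        slope = slope, net_change = net, diff_rms = diff_rms)
}

# all windows x 134 for one preprocessed sensor
sensor_feature_matrix <- function(channels, starts, window, fs) {
  vals <- rbind(
    triaxial_features(channels$posture_acc, starts, window, fs),
    triaxial_features(channels$activity_acc, starts, window, fs),
    triaxial_features(channels$gyro_filt, starts, window, fs),
    baro_features(channels$baro_filt, starts, window, fs))
  t(vals)
}

#' Extract the 134-feature vector of a single window
#'
#' @param channels a [preprocess_stream()] result, or a window-length slice
#'   of one.
#' @param fs sampling rate, Hz.
#' @param start 0-based start index of the window within `channels`.
#' @param window window length in samples (must match the slice).
#' @return Named numeric vector of length 134, ordered per
#'   [feature_registry()].
#' @export
extract_sensor_features <- function(channels, fs, start = 0L, window = 128L) {
  if (nrow(channels$posture_acc) < start + window)
    stop("window exceeds slice length")
  vals <- sensor_feature_matrix(channels, start, window, fs)[1, ]
  names(vals) <- feature_registry()$name
  vals
}

#' Extract the feature matrix of a session under a sensor configuration
#'
#' Each row concatenates one 134-feature block per sensor, sensors in
#' canonical configuration order, giving `134 * k` columns for `k` sensors
#' (670 for the all-sensors configuration A).
#'
#' @param session a [recording_session()].
#' @param config_id sensor configuration `"A"`..`"E"`.
#' @param windows a `labeled_windows` data frame for this session
#'   (default: computed from the session's label track).
#' @param params filter constants, see [preprocess_defaults()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (n_windows x d), `feature_names`, `subject_ids`.
#' @export
extract_features <- function(session, config_id = "A", windows = NULL,
                             params = preprocess_defaults()) {
  if (is.null(windows)) {
    wd <- window_defaults()
    windows <- label_windows(session$label_track, session$subject_id,
                             wd$length, wd$hop)
  }
  streams <- select_configuration(session, config_id)
  fs <- session$label_track$sample_rate_hz
  window <- if (nrow(windows)) windows$length[1] else window_defaults()$length
  reg <- feature_registry()
  # unilateral configurations resolve to a different body side per subject;
  # name columns by sensor role so feature matrices align across subjects
  prefix <- if (config_id %in% c("C", "D")) {
    sub("_(left|right)$", "", names(streams))
  } else names(streams)
  names_all <- unlist(lapply(prefix,
                             function(p) paste(p, reg$name, sep = ".")))
  if (nrow(windows) == 0) {
    return(structure(list(values = matrix(numeric(0), 0, length(names_all),
                                          dimnames = list(NULL, names_all)),
                          feature_names = names_all, subject_ids = character(0)),
                     class = "feature_matrix"))
  }
  blocks <- lapply(streams, function(s) {
    ch <- preprocess_stream(s, params)
    sensor_feature_matrix(ch, windows$start, window, fs)
  })
  values <- do.call(cbind, blocks)
  colnames(values) <- names_all
  structure(list(values = values, feature_names = names_all,
                 subject_ids = windows$subject_id),
            class = "feature_matrix")
}

#' Bind feature matrices of several sessions
#' @param fms list of `feature_matrix` objects with identical columns.
#' @return A single `feature_matrix`.
#' @export
bind_features <- function(fms) {
  stopifnot(length(fms) >= 1)
  nm <- fms[[1]]$feature_names
  for (f in fms) stopifnot(identical(f$feature_names, nm))
  structure(list(values = do.call(rbind, lapply(fms, `[[`, "values")),
                 feature_names = nm,
                 subject_ids = unlist(lapply(fms, `[[`, "subject_ids"),
                                      use.names = FALSE)),
            class = "feature_matrix")
}

#' Standardize features within each subject
#'
#' Every feature is centred and scaled per subject using that subject's own
#' windows: `x~ = (x - mu) / sigma` with `mu` the per-subject mean and
#' `sigma` the population standard deviation (`1/n` denominator). Degenerate
#' features (`sigma = 0`) map to 0. Because scaling is strictly
#' within-subject it leaks no information across subjects in
#' leave-one-subject-out evaluation.
#'
#' @param fm a `feature_matrix`.
#' @return List with `matrix` (standardized `feature_matrix`) and `stats`
#'   (per-subject list of `mu` and `sigma` vectors).
#' @export
standardize_per_subject <- function(fm) {
  values <- fm$values
  subjects <- unique(fm$subject_ids)
  stats_out <- list()
  for (s in subjects) {
    rows <- which(fm$subject_ids == s)
    if (length(rows) < 2)
      stop("subject with fewer than 2 windows cannot be standardized: ", s)
    block <- values[rows, , drop = FALSE]
    mu <- stats::setNames(colMeans(block), fm$feature_names)
    sigma <- stats::setNames(numeric(ncol(block)), fm$feature_names)
    sigma[] <- sqrt(colMeans(
      (block - matrix(mu, nrow(block), ncol(block), byrow = TRUE))^2))
    scaled <- (block - matrix(mu, nrow(block), ncol(block), byrow = TRUE)) /
      matrix(ifelse(sigma > 0, sigma, 1), nrow(block), ncol(block), byrow = TRUE)
    scaled[, sigma == 0] <- 0
    values[rows, ] <- scaled
    stats_out[[s]] <- list(mu = mu, sigma = sigma)
  }
  out <- fm
  out$values <- values
  list(matrix = out, stats = stats_out)
}
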