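# Data model and I/O for multi-sensor daily-life recording sessions.

#' Label vocabulary
#'
#' The eight per-sample ground-truth classes: three body postures, two gait
#' types, and three undirected transition classes between adjoining postures
#' or gait types.
#'
#' @return Character vector of the eight valid labels.
#' @export
label_vocabulary <- function() {
  c("lying", "sitting", "standing", "walking", "stairs",
    "trans_lying_sit", "trans_sit_stand", "trans_stand_walk")
}

#' @rdname label_vocabulary
#' @export
activity_classes <- function() {
  c("lying", "sitting", "standing", "walking", "stairs")
}

#' @rdname label_vocabulary
#' @export
transition_classes <- function() {
  c("trans_lying_sit", "trans_sit_stand", "trans_stand_walk")
}

#' Canonical sensor wearing locations, in fixed order
#'
#' The ordering (chest, left wrist, right wrist, left ankle, right ankle) is
#' fixed so that feature-vector column order is reproducible across runs.
#'
#' @return Character vector of the five location names.
#' @export
sensor_locations <- function() {
  c("chest", "wrist_left", "wrist_right", "ankle_left", "ankle_right")
}

#' Adjoining classes of a transition label
#'
#' Transition labels are undirected; the pair order follows the class name
#' (e.g. `trans_sit_stand` -> sitting, standing).
#'
#' @param label a transition class name.
#' @return Character vector of length 2.
#' @export
transition_pair <- function(label) {
  switch(label,
    trans_lying_sit  = c("lying", "sitting"),
    trans_sit_stand  = c("sitting", "standing"),
    trans_stand_walk = c("standing", "walking"),
    stop("not a transition label: ", label)
  )
}

#' Construct a sensor stream
#'
#' One body-worn unit's synchronized channels: tri-axial accelerometer
#' (m/s^2), tri-axial gyroscope (deg/s) and barometric altitude (m, 0.1 m
#' device quantization).
#'
#' @param location one of [sensor_locations()].
#' @param accel N x 3 numeric matrix, m/s^2.
#' @param gyro N x 3 numeric matrix, deg/s.
#' @param baro_alt length-N numeric vector, meters.
#' @param sample_rate_hz sampling frequency, Hz (default 50).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(location, accel, gyro, baro_alt, sample_rate_hz = 50) {
  location <- match.arg(location, sensor_locations())
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  baro_alt <- as.numeric(baro_alt)
  stopifnot(ncol(accel) == 3, ncol(gyro) == 3)
  n <- nrow(accel)
  if (nrow(gyro) != n || length(baro_alt) != n)
    stop("desynchronized stream: accel, gyro and baro_alt lengths differ")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be > 0")
  structure(
    list(location = location, accel = unname(accel), gyro = unname(gyro),
         baro_alt = baro_alt, sample_rate_hz = sample_rate_hz),
    class = "sensor_stream")
}

#' Construct a per-sample label track
#'
#' @param labels character vector over [label_vocabulary()].
#' @param sample_rate_hz sampling frequency, Hz.
#' @return An object of class `label_track`.
#' @export
label_track <- function(labels, sample_rate_hz = 50) {
  labels <- as.character(labels)
  bad <- which(!(labels %in% label_vocabulary()))
  if (length(bad))
    stop(sprintf("label vocabulary violation: token \"%s\" at position %d",
                 labels[bad[1]], bad[1]))
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be > 0")
  structure(list(labels = labels, sample_rate_hz = sample_rate_hz),
            class = "label_track")
}

#' Construct a recording session
#'
#' One subject's synchronized sensor streams, ground-truth label track and
#' clinical metadata.
#'
#' @param subject_id subject identifier string.
#' @param affected_side `"left"` or `"right"` (hemiparetic side).
#' @param streams named list of [sensor_stream()] objects keyed by location.
#' @param label_track a [label_track()] of the same length as the streams.
#' @param clinical optional named list with entries `bbs` (0-56),
#'   `walk_speed_10mwt` (m/s), `tug_s` (s), `fac` (0-5).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(subject_id, affected_side, streams, label_track,
                              clinical = NULL) {
  affected_side <- match.arg(affected_side, c("left", "right"))
  stopifnot(inherits(label_track, "label_track"), length(streams) >= 1)
  locs <- vapply(streams, function(s) s$location, character(1))
  names(streams) <- locs
  lens <- vapply(streams, function(s) nrow(s$accel), integer(1))
  if (length(unique(lens)) > 1)
    stop("desynchronized session: stream lengths differ")
  if (length(label_track$labels) != lens[1])
    stop("desynchronized session: label track length differs from streams")
  structure(
    list(subject_id = as.character(subject_id), affected_side = affected_side,
         streams = streams[intersect(sensor_locations(), locs)],
         label_track = label_track, clinical = clinical),
    class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  n <- length(x$label_track$labels)
  cat(sprintf("<recording_session> subject %s (affected side: %s)\n",
              x$subject_id, x$affected_side))
  cat(sprintf("  %d sensors [%s], %d samples @ %g Hz (%.1f min)\n",
              length(x$streams), paste(names(x$streams), collapse = ", "),
              n, x$label_track$sample_rate_hz,
              n / x$label_track$sample_rate_hz / 60))
  invisible(x)
}

# ---- session directory I/O --------------------------------------------------

#' Write a recording session to a directory
#'
#' Layout: one `<location>.csv` per sensor (header
#' `time_s,acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z,baro_m`), a `labels.csv`
#' (`time_s,label`) and a `meta.yaml` with subject metadata. All files UTF-8
#' with '.' decimal separator.
#'
#' @param session a [recording_session()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fs <- session$label_track$sample_rate_hz
  for (loc in names(session$streams)) {
    s <- session$streams[[loc]]
    n <- nrow(s$accel)
    df <- data.frame(
      time_s = (seq_len(n) - 1) / fs,
      acc_x = s$accel[, 1], acc_y = s$accel[, 2], acc_z = s$accel[, 3],
      gyro_x = s$gyro[, 1], gyro_y = s$gyro[, 2], gyro_z = s$gyro[, 3],
      baro_m = s$baro_alt)
    utils::write.csv(df, file.path(path, paste0(loc, ".csv")),
                     row.names = FALSE)
  }
  lab <- data.frame(
    time_s = (seq_along(session$label_track$labels) - 1) / fs,
    label = session$label_track$labels)
  utils::write.csv(lab, file.path(path, "labels.csv"), row.names = FALSE)
  meta <- list(
    subject_id = session$subject_id,
    affected_side = session$affected_side,
    sample_rate_hz = fs,
    sensors = as.list(names(session$streams)),
    clinical = session$clinical)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a recording session from a directory
#'
#' Inverse of [write_session()]. All declared sensors must be present and the
#' streams, labels and metadata are validated on load.
#'
#' @param path session directory.
#' @return A validated [recording_session()].
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.yaml")
  if (!file.exists(meta_file))
    stop("incomplete session: missing meta.yaml in ", path)
  meta <- yaml::read_yaml(meta_file)
  fs <- meta$sample_rate_hz
  sensors <- unlist(meta$sensors)
  streams <- list()
  for (loc in sensors) {
    f <- file.path(path, paste0(loc, ".csv"))
    if (!file.exists(f))
      stop("incomplete session: missing ", basename(f))
    df <- utils::read.csv(f)
    streams[[loc]] <- sensor_stream(
      loc,
      accel = as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
      gyro = as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")]),
      baro_alt = df$baro_m, sample_rate_hz = fs)
  }
  lf <- file.path(path, "labels.csv")
  if (!file.exists(lf)) stop("incomplete session: missing labels.csv")
  lab <- utils::read.csv(lf, colClasses = c(time_s = "numeric",
                                            label = "character"))
  clinical <- meta$clinical
  if (!is.null(clinical) && !length(clinical)) clinical <- NULL
  recording_session(meta$subject_id, meta$affected_side, streams,
                    label_track(lab$label, fs), clinical)
}

# ---- label resampling -------------------------------------------------------

#' Resample a per-frame label sequence to the sensor rate
#'
#' Video ground truth is labeled per frame (typically 30 fps) while the
#' inertial streams run at 50 Hz. Each output sample takes the label of the
#' nearest source frame in time (nearest-neighbour; exact ties resolve to the
#' earlier frame). Nearest-neighbour, rather than majority over frame spans,
#' preserves short transition segments.
#'
#' @param video_labels character vector of per-frame labels.
#' @param source_rate_hz frame rate of `video_labels`.
#' @param target_rate_hz sensor sampling rate.
#' @return A [label_track()] of length `round(n * target/source)`.
#' @export
resample_labels <- function(video_labels, source_rate_hz, target_rate_hz) {
  if (length(video_labels) == 0) stop("empty label sequence")
  stopifnot(source_rate_hz > 0, target_rate_hz > 0)
  n_in <- length(video_labels)
  n_out <- round(n_in * target_rate_hz / source_rate_hz)
  i <- seq_len(n_out) - 1
  # nearest source index; ceiling(x - 0.5) rounds half-way points down,
  # i.e. ties go to the earlier frame (small epsilon absorbs float error
  # in the rate ratio so exact ties resolve deterministically)
  j <- ceiling(i * source_rate_hz / target_rate_hz - 0.5 - 1e-9)
  j <- pmin(pmax(j, 0), n_in - 1)
  label_track(video_labels[j + 1], target_rate_hz)
}

# ---- sensor configurations --------------------------------------------------

#' Sensor placement configurations
#'
#' Five wearing-location subsets: A = all five sensors; B = no chest
#' (bilateral wrists + ankles); C = one wrist + one ankle on the
#' non-affected side; D = the same on the affected side; E = wrists only.
#'
#' @param config_id one of `"A"`..`"E"`.
#' @param affected_side `"left"` or `"right"`; required for C and D.
#' @return Character vector of resolved locations in canonical order.
#' @export
configuration_locations <- function(config_id, affected_side = NULL) {
  config_id <- match.arg(config_id, c("A", "B", "C", "D", "E"))
  side <- function(s) c(paste0("wrist_", s), paste0("ankle_", s))
  locs <- switch(config_id,
    A = sensor_locations(),
    B = setdiff(sensor_locations(), "chest"),
    C = {
      if (is.null(affected_side)) stop("affected_side required for configuration C")
      side(if (affected_side == "left") "right" else "left")
    },
    D = {
      if (is.null(affected_side)) stop("affected_side required for configuration D")
      side(affected_side)
    },
    E = c("wrist_left", "wrist_right"))
  intersect(sensor_locations(), locs)
}

#' Select a session's streams for a sensor configuration
#'
#' @param session a [recording_session()].
#' @param config_id one of `"A"`..`"E"` (see [configuration_locations()]).
#' @return Ordered list of `sensor_stream` objects (canonical location order).
#' @export
select_configuration <- function(session, config_id) {
  locs <- configuration_locations(config_id, session$affected_side)
  missing <- setdiff(locs, names(session$streams))
  if (length(missing))
    stop("configuration unavailable for session: missing ",
         paste(missing, collapse = ", "))
  session$streams[locs]
}
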