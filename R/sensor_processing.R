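#' Composite forefoot load signal
#'
#' Collapses the two forefoot force-sensitive resistors (first and fifth
#' metatarsal head) into a single load signal by taking their sample-wise
#' maximum. Foot load is usually not distributed symmetrically across the
#' forefoot, so the larger of the two sensors indicates forefoot contact.
#'
#' @param mt1,mt5 Numeric vectors, non-negative load signals (arbitrary
#'   units) from the first and fifth metatarsal head FSRs. Recycled to a
#'   common length if one is scalar.
#' @return Numeric vector `pmax(mt1, mt5)`.
#' @examples
#' forefoot_signal(0.2, 0.7)
#' @export
forefoot_signal <- function(mt1, mt5) {
  if (!is.numeric(mt1) || !is.numeric(mt5)) {
    stop("invalid signal: forefoot FSR inputs must be numeric", call. = FALSE)
  }
  if (any(!is.finite(mt1)) || any(!is.finite(mt5))) {
    stop("invalid signal: non-finite forefoot FSR value", call. = FALSE)
  }
  if (any(mt1 < 0) || any(mt5 < 0)) {
    stop("invalid signal: negative forefoot FSR value", call. = FALSE)
  }
  pmax(mt1, mt5)
}

#' Sagittal angle estimation by complementary filtering
#'
#' Fuses gyroscope and accelerometer streams into a sagittal tilt angle with
#' the standard complementary-filter recursion
#' \deqn{\theta_t = b\,(\theta_{t-1} + \omega_t\,\Delta t) + (1-b)\,\theta^{acc}_t,}
#' where \eqn{\omega_t} is the sagittal (y-axis) angular rate and
#' \eqn{\theta^{acc}_t = \mathrm{atan2}(a_x, a_z)} is the tilt implied by the
#' gravity direction. The gyroscope term tracks fast motion; the
#' accelerometer term anchors the low-frequency drift.
#'
#' @param accel Numeric matrix (n x 3) of accelerometer samples, m/s^2,
#'   columns x/y/z, or a numeric vector already expressing the
#'   accelerometer tilt angle in degrees.
#' @param gyro Numeric matrix (n x 3) of gyroscope samples (sagittal rate in
#'   column 2), or a numeric vector of sagittal rates.
#' @param dt Sample interval in seconds (default 0.01, i.e. 100 Hz).
#' @param blend Dimensionless blend coefficient in `[0, 1]`; weight of the
#'   integrated gyroscope path. Default 0.98 at 100 Hz.
#' @param gyro_unit Unit of the gyroscope rates, `"rad/s"` (default) or
#'   `"deg/s"`.
#' @param init Initial angle in degrees; default is the first accelerometer
#'   tilt sample (0 if that sample has zero norm).
#' @return Numeric vector of sagittal angles in degrees, flexion positive,
#'   one per input sample.
#' @details Samples whose accelerometer vector has (numerically) zero norm
#'   carry no gravity information; the filter falls back to a pure gyroscope
#'   update there and emits one warning per call.
#' @export
complementary_filter <- function(accel, gyro, dt = 0.01, blend = 0.98,
                                 gyro_unit = c("rad/s", "deg/s"),
                                 init = NULL) {
  gyro_unit <- match.arg(gyro_unit)
  stopifnot(dt > 0, blend >= 0, blend <= 1)
  if (is.matrix(accel)) {
    ax <- accel[, 1]; az <- accel[, 3]
    nrm <- sqrt(ax^2 + az^2 + accel[, 2]^2)
    tilt <- ifelse(nrm > 1e-12, atan2(ax, az) * 180 / pi, NA_real_)
  } else {
    tilt <- as.numeric(accel)
    nrm <- rep(1, length(tilt))
  }
  rate <- if (is.matrix(gyro)) gyro[, 2] else as.numeric(gyro)
  if (gyro_unit == "rad/s") rate <- rate * 180 / pi
  n <- length(tilt)
  if (length(rate) != n) stop("accel and gyro streams must have equal length", call. = FALSE)
  if (anyNA(tilt)) warning("zero-norm accelerometer sample(s): gyro-only update used there")
  angle <- numeric(n)
  prev <- if (!is.null(init)) init else if (is.finite(tilt[1]) && !is.na(tilt[1])) tilt[1] else 0
  for (i in seq_len(n)) {
    pred <- prev + rate[i] * dt
    angle[i] <- if (is.na(tilt[i])) pred else blend * pred + (1 - blend) * tilt[i]
    prev <- angle[i]
  }
  angle
}

#' Schmitt-trigger binarization of a sensor value
#'
#' Converts a load or angle signal into the logic value used by the gait
#' phase detector. The output switches to 1 above `theta * (1 +
#' hysteresis_frac)`, to 0 below `theta * (1 - hysteresis_frac)`, and holds
#' the previous state inside the band, which suppresses chatter when the
#' signal rides near the threshold.
#'
#' @param value Numeric scalar or vector, the signal sample(s).
#' @param theta Positive threshold in the signal's units.
#' @param hysteresis_frac Half-width of the dead band as a fraction of
#'   `theta`, in `[0, 1)`. Default 0.1.
#' @param prev Previous binary state (0 or 1) used inside the band.
#' @return Integer 0 or 1 (vectorized over `value`, threading `prev`
#'   through consecutive samples when `value` is a vector).
#' @export
binarize <- function(value, theta, hysteresis_frac = 0.1, prev = 0L) {
  stopifnot(is.numeric(theta), length(theta) == 1, is.finite(theta), theta > 0,
            hysteresis_frac >= 0, hysteresis_frac < 1)
  hi <- theta * (1 + hysteresis_frac)
  lo <- theta * (1 - hysteresis_frac)
  out <- integer(length(value))
  state <- as.integer(prev)
  for (i in seq_along(value)) {
    if (value[i] > hi) state <- 1L
    else if (value[i] < lo) state <- 0L
    out[i] <- state
  }
  if (length(value) == 1L) out[1] else out
}

#' Adaptive threshold from a calibration window
#'
#' Places the detection threshold a fixed fraction of the way between the
#' minimum and maximum observed over a recent window of samples:
#' `theta = min + k * (max - min)`. This adapts to inter-subject and
#' inter-sensor amplitude differences in the FSR signals.
#'
#' @param window Numeric vector of recent samples for one channel.
#' @param k Fraction of the window range, in (0, 1). Default 0.3.
#' @param prev_theta Threshold to retain when the window is flat
#'   (max == min); default `NA`.
#' @return The threshold (numeric scalar). A flat window returns
#'   `prev_theta` with a warning.
#' @export
update_thresholds <- function(window, k = 0.3, prev_theta = NA_real_) {
  stopifnot(length(window) > 0, k > 0, k < 1)
  lo <- min(window); hi <- max(window)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    warning("flat calibration window: previous threshold retained")
    return(prev_theta)
  }
  lo + k * (hi - lo)
}

# Running threshold for every sample of a stream. mode "batch" uses the
# whole recording's min/max (offline analysis default); "sliding" uses a
# trailing window of `width` samples (causal, expanding during warm-up).
running_threshold <- function(x, k = 0.3, mode = c("batch", "sliding"),
                              width = 400L) {
  mode <- match.arg(mode)
  if (mode == "batch") {
    th <- update_thresholds(x, k)
    return(rep(th, length(x)))
  }
  lo <- zoo::rollapplyr(x, width, min, partial = TRUE)
  hi <- zoo::rollapplyr(x, width, max, partial = TRUE)
  th <- lo + k * (hi - lo)
  flat <- hi <= lo
  if (any(flat)) th[flat] <- NA_real_
  th <- zoo::na.locf(zoo::zoo(th), na.rm = FALSE)
  as.numeric(th)
}

#' Convert raw sensor streams into binary FSM inputs
#'
#' Full front-end of the gait phase detector: builds the composite forefoot
#' signal, obtains the sagittal hip angle (from a precomputed `phi_h` column
#' if present, otherwise by complementary filtering of the inertial
#' channels), derives per-channel adaptive thresholds, and binarizes heel
#' contact (`GH`), forefoot contact (`GT`) and hip flexion (`PhiH`).
#'
#' The hip threshold is a fraction `theta_h_frac` of the peak hip flexion
#' seen in the recording (batch mode) or trailing window (sliding mode); its
#' binarization uses no hysteresis by default because the filtered angle is
#' smooth and a dead band would systematically delay the terminal-swing
#' event.
#'
#' @param sensors Data frame with columns `t`, `fsr_heel`, `fsr_mt1`,
#'   `fsr_mt5`, and either `phi_h` or `ax,ay,az,gx,gy,gz`. An `fsr_toe`
#'   column is accepted and ignored by the controller.
#' @param k Adaptive-threshold fraction of the signal range (default 0.3).
#' @param hysteresis Hysteresis fraction for the FSR channels (default 0.1).
#' @param hip_hysteresis Hysteresis fraction for the hip channel (default 0).
#' @param theta_h_frac Hip threshold as a fraction of peak flexion
#'   (default 0.6).
#' @param mode Threshold adaptation mode, `"batch"` (default) or
#'   `"sliding"`.
#' @param window Sliding-window width in samples (default 400, i.e. about
#'   two slow gait cycles at 100 Hz).
#' @param blend Complementary-filter blend coefficient (default 0.98).
#' @return Data frame with columns `t`, `GH`, `GT`, `PhiH` (one row per
#'   input sample), with the thresholds used attached as attribute
#'   `"thresholds"` and the hip angle as attribute `"phi_h"`.
#' @export
process_sensors <- function(sensors, k = 0.3, hysteresis = 0.1,
                            hip_hysteresis = 0, theta_h_frac = 0.6,
                            mode = c("batch", "sliding"), window = 400L,
                            blend = 0.98) {
  mode <- match.arg(mode)
  need <- c("t", "fsr_heel", "fsr_mt1", "fsr_mt5")
  missing_cols <- setdiff(need, names(sensors))
  if (length(missing_cols)) {
    stop("sensor stream lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ft <- forefoot_signal(sensors$fsr_mt1, sensors$fsr_mt5)
  fh <- sensors$fsr_heel
  if ("phi_h" %in% names(sensors)) {
    phi <- sensors$phi_h
  } else {
    imu <- c("ax", "ay", "az", "gx", "gy", "gz")
    if (!all(imu %in% names(sensors))) {
      stop("sensor stream needs either phi_h or the six inertial columns",
           call. = FALSE)
    }
    dt <- stats::median(diff(sensors$t))
    phi <- complementary_filter(as.matrix(sensors[, c("ax", "ay", "az")]),
                                as.matrix(sensors[, c("gx", "gy", "gz")]),
                                dt = dt, blend = blend)
  }
  th_fh <- running_threshold(fh, k, mode, window)
  th_ft <- running_threshold(ft, k, mode, window)
  # hip threshold tracks peak flexion, not the min-max range
  th_h <- if (mode == "batch") rep(theta_h_frac * max(phi), length(phi))
          else theta_h_frac * zoo::rollapplyr(phi, window, max, partial = TRUE)

  bin_stream <- function(x, th, hyst) {
    out <- integer(length(x))
    state <- 0L
    for (i in seq_along(x)) {
      if (is.finite(th[i]) && th[i] > 0) {
        state <- binarize(x[i], th[i], hyst, state)
      }
      out[i] <- state
    }
    out
  }
  res <- data.frame(
    t = sensors$t,
    GH = bin_stream(fh, th_fh, hysteresis),
    GT = bin_stream(ft, th_ft, hysteresis),
    PhiH = bin_stream(phi, th_h, hip_hysteresis)
  )
  attr(res, "thresholds") <- list(theta_FH = th_fh[length(th_fh)],
                                  theta_FT = th_ft[length(th_ft)],
                                  theta_H = th_h[length(th_h)])
  attr(res, "phi_h") <- phi
  res
}

#' Read and write the sensor CSV dialect
#'
#' Time-series CSV with a mandatory header row and a leading `#` comment
#' line documenting units. Columns: `t` (s), `fsr_heel`, `fsr_mt1`,
#' `fsr_mt5` (load units), optional `fsr_toe`, `ax,ay,az` (m/s^2),
#' `gx,gy,gz` (rad/s), and optional `phi_h`, `hip`, `knee`, `ankle`
#' (degrees).
#'
#' @param path File path.
#' @return `read_sensor_csv` returns the data frame; `write_sensor_csv`
#'   returns `path` invisibly.
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"t" %in% names(df)) stop("sensor CSV lacks a 't' column", call. = FALSE)
  if (is.unsorted(df$t, strictly = TRUE)) {
    stop("sensor CSV times must be strictly increasing", call. = FALSE)
  }
  df
}

#' @rdname read_sensor_csv
#' @param df Data frame to write.
#' @export
write_sensor_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: t=s fsr_*=load ax,ay,az=m/s^2 ",
                    "gx,gy,gz=rad/s angles=deg"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
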