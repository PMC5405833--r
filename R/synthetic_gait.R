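#' Default gait phase fractions
#'
#' Nominal fractions of one gait cycle spent in each phase (loading
#' response 10%, stance 30%, pre-swing 15%, swing 35%, terminal swing
#' 10%), consistent with standard gait-analysis texts for slow treadmill
#' walking.
#'
#' @return Named numeric vector over `LR`, `ST`, `PS`, `SW`, `TSW`,
#'   summing to 1.
#' @export
default_phase_fractions <- function() {
  c(LR = 0.10, ST = 0.30, PS = 0.15, SW = 0.35, TSW = 0.10)
}

# Canonical joint-angle shapes over cycle fraction x in [0, 1), normalized
# numerically to zero midrange and unit range at template creation. The
# knee shows the small loading-response bump and the large swing flexion
# peak near 72% of the cycle; the ankle the plantar/dorsiflexion
# alternation. These are idealized textbook curves, not digitized data.
.knee_shape <- function(x) -cos(2 * pi * (x - 0.72)) + 0.35 * cos(4 * pi * (x - 0.15))
.ankle_shape <- function(x) sin(2 * pi * x + 0.3) + 0.6 * sin(4 * pi * x + 1.2)

.normalize_shape <- function(f) {
  g <- f(seq(0, 1, length.out = 2001))
  m <- (max(g) + min(g)) / 2
  r <- max(g) - min(g)
  function(x) (f(x) - m) / r
}

# Hip trajectory: sinusoid mid + (rom/2) cos(2 pi (x - x_peak)), with the
# peak placed so that the rising crossing of theta = theta_h_frac * hip_max
# falls exactly at the swing -> terminal-swing boundary fraction.
.hip_params <- function(hip_max, hip_rom, theta_h_frac, tsw_start) {
  A <- hip_rom / 2
  mid <- hip_max - A
  theta <- theta_h_frac * hip_max
  z <- (theta - mid) / A
  if (!is.finite(z) || z <= -1 || z >= 1) {
    stop("configuration error: hip threshold fraction incompatible with ",
         "hip range (no crossing inside the cycle)", call. = FALSE)
  }
  list(A = A, mid = mid, theta = theta,
       x_peak = tsw_start + acos(z) / (2 * pi))
}

#' Parametric template for synthetic gait recordings
#'
#' Describes one leg's periodic gait at the 100 Hz sensor rate: cycle
#' duration and phase fractions, FSR plateau amplitudes, idealized
#' hip/knee/ankle angle trajectories, and per-channel additive Gaussian
#' noise. The heel FSR is loaded exactly during loading response and
#' stance; the forefoot loads partway through the loading response
#' (foot-flat progression) and unloads at the end of pre-swing; the hip
#' angle rises through its detection threshold exactly once per swing, at
#' the terminal-swing boundary.
#'
#' @param cycle_duration Nominal cycle duration in seconds (default 2.0,
#'   slow treadmill walking).
#' @param phase_fractions Named fractions per phase summing to 1.
#' @param fs Sampling rate in Hz (default 100).
#' @param fsr_amplitude Named loads for `heel`, `mt1`, `mt5`, `toe`
#'   (arbitrary units).
#' @param forefoot_contact_frac Fraction of the loading response after
#'   which the forefoot contacts the ground (default 0.6).
#' @param hip_max Peak hip flexion, degrees (default 30).
#' @param hip_rom Hip range of motion, degrees (default 40, i.e. extension
#'   to -10).
#' @param theta_h_frac Hip threshold as a fraction of peak flexion
#'   (default 0.6; must leave the threshold inside the hip range).
#' @param knee_offset,knee_rom Knee midrange and range, degrees (defaults
#'   30 and 60).
#' @param ankle_offset,ankle_rom Ankle midrange and range, degrees
#'   (defaults 0 and 25).
#' @param noise_sd Named Gaussian SDs. Additive white measurement noise:
#'   `fsr` (load units), `accel` (m/s^2), `gyro` (rad/s), `hip` (deg, the
#'   inertial hip-angle channel), `angle` (deg, the joint-angle channels).
#'   Stride-to-stride kinematic variability, drawn once per cycle and
#'   joint: `cycle_rom` (deg, range-of-motion fluctuation about the
#'   template value) and `cycle_offset` (deg, baseline shift). Cycle-level
#'   variability dominates in real gait, which is why per-cycle RoM
#'   estimates are approximately Gaussian around the template RoM rather
#'   than extreme-value distributed.
#' @param cadence_jitter_sd SD of per-cycle duration jitter in seconds
#'   (default 0: exactly periodic; set > 0 for stride-time variability).
#' @return A `gait_template` object.
#' @export
gait_template <- function(cycle_duration = 2.0,
                          phase_fractions = default_phase_fractions(),
                          fs = 100,
                          fsr_amplitude = c(heel = 1.0, mt1 = 1.0,
                                            mt5 = 0.8, toe = 0.6),
                          forefoot_contact_frac = 0.6,
                          hip_max = 30, hip_rom = 40, theta_h_frac = 0.6,
                          knee_offset = 30, knee_rom = 60,
                          ankle_offset = 0, ankle_rom = 25,
                          noise_sd = c(fsr = 0.03, accel = 0.05,
                                       gyro = 0.01, hip = 0.3, angle = 0.2,
                                       cycle_rom = 1.0, cycle_offset = 0.5),
                          cadence_jitter_sd = 0) {
  if (abs(sum(phase_fractions) - 1) > 1e-9) {
    stop("configuration error: phase fractions must sum to 1", call. = FALSE)
  }
  stopifnot(cycle_duration > 0, fs > 0, all(noise_sd >= 0),
            cadence_jitter_sd >= 0,
            forefoot_contact_frac > 0, forefoot_contact_frac <= 1)
  defaults <- c(fsr = 0.03, accel = 0.05, gyro = 0.01, hip = 0.3,
                angle = 0.2, cycle_rom = 1.0, cycle_offset = 0.5)
  if (length(bad <- setdiff(names(noise_sd), names(defaults)))) {
    stop("configuration error: unknown noise_sd component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(noise_sd)] <- noise_sd
  noise_sd <- defaults
  phase_fractions <- phase_fractions[gait_phases()]
  tsw_start <- sum(phase_fractions[c("LR", "ST", "PS", "SW")])
  hp <- .hip_params(hip_max, hip_rom, theta_h_frac, tsw_start)
  structure(list(cycle_duration = cycle_duration,
                 phase_fractions = phase_fractions, fs = fs,
                 fsr_amplitude = fsr_amplitude,
                 forefoot_contact_frac = forefoot_contact_frac,
                 hip_max = hip_max, hip_rom = hip_rom,
                 theta_h_frac = theta_h_frac, hip = hp,
                 knee_offset = knee_offset, knee_rom = knee_rom,
                 ankle_offset = ankle_offset, ankle_rom = ankle_rom,
                 knee_fn = .normalize_shape(.knee_shape),
                 ankle_fn = .normalize_shape(.ankle_shape),
                 noise_sd = noise_sd,
                 cadence_jitter_sd = cadence_jitter_sd),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf("gait template: %.3g s cycle @ %g Hz, phases %s\n",
              x$cycle_duration, x$fs,
              paste(sprintf("%s %.0f%%", names(x$phase_fractions),
                            100 * x$phase_fractions), collapse = ", ")))
  invisible(x)
}

# run expr with a locally seeded RNG, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic gait recording with ground truth
#'
#' Produces `n_cycles` of periodic gait at the template's sampling rate:
#' FSR load plateaus with step contact edges, inertial channels consistent
#' with the hip trajectory (gravity components plus the sagittal angular
#' rate), a precomputed hip-angle channel, joint-angle streams, and the
#' embedded ground truth (per-sample phase labels, transition event times,
#' cycle-start times).
#'
#' The heel strike at the very first sample starts the recording and is
#' not a detectable transition, so it is excluded from the ground-truth
#' event list; cycle-start times (including t = 0) are reported separately
#' for segmentation.
#'
#' @param template A `gait_template`.
#' @param n_cycles Number of gait cycles (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#'   The same template and seed yield identical recordings.
#' @return A `synthetic_recording` object: list with
#'   \describe{
#'     \item{sensors}{data frame `t, fsr_heel, fsr_mt1, fsr_mt5, fsr_toe,
#'       ax, ay, az, gx, gy, gz, phi_h`;}
#'     \item{angles}{data frame `t, hip, knee, ankle` (degrees);}
#'     \item{truth}{list: `phase` (label per sample), `events` (data frame
#'       `t, index, kind, cycle`), `hs_times` (cycle-start times),
#'       `theta_h` (hip threshold, degrees).}
#'   }
#' @export
generate_gait <- function(template, n_cycles, seed = NULL) {
  stopifnot(inherits(template, "gait_template"), n_cycles >= 1)
  .with_seed(seed, {
    fs <- template$fs
    cd <- template$cycle_duration
    jit <- template$cadence_jitter_sd
    durs <- if (jit > 0) pmax(cd / 2, stats::rnorm(n_cycles, cd, jit))
            else rep(cd, n_cycles)
    n_i <- pmax(10L, as.integer(round(durs * fs)))
    frac <- cumsum(template$phase_fractions)
    amp <- template$fsr_amplitude
    ns <- template$noise_sd
    phase_l <- list(); heel_l <- list(); ff_l <- list(); toe_l <- list()
    hip_l <- list(); knee_l <- list(); ankle_l <- list(); rate_l <- list()
    ev_idx <- integer(0); ev_kind <- character(0); ev_cyc <- integer(0)
    starts <- integer(n_cycles)
    offset <- 0L
    for (c in seq_len(n_cycles)) {
      n <- n_i[c]
      b <- as.integer(round(frac * n))            # phase boundary samples
      for (i in seq_along(b)[-1]) b[i] <- max(b[i], b[i - 1] + 1L)
      b <- pmin(pmax(b, seq_along(b)), n)         # each phase >= 1 sample
      b[length(b)] <- n
      j <- seq_len(n)
      x <- (j - 1) / n
      lab <- cut(j, breaks = c(0, b), labels = gait_phases())
      phase_l[[c]] <- as.character(lab)
      heel_l[[c]] <- amp[["heel"]] * as.numeric(j <= b[2])
      ff_start <- max(1L, as.integer(round(template$forefoot_contact_frac * b[1])))
      ff_l[[c]] <- as.numeric(j > ff_start & j <= b[3])
      toe_l[[c]] <- amp[["toe"]] * as.numeric(j > b[1] & j <= b[3])
      # stride-to-stride variability: per-cycle RoM and baseline draws
      sd_r <- ns[["cycle_rom"]]; sd_o <- ns[["cycle_offset"]]
      d_rom <- if (sd_r > 0) stats::rnorm(3, 0, sd_r) else numeric(3)
      d_off <- if (sd_o > 0) stats::rnorm(3, 0, sd_o) else numeric(3)
      hp <- template$hip
      A_c <- hp$A + d_rom[1] / 2
      hip_l[[c]] <- hp$mid + d_off[1] + A_c * cos(2 * pi * (x - hp$x_peak))
      knee_l[[c]] <- template$knee_offset + d_off[2] +
        (template$knee_rom + d_rom[2]) * template$knee_fn(x)
      ankle_l[[c]] <- template$ankle_offset + d_off[3] +
        (template$ankle_rom + d_rom[3]) * template$ankle_fn(x)
      # analytic sagittal hip rate for the gyroscope, rad/s
      rate_l[[c]] <- -2 * pi * A_c * sin(2 * pi * (x - hp$x_peak)) *
        (pi / 180) / durs[c]
      starts[c] <- offset + 1L
      kinds <- c("HS", "HO", "SW", "TSW")
      idxs <- offset + c(1L, b[2] + 1L, b[3] + 1L, b[4] + 1L)
      if (c == 1L) { kinds <- kinds[-1]; idxs <- idxs[-1] }
      ev_idx <- c(ev_idx, idxs); ev_kind <- c(ev_kind, kinds)
      ev_cyc <- c(ev_cyc, rep(c, length(kinds)))
      offset <- offset + n
    }
    N <- offset
    t <- (seq_len(N) - 1) / fs
    hip <- unlist(hip_l); knee <- unlist(knee_l); ankle <- unlist(ankle_l)
    rate <- unlist(rate_l)
    phi_rad <- hip * pi / 180
    g0 <- 9.81
    rn <- function(sd) if (sd > 0) stats::rnorm(N, 0, sd) else numeric(N)
    sensors <- data.frame(
      t = t,
      fsr_heel = pmax(0, unlist(heel_l) + rn(ns[["fsr"]])),
      fsr_mt1 = pmax(0, amp[["mt1"]] * unlist(ff_l) + rn(ns[["fsr"]])),
      fsr_mt5 = pmax(0, amp[["mt5"]] * unlist(ff_l) + rn(ns[["fsr"]])),
      fsr_toe = pmax(0, unlist(toe_l) + rn(ns[["fsr"]])),
      ax = g0 * sin(phi_rad) + rn(ns[["accel"]]),
      ay = rn(ns[["accel"]]),
      az = g0 * cos(phi_rad) + rn(ns[["accel"]]),
      gx = rn(ns[["gyro"]]),
      gy = rate + rn(ns[["gyro"]]),
      gz = rn(ns[["gyro"]]),
      phi_h = hip + rn(ns[["hip"]])
    )
    angles <- data.frame(
      t = t,
      hip = hip + rn(ns[["angle"]]),
      knee = knee + rn(ns[["angle"]]),
      ankle = ankle + rn(ns[["angle"]])
    )
    structure(list(
      sensors = sensors, angles = angles,
      truth = list(phase = unlist(phase_l),
                   events = data.frame(t = t[ev_idx], index = ev_idx,
                                       kind = ev_kind, cycle = ev_cyc),
                   hs_times = t[starts],
                   cycle_starts = starts,
                   theta_h = template$hip$theta),
      template = template, n_cycles = n_cycles),
      class = "synthetic_recording")
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("synthetic gait recording: %d cycles, %d samples @ %g Hz\n",
              x$n_cycles, nrow(x$sensors), x$template$fs))
  invisible(x)
}

# shift template parameters by named effects; "<joint>_rom" widens the
# joint's range about its midrange, "<joint>_offset" shifts the midrange
.apply_effect <- function(template, effect) {
  for (nm in names(effect)) {
    val <- effect[[nm]]
    switch(nm,
      hip_rom = { template$hip_rom <- template$hip_rom + val },
      hip_offset = { template$hip_max <- template$hip_max + val },
      knee_rom = { template$knee_rom <- template$knee_rom + val },
      knee_offset = { template$knee_offset <- template$knee_offset + val },
      ankle_rom = { template$ankle_rom <- template$ankle_rom + val },
      ankle_offset = { template$ankle_offset <- template$ankle_offset + val },
      stop("unknown effect parameter: ", nm, call. = FALSE)
    )
  }
  tsw_start <- sum(template$phase_fractions[c("LR", "ST", "PS", "SW")])
  template$hip <- .hip_params(template$hip_max, template$hip_rom,
                              template$theta_h_frac, tsw_start)
  template
}

#' Generate a matched pair of recordings for a two-condition comparison
#'
#' Emulates a within-subject two-condition trial (e.g. walking with and
#' without stimulation): condition A uses the template as given; condition
#' B applies the stated joint-angle effects (range-of-motion widening
#' about the midrange, or offset shifts) before generation. Noise draws
#' are independent between conditions.
#'
#' @param template A `gait_template`.
#' @param effect Named list of effect sizes in degrees, e.g.
#'   `list(ankle_rom = 5)`; names are `<joint>_rom` or `<joint>_offset`
#'   for joints `hip`, `knee`, `ankle`.
#' @param n_cycles Cycles per condition (default 31, enough for 30
#'   segmented cycles).
#' @param seed Optional integer seed.
#' @return List with `synthetic_recording` elements `A` and `B`.
#' @export
two_condition_experiment <- function(template, effect = list(),
                                     n_cycles = 31, seed = NULL) {
  stopifnot(inherits(template, "gait_template"))
  .with_seed(seed, {
    list(A = generate_gait(template, n_cycles),
         B = generate_gait(.apply_effect(template, effect), n_cycles))
  })
}

#' Write a recording's ground truth to CSV
#'
#' One row per sample with the phase label, plus the event kind at
#' transition samples (empty elsewhere).
#'
#' @param rec A `synthetic_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(rec, path) {
  stopifnot(inherits(rec, "synthetic_recording"))
  kind <- character(nrow(rec$sensors))
  kind[rec$truth$events$index] <- rec$truth$events$kind
  utils::write.csv(data.frame(t = rec$sensors$t, phase = rec$truth$phase,
                              event = kind),
                   path, row.names = FALSE)
  invisible(path)
}
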