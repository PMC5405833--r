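#' Design a stimulation-envelope transfer function
#'
#' Builds the discrete impulse response of a unity-DC-gain second-order
#' low-pass Butterworth filter (bilinear-transform discretization at
#' sampling rate `fs`, cutoff prewarped so the -3 dB point falls exactly at
#' `fc`). The kernel is truncated where the remaining tail energy drops
#' below `tol` of the total, and a gain `g = 1 / max(kernel)` is stored so
#' that the response to an isolated unit impulse peaks at exactly 1.
#'
#' The cutoff frequency controls the envelope's duration: a muscle gated
#' over a phase of nominal duration `d` seconds uses `fc = 1 / (2 d)` by
#' default, so the impulse response roughly spans the phase.
#'
#' @param fc Cutoff frequency in Hz, `0 < fc < fs/2`.
#' @param fs Sampling rate in Hz (default 100, the sensor rate).
#' @param tol Tail-energy truncation tolerance (default 1e-6).
#' @return A `transfer_function` object: list with `fc`, `fs`, `order`,
#'   filter coefficients `b`, `a`, the truncated `kernel`, its length `L`,
#'   and the normalization gain `g`.
#' @export
design_kernel <- function(fc, fs = 100, tol = 1e-6) {
  if (!is.numeric(fc) || length(fc) != 1 || !is.finite(fc) ||
      fc <= 0 || fc >= fs / 2) {
    stop("invalid cutoff: fc must satisfy 0 < fc < fs/2", call. = FALSE)
  }
  bw <- signal::butter(2, fc / (fs / 2), type = "low")
  b <- as.numeric(bw$b); a <- as.numeric(bw$a)
  # impulse response by direct recursion, extended until the tail is quiet
  n <- max(64L, ceiling(4 * fs / fc))
  repeat {
    h <- as.numeric(signal::filter(bw, c(1, rep(0, n - 1))))
    etot <- sum(h^2)
    ecum <- cumsum(h^2)
    keep <- which(etot - ecum < tol * etot)
    if (length(keep) && keep[1] < n) break
    n <- n * 2L
    if (n > 1e7) stop("kernel did not decay; check fc", call. = FALSE)
  }
  L <- keep[1]
  kernel <- h[seq_len(L)]
  structure(list(fc = fc, fs = fs, order = 2L, b = b, a = a,
                 kernel = kernel, L = L, g = 1 / max(kernel)),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("2nd-order Butterworth low-pass: fc = %.4g Hz, fs = %g Hz, L = %d, g = %.4g\n",
              x$fc, x$fs, x$L, x$g))
  invisible(x)
}

#' Normalized response to an impulse train
#'
#' Convolves a unit impulse train with the transfer function's kernel and
#' applies the normalization gain: `u = g * (h * I)`. An isolated impulse
#' therefore produces a response peaking at exactly 1; responses from
#' impulses of consecutive gait cycles superpose and may exceed 1 (the
#' caller clamps before mapping to current). Values above 1 by less than
#' 1e-9 are tidied to 1. The underdamped second-order kernel has a small
#' negative tail lobe (about 4% of the peak); a negative stimulation
#' envelope is meaningless, so negative response values are clamped to 0
#' unless `clamp = FALSE` (useful for inspecting the raw linear
#' convolution).
#'
#' @param impulses Numeric vector, the impulse train sampled on the
#'   transfer function's grid (`tf$fs`).
#' @param tf A `transfer_function` from [design_kernel()].
#' @param fs Optional sampling rate of the impulse train; must equal
#'   `tf$fs` (a mismatch signals a resampling-required error).
#' @param clamp Clamp negative response values to 0 (default `TRUE`).
#' @return Numeric vector `u`, same length as `impulses`.
#' @export
response_output <- function(impulses, tf, fs = NULL, clamp = TRUE) {
  stopifnot(inherits(tf, "transfer_function"))
  if (!is.null(fs) && !isTRUE(all.equal(fs, tf$fs))) {
    stop("resampling required: impulse train rate ", fs,
         " Hz does not match transfer function rate ", tf$fs, " Hz",
         call. = FALSE)
  }
  n <- length(impulses)
  if (n == 0L) return(numeric(0))
  u <- tf$g * stats::convolve(impulses, rev(tf$kernel),
                              type = "open")[seq_len(n)]
  u[u > 1 & u - 1 < 1e-9] <- 1
  if (clamp) u[u < 0] <- 0 else u[u < 0 & u > -1e-9] <- 0
  u
}

# muscle -> component wiring: driving event kind and gating phase set
.component_table <- list(
  TA = list(list(event = "SW", phases = c("SW", "TSW"))),
  BF = list(list(event = "SW", phases = c("SW", "TSW"))),
  LG = list(list(event = "HS", phases = "LR"),
            list(event = "HO", phases = "PS")),
  RF = list(list(event = "HS", phases = "LR"),
            list(event = "TSW", phases = "TSW"))
)

#' Phase gate of a stimulation component
#'
#' The top level of the hierarchical controller switches each muscle's
#' stimulation on only during its pre-set phases: tibialis anterior (TA)
#' and biceps femoris (BF) during swing and terminal swing; lateral
#' gastrocnemius (LG) during loading response (heel-strike component) and
#' pre-swing (heel-off component); rectus femoris (RF) during loading
#' response and terminal swing.
#'
#' @param phase Gait phase label (or vector of labels).
#' @param phases Character vector, the component's gating phase set.
#' @return Integer 0/1 (vectorized over `phase`).
#' @export
gate <- function(phase, phases) {
  stopifnot(all(phase %in% gait_phases()), all(phases %in% gait_phases()))
  as.integer(phase %in% phases)
}

#' Configure one stimulation channel
#'
#' Bundles one muscle's stimulation parameters: the current band
#' `[cmin, cmax]` (mA) measured per subject during setup, the pulse train
#' annotation (350 us pulse width, 40 Hz by default), and the channel's
#' reflex components (driving event, gating phases, transfer function).
#' Each component's default cutoff is `fc = 1/(2 d)` where `d` is the
#' nominal duration of its gated phases.
#'
#' @param muscle One of `"TA"`, `"LG"`, `"BF"`, `"RF"`.
#' @param side `"left"` or `"right"`.
#' @param cmin,cmax Minimum / maximum threshold currents in mA,
#'   `0 <= cmin <= cmax`.
#' @param pulse_width Pulse width in microseconds (default 350).
#' @param stim_frequency Stimulation frequency in Hz (default 40).
#' @param fs Control/sampling rate in Hz (default 100).
#' @param cycle_duration Nominal gait cycle duration in seconds used for
#'   the default cutoffs (default 2).
#' @param phase_fractions Named fractions of the cycle per phase (default
#'   [default_phase_fractions()]).
#' @param fc Optional numeric vector overriding the cutoff of each
#'   component (recycled).
#' @return A `muscle_channel_config` object; its `components` element is a
#'   list of `(event, phases, tf)` triples with pairwise-disjoint gating
#'   phase sets.
#' @export
muscle_channel_config <- function(muscle, side = c("left", "right"),
                                  cmin, cmax, pulse_width = 350,
                                  stim_frequency = 40, fs = 100,
                                  cycle_duration = 2,
                                  phase_fractions = default_phase_fractions(),
                                  fc = NULL) {
  muscle <- match.arg(muscle, names(.component_table))
  side <- match.arg(side)
  stopifnot(is.numeric(cmin), is.numeric(cmax), cmin >= 0, cmax >= cmin)
  comps <- .component_table[[muscle]]
  if (!is.null(fc)) fc <- rep_len(fc, length(comps))
  comps <- lapply(seq_along(comps), function(i) {
    cmp <- comps[[i]]
    d <- cycle_duration * sum(phase_fractions[cmp$phases])
    cmp$tf <- design_kernel(if (is.null(fc)) 1 / (2 * d) else fc[i], fs = fs)
    cmp
  })
  gsets <- lapply(comps, `[[`, "phases")
  if (length(gsets) > 1 && length(Reduce(intersect, gsets)) > 0) {
    stop("component gating phase sets must be pairwise disjoint", call. = FALSE)
  }
  structure(list(muscle = muscle, side = side,
                 cmin = cmin, cmax = cmax, delta_c = cmax - cmin,
                 pulse_width = pulse_width, stim_frequency = stim_frequency,
                 fs = fs, components = comps,
                 id = paste0(toupper(substr(side, 1, 1)), "_", muscle)),
            class = "muscle_channel_config")
}

#' @export
print.muscle_channel_config <- function(x, ...) {
  cat(sprintf("%s: cmin %g mA, cmax %g mA, %g us @ %g Hz, %d component(s)\n",
              x$id, x$cmin, x$cmax, x$pulse_width, x$stim_frequency,
              length(x$components)))
  invisible(x)
}

#' Map normalized responses to a stimulation current
#'
#' The low-level current mapping: each component contributes
#' `(u * delta_c + cmin) * S`, so a fully gated channel spans
#' `[cmin, cmax]` as `u` spans `[0, 1]` and is silent (`0` mA) when no
#' gate is active. Multi-component channels (LG, RF) sum their
#' contributions; their disjoint gating phases guarantee at most one
#' nonzero term at a time.
#'
#' @param u Normalized response(s) in `[0, 1]`, one per component
#'   (recycled).
#' @param S Gate value(s) 0/1, one per component (recycled).
#' @param cfg A `muscle_channel_config`.
#' @return Commanded current in mA.
#' @export
channel_current <- function(u, S, cfg) {
  stopifnot(inherits(cfg, "muscle_channel_config"))
  if (any(u < -1e-9 | u > 1 + 1e-9)) {
    stop("contract violation: normalized response outside [0, 1]",
         call. = FALSE)
  }
  u <- pmin(pmax(u, 0), 1)
  k <- length(cfg$components)
  u <- rep_len(u, k); S <- rep_len(S, k)
  sum((u * cfg$delta_c + cfg$cmin) * S)
}

#' Run the reflexive FES controller over a binary-frame stream
#'
#' End-to-end hierarchical control at the 100 Hz tick rate: the gait FSM
#' detects phases and event impulses; each channel component convolves its
#' driving impulse train with its Butterworth envelope, the phase gate
#' switches the component on or off, and the current mapping bounds every
#' nonzero command within the channel's `[cmin, cmax]`. Responses from
#' consecutive cycles superpose and are clamped to 1 before the current
#' mapping so commands never exceed `cmax`.
#'
#' @param frames Binary-frame data frame (`t`, `GH`, `GT`, `PhiH`), e.g.
#'   from [process_sensors()].
#' @param configs List of `muscle_channel_config` objects.
#' @param initial_phase FSM phase at stream start (default `"ST"`).
#' @return A `stim_commands` object: list with `commands` (data frame `t`
#'   plus one current column in mA per channel id), `phases`, `events`,
#'   and `meta` (per-channel pulse width and frequency annotations).
#' @export
run_controller <- function(frames, configs, initial_phase = "ST") {
  if (length(configs) == 0) stop("configuration error: no channels", call. = FALSE)
  stopifnot(all(vapply(configs, inherits, TRUE, "muscle_channel_config")))
  det <- detect_events(frames, initial_phase)
  n <- nrow(frames)
  out <- data.frame(t = frames$t)
  meta <- list()
  for (cfg in configs) {
    cur <- numeric(n)
    for (cmp in cfg$components) {
      u <- response_output(det$impulses[, cmp$event], cmp$tf)
      u <- pmin(u, 1)
      S <- gate(det$phases, cmp$phases)
      cur <- cur + (u * cfg$delta_c + cfg$cmin) * S
    }
    out[[cfg$id]] <- cur
    meta[[cfg$id]] <- list(pulse_width = cfg$pulse_width,
                           frequency = cfg$stim_frequency)
  }
  structure(list(commands = out, phases = det$phases, events = det$events,
                 meta = meta),
            class = "stim_commands")
}

#' @export
print.stim_commands <- function(x, ...) {
  cat(sprintf("stimulation commands: %d ticks, channels %s\n",
              nrow(x$commands),
              paste(setdiff(names(x$commands), "t"), collapse = ", ")))
  invisible(x)
}

#' Write stimulation commands to CSV with a JSON sidecar
#'
#' The CSV holds `t` and one current column (mA) per channel; the sidecar
#' (`<path>.meta.json`) records each channel's pulse width (us) and
#' stimulation frequency (Hz).
#'
#' @param cmds A `stim_commands` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stim_csv <- function(cmds, path) {
  stopifnot(inherits(cmds, "stim_commands"))
  utils::write.csv(cmds$commands, path, row.names = FALSE)
  jsonlite::write_json(cmds$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load subject stimulation parameters
#'
#' Reads a YAML configuration mirroring the per-subject setup table:
#' for each subject and muscle-side, the measured `cmin`/`cmax` currents
#' (mA), plus optional `pulse_width`, `stim_frequency` and per-muscle `fc`
#' overrides. The packaged fixture (`stim_params.yaml`) carries the
#' measured bands of the seven study subjects A-G.
#'
#' @param subject Subject identifier (e.g. `"A"`).
#' @param sides Which legs to configure (default both).
#' @param path YAML file; default the packaged fixture.
#' @param ... Passed on to [muscle_channel_config()] (e.g.
#'   `cycle_duration`).
#' @return Named list of `muscle_channel_config` objects keyed by channel
#'   id (`L_TA`, `R_RF`, ...).
#' @export
load_stim_config <- function(subject, sides = c("left", "right"),
                             path = NULL, ...) {
  if (is.null(path)) {
    path <- system.file("extdata", "stim_params.yaml", package = "gaitfes")
  }
  cfgl <- yaml::read_yaml(path)
  if (!subject %in% names(cfgl$subjects)) {
    stop("unknown subject '", subject, "' in ", path, call. = FALSE)
  }
  sub <- cfgl$subjects[[subject]]
  pw <- if (!is.null(cfgl$pulse_width)) cfgl$pulse_width else 350
  sf <- if (!is.null(cfgl$stim_frequency)) cfgl$stim_frequency else 40
  out <- list()
  for (side in sides) {
    key <- paste0(toupper(substr(side, 1, 1)))
    for (m in c("TA", "LG", "BF", "RF")) {
      entry <- sub[[paste0(key, m)]]
      if (is.null(entry)) {
        stop("config missing channel ", key, m, " for subject ", subject,
             call. = FALSE)
      }
      cfg <- muscle_channel_config(m, side, cmin = entry$cmin,
                                   cmax = entry$cmax, pulse_width = pw,
                                   stim_frequency = sf,
                                   fc = entry$fc, ...)
      out[[cfg$id]] <- cfg
    }
  }
  out
}
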