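#' Gait phases and event kinds
#'
#' The controller divides one gait cycle into five phases: loading response
#' (`LR`, initial contact to foot flat), stance (`ST`, foot flat), pre-swing
#' (`PS`, heel off with the forefoot loaded), swing (`SW`, foot airborne)
#' and terminal swing (`TSW`, hip flexed past its threshold before contact).
#' Transitions between phases produce four unit event impulses: heel strike
#' (`HS`), heel off (`HO`), swing onset (`SW`) and terminal-swing onset
#' (`TSW`).
#'
#' @return Character vector of phase or event names.
#' @export
gait_phases <- function() c("LR", "ST", "PS", "SW", "TSW")

#' @rdname gait_phases
#' @export
event_kinds <- function() c("HS", "HO", "SW", "TSW")

#' Initialize the gait finite state machine
#'
#' @param phase Initial phase label; default `"ST"` (a stream normally
#'   starts with the foot on the ground).
#' @return An `fsm_state` list with the current phase and the previously
#'   seen binary frame (`NULL` before the first sample).
#' @export
fsm_state <- function(phase = "ST") {
  phase <- match.arg(phase, gait_phases())
  structure(list(phase = phase, prev_frame = NULL), class = "fsm_state")
}

#' Advance the gait FSM by one binary frame
#'
#' Evaluates the four IF-THEN event rules on the pair (previous frame,
#' current frame) and updates the phase. The sensor conditions are:
#' \describe{
#'   \item{HS}{`(GH=1 or GT=1)` now and `(GH=0 or GT=0)` before — any part
#'     of the foot touches the ground after the swing (fires from `SW` or
#'     `TSW`; a forefoot-first contact counts, as pathological gait may
#'     land on the forefoot). Phase becomes `LR`.}
#'   \item{HO}{`(GH=0 and GT=1)` now and `(GH=1 and GT=1)` before — the
#'     heel lifts while the forefoot stays loaded (from foot-flat stance).
#'     Phase becomes `PS`.}
#'   \item{SW}{`(GH=0 and GT=0)` now and `GT=1` before — the foot leaves
#'     the ground entirely (from stance or pre-swing; a direct stance to
#'     swing transition skips `PS`). Phase becomes `SW`.}
#'   \item{TSW}{`(GH=0 and GT=0)` and the binary hip-flexion signal rises
#'     `0 -> 1` while airborne (from `SW` only; `PhiH` is ignored whenever
#'     the foot is loaded). Phase becomes `TSW`.}
#' }
#' In addition the silent foot-flat transition `LR -> ST` occurs when
#' `GH=1 and GT=1`, which is required before heel-off can fire.
#'
#' The first frame only initializes the internal state and emits nothing.
#'
#' @param state An `fsm_state` object.
#' @param frame One-row data frame (or list) with `t`, `GH`, `GT`, `PhiH`.
#' @return List with elements `state` (updated `fsm_state`) and `events`
#'   (character vector of the impulse kinds emitted this sample, possibly
#'   empty).
#' @export
step_fsm <- function(state, frame) {
  stopifnot(inherits(state, "fsm_state"))
  gh <- as.integer(frame$GH); gt <- as.integer(frame$GT)
  ph <- as.integer(frame$PhiH)
  prev <- state$prev_frame
  if (is.null(prev)) {
    state$prev_frame <- list(GH = gh, GT = gt, PhiH = ph)
    return(list(state = state, events = character(0)))
  }
  events <- character(0)
  phase <- state$phase
  entry <- phase

  if (entry %in% c("SW", "TSW") &&
      (gh == 1L || gt == 1L) && (prev$GH == 0L || prev$GT == 0L)) {
    events <- c(events, "HS"); phase <- "LR"
  }
  if (entry %in% c("LR", "ST") &&
      gh == 0L && gt == 1L && prev$GH == 1L && prev$GT == 1L) {
    events <- c(events, "HO"); phase <- "PS"
  }
  if (entry %in% c("LR", "ST", "PS") &&
      gh == 0L && gt == 0L && prev$GT == 1L) {
    events <- c(events, "SW"); phase <- "SW"
  }
  if (entry == "SW" &&
      gh == 0L && gt == 0L && ph == 1L && prev$PhiH == 0L) {
    events <- c(events, "TSW"); phase <- "TSW"
  }
  if (length(events) == 0L && phase == "LR" && gh == 1L && gt == 1L) {
    phase <- "ST"
  }
  state$phase <- phase
  state$prev_frame <- list(GH = gh, GT = gt, PhiH = ph)
  list(state = state, events = events)
}

#' Detect gait events over a whole binary-frame stream
#'
#' Batch wrapper folding [step_fsm()] over the stream. Returns the phase
#' label at every sample, the detected events, and the four unit impulse
#' trains aligned to the sampling grid.
#'
#' @param frames Data frame with columns `t`, `GH`, `GT`, `PhiH`.
#' @param initial_phase Phase assumed at stream start (default `"ST"`).
#' @return List with
#'   \describe{
#'     \item{phases}{character vector, one label per sample;}
#'     \item{events}{data frame `t`, `index`, `kind` of detected impulses;}
#'     \item{impulses}{numeric matrix (n x 4), columns `HS`, `HO`, `SW`,
#'       `TSW`, value 1 at event samples and 0 elsewhere.}
#'   }
#' @export
detect_events <- function(frames, initial_phase = "ST") {
  n <- nrow(frames)
  imp <- matrix(0, nrow = max(n, 0L), ncol = 4,
                dimnames = list(NULL, event_kinds()))
  if (is.null(n) || n == 0L) {
    return(list(phases = character(0),
                events = data.frame(t = numeric(0), index = integer(0),
                                    kind = character(0)),
                impulses = imp))
  }
  st <- fsm_state(initial_phase)
  phases <- character(n)
  ev_t <- numeric(0); ev_i <- integer(0); ev_k <- character(0)
  gh <- as.integer(frames$GH); gt <- as.integer(frames$GT)
  ph <- as.integer(frames$PhiH); tt <- frames$t
  for (i in seq_len(n)) {
    res <- step_fsm(st, list(GH = gh[i], GT = gt[i], PhiH = ph[i]))
    st <- res$state
    phases[i] <- st$phase
    for (k in res$events) {
      ev_t <- c(ev_t, tt[i]); ev_i <- c(ev_i, i); ev_k <- c(ev_k, k)
      imp[i, k] <- 1
    }
  }
  list(phases = phases,
       events = data.frame(t = ev_t, index = ev_i, kind = ev_k),
       impulses = imp)
}

#' Write detected events / phase labels to CSV
#'
#' @param events Event data frame from [detect_events()] (`t`, `index`,
#'   `kind`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("t", "index", "kind")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param t Sample times.
#' @param phases Phase label per sample.
#' @export
write_phases_csv <- function(t, phases, path) {
  utils::write.csv(data.frame(t = t, phase = phases), path, row.names = FALSE)
  invisible(path)
}
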