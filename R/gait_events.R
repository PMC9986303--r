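#' Gait-event detection specification
#'
#' Stance and swing are separated by thresholding the sagittal-plane speed
#' of the hoof marker (vertical + progression components), after
#' Ghoussayni's velocity-threshold method.  The default threshold is the
#' original 50 mm/s; phases shorter than `min_phase_duration` are treated
#' as threshold chatter and absorbed into the longer adjacent phase.
#'
#' @param speed_threshold sagittal-plane speed threshold, m/s
#' @param min_phase_duration shortest admissible phase, s (>= 2 frames)
#' @return object of class `event_spec`
#' @export
event_spec <- function(speed_threshold = 0.05, min_phase_duration = 0.1) {
  if (speed_threshold <= 0) stop("speed_threshold must be positive")
  structure(list(speed_threshold = speed_threshold,
                 min_phase_duration = min_phase_duration),
            class = "event_spec")
}

#' Detect stance/swing phases from hoof velocity
#'
#' Stance frames are maximal runs where the sagittal-plane speed
#' `sqrt(v_y^2 + v_z^2)` stays below the threshold; swing is the
#' complement.  Runs shorter than the debounce duration are merged into
#' the longer neighbouring phase.  A foot strike is the first frame of a
#' stance run, a toe off the first frame of a swing run.
#'
#' @param hoof_velocity n x 3 velocity matrix (m/s) of the limb's distal
#'   phalange (DPHAL) marker, post-filtering; columns x, y, z
#' @param spec an [event_spec()]
#' @param sample_rate sampling rate, Hz
#' @return list with `phases` (data.frame: phase, start, end — 1-based,
#'   inclusive frame intervals) and `events` (data.frame: foot_strike,
#'   toe_off, next_foot_strike for each complete cycle; zero rows when no
#'   alternation was found)
#' @export
detect_phases <- function(hoof_velocity, spec = event_spec(), sample_rate) {
  if (is.null(dim(hoof_velocity)) || nrow(hoof_velocity) == 0L)
    stop("empty velocity series")
  speed <- sqrt(hoof_velocity[, "y"]^2 + hoof_velocity[, "z"]^2)
  stance <- speed < spec$speed_threshold
  min_frames <- max(2L, round(spec$min_phase_duration * sample_rate))

  r <- rle(stance)
  # absorb sub-debounce runs into the longer adjacent phase (interior runs
  # only; truncated edge phases are legitimate partial phases)
  repeat {
    if (length(r$lengths) <= 1L) break
    interior <- seq_along(r$lengths)[-c(1L, length(r$lengths))]
    short <- interior[r$lengths[interior] < min_frames]
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    absorb <- if (r$lengths[k - 1L] >= r$lengths[k + 1L]) k - 1L else k + 1L
    r$values[k] <- r$values[absorb]
    r <- rle(inverse.rle(r))
  }

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  phases <- data.frame(
    phase = ifelse(r$values, "stance", "swing"),
    start = starts, end = ends, stringsAsFactors = FALSE)

  # events are observed transitions only: the first run has no preceding
  # phase, so its start is not a foot strike / toe off
  genuine <- phases$start > 1L
  strikes <- phases$start[phases$phase == "stance" & genuine]
  toeoffs <- phases$start[phases$phase == "swing" & genuine]
  events <- NULL
  for (fs in strikes) {
    to <- toeoffs[toeoffs > fs][1L]
    nfs <- strikes[strikes > fs][1L]
    if (!is.na(to) && !is.na(nfs) && to < nfs)
      events <- rbind(events, data.frame(foot_strike = fs, toe_off = to,
                                         next_foot_strike = nfs))
  }
  if (is.null(events))
    events <- data.frame(foot_strike = integer(0), toe_off = integer(0),
                         next_foot_strike = integer(0))
  list(phases = phases, events = events)
}

#' A single gait cycle
#'
#' One stance + swing cycle of a limb, delimited by a foot strike, the
#' following toe off, and the next foot strike.  Stance frames are
#' `[foot_strike, toe_off)` and swing frames `[toe_off, next_foot_strike)`,
#' so the two partition the cycle and stance + swing = stride exactly.
#'
#' @param limb limb identifier (`FL_L`, `FL_R`, `HL_L`, `HL_R`)
#' @param foot_strike,toe_off,next_foot_strike frame indices (1-based)
#' @return object of class `gait_cycle`
#' @export
gait_cycle <- function(limb, foot_strike, toe_off, next_foot_strike) {
  if (!(foot_strike < toe_off && toe_off < next_foot_strike))
    stop("need foot_strike < toe_off < next_foot_strike")
  structure(list(limb = limb, foot_strike = as.integer(foot_strike),
                 toe_off = as.integer(toe_off),
                 next_foot_strike = as.integer(next_foot_strike)),
            class = "gait_cycle")
}

stance_frames <- function(cycle) cycle$foot_strike:(cycle$toe_off - 1L)
swing_frames <- function(cycle) cycle$toe_off:(cycle$next_foot_strike - 1L)

#' Extract the analysis cycle of a limb
#'
#' One complete gait cycle per limb is used per trial: the cycle whose
#' mid-cycle hoof position along the progression axis lies nearest the
#' centre of the capture volume (ties broken toward the earlier cycle).
#'
#' @param detection result of [detect_phases()]
#' @param trial the trial the events belong to
#' @param limb limb identifier
#' @param volume_centre y-coordinate of the capture-volume centre, metres
#' @return a [gait_cycle()]
#' @export
extract_cycle <- function(detection, trial, limb, volume_centre) {
  ev <- detection$events
  if (nrow(ev) == 0L)
    stop("no complete gait cycle for limb ", limb, "; trial unusable")
  hoof <- marker_positions(trial, hoof_marker(limb))
  mid <- floor((ev$foot_strike + ev$next_foot_strike) / 2)
  midy <- hoof[mid, "y"] / 1000
  best <- which.min(abs(midy - volume_centre))  # which.min takes the earlier tie
  gait_cycle(limb, ev$foot_strike[best], ev$toe_off[best],
             ev$next_foot_strike[best])
}
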