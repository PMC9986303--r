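#' Sagittal-plane joint definitions
#'
#' Each joint angle is defined between two vectors in the sagittal (y, z)
#' plane, each vector running proximal-to-distal between two markers of
#' the limb chain:
#'
#' * fetlock (fore): METAR->PPHAL vs PPHAL->PHAL
#' * carpus: LEPIRAD->ULNA vs METAR->PPHAL
#' * elbow: GTUB->LEPIRAD vs LEPIRAD->ULNA
#' * fetlock (hind): FTAR->PPHAL vs PPHAL->PHAL
#' * tarsus: TIB->LMAL vs FTAR->PPHAL
#' * stifle: GTROC->LEPI vs LTIB->LMAL
#'
#' The angle is 0 when the distal vector is the straight-line continuation
#' of the proximal vector (full extension) and negative in flexion.
#'
#' @param limb_type `"fore"` or `"hind"`
#' @return named list of joint definitions, each with `joint`, `proximal`
#'   and `distal` marker label pairs (unsuffixed)
#' @export
joint_definitions <- function(limb_type = c("fore", "hind")) {
  limb_type <- match.arg(limb_type)
  if (limb_type == "fore") {
    list(
      fetlock = list(joint = "fetlock", proximal = c("METAR", "PPHAL"),
                     distal = c("PPHAL", "PHAL")),
      carpus  = list(joint = "carpus", proximal = c("LEPIRAD", "ULNA"),
                     distal = c("METAR", "PPHAL")),
      elbow   = list(joint = "elbow", proximal = c("GTUB", "LEPIRAD"),
                     distal = c("LEPIRAD", "ULNA")))
  } else {
    list(
      fetlock = list(joint = "fetlock", proximal = c("FTAR", "PPHAL"),
                     distal = c("PPHAL", "PHAL")),
      tarsus  = list(joint = "tarsus", proximal = c("TIB", "LMAL"),
                     distal = c("FTAR", "PPHAL")),
      stifle  = list(joint = "stifle", proximal = c("GTROC", "LEPI"),
                     distal = c("LTIB", "LMAL")))
  }
}

limb_joints <- function(limb) {
  joint_definitions(if (startsWith(limb, "FL")) "fore" else "hind")
}

#' Per-frame sagittal joint angle
#'
#' Both segment vectors are projected to the (y, z) plane; the reported
#' angle is the signed angle from the proximal to the distal vector,
#' 0 degrees at full extension (collinear continuation) and negative in
#' flexion.  Frames where either projected vector is shorter than 1 mm are
#' flagged: the angle is set missing there and excluded from summaries.
#'
#' @param trial an `ovigait_trial` (preprocessed)
#' @param jdef one joint definition from [joint_definitions()]
#' @param limb limb identifier (`FL_L`, ...); marker labels in `jdef` are
#'   resolved against this limb's suffix
#' @return numeric vector of angles in degrees (NA at flagged frames)
#' @export
joint_angle_series <- function(trial, jdef, limb) {
  limb <- match.arg(limb, LIMBS)
  tagged <- function(lab) paste0(lab, "_", limb)
  p1 <- marker_positions(trial, tagged(jdef$proximal[1L]))
  p2 <- marker_positions(trial, tagged(jdef$proximal[2L]))
  d1 <- marker_positions(trial, tagged(jdef$distal[1L]))
  d2 <- marker_positions(trial, tagged(jdef$distal[2L]))
  p <- (p2 - p1)[, c("y", "z"), drop = FALSE]
  q <- (d2 - d1)[, c("y", "z"), drop = FALSE]
  lp <- sqrt(rowSums(p^2)); lq <- sqrt(rowSums(q^2))
  ang <- atan2(p[, 1L] * q[, 2L] - p[, 2L] * q[, 1L],
               p[, 1L] * q[, 1L] + p[, 2L] * q[, 2L]) * 180 / pi
  ang[lp < 1 | lq < 1] <- NA_real_       # projected length < 1 mm
  ang
}

#' Global (whole-trial) gait parameters
#'
#' Mean forward velocity of T1 (progression component of its derivative)
#' and the mean vertical offsets HEAD-T1, T1-T13, T13-L7 plus the lateral
#' HEAD-T1 offset (positive towards the animal's right), all averaged
#' over the entire trial.  Heights are reported in cm, velocity in m/s.
#'
#' @param trial an `ovigait_trial` containing HEAD, T1, T13 and L7
#' @return list of class `global_parameters`
#' @export
global_parameters <- function(trial) {
  rep_ <- validate_marker_set(trial, "global")
  if (!rep_$pass)
    stop("missing axial markers: ", paste(rep_$missing, collapse = ", "))
  t1 <- trial$markers[["T1"]]
  v <- differentiate(t1, trial$sample_rate)
  head <- marker_positions(trial, "HEAD")
  t13 <- marker_positions(trial, "T13")
  l7 <- marker_positions(trial, "L7")
  p1 <- t1$positions
  structure(list(
    mean_forward_velocity = mean(v[, "y"]),
    head_to_T1_vertical = mean(head[, "z"] - p1[, "z"]) / 10,
    head_to_T1_lateral = mean(head[, "x"] - p1[, "x"]) / 10,
    T1_to_T13_vertical = mean(p1[, "z"] - t13[, "z"]) / 10,
    T13_to_L7_vertical = mean(t13[, "z"] - l7[, "z"]) / 10),
    class = "global_parameters")
}

phase_minmax <- function(ang, frames) {
  a <- ang[frames]
  a <- a[!is.na(a)]
  if (!length(a)) return(c(min = NA_real_, max = NA_real_, range = NA_real_))
  c(min = min(a), max = max(a), range = max(a) - min(a))
}

#' Limb-specific parameters of one gait cycle
#'
#' Spatiotemporal and joint-angle outcome measures computed over a single
#' extracted cycle: phase durations and their ratios, stride length
#' (hoof progression displacement strike to strike), hoof height range and
#' lateral deviation in swing, mean absolute forward/vertical hoof swing
#' velocities, mean planar distance between the left and right hooves of
#' the limb pair while both are in stance, and min/max/range of each joint
#' angle within stance and within swing.  Lengths in cm, durations in s,
#' velocities in m/s, angles in degrees.
#'
#' @param trial an `ovigait_trial` (preprocessed)
#' @param cycle a [gait_cycle()]
#' @param contralateral_phases optional [detect_phases()] result for the
#'   contralateral limb of the pair (computed from the trial if omitted);
#'   used only for the inter-limb stance distance
#' @param spec [event_spec()] used if contralateral phases are computed here
#' @return list of class `limb_parameters`
#' @export
limb_parameters <- function(trial, cycle, contralateral_phases = NULL,
                            spec = event_spec()) {
  fs <- trial$sample_rate
  limb <- cycle$limb
  hoof <- marker_positions(trial, hoof_marker(limb))
  if (cycle$next_foot_strike > nrow(hoof))
    stop("cycle extends beyond the trial")
  st <- stance_frames(cycle); sw <- swing_frames(cycle)

  stance_duration <- length(st) / fs
  swing_duration <- length(sw) / fs
  stride_duration <- stance_duration + swing_duration

  v <- differentiate(trial$markers[[hoof_marker(limb)]], fs)
  out <- list(
    limb = limb,
    stance_duration = stance_duration,
    swing_duration = swing_duration,
    stride_duration = stride_duration,
    stance_to_stride = stance_duration / stride_duration,
    swing_to_stride = swing_duration / stride_duration,
    stance_to_swing = stance_duration / swing_duration,
    stride_length = unname(hoof[cycle$next_foot_strike, "y"] -
                           hoof[cycle$foot_strike, "y"]) / 10,
    hoof_height_range_swing = (max(hoof[sw, "z"]) - min(hoof[sw, "z"])) / 10,
    hoof_lateral_deviation = (max(hoof[sw, "x"]) - min(hoof[sw, "x"])) / 10,
    hoof_forward_swing_velocity = mean(abs(v[sw, "y"])),
    hoof_vertical_swing_velocity = mean(abs(v[sw, "z"])))

  # inter-limb stance distance needs the contralateral hoof of the pair
  other <- contralateral_limb(limb)
  out$inter_limb_stance_distance <- NA_real_
  if (hoof_marker(other) %in% names(trial$markers)) {
    if (is.null(contralateral_phases)) {
      vo <- differentiate(trial$markers[[hoof_marker(other)]], fs)
      contralateral_phases <- detect_phases(vo, spec, fs)
    }
    ost <- contralateral_phases$phases
    o_stance <- unlist(mapply(seq, ost$start[ost$phase == "stance"],
                              ost$end[ost$phase == "stance"],
                              SIMPLIFY = FALSE))
    both <- intersect(st, o_stance)
    if (length(both)) {
      oh <- marker_positions(trial, hoof_marker(other))
      d <- sqrt((hoof[both, "x"] - oh[both, "x"])^2 +
                (hoof[both, "y"] - oh[both, "y"])^2)
      out$inter_limb_stance_distance <- mean(d) / 10
    }
  }

  for (jd in limb_joints(limb)) {
    ang <- joint_angle_series(trial, jd, limb)
    out[[paste0(jd$joint, "_stance")]] <- phase_minmax(ang, st)
    out[[paste0(jd$joint, "_swing")]] <- phase_minmax(ang, sw)
  }
  class(out) <- "limb_parameters"
  out
}

contralateral_limb <- function(limb) {
  paste0(substr(limb, 1, 3), if (endsWith(limb, "L")) "R" else "L")
}

#' Flatten trial parameters into study-table rows
#'
#' Computes global parameters and, for each limb with a usable cycle, the
#' limb parameters, and returns them as long-format study-table rows in
#' reporting units.
#'
#' @param trial a preprocessed `ovigait_trial`
#' @param cycles named list of [gait_cycle()] per limb (missing limbs are
#'   skipped)
#' @return an [study_table()]
#' @export
trial_parameters <- function(trial, cycles) {
  rows <- list()
  gp <- global_parameters(trial)
  gunits <- c(mean_forward_velocity = "m/s", head_to_T1_vertical = "cm",
              head_to_T1_lateral = "cm", T1_to_T13_vertical = "cm",
              T13_to_L7_vertical = "cm")
  for (nm in names(gunits))
    rows[[length(rows) + 1L]] <- data.frame(
      animal = trial$animal_id, session = trial$session, limb = "global",
      measure = nm, value = gp[[nm]], units = gunits[[nm]])

  lunits <- c(stance_duration = "s", swing_duration = "s",
              stride_duration = "s", stance_to_stride = "ratio",
              swing_to_stride = "ratio", stance_to_swing = "ratio",
              stride_length = "cm", hoof_height_range_swing = "cm",
              hoof_lateral_deviation = "cm",
              hoof_forward_swing_velocity = "m/s",
              hoof_vertical_swing_velocity = "m/s",
              inter_limb_stance_distance = "cm")
  for (limb in names(cycles)) {
    lp <- limb_parameters(trial, cycles[[limb]])
    for (nm in names(lunits))
      rows[[length(rows) + 1L]] <- data.frame(
        animal = trial$animal_id, session = trial$session, limb = limb,
        measure = nm, value = lp[[nm]], units = lunits[[nm]])
    for (jd in limb_joints(limb))
      for (ph in c("stance", "swing")) {
        mm <- lp[[paste0(jd$joint, "_", ph)]]
        for (stat in c("min", "max", "range"))
          rows[[length(rows) + 1L]] <- data.frame(
            animal = trial$animal_id, session = trial$session, limb = limb,
            measure = paste(jd$joint, stat, ph, sep = "_"),
            value = unname(mm[stat]), units = "deg")
      }
  }
  df <- do.call(rbind, rows)
  study_table(df$animal, df$session, df$limb, df$measure, df$value, df$units)
}

#' Average repeated trials into session-level values
#'
#' The trial-level value of each (animal, session, limb, measure) cell is
#' the mean over the reconstructed trials of that session.
#'
#' @param tables list of per-trial study tables
#' @return an [study_table()] with one row per cell
#' @export
aggregate_trials <- function(tables) {
  df <- do.call(rbind, lapply(tables, as.data.frame))
  agg <- stats::aggregate(value ~ animal + session + limb + measure + units,
                          data = df, FUN = mean, na.rm = TRUE, na.action = NULL)
  study_table(agg$animal, agg$session, agg$limb, agg$measure, agg$value,
              agg$units)
}
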