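#' Gait design for the synthetic walking generator
#'
#' Describes the deterministic "skeleton" of a healthy overland walking
#' trial of a four-limbed walker: cycle timing, stride geometry, the
#' lateral-sequence limb phasing typical of walking sheep, per-joint angle
#' waveforms (phase-wise minima and maxima) and trunk/head posture.  The
#' defaults are the healthy-sheep condition: forward velocity 1.28 m/s,
#' cycle duration 0.77 s with stance 0.41 s (duty factor 0.532), which
#' implies the observed ~98 cm stride, a 5 cm hoof lift, the head held
#' about 3 cm to the animal's right, and a stifle excursion of -69..-45
#' degrees in stance and -81..-35 degrees in swing.
#'
#' @param forward_velocity trunk progression velocity, m/s
#' @param cycle_duration stride (cycle) duration, s
#' @param duty_factor stance fraction of the cycle (0-1)
#' @param stride_length stride length, m; `NULL` derives
#'   `forward_velocity * cycle_duration`
#' @param hoof_lift_height peak swing hoof lift, m
#' @param phase_offsets named per-limb cycle-fraction offsets
#'   (lateral-sequence walk default: HL_L 0, FL_L 0.25, HL_R 0.5, FL_R 0.75)
#' @param joint_waveforms per-joint phase extremes, see
#'   [default_joint_waveforms()]
#' @param trunk_heights named vector, cm: `head_to_T1`, `T1_to_T13`,
#'   `T13_to_L7` vertical drops along the axial chain
#' @param head_lateral_offset mean lateral head offset, cm (positive right)
#' @return object of class `gait_design`
#' @export
gait_design <- function(forward_velocity = 1.28,
                        cycle_duration = 0.77,
                        duty_factor = 0.41 / 0.77,
                        stride_length = NULL,
                        hoof_lift_height = 0.05,
                        phase_offsets = c(HL_L = 0, FL_L = 0.25,
                                          HL_R = 0.5, FL_R = 0.75),
                        joint_waveforms = default_joint_waveforms(),
                        trunk_heights = c(head_to_T1 = 12, T1_to_T13 = 6,
                                          T13_to_L7 = 4),
                        head_lateral_offset = 3) {
  if (cycle_duration <= 0) stop("cycle_duration must be positive")
  if (duty_factor <= 0 || duty_factor >= 1)
    stop("duty_factor must lie strictly between 0 and 1")
  if (forward_velocity < 0) stop("forward_velocity cannot be negative")
  auto <- forward_velocity * cycle_duration
  if (is.null(stride_length)) stride_length <- auto
  else if (abs(stride_length - auto) > 1e-9)
    stop("stride_length is inconsistent with velocity * cycle_duration")
  d <- structure(list(
    forward_velocity = forward_velocity,
    cycle_duration = cycle_duration,
    duty_factor = duty_factor,
    stride_length = stride_length,
    hoof_lift_height = hoof_lift_height,
    phase_offsets = phase_offsets[LIMBS],
    joint_waveforms = joint_waveforms,
    trunk_heights = trunk_heights,
    head_lateral_offset = head_lateral_offset,
    per_limb_duty = stats::setNames(rep(duty_factor, 4L), LIMBS),
    limb_waveform_overrides = list()),
    class = "gait_design")
  d
}

#' Per-joint angle waveform extremes
#'
#' Each joint's waveform is parameterised by its minimum and maximum in
#' stance and in swing (degrees; 0 = full extension, flexion negative).
#' The stifle values are the healthy left-hindlimb means; the remaining
#' joints use representative ovine walking excursions.
#'
#' @return nested list `fore`/`hind` of per-joint
#'   `c(stance_min, stance_max, swing_min, swing_max)`
#' @export
default_joint_waveforms <- function() {
  wf <- function(st_min, st_max, sw_min, sw_max)
    c(stance_min = st_min, stance_max = st_max,
      swing_min = sw_min, swing_max = sw_max)
  list(
    fore = list(fetlock = wf(-15, 5, -25, 10),
                carpus  = wf(-12, 0, -45, -4),
                elbow   = wf(-60, -35, -62, -33)),
    hind = list(fetlock = wf(-15, 5, -25, 10),
                tarsus  = wf(-35, -15, -50, -12),
                stifle  = wf(-69, -45, -81, -35)))
}

#' Post-stroke deficit to inject into a gait design
#'
#' All deltas default to zero (no deficit).  [stroke_effect_preset()]
#' carries the observed 3-day post-stroke point estimates: velocity
#' -0.28 m/s, head-to-T1 height -8.21 cm, stance prolonged by
#' 0.13/0.14/0.13/0.12 s and swing by 0.02/0.02/0.03/0.03 s
#' (FL_L/FL_R/HL_L/HL_R), and fetlock swing range reduced by
#' 3.9/3.31/8.34/8.19 degrees.
#'
#' @param delta_velocity change in forward velocity, m/s
#' @param delta_head_vertical change in head-to-T1 height, cm
#' @param delta_stance,delta_swing named per-limb phase-duration changes, s
#' @param delta_fetlock_swing_range named per-limb change in fetlock swing
#'   range, degrees (negative = reduced excursion, applied about the
#'   waveform midpoint)
#' @param asymmetry named multipliers `c(L = , R = )` applied to the
#'   per-limb deltas of each body side
#' @return object of class `stroke_effect`
#' @export
stroke_effect <- function(delta_velocity = 0,
                          delta_head_vertical = 0,
                          delta_stance = stats::setNames(rep(0, 4), LIMBS),
                          delta_swing = stats::setNames(rep(0, 4), LIMBS),
                          delta_fetlock_swing_range = stats::setNames(rep(0, 4), LIMBS),
                          asymmetry = c(L = 1, R = 1)) {
  fill <- function(x) { out <- stats::setNames(rep(0, 4), LIMBS)
                        out[names(x)] <- x; out }
  structure(list(delta_velocity = delta_velocity,
                 delta_head_vertical = delta_head_vertical,
                 delta_stance = fill(delta_stance),
                 delta_swing = fill(delta_swing),
                 delta_fetlock_swing_range = fill(delta_fetlock_swing_range),
                 asymmetry = asymmetry),
            class = "stroke_effect")
}

#' @rdname stroke_effect
#' @export
stroke_effect_preset <- function() {
  stroke_effect(
    delta_velocity = -0.28,
    delta_head_vertical = -8.21,
    delta_stance = c(FL_L = 0.13, FL_R = 0.14, HL_L = 0.13, HL_R = 0.12),
    delta_swing = c(FL_L = 0.02, FL_R = 0.02, HL_L = 0.03, HL_R = 0.03),
    delta_fetlock_swing_range = c(FL_L = -3.9, FL_R = -3.31,
                                  HL_L = -8.34, HL_R = -8.19))
}

is_zero_effect <- function(effect) {
  all(effect$delta_velocity == 0, effect$delta_head_vertical == 0,
      effect$delta_stance == 0, effect$delta_swing == 0,
      effect$delta_fetlock_swing_range == 0)
}

#' Apply a stroke effect to a gait design
#'
#' Velocity and head height shift additively.  Per-limb stance/swing
#' deltas (scaled by the side asymmetry multipliers) extend the phase
#' durations; since steady gait needs one shared cycle duration, the new
#' cycle duration is the mean of the per-limb totals and per-limb
#' differences are absorbed into per-limb duty factors.  Fetlock swing
#' range deltas rescale the swing waveform about its midpoint.
#' A zero effect returns the design unchanged.
#'
#' @param design a [gait_design()]
#' @param effect a [stroke_effect()]
#' @return modified `gait_design`
#' @export
apply_stroke_effect <- function(design, effect) {
  if (is_zero_effect(effect)) return(design)
  side <- ifelse(endsWith(LIMBS, "L"), effect$asymmetry[["L"]],
                 effect$asymmetry[["R"]])
  dst <- effect$delta_stance[LIMBS] * side
  dsw <- effect$delta_swing[LIMBS] * side
  T0 <- design$cycle_duration
  stance0 <- design$per_limb_duty[LIMBS] * T0
  swing0 <- T0 - stance0
  totals <- stance0 + dst + swing0 + dsw
  T1 <- mean(totals)
  duty <- (stance0 + dst) / T1
  if (any(duty <= 0 | duty >= 1))
    stop("stroke effect drives a duty factor outside (0, 1)")
  design$cycle_duration <- T1
  design$duty_factor <- mean(duty)
  design$per_limb_duty <- stats::setNames(duty, LIMBS)
  design$forward_velocity <- design$forward_velocity + effect$delta_velocity
  if (design$forward_velocity < 0) stop("stroke effect drives velocity negative")
  design$stride_length <- design$forward_velocity * design$cycle_duration
  design$trunk_heights[["head_to_T1"]] <-
    design$trunk_heights[["head_to_T1"]] + effect$delta_head_vertical
  dfr <- effect$delta_fetlock_swing_range[LIMBS] * side
  for (limb in LIMBS) {
    if (dfr[[limb]] == 0) next
    type <- if (startsWith(limb, "FL")) "fore" else "hind"
    wf <- design$joint_waveforms[[type]]$fetlock
    mid <- (wf[["swing_min"]] + wf[["swing_max"]]) / 2
    rng <- max(1, wf[["swing_max"]] - wf[["swing_min"]] + dfr[[limb]])
    wf[["swing_min"]] <- mid - rng / 2
    wf[["swing_max"]] <- mid + rng / 2
    ov <- design$limb_waveform_overrides[[limb]]
    if (is.null(ov)) ov <- list()
    ov$fetlock <- wf
    design$limb_waveform_overrides[[limb]] <- ov
  }
  design
}

#' Measurement noise model for synthetic trials
#'
#' White marker noise, a low-frequency skin-motion artifact (random-phase
#' sinusoid per marker) and random occlusion gaps with geometric lengths.
#' All components are reproducible from the seed; `noise_model(seed = s)`
#' with all amplitudes zero is a noiseless (but still seeded) model.
#'
#' @param white_sd white noise SD per axis, mm
#' @param skin_amplitude skin artifact amplitude, mm
#' @param skin_freq skin artifact frequency, Hz
#' @param occlusion_rate per-marker per-frame gap start probability
#' @param mean_gap mean occlusion gap length, frames
#' @param seed RNG seed
#' @return object of class `noise_model`
#' @export
noise_model <- function(white_sd = 0.5, skin_amplitude = 2, skin_freq = 3,
                        occlusion_rate = 2e-4, mean_gap = 4, seed = 1L) {
  stopifnot(white_sd >= 0, skin_amplitude >= 0, skin_freq >= 0,
            occlusion_rate >= 0, mean_gap >= 1)
  structure(list(white_sd = white_sd, skin_amplitude = skin_amplitude,
                 skin_freq = skin_freq, occlusion_rate = occlusion_rate,
                 mean_gap = mean_gap, seed = as.integer(seed)),
            class = "noise_model")
}

# raised-cosine bump of unit height centred at c with support width w
.bump <- function(x, centre, width) {
  out <- numeric(length(x))
  inside <- abs(x - centre) < width / 2
  out[inside] <- cos(pi * (x[inside] - centre) / width)^2
  out
}

# phase-wise waveform: baseline b at phase boundaries, a maximum bump
# centred at 0.30 and a minimum bump at 0.70 of each phase (width 0.6 of
# the phase, so each centre lies outside the other bump's support).  The
# designed extremes are attained exactly at the bump centres with no
# overshoot, and the wide supports keep the spectral content of the
# waveform low enough that zero-lag 10 Hz filtering leaves the extremes
# essentially untouched.
joint_angle_waveform <- function(wf, stance_mask, stance_frac, swing_frac) {
  m_star <- max(wf[["stance_min"]], wf[["swing_min"]])
  M_star <- min(wf[["stance_max"]], wf[["swing_max"]])
  if (m_star > M_star)
    stop("joint waveform extremes admit no common boundary value")
  b <- (m_star + M_star) / 2
  ang <- rep(b, length(stance_mask))
  st <- stance_mask
  ang[st] <- b +
    (wf[["stance_max"]] - b) * .bump(stance_frac[st], 0.28, 0.56) +
    (wf[["stance_min"]] - b) * .bump(stance_frac[st], 0.72, 0.56)
  ang[!st] <- b +
    (wf[["swing_max"]] - b) * .bump(swing_frac[!st], 0.28, 0.56) +
    (wf[["swing_min"]] - b) * .bump(swing_frac[!st], 0.72, 0.56)
  ang
}

# Normalised swing advance profile p(s), s in [0, 1].  The velocity shape
# is a sin^4 hump carrying the stride plus a "approach taper" at lift-off
# and touch-down: a square-root ramp to a low plateau (APPROACH_SPEED m/s
# over APPROACH_FRAC of swing per edge).  The taper makes the low-pass
# filtered hoof speed cross the stance threshold at the true phase
# boundary (phase timing recovered at frame resolution downstream), and
# its steep initial rise keeps the unfiltered crossing frame essentially
# independent of the threshold value.
APPROACH_SPEED <- c(fore = 0.27, hind = 0.30)   # m/s
APPROACH_FRAC <- 0.17    # fraction of swing duration per edge

swing_progress_fun <- function(stride_m, swing_s, limb_type = "fore") {
  ss <- seq(0, 1, length.out = 4001)
  edge <- pmin(1, sqrt(ss / APPROACH_FRAC), sqrt((1 - ss) / APPROACH_FRAC))
  a <- APPROACH_SPEED[[limb_type]] * swing_s / stride_m
  a <- min(a, 0.9 / mean(edge))        # degenerate short/slow strides
  b <- (1 - a * mean(edge)) / mean(sin(pi * ss)^4)
  g <- a * edge + b * sin(pi * ss)^4
  cdf <- cumsum(g)
  cdf <- cdf / cdf[length(cdf)]
  function(s) stats::approx(ss, cdf, xout = s, yleft = 0, yright = 1)$y
}

# rotate sagittal-plane direction columns (y, z) by deg degrees
.rot_dir <- function(u, deg) {
  th <- deg * pi / 180
  cbind(y = u[, 1L] * cos(th) - u[, 2L] * sin(th),
        z = u[, 1L] * sin(th) + u[, 2L] * cos(th))
}

# segment lengths of the idealised skeleton, mm
SEGMENT_MM <- list(
  fore = c(PHAL_DPHAL = 30, PPHAL_PHAL = 35, METAR_PPHAL = 80,
           ULNA_METAR = 180, LEPIRAD_ULNA = 60, GTUB_LEPIRAD = 250),
  hind = c(PHAL_DPHAL = 30, PPHAL_PHAL = 35, FTAR_PPHAL = 90,
           LMAL_FTAR = 60, TIB_LMAL = 120, LTIB_TIB = 80,
           LEPI_LTIB = 60, GTROC_LEPI = 260))

#' Generate one synthetic walking trial
#'
#' Produces a 200 Hz trial containing all 42 markers.  Hoof (DPHAL)
#' markers are exactly stationary in stance and follow a smooth
#' lift-and-advance path in swing; trunk markers advance at the design
#' velocity with a small vertical oscillation; each limb's marker chain is
#' placed by planar forward kinematics from the hoof upward so that the
#' sagittal joint angles computed downstream reproduce the designed
#' waveforms.  A zero-velocity design yields a static standing posture.
#'
#' @param design a [gait_design()]
#' @param effect optional [stroke_effect()] applied to the design
#' @param noise optional [noise_model()]; `NULL` = noiseless
#' @param n_cycles number of complete cycles to cover per limb (>= 1)
#' @param sample_rate sampling rate, Hz
#' @param animal_id,session trial metadata
#' @return an `ovigait_trial`; attribute `"truth"` records the applied
#'   design and the designed per-limb stance/swing/stride durations,
#'   stride length and joint phase extremes
#' @export
generate_trial <- function(design, effect = NULL, noise = NULL, n_cycles = 5,
                           sample_rate = 200, animal_id = "S1", session = "B1") {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (!is.null(effect)) design <- apply_stroke_effect(design, effect)
  T <- design$cycle_duration
  fs <- sample_rate
  nf <- round((n_cycles + 1) * T * fs) + 1L
  t <- (0:(nf - 1L)) / fs
  v_mm <- design$forward_velocity * 1000
  S_mm <- design$stride_length * 1000
  static <- design$forward_velocity == 0

  markers <- list()

  # axial chain
  osc <- if (static) 0 else 5 * sin(2 * pi * (2 / T) * t)
  th <- design$trunk_heights * 10           # cm -> mm
  t1 <- cbind(x = rep(0, nf), y = v_mm * t, z = 850 + osc)
  markers$HEAD <- cbind(x = t1[, "x"] + design$head_lateral_offset * 10,
                        y = t1[, "y"] + 150, z = t1[, "z"] + th[["head_to_T1"]])
  markers$T1 <- t1
  markers$T13 <- cbind(x = t1[, "x"], y = t1[, "y"] - 300,
                       z = t1[, "z"] - th[["T1_to_T13"]])
  markers$L7 <- cbind(x = t1[, "x"], y = t1[, "y"] - 550,
                      z = t1[, "z"] - th[["T1_to_T13"]] - th[["T13_to_L7"]])

  anchors_y <- c(FL_L = -100, FL_R = -100, HL_L = -650, HL_R = -650)
  lat_x <- c(FL_L = -110, FL_R = 110, HL_L = -100, HL_R = 100)
  z_hoof <- 30
  lift_mm <- if (static) 0 else design$hoof_lift_height * 1000
  progress <- if (static) NULL else
    lapply(stats::setNames(LIMBS, LIMBS), function(l)
      swing_progress_fun(design$stride_length,
                         (1 - design$per_limb_duty[[l]]) * T,
                         if (startsWith(l, "FL")) "fore" else "hind"))

  truth_limb <- list()
  for (limb in LIMBS) {
    d_l <- design$per_limb_duty[[limb]]
    phi0 <- design$phase_offsets[[limb]]
    u <- t / T + phi0
    k <- floor(u)
    phi <- u - k
    in_stance <- phi < d_l
    s <- pmax(0, (phi - d_l) / (1 - d_l))     # swing progress
    sigma <- pmin(1, phi / d_l)               # stance progress
    # smooth advance with approach tapers; parabolic lift vs progress
    p <- if (static) s * 0 else progress[[limb]](s)
    y0 <- anchors_y[[limb]] + (d_l / 2 - phi0) * S_mm
    hoof_y <- y0 + k * S_mm + ifelse(in_stance, 0, S_mm * p)
    hoof_z <- z_hoof + ifelse(in_stance, 0, lift_mm * 4 * p * (1 - p))
    hoof <- cbind(x = rep(lat_x[[limb]], nf), y = hoof_y, z = hoof_z)

    type <- if (startsWith(limb, "FL")) "fore" else "hind"
    wfs <- design$joint_waveforms[[type]]
    ov <- design$limb_waveform_overrides[[limb]]
    if (!is.null(ov)) wfs[names(ov)] <- ov
    seg <- SEGMENT_MM[[type]]

    ang <- lapply(wfs, function(wf) {
      if (static) rep((max(wf[["stance_min"]], wf[["swing_min"]]) +
                       min(wf[["stance_max"]], wf[["swing_max"]])) / 2, nf)
      else joint_angle_waveform(wf, in_stance, sigma, s)
    })

    beta <- 20                                 # pastern inclination, degrees
    u0 <- cbind(y = rep(sin(beta * pi / 180), nf),
                z = rep(-cos(beta * pi / 180), nf))
    place <- function(from, len, dir)
      cbind(x = from[, "x"], y = from[, "y"] - len * dir[, "y"],
            z = from[, "z"] - len * dir[, "z"])
    lm <- list(DPHAL = hoof)
    lm$PHAL <- place(hoof, seg[["PHAL_DPHAL"]], u0)
    lm$PPHAL <- place(lm$PHAL, seg[["PPHAL_PHAL"]], u0)
    u2 <- .rot_dir(u0, -ang$fetlock)
    if (type == "fore") {
      lm$METAR <- place(lm$PPHAL, seg[["METAR_PPHAL"]], u2)
      lm$ULNA <- place(lm$METAR, seg[["ULNA_METAR"]], u2)
      u3 <- .rot_dir(u2, -ang$carpus)
      lm$LEPIRAD <- place(lm$ULNA, seg[["LEPIRAD_ULNA"]], u3)
      u4 <- .rot_dir(u3, -ang$elbow)
      lm$GTUB <- place(lm$LEPIRAD, seg[["GTUB_LEPIRAD"]], u4)
    } else {
      lm$FTAR <- place(lm$PPHAL, seg[["FTAR_PPHAL"]], u2)
      lm$LMAL <- place(lm$FTAR, seg[["LMAL_FTAR"]], u2)
      u3 <- .rot_dir(u2, -ang$tarsus)
      lm$TIB <- place(lm$LMAL, seg[["TIB_LMAL"]], u3)
      lm$LTIB <- place(lm$TIB, seg[["LTIB_TIB"]], u3)
      lm$LEPI <- place(lm$LTIB, seg[["LEPI_LTIB"]], u3)
      u4 <- .rot_dir(u3, -ang$stifle)
      lm$GTROC <- place(lm$LEPI, seg[["GTROC_LEPI"]], u4)
      lm$CALC <- cbind(x = lm$LMAL[, "x"], y = lm$LMAL[, "y"] - 40,
                       z = lm$LMAL[, "z"] + 50)
      side_sign <- if (endsWith(limb, "L")) -1 else 1
      lm$ILIUM <- cbind(x = markers$L7[, "x"] + side_sign * 80,
                        y = markers$L7[, "y"] + 80, z = markers$L7[, "z"] - 60)
      lm$ISCHTUB <- cbind(x = markers$L7[, "x"] + side_sign * 70,
                          y = markers$L7[, "y"] - 120,
                          z = markers$L7[, "z"] - 100)
    }
    for (nm in names(lm)) markers[[paste0(nm, "_", limb)]] <- lm[[nm]]

    truth_limb[[limb]] <- list(
      stance_duration = d_l * T, swing_duration = (1 - d_l) * T,
      stride_duration = T, stride_length_cm = S_mm / 10,
      joints = lapply(wfs, function(wf)
        list(stance = c(min = wf[["stance_min"]], max = wf[["stance_max"]]),
             swing = c(min = wf[["swing_min"]], max = wf[["swing_max"]]))))
  }

  trajs <- lapply(names(markers), function(nm)
    marker_trajectory(nm, markers[[nm]], occluded = rep(FALSE, nf)))
  names(trajs) <- names(markers)

  if (!is.null(noise)) trajs <- add_noise(trajs, noise, fs)

  tr <- trial(trajs, animal_id = animal_id, session = session,
              sample_rate = fs)
  attr(tr, "truth") <- list(design = design, limbs = truth_limb)
  tr
}

add_noise <- function(trajs, noise, fs) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(noise$seed)
  nf <- nrow(trajs[[1L]]$positions)
  t <- (0:(nf - 1L)) / fs
  lapply(trajs, function(m) {
    pos <- m$positions
    if (noise$white_sd > 0)
      pos <- pos + matrix(stats::rnorm(3L * nf, 0, noise$white_sd), nf, 3L)
    if (noise$skin_amplitude > 0) {
      ph <- stats::runif(3L, 0, 2 * pi)
      for (j in 1:3)
        pos[, j] <- pos[, j] +
          noise$skin_amplitude * sin(2 * pi * noise$skin_freq * t + ph[j])
    }
    occ <- rep(FALSE, nf)
    if (noise$occlusion_rate > 0) {
      starts <- which(stats::rbinom(nf, 1L, noise$occlusion_rate) == 1L)
      for (s in starts) {
        len <- 1L + stats::rgeom(1L, 1 / noise$mean_gap)
        occ[s:min(nf, s + len - 1L)] <- TRUE
      }
      pos[occ, ] <- NA_real_
    }
    marker_trajectory(m$label, pos, occluded = occ)
  })
}

#' Between-animal dispersion for cohort simulation
#'
#' SDs of the animal-level random effects drawn once per animal and shared
#' across its sessions.  The within/between decomposition of inter-trial
#' variability is not identified by the study report, so these defaults
#' are free parameters chosen to give realistic between-animal spread.
#'
#' @param velocity SD of the animal velocity offset, m/s
#' @param cycle SD of the animal cycle-duration offset, s
#' @param head_height SD of the animal head-height offset, cm
#' @return named list
#' @export
cohort_dispersion <- function(velocity = 0.15, cycle = 0.03, head_height = 2) {
  list(velocity = velocity, cycle = cycle, head_height = head_height)
}

#' Generate a multi-session cohort of synthetic trials
#'
#' Draws per-animal random effects once and shares them across the
#' animal's sessions; applies the stroke effect to post-stroke sessions
#' (labels starting with "D"); and returns the trials together with a
#' ground-truth study table of the designed parameters, simple synthetic
#' neurological score sheets and infarct volumes.
#'
#' @param n_animals number of animals
#' @param sessions session labels, e.g. `c("B1","B2","B3","D3")`; at least
#'   one baseline ("B") label is required
#' @param design baseline [gait_design()]
#' @param effect_post [stroke_effect()] applied to post sessions
#' @param between_sd [cohort_dispersion()] record (`NULL` = no dispersion)
#' @param noise [noise_model()] or `NULL`
#' @param n_trials trials per animal per session
#' @param n_cycles cycles per trial
#' @param seed RNG seed governing all random draws
#' @return list with elements `trials` (list), `truth` (study table of
#'   designed values), `neuroscores` (score-sheet data.frame) and
#'   `infarct_volumes` (named numeric, cm^3)
#' @export
generate_cohort <- function(n_animals, sessions = c("B1", "B2", "B3", "D3"),
                            design = gait_design(),
                            effect_post = stroke_effect_preset(),
                            between_sd = cohort_dispersion(),
                            noise = NULL, n_trials = 5, n_cycles = 5,
                            seed = 1L) {
  if (!any(startsWith(sessions, "B")))
    stop("sessions must include at least one baseline (B*) label")
  if (n_animals < 2 && !is.null(between_sd))
    stop("between-animal dispersion needs n_animals >= 2")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  trials <- list()
  truth_rows <- list()
  for (a in seq_len(n_animals)) {
    aid <- sprintf("A%02d", a)
    dv <- if (is.null(between_sd)) 0 else stats::rnorm(1, 0, between_sd$velocity)
    dc <- if (is.null(between_sd)) 0 else stats::rnorm(1, 0, between_sd$cycle)
    dh <- if (is.null(between_sd)) 0 else stats::rnorm(1, 0, between_sd$head_height)
    a_design <- design
    a_design$forward_velocity <- max(0.2, design$forward_velocity + dv)
    a_design$cycle_duration <- max(0.3, design$cycle_duration + dc)
    a_design$stride_length <- a_design$forward_velocity * a_design$cycle_duration
    a_design$trunk_heights[["head_to_T1"]] <-
      design$trunk_heights[["head_to_T1"]] + dh
    for (ses in sessions) {
      post <- startsWith(ses, "D")
      eff <- if (post) effect_post else NULL
      for (k in seq_len(n_trials)) {
        nz <- if (is.null(noise)) NULL else {
          n2 <- noise; n2$seed <- noise$seed + 1000L * a + 50L * match(ses, sessions) + k
          n2
        }
        tr <- generate_trial(a_design, effect = eff, noise = nz,
                             n_cycles = n_cycles, animal_id = aid,
                             session = ses)
        trials[[paste(aid, ses, k, sep = "_")]] <- tr
        tru <- attr(tr, "truth")
        for (limb in LIMBS)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            animal = aid, session = ses, limb = limb,
            measure = c("stance_duration", "swing_duration",
                        "stride_duration", "stride_length"),
            value = c(tru$limbs[[limb]]$stance_duration,
                      tru$limbs[[limb]]$swing_duration,
                      tru$limbs[[limb]]$stride_duration,
                      tru$limbs[[limb]]$stride_length_cm),
            units = c("s", "s", "s", "cm"), trial = k)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  truth <- stats::aggregate(value ~ animal + session + limb + measure + units,
                            truth, mean)
  ns <- simulate_neuroscore_sheets(n_animals, sessions, seed = seed + 7L)
  iv <- stats::setNames(round(stats::rlnorm(n_animals, log(2.7), 1.1), 2),
                        sprintf("A%02d", seq_len(n_animals)))
  list(trials = trials,
       truth = study_table(truth$animal, truth$session, truth$limb,
                           truth$measure, truth$value, truth$units),
       neuroscores = ns, infarct_volumes = iv)
}

#' Measure-level cohort simulator for the mixed-model statistics
#'
#' Simulates session-level values of a limb-pair measure directly at the
#' observation level: animal random intercepts, per-trial residual noise
#' averaged over the trials of each session, and an additive post-stroke
#' effect per side.  This is the fast ground-truth path used to exercise
#' the pre/post mixed model at cohort scale; the marker-level generator
#' produces the same quantities through the full pipeline.
#'
#' @param n_animals number of animals
#' @param n_baseline number of baseline sessions
#' @param n_trials trials per session (averaged into the session value)
#' @param base healthy mean of the measure
#' @param effect named `c(L = , R = )` post-stroke additive effect
#' @param between_sd SD of the animal random intercept
#' @param resid_sd per-trial residual SD
#' @param measure,units,limbs measure naming (default forelimb stance)
#' @param seed RNG seed
#' @return an [study_table()] with sessions `B1..Bk` and `D3`
#' @export
simulate_stance_cohort <- function(n_animals = 24, n_baseline = 3,
                                   n_trials = 5, base = 0.41,
                                   effect = c(L = 0.13, R = 0.14),
                                   between_sd = 0.03, resid_sd = 0.03,
                                   measure = "stance_duration", units = "s",
                                   limbs = c("FL_L", "FL_R"), seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sessions <- c(paste0("B", seq_len(n_baseline)), "D3")
  rows <- list()
  for (a in seq_len(n_animals)) {
    aid <- sprintf("A%02d", a)
    u <- stats::rnorm(1, 0, between_sd)
    for (ses in sessions) {
      post <- startsWith(ses, "D")
      for (limb in limbs) {
        side <- if (endsWith(limb, "L")) "L" else "R"
        mu <- base + u + if (post) effect[[side]] else 0
        val <- mean(mu + stats::rnorm(n_trials, 0, resid_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          animal = aid, session = ses, limb = limb, measure = measure,
          value = val, units = units)
      }
    }
  }
  df <- do.call(rbind, rows)
  study_table(df$animal, df$session, df$limb, df$measure, df$value, df$units)
}

#' Synthetic neurological score sheets
#'
#' Baseline sessions carry the occasional minor postural quarter-score;
#' post-stroke sessions inject a designed deficit (apathy, behavioural
#' signs and left-sided postural failure) totalling about 7 points above
#' baseline, mirroring the reported median post-stroke increase.
#'
#' @param n_animals number of animals
#' @param sessions session labels
#' @param post_deficit approximate designed increase of the total score
#' @param seed RNG seed
#' @return data.frame in score-sheet layout (see [read_score_sheet()])
#' @export
simulate_neuroscore_sheets <- function(n_animals, sessions,
                                       post_deficit = 7, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rows <- list()
  add <- function(aid, ses, criterion, component, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      animal = aid, session = ses, criterion = criterion,
      component = component, value = value)
  for (a in seq_len(n_animals)) {
    aid <- sprintf("A%02d", a)
    for (ses in sessions) {
      post <- startsWith(ses, "D")
      # designed post-stroke deficit: apathy 1 + dysmetria 1 + left
      # hemi-standing 3 + left hopping 1 + wheelbarrow 1 = 7 points, with
      # any non-default remainder placed on left lateral dragging
      rem <- min(2, max(0, round((post_deficit - 7) * 4) / 4))
      add(aid, ses, 1L, "base", if (post) 1 else 0)
      for (cr in 2:4) add(aid, ses, cr, "base", 0)
      add(aid, ses, 5L, "base", if (post) 1 else 0)
      add(aid, ses, 6L, "base", 0)
      # criterion 7: hemi-standing per side, with occasional baseline wobble
      b7l <- if (post) 3 else stats::rbinom(1, 1, 0.2)
      add(aid, ses, 7L, "base_left", b7l)
      add(aid, ses, 7L, "base_right", 0)
      add(aid, ses, 7L, "knuckling_left", 0)
      add(aid, ses, 7L, "knuckling_right", 0)
      add(aid, ses, 8L, "base_left", if (post) 1 else 0)
      add(aid, ses, 8L, "base_right", 0)
      add(aid, ses, 8L, "knuckling_left", 0)
      add(aid, ses, 8L, "knuckling_right", 0)
      for (sd_ in c("left", "right")) for (lb in c("fore", "hind")) {
        add(aid, ses, 9L, paste("base", sd_, lb, sep = "_"),
            if (post && sd_ == "left" && lb == "fore") floor(rem) else 0)
        add(aid, ses, 9L, paste("partial", sd_, lb, sep = "_"),
            if (post && sd_ == "left" && lb == "fore")
              min(0.25, rem - floor(rem)) else 0)
        add(aid, ses, 9L, paste("drag", sd_, lb, sep = "_"), 0)
      }
      add(aid, ses, 10L, "base", if (post) 1 else 0)
    }
  }
  do.call(rbind, rows)
}
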