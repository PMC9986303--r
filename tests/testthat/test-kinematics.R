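test_that("global parameters on a static trial are the constructed offsets", {
  tr <- static_global_trial(head_up_cm = 10, head_right_cm = 3)
  gp <- global_parameters(tr)
  expect_equal(gp$mean_forward_velocity, 0)
  expect_equal(gp$head_to_T1_vertical, 10)
  expect_equal(gp$head_to_T1_lateral, 3)
  expect_equal(gp$T1_to_T13_vertical, 6)
  expect_equal(gp$T13_to_L7_vertical, 4)

  tr$markers$L7 <- NULL
  expect_error(global_parameters(tr), "L7")
})

test_that("the zero-noise generator reproduces its designed velocity", {
  tr <- preprocess_trial(generate_trial(gait_design(), n_cycles = 4))
  gp <- global_parameters(tr)
  expect_equal(gp$mean_forward_velocity, 1.28, tolerance = 0.01 / 1.28)
})

test_that("collinear markers give 0 degrees and 90-degree flexion is -90", {
  tr0 <- fetlock_trial(0)
  ang0 <- joint_angle_series(tr0, joint_definitions("fore")$fetlock, "FL_L")
  expect_equal(max(abs(ang0)), 0)

  tr90 <- fetlock_trial(-90)
  ang90 <- joint_angle_series(tr90, joint_definitions("fore")$fetlock, "FL_L")
  expect_equal(unique(round(ang90, 9)), -90)
})

test_that("degenerate projected segments are flagged as missing", {
  # distal segment along pure x has ~zero sagittal projection
  tr <- fetlock_trial(0)
  pp <- marker_positions(tr, "PPHAL_FL_L")
  tr$markers$PHAL_FL_L <- marker_trajectory(
    "PHAL_FL_L", pp + matrix(c(40, 0, 0), nrow(pp), 3, byrow = TRUE))
  ang <- joint_angle_series(tr, joint_definitions("fore")$fetlock, "FL_L")
  expect_true(all(is.na(ang)))
})

test_that("cycle durations and ratios follow frame arithmetic exactly", {
  tr <- preprocess_trial(generate_trial(gait_design(), n_cycles = 3))
  cyc <- gait_cycle("FL_L", 1, 83, 155)      # 82 stance + 72 swing frames
  lp <- limb_parameters(tr, cyc)
  expect_equal(lp$stance_duration, 0.41)
  expect_equal(lp$swing_duration, 0.36)
  expect_equal(lp$stride_duration, 0.77)
  expect_equal(lp$stance_to_stride, 82 / 154)
  expect_equal(lp$stance_to_stride + lp$swing_to_stride, 1, tolerance = 1e-12)
  expect_equal(lp$stance_to_swing, lp$stance_to_stride / lp$swing_to_stride,
               tolerance = 1e-9)
})

test_that("a 5 cm mid-swing hoof lift is measured as a 5 cm height range", {
  tr <- generate_trial(gait_design(hoof_lift_height = 0.05), n_cycles = 4)
  trp <- preprocess_trial(tr)
  v <- differentiate(trp$markers[[hoof_marker("HL_L")]], 200)
  det <- detect_phases(v, event_spec(), 200)
  cyc <- extract_cycle(det, trp, "HL_L",
                       mean(range(marker_positions(trp, "T1")[, "y"])) / 1000)
  lp <- limb_parameters(trp, cyc)
  expect_equal(lp$hoof_height_range_swing, 5, tolerance = 0.05)
})

test_that("limb parameters are invariant to rigid translation", {
  tr <- preprocess_trial(generate_trial(gait_design(), n_cycles = 3))
  shift <- c(250, -1300, 40)
  tr2 <- tr
  tr2$markers <- lapply(tr$markers, function(m) {
    m$positions <- m$positions + matrix(shift, nrow(m$positions), 3,
                                        byrow = TRUE)
    m
  })
  cyc <- gait_cycle("FL_R", 20, 100, 174)
  lp1 <- limb_parameters(tr, cyc)
  lp2 <- limb_parameters(tr2, cyc)
  for (nm in setdiff(names(lp1), "limb"))
    expect_equal(lp2[[nm]], lp1[[nm]], tolerance = 1e-9, label = nm)
  g1 <- global_parameters(tr); g2 <- global_parameters(tr2)
  expect_equal(g2$head_to_T1_vertical, g1$head_to_T1_vertical)
  expect_equal(g2$mean_forward_velocity, g1$mean_forward_velocity)
})

test_that("doubling design velocity doubles measured stride length", {
  measure <- function(vel) {
    tr <- preprocess_trial(generate_trial(
      gait_design(forward_velocity = vel), n_cycles = 3))
    v <- differentiate(tr$markers[[hoof_marker("FL_L")]], 200)
    det <- detect_phases(v, event_spec(), 200)
    cyc <- extract_cycle(det, tr, "FL_L",
                         mean(range(marker_positions(tr, "T1")[, "y"])) / 1000)
    limb_parameters(tr, cyc)$stride_length
  }
  s1 <- measure(0.8); s2 <- measure(1.6)
  expect_equal(s2 / s1, 2, tolerance = 0.01)
})

test_that("inter-limb stance distance uses frames where both hooves stand", {
  tr <- preprocess_trial(generate_trial(gait_design(), n_cycles = 3))
  v <- differentiate(tr$markers[[hoof_marker("FL_L")]], 200)
  det <- detect_phases(v, event_spec(), 200)
  cyc <- extract_cycle(det, tr, "FL_L",
                       mean(range(marker_positions(tr, "T1")[, "y"])) / 1000)
  lp <- limb_parameters(tr, cyc)
  expect_true(is.finite(lp$inter_limb_stance_distance))
  expect_gt(lp$inter_limb_stance_distance, 0)
  # contralateral hoof missing: the field is NA, everything else computed
  tr2 <- tr
  tr2$markers[[hoof_marker("FL_R")]] <- NULL
  lp2 <- limb_parameters(tr2, cyc)
  expect_true(is.na(lp2$inter_limb_stance_distance))
  expect_equal(lp2$stride_length, lp$stride_length)
})

test_that("trial parameters flatten into a unit-labelled study table", {
  tr <- preprocess_trial(generate_trial(gait_design(), n_cycles = 3,
                                        animal_id = "A7", session = "B2"))
  v <- differentiate(tr$markers[[hoof_marker("FL_L")]], 200)
  det <- detect_phases(v, event_spec(), 200)
  cyc <- extract_cycle(det, tr, "FL_L",
                       mean(range(marker_positions(tr, "T1")[, "y"])) / 1000)
  st <- trial_parameters(tr, list(FL_L = cyc))
  expect_s3_class(st, "ovigait_study_table")
  expect_true(all(c("mean_forward_velocity", "stance_duration",
                    "fetlock_min_swing") %in% st$measure))
  expect_equal(unique(st$animal), "A7")
  expect_equal(st$units[st$measure == "stride_length"], "cm")

  # averaging across repeated trials
  st2 <- st; st2$value <- st2$value + 1
  agg <- aggregate_trials(list(st, st2))
  expect_equal(agg$value[agg$measure == "stance_duration"],
               st$value[st$measure == "stance_duration"] + 0.5)
})
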