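test_that("identical seeds give bit-identical trials", {
  a <- generate_trial(gait_design(), noise = noise_model(seed = 7), n_cycles = 2)
  b <- generate_trial(gait_design(), noise = noise_model(seed = 7), n_cycles = 2)
  expect_identical(a$markers, b$markers)
  fa <- tempfile(fileext = ".tsv"); fb <- tempfile(fileext = ".tsv")
  write_trial(a, fa); write_trial(b, fb)
  expect_identical(readBin(fa, raw(), file.size(fa)),
                   readBin(fb, raw(), file.size(fb)))
  c <- generate_trial(gait_design(), noise = noise_model(seed = 8), n_cycles = 2)
  expect_false(identical(a$markers, c$markers))
})

test_that("a zero-velocity design is a static posture with no cycles", {
  tr <- generate_trial(gait_design(forward_velocity = 0), n_cycles = 2)
  for (m in tr$markers)
    expect_equal(max(apply(m$positions, 2, function(x) diff(range(x)))), 0)
  v <- differentiate(tr$markers[[hoof_marker("FL_L")]], 200)
  det <- detect_phases(v, event_spec(), 200)
  expect_equal(nrow(det$events), 0)
  expect_equal(det$phases$phase, "stance")
})

test_that("a zero stroke effect leaves the design untouched", {
  d <- gait_design()
  expect_identical(apply_stroke_effect(d, stroke_effect()), d)
})

test_that("the post-stroke preset shifts velocity, posture and timing", {
  d <- apply_stroke_effect(gait_design(), stroke_effect_preset())
  expect_equal(d$forward_velocity, 1.0)
  expect_equal(d$trunk_heights[["head_to_T1"]], 12 - 8.21)
  # stance extended by the per-limb deltas exactly
  expect_equal(unname(d$per_limb_duty["FL_L"] * d$cycle_duration),
               0.41 + 0.13, tolerance = 1e-9)
  expect_equal(unname(d$per_limb_duty["HL_R"] * d$cycle_duration),
               0.41 + 0.12, tolerance = 1e-9)
  # fetlock swing range reduced about the midpoint
  wf <- d$limb_waveform_overrides$FL_L$fetlock
  expect_equal(unname(wf["swing_max"] - wf["swing_min"]), 35 - 3.9)
})

test_that("zero-noise pipeline recovers the designed gait ground truth", {
  tr <- generate_trial(gait_design(), n_cycles = 5)
  trp <- preprocess_trial(tr)
  truth <- attr(tr, "truth")
  centre <- mean(range(marker_positions(trp, "T1")[, "y"])) / 1000
  for (limb in LIMBS) {
    v <- differentiate(trp$markers[[hoof_marker(limb)]], 200)
    det <- detect_phases(v, event_spec(), 200)
    cyc <- extract_cycle(det, trp, limb, centre)
    lp <- limb_parameters(trp, cyc)
    des <- truth$limbs[[limb]]
    expect_lt(abs(lp$stride_duration - des$stride_duration), 0.0051)
    expect_lt(abs(lp$stance_duration - des$stance_duration), 0.0051)
    # stride length within 1 mm = 0.1 cm
    expect_lt(abs(lp$stride_length - des$stride_length_cm), 0.1)
    for (joint in names(des$joints)) {
      for (ph in c("stance", "swing")) {
        got <- lp[[paste0(joint, "_", ph)]]
        want <- des$joints[[joint]][[ph]]
        expect_lt(abs(got[["min"]] - want[["min"]]), 0.5)
        expect_lt(abs(got[["max"]] - want[["max"]]), 0.5)
      }
    }
  }
})

test_that("longer designed phase durations give longer measured ones", {
  measure_stance <- function(extra) {
    eff <- stroke_effect(delta_stance = c(FL_L = extra, FL_R = extra,
                                          HL_L = extra, HL_R = extra))
    tr <- generate_trial(gait_design(), effect = eff, n_cycles = 3)
    trp <- preprocess_trial(tr)
    v <- differentiate(trp$markers[[hoof_marker("FL_L")]], 200)
    ev <- detect_phases(v, event_spec(), 200)$events
    c(stance = mean((ev$toe_off - ev$foot_strike) / 200),
      stride = mean((ev$next_foot_strike - ev$foot_strike) / 200))
  }
  m0 <- measure_stance(0); m1 <- measure_stance(0.06); m2 <- measure_stance(0.13)
  expect_true(m0["stance"] < m1["stance"] && m1["stance"] < m2["stance"])
  expect_true(m0["stride"] < m1["stride"] && m1["stride"] < m2["stride"])
})

test_that("generate_cohort wires animals, sessions and ground truth together", {
  co <- generate_cohort(2, sessions = c("B1", "D3"), n_trials = 1,
                        n_cycles = 2, seed = 3)
  expect_length(co$trials, 4)
  expect_s3_class(co$truth, "ovigait_study_table")
  expect_setequal(unique(co$truth$session), c("B1", "D3"))
  # post sessions carry the injected stance prolongation in the truth table
  tru <- as.data.frame(co$truth)
  st_b <- tru$value[tru$session == "B1" & tru$measure == "stance_duration" &
                      tru$limb == "FL_L"]
  st_d <- tru$value[tru$session == "D3" & tru$measure == "stance_duration" &
                      tru$limb == "FL_L"]
  expect_equal(unique(st_d - st_b), 0.13, tolerance = 1e-9)
  expect_length(co$infarct_volumes, 2)
  expect_true(all(c("animal", "session", "criterion", "component", "value")
                  %in% names(co$neuroscores)))

  expect_error(generate_cohort(1, sessions = c("B1", "D3"), seed = 1),
               "n_animals >= 2")
  solo <- generate_cohort(1, sessions = c("B1", "D3"), between_sd = NULL,
                          n_trials = 1, n_cycles = 1, seed = 1)
  expect_length(solo$trials, 2)
  expect_error(generate_cohort(2, sessions = c("D3"), seed = 1), "baseline")
})

test_that("an inconsistent design is rejected", {
  expect_error(gait_design(cycle_duration = -1), "positive")
  expect_error(gait_design(duty_factor = 1.2), "between 0 and 1")
  expect_error(gait_design(stride_length = 2), "inconsistent")
  expect_silent(gait_design(stride_length = 1.28 * 0.77))
})
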