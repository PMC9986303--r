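test_that("an all-zero sheet scores zero everywhere", {
  ns <- validate_sheet(zero_sheet())
  expect_equal(ns$total, 0)
  expect_equal(ns$demeanour, 0)
  expect_equal(ns$behaviour, 0)
  expect_equal(ns$postural_left, 0)
  expect_equal(ns$postural_right, 0)
  expect_equal(ns$wheelbarrow, 0)
})

test_that("worked rubric entries score as printed", {
  # stupor is the third level of the demeanour criterion
  ns <- validate_sheet(sheet_set(zero_sheet(), 1, "base", 2))
  expect_equal(ns$demeanour, 2)

  # no adjustment of both limbs (4) plus knuckling on both left limbs (+0.5)
  s <- zero_sheet()
  s <- sheet_set(s, 7, "base_left", 4)
  s <- sheet_set(s, 7, "knuckling_left", 0.5)
  ns <- validate_sheet(s)
  expect_equal(ns$postural_left, 4.5)
  expect_equal(ns$postural_right, 0)
  expect_equal(ns$total, 4.5)
})

test_that("the rubric maximum is computed, and its published discrepancy surfaced", {
  mx <- rubric_max()
  # per-side postural: hemi-standing 4 + 2x0.25, hopping 2 + 0.25,
  # dragging 2 limbs x (2 + 0.25 + 0.25)
  expect_equal(mx$per_side_postural, 4.5 + 2.25 + 5)
  expect_equal(mx$total, 3 + 8 + 2 * mx$per_side_postural + 2)
  expect_equal(mx$discrepancy, mx$total - mx$stated_total)
  expect_true(mx$discrepancy != 0)   # the published total disagrees; never hidden
})

test_that("totals are invariant to row order", {
  s <- zero_sheet()
  s <- sheet_set(s, 5, "base", 2)
  s <- sheet_set(s, 9, "base_left_fore", 1)
  s <- sheet_set(s, 9, "drag_left_fore", 0.25)
  shuffled <- s[sample.int(nrow(s)), ]
  expect_equal(validate_sheet(shuffled)$total, validate_sheet(s)$total)
})

test_that("out-of-range, off-grid and missing entries are rejected by name", {
  expect_error(validate_sheet(sheet_set(zero_sheet(), 1, "base", 4)),
               "outside")
  expect_error(validate_sheet(sheet_set(zero_sheet(), 7, "base_left", 2.3)),
               "0.25 grid")
  expect_error(validate_sheet(sheet_set(zero_sheet(), 5, "base", 1.5)),
               "integer")
  s <- zero_sheet()
  s <- s[!(s$criterion == 3 & s$component == "base"), ]
  expect_error(validate_sheet(s), "criterion 3")
  # absent modifier rows default to zero
  s2 <- zero_sheet()
  s2 <- s2[!(s2$criterion == 7 & s2$component == "knuckling_left"), ]
  expect_equal(validate_sheet(s2)$total, 0)
})

test_that("subscore summaries average baselines and pair with post values", {
  sheets <- rbind(
    sheet_set(zero_sheet("A1", "B1"), 10, "base", 0),
    sheet_set(zero_sheet("A1", "B2"), 10, "base", 0),
    sheet_set(zero_sheet("A1", "B3"), 7, "base_left", 1),
    sheet_set(sheet_set(zero_sheet("A1", "D3"), 1, "base", 1),
              7, "base_left", 4))
  # baseline totals 0, 0, 1.5? -> here 0, 0, 1 from one postural point
  sheets$value[sheets$animal == "A1" & sheets$session == "B3" &
                 sheets$criterion == 7 & sheets$component == "knuckling_left"] <- 0.5
  scores <- read_score_sheet(sheets)
  summ <- subscore_summary(scores, baseline_sessions = c("B1", "B2", "B3"),
                           post_sessions = "D3")
  tot <- summ[summ$subscore == "total", ]
  expect_equal(tot$mean_baseline, mean(c(0, 0, 1.5)))
  expect_equal(tot$post, 5)

  # single-baseline animal: the mean is that value
  one <- rbind(sheet_set(zero_sheet("A2", "B1"), 5, "base", 1),
               zero_sheet("A2", "D3"))
  s2 <- subscore_summary(read_score_sheet(one), baseline_sessions = "B1",
                         post_sessions = "D3")
  expect_equal(s2$mean_baseline[s2$subscore == "total"], 1)

  # animal without a post session is excluded with a warning
  nopost <- read_score_sheet(zero_sheet("A3", "B1"))
  expect_warning(out <- subscore_summary(nopost, baseline_sessions = "B1",
                                         post_sessions = "D3"),
                 "no post session")
  expect_null(out)
})

test_that("a synthetic cohort carries its designed post-stroke deficit", {
  sheets <- simulate_neuroscore_sheets(6, c("B1", "B2", "B3", "D3"), seed = 2)
  scores <- read_score_sheet(sheets)
  summ <- subscore_summary(scores)
  tot <- summ[summ$subscore == "total", ]
  expect_equal(median(tot$post - tot$mean_baseline), 7, tolerance = 0.5 / 7)
})
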