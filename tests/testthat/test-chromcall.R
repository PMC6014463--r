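cfg <- caller_config()

test_that("copy-number calling is modal with the four-cell mosaic rule", {
  # uniform trisomy
  tc <- call_copy_number(make_cohort(20, c(YELLOW = 3)), "YELLOW", cfg)
  expect_equal(tc$primary_copy_number, 3L)
  expect_true(is.na(tc$secondary_copy_number))

  # mosaic monosomy X: 16 cells one copy + 4 cells two copies
  pats <- c(make_cohort(16, c(GREEN = 1)), make_cohort(4, c(GREEN = 2)))
  tc <- call_copy_number(pats, "GREEN", cfg)
  expect_equal(tc$primary_copy_number, 1L)
  expect_equal(tc$secondary_copy_number, 2L)
  expect_equal(tc$secondary_fraction, 0.20)

  # below the four-cell rule: no secondary
  pats <- c(make_cohort(18, c(RED = 2)), make_cohort(2, c(RED = 3)))
  tc <- call_copy_number(pats, "RED", cfg)
  expect_equal(tc$primary_copy_number, 2L)
  expect_true(is.na(tc$secondary_copy_number))

  expect_error(call_copy_number(list(), "RED", cfg), "no cells")
})

test_that("modal ties break toward the diploid count, then the smaller", {
  pats <- c(make_cohort(10, c(RED = 2)), make_cohort(10, c(RED = 3)))
  expect_equal(call_copy_number(pats, "RED", cfg)$primary_copy_number, 2L)
  pats <- c(make_cohort(10, c(RED = 1)), make_cohort(10, c(RED = 3)))
  expect_equal(call_copy_number(pats, "RED", cfg)$primary_copy_number, 1L)
})

test_that("the mosaic rule needs both four cells and twenty percent", {
  # 40 cells: 5 cells is >= 4 but only 12.5% -> no mosaic call
  pats <- c(make_cohort(35, c(RED = 2)), make_cohort(5, c(RED = 3)))
  expect_true(is.na(call_copy_number(pats, "RED", cfg)$secondary_copy_number))
  # 10 cells: 3 cells is 30% but < 4 cells -> no mosaic call
  pats <- c(make_cohort(7, c(RED = 2)), make_cohort(3, c(RED = 3)))
  tc <- call_copy_number(pats, "RED", cfg)
  expect_true(is.na(tc$secondary_copy_number))
  expect_true(tc$low_cells)
})

test_that("exhaustive sweep: minimum mosaic secondary population is 4 of 20", {
  min_k <- NA
  for (k in 0:20) {
    pats <- c(make_cohort(20 - k, c(RED = 2)), make_cohort(k, c(RED = 3)))
    tc <- call_copy_number(pats, "RED", cfg)
    mosaic <- !is.na(tc$secondary_copy_number)
    if (k <= 10) {                     # secondary stays the minority here
      if (mosaic && is.na(min_k)) min_k <- k
      expect_equal(mosaic, k >= 4, label = paste("k =", k))
    }
  }
  expect_equal(min_k, 4L)
})

test_that("fusion calls use the strict >20% cut-off", {
  counts <- c(YELLOW = 2, GREEN = 2)
  pair <- c("YELLOW", "GREEN")
  fc4 <- call_fusion(make_cohort(20, counts, 4, pair), pair, cfg)
  expect_equal(fc4$fraction, 0.20)
  expect_false(fc4$abnormal)
  fc5 <- call_fusion(make_cohort(20, counts, 5, pair), pair, cfg)
  expect_equal(fc5$fraction, 0.25)
  expect_true(fc5$abnormal)
  fc20 <- call_fusion(make_cohort(20, counts, 20, pair), pair, cfg)
  expect_true(fc20$abnormal)
  expect_error(call_fusion(make_cohort(5, counts), c("RED", "RED"), cfg),
               "distinct")
})

test_that("exhaustive sweep: abnormal juxtaposition starts at 5 of 20 cells", {
  abnormal_at <- vapply(0:20, function(k) {
    pats <- make_cohort(20, c(YELLOW = 2, GREEN = 2), k,
                        c("YELLOW", "GREEN"))
    call_fusion(pats, c("YELLOW", "GREEN"), cfg)$abnormal
  }, logical(1))
  expect_equal(abnormal_at, 0:20 >= 5)
})

test_that("raising the cut-off never converts a normal call to abnormal", {
  pats <- make_cohort(20, c(YELLOW = 2, GREEN = 2), 6, c("YELLOW", "GREEN"))
  cuts <- c(0.1, 0.2, 0.3, 0.4, 0.6)
  ab <- vapply(cuts, function(cut) {
    call_fusion(pats, c("YELLOW", "GREEN"),
                caller_config(fusion_cutoff = cut))$abnormal
  }, logical(1))
  expect_true(all(diff(as.integer(ab)) <= 0))
})

test_that("cut-off estimation matches the exact binomial search oracle", {
  # zero fused cells in 100: the 95% upper bound
  controls <- list(make_cohort(100, c(YELLOW = 2, GREEN = 2)))
  got <- estimate_cutoff(controls, confidence = 0.95)
  expect_equal(got, binomial_upper_oracle(0, 100, 0.95), tolerance = 1e-6)

  # pooled bound vs max-observed floor with wide n
  controls <- list(
    make_cohort(200, c(YELLOW = 2, GREEN = 2), 20),   # 10%
    make_cohort(200, c(YELLOW = 2, GREEN = 2), 30)    # 15%
  )
  got <- estimate_cutoff(controls, confidence = 0.95)
  expect_gte(got, 0.15)
  oracle <- binomial_upper_oracle(50, 400, 0.95)
  expect_equal(got, max(0.15, oracle), tolerance = 1e-6)

  # degenerate single-cell control stays a proportion
  got <- estimate_cutoff(list(make_cohort(1, c(RED = 2))), 0.95)
  expect_lte(got, 1)
  expect_error(estimate_cutoff(list()), "control")
})

test_that("chromosome interpretation maps count signatures to event types", {
  mk <- function(p, c, q) list(
    PTER = call_copy_number(make_cohort(20, c(GREEN = p)), "GREEN", cfg),
    CEN = call_copy_number(make_cohort(20, c(YELLOW = c)), "YELLOW", cfg),
    QTER = call_copy_number(make_cohort(20, c(RED = q)), "RED", cfg)
  )
  expect_equal(interpret_chromosome("9", mk(1, 2, 2))$interpretation,
               "TERMINAL_DEL_P")
  expect_equal(interpret_chromosome("16", mk(2, 2, 1))$interpretation,
               "TERMINAL_DEL_Q")
  expect_equal(interpret_chromosome("21", mk(3, 3, 3))$interpretation, "GAIN")
  expect_equal(interpret_chromosome("16", mk(1, 1, 1))$interpretation, "LOSS")
  expect_equal(interpret_chromosome("7", mk(2, 2, 2))$interpretation,
               "NORMAL")
  # extra terminal without a pericentromeric gain: displaced-terminal
  cc <- interpret_chromosome("7", mk(3, 2, 2))
  expect_equal(cc$interpretation, "DISPLACED_TERMINAL")
  # gain relative to a triploid baseline needs four copies
  expect_equal(interpret_chromosome("4", mk(3, 3, 3),
                                    baseline = 3L)$interpretation, "NORMAL")
  # conflicting evidence is MIXED with everything retained
  cc <- interpret_chromosome("5", mk(3, 3, 2))
  expect_equal(cc$interpretation, "MIXED")
  expect_length(cc$events, 2)
})

test_that("breakpoint refinement brackets the terminal absent run", {
  bp <- refine_breakpoint(data.frame(
    band_label = c("12p11", "12p12", "12p13", "12pter"),
    present = c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(bp$status, "breakpoint")
  expect_equal(bp$proximal, "12p13")
  expect_equal(bp$distal, "12pter")

  expect_equal(refine_breakpoint(data.frame(
    band_label = c("q12", "q14", "q21"),
    present = c(TRUE, TRUE, TRUE)))$status, "none")

  bp <- refine_breakpoint(data.frame(
    band_label = c("q12", "q14", "q21"),
    present = c(TRUE, FALSE, FALSE)))
  expect_equal(bp$proximal, "q12")
  expect_equal(bp$distal, "q14")

  bp <- refine_breakpoint(data.frame(band_label = c("q1", "q2"),
                                     present = c(FALSE, FALSE)))
  expect_equal(bp$status, "whole_arm")
  expect_equal(bp$distal, "q1")

  expect_error(refine_breakpoint(data.frame(band_label = character(0),
                                            present = logical(0))), "empty")
})
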