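std <- build_standard_panel()
acro <- build_acrocentric_panel()

test_that("expected patterns match the canonical abnormality signatures", {
  # trisomy 13 in its own hybridization: three yellow + three red, no fusion
  p <- expected_pattern("47,XY,+13", std$hybridizations$chr13)
  expect_equal(unname(p$color_counts[c("YELLOW", "RED")]), c(3L, 3L))
  expect_length(p$fusions, 0)

  # unbalanced Robertsonian in the acrocentric mix: one fused yellow+green,
  # one free yellow (13), two free green (14), pairs elsewhere
  p <- expected_pattern("46,XY,der(13;14)(q10;q10),+14",
                        acro$hybridizations$acro)
  expect_equal(unname(p$color_counts[c("YELLOW", "GREEN", "RED", "AQUA",
                                       "FARRED")]),
               c(2L, 3L, 2L, 2L, 2L))
  expect_equal(p$fusions, list(c("GREEN", "YELLOW")))

  # monosomy X in the joint X/Y hybridization
  p <- expected_pattern("45,X", std$hybridizations$chrXY)
  expect_equal(unname(p$color_counts[c("GREEN", "YELLOW", "RED", "AQUA")]),
               c(1L, 1L, 1L, 0L))

  # terminal deletion decrements only the deleted arm's terminal color
  p <- expected_pattern("46,XY,del(9)(p?)", std$hybridizations$chr9)
  expect_equal(unname(p$color_counts[c("GREEN", "YELLOW", "RED")]),
               c(1L, 2L, 2L))

  # chromosomes absent from the hybridization contribute an empty pattern
  p <- expected_pattern("47,XX,+21", std$hybridizations$chr7)
  expect_equal(unname(p$color_counts[c("GREEN", "YELLOW", "RED")]),
               c(2L, 2L, 2L))
})

test_that("counts conserve ploidy arithmetic for all chromosomes and ploidies", {
  # exhaustive: every chromosome x ploidy 1..4, no structural events
  for (ploidy in 1:4) {
    sex <- strrep("X", ploidy)
    count <- 22 * ploidy + ploidy
    spec <- parse_karyotype_spec(sprintf("%d,%s", count, sex))
    for (id in names(std$hybridizations)) {
      hyb <- std$hybridizations[[id]]
      p <- expected_pattern(spec, hyb)
      for (col in unique(hyb$targets$color)) {
        # per-color count sums copy numbers over all chromosomes sharing
        # the color in this hybridization (YELLOW/RED are shared by X and
        # Y); the complement here is all-X so Y contributes zero
        chroms <- hyb$targets$chromosome[hyb$targets$color == col]
        want <- sum(ifelse(chroms == "Y", 0L, ploidy))
        expect_equal(unname(p$color_counts[[col]]), want,
                     label = sprintf("ploidy %d %s %s", ploidy, id, col))
      }
      expect_length(p$fusions, 0)
    }
  }
})

test_that("gains and losses shift exactly the targeted chromosome's counts", {
  for (chr in c("4", "13", "16", "21")) {
    hyb <- std$hybridizations[[paste0("chr", chr)]]
    gain <- expected_pattern(sprintf("47,XX,+%s", chr), hyb)
    loss <- expected_pattern(sprintf("45,XX,-%s", chr), hyb)
    for (i in seq_len(nrow(hyb$targets))) {
      col <- hyb$targets$color[i]
      expect_equal(unname(gain$color_counts[[col]]), 3L)
      expect_equal(unname(loss$color_counts[[col]]), 1L)
    }
  }
})

test_that("a balanced Robertsonian keeps counts and adds exactly one fusion", {
  p0 <- expected_pattern("46,XX", acro$hybridizations$acro)
  p1 <- expected_pattern("45,XX,der(13;22)", acro$hybridizations$acro)
  # the derivative holds one 13 and one 22 centromeric region: totals equal
  expect_equal(p1$color_counts, p0$color_counts)
  expect_equal(p1$fusions, list(c("FARRED", "YELLOW")))
})

test_that("unbalanced derivatives move one terminal signal between hybridizations", {
  spec <- parse_karyotype_spec("46,XX,der(18)t(7;18)(p?;q?)")
  p18 <- expected_pattern(spec, std$hybridizations$chr18)
  expect_equal(unname(p18$color_counts[c("GREEN", "YELLOW", "RED")]),
               c(2L, 2L, 1L))
  p7 <- expected_pattern(spec, std$hybridizations$chr7)
  expect_equal(unname(p7$color_counts[c("GREEN", "YELLOW", "RED")]),
               c(3L, 2L, 2L))
  # the extra 7p signal is a displaced territory in the layout
  layout <- icprofiler:::expected_signal_layout(spec,
                                                std$hybridizations$chr7)
  displaced <- Filter(function(t) isTRUE(t$displaced), layout)
  expect_length(displaced, 1)
  expect_equal(displaced[[1]]$groups[[1]]$colors, "GREEN")
})

test_that("balanced translocations keep counts but displace both terminals", {
  spec <- parse_karyotype_spec("46,XX,t(2;10)(q?;q?)")
  for (chr in c("2", "10")) {
    hyb <- std$hybridizations[[paste0("chr", chr)]]
    p <- expected_pattern(spec, hyb)
    expect_equal(unname(p$color_counts[c("GREEN", "YELLOW", "RED")]),
                 c(2L, 2L, 2L))
    layout <- icprofiler:::expected_signal_layout(spec, hyb)
    displaced <- Filter(function(t) isTRUE(t$displaced), layout)
    expect_length(displaced, 1)
    expect_equal(displaced[[1]]$groups[[1]]$colors, "RED")
  }
})
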