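std <- build_standard_panel()
acro <- build_acrocentric_panel()

test_that("noise-free simulation recovers the expected pattern in every cell", {
  cfg <- simulation_config(seed = 3)
  hyb <- std$hybridizations$chr7
  tab <- simulate_hybridization("46,XX", hyb, cfg)
  expect_true(all(tab$x^2 + tab$y^2 <= 1))
  pats <- extract_patterns(tab, cfg$fusion_distance, n_cells = cfg$n_cells)
  for (p in pats) {
    expect_equal(unname(p$color_counts[c("GREEN", "YELLOW", "RED")]),
                 c(2L, 2L, 2L))
    expect_length(p$fusions, 0)
  }
})

test_that("noise-free extraction is exact for structurally complex karyotypes", {
  # every cell, every hybridization, several event classes
  cfg <- simulation_config(seed = 8)
  for (k in c("46,XY,der(13;14)(q10;q10),+14", "69,XXX",
              "46,XX,der(18)t(7;18)(p?;q?)", "45,X")) {
    spec <- parse_karyotype_spec(k)
    tables <- simulate_icp_case(spec, cfg)
    for (id in names(tables)) {
      hyb <- if (id == "acro") acro$hybridizations$acro
             else std$hybridizations[[id]]
      want <- expected_pattern(spec, hyb)
      pats <- extract_patterns(tables[[id]], cfg$fusion_distance,
                               n_cells = cfg$n_cells)
      for (p in pats) {
        expect_equal(p$color_counts, want$color_counts,
                     label = paste(k, id))
        expect_equal(lapply(p$fusions, sort), want$fusions,
                     label = paste(k, id))
      }
    }
  }
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  cfg <- simulation_config(seed = 21)
  a <- simulate_hybridization("46,XY", std$hybridizations$chr2, cfg)
  b <- simulate_hybridization("46,XY", std$hybridizations$chr2, cfg)
  expect_identical(a, b)
  cfg2 <- simulation_config(seed = 22)
  c <- simulate_hybridization("46,XY", std$hybridizations$chr2, cfg2)
  expect_false(identical(a$x, c$x))

  t1 <- simulate_case("46,XY", std, cfg)
  t2 <- simulate_case("46,XY", std, cfg)
  expect_identical(t1, t2)
})

test_that("population mixtures hit their fractions within binomial error", {
  # tetraploid mosaic scenario: fraction of 4-red cells near 0.35
  cfg <- simulation_config(n_cells = 400L, seed = 13)
  pops <- list(list(karyotype = "46,XX", fraction = 0.65),
               list(karyotype = "92,XXXX", fraction = 0.35))
  tab <- simulate_hybridization(pops, std$hybridizations$chr1, cfg)
  pats <- extract_patterns(tab, cfg$fusion_distance, n_cells = 400L)
  frac4 <- mean(vapply(pats, function(p)
    p$color_counts[["RED"]] == 4L, logical(1)))
  se <- sqrt(0.35 * 0.65 / 400)
  expect_lt(abs(frac4 - 0.35), 3 * se)
})

test_that("invalid populations and cell counts are rejected", {
  expect_error(simulate_hybridization(list(), std$hybridizations$chr1),
               "empty")
  bad <- list(list(karyotype = "46,XX", fraction = 0.5),
              list(karyotype = "47,XX,+16", fraction = 0.6))
  expect_error(simulate_hybridization(bad, std$hybridizations$chr1),
               "sum to 1")
  expect_error(simulation_config(n_cells = 0), "n_cells")
})

test_that("sex chromatin simulates correctly in the joint X/Y hybridization", {
  cfg <- simulation_config(seed = 31)
  tab <- simulate_hybridization("46,XX", std$hybridizations$chrXY, cfg)
  expect_false("AQUA" %in% tab$color)
  tab2 <- simulate_hybridization("46,XY", std$hybridizations$chrXY, cfg)
  pats <- extract_patterns(tab2, cfg$fusion_distance, n_cells = 20)
  for (p in pats) {
    expect_equal(unname(p$color_counts[c("GREEN", "AQUA", "YELLOW", "RED")]),
                 c(1L, 1L, 2L, 2L))
  }
})

test_that("chance juxtaposition in uniform mode matches the Monte-Carlo oracle", {
  # 46,XY on the acrocentric mix: ten singleton signals, i.i.d. uniform
  r <- 0.05
  cfg <- simulation_config(n_cells = 2000L, territory_sd = Inf,
                           fusion_distance = r, seed = 17)
  tab <- simulate_hybridization("46,XY", acro$hybridizations$acro, cfg)
  pats <- extract_patterns(tab, r, n_cells = cfg$n_cells)
  sim_rate <- mean(vapply(pats, function(p) length(p$fusions) > 0,
                          logical(1)))
  colors <- rep(c("YELLOW", "GREEN", "RED", "AQUA", "FARRED"), each = 2)
  oracle <- mc_juxtaposition_oracle(colors, r, n_rep = 2e4, seed = 555)
  se <- sqrt(oracle * (1 - oracle) * (1 / cfg$n_cells + 1 / 2e4))
  expect_lt(abs(sim_rate - oracle), 3 * se + 1e-12)
})

test_that("chance-fusion rate grows with radius and with spot count", {
  rate_at <- function(karyotype, r) {
    cfg <- simulation_config(n_cells = 600L, territory_sd = Inf,
                             fusion_distance = r, seed = 19)
    tab <- simulate_hybridization(karyotype, acro$hybridizations$acro, cfg)
    pats <- extract_patterns(tab, r, n_cells = cfg$n_cells)
    mean(vapply(pats, function(p) length(p$fusions) > 0, logical(1)))
  }
  radii <- c(0.02, 0.05, 0.12, 0.25)
  rates <- vapply(radii, function(r) rate_at("46,XY", r), numeric(1))
  expect_true(all(diff(rates) > 0))
  # more spots (tetraploid acrocentric complement) colocalize more often
  expect_gt(rate_at("92,XXYY", 0.05), rate_at("46,XY", 0.05))
})

test_that("detection noise drops spots and splitting re-merges at extraction", {
  cfg <- simulation_config(p_detect = 0.5, seed = 23)
  tab <- simulate_hybridization("46,XX", std$hybridizations$chr3, cfg)
  expect_lt(nrow(tab), 20 * 6)        # many spots dropped
  cfg2 <- simulation_config(p_split = 1, seed = 23)
  tab2 <- simulate_hybridization("46,XX", std$hybridizations$chr3, cfg2)
  expect_equal(nrow(tab2), 20 * 12)   # every signal doubled...
  pats <- extract_patterns(tab2, cfg2$fusion_distance, n_cells = 20)
  for (p in pats) {                   # ...but counts are unchanged
    expect_equal(unname(p$color_counts[c("GREEN", "YELLOW", "RED")]),
                 c(2L, 2L, 2L))
  }
})

test_that("spot tables round-trip through TSV", {
  cfg <- simulation_config(seed = 29)
  tab <- simulate_hybridization("47,XX,+16", std$hybridizations$chr16, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(tab, f)
  back <- read_spot_table(f)
  expect_equal(back$cell_id, tab$cell_id)
  expect_equal(back$color, tab$color)
  expect_equal(back$x, tab$x, tolerance = 1e-12)
})
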