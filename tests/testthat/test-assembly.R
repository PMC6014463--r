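cfg <- caller_config()

test_that("ploidy inference maps the modal pericentromeric count", {
  expect_equal(infer_ploidy(rep(3L, 22))$ploidy, "TRIPLOID")
  expect_equal(infer_ploidy(rep(4L, 22))$ploidy, "TETRAPLOID")
  expect_equal(infer_ploidy(c(rep(2L, 21), 3L))$baseline, 2L)
  expect_equal(infer_ploidy(rep(5L, 22))$ploidy, "OTHER")
  expect_error(infer_ploidy(2L), "at least 2")
  expect_true("few_autosomes_for_ploidy" %in% infer_ploidy(rep(2L, 5))$flags)
})

test_that("sex complement follows the aqua and green counts", {
  mk_xy <- function(x, y, cenq = NULL) {
    cen <- if (is.null(cenq)) x + y else cenq
    list(X_PTER = call_copy_number(make_cohort(20, c(GREEN = x)), "GREEN", cfg),
         Y_PTER = call_copy_number(make_cohort(20, c(AQUA = y)), "AQUA", cfg),
         CEN = call_copy_number(make_cohort(20, c(YELLOW = cen)), "YELLOW", cfg),
         QTER = call_copy_number(make_cohort(20, c(RED = cen)), "RED", cfg))
  }
  expect_equal(infer_sex(mk_xy(1, 0))$sex, "X")
  expect_equal(infer_sex(mk_xy(2, 1))$sex, c("X", "X", "Y"))
  expect_equal(infer_sex(mk_xy(2, 0))$sex, c("X", "X"))
  # pericentromeric total inconsistent with X+Y is flagged, not fatal
  res <- infer_sex(mk_xy(2, 1, cenq = 2))
  expect_true(any(grepl("xy_cen", res$flags)))
})

test_that("an Xq deletion on a single X is attributed to the X", {
  xy <- list(
    X_PTER = call_copy_number(make_cohort(20, c(GREEN = 1)), "GREEN", cfg),
    Y_PTER = call_copy_number(make_cohort(20, c(AQUA = 0)), "AQUA", cfg),
    CEN = call_copy_number(make_cohort(20, c(YELLOW = 1)), "YELLOW", cfg),
    QTER = call_copy_number(make_cohort(20, c(RED = 0)), "RED", cfg)
  )
  res <- infer_sex(xy)
  expect_equal(res$sex, "X")
  expect_length(res$events, 1)
  expect_equal(res$events[[1]]$type, "TERMINAL_DEL")
  expect_equal(res$events[[1]]$chromosome, "X")
  expect_equal(res$events[[1]]$arm, "q")
})

test_that("Robertsonian detection resolves balance from participant totals", {
  # unbalanced 13;14 with trisomy 14: fused yellow+green in every cell
  pats <- lapply(1:20, function(i) make_pattern(
    c(YELLOW = 2, GREEN = 3, RED = 2, AQUA = 2, FARRED = 2),
    fusions = list(c("YELLOW", "GREEN")), cell_id = i))
  rb <- detect_robertsonian(pats, cfg, baseline = 2L)
  expect_length(rb$events, 1)
  ev <- rb$events[[1]]
  expect_equal(ev$chromosomes, c("13", "14"))
  expect_equal(ev$extra_copy_of, "14")
  expect_false(ev$balanced)

  # 14;21 translocation trisomy 21: fused green+aqua, third aqua
  pats <- lapply(1:20, function(i) make_pattern(
    c(YELLOW = 2, GREEN = 2, RED = 2, AQUA = 3, FARRED = 2),
    fusions = list(c("GREEN", "AQUA")), cell_id = i))
  ev <- detect_robertsonian(pats, cfg, 2L)$events[[1]]
  expect_equal(ev$chromosomes, c("14", "21"))
  expect_equal(ev$extra_copy_of, "21")

  # balanced 13;22: totals at baseline
  pats <- lapply(1:20, function(i) make_pattern(
    c(YELLOW = 2, GREEN = 2, RED = 2, AQUA = 2, FARRED = 2),
    fusions = list(c("YELLOW", "FARRED")), cell_id = i))
  ev <- detect_robertsonian(pats, cfg, 2L)$events[[1]]
  expect_equal(ev$chromosomes, c("13", "22"))
  expect_true(ev$balanced)
  expect_null(ev$extra_copy_of)

  # a color fused with two partners is flagged, not auto-resolved
  pats <- lapply(1:20, function(i) make_pattern(
    c(YELLOW = 2, GREEN = 2, RED = 2, AQUA = 2, FARRED = 2),
    fusions = list(c("YELLOW", "GREEN", "RED")), cell_id = i))
  rb <- detect_robertsonian(pats, cfg, 2L)
  expect_length(rb$events, 0)
  expect_true(any(grepl("complex_acro_fusion", rb$flags)))

  # sub-threshold juxtaposition (4 of 20) yields no event
  pats <- lapply(1:20, function(i) make_pattern(
    c(YELLOW = 2, GREEN = 2, RED = 2, AQUA = 2, FARRED = 2),
    fusions = if (i <= 4) list(c("YELLOW", "GREEN")) else list(),
    cell_id = i))
  expect_length(detect_robertsonian(pats, cfg, 2L)$events, 0)
})

test_that("translocation pairing assembles derivatives and balanced events", {
  # terminal 18q loss + extra 7p -> der(18)t(7;18)(p?;q?)
  ev <- pair_translocations(list(
    list(type = "TERMINAL_DEL", chromosome = "18", arm = "q"),
    list(type = "EXTRA_TERMINAL", chromosome = "7", arm = "p",
         displaced = TRUE)
  ))
  expect_length(ev$events, 1)
  e <- ev$events[[1]]
  expect_equal(e$kind, "UNBALANCED_DER")
  expect_equal(e$der_chromosome, "18")
  expect_equal(e$chromosomes, c("7", "18"))
  expect_equal(e$bands, c("p?", "q?"))

  # two displaced terminals with normal counts -> balanced translocation
  ev <- pair_translocations(list(
    list(type = "DISPLACED", chromosome = "10", arm = "q"),
    list(type = "DISPLACED", chromosome = "2", arm = "q")
  ))
  e <- ev$events[[1]]
  expect_equal(e$kind, "RECIPROCAL_TRANSLOCATION")
  expect_equal(e$chromosomes, c("2", "10"))

  # an unpaired loss stays a terminal deletion
  ev <- pair_translocations(list(
    list(type = "TERMINAL_DEL", chromosome = "10", arm = "p")
  ))
  expect_equal(ev$events[[1]]$kind, "TERMINAL_DELETION")
  expect_equal(ev$events[[1]]$chromosomes, "10")

  # competing pairings are reported as ambiguous
  ev <- pair_translocations(list(
    list(type = "TERMINAL_DEL", chromosome = "18", arm = "q"),
    list(type = "TERMINAL_DEL", chromosome = "11", arm = "p"),
    list(type = "EXTRA_TERMINAL", chromosome = "7", arm = "p")
  ))
  expect_true("ambiguous_translocation_pairing" %in% ev$flags)
  kinds <- vapply(ev$events, function(e) e$kind, character(1))
  expect_setequal(kinds, c("UNBALANCED_DER", "TERMINAL_DELETION"))
})

test_that("male/female admixture is reported as two populations", {
  mk_cells <- function(n_xx, n_xy) {
    c(lapply(seq_len(n_xx), function(i)
        make_pattern(c(GREEN = 2, YELLOW = 2, RED = 2), cell_id = i)),
      lapply(seq_len(n_xy), function(i)
        make_pattern(c(GREEN = 1, AQUA = 1, YELLOW = 2, RED = 2),
                     cell_id = n_xx + i)))
  }
  pops <- detect_mcc(mk_cells(15, 5), cfg)
  expect_length(pops, 2)
  expect_equal(paste(pops[[1]]$sex, collapse = ""), "XX")
  expect_equal(paste(pops[[2]]$sex, collapse = ""), "XY")
  expect_equal(pops[[2]]$fraction, 0.25)

  expect_null(detect_mcc(mk_cells(20, 0), cfg))
  expect_null(detect_mcc(mk_cells(18, 2), cfg))   # below the mosaic rule
})

test_that("end-to-end: numerical, Robertsonian and derivative calls rebuild their strings", {
  cases <- c("icp.45,X", "icp.47,XX,+15",
             "icp.46,XY,der(13;14)(q10;q10),+14",
             "icp.46,XX,der(18)t(7;18)(p?;q?)",
             "icp.47,XY,t(2;11)(q?;q?),+22",
             "icp.69,XXY", "icp.46,XY,del(16)(q?)")
  for (k in cases) {
    call <- run_icp_case(k, simulation_config(seed = 41))
    expect_true(same_karyotype_class(call$icp_string, k), label = k)
    expect_match(call$icp_string, "\\[cp20\\]$")
  }
})

test_that("end-to-end: a mosaic tetraploid resolves into two ploidy populations", {
  call <- run_icp_case("icp.92,XXXX/46,XX", simulation_config(seed = 47))
  expect_true(same_karyotype_class(call$icp_string, "icp.92,XXXX/46,XX"))
  expect_length(call$populations, 1)
  expect_equal(call$populations[[1]]$kind, "mosaic_ploidy")
  expect_lt(abs(call$populations[[1]]$fraction - 0.35), 0.2)
})

test_that("end-to-end: maternal-cell admixture yields two sex populations and a flag", {
  pops <- list(list(karyotype = "46,XX", fraction = 0.7),
               list(karyotype = "46,XY", fraction = 0.3))
  call <- run_icp_case(pops, simulation_config(seed = 53))
  expect_true("possible_maternal_cell_admixture" %in% call$flags)
  expect_length(call$populations, 1)
  expect_equal(paste(sort(call$populations[[1]]$spec$sex), collapse = ""),
               "XY")
})

test_that("to_icp_string renders nomenclature with ordering and composite suffix", {
  call <- run_icp_case("icp.46,XY,der(13;14)(q10;q10),+14",
                       simulation_config(seed = 59))
  expect_equal(call$icp_string,
               "icp.46,XY,der(13;14)(q10;q10),+14[cp20]")
  call <- run_icp_case("46,XX", simulation_config(seed = 59))
  expect_equal(call$icp_string, "icp.46,XX[cp20]")
})
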