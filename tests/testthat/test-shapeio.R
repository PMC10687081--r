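test_that("read_tps applies the scale and the missing-landmark convention", {
  f <- write_fixture(c("LM=2", "0 0", "3 4", "SCALE=2.0"), name = "a_C.tps")
  cfgs <- read_tps(f)
  expect_length(cfgs, 1L)
  expect_equal(cfgs[[1]]$landmarks, matrix(c(0, 6, 0, 8), 2, 2))
  expect_equal(cfgs[[1]]$scale, 2)
  expect_false(cfgs[[1]]$unscaled)
  expect_equal(cfgs[[1]]$structure, "cephalon")

  # scale equivariance: doubling SCALE doubles the coordinates exactly
  f2 <- write_fixture(c("LM=2", "0 0", "3 4", "SCALE=4.0"), name = "b_C.tps")
  expect_identical(read_tps(f2)[[1]]$landmarks, 2 * cfgs[[1]]$landmarks)

  # no SCALE line: unscaled flag, raw coordinates kept
  f3 <- write_fixture(c("LM=1", "3 4"), name = "c_C.tps")
  expect_true(read_tps(f3)[[1]]$unscaled)

  # both-negative landmark is missing under the toggle, kept without it
  f4 <- write_fixture(c("LM=1", "-1 -1"), name = "d_C.tps")
  expect_true(read_tps(f4, missing_as_negative = TRUE)[[1]]$missing)
  expect_false(read_tps(f4, missing_as_negative = FALSE)[[1]]$missing)
})

test_that("read_tps parses curves and multi-record files", {
  lines <- c("LM=2", "0 0", "1 1",
             "CURVES=2", "POINTS=3", "0 0", "1 0", "2 0",
             "POINTS=2", "5 5", "6 6",
             "ID=sp1", "SCALE=1",
             "LM=2", "2 2", "3 3", "ID=sp2")
  f <- write_fixture(lines, name = "multi_C.tps")
  cfgs <- read_tps(f)
  expect_length(cfgs, 2L)
  expect_equal(vapply(cfgs, `[[`, "", "specimen_id"), c("sp1", "sp2"))
  expect_length(cfgs[[1]]$curves, 2L)
  expect_equal(nrow(cfgs[[1]]$curves[[1]]), 3L)
  # parser never invents points
  expect_equal(nrow(cfgs[[1]]$landmarks) + sum(vapply(cfgs[[1]]$curves, nrow, 1L)),
               2L + 5L)
})

test_that("malformed tps files raise parse errors naming the position", {
  expect_error(read_tps(write_fixture(c("LM=3", "0 0", "1 1"),
                                      name = "short_C.tps")), ":")
  expect_error(read_tps(write_fixture(c("LM=1", "0 0", "CURVES=1",
                                        "POINTS=3", "0 0", "1 1", "ID=x"),
                                      name = "pts_C.tps")), "POINTS")
  expect_error(read_tps(write_fixture(c("XX=1", "0 0"), name = "kw_C.tps")),
               "LM=")
  expect_error(read_tps(file.path(tempdir(), "nope_C.tps")), "no such file")
})

test_that("tps writing round-trips coordinates, curves and missing flags", {
  cfg <- base_shape("cephalon")
  cfg$landmarks[9, ] <- NA
  cfg <- landmark_config("RT-1", "cephalon", cfg$landmarks, cfg$curves,
                         scale = 1)
  f <- file.path(tempdir(), "rt_C.tps")
  write_tps(list(cfg), f)
  back <- read_tps(f)[[1]]
  expect_equal(back$missing, cfg$missing)
  expect_equal(back$landmarks[!cfg$missing, ],
               cfg$landmarks[!cfg$missing, ], tolerance = 1e-9)
  expect_equal(names(back$curves), names(cfg$curves))
  for (nm in names(cfg$curves))
    expect_equal(back$curves[[nm]], cfg$curves[[nm]], tolerance = 1e-9)
  expect_equal(back$specimen_id, "RT-1")

  expect_error(write_tps(list(), f), "nothing to write")
  expect_error(write_tps(list(cfg, base_shape("pygidium")), f), "structure")
})

test_that("structure suffixes resolve case-insensitively on the last token", {
  expect_equal(resolve_structure_suffix("CEGH-UNC_7316_C.txt"),
               list(specimen_id = "CEGH-UNC_7316", structure = "cephalon"))
  expect_equal(resolve_structure_suffix("X_12_P.tps"),
               list(specimen_id = "X_12", structure = "pygidium"))
  expect_equal(resolve_structure_suffix("path/to/x_7_c.tps")$structure,
               "cephalon")
  expect_error(resolve_structure_suffix("X_12.tps"), "X_12")
})

test_that("stereomorph reader orders landmarks by template name", {
  cfg <- base_shape("cephalon")
  f <- file.path(tempdir(), "sm_full_C.txt")
  write_stereomorph(cfg, f)
  back <- read_stereomorph(f)
  expect_equal(nrow(back$landmarks), 16L)
  expect_length(back$curves, 4L)
  expect_equal(back$landmarks, cfg$landmarks, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(back$curves$glabella, cfg$curves$glabella, tolerance = 1e-9)

  # name order in the file does not matter; absent names become missing
  lines <- c("landmarks.pixel",
             sprintf("LM%d\t%g\t%g", c(5, 1, 2), c(9, 1, 2), c(9, 1, 2)))
  f2 <- write_fixture(lines, name = "sm_part_C.txt")
  part <- read_stereomorph(f2)
  expect_equal(part$landmarks[1, ], c(x = 1, y = 1), ignore_attr = TRUE)
  expect_equal(part$landmarks[5, ], c(9, 9), ignore_attr = TRUE)
  expect_equal(which(!part$missing), c(1L, 2L, 5L))
})

test_that("stereomorph scaling comes from a scaling block or a ruler", {
  mk <- function(extra, name) {
    write_fixture(c("landmarks.pixel", "LM1\t2\t0", "LM2\t0\t4", extra),
                  name = name)
  }
  plain <- read_stereomorph(mk(character(0), "sm_a_C.txt"))
  expect_true(plain$unscaled)
  scaled <- read_stereomorph(mk(c("scaling", "0.5"), "sm_b_C.txt"))
  expect_equal(scaled$landmarks[1:2, ][!scaled$missing[1:2], ],
               0.5 * plain$landmarks[1:2, ][!plain$missing[1:2], ])
  # ruler: 20 px spanning 10 units -> 0.5 units/px
  ruler <- read_stereomorph(mk(c("ruler.pixel", "r1\t0\t0", "r2\t0\t20",
                                 "ruler.interval", "10"), "sm_c_C.txt"))
  expect_equal(ruler$scale, 0.5)
  expect_warning(read_stereomorph(mk(c("mystery.block", "x\t1\t2"),
                                     "sm_d_C.txt")), "unknown block")
  expect_error(read_stereomorph(write_fixture(c("curves.pixel", "g\t0\t0"),
                                              name = "sm_e_C.txt")),
               "landmarks.pixel")
})

test_that("metadata reading collects violations instead of repairing", {
  doc <- list(
    GOOD_1 = meta_entry(),
    BAD_NO_SP = local({e <- meta_entry(); e$taxonomy$sp <- NULL; e}),
    BAD_LAT = meta_entry(lat = 123),
    BAD_STRUCT = local({
      e <- meta_entry()
      e$morphology$cephalon <- FALSE
      e
    })
  )
  f <- tempfile(fileext = ".yml")
  yaml::write_yaml(doc, f)
  recs <- read_metadata(f)
  expect_length(recs, 4L)
  expect_length(recs$GOOD_1$violations, 0L)
  expect_match(recs$BAD_NO_SP$violations, "taxonomy.sp", all = FALSE)
  expect_true("lat out of range" %in% recs$BAD_LAT$violations)
  expect_match(recs$BAD_STRUCT$violations, "no digitised structure",
               all = FALSE)
  viol <- attr(recs, "violations")
  expect_setequal(unique(viol$id), c("BAD_NO_SP", "BAD_LAT", "BAD_STRUCT"))

  dup <- tempfile(fileext = ".yml")
  writeLines(c("A:", "  ref_pic: x", "A:", "  ref_pic: y"), dup)
  expect_error(read_metadata(dup), "[Dd]uplicate")
})

test_that("references table enforces unique ids", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("ref_id,citation", "r1,Alpha 1999", "r2,Beta 2004"), f)
  expect_equal(nrow(read_references(f)), 2L)
  writeLines(c("ref_id,citation", "r1,Alpha 1999", "r1,Beta 2004"), f)
  expect_error(read_references(f), "duplicate")
})
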