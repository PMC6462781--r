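write_table1_csv <- function(path) {
  e <- assemble_experiment(table1_fixture())
  write_tidy_long(e, path)
}

test_that("tidy long reader parses values, nan markers and errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_table1_csv(path)
  pts <- read_tidy_long(path)
  expect_length(pts, 12)
  vals <- vapply(pts, function(p) p$value, numeric(1))
  expect_equal(sum(is.finite(vals)), 9)

  # header only -> empty list
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("trial_identifier,analyte_name,time_h,value,unit", p2)
  expect_length(read_tidy_long(p2), 0)

  # missing column named in the error
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_identifier,analyte_name,value,unit",
               "strain:A|media:M9,OD600,1,OD"), p3)
  expect_error(read_tidy_long(p3), "time_h")

  # unparseable time carries the row number
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_identifier,analyte_name,time_h,value,unit",
               "strain:A|media:M9,OD600,abc,1,OD"), p4)
  expect_error(read_tidy_long(p4), "row 1")
})

test_that("HPLC wide rows become one point per finite analyte cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,glucose,acetate",
               "strain:A|media:M9|rep:1|time:2,8.0,0.5",
               "strain:A|media:M9|rep:1|time:4,6.0,"), path)
  pts <- read_hplc_wide(path)
  expect_length(pts, 3)  # empty acetate cell skipped
  p1 <- pts[[1]]
  expect_equal(p1$identifier$sample_time, 2)
  expect_equal(p1$identifier$analyte_name, "glucose")
  expect_equal(p1$value, 8.0)

  # missing time: key -> row-level error
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,glucose", "strain:A|media:M9|rep:1,8.0"), p2)
  expect_error(read_hplc_wide(p2), "row 1")

  # no analyte columns -> format error
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample", "strain:A|time:1"), p3)
  expect_error(read_hplc_wide(p3), "analyte")
})

test_that("repeated injections of one sample average at assembly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,glucose",
               "strain:A|media:M9|rep:1|time:2,8.0",
               "strain:A|media:M9|rep:1|time:2,10.0"), path)
  expect_warning(e <- assemble_experiment(read_hplc_wide(path)), "averaged")
  expect_equal(e$replicates[[1]]$singles[[1]]$courses$glucose$values, 9.0)
})

test_that("plate matrix reader uses the layout and skips unknown wells", {
  layout_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,identifier",
               "A1,strain:A|media:M9|rep:1",
               "A2,strain:A|media:M9|rep:2"), layout_path)
  layout <- read_plate_layout(layout_path)

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A1,A2,C7",
               "0,0.05,0.06,0.1",
               "2,0.2,0.21,0.1",
               "4,0.8,0.79,0.1"), path)
  expect_warning(pts <- read_plate_matrix(path, layout), "C7")
  expect_length(pts, 6)
  expect_true(all(vapply(pts, function(p) p$identifier$analyte_name, "") ==
                    "OD600"))
  e <- assemble_experiment(pts)
  expect_length(e$replicates, 1)
  expect_length(e$replicates[[1]]$singles, 2)

  # time unit rescaling
  pts_min <- suppressWarnings(read_plate_matrix(path, layout,
                                                time_unit = "min"))
  expect_equal(pts_min[[3]]$identifier$sample_time, 2 / 60)

  # non-numeric time errors with its row; header-only file is empty
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A1", "x,0.1"), bad)
  expect_error(read_plate_matrix(bad, layout), "row 1")
  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("time,A1", hdr)
  expect_length(read_plate_matrix(hdr, layout), 0)

  # invalid well labels and unparseable layout identifiers are rejected
  badlay <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,identifier", "Z9,strain:A"), badlay)
  expect_error(read_plate_layout(badlay), "Z9")
  badlay2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,identifier", "A1,nocolon"), badlay2)
  expect_error(read_plate_layout(badlay2), "A1")
})

test_that("write -> read -> assemble is the identity on experiments", {
  g <- generate_experiment(synthetic_config(n_strains = 2, seed = 21,
                                            missing_frac = 0.15,
                                            blank_level = 0.05))
  e1 <- assemble_experiment(g$points, "roundtrip")
  path <- withr::local_tempfile(fileext = ".csv")
  n <- write_tidy_long(e1, path)
  expect_equal(n, n_time_points(e1))
  e2 <- assemble_experiment(read_tidy_long(path), "roundtrip")
  expect_equal(e2, e1)

  # Table 1 layout writes exactly 12 rows; empty experiment writes none
  p2 <- withr::local_tempfile(fileext = ".csv")
  expect_equal(write_tidy_long(assemble_experiment(table1_fixture()), p2), 12)
  p3 <- withr::local_tempfile(fileext = ".csv")
  expect_equal(write_tidy_long(assemble_experiment(list()), p3), 0)
  expect_length(read_tidy_long(p3), 0)
})
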