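test_that("peak lists parse, map columns, and drop malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,rt,intensity,group_id",
               "f1,100.1,5.0,1000,g1", "f2,101.1,5.0,500,g1",
               "f3,200.2,8.0,2000,g2", "f4,201.2,8.0,700,g2"), path)
  ft <- readPeaklist(path, "fragment_run")
  expect_s4_class(ft, "FeatureTable")
  expect_equal(nrow(features(ft)), 4L)
  expect_equal(sort(groupIds(ft)), c("g1", "g2"))
  expect_true(all(features(ft)$isotope_flag == "none"))

  # malformed m/z is dropped with a count, not fatal
  writeLines(c("feature_id,mz,rt,intensity,group_id",
               "f1,abc,5.0,1000,g1", "f2,101.1,5.0,500,g1"), path)
  expect_warning(ft2 <- readPeaklist(path, "fragment_run"),
                 "1 malformed row")
  expect_equal(nrow(features(ft2)), 1L)

  # arbitrary headers via columnMap parse identically
  writeLines(c("id,mass,rt_min,area,spec",
               "f1,100.1,5.0,1000,g1", "f3,200.2,8.0,2000,g2"), path)
  ft3 <- readPeaklist(path, "fragment_run",
                      columnMap = c(feature_id = "id", mz = "mass",
                                    rt = "rt_min", intensity = "area",
                                    group_id = "spec"))
  expect_equal(features(ft3)$mz, c(100.1, 200.2))

  # missing required column names the culprit
  writeLines(c("feature_id,mz,rt,intensity", "f1,100.1,5.0,1000"), path)
  expect_error(readPeaklist(path, "fragment_run"), "group_id")
  writeLines("feature_id,mz,rt,intensity,group_id", path)
  expect_error(readPeaklist(path, "fragment_run"), "empty")
})

test_that("a written feature table round-trips every numeric to full precision", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(feature_id = c("a", "b"),
                   mz = c(181.07066454, 209.10196460123),
                   rt = c(10.123456789, 11.987654321),
                   intensity = c(123456.789, 0.000123456789),
                   group_id = c("g1", "g1"))
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  back <- features(readPeaklist(path, "fragment_run"))
  expect_equal(back$mz, df$mz, tolerance = 1e-12)
  expect_equal(back$rt, df$rt, tolerance = 1e-12)
  expect_equal(back$intensity, df$intensity, tolerance = 1e-12)
})

test_that("RT standards read, sort, and reject crossing pairs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("10.00,10.06", "5.00,5.02"), path)
  std <- readRtStandards(path)
  expect_equal(rtPairs(std)$rt_fragment_run, c(5, 10))
  expect_equal(rtPairs(std)$rt_molion_run, c(5.02, 10.06))

  writeLines("5.00,5.02", path)
  expect_equal(nrow(rtPairs(readRtStandards(path))), 1L)

  writeLines(c("5.00,5.02", "10.00,4.00"), path)
  expect_error(readRtStandards(path), "crossing|increasing")
})

test_that("mzML round trip preserves scans and converts rt to minutes", {
  raw <- RawRun(scanTimes = c(10.00, 10.01, 10.02),
                scanPeaks = list(cbind(c(100, 200), c(10, 20)),
                                 cbind(150, 15),
                                 cbind(c(100, 300), c(5, 30))))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(raw, path)
  back <- readRawRun(path)
  expect_equal(nScans(back), 3L)
  expect_equal(scanTimes(back), scanTimes(raw), tolerance = 1e-9)
  expect_equal(scanPeaks(back)[[1]][, 1], c(100, 200), tolerance = 1e-9)
  expect_error(readRawRun(withr::local_tempfile(fileext = ".mzML")),
               "not found")
})

test_that("scan order is rt-sorted regardless of input order", {
  raw <- RawRun(scanTimes = c(12, 10, 11),
                scanPeaks = list(cbind(3, 1), cbind(1, 1), cbind(2, 1)))
  expect_equal(scanTimes(raw), c(10, 11, 12))
  expect_equal(vapply(scanPeaks(raw), function(p) p[1, 1], numeric(1)),
               c(1, 2, 3))
})

test_that("profile scans centroid to local maxima", {
  # triangle over 5 points -> single centroid at the apex
  tri <- cbind(mz = seq(100, 100.04, by = 0.01), intensity = c(1, 5, 9, 5, 1))
  cen <- centroidScan(tri)
  expect_equal(nrow(cen), 1L)
  expect_equal(unname(cen[1, 1]), 100.02)
  # two peaks separated by a valley
  two <- cbind(mz = 1:7, intensity = c(0, 4, 1, 0, 2, 6, 2))
  expect_equal(centroidScan(two)[, 1], c(2, 6))
  # empty scans are legal
  expect_equal(nrow(centroidScan(cbind(numeric(0), numeric(0)))), 0L)
})

test_that("result CSVs have stable order, Hill formulas, and a header-only empty form", {
  path <- withr::local_tempfile(fileext = ".csv")
  res <- data.frame(
    ei_group_id = c("g2", "g1", "g1"), rank = c(1L, 2L, 1L),
    candidate_mz = c(300.2, 181.07, 209.1), candidate_rt = c(8, 10, 10),
    assigned_formula = c(formulaToString(c(O = 6L, H = 12L, C = 6L)), "", "C9H13N"),
    probability_score = c(90, 10, 80), n_supporting_fragments = c(5L, 0L, 4L),
    adduct_evidence = c("+28.03130", "", "+28.03130;+40.03130"))
  writeResults(res, path)
  out <- read.csv(path)
  expect_equal(out$ei_group_id, c("g1", "g1", "g2"))
  expect_equal(out$rank, c(1L, 2L, 1L))
  expect_equal(out$assigned_formula[3], "C6H12O6")

  writeResults(res[0, ], path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^ei_group_id,")
})
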