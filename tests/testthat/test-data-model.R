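test_that("a toy CSV parses into records and circles, preserving zeros", {
  path <- write_toy_csv()
  d <- read_count_table(path)
  expect_s3_class(d, "survey_dataset")
  expect_equal(nrow(d$records), 3)
  expect_equal(nrow(d$circles), 1)
  expect_setequal(d$records$species, c("WEST", "CLARK", "UNID"))

  # a recorded zero is kept as a zero count, not dropped
  path2 <- write_toy_csv(count_values = c(0, 10, 20))
  d2 <- read_count_table(path2)
  expect_equal(d2$records$count[d2$records$species == "WEST"], 0)
})

test_that("invalid tables are rejected with informative errors", {
  path <- write_toy_csv(count_values = c(-2, 10, 20))
  expect_error(read_count_table(path), "negative")

  path <- write_toy_csv(count_values = c("abc", 10, 20))
  expect_error(read_count_table(path), "parse error.*count.*1")

  lines <- readLines(write_toy_csv())
  path <- tempfile(fileext = ".csv")
  writeLines(c(lines, lines[2]), path)  # duplicate (circle, year, species)
  expect_error(read_count_table(path), "duplicate")

  # effort of unknown hours is rejected, not silently imputed
  lines[2] <- sub(",40,0$", ",,0", lines[2])
  writeLines(lines, path)
  expect_error(read_count_table(path), "effort")

  expect_error(read_count_table(tempfile()), "not found")
})

test_that("a simulated dataset round-trips through CSV unchanged", {
  cfg <- simulation_config(region_names = c("a", "b"),
                           circles_per_region = c(2, 2),
                           region_intercepts = log(c(100, 20)),
                           region_trends = c(-0.02, 0.01),
                           years = 2000:2006, missing_probability = 0.2,
                           seed = 9)
  sim <- simulate_dataset(cfg)
  path <- tempfile(fileext = ".csv")
  write_count_table(sim$dataset, path)
  back <- read_count_table(path, year_range = c(2000, 2006))
  expect_equal(back$records, sim$dataset$records, tolerance = 1e-12)
  expect_equal(back$circles[order(back$circles$circle_id), ],
               sim$dataset$circles[order(sim$dataset$circles$circle_id), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$year_range, sim$dataset$year_range)
})

test_that("region assignment follows the coast-distance and latitude rules", {
  circ <- make_circles(c("nc", "int", "nc2", "ak", "salish", "outer",
                         "socal", "nint", "canv", "swint"),
                       latitude = c(37.5, 37.5, 37.5, 55, 48.5, 46,
                                    34, 45, 38, 33),
                       longitude = c(-122, -120, -122, -133, -122.8, -124.5,
                                     -118, -119, -119, -106),
                       coast_distance_km = c(30, 50, 49.99, 10, 5, 8,
                                             12, 200, NA, NA))
  out <- assign_region(circ)
  expect_equal(out$region[out$circle_id == "nc"], "Northern California Coast")
  # a centre exactly 50 km from the coast is interior
  expect_equal(out$region[out$circle_id == "int"], "Interior California/Nevada")
  expect_equal(out$region[out$circle_id == "nc2"], "Northern California Coast")
  expect_equal(out$region[out$circle_id == "ak"], "Alaska/North BC")
  expect_equal(out$region[out$circle_id == "salish"], "Salish Sea")
  expect_equal(out$region[out$circle_id == "outer"], "Outer Washington/Oregon Coast")
  expect_equal(out$region[out$circle_id == "socal"], "Southern California Coast")
  expect_equal(out$region[out$circle_id == "nint"], "Northern Interior")
  expect_equal(out$region[out$circle_id == "canv"], "Interior California/Nevada")
  expect_equal(out$region[out$circle_id == "swint"], "Southwestern Interior")

  # assignment is single-valued and total; an uncovered circle errors
  orphan <- make_circles("x", latitude = 30, longitude = -120,
                         coast_distance_km = 300)
  expect_error(assign_region(orphan), "x")
})

test_that("circle filtering applies the total and coverage thresholds at their boundaries", {
  years36 <- 1975:2010
  rec <- rbind(
    make_records("low", 1975:2010, count = c(9, rep(0, 35))),
    make_records("half", 1975:1992, count = 2),          # 18 of 36 years
    make_records("under", 1975:1991, count = 2),         # 17 of 36 years
    make_records("good", years36, count = 5))
  d <- survey_dataset(rec, make_circles(c("low", "half", "under", "good")),
                      year_range = c(1975, 2010))
  f <- filter_circles(d)
  expect_setequal(f$circles$circle_id, c("half", "good"))
  excl <- attr(f, "exclusions")
  expect_match(excl$reason[excl$circle_id == "low"], "total")
  expect_match(excl$reason[excl$circle_id == "under"], "coverage")

  # idempotent
  f2 <- filter_circles(f)
  expect_equal(f2$records, f$records)
  expect_equal(f2$circles, f$circles)

  # filtering everything is an explicit signal, not silent success
  expect_error(filter_circles(d, min_total = 1e6),
               class = "grebetrends_empty_filter")
})

test_that("unidentified counts are apportioned by the identified ratio and conserved", {
  d <- read_count_table(write_toy_csv())  # 90 WEST, 10 CLARK, 20 UNID
  out <- allocate_unidentified(d)
  expect_equal(out$records$count[out$records$species == "WEST"], 108)
  expect_equal(out$records$count[out$records$species == "CLARK"], 12)
  expect_false("UNID" %in% out$records$species)

  # nothing unidentified: records unchanged
  rec <- rbind(make_records("c1", 2000, "WEST", 5),
               make_records("c1", 2000, "CLARK", 3))
  d0 <- survey_dataset(rec, make_circles("c1"))
  expect_equal(allocate_unidentified(d0)$records, d0$records)
})

test_that("allocation falls back to region-year then region ratios, else warns", {
  circ <- make_circles(c("A", "B", "C", "Y1"), region = c("X", "X", "X", "Y"))
  rec <- rbind(
    make_records("A", 2000, "WEST", 19), make_records("A", 2000, "CLARK", 1),
    make_records("B", 2000, "UNID", 40),   # no identified birds on this count
    make_records("C", 2001, "UNID", 10),   # none in its region-year either
    make_records("Y1", 2000, "UNID", 7))   # none anywhere in region Y
  d <- survey_dataset(rec, circ)
  expect_warning(out <- allocate_unidentified(d), "unallocated")
  r <- out$records
  # region-year ratio 19/20 = 0.95
  expect_equal(r$count[r$circle_id == "B" & r$species == "WEST"], 38)
  expect_equal(r$count[r$circle_id == "B" & r$species == "CLARK"], 2)
  # region all-years ratio, fractional result conserved exactly
  expect_equal(r$count[r$circle_id == "C" & r$species == "WEST"], 9.5)
  expect_equal(r$count[r$circle_id == "C" & r$species == "CLARK"], 0.5)
  # nothing to lean on: left unallocated
  expect_equal(r$count[r$circle_id == "Y1" & r$species == "UNID"], 7)
})

test_that("allocation conserves every circle-year total on simulated data", {
  cfg <- simulation_config(region_names = c("a", "b"),
                           circles_per_region = c(3, 3),
                           region_intercepts = log(c(200, 50)),
                           region_trends = c(0, 0), years = 2000:2009,
                           unidentified_fraction = 0.3,
                           clark_fraction = c(0.1, 0.4), seed = 21)
  sim <- simulate_dataset(cfg)
  out <- allocate_unidentified(sim$dataset)
  tot_before <- tapply(sim$dataset$records$count,
                       paste(sim$dataset$records$circle_id, sim$dataset$records$year),
                       sum)
  tot_after <- tapply(out$records$count,
                      paste(out$records$circle_id, out$records$year), sum)
  expect_identical(names(tot_before), names(tot_after))
  expect_equal(as.numeric(tot_after), as.numeric(tot_before), tolerance = 0)
})

test_that("coverage summary bins circles by missing years", {
  # 163 circles: 50 complete, 54 missing 3, 28 missing 8, 31 missing 14
  n_miss <- rep(c(0, 3, 8, 14), c(50, 54, 28, 31))
  rec <- do.call(rbind, lapply(seq_along(n_miss), function(i)
    make_records(sprintf("c%03d", i), 1975:(2010 - n_miss[i]), count = 1)))
  d <- survey_dataset(rec, make_circles(sprintf("c%03d", seq_along(n_miss))),
                      year_range = c(1975, 2010))
  cs <- coverage_summary(d)
  expect_equal(cs$n_circles, c(50L, 54L, 28L, 31L, 0L))
  expect_equal(cs$percent[cs$bin == "0"], 30.7)
  expect_equal(sum(cs$percent), 100, tolerance = 0.3)

  # all circles complete
  rec <- rbind(make_records("a", 1975:2010), make_records("b", 1975:2010))
  d <- survey_dataset(rec, make_circles(c("a", "b")), c(1975, 2010))
  expect_equal(coverage_summary(d)$percent, c(100, 0, 0, 0, 0))

  # empty dataset
  empty <- survey_dataset(make_records(character(0), integer(0)),
                          make_circles(character(0)))
  expect_equal(coverage_summary(empty)$n_circles, rep(0L, 5))
})
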