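cfg_flat <- function(intercept, n_circles = 10, years = 2000:2009, trend = 0,
                     sigma_noise = 0, seed = 3, ...) {
  simulation_config(region_names = "r1", circles_per_region = n_circles,
                    region_intercepts = intercept, region_trends = trend,
                    years = years, boat_probability = 0, sigma_circle = 0,
                    sigma_year = 0, sigma_noise = sigma_noise,
                    effort_sdlog = 0, missing_probability = 0,
                    unidentified_fraction = 0, seed = seed, ...)
}

test_that("identical configurations generate identical datasets", {
  cfg <- default_config(seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$records, s2$dataset$records)
  expect_identical(s1$dataset$circles, s2$dataset$circles)
  expect_identical(s1$truth$records, s2$truth$records)

  s3 <- simulate_dataset(default_config(seed = 8))
  expect_false(identical(s1$dataset$records, s3$dataset$records))
})

test_that("enlarging one region leaves other regions' circles untouched", {
  base <- default_config(seed = 5)
  bigger <- default_config(seed = 5)
  bigger$circles_per_region[1] <- bigger$circles_per_region[1] + 3L
  s1 <- simulate_dataset(base)
  s2 <- simulate_dataset(bigger)
  other <- s1$dataset$circles$circle_id[s1$dataset$circles$region != "Salish Sea"]
  r1 <- s1$dataset$records[s1$dataset$records$circle_id %in% other, ]
  r2 <- s2$dataset$records[s2$dataset$records$circle_id %in% other, ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
})

test_that("with all variation off the counts are Poisson around exp(beta0)", {
  # 10,008 circle-years at constant mu = exp(log 20)
  sim <- simulate_dataset(cfg_flat(log(20), n_circles = 278, years = 1975:2010))
  counts <- tapply(sim$dataset$records$count,
                   paste(sim$dataset$records$circle_id, sim$dataset$records$year),
                   sum)
  n <- length(counts)
  expect_equal(n, 278 * 36)
  se <- sqrt(20 / n)
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("a log-linear trend gives the exact expected-count ratio between years", {
  sim <- simulate_dataset(cfg_flat(log(500), n_circles = 2, trend = log(0.9071)))
  tr <- sim$truth$records
  one <- tr[tr$circle_id == tr$circle_id[1], ]
  one <- one[order(one$year), ]
  ratios <- one$mu[-1] / one$mu[-nrow(one)]
  expect_equal(ratios, rep(0.9071, nrow(one) - 1), tolerance = 1e-12)
})

test_that("noise induces over-dispersion: variance exceeds the mean", {
  sim <- simulate_dataset(cfg_flat(log(30), n_circles = 200, sigma_noise = 0.5))
  counts <- sim$truth$records$total_count
  expect_gt(var(counts), 2 * mean(counts))
})

test_that("no genus-level records appear when the reporting rate is zero, and effort is positive", {
  sim <- simulate_dataset(default_config(seed = 3))
  expect_true(all(sim$dataset$records$effort_hours > 0))
  cfg <- default_config(seed = 3)
  cfg$unidentified_fraction <- 0
  sim0 <- simulate_dataset(cfg)
  expect_false("UNID" %in% sim0$dataset$records$species)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simulation_config(region_names = "a", circles_per_region = 1,
                                 region_intercepts = 1, region_trends = 0,
                                 sigma_noise = -0.1),
               "configuration error")
  expect_error(simulation_config(region_names = "a", circles_per_region = 1,
                                 region_intercepts = 1, region_trends = 0,
                                 missing_probability = 1.2),
               "configuration error")
  expect_error(simulation_config(region_names = "a", circles_per_region = 1,
                                 region_intercepts = 1, region_trends = 0,
                                 effort_p = 0),
               "configuration error")
  cfg <- default_config()
  cfg$region_trends <- cfg$region_trends[-1]
  expect_error(simulate_dataset(cfg), "configuration error")
})

test_that("the default scenario is valid and calibrated to realistic magnitudes", {
  cfg <- default_config()
  expect_s3_class(cfg, "simulation_config")
  expect_length(cfg$years, 36)
  expect_true(cfg$n_regions >= 3 && cfg$n_regions <= 8)
  # the steeply declining inshore-sea region sits near its observed mean count
  salish <- exp(cfg$region_intercepts[cfg$region_names == "Salish Sea"])
  expect_gt(salish / 934, 0.1)
  expect_lt(salish / 934, 10)
  # intercepts span two orders of magnitude across regions
  expect_gt(max(cfg$region_intercepts) - min(cfg$region_intercepts), log(50))
  expect_gt(cfg$missing_probability, 0)
  expect_lt(cfg$missing_probability, 0.5)

  # generated circles fall back onto their generating regions under the
  # default rule table
  sim <- simulate_dataset(cfg)
  reassigned <- assign_region(sim$dataset$circles, overwrite = TRUE)
  expect_identical(reassigned$region, sim$dataset$circles$region)
})
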