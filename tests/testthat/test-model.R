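# small single-region dataset with one genuinely missing survey
model_test_dataset <- function() {
  rec <- rbind(
    make_records("A", c(2000, 2001, 2003, 2004), count = c(12, 9, 14, 8),
                 effort_hours = c(30, 45, 50, 38), boat_used = c(0, 1, 0, 0)),
    make_records("B", 2000:2004, count = c(3, 5, 2, 4, 6),
                 effort_hours = c(60, 55, 40, 42, 44), boat_used = 0),
    make_records("C", 2000:2004, count = c(25, 30, 22, 28, 35),
                 effort_hours = c(35, 36, 37, 38, 39), boat_used = c(1, 1, 0, 0, 1)))
  survey_dataset(rec, make_circles(c("A", "B", "C"), region = "all"),
                 year_range = c(2000, 2004))
}

test_that("the linear predictor assembles every model term", {
  params <- list(beta0 = c(all = 1), beta1 = c(all = 0.1), beta2 = 0.5,
                 effort_B = 0, effort_p = 1,
                 circle_effects = c(A = 0), year_effects = c("2002" = 0),
                 zeta_m = 40, t_mid = 2000)
  rec <- list(year = 2002, effort_hours = 40, boat_used = 0)
  circ <- list(circle_id = "A", region = "all")
  # beta0 alone at centred time 0
  rec0 <- list(year = 2002, effort_hours = 40, boat_used = 0)
  params0 <- params; params0$beta1 <- c(all = 0); params0$year_effects <- c("2002" = 0)
  expect_equal(log_expected_count(rec0, circ, params0), 1)
  # beta0 + beta1 * 2 = 1.2
  expect_equal(log_expected_count(rec, circ, params), 1.2)

  # unknown region or circle is a lookup error
  expect_error(log_expected_count(rec, list(circle_id = "A", region = "nowhere"),
                                  params), "lookup error")
  expect_error(log_expected_count(rec, list(circle_id = "Z", region = "all"),
                                  params), "lookup error")
})

test_that("the linear predictor matches an independently coded sum of terms", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_params_1region(c("A", "B", "C"), 2000:2004, 1)
    rec <- list(year = sample(2000:2004, 1),
                effort_hours = runif(1, 20, 80),
                boat_used = rbinom(1, 1, 0.5))
    cid <- sample(c("A", "B", "C"), 1)
    params <- list(beta0 = c(all = p$beta0), beta1 = c(all = p$beta1),
                   beta2 = p$beta2, effort_B = p$effort_B, effort_p = p$effort_p,
                   circle_effects = p$circle_effects,
                   year_effects = p$year_effects,
                   noise = p$noise[1], zeta_m = 42, t_mid = 2002)
    manual <- p$beta0 + p$beta1 * (rec$year - 2002) + p$beta2 * rec$boat_used +
      p$circle_effects[[cid]] + p$year_effects[[as.character(rec$year)]] +
      p$effort_B * ((rec$effort_hours / 42)^p$effort_p - 1) / p$effort_p +
      p$noise[1]
    got <- log_expected_count(rec, list(circle_id = cid, region = "all"), params)
    expect_equal(got, manual, tolerance = 1e-12)
  }
})

make_lp_params <- function(d, seed = 7) {
  set.seed(seed)
  n_obs <- length(unique(paste(d$records$circle_id, d$records$year)))
  p <- random_params_1region(sort(unique(d$records$circle_id)),
                             d$year_range[1]:d$year_range[2], n_obs)
  list(oracle = p,
       pkg = list(beta0 = c(all = p$beta0), beta1 = c(all = p$beta1),
                  beta2 = p$beta2, effort_B = p$effort_B, effort_p = p$effort_p,
                  circle_effects = p$circle_effects,
                  year_effects = p$year_effects, noise = p$noise,
                  var_circle = p$var_circle, var_year = p$var_year,
                  var_noise = p$var_noise, var_B = p$var_B))
}

test_that("the log posterior matches direct summation and skips missing surveys", {
  d <- model_test_dataset()
  priors <- hyperpriors()
  for (seed in c(7, 8, 9)) {
    ps <- make_lp_params(d, seed)
    # observation order: circles sorted, years within circle
    obs <- d$records[order(d$records$circle_id, d$records$year), ]
    ref <- oracle_log_posterior_1region(
      counts = obs$count, years = obs$year, circle_ids = obs$circle_id,
      effort = obs$effort_hours, boat = obs$boat_used,
      year_span = d$year_range, params = ps$oracle, priors = priors)
    expect_equal(log_posterior(ps$pkg, d, priors), ref, tolerance = 1e-9)
  }
  # circle A's missing 2002 survey contributed nothing: only 14 Poisson terms
  # entered the sum above, which the oracle already encodes; a dataset that
  # never had the missing year at all gives the same value
  expect_equal(length(unique(paste(d$records$circle_id, d$records$year))), 14)
})

test_that("a zero count at log mu = 0 contributes exactly -1 to the likelihood", {
  rec <- rbind(make_records("A", 2000:2001, count = c(0, 3), effort_hours = 40),
               make_records("B", 2000:2001, count = c(1, 1), effort_hours = 40))
  d <- survey_dataset(rec, make_circles(c("A", "B"), region = "all"),
                      year_range = c(2000, 2001))
  base <- list(beta0 = c(all = 0), beta1 = c(all = 0), beta2 = 0,
               effort_B = 0, effort_p = 1,
               circle_effects = c(A = 0, B = 0),
               year_effects = c("2000" = 0, "2001" = 0),
               noise = rep(0, 4), var_circle = 1, var_year = 1,
               var_noise = 1, var_B = 1)
  lp0 <- log_posterior(base, d)
  # replace the zero count by a one: the Poisson term changes from
  # log dpois(0, 1) = -1 to log dpois(1, 1) = -1, i.e. not at all;
  # replacing it by a three changes it by log(1/3!)
  d3 <- d
  d3$records$count[d3$records$count == 0] <- 3
  expect_equal(log_posterior(base, d3) - lp0, -log(factorial(3)),
               tolerance = 1e-12)
  # the zero-count cell's own term is log dpois(0, 1) = -1 exactly:
  # removing that record removes -1 plus its noise density
  d_drop <- d
  d_drop$records <- d_drop$records[!(d_drop$records$circle_id == "A" &
                                       d_drop$records$year == 2000), ]
  base_drop <- base; base_drop$noise <- rep(0, 3)
  expect_equal(lp0 - log_posterior(base_drop, d_drop),
               -1 + dnorm(0, 0, 1, log = TRUE), tolerance = 1e-12)
})

test_that("constraint-violating parameters give -Inf, never an exception", {
  d <- model_test_dataset()
  ps <- make_lp_params(d)$pkg
  bad <- ps; bad$var_noise <- -1
  expect_identical(log_posterior(bad, d), -Inf)
  bad <- ps; bad$effort_p <- 0
  expect_identical(log_posterior(bad, d), -Inf)
  bad <- ps; bad$circle_effects <- ps$circle_effects + 1  # breaks sum-to-zero
  expect_identical(log_posterior(bad, d), -Inf)
  bad <- ps; bad$year_effects <- ps$year_effects + 0.5
  expect_identical(log_posterior(bad, d), -Inf)
  expect_true(is.finite(log_posterior(ps, d)))
})
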