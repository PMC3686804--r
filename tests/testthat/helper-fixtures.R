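# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

write_toy_csv <- function(path = tempfile(fileext = ".csv"),
                          count_values = c(90, 10, 20)) {
  lines <- c(
    "circle_id,latitude,longitude,coast_distance_km,year,species,count,effort_hours,boat_used",
    sprintf("c1,48.5,-123.0,5,2000,WEST,%s,40,0", count_values[1]),
    sprintf("c1,48.5,-123.0,5,2000,CLARK,%s,40,0", count_values[2]),
    sprintf("c1,48.5,-123.0,5,2000,UNID,%s,40,0", count_values[3]))
  writeLines(lines, path)
  path
}

make_records <- function(circle_id, year, species = "WEST", count = 1,
                         effort_hours = 40, boat_used = 0) {
  if (length(circle_id) == 0)
    return(data.frame(circle_id = character(0), year = integer(0),
                      species = character(0), count = numeric(0),
                      effort_hours = numeric(0), boat_used = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(circle_id = circle_id, year = year, species = species,
             count = count, effort_hours = effort_hours,
             boat_used = boat_used, stringsAsFactors = FALSE)
}

make_circles <- function(circle_id, latitude = 48, longitude = -123,
                         coast_distance_km = 5, region = NA_character_) {
  if (length(circle_id) == 0)
    return(data.frame(circle_id = character(0), latitude = numeric(0),
                      longitude = numeric(0), coast_distance_km = numeric(0),
                      region = character(0), stringsAsFactors = FALSE))
  data.frame(circle_id = circle_id, latitude = latitude, longitude = longitude,
             coast_distance_km = coast_distance_km, region = region,
             stringsAsFactors = FALSE)
}

# one shared small fitted model for the posterior-processing tests;
# built once per test run
.fixture_env <- new.env(parent = emptyenv())

small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    cfg <- single_region_config("Salish Sea", mean_count = 150,
                                annual_percent = -2, n_circles = 6, seed = 42)
    sim <- simulate_dataset(cfg)
    d <- allocate_unidentified(filter_circles(sim$dataset))
    .fixture_env$sim <- sim
    .fixture_env$fit <- fit(d, mcmc_config(burn_in = 800, n_samples = 800,
                                           seed = 42))
  }
  list(fit = .fixture_env$fit, sim = .fixture_env$sim)
}

# a hand-built two-chain fit-like object with degenerate (constant)
# posteriors, for exact-identity checks of the derived quantities
constant_fit <- function(a = log(10), beta1 = 0, years = 2000:2003,
                         latitude = 45) {
  Tn <- length(years)
  nd <- 20
  cols <- c("a", "beta1", paste0("yeff[", seq_len(Tn), "]"))
  m <- matrix(rep(c(a, beta1, rep(0, Tn)), each = nd), nrow = nd,
              dimnames = list(NULL, cols))
  samples <- coda::mcmc.list(coda::mcmc(m), coda::mcmc(m))
  agg <- list(region_names = "all",
              circles = data.frame(circle_id = "c1", latitude = latitude,
                                   region = "all", creg = 1, cidx = 1,
                                   stringsAsFactors = FALSE),
              years = years, t_mid = mean(range(years)), zeta_m = 40)
  structure(list(samples = samples, agg = agg, n_regions = 1,
                 mcmc = mcmc_config(n_samples = nd, seed = 1),
                 converged = TRUE),
            class = "cbc_fit")
}
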