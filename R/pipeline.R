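#' Pipeline run configuration
#'
#' Bundles every choice of an end-to-end analysis: the data source
#' (either an input CSV or a simulation scenario), filtering thresholds,
#' the region rule table, MCMC settings, priors, the centre-of-occurrence
#' comparison years, and the output directory.  The configuration is
#' serialized into the run manifest so that a finished run can be
#' reproduced exactly.
#'
#' @param scenario a [simulation_config], used when `input` is `NULL`
#' @param input optional path to a count-table CSV
#' @param out_dir output directory (created if absent)
#' @param min_total,min_coverage circle filtering thresholds
#' @param region_rules region rule table
#' @param mcmc an [mcmc_config]
#' @param priors a [hyperpriors]
#' @param centre_years two years for the range-shift comparison
#' @param allow_nonconverged continue past a non-converged fit?
#' @return object of class `run_config`
#' @export
run_config <- function(scenario = default_config(), input = NULL,
                       out_dir = tempfile("grebetrends_run_"),
                       min_total = 10, min_coverage = 0.5,
                       region_rules = default_region_rules(),
                       mcmc = mcmc_config(), priors = hyperpriors(),
                       centre_years = c(1980, 2010),
                       allow_nonconverged = FALSE) {
  structure(list(scenario = scenario, input = input, out_dir = out_dir,
                 min_total = min_total, min_coverage = min_coverage,
                 region_rules = region_rules, mcmc = mcmc, priors = priors,
                 centre_years = centre_years,
                 allow_nonconverged = allow_nonconverged),
            class = "run_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- data (simulate or read), region
#' assignment, circle filtering, species allocation, model fitting,
#' posterior predictive check, abundance indices and trends, and the
#' centre-of-occurrence shift -- writing every intermediate artifact
#' under `config$out_dir` and a `manifest.yaml` describing the run.
#' The pipeline halts after writing diagnostics if the fit has not
#' converged, unless `allow_nonconverged` is set.
#'
#' @param config a [run_config]
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), s, units = "secs")), 2)
    out
  }

  truth <- NULL
  dataset <- tick("data", {
    if (is.null(config$input)) {
      sim <- simulate_dataset(config$scenario)
      truth <- sim$truth
      write_truth_sidecar(truth, file.path(config$out_dir, "truth.csv"))
      stage_log("data", "simulated %d records in %d circles",
                nrow(sim$dataset$records), nrow(sim$dataset$circles))
      sim$dataset
    } else {
      d <- read_count_table(config$input)
      stage_log("data", "read %d records from %s", nrow(d$records), config$input)
      d
    }
  })
  write_count_table(dataset, file.path(config$out_dir, "dataset.csv"))

  dataset <- tick("regions", assign_region(dataset, config$region_rules))

  dataset <- tick("filter", {
    d <- filter_circles(dataset, config$min_total, config$min_coverage)
    excl <- attr(d, "exclusions")
    writeLines(
      if (nrow(excl) == 0) "no circles excluded"
      else sprintf("%s: total=%g, years_surveyed=%d (%s)", excl$circle_id,
                   excl$total, excl$years_surveyed, excl$reason),
      file.path(config$out_dir, "exclusions.txt"))
    stage_log("filter", "%d circles retained, %d excluded",
              nrow(d$circles), nrow(excl))
    d
  })

  dataset <- tick("allocate", allocate_unidentified(dataset))
  write_count_table(dataset, file.path(config$out_dir, "dataset_allocated.csv"))

  model_fit <- tick("fit", fit(dataset, config$mcmc, config$priors))
  diag_tab <- model_fit$diagnostics
  utils::write.csv(diag_tab[!grepl("^eta", diag_tab$parameter), ],
                   file.path(config$out_dir, "diagnostics.csv"), row.names = FALSE)
  stage_log("fit", "converged = %s (max R-hat %.3f)", model_fit$converged,
            max(diag_tab$rhat[!grepl("^eta", diag_tab$parameter)], na.rm = TRUE))
  if (!model_fit$converged && !config$allow_nonconverged)
    stop("pipeline halted at stage 'fit': chains have not converged ",
         "(diagnostics written to ", config$out_dir,
         "); rerun with longer chains or allow_nonconverged = TRUE",
         call. = FALSE)

  ppc <- tick("ppc", posterior_predictive_check(model_fit))
  utils::write.csv(ppc$pairs, file.path(config$out_dir, "ppc.csv"),
                   row.names = FALSE)
  stage_log("ppc", "Bayesian p-value %.3f", ppc$bayesian_p)

  derived <- tick("derived", {
    idx <- abundance_index(model_fit)
    trends <- geometric_mean_trend(model_fit)
    utils::write.csv(idx, file.path(config$out_dir, "indices.csv"), row.names = FALSE)
    utils::write.csv(trends, file.path(config$out_dir, "trends.csv"), row.names = FALSE)
    list(indices = idx, trends = trends)
  })

  shift <- tick("shift", {
    ys <- config$centre_years
    rc <- range_centre(model_fit)
    s <- range_shift(model_fit, ys[1], ys[2])
    utils::write.csv(rc, file.path(config$out_dir, "centres.csv"), row.names = FALSE)
    utils::write.csv(s, file.path(config$out_dir, "shift.csv"), row.names = FALSE)
    s
  })
  stage_log("shift", "centre %d: %.2f deg -> %d: %.2f deg (%.0f km)",
            shift$year_a, shift$latitude_a, shift$year_b, shift$latitude_b,
            shift$shift_km)

  manifest <- list(
    package_version = as.character(utils::packageVersion("grebetrends")),
    config = serialize_config(config),
    converged = model_fit$converged,
    bayesian_p = ppc$bayesian_p,
    trends = lapply(seq_len(nrow(derived$trends)), function(i)
      as.list(derived$trends[i, ])),
    shift_km = shift$shift_km,
    timings_seconds = timings,
    total_seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  # precision 17 makes every double round-trip exactly, so a manifest
  # re-run regenerates identical data
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"),
                   precision = 17L)
  invisible(manifest)
}

# run_config -> plain lists for YAML round-tripping
serialize_config <- function(config) {
  x <- unclass(config)
  x$scenario <- if (is.null(x$scenario)) NULL else {
    s <- unclass(x$scenario)
    s$region_geography <- as.list(s$region_geography)
    s
  }
  x$region_rules <- as.list(x$region_rules)
  x$mcmc <- unclass(x$mcmc)
  x$priors <- unclass(x$priors)
  x
}

#' Rebuild a run configuration from a manifest
#'
#' Reads the `manifest.yaml` written by [run_pipeline()] and
#' reconstitutes the `run_config`, so that re-running reproduces the
#' original outputs bit for bit (all randomness is keyed by the seeds
#' stored in the manifest).
#'
#' @param path path to a manifest YAML file
#' @param out_dir output directory for the re-run (defaults to the one
#'   recorded in the manifest)
#' @return a [run_config]
#' @export
read_manifest_config <- function(path, out_dir = NULL) {
  m <- yaml::read_yaml(path)
  cfg <- m$config
  scenario <- NULL
  if (!is.null(cfg$scenario)) {
    s <- cfg$scenario
    scenario <- simulation_config(
      region_names = s$region_names,
      circles_per_region = unlist(s$circles_per_region),
      region_intercepts = unlist(s$region_intercepts),
      region_trends = unlist(s$region_trends),
      years = unlist(s$years),
      boat_effect = s$boat_effect, boat_probability = s$boat_probability,
      sigma_circle = s$sigma_circle, sigma_year = s$sigma_year,
      sigma_noise = s$sigma_noise,
      effort_B = s$effort_B, effort_p = s$effort_p,
      effort_meanlog = s$effort_meanlog, effort_sdlog = s$effort_sdlog,
      missing_probability = s$missing_probability,
      unidentified_fraction = s$unidentified_fraction,
      clark_fraction = unlist(s$clark_fraction),
      region_geography = as.data.frame(s$region_geography,
                                       stringsAsFactors = FALSE),
      seed = s$seed)
  }
  run_config(
    scenario = scenario, input = cfg$input,
    out_dir = if (is.null(out_dir)) cfg$out_dir else out_dir,
    min_total = cfg$min_total, min_coverage = cfg$min_coverage,
    region_rules = as.data.frame(cfg$region_rules, stringsAsFactors = FALSE),
    mcmc = mcmc_config(cfg$mcmc$n_chains, cfg$mcmc$burn_in, cfg$mcmc$n_samples,
                       cfg$mcmc$thinning, cfg$mcmc$n_adapt, cfg$mcmc$seed),
    priors = hyperpriors(cfg$priors$coef_mean, cfg$priors$coef_var,
                         cfg$priors$prec_shape, cfg$priors$prec_scale,
                         cfg$priors$logp_mean, cfg$priors$logp_var),
    centre_years = unlist(cfg$centre_years),
    allow_nonconverged = isTRUE(cfg$allow_nonconverged))
}
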