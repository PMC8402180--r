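#' Read a run configuration
#'
#' A run configuration is a single YAML file with (all optional, defaults
#' shown by [default_run_config()]): `site` (latitude, ground_area), the
#' season calendar (`sprouting`, `harvest`), the three parameter blocks
#' (`photosynthesis`, `respiration`, `balance`), input file paths
#' (`weather`, `canopy`, `dm_obs`, `brix_obs` — omitted paths trigger
#' synthetic generation), `scenario_clusters`, and `seed`.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  cfg <- list(
    site = list(latitude = 43.668, ground_area = 3.6),
    sprouting = "2014-04-01",
    season_length = 165L,
    profile = "vsp",
    photosynthesis = list(pn_max = 1e-3, quantum_yield = 2.0, k = 0.55,
                          t_base = 10, t_opt = 27.5, t_ceiling = 45),
    respiration = list(r20_shoot = 1.0, r20_cluster = 1e-3,
                       growth_coeff = 5.0, ea = 51200),
    balance = list(co2_to_dm = 30 / 44, n_steps = 48L),
    weather = NULL, canopy = NULL, dm_obs = NULL, brix_obs = NULL,
    scenario_clusters = c(6, 12),
    seed = 1L
  )
  class(cfg) <- "run_config"
  cfg
}

config_params <- function(cfg) {
  carbon_params(
    photo = do.call(photosynthesis_params,
                    c(cfg$photosynthesis,
                      list(ground_area = cfg$site$ground_area))),
    resp = do.call(respiration_params, cfg$respiration),
    co2_to_dm = cfg$balance$co2_to_dm,
    n_steps = cfg$balance$n_steps
  )
}

#' Run the full simulation pipeline
#'
#' Executes weather -> canopy -> carbon balance -> evaluation -> sugar fit
#' -> cluster scenarios in order.  File paths in the configuration are read
#' with [read_weather()] / [read_canopy()]; any missing input is generated
#' synthetically from the configuration's seed and profile, so the default
#' configuration runs self-contained.  When `out_dir` is given, each result
#' table is written as CSV alongside a `run_metadata.yml` echoing the
#' resolved configuration and its digest; every output file embeds the
#' digest as a comment line, so re-runs with changed parameters are
#' distinguishable.
#'
#' @param config A `run_config` (from [read_run_config()] or
#'   [default_run_config()]).
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with `sim`, `gof`, `fit`, `scenarios`,
#'   `config`, `digest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  params <- stage("config", config_params(config))
  scfg <- synthetic_config(
    seed = config$seed, profile = config$profile,
    season_length = config$season_length,
    latitude = config$site$latitude,
    sprouting = as.Date(config$sprouting)
  )

  say("stage: weather")
  weather <- stage("weather", {
    if (is.null(config$weather)) generate_weather(scfg)
    else read_weather(config$weather, latitude = config$site$latitude)
  })
  say("stage: canopy")
  canopy_obs <- stage("canopy", {
    if (is.null(config$canopy)) generate_canopy(scfg)
    else read_canopy(config$canopy)
  })
  canopy <- stage("canopy", interpolate_canopy(
    canopy_obs, das_range = range(weather[["das"]] %||% (seq_len(nrow(weather)) - 1L))
  ))

  say("stage: simulate")
  sim <- stage("simulate", simulate_season(weather, canopy, params))

  obs <- NULL
  if (is.null(config$dm_obs) || is.null(config$brix_obs)) {
    obs <- stage("observations", generate_observations(scfg, weather, canopy, params))
  }
  dm_obs <- stage("observations", {
    if (is.null(config$dm_obs)) obs$dm_obs
    else tibble::as_tibble(utils::read.csv(config$dm_obs))
  })
  brix_obs <- stage("observations", {
    if (is.null(config$brix_obs)) obs$brix_obs
    else tibble::as_tibble(utils::read.csv(config$brix_obs))
  })

  say("stage: evaluate")
  gof <- stage("evaluate", {
    pred <- sim$dm_cumulative[match(dm_obs$das, sim$das)]
    evaluate_fit(dm_obs$dm, pred)
  })
  say("stage: fit-sugar")
  fit <- stage("fit-sugar", fit_brix_dm(brix_obs, sim))
  say("stage: scenario")
  scenarios <- stage("scenario", run_cluster_scenarios(
    weather, canopy, params, fit, config$scenario_clusters
  ))

  digest <- rlang::hash(config)
  result <- list(sim = sim, gof = gof, fit = fit, scenarios = scenarios,
                 config = config, digest = digest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stamped <- function(df, file) {
      path <- file.path(out_dir, file)
      con <- file(path, "w")
      writeLines(paste0("# config_digest: ", digest), con)
      utils::write.csv(as.data.frame(df), con, row.names = FALSE)
      close(con)
    }
    write_stamped(sim, "simulation.csv")
    write_stamped(tibble::as_tibble(unclass(gof)), "gof.csv")
    write_stamped(glance(fit), "sugar_fit.csv")
    write_stamped(scenarios, "scenarios.csv")
    meta <- list(config_digest = digest,
                 package_version = as.character(utils::packageVersion("vitisim")),
                 config = rapply(unclass(config), as.character,
                                 how = "replace"))
    yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yml"))
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
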