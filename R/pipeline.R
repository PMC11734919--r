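# End-to-end orchestration: simulate -> link -> sample -> fit -> split ->
# mortality, with per-stage logging and deterministic outputs.

#' Pipeline configuration
#'
#' Defaults match the main analysis: 25/50/75/100 km bands, ages 6-12
#' exposure, outcomes at 15-18, non-migrant filter on, weights on, SEs
#' clustered on the survey cluster.
#'
#' @param input_dir Directory with `events.csv`, `clusters.csv`,
#'   `respondents.csv`, `fractions.csv`; `NULL` to simulate instead.
#' @param sim A [sim_config()] used when `input_dir` is `NULL`.
#' @param bands Distance-band outer edges, km.
#' @param max_precision Coarsest event precision code retained.
#' @param variant Sample variant (see [assemble_sample()]).
#' @param age_window Outcome age window.
#' @param controls Control columns for the regressions.
#' @param mortality A [mortality_inputs()] or `NULL` to skip that stage.
#' @param out_dir Output directory for intermediate tables and the results
#'   bundle, or `NULL` to keep results in memory only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, sim = sim_config(),
                       bands = c(25, 50, 75, 100), max_precision = 3L,
                       variant = "main", age_window = c(15, 18),
                       controls = c("hh_size", "head_age", "head_female",
                                    "mother_in_hh", "wealth_index",
                                    "nightlight_age6", "rainfall_age6",
                                    "temperature_age6"),
                       mortality = NULL, out_dir = NULL) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes: simulate (or load) -> precision filter -> exposure linkage ->
#' sample assembly (female and male) -> main fixed-effects fit per sex and
#' the female-male contrast -> distance-band and age-specific fits ->
#' logistic no-education fit -> heterogeneity splits -> mortality
#' counterfactual (if configured).  Writes intermediates and a
#' machine-readable results bundle when `out_dir` is set.
#'
#' @param config A [run_config()].
#' @return List with all stage outputs and a `log` data.table of per-stage
#'   row counts.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stamp <- function(stage, n)
    log[[length(log) + 1L]] <<- data.table(stage = stage, rows = n)

  if (is.null(config$input_dir)) {
    world <- generate_world(config$sim)
  } else {
    world <- read_bundle(config$input_dir)
  }
  stamp("events", nrow(world$events))
  stamp("clusters", nrow(world$clusters))
  stamp("respondents", nrow(world$respondents))

  events <- filter_events_by_precision(world$events, config$max_precision)
  stamp("events_precise", nrow(events))

  profiles <- build_profiles(world$respondents, world$clusters, events,
                             config$bands)
  profiles <- classify_intensity(profiles)
  stamp("profiles", nrow(profiles))

  samples <- lapply(c(F = "F", M = "M"), function(s)
    assemble_sample(profiles, world$respondents, world$clusters,
                    world$fractions, sex = s, variant = config$variant,
                    events = events, age_window = config$age_window))
  stamp("sample_F", nrow(samples$F$data))
  stamp("sample_M", nrow(samples$M$data))

  fe_cols <- c("cluster_id", "fe_country_year", "fe_country_month")
  for (s in c("F", "M")) {
    samples[[s]]$data[, fe_country_year := paste(country, birth_year)]
    samples[[s]]$data[, fe_country_month := paste(country, birth_month)]
  }

  spec_main <- edu_spec(outcome = "years_schooling", treatments = "exposed",
                        controls = config$controls, fixed_effects = fe_cols)
  fits <- list(
    female = fe_fit(samples$F, spec_main),
    male = fe_fit(samples$M, spec_main))
  contrast <- sex_contrast(spec_main, samples$F, samples$M)
  stamp("fit_main", fits$female$n_obs)

  spec_bands <- edu_spec(outcome = "years_schooling",
                         treatments = paste0("any_d", seq_along(config$bands)),
                         controls = config$controls, fixed_effects = fe_cols)
  fits$female_bands <- fe_fit(samples$F, spec_bands)

  spec_ages <- edu_spec(outcome = "years_schooling",
                        treatments = paste0("exp_a", 6:12, "_d1"),
                        controls = config$controls, fixed_effects = fe_cols)
  fits$female_ages <- fe_fit(samples$F, spec_ages)

  dfl <- samples$F$data
  dfl[, no_education := as.integer(edu_category == "none")]
  spec_noedu <- edu_spec(outcome = "no_education",
                         treatments = paste0("exp_a", 6:12, "_d1"),
                         controls = config$controls,
                         fixed_effects = fe_cols, family = "logistic")
  fits$female_noedu <- tryCatch(fit_logistic(dfl, spec_noedu),
                                error = function(e) e)

  classification <- classify_locations(world$respondents, world$clusters,
                                       unique(samples$F$data$cluster_id))
  het <- lapply(c(urbanicity = "urbanicity",
                  wealth_quartile = "wealth_quartile",
                  gender_gap = "gender_gap", region = "region"),
                function(s) run_heterogeneity(samples$F, classification, s,
                                              spec_main))

  mort <- if (!is.null(config$mortality))
    counterfactual_deaths(config$mortality) else NULL

  result <- list(world = world, profiles = profiles, samples = samples,
                 fits = fits, contrast = contrast$contrast,
                 heterogeneity = het, mortality = mort,
                 log = rbindlist(log))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(world$events, file.path(config$out_dir, "events.csv"))
    write_table(world$clusters, file.path(config$out_dir, "clusters.csv"))
    write_table(world$respondents,
                file.path(config$out_dir, "respondents.csv"))
    write_table(profiles, file.path(config$out_dir, "profiles.csv"))
    write_table(samples$F$data, file.path(config$out_dir, "sample_F.csv"))
    write_table(samples$M$data, file.path(config$out_dir, "sample_M.csv"))
    bundle <- list(
      main = list(female = tidy_fit(fits$female),
                  male = tidy_fit(fits$male),
                  contrast = contrast$contrast),
      bands = tidy_fit(fits$female_bands),
      ages = tidy_fit(fits$female_ages),
      heterogeneity = lapply(het, `[[`, "results"),
      log = rbindlist(log))
    jsonlite::write_json(bundle, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  result
}
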