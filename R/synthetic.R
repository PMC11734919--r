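# Synthetic DHS/UCDP-like microdata with planted effects.
#
# The generator builds a small multi-country world: survey clusters scattered
# over longitude strips (one strip per country), a subset of clusters acting
# as conflict hotspots around which violent events are placed with Gaussian
# spatial scatter, and respondents whose years of schooling follow an
# additive fixed-effects model with a planted, sex-specific conflict-exposure
# effect.  Exposure truth is computed from the *true* (un-jittered) cluster
# coordinates; released coordinates are displaced like DHS GPS data (uniform
# angle, uniform distance up to a per-stratum maximum).

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic world.  Defaults
#' emulate the study conditions of the analysis the package implements:
#' a planted female effect of -0.38 years of schooling for conflict
#' exposure within 25 km during ages 6-12, no male effect, an exposure
#' rate among respondents near 21%, heavy-tailed casualty counts, and DHS
#' jitter of up to 2 km (urban) / 5 km (rural).
#'
#' @param n_countries Number of countries (longitude strips).
#' @param n_clusters_per_country Survey clusters per country.
#' @param n_admin2_per_country Admin-2 units per country (clusters assigned
#'   by latitude).
#' @param respondents_per_cluster Respondents sampled per cluster.
#' @param birth_year_range Inclusive birth-year interval `c(lo, hi)`.
#' @param survey_year Calendar year of the (single) survey per country.
#' @param event_rate Expected events per hotspot-year (Poisson).
#' @param hotspot_fraction Fraction of clusters that are conflict hotspots.
#' @param hotspot_scatter_km SD of the Gaussian spatial scatter of events
#'   around their hotspot, km.
#' @param casualty_mean,casualty_dispersion Mean and dispersion (negative
#'   binomial `size`) of the casualty count law; counts are shifted so the
#'   minimum is 1.
#' @param beta_female,beta_male Planted any-exposure effects on years of
#'   schooling.
#' @param beta_age_female Optional length-7 vector of age-specific effects
#'   (ages 6-12) replacing the scalar female effect.
#' @param beta_new_female,beta_recurring_female Optional length-7 vectors of
#'   age-specific effects for new vs recurring exposure; when supplied they
#'   take precedence over `beta_age_female` and `beta_female`.
#' @param effect_multiplier_urban Multiplier applied to the planted effect in
#'   urban clusters (1 = homogeneous).
#' @param sigma_cluster,sigma_country_year,sigma_month,sigma_noise SDs of the
#'   cluster, country-by-birth-year and country-by-birth-month fixed effects
#'   and the idiosyncratic error, in years of schooling.
#' @param baseline_schooling Grand mean of latent schooling, years.
#' @param covariate_effects Named numeric vector of linear covariate effects
#'   on schooling.
#' @param nonmigrant_fraction Fraction of respondents whose residence history
#'   satisfies the lived-here-since-age-6 condition.
#' @param always_fraction Among non-migrants, fraction answering ALWAYS.
#' @param urban_fraction Fraction of urban clusters.
#' @param jitter_km_urban,jitter_km_rural Maximum released-coordinate
#'   displacement, km.
#' @param p_none_base Baseline probability of the no-education category.
#' @param or_none_age6 Planted odds ratio of exposure at age 6 on having no
#'   education.
#' @param binary_outcomes Named list of `c(base, or)` pairs: baseline
#'   probability and planted any-exposure odds ratio for each generated
#'   binary outcome.
#' @param precision_fine_share Share of events carrying a precision code
#'   fine enough for 25 km analysis (codes 1-3); the rest get codes 4-6.
#' @param seed Master integer seed; per-component streams (clusters, events,
#'   population, jitter) are derived from it deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_countries = 3L,
                       n_clusters_per_country = 60L,
                       n_admin2_per_country = 8L,
                       respondents_per_cluster = 25L,
                       birth_year_range = c(1966L, 2000L),
                       survey_year = 2015L,
                       event_rate = 0.6,
                       hotspot_fraction = 0.15,
                       hotspot_scatter_km = 15,
                       casualty_mean = 6,
                       casualty_dispersion = 0.5,
                       beta_female = -0.38,
                       beta_male = 0,
                       beta_age_female = NULL,
                       beta_new_female = NULL,
                       beta_recurring_female = NULL,
                       effect_multiplier_urban = 1,
                       sigma_cluster = 1.0,
                       sigma_country_year = 0.5,
                       sigma_month = 0.1,
                       sigma_noise = 2.0,
                       baseline_schooling = 6.5,
                       covariate_effects = c(wealth_index = 0.3,
                                             hh_size = -0.02,
                                             head_age = 0.005,
                                             head_female = 0.1,
                                             mother_in_hh = 0.2,
                                             nightlight_age6 = 0.15,
                                             rainfall_age6 = 2e-4,
                                             temperature_age6 = -0.01),
                       nonmigrant_fraction = 0.7,
                       always_fraction = 0.3,
                       urban_fraction = 0.35,
                       jitter_km_urban = 2,
                       jitter_km_rural = 5,
                       p_none_base = 0.08,
                       or_none_age6 = 1.87,
                       binary_outcomes = list(
                         ever_married = c(base = 0.15, or = 1.2),
                         mother_alive = c(base = 0.92, or = 0.9),
                         father_alive = c(base = 0.85, or = 0.85),
                         attending_school = c(base = 0.5, or = 1.0)),
                       precision_fine_share = 0.76,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_countries", "n_clusters_per_country", "n_admin2_per_country",
              "respondents_per_cluster")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1)
      stop(nm, " must be a count >= 1", call. = FALSE)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  sds <- c("sigma_cluster", "sigma_country_year", "sigma_month", "sigma_noise")
  if (any(unlist(cfg[sds]) < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  if (hotspot_fraction < 0 || hotspot_fraction > 1)
    stop("hotspot_fraction must be in [0, 1]", call. = FALSE)
  if (event_rate < 0) stop("event_rate must be >= 0", call. = FALSE)
  if (length(birth_year_range) != 2L ||
      birth_year_range[1] > birth_year_range[2])
    stop("birth_year_range must be an ordered pair", call. = FALSE)
  if (birth_year_range[2] > survey_year)
    stop("birth years after the survey year are impossible", call. = FALSE)
  for (v in c("beta_age_female", "beta_new_female", "beta_recurring_female"))
    if (!is.null(cfg[[v]]) && length(cfg[[v]]) != 7L)
      stop(v, " must have length 7 (ages 6-12)", call. = FALSE)
  cfg$birth_year_range <- as.integer(birth_year_range)
  cfg$survey_year <- as.integer(survey_year)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Deterministic per-component stream seeds from the master seed.
stream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("clusters", "events", "population", "jitter")
  s
}

# Calendar years over which school-age exposure can occur (including the
# age-5 year, needed for recurrence at age 6).
exposure_year_span <- function(config) {
  c(config$birth_year_range[1] + 5L, config$birth_year_range[2] + 12L)
}

# World geometry: one longitude strip of 3 degrees per country, latitudes
# in [-5, 5].  True coordinates; jitter applied later.
make_clusters <- function(config) {
  ss <- stream_seeds(config$seed)
  set.seed(ss[["clusters"]])
  n <- config$n_countries * config$n_clusters_per_country
  country <- rep(sprintf("C%02d", seq_len(config$n_countries)),
                 each = config$n_clusters_per_country)
  strip <- rep(seq_len(config$n_countries) - 1L,
               each = config$n_clusters_per_country)
  lat <- runif(n, -5, 5)
  lon <- 10 + strip * 3 + runif(n, 0.1, 2.9)
  urban <- as.integer(runif(n) < config$urban_fraction)
  cl <- data.table(
    cluster_id = sprintf("%s-L%04d", country, seq_len(n)),
    country = country,
    latitude = lat,
    longitude = lon,
    urban = urban,
    survey_year = config$survey_year,
    survey_id = paste0(country, "-S1"))
  # admin2 by latitude bins within country
  cl[, admin2 := paste0(country, "-A",
                        as.integer(cut(latitude,
                                       breaks = config$n_admin2_per_country)) ),
     by = country]
  setcolorder(cl, c("cluster_id", "country", "admin2", "latitude",
                    "longitude", "urban", "survey_year", "survey_id"))
  cl
}

#' Generate synthetic violent events
#'
#' Places events around a random subset of hotspot clusters with Gaussian
#' spatial scatter; event years cover the schooling-exposure span implied by
#' the birth-year range, counts per hotspot-year are Poisson, casualty
#' counts follow a shifted negative binomial (minimum 1, heavy tail), and
#' each event carries an ordinal geographic-precision code.
#'
#' @param config A [sim_config()].
#' @return `data.table` with columns `event_id`, `latitude`, `longitude`,
#'   `year`, `casualties`, `precision_code`.
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  empty <- data.table(event_id = character(), latitude = numeric(),
                      longitude = numeric(), year = integer(),
                      casualties = integer(), precision_code = integer())
  if (config$event_rate == 0) return(empty)
  clusters <- make_clusters(config)
  n_hot <- round(config$hotspot_fraction * nrow(clusters))
  if (n_hot == 0)
    stop("degenerate config: event_rate > 0 but no hotspot clusters ",
         "(hotspot_fraction too small)", call. = FALSE)
  ss <- stream_seeds(config$seed)
  set.seed(ss[["events"]])
  hot <- clusters[sample.int(nrow(clusters), n_hot)]
  span <- exposure_year_span(config)
  years <- span[1]:span[2]
  counts <- rpois(n_hot * length(years), config$event_rate)
  if (sum(counts) == 0L) return(empty)
  hot_idx <- rep(rep(seq_len(n_hot), times = length(years)), counts)
  yr <- rep(rep(years, each = n_hot), counts)
  n <- length(yr)
  # Gaussian scatter in km -> degrees
  dx <- rnorm(n, 0, config$hotspot_scatter_km)
  dy <- rnorm(n, 0, config$hotspot_scatter_km)
  lat0 <- hot$latitude[hot_idx]
  lat <- pmin(pmax(lat0 + dy / 111.32, -90), 90)
  lon <- hot$longitude[hot_idx] + dx / (111.32 * cos(lat0 * pi / 180))
  cas <- 1L + rnbinom(n, size = config$casualty_dispersion,
                      mu = config$casualty_mean - 1)
  fine <- runif(n) < config$precision_fine_share
  prec <- ifelse(fine, sample(1:3, n, replace = TRUE, prob = c(.5, .3, .2)),
                 sample(4:6, n, replace = TRUE, prob = c(.6, .3, .1)))
  out <- data.table(event_id = sprintf("E%06d", seq_len(n)),
                    latitude = lat, longitude = lon,
                    year = as.integer(yr), casualties = as.integer(cas),
                    precision_code = as.integer(prec))
  setorder(out, year, event_id)
  out[, event_id := sprintf("E%06d", .I)]
  out[]
}

# Planted treatment effect per respondent, given exposure profile columns.
planted_effect <- function(config, prof, sex_is_f, urban) {
  ages <- 6:12
  eff_f <- if (!is.null(config$beta_new_female) ||
               !is.null(config$beta_recurring_female)) {
    bn <- config$beta_new_female %||% rep(0, 7)
    br <- config$beta_recurring_female %||% rep(0, 7)
    v <- rep(0, nrow(prof))
    for (j in seq_along(ages)) {
      lab <- prof[[paste0("recur_a", ages[j])]]
      v <- v + bn[j] * (lab == "new") + br[j] * (lab == "recurring")
    }
    v
  } else if (!is.null(config$beta_age_female)) {
    v <- rep(0, nrow(prof))
    for (j in seq_along(ages))
      v <- v + config$beta_age_female[j] * prof[[paste0("exp_a", ages[j], "_d1")]]
    v
  } else {
    config$beta_female * prof$exposed
  }
  eff_m <- config$beta_male * prof$exposed
  mult <- ifelse(urban == 1L, config$effect_multiplier_urban, 1)
  ifelse(sex_is_f, eff_f, eff_m) * mult
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the synthetic survey population
#'
#' Builds clusters (with jittered released coordinates), respondents and the
#' planted-truth sidecar.  Latent schooling is the sum of a baseline, cluster
#' fixed effects, country-by-birth-year and country-by-birth-month fixed
#' effects, covariate effects, the planted sex-specific exposure effect and
#' Gaussian noise, truncated to `[0, 25]` and rounded half-up to whole
#' years.  The exposure indicator entering the truth is computed from the
#' true (un-jittered) coordinates using precision-filtered events, exactly
#' as the downstream linkage would with perfect location data.
#'
#' @param config A [sim_config()].
#' @param events Event table from [generate_events()] under the same config.
#' @return List with elements `clusters`, `respondents`, `fractions` (the
#'   sampled-population-fraction table used for weighting) and `truth`
#'   (planted parameters and the realized exposure rate).  The cluster table
#'   carries the true coordinates as attribute `true_coords`.
#' @export
generate_population <- function(config, events) {
  stopifnot(inherits(config, "sim_config"))
  clusters <- make_clusters(config)
  ss <- stream_seeds(config$seed)
  set.seed(ss[["population"]])

  nC <- nrow(clusters)
  npc <- config$respondents_per_cluster
  n <- nC * npc
  byr <- config$birth_year_range

  ci <- rep(seq_len(nC), each = npc)  # cluster index per respondent
  resp <- data.table(
    respondent_id = sprintf("R%06d", seq_len(n)),
    cluster_id = clusters$cluster_id[ci],
    country = clusters$country[ci],
    urban = clusters$urban[ci],
    survey_year = clusters$survey_year[ci])
  resp[, sex := fifelse(runif(n) < 0.5, "F", "M")]
  yrs <- byr[1]:byr[2]
  resp[, birth_year := yrs[sample.int(length(yrs), n, replace = TRUE)]]
  resp[, birth_month := sample.int(12L, n, replace = TRUE)]
  resp[, age_at_survey := survey_year - birth_year]
  if (any(resp$age_at_survey < 0))
    stop("impossible age/birth-year combination", call. = FALSE)

  # residence history: non-migrants satisfy years_in_residence >= age - 6
  nonmig <- runif(n) < config$nonmigrant_fraction
  always <- nonmig & runif(n) < config$always_fraction
  age <- resp$age_at_survey
  yr_res <- integer(n)
  lo_nm <- pmax(age - 6L, 0L)
  yr_res[nonmig] <- lo_nm[nonmig] +
    floor(runif(sum(nonmig)) * (age[nonmig] - lo_nm[nonmig] + 1L))
  mig <- !nonmig
  hi_m <- pmax(age - 7L, 0L)
  yr_res[mig] <- floor(runif(sum(mig)) * (hi_m[mig] + 1L))
  # movers with age <= 6 cannot violate the condition; force them migrant by
  # residence 0 which still passes when age - 6 <= 0 -- acceptable edge.
  resp[, years_in_residence := fifelse(always, "ALWAYS", as.character(yr_res))]

  # covariates
  z_wealth <- rnorm(nC, 0, 1)  # cluster wealth propensity, urban tilt
  z_wealth <- z_wealth + 0.8 * clusters$urban
  resp[, wealth_index := 1L + rbinom(n, 4L, plogis(z_wealth[ci] +
                                                     rnorm(n, 0, 0.5) - 0.2))]
  resp[, hh_size := 1L + rpois(n, 5)]
  resp[, head_age := pmin(pmax(round(rnorm(n, 45, 10)), 18L), 90L)]
  resp[, head_female := as.integer(runif(n) < 0.25)]
  resp[, mother_in_hh := as.integer(runif(n) < 0.8)]
  resp[, nightlight_age6 := round(exp(rnorm(n, 0, 0.6)) *
                                    (1 + clusters$urban[ci]), 3)]
  resp[, rainfall_age6 := round(rnorm(n, 1000, 200), 1)]
  resp[, temperature_age6 := round(rnorm(n, 25, 2), 2)]
  resp[, survey_weight := round(rlnorm(n, 0, 0.25), 6)]

  # exposure truth from true coordinates, precision-filtered events
  ev_fine <- filter_events_by_precision(events, 3L)
  prof <- build_profiles(resp[, .(respondent_id, cluster_id, birth_year)],
                         clusters, ev_fine, bands = 25)
  prof <- prof[resp$respondent_id, on = "respondent_id"]

  # fixed-effect components
  gamma <- rnorm(nC, 0, config$sigma_cluster)
  cy <- CJ(country = unique(clusters$country), birth_year = byr[1]:byr[2])
  cy[, lambda := rnorm(.N, 0, config$sigma_country_year)]
  cm <- CJ(country = unique(clusters$country), birth_month = 1:12)
  cm[, tau := rnorm(.N, 0, config$sigma_month)]
  resp[, gamma_cl := gamma[ci]]
  resp[, lambda := cy$lambda[match(paste(country, birth_year),
                                   paste(cy$country, cy$birth_year))]]
  resp[, tau := cm$tau[match(paste(country, birth_month),
                             paste(cm$country, cm$birth_month))]]

  ce <- config$covariate_effects
  xb <- rep(0, n)
  for (nm in names(ce)) xb <- xb + ce[[nm]] * as.numeric(resp[[nm]])
  eff <- planted_effect(config, prof, resp$sex == "F", resp$urban)
  latent <- config$baseline_schooling + resp$gamma_cl + resp$lambda +
    resp$tau + xb + eff + rnorm(n, 0, config$sigma_noise)
  years <- floor(pmin(pmax(latent, 0), 25) + 0.5)

  # no-education category via its own logistic channel (exposure at age 6)
  eta_none <- qlogis(config$p_none_base) +
    log(config$or_none_age6) * prof$exp_a6_d1 + 0.3 * resp$gamma_cl
  none <- runif(n) < plogis(eta_none)
  years[none] <- 0
  resp[, years_schooling := as.integer(years)]
  resp[, edu_category := fcase(
    years == 0, "none",
    years <= 5, "incomplete_primary",
    years == 6, "complete_primary",
    years <= 11, "incomplete_secondary",
    years == 12, "complete_secondary",
    default = "higher")]

  for (nm in names(config$binary_outcomes)) {
    par <- config$binary_outcomes[[nm]]
    eta <- qlogis(par[["base"]]) + log(par[["or"]]) * prof$exposed +
      0.3 * resp$gamma_cl
    resp[, (nm) := as.integer(runif(n) < plogis(eta))]
  }

  resp[, c("gamma_cl", "lambda", "tau", "urban", "country",
           "survey_year") := NULL]
  setcolorder(resp, c("respondent_id", "cluster_id", "sex", "birth_year",
                      "birth_month", "age_at_survey", "years_in_residence",
                      "years_schooling", "edu_category", "hh_size",
                      "head_age", "head_female", "mother_in_hh",
                      "wealth_index", "ever_married", "mother_alive",
                      "father_alive", "attending_school", "nightlight_age6",
                      "rainfall_age6", "temperature_age6", "survey_weight"))

  # released (jittered) coordinates
  released <- jitter_clusters(clusters, config)

  # population fractions interviewed per (country, survey, sex)
  frac <- CJ(country = unique(clusters$country), sex = c("F", "M"))
  frac[, survey_id := paste0(country, "-S1")]
  frac[, fraction := round(runif(.N, 0.3, 0.9), 4)]
  setcolorder(frac, c("country", "survey_id", "sex", "fraction"))

  truth <- list(
    beta_by_sex = list(F = config$beta_female, M = config$beta_male),
    beta_age_female = config$beta_age_female,
    beta_new_female = config$beta_new_female,
    beta_recurring_female = config$beta_recurring_female,
    heterogeneity_multipliers = list(
      urban = config$effect_multiplier_urban, rural = 1),
    or_none_age6 = config$or_none_age6,
    exposure_rate = mean(prof$exposed),
    seed = config$seed)
  stopifnot(truth$exposure_rate >= 0, truth$exposure_rate <= 1)

  list(clusters = released, respondents = resp, fractions = frac,
       truth = truth)
}

#' Apply DHS-style release jitter to true cluster coordinates
#'
#' Displaces each cluster by a uniform angle and a uniform distance up to
#' the per-stratum maximum (urban/rural).  Uses the jitter stream derived
#' from the master seed, so the same world can be re-released under
#' different jitter magnitudes with paired displacement draws (the unit
#' draws are identical; only the scale changes).
#'
#' @param clusters_true Cluster table with true coordinates.
#' @param config A [sim_config()] providing `jitter_km_urban`,
#'   `jitter_km_rural` and the master seed.
#' @return Cluster table with released coordinates; the true coordinates are
#'   attached as attribute `true_coords`.
#' @export
jitter_clusters <- function(clusters_true, config) {
  stopifnot(inherits(config, "sim_config"))
  clusters_true <- as.data.table(clusters_true)
  ss <- stream_seeds(config$seed)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(ss[["jitter"]])
  nC <- nrow(clusters_true)
  jmax <- ifelse(clusters_true$urban == 1L, config$jitter_km_urban,
                 config$jitter_km_rural)
  ang <- runif(nC, 0, 2 * pi)
  dist <- runif(nC) * jmax
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  released <- copy(clusters_true)
  released[, latitude := latitude + dist * sin(ang) / 111.32]
  released[, longitude := longitude +
             dist * cos(ang) /
             (111.32 * cos(clusters_true$latitude * pi / 180))]
  setattr(released, "true_coords",
          clusters_true[, .(cluster_id, latitude, longitude)])
  released
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: events plus population under one config.
#'
#' @param config A [sim_config()].
#' @return List with `events`, `clusters`, `respondents`, `fractions`,
#'   `truth`.
#' @export
generate_world <- function(config) {
  events <- generate_events(config)
  pop <- generate_population(config, events)
  c(list(events = events), pop)
}

#' Write a synthetic world to delimited-text fixture files
#'
#' Writes `events.csv`, `clusters.csv`, `respondents.csv`, `fractions.csv`
#' and a `truth.json` sidecar with the planted parameters.  The output
#' directory must already exist; nothing is written otherwise.
#'
#' @param world Output of [generate_world()] (or a compatible list).
#' @param path Existing output directory.
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(world, path) {
  if (!dir.exists(path))
    stop("output directory does not exist: ", path, call. = FALSE)
  files <- c(events = file.path(path, "events.csv"),
             clusters = file.path(path, "clusters.csv"),
             respondents = file.path(path, "respondents.csv"),
             fractions = file.path(path, "fractions.csv"),
             truth = file.path(path, "truth.json"))
  fwrite(world$events, files[["events"]])
  fwrite(world$clusters, files[["clusters"]])
  fwrite(world$respondents, files[["respondents"]])
  fwrite(world$fractions, files[["fractions"]])
  jsonlite::write_json(world$truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}
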