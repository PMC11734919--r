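# Shared fixture builders.  All fixtures are generated in code.

library(data.table)

# Small world for module-level tests: quick but with real conflict contrast.
tiny_config <- function(seed = 1, hotspot_fraction = 0.2, ...) {
  sim_config(seed = seed, n_countries = 2, n_clusters_per_country = 25,
             respondents_per_cluster = 20, birth_year_range = c(1990, 2000),
             survey_year = 2015, hotspot_fraction = hotspot_fraction, ...)
}

# Study-scale world for parameter-recovery checks: every respondent is in
# the 15-18 outcome window (cohorts 1997-2000 surveyed in 2015), releases
# are un-jittered and the no-education channel is off, so the planted
# linear coefficient is exactly the estimand.  The hotspot share is kept at
# 0.2 so identifying variation is spread over many clusters, which the
# CR1 coverage check needs.
recovery_config <- function(seed, jitter = 0, ...) {
  sim_config(seed = seed, n_countries = 3, n_clusters_per_country = 250,
             respondents_per_cluster = 76, birth_year_range = c(1997, 2000),
             survey_year = 2015, hotspot_fraction = 0.2,
             jitter_km_urban = jitter, jitter_km_rural = jitter,
             p_none_base = 1e-6, or_none_age6 = 1, ...)
}

# Mid-size world dense enough to identify the main fit in module tests.
fit_config <- function(seed = 1, hotspot_fraction = 0.2, ...) {
  sim_config(seed = seed, n_countries = 2, n_clusters_per_country = 60,
             respondents_per_cluster = 40, birth_year_range = c(1997, 2000),
             survey_year = 2015, hotspot_fraction = hotspot_fraction,
             jitter_km_urban = 0, jitter_km_rural = 0,
             p_none_base = 1e-6, or_none_age6 = 1, ...)
}

default_controls <- c("hh_size", "head_age", "head_female", "mother_in_hh",
                      "wealth_index", "nightlight_age6", "rainfall_age6",
                      "temperature_age6")

# Link exposure, assemble one sex's main sample and attach FE columns.
make_sample <- function(world, sex = "F", respondents = NULL,
                        clusters = NULL, variant = "main") {
  if (is.null(clusters)) clusters <- world$clusters
  if (is.null(respondents)) respondents <- world$respondents
  ev <- filter_events_by_precision(world$events)
  prof <- build_profiles(respondents, clusters, ev)
  s <- assemble_sample(prof, respondents, clusters, world$fractions,
                       sex = sex, variant = variant, events = ev)
  s$data[, fe_cy := paste(country, birth_year)]
  s$data[, fe_cm := paste(country, birth_month)]
  s
}

main_spec <- function(treatments = "exposed", controls = default_controls,
                      family = "linear", outcome = "years_schooling") {
  edu_spec(outcome = outcome, treatments = treatments, controls = controls,
           fixed_effects = c("cluster_id", "fe_cy", "fe_cm"),
           weights = "w", cluster_se_on = "cluster_id", family = family)
}

random_linkage_fixture <- function(seed, n_cl, n_ev, n_resp) {
  set.seed(seed)
  cl <- data.table(cluster_id = sprintf("c%04d", seq_len(n_cl)),
                   country = "X", admin2 = "A",
                   latitude = runif(n_cl, -4, 4),
                   longitude = runif(n_cl, 8, 16), urban = 1L,
                   survey_year = 2015L, survey_id = "S")
  ev <- data.table(event_id = sprintf("E%04d", seq_len(n_ev)),
                   latitude = runif(n_ev, -4, 4),
                   longitude = runif(n_ev, 8, 16),
                   year = sample(1996:2012, n_ev, TRUE),
                   casualties = sample(1:30, n_ev, TRUE),
                   precision_code = 1L)
  rr <- data.table(respondent_id = sprintf("r%04d", seq_len(n_resp)),
                   cluster_id = sample(cl$cluster_id, n_resp, TRUE),
                   birth_year = sample(1990:2000, n_resp, TRUE))
  list(cl = cl, ev = ev, rr = rr)
}

# Random crossed-FE regression fixture (three dimensions, weights).
rand_fe_fixture <- function(seed, n = 200, n_g1 = 15, n_g2 = 6, n_g3 = 4,
                            p = 2) {
  set.seed(seed)
  d <- data.table(g1 = sample(paste0("a", 1:n_g1), n, TRUE),
                  g2 = sample(paste0("b", 1:n_g2), n, TRUE),
                  g3 = sample(paste0("c", 1:n_g3), n, TRUE),
                  w = runif(n, 0.5, 2))
  for (j in seq_len(p)) d[, paste0("x", j) := rnorm(n)]
  xb <- as.matrix(d[, paste0("x", 1:p), with = FALSE]) %*%
    seq(0.5, by = 0.3, length.out = p)
  d[, y := as.vector(xb) + rnorm(n) +
      rnorm(n_g1)[as.integer(factor(g1))] +
      rnorm(n_g2)[as.integer(factor(g2))]]
  d
}

# All-pairs linkage oracle for one respondent.
brute_profile <- function(rr_row, cl, ev, bands = c(25, 50, 75, 100)) {
  ci <- cl[cluster_id == rr_row$cluster_id]
  d <- haversine_km(ci$latitude, ci$longitude, ev$latitude, ev$longitude)
  byear <- rr_row$birth_year
  flags <- matrix(FALSE, 7, length(bands))
  for (a in 6:12) for (b in seq_along(bands)) {
    lo <- if (b == 1) -Inf else bands[b - 1]
    flags[a - 5, b] <- any(ev$year == byear + a & d <= bands[b] & d > lo)
  }
  in25 <- d <= 25 & ev$year %in% (byear + 6):(byear + 12)
  prev <- vapply(6:12, function(a)
    any(ev$year == byear + a - 1 & d <= 25), logical(1))
  list(flags = flags, n_events = sum(in25),
       total_casualties = sum(ev$casualties[in25]),
       n_years_violent = length(unique(ev$year[in25])),
       recur = ifelse(!flags[, 1], "none",
                      ifelse(prev, "recurring", "new")))
}

# One full recovery run; returns the named treatment row of the fit.
recover_beta <- function(seed, sex = "F", jitter = 0, treatments = "exposed",
                         controls = c("wealth_index", "mother_in_hh"),
                         config = NULL) {
  cfg <- if (is.null(config)) recovery_config(seed, jitter = jitter) else
    config
  world <- generate_world(cfg)
  s <- make_sample(world, sex = sex)
  fe_fit(s, main_spec(treatments = treatments, controls = controls))
}
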