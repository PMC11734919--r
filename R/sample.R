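# Eligibility filters and analysis-weight construction.

parse_residence <- function(x) {
  # returns list(always, years, asked); non-numeric non-ALWAYS codes -> NA
  x <- as.character(x)
  always <- !is.na(x) & x == "ALWAYS"
  yrs <- suppressWarnings(as.numeric(x))
  if (any(yrs < 0, na.rm = TRUE))
    stop("negative years_in_residence", call. = FALSE)
  list(always = always, years = yrs, asked = !is.na(x) & x != "")
}

#' Keep respondents who lived at the surveyed location since age 6
#'
#' Retains rows with `years_in_residence == "ALWAYS"` or with a numeric
#' residence duration of at least `age_at_survey - 6` years.  Rows with
#' missing or non-numeric other codes are excluded.
#'
#' @param respondents Respondent table.
#' @return Filtered table.
#' @export
filter_nonmigrants <- function(respondents) {
  respondents <- as.data.table(respondents)
  r <- parse_residence(respondents$years_in_residence)
  keep <- r$always |
    (!is.na(r$years) & r$years >= respondents$age_at_survey - 6)
  respondents[keep]
}

#' Keep respondents inside the outcome age window
#'
#' @param respondents Respondent table.
#' @param low,high Inclusive age bounds, default 15-18.
#' @export
filter_age_window <- function(respondents, low = 15, high = 18) {
  if (low > high) stop("low > high in age window", call. = FALSE)
  respondents <- as.data.table(respondents)
  respondents[age_at_survey >= low & age_at_survey <= high]
}

#' Build analysis weights
#'
#' Analysis weight = survey weight times the inverse of the fraction of the
#' relevant population interviewed for the respondent's (country, survey,
#' sex) stratum, normalized to mean 1 over the sample.
#'
#' @param respondents Respondent table with `survey_weight`, `country`,
#'   `survey_id`, `sex` columns.
#' @param fractions Table `country, survey_id, sex, fraction`.
#' @return Numeric weight vector aligned with `respondents` rows.
#' @export
build_weights <- function(respondents, fractions) {
  respondents <- as.data.table(respondents)
  fractions <- as.data.table(fractions)
  if (any(fractions$fraction <= 0))
    stop("population fractions must be > 0", call. = FALSE)
  key <- paste(respondents$country, respondents$survey_id, respondents$sex)
  fkey <- paste(fractions$country, fractions$survey_id, fractions$sex)
  fr <- fractions$fraction[match(key, fkey)]
  if (any(is.na(fr)))
    stop("missing population fraction for strata: ",
         paste(head(unique(key[is.na(fr)]), 10), collapse = "; "),
         call. = FALSE)
  w <- respondents$survey_weight / fr
  w / mean(w)
}

#' Assemble an analysis sample
#'
#' Joins respondents to their exposure profiles and cluster attributes,
#' applies the eligibility filters of the named variant, builds normalized
#' analysis weights, and records a per-filter attrition table.
#'
#' Variants: `main` (ages 15-18, non-migrants), `no_residence_filter`,
#' `movers_only` (complement of the residence condition among rows where it
#' was asked), `no_recent_conflict` (main, additionally dropping clusters
#' with a band-1 event in the survey year or the year before; requires
#' `events`), `fifty_km` (same rows as main; downstream fits should use the
#' `exposed_50` treatment column).
#'
#' @param profiles Output of [build_profiles()].
#' @param respondents Respondent table.
#' @param clusters Cluster table (for country/admin2/urban attributes).
#' @param fractions Population-fraction table for [build_weights()].
#' @param sex `"F"` or `"M"`.
#' @param variant Sample variant name.
#' @param events Precision-filtered events; needed for `no_recent_conflict`.
#' @param age_window Inclusive outcome age bounds.
#' @return An object of class `edu_sample`: list with `data` (joined
#'   `data.table` including weight column `w`), `sex`, `variant`,
#'   `attrition`.
#' @export
assemble_sample <- function(profiles, respondents, clusters, fractions,
                            sex = c("F", "M"),
                            variant = c("main", "no_residence_filter",
                                        "movers_only", "no_recent_conflict",
                                        "fifty_km"),
                            events = NULL, age_window = c(15, 18)) {
  sex <- match.arg(sex)
  variant <- match.arg(variant)
  respondents <- as.data.table(respondents)
  clusters <- as.data.table(clusters)
  profiles <- as.data.table(profiles)

  attr_tab <- list()
  note <- function(step, n_in, n_out)
    attr_tab[[length(attr_tab) + 1L]] <<-
      data.table(filter = step, n_in = n_in, n_out = n_out)

  sex_keep <- which(respondents[["sex"]] == sex)
  d <- respondents[sex_keep]
  note("sex", nrow(respondents), nrow(d))

  n0 <- nrow(d)
  d <- filter_age_window(d, age_window[1], age_window[2])
  note("age_window", n0, nrow(d))

  r <- parse_residence(d$years_in_residence)
  nonmig <- r$always | (!is.na(r$years) & r$years >= d$age_at_survey - 6)
  n0 <- nrow(d)
  if (variant %in% c("main", "no_recent_conflict", "fifty_km")) {
    d <- d[r$asked & nonmig]
    note("residence_since_age6", n0, nrow(d))
  } else if (variant == "movers_only") {
    d <- d[r$asked & !nonmig]
    note("movers_only", n0, nrow(d))
  } else {
    note("residence_filter_skipped", n0, nrow(d))
  }

  cl_cols <- clusters[, .(cluster_id, country, admin2, urban, survey_year,
                          survey_id)]
  d <- cl_cols[d, on = "cluster_id"]

  if (variant == "no_recent_conflict") {
    if (is.null(events))
      stop("variant no_recent_conflict requires the events table",
           call. = FALSE)
    ebt <- event_band_table(clusters, events)
    n0 <- nrow(d)
    # band-1 events in survey_year or survey_year - 1
    b1 <- ebt[band == 1L]
    recent <- unique(b1[d[, .(cluster_id, y1 = survey_year - 1L,
                              y2 = survey_year)],
                        on = .(cluster_id, year >= y1, year <= y2),
                        nomatch = NULL]$cluster_id)
    d <- d[!cluster_id %in% recent]
    note("no_recent_conflict", n0, nrow(d))
  }

  n0 <- nrow(d)
  d <- profiles[d, on = "respondent_id", nomatch = NULL]
  note("profile_join", n0, nrow(d))
  if ("i.cluster_id" %in% names(d)) d[, i.cluster_id := NULL]
  if ("i.birth_year" %in% names(d)) d[, i.birth_year := NULL]

  if (nrow(d)) d[, w := build_weights(d, fractions)]
  else d[, w := numeric(0)]

  structure(list(data = d[], sex = sex, variant = variant,
                 attrition = rbindlist(attr_tab)),
            class = "edu_sample")
}

#' @export
print.edu_sample <- function(x, ...) {
  cat(sprintf("Analysis sample: sex %s, variant %s, %d rows\n",
              x$sex, x$variant, nrow(x$data)))
  print(x$attrition)
  invisible(x)
}
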