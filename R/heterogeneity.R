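# Location classifications and subset regressions.

# Quartile assignment with inverse-ECDF (type 1) cut points; boundary values
# go to the lower quartile.
quartile_assign <- function(x) {
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  1L + (x > qs[1]) + (x > qs[2]) + (x > qs[3])
}

#' Cluster wealth quartiles
#'
#' Computes the mean of the chosen wealth measure over all sampled
#' households (respondent rows) of each cluster and splits clusters into
#' quartiles at the 25/50/75 empirical percentiles over the clusters in the
#' regression sample.
#'
#' @param respondents Respondent table (all sampled rows, any age).
#' @param clusters Optional vector of cluster ids defining the regression
#'   sample; defaults to every cluster present.
#' @param source `"dhs_index"` (the 1-5 wealth index),
#'   `"nightlight_age6"`, `"nightlight_survey_year"`, or any column name.
#' @return `data.table` with `cluster_id`, `value` (cluster mean),
#'   `wealth_quartile`.
#' @export
wealth_quartiles <- function(respondents, clusters = NULL,
                             source = "dhs_index") {
  respondents <- as.data.table(respondents)
  col <- switch(source,
                dhs_index = "wealth_index",
                nightlight_age6 = "nightlight_age6",
                nightlight_survey_year = "nightlight_survey_year",
                source)
  if (!col %in% names(respondents))
    stop("wealth source column not found: ", col, call. = FALSE)
  d <- respondents
  if (!is.null(clusters)) d <- d[cluster_id %in% clusters]
  m <- d[, .(value = mean(as.numeric(get(col)))), by = cluster_id]
  if (nrow(m) < 4L) stop("need at least 4 clusters for quartiles",
                         call. = FALSE)
  if (length(unique(m$value)) == 1L)
    warning("all cluster means equal; every cluster in quartile 1")
  m[, wealth_quartile := quartile_assign(value)]
  setkey(m, cluster_id)
  m[]
}

#' Cluster quartiles of older-female educational attainment
#'
#' For each cluster, the mean years of schooling among sampled women aged
#' 40-50 (approximately the mothers' generation) defines a baseline
#' education level; clusters are split into quartiles.  Clusters with no
#' such women are unclassified and excluded from this split.
#'
#' @inheritParams wealth_quartiles
#' @return `data.table` with `cluster_id`, `value`, `education_quartile`.
#' @export
education_quartiles <- function(respondents, clusters = NULL) {
  respondents <- as.data.table(respondents)
  d <- respondents[sex == "F" & age_at_survey >= 40 & age_at_survey <= 50]
  if (!is.null(clusters)) d <- d[cluster_id %in% clusters]
  if (nrow(d) == 0L)
    stop("no cluster has females aged 40-50; nothing classifiable",
         call. = FALSE)
  m <- d[, .(value = mean(years_schooling)), by = cluster_id]
  if (nrow(m) < 4L) stop("need at least 4 classifiable clusters",
                         call. = FALSE)
  m[, education_quartile := quartile_assign(value)]
  setkey(m, cluster_id)
  m[]
}

#' Gender-gap split of clusters
#'
#' The gender gap of an admin-2 unit is mean male minus mean female years
#' of schooling over all sampled respondents.  Clusters are labelled
#' `larger` or `smaller` according to whether their admin-2 gap exceeds the
#' median gap over admin-2 units.
#'
#' @param respondents Respondent table (all sampled rows).
#' @param cluster_admin2 `data.table` mapping `cluster_id` to `admin2`.
#' @return List: `clusters` (`cluster_id`, `admin2`, `gap`, `gender_gap`
#'   label), `admin2` (per-unit gaps), `median_gap`.
#' @export
gender_gap_split <- function(respondents, cluster_admin2) {
  respondents <- as.data.table(respondents)
  cluster_admin2 <- as.data.table(cluster_admin2)
  d <- cluster_admin2[respondents, on = "cluster_id", nomatch = NULL]
  gaps <- d[, .(
    gap = mean(years_schooling[sex == "M"]) -
      mean(years_schooling[sex == "F"]),
    n_m = sum(sex == "M"), n_f = sum(sex == "F")), by = admin2]
  bad <- gaps[n_m == 0L | n_f == 0L]
  if (nrow(bad))
    message("admin2 units lacking one sex left unclassified: ",
            paste(bad$admin2, collapse = ", "))
  gaps <- gaps[n_m > 0L & n_f > 0L]
  med <- median(gaps$gap)
  if (all(gaps$gap == med))
    warning("all admin2 gender gaps equal; split is degenerate")
  gaps[, gender_gap := fifelse(gap > med, "larger", "smaller")]
  cl <- unique(cluster_admin2[, .(cluster_id, admin2)])
  cl <- gaps[, .(admin2, gap, gender_gap)][cl, on = "admin2"]
  list(clusters = cl[], admin2 = gaps[], median_gap = med)
}

#' Combined location classification
#'
#' Convenience constructor assembling urban/rural, wealth and education
#' quartiles, the wealth-versus-education comparison and the gender-gap
#' split into one per-cluster table.
#'
#' @param respondents All sampled respondents.
#' @param clusters Cluster table (`cluster_id`, `admin2`, `urban`,
#'   `country`).
#' @param sample_clusters Optional cluster ids restricting quartile cut
#'   points to the regression sample.
#' @param region_map Optional `data.table(country, region)`; defaults to a
#'   synthetic three-region assignment by country order.
#' @return `data.table` keyed by `cluster_id` with columns `urbanicity`,
#'   `wealth_quartile`, `education_quartile`, `wealth_vs_education`,
#'   `gender_gap`, `region`.
#' @export
classify_locations <- function(respondents, clusters,
                               sample_clusters = NULL, region_map = NULL) {
  clusters <- as.data.table(clusters)
  out <- clusters[, .(cluster_id, country, admin2,
                      urbanicity = fifelse(urban == 1L, "urban", "rural"))]
  wq <- wealth_quartiles(respondents, sample_clusters)
  out[wq, wealth_quartile := i.wealth_quartile, on = "cluster_id"]
  eq <- tryCatch(education_quartiles(respondents, sample_clusters),
                 error = function(e) NULL)
  if (!is.null(eq))
    out[eq, education_quartile := i.education_quartile, on = "cluster_id"]
  else out[, education_quartile := NA_integer_]
  out[, wealth_vs_education :=
        fifelse(!is.na(wealth_quartile) & !is.na(education_quartile),
                fifelse(wealth_quartile > education_quartile,
                        "wealth>edu", "edu>=wealth"), NA_character_)]
  gg <- gender_gap_split(respondents, clusters[, .(cluster_id, admin2)])
  out[gg$clusters, gender_gap := i.gender_gap, on = "cluster_id"]
  if (is.null(region_map)) {
    cn <- sort(unique(clusters$country))
    region_map <- data.table(
      country = cn,
      region = c("Central SSA", "Eastern SSA",
                 "Western SSA")[(seq_along(cn) - 1L) %% 3L + 1L])
  }
  out[as.data.table(region_map), region := i.region, on = "country"]
  setkey(out, cluster_id)
  out[]
}

#' Subset regressions across a location classification
#'
#' Refits the base specification on the subsample of each class level,
#' renormalizing analysis weights within the subset.  Levels whose subset
#' is too small to identify the treatment are skipped with a log record.
#'
#' @param sample An `edu_sample` (or data.table with weight column).
#' @param classification `data.table` with `cluster_id` and the column named
#'   by `split`.
#' @param split Name of the classification column to split on.
#' @param base_spec The [edu_spec()] to refit per level.
#' @return List: `results` (tidy `data.table` of treatment estimates per
#'   class), `fits` (named list of `edu_fit`), `skipped`.
#' @export
run_heterogeneity <- function(sample, classification, split, base_spec) {
  dat <- if (inherits(sample, "edu_sample")) sample$data else
    as.data.table(sample)
  classification <- as.data.table(classification)
  if (!split %in% names(classification))
    stop("classification lacks column ", split, call. = FALSE)
  lab <- classification[[split]][match(dat$cluster_id,
                                       classification$cluster_id)]
  levels <- sort(unique(lab[!is.na(lab)]))
  fits <- list(); skipped <- character(); rows <- list()
  for (lv in levels) {
    sub <- dat[which(lab == lv)]
    if (!is.null(base_spec$weights))
      sub[[base_spec$weights]] <-
        sub[[base_spec$weights]] / mean(sub[[base_spec$weights]])
    fit <- tryCatch(fe_fit(sub, base_spec), error = function(e) e)
    if (inherits(fit, "error") ||
        !any(base_spec$treatments %in% names(fit$coefficients))) {
      skipped <- c(skipped, as.character(lv))
      next
    }
    fits[[as.character(lv)]] <- fit
    tr <- intersect(base_spec$treatments, names(fit$coefficients))
    rows[[as.character(lv)]] <- data.table(
      class = as.character(lv), term = tr,
      estimate = unname(fit$coefficients[tr]),
      se = unname(fit$se[tr]),
      ci_low = unname(fit$ci_low[tr]), ci_high = unname(fit$ci_high[tr]),
      p = unname(fit$p[tr]), n_obs = fit$n_obs)
  }
  list(results = rbindlist(rows), fits = fits, skipped = skipped)
}
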