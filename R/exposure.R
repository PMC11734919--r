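# Spatial-temporal linkage of violent events to survey clusters.

# Mean earth radius (IUGG), km.
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km.  All four
#' arguments are recycled to a common length, so the function computes
#' element-wise distances between two sets of points.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.2 km along the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  # guard tiny negative / >1 from roundoff
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude out of range [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

# Cross-distance matrix (n1 x n2), km.  Used for cluster-event linkage;
# sizes here are moderate (hundreds by thousands) so a dense matrix is fine.
dist_cross_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  sdlat <- sin(outer(p2, p1, "-") / 2)^2           # n2 x n1
  sdlon <- sin(outer(lon2 * rad, lon1 * rad, "-") / 2)^2
  a <- t(sdlat + outer(cos(p2), cos(p1)) * sdlon)  # n1 x n2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Keep only events located precisely enough for a 25 km analysis
#'
#' UCDP-style geographic precision codes are ordinal, smaller = finer.
#' Events with a code above `max_precision` are judged not locatable to a
#' 25 km radius and are discarded.
#'
#' @param events Event table with a `precision_code` column.
#' @param max_precision Largest (coarsest) code retained; default 3.
#' @return The filtered event table.
#' @export
filter_events_by_precision <- function(events, max_precision = 3) {
  events <- as.data.table(events)
  pc <- events$precision_code
  bad <- which(is.na(pc) | pc != as.integer(pc) | pc < 1)
  if (length(bad)) {
    stop("unknown precision code in rows: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  events[pc <= max_precision]
}

# Aggregate events into (cluster, year, band) cells.  Bands are a disc
# (<= bands[1]) followed by half-open rings (bands[d-1], bands[d]].
# Returns a keyed data.table: cluster_id, year, band, n_events, casualties.
event_band_table <- function(clusters, events, bands = c(25, 50, 75, 100)) {
  stopifnot(length(bands) >= 1, !is.unsorted(bands), all(bands > 0))
  clusters <- as.data.table(clusters)
  events <- as.data.table(events)
  empty <- data.table(cluster_id = character(), year = integer(),
                      band = integer(), n_events = integer(),
                      casualties = integer())
  setkey(empty, cluster_id, year, band)
  if (nrow(events) == 0L || nrow(clusters) == 0L) return(empty)

  pairs <- vector("list", ceiling(nrow(clusters) / 200L))
  idx <- split(seq_len(nrow(clusters)),
               ceiling(seq_len(nrow(clusters)) / 200L))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    d <- dist_cross_km(clusters$latitude[i], clusters$longitude[i],
                       events$latitude, events$longitude)
    hit <- which(d <= bands[length(bands)], arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    dk <- d[hit]
    band <- rep(1L, length(dk))
    for (b in seq_len(length(bands) - 1L))
      band <- band + as.integer(dk > bands[b])
    pairs[[k]] <- data.table(
      cluster_id = clusters$cluster_id[i[hit[, 1L]]],
      year = events$year[hit[, 2L]],
      band = band,
      casualties = events$casualties[hit[, 2L]])
  }
  pairs <- rbindlist(pairs)
  if (nrow(pairs) == 0L) return(empty)
  out <- pairs[, .(n_events = .N, casualties = sum(casualties)),
               by = .(cluster_id, year, band)]
  setkey(out, cluster_id, year, band)
  out
}

#' Yearly exposure flags for one cluster and birth cohort
#'
#' For each age 6-12 and each distance band, flags whether at least one
#' event occurred within the band of the cluster in the calendar year the
#' child turned that age.  Band 1 is the disc `<= bands[1]` km; later bands
#' are half-open rings `(bands[d-1], bands[d]]`.
#'
#' @param cluster One-row cluster table (needs `latitude`, `longitude`).
#' @param events Precision-filtered event table.
#' @param birth_year Birth year of the cohort.
#' @param bands Outer band edges in km, default `c(25, 50, 75, 100)`.
#' @return Logical matrix, rows ages 6-12, columns bands.
#' @export
yearly_exposure <- function(cluster, events, birth_year,
                            bands = c(25, 50, 75, 100)) {
  cluster <- as.data.table(cluster)
  stopifnot(nrow(cluster) == 1L)
  ebt <- event_band_table(cluster, events, bands)
  ages <- 6:12
  out <- matrix(FALSE, length(ages), length(bands),
                dimnames = list(paste0("age", ages),
                                paste0("band", seq_along(bands))))
  if (nrow(ebt)) {
    for (a in ages) {
      rows <- ebt[year == birth_year + a]
      if (nrow(rows)) out[a - 5L, rows$band] <- TRUE
    }
  }
  out
}

#' Exposure profiles for a respondent table
#'
#' Links every respondent to the events near their cluster and summarises
#' exposure over the primary-school window (ages 6-12): per-age, per-band
#' flags; any-exposure flags per band; event/casualty/violent-year counts
#' within band 1; and a new/recurring label per exposed age (an exposed age
#' is `recurring` when a band-1 event also occurred in the preceding
#' calendar year -- evaluated even at age 6, using the age-5 year).
#'
#' @param respondents Respondent table (`respondent_id`, `cluster_id`,
#'   `birth_year`).
#' @param clusters Cluster table with released coordinates.
#' @param events Precision-filtered event table.
#' @param bands Outer band edges in km.
#' @return A `data.table` with one row per respondent: columns
#'   `exp_a{6..12}_d{band}`, `any_d{band}`, `exposed` (= `any_d1`),
#'   `exposed_50` (exposure within the 50 km disc), `n_events`,
#'   `total_casualties`, `n_years_violent`, `recur_a{6..12}`.
#' @export
build_profiles <- function(respondents, clusters, events,
                           bands = c(25, 50, 75, 100)) {
  respondents <- as.data.table(respondents)
  clusters <- as.data.table(clusters)
  missing_cl <- setdiff(respondents$cluster_id, clusters$cluster_id)
  if (length(missing_cl))
    stop("respondents reference unknown cluster_id: ",
         paste(head(missing_cl, 10), collapse = ", "), call. = FALSE)

  ebt <- event_band_table(clusters, events, bands)
  ages <- 6:12
  nb <- length(bands)

  prof <- respondents[, .(respondent_id, cluster_id, birth_year)]

  # one wide (cluster, year) cell table: per-band hit flags + band-1 counts
  cells <- dcast(ebt, cluster_id + year ~ band,
                 value.var = list("n_events", "casualties"), fill = 0L)
  hitcols <- paste0("hit", seq_len(nb))
  for (b in seq_len(nb)) {
    nc <- paste0("n_events_", b)
    cells[, (hitcols[b]) := if (nc %in% names(cells)) get(nc) > 0L else FALSE]
  }
  if (!"n_events_1" %in% names(cells)) cells[, n_events_1 := 0L]
  if (!"casualties_1" %in% names(cells)) cells[, casualties_1 := 0L]
  cells <- cells[, c("cluster_id", "year", "n_events_1", "casualties_1",
                     hitcols), with = FALSE]
  setkey(cells, cluster_id, year)

  # respondent x age (5..12; age 5 only feeds recurrence) single join
  nR <- nrow(prof)
  long <- prof[rep(seq_len(nR), each = 8L)]
  long[, age := rep(5:12, times = nR)]
  long[, year := birth_year + age]
  long <- cells[long, on = c("cluster_id", "year")]
  for (h in hitcols) long[is.na(get(h)), (h) := FALSE]
  long[is.na(n_events_1), `:=`(n_events_1 = 0L, casualties_1 = 0L)]

  counts <- long[age >= 6L,
                 .(n_events = sum(n_events_1),
                   total_casualties = sum(casualties_1),
                   n_years_violent = sum(hit1)),
                 by = respondent_id]

  wide <- dcast(long, respondent_id ~ age, value.var = hitcols)
  # dcast names: hit{b}_{age} (or {age} alone when nb == 1)
  if (nb == 1L) setnames(wide, as.character(5:12), paste0("hit1_", 5:12))

  out <- merge(prof, counts, by = "respondent_id")
  out <- merge(out, wide, by = "respondent_id")
  for (b in seq_len(nb)) for (a in ages)
    setnames(out, paste0("hit", b, "_", a), paste0("exp_a", a, "_d", b))
  for (b in seq_len(nb)) {
    cols <- paste0("exp_a", ages, "_d", b)
    out[, paste0("any_d", b) := Reduce(`|`, .SD), .SDcols = cols]
  }
  out[, exposed := any_d1]
  if (nb >= 2L) out[, exposed_50 := any_d1 | any_d2]

  # new / recurring labels per age (previous calendar year, incl. age 5)
  for (a in ages) {
    cur <- out[[paste0("exp_a", a, "_d1")]]
    prev <- if (a == 6L) out[["hit1_5"]] else
      out[[paste0("exp_a", a - 1L, "_d1")]]
    out[, paste0("recur_a", a) :=
          fifelse(!cur, "none", fifelse(prev, "recurring", "new"))]
  }
  drop_h5 <- grep("^hit[0-9]+_5$", names(out), value = TRUE)
  if (length(drop_h5)) out[, (drop_h5) := NULL]
  setkey(out, respondent_id)
  out[]
}

#' Exposure profile for a single respondent
#'
#' Convenience wrapper around [build_profiles()] for one respondent; returns
#' the profile as a list with an explicit `age_flags` matrix.
#'
#' @inheritParams build_profiles
#' @param respondent One-row respondent table.
#' @param cluster One-row cluster table matching the respondent's cluster.
#' @export
build_profile <- function(respondent, cluster, events,
                          bands = c(25, 50, 75, 100)) {
  respondent <- as.data.table(respondent)
  cluster <- as.data.table(cluster)
  stopifnot(nrow(respondent) == 1L, nrow(cluster) == 1L)
  if (!identical(respondent$cluster_id, cluster$cluster_id))
    stop("cluster does not match respondent's cluster_id", call. = FALSE)
  wide <- build_profiles(respondent, cluster, events, bands)
  ages <- 6:12
  af <- sapply(seq_along(bands), function(b)
    unlist(wide[, paste0("exp_a", ages, "_d", b), with = FALSE]))
  dimnames(af) <- list(paste0("age", ages), paste0("band", seq_along(bands)))
  list(respondent_id = respondent$respondent_id,
       age_flags = af,
       any_6_12 = apply(af, 2L, any),
       n_events = wide$n_events,
       total_casualties = wide$total_casualties,
       n_years_violent = wide$n_years_violent,
       recurring_flags = setNames(
         unlist(wide[, paste0("recur_a", ages), with = FALSE]),
         paste0("age", ages)))
}

#' Classify exposed respondents into low- and high-intensity violence
#'
#' Among exposed respondents the casualty threshold is the given quantile
#' (default the bottom quintile) of total casualties experienced over ages
#' 6-12; respondents at or below the threshold are `low`, the rest `high`,
#' and unexposed respondents stay `unexposed`.
#'
#' @param profiles Output of [build_profiles()].
#' @param quantile Quantile defining the low-intensity cut, default 0.2.
#' @return The profile table with an added `intensity` column.
#' @export
classify_intensity <- function(profiles, quantile = 0.2) {
  stopifnot(quantile > 0, quantile < 1)
  profiles <- as.data.table(profiles)
  out <- copy(profiles)
  out[, intensity := "unexposed"]
  exp_idx <- which(out$exposed)
  if (length(exp_idx) == 0L) {
    warning("no exposed respondents; all labelled unexposed")
    return(out[])
  }
  thr <- stats::quantile(out$total_casualties[exp_idx], probs = quantile,
                         type = 1, names = FALSE)
  out[exp_idx, intensity := fifelse(total_casualties <= thr, "low", "high")]
  attr(out, "casualty_threshold") <- thr
  out[]
}
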