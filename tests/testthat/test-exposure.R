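test_that("haversine distance matches closed forms and is symmetric", {
  expect_equal(haversine_km(12.3, -4.5, 12.3, -4.5), 0)
  # one degree along the equator: R * pi / 180
  expect_equal(haversine_km(0, 0, 1, 0), 111.19508, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 1), 111.19508, tolerance = 1e-6)
  # antipodal along the equator: half circumference pi * R
  expect_equal(haversine_km(0, 0, 0, 180), 20015.1144, tolerance = 1e-6)
  set.seed(42)
  a <- runif(50, -60, 60); b <- runif(50, -170, 170)
  c2 <- runif(50, -60, 60); d2 <- runif(50, -170, 170)
  expect_equal(haversine_km(a, b, c2, d2), haversine_km(c2, d2, a, b))
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 181, 0, 0), "longitude")
})

test_that("haversine agrees with geosphere on random point pairs", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  p1 <- cbind(runif(200, -179, 179), runif(200, -85, 85))
  p2 <- cbind(runif(200, -179, 179), runif(200, -85, 85))
  ours <- haversine_km(p1[, 2], p1[, 1], p2[, 2], p2[, 1])
  ref <- geosphere::distHaversine(p1, p2, r = 6371008.8) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("precision filter keeps only finely located events", {
  ev <- data.table(event_id = paste0("E", 1:5), latitude = 0, longitude = 0,
                   year = 2000L, casualties = 1L,
                   precision_code = c(1L, 4L, 2L, 6L, 3L))
  expect_equal(nrow(filter_events_by_precision(ev)), 3L)
  expect_equal(filter_events_by_precision(ev)$event_id,
               c("E1", "E3", "E5"))
  all_fine <- copy(ev)[, precision_code := 1L]
  expect_equal(filter_events_by_precision(all_fine), all_fine)
  all_coarse <- copy(ev)[, precision_code := 5L]
  expect_equal(nrow(filter_events_by_precision(all_coarse)), 0L)
  bad <- copy(ev)[2, precision_code := NA_integer_]
  expect_error(filter_events_by_precision(bad), "precision code")
})

test_that("yearly exposure flags the right age-band cells", {
  cl <- data.table(cluster_id = "c1", country = "X", admin2 = "A",
                   latitude = 0, longitude = 10, urban = 1L,
                   survey_year = 2016L, survey_id = "S")
  # 10 km east, in the year the child turns 6
  ev <- data.table(event_id = "E1", latitude = 0,
                   longitude = 10 + 10 / 111.19508, year = 2006L,
                   casualties = 3L, precision_code = 1L)
  af <- yearly_exposure(cl, ev, birth_year = 2000L)
  expect_true(af["age6", "band1"])
  expect_equal(sum(af), 1L)  # no other cell set
  # no events at all
  af0 <- yearly_exposure(cl, ev[0], birth_year = 2000L)
  expect_false(any(af0))
  # event at exactly 25.0 km along the meridian falls in band 1 (inclusive)
  dlat <- 25 / 6371.0088 * 180 / pi
  ev25 <- data.table(event_id = "E2", latitude = dlat, longitude = 10,
                     year = 2008L, casualties = 1L, precision_code = 1L)
  af25 <- yearly_exposure(cl, ev25, birth_year = 2000L)
  expect_true(af25["age8", "band1"])
  expect_false(af25["age8", "band2"])
  # 60 km away -> ring 3 (50, 75]
  ev60 <- data.table(event_id = "E3", latitude = 60 / 111.19508,
                     longitude = 10, year = 2010L, casualties = 1L,
                     precision_code = 1L)
  af60 <- yearly_exposure(cl, ev60, birth_year = 2000L)
  expect_true(af60["age10", "band3"])
  expect_false(af60["age10", "band1"])
})

test_that("profile builder equals the brute-force all-pairs oracle", {
  fx <- random_linkage_fixture(11, n_cl = 200, n_ev = 500, n_resp = 150)
  prof <- build_profiles(fx$rr, fx$cl, fx$ev)
  for (i in seq_len(nrow(fx$rr))) {
    o <- brute_profile(fx$rr[i], fx$cl, fx$ev)
    p <- prof[fx$rr$respondent_id[i], on = "respondent_id"]
    got <- sapply(1:4, function(b)
      unlist(p[, paste0("exp_a", 6:12, "_d", b), with = FALSE]))
    expect_equal(unname(got), unname(o$flags))
    expect_equal(p$n_events, o$n_events)
    expect_equal(p$total_casualties, o$total_casualties)
    expect_equal(p$n_years_violent, o$n_years_violent)
    expect_equal(unname(unlist(p[, paste0("recur_a", 6:12), with = FALSE])),
                 unname(o$recur))
  }
})

test_that("event order never changes a profile", {
  fx <- random_linkage_fixture(13, n_cl = 30, n_ev = 120, n_resp = 40)
  p1 <- build_profiles(fx$rr, fx$cl, fx$ev)
  set.seed(1)
  p2 <- build_profiles(fx$rr, fx$cl, fx$ev[sample(.N)])
  expect_equal(p1, p2)
})

test_that("any-band flags aggregate per-age flags; nested discs are monotone", {
  fx <- random_linkage_fixture(17, n_cl = 40, n_ev = 200, n_resp = 60)
  prof <- build_profiles(fx$rr, fx$cl, fx$ev)
  for (b in 1:4) {
    agg <- Reduce(`|`, lapply(6:12, function(a)
      prof[[paste0("exp_a", a, "_d", b)]]))
    expect_equal(prof[[paste0("any_d", b)]], agg)
  }
  # widening the disc can only add exposure
  expect_true(all(prof$exposed_50[prof$exposed]))
  expect_true(all((prof$any_d1 | prof$any_d2) == prof$exposed_50))
})

test_that("recurrence needs a band-1 event in the preceding calendar year", {
  cl <- data.table(cluster_id = "c1", country = "X", admin2 = "A",
                   latitude = 0, longitude = 10, urban = 1L,
                   survey_year = 2016L, survey_id = "S")
  rr <- data.table(respondent_id = "r1", cluster_id = "c1",
                   birth_year = 2000L)
  mk_ev <- function(years) data.table(
    event_id = paste0("E", seq_along(years)), latitude = 0, longitude = 10,
    year = as.integer(years), casualties = 1L, precision_code = 1L)
  # events in the years the child turns 7 and 8
  p <- build_profiles(rr, cl, mk_ev(c(2007, 2008)))
  expect_equal(p$recur_a7, "new")
  expect_equal(p$recur_a8, "recurring")
  expect_equal(p$n_years_violent, 2L)
  # event in the age-5 year makes age-6 exposure recurring
  p2 <- build_profiles(rr, cl, mk_ev(c(2005, 2006)))
  expect_equal(p2$recur_a6, "recurring")
  expect_equal(p2$n_years_violent, 1L)
  # unexposed ages are 'none'
  p3 <- build_profiles(rr, cl, mk_ev(2007)[0])
  expect_true(all(unlist(p3[, paste0("recur_a", 6:12), with = FALSE]) ==
                    "none"))
  expect_false(p3$exposed)
  expect_equal(p3$n_events, 0L)
})

test_that("intensity classification splits exposed at the bottom quintile", {
  mk <- function(totals) data.table(
    respondent_id = sprintf("r%02d", seq_along(totals)),
    exposed = totals > 0, total_casualties = totals)
  # bottom-quintile threshold 2: totals <= 2 are low-intensity
  p <- classify_intensity(mk(c(0, 1, 2, 2, 5, 9, 20, 30, 40, 50, 60)))
  expect_equal(p$intensity[1], "unexposed")
  expect_equal(p$intensity[2:4], rep("low", 3))
  expect_equal(p$intensity[5:11], rep("high", 7))
  # ties: everyone shares one total -> all low
  p2 <- classify_intensity(mk(c(7, 7, 7, 7)))
  expect_true(all(p2$intensity == "low"))
  # brute-force quantile oracle on a random 10-respondent fixture
  set.seed(5)
  totals <- c(0, 0, sample(1:100, 8))
  p3 <- classify_intensity(mk(totals))
  expos <- totals[totals > 0]
  thr <- sort(expos)[ceiling(0.2 * length(expos))]
  expect_equal(p3$intensity,
               ifelse(totals == 0, "unexposed",
                      ifelse(totals <= thr, "low", "high")))
  # degenerate: nobody exposed
  expect_warning(p4 <- classify_intensity(mk(c(0, 0, 0))), "no exposed")
  expect_true(all(p4$intensity == "unexposed"))
})

test_that("single-respondent profile wrapper mirrors the table builder", {
  fx <- random_linkage_fixture(19, n_cl = 10, n_ev = 60, n_resp = 5)
  wide <- build_profiles(fx$rr, fx$cl, fx$ev)
  i <- 3L
  one <- build_profile(fx$rr[i], fx$cl[cluster_id == fx$rr$cluster_id[i]],
                       fx$ev)
  row <- wide[fx$rr$respondent_id[i], on = "respondent_id"]
  expect_equal(one$n_events, row$n_events)
  expect_equal(one$total_casualties, row$total_casualties)
  expect_equal(unname(one$any_6_12),
               unname(unlist(row[, paste0("any_d", 1:4), with = FALSE])))
  expect_equal(unname(one$age_flags[, 1]),
               unname(unlist(row[, paste0("exp_a", 6:12, "_d1"),
                                 with = FALSE])))
  expect_error(build_profile(fx$rr[1], fx$cl[2], fx$ev), "cluster")
})
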