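# Delimited-text I/O with strict schema validation.

.SCHEMAS <- list(
  events = list(
    required = c("event_id", "latitude", "longitude", "year", "casualties",
                 "precision_code"),
    checks = list(
      latitude = function(x) x >= -90 & x <= 90,
      longitude = function(x) x >= -180 & x <= 180,
      casualties = function(x) x >= 1,
      precision_code = function(x) x >= 1 & x == floor(x))),
  clusters = list(
    required = c("cluster_id", "country", "admin2", "latitude", "longitude",
                 "urban", "survey_year", "survey_id"),
    checks = list(
      latitude = function(x) x >= -90 & x <= 90,
      longitude = function(x) x >= -180 & x <= 180,
      urban = function(x) x %in% c(0, 1))),
  respondents = list(
    required = c("respondent_id", "cluster_id", "sex", "birth_year",
                 "birth_month", "age_at_survey", "years_in_residence",
                 "years_schooling", "edu_category", "hh_size", "head_age",
                 "head_female", "mother_in_hh", "wealth_index",
                 "ever_married", "mother_alive", "father_alive",
                 "attending_school", "nightlight_age6", "rainfall_age6",
                 "temperature_age6", "survey_weight"),
    checks = list(
      sex = function(x) x %in% c("F", "M"),
      birth_month = function(x) x >= 1 & x <= 12,
      years_schooling = function(x) x >= 0 & x <= 25,
      edu_category = function(x) x %in% c(
        "none", "incomplete_primary", "complete_primary",
        "incomplete_secondary", "complete_secondary", "higher"),
      wealth_index = function(x) x >= 1 & x <= 5,
      survey_weight = function(x) x > 0,
      head_female = function(x) x %in% c(0, 1),
      mother_in_hh = function(x) x %in% c(0, 1),
      ever_married = function(x) x %in% c(0, 1),
      mother_alive = function(x) x %in% c(0, 1),
      father_alive = function(x) x %in% c(0, 1),
      attending_school = function(x) x %in% c(0, 1))),
  fractions = list(
    required = c("country", "survey_id", "sex", "fraction"),
    checks = list(
      sex = function(x) x %in% c("F", "M"),
      fraction = function(x) x > 0 & x <= 1)))

#' Read a delimited table with schema validation
#'
#' Parses a comma-separated UTF-8 table and validates it against one of the
#' built-in schemas (`events`, `clusters`, `respondents`, `fractions`):
#' required columns must be present, typed range checks must hold (the
#' first 10 offending rows are reported otherwise), and unknown columns are
#' preserved but flagged with a message.
#'
#' @param path File path.
#' @param schema Schema name.
#' @return A validated `data.table`.
#' @export
read_table <- function(path, schema = c("events", "clusters", "respondents",
                                        "fractions")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- .SCHEMAS[[schema]]
  d <- fread(path, colClasses = if (schema == "respondents")
    list(character = "years_in_residence") else NULL)
  miss <- setdiff(sc$required, names(d))
  if (length(miss))
    stop(schema, ": missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(d), sc$required)
  if (length(extra))
    message(schema, ": unknown columns preserved: ",
            paste(extra, collapse = ", "))
  for (col in names(sc$checks)) {
    ok <- sc$checks[[col]](d[[col]])
    ok[is.na(ok)] <- FALSE
    if (!all(ok))
      stop(schema, ": column ", col, " violates schema in rows: ",
           paste(head(which(!ok), 10), collapse = ", "), call. = FALSE)
  }
  d
}

#' Read and cross-validate a full input bundle
#'
#' Reads events, clusters, respondents and fractions from a directory and
#' checks referential integrity (every respondent's `cluster_id` exists).
#'
#' @param dir Directory containing `events.csv`, `clusters.csv`,
#'   `respondents.csv`, `fractions.csv`.
#' @return Named list of validated tables.
#' @export
read_bundle <- function(dir) {
  out <- list(
    events = read_table(file.path(dir, "events.csv"), "events"),
    clusters = read_table(file.path(dir, "clusters.csv"), "clusters"),
    respondents = read_table(file.path(dir, "respondents.csv"),
                             "respondents"),
    fractions = read_table(file.path(dir, "fractions.csv"), "fractions"))
  orphan <- setdiff(out$respondents$cluster_id, out$clusters$cluster_id)
  if (length(orphan))
    stop("respondents reference absent cluster_id: ",
         paste(head(orphan, 10), collapse = ", "), call. = FALSE)
  out
}

#' Write a table as comma-separated UTF-8 text
#' @param x Table to write.
#' @param path Output file path (directory must exist).
#' @export
write_table <- function(x, path) {
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path), call. = FALSE)
  fwrite(as.data.table(x), path)
  invisible(path)
}
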