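# Counterfactual excess under-5 mortality from conflict-driven schooling loss.
#
# Exposed mothers (share p) lost delta years of schooling; each year of
# maternal schooling reduces under-5 mortality by a proportional gradient q.
# Under a conflict-free counterfactual the same mothers would have had the
# extra schooling, so observed deaths D split into a counterfactual part
# D * (1 - p * f(delta, q)) and excess deaths D * p * f(delta, q), with
# f(delta, q) = 1 - (1 - q)^delta (compound form, default) or delta * q
# (linear first-order form).

#' Mortality-calculation inputs
#'
#' @param years Calendar years of the deaths series.
#' @param deaths Observed under-5 deaths per year; alternatively supply
#'   `rate` and `population` (deaths = rate * population).
#' @param rate,population Optional mortality rate and child population per
#'   year, used when `deaths` is missing.
#' @param p Fraction of mothers conflict-exposed (0-1).
#' @param delta Schooling loss among exposed mothers, years.
#' @param q Proportional reduction in under-5 mortality per year of maternal
#'   schooling (0-1).
#' @param delta_ci,q_ci Length-2 confidence bounds for `delta` and `q` used
#'   by the low/high series (magnitudes; `delta_ci` low first).
#' @param deaths_low,deaths_high Optional low/high deaths series.
#' @return A list of class `mortality_inputs`.
#' @export
mortality_inputs <- function(years, deaths = NULL, rate = NULL,
                             population = NULL,
                             p = 0.21, delta = 0.38, q = 0.0304,
                             delta_ci = c(0.18, 0.57),
                             q_ci = NULL,
                             deaths_low = NULL, deaths_high = NULL) {
  if (is.null(deaths)) {
    if (is.null(rate) || is.null(population))
      stop("supply deaths, or rate and population", call. = FALSE)
    deaths <- rate * population
  }
  if (length(deaths) != length(years))
    stop("deaths series length must match years", call. = FALSE)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (q < 0 || q >= 1) stop("q must be in [0, 1)", call. = FALSE)
  if (is.null(q_ci)) q_ci <- c(q, q)
  if (any(deaths < 0)) stop("deaths must be >= 0", call. = FALSE)
  if (delta_ci[1] > delta_ci[2] || q_ci[1] > q_ci[2])
    stop("crossed confidence bounds (low > high)", call. = FALSE)
  if (any(q_ci >= 1)) stop("q bounds must be < 1", call. = FALSE)
  if (is.null(deaths_low)) deaths_low <- deaths
  if (is.null(deaths_high)) deaths_high <- deaths
  if (any(deaths_low > deaths_high))
    stop("crossed deaths bounds (low > high)", call. = FALSE)
  structure(list(years = years, deaths = deaths, p = p, delta = delta,
                 q = q, delta_ci = delta_ci, q_ci = q_ci,
                 deaths_low = deaths_low, deaths_high = deaths_high),
            class = "mortality_inputs")
}

# fraction of deaths among exposed-mother children averted by delta years
mortality_reduction <- function(delta, q, form) {
  switch(form,
         compound = 1 - (1 - q)^delta,
         linear = delta * q,
         stop("unknown form: ", form, call. = FALSE))
}

#' Counterfactual and excess under-5 deaths
#'
#' Computes, per year, the counterfactual deaths under the conflict-free
#' schooling scenario and the excess deaths attributable to the schooling
#' channel, with low/high bounds propagating the confidence bounds of the
#' schooling loss and the mortality gradient together with the low/high
#' deaths series.
#'
#' @param inputs A [mortality_inputs()].
#' @param form `"compound"` (default): each schooling year multiplies
#'   mortality by `1 - q`; `"linear"`: first-order form `delta * q`.
#' @return A `data.table`: `year`, `observed`, `counterfactual`, `excess`,
#'   `excess_low`, `excess_high`; total excess as attribute `totals`.
#' @export
counterfactual_deaths <- function(inputs, form = c("compound", "linear")) {
  stopifnot(inherits(inputs, "mortality_inputs"))
  form <- match.arg(form)
  f <- mortality_reduction(inputs$delta, inputs$q, form)
  f_lo <- mortality_reduction(inputs$delta_ci[1], inputs$q_ci[1], form)
  f_hi <- mortality_reduction(inputs$delta_ci[2], inputs$q_ci[2], form)
  out <- data.table(
    year = inputs$years,
    observed = inputs$deaths,
    counterfactual = inputs$deaths * (1 - inputs$p * f),
    excess = inputs$deaths * inputs$p * f,
    excess_low = inputs$deaths_low * inputs$p * f_lo,
    excess_high = inputs$deaths_high * inputs$p * f_hi)
  setattr(out, "totals",
          c(excess = sum(out$excess), excess_low = sum(out$excess_low),
            excess_high = sum(out$excess_high)))
  out[]
}

#' Low/high excess-death bounds
#'
#' Convenience accessor returning the per-year low and high excess series.
#'
#' @inheritParams counterfactual_deaths
#' @export
excess_bounds <- function(inputs, form = c("compound", "linear")) {
  res <- counterfactual_deaths(inputs, form)
  res[, .(year, excess_low, excess_high)]
}
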