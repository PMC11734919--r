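# Weighted fixed-effects estimation with cluster-robust (CR1) inference.
#
# Linear models absorb the fixed effects by weighted alternating projections
# (the within transformation iterated across FE dimensions); logistic models
# use explicit sparse indicator encoding with IRLS, which is adequate at the
# data sizes this package targets.

#' Regression specification
#'
#' @param outcome Outcome column name.
#' @param treatments Character vector of exposure columns.
#' @param controls Character vector of covariate columns (may be empty).
#' @param fixed_effects Character vector of grouping columns, e.g. cluster,
#'   country-by-birth-year, country-by-birth-month.
#' @param weights Weight column name, or `NULL` for unweighted.
#' @param cluster_se_on Column on which to cluster standard errors.
#' @param family `"linear"` or `"logistic"`.
#' @return A list of class `edu_spec`.
#' @export
edu_spec <- function(outcome, treatments,
                     controls = character(),
                     fixed_effects,
                     weights = "w",
                     cluster_se_on = "cluster_id",
                     family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (length(treatments) == 0L) stop("treatments must be non-empty")
  if (length(fixed_effects) == 0L) stop("fixed_effects must be non-empty")
  structure(list(outcome = outcome, treatments = treatments,
                 controls = controls, fixed_effects = fixed_effects,
                 weights = weights, cluster_se_on = cluster_se_on,
                 family = family),
            class = "edu_spec")
}

# Greedy Cholesky rank selection on a Gram matrix: returns a logical mask of
# the earliest maximal set of linearly independent columns.
greedy_chol_keep <- function(G, tol = 1e-9) {
  p <- ncol(G)
  keep <- logical(p)
  R <- matrix(0, p, p)  # upper-left k x k holds the Cholesky factor
  sel <- integer(0)
  k <- 0L
  for (j in seq_len(p)) {
    a <- if (k) backsolve(R[seq_len(k), seq_len(k), drop = FALSE],
                          G[sel, j], transpose = TRUE) else numeric(0)
    d <- G[j, j] - sum(a^2)
    if (d > tol * max(G[j, j], 1)) {
      keep[j] <- TRUE
      k <- k + 1L
      sel[k] <- j
      if (k > 1L) R[seq_len(k - 1L), k] <- a
      R[k, k] <- sqrt(d)
    }
  }
  keep
}

# Iteratively drop observations that are singletons within any FE group
# (their FE absorbs them completely; keeping them biases the dof).
drop_singletons <- function(fe_list) {
  n <- length(fe_list[[1]])
  keep <- rep(TRUE, n)
  repeat {
    changed <- FALSE
    for (g in fe_list) {
      idx <- which(keep)
      tb <- table(g[idx])
      single <- names(tb)[tb == 1L]
      if (length(single)) {
        keep[idx[g[idx] %in% single]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep
}

#' Absorb fixed effects by weighted alternating projections
#'
#' Applies the weighted within transformation across the FE dimensions in
#' turn until the largest absolute change of any cell is below `tol`.
#' Observations that are singletons across the combined FE structure are
#' dropped first and counted.
#'
#' @param X Numeric matrix of columns to demean (outcome and regressors).
#' @param fe_list List of factors/vectors, one per FE dimension.
#' @param w Positive weights.
#' @param tol Convergence tolerance on the max absolute change, default 1e-8.
#' @param max_sweeps Sweep cap, default 1000; non-convergence is an error.
#' @return List: `X` (demeaned, singleton rows removed), `keep` (logical row
#'   filter), `n_dropped` (singleton rows), `fe_levels` (identified FE
#'   coefficients, for degrees of freedom), `sweeps`.
#' @export
absorb_fixed_effects <- function(X, fe_list, w = NULL, tol = 1e-8,
                                 max_sweeps = 1000L) {
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, nrow(X))
  if (any(w <= 0)) stop("weights must be > 0", call. = FALSE)
  stopifnot(length(fe_list) >= 1L, all(lengths(fe_list) == nrow(X)))

  keep <- drop_singletons(fe_list)
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("empty sample after singleton drops", call. = FALSE)
  X <- X[keep, , drop = FALSE]
  w <- w[keep]
  fe <- lapply(fe_list, function(g) as.integer(factor(g[keep])))
  ngrp <- vapply(fe, max, integer(1))

  sweeps <- 0L
  repeat {
    delta <- 0
    for (d in seq_along(fe)) {
      g <- fe[[d]]
      sw <- rowsum(w, g, reorder = TRUE)
      m <- rowsum(X * w, g, reorder = TRUE) / as.vector(sw)
      Xnew <- X - m[g, , drop = FALSE]
      delta <- max(delta, max(abs(Xnew - X)))
      X <- Xnew
    }
    sweeps <- sweeps + 1L
    if (delta < tol) break
    if (sweeps >= max_sweeps)
      stop("fixed-effect absorption did not converge in ", max_sweeps,
           " sweeps (last max change ", format(delta), ")", call. = FALSE)
  }
  # identified FE coefficients: total levels minus (dims - 1) connecting
  # normalizations (one shared intercept across dimensions)
  fe_levels <- sum(ngrp) - (length(fe) - 1L)
  list(X = X, keep = keep, n_dropped = n_dropped,
       fe_levels = fe_levels, sweeps = sweeps)
}

#' Weighted least squares with deterministic collinearity handling
#'
#' Solves the weighted normal equations; columns that are collinear with
#' earlier-listed ones are dropped deterministically and reported.
#'
#' @param y Outcome vector (already demeaned if FEs are absorbed).
#' @param X Regressor matrix with column names.
#' @param w Positive weights.
#' @return List: `coef` (named, dropped columns absent), `residuals`,
#'   `XtWX_inv`, `dropped` (names of dropped columns).
#' @export
wls_fit <- function(y, X, w = NULL) {
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  sw <- sqrt(w)
  Xs <- X * sw
  qrx <- qr(Xs)
  dropped <- character()
  if (qrx$rank < ncol(X)) {
    # keep earliest maximal independent set
    keep_cols <- logical(ncol(X))
    r <- 0L
    base <- NULL
    for (j in seq_len(ncol(X))) {
      cand <- cbind(base, Xs[, j])
      if (qr(cand)$rank > r) {
        keep_cols[j] <- TRUE
        base <- cand
        r <- r + 1L
      }
    }
    dropped <- colnames(X)[!keep_cols]
    X <- X[, keep_cols, drop = FALSE]
    Xs <- Xs[, keep_cols, drop = FALSE]
    if (ncol(X) == 0L)
      stop("design rank-deficient after drops; no columns left",
           call. = FALSE)
    qrx <- qr(Xs)
  }
  XtWX <- crossprod(Xs)
  coef <- as.vector(solve(XtWX, crossprod(Xs, y * sw)))
  names(coef) <- colnames(X)
  res <- as.vector(y - X %*% coef)
  XtWX_inv <- chol2inv(chol(XtWX))
  dimnames(XtWX_inv) <- list(colnames(X), colnames(X))
  list(coef = coef, residuals = res, XtWX_inv = XtWX_inv, dropped = dropped)
}

#' Cluster-robust (CR1) covariance for a weighted fit
#'
#' Sandwich estimator with cluster-summed weighted scores and the CR1
#' small-sample factor `G/(G-1) * (N-1)/(N-K)`, where `K` counts absorbed
#' fixed-effect levels plus estimated slopes.
#'
#' @param X Regressor matrix (demeaned).
#' @param residuals Fit residuals.
#' @param w Weights.
#' @param cluster_ids Cluster membership per row.
#' @param K Total parameter count for the dof correction.
#' @return Covariance matrix over the columns of `X`.
#' @export
cluster_robust_vcov <- function(X, residuals, w, cluster_ids, K) {
  X <- as.matrix(X)
  g <- as.integer(factor(cluster_ids))
  G <- max(g)
  if (G < 2L) stop("need at least 2 clusters for clustered SEs",
                   call. = FALSE)
  N <- nrow(X)
  S <- rowsum(X * (w * residuals), g, reorder = FALSE)   # G x K scores
  meat <- crossprod(S)
  bread <- chol2inv(chol(crossprod(X * sqrt(w))))
  adj <- G / (G - 1) * (N - 1) / (N - K)
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

fit_result <- function(coef, vcov, n_obs, n_clusters, n_dropped_singletons,
                       family, dropped = character(), converged = TRUE,
                       notes = character()) {
  se <- sqrt(diag(vcov))
  z <- coef / se
  p <- 2 * pnorm(-abs(z))
  structure(list(
    coefficients = coef, vcov = vcov, se = se,
    ci_low = coef - qnorm(0.975) * se,
    ci_high = coef + qnorm(0.975) * se,
    p = p, n_obs = n_obs, n_clusters = n_clusters,
    n_dropped_singletons = n_dropped_singletons,
    converged = converged, family = family,
    dropped_collinear = dropped, notes = notes), class = "edu_fit")
}

#' @export
print.edu_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects %s fit: %d obs, %d SE clusters, %d singletons dropped\n",
              x$family, x$n_obs, x$n_clusters, x$n_dropped_singletons))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p)
  print(round(tab, 4))
  if (length(x$dropped_collinear))
    cat("dropped (collinear):", paste(x$dropped_collinear, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fit into a data.table
#' @param fit An `edu_fit`.
#' @export
tidy_fit <- function(fit) {
  data.table(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se), ci_low = unname(fit$ci_low),
             ci_high = unname(fit$ci_high), p = unname(fit$p),
             n_obs = fit$n_obs)
}

# Pull outcome/regressor matrices from a data table per spec.
build_design <- function(data, spec) {
  data <- as.data.table(data)
  cols <- c(spec$outcome, spec$treatments, spec$controls, spec$fixed_effects,
            spec$cluster_se_on, spec$weights)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("columns missing from sample: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- as.numeric(data[[spec$outcome]])
  Xcols <- c(spec$treatments, spec$controls)
  X <- as.matrix(data[, lapply(.SD, as.numeric), .SDcols = Xcols])
  w <- if (is.null(spec$weights)) rep(1, nrow(data)) else
    as.numeric(data[[spec$weights]])
  fe <- lapply(spec$fixed_effects, function(f) data[[f]])
  list(y = y, X = X, w = w, fe = fe, cl = data[[spec$cluster_se_on]])
}

#' Fit a weighted fixed-effects regression
#'
#' Linear family: absorbs the fixed effects by alternating projections,
#' solves weighted least squares and reports cluster-robust CR1 standard
#' errors, normal-reference 95% CIs and two-sided p-values.  Logistic
#' family dispatches to [fit_logistic()].
#'
#' @param data Analysis sample (a `data.table`/`data.frame`, or an
#'   `edu_sample` from [assemble_sample()]).
#' @param spec An [edu_spec()].
#' @return An `edu_fit`.
#' @export
fe_fit <- function(data, spec) {
  if (inherits(data, "edu_sample")) data <- data$data
  stopifnot(inherits(spec, "edu_spec"))
  if (spec$family == "logistic") return(fit_logistic(data, spec))
  d <- build_design(data, spec)
  if (length(d$y) == 0L) stop("empty sample", call. = FALSE)

  M <- cbind(y = d$y, d$X)
  ab <- absorb_fixed_effects(M, d$fe, d$w)
  if (nrow(ab$X) == 0L) stop("empty sample after singleton drops",
                             call. = FALSE)
  y <- ab$X[, 1L]
  X <- ab$X[, -1L, drop = FALSE]
  w <- d$w[ab$keep]
  cl <- d$cl[ab$keep]

  # columns with no remaining variation (e.g. a band no one occupies)
  novar <- apply(X, 2L, function(col) max(abs(col)) < 1e-10)
  novar_names <- colnames(X)[novar]
  notes <- character()
  if (any(novar)) {
    notes <- paste0("no variation after absorption: ",
                    paste(novar_names, collapse = ", "))
    X <- X[, !novar, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no identifiable regressors", call. = FALSE)

  fit <- wls_fit(y, X, w)
  Xk <- X[, setdiff(colnames(X), fit$dropped), drop = FALSE]
  K <- ab$fe_levels + ncol(Xk)
  if (nrow(Xk) <= K)
    stop("too few observations for cluster-robust inference (n = ",
         nrow(Xk), ", parameters = ", K, ")", call. = FALSE)
  V <- cluster_robust_vcov(Xk, fit$residuals, w, cl, K)
  fit_result(fit$coef, V, n_obs = nrow(Xk),
             n_clusters = length(unique(cl)),
             n_dropped_singletons = ab$n_dropped,
             family = "linear",
             dropped = c(novar_names, fit$dropped),
             notes = notes)
}

#' Logistic fixed-effects fit with explicit indicator encoding
#'
#' Encodes every FE dimension as sparse indicators (first level of each
#' dimension after the first serves as reference, plus a global intercept),
#' drops FE groups without outcome variation (their effect is not
#' identified), and fits by iteratively reweighted least squares to a
#' gradient max-norm below `1e-8` (cap 100 iterations).  Inference is a
#' cluster-robust sandwich on the score scale with the CR1 factor.  Reported
#' terms are the treatments and controls; odds ratios are available as
#' `exp(coefficients)`.
#'
#' @inheritParams fe_fit
#' @return An `edu_fit` (family `"logistic"`) with an `odds_ratio` element.
#' @export
fit_logistic <- function(data, spec) {
  if (inherits(data, "edu_sample")) data <- data$data
  d <- build_design(data, spec)
  y <- d$y
  if (!all(y %in% c(0, 1))) stop("logistic outcome must be binary 0/1",
                                 call. = FALSE)

  # drop groups with no outcome variation, iterating across dimensions
  keep <- rep(TRUE, length(y))
  repeat {
    changed <- FALSE
    for (g in d$fe) {
      idx <- which(keep)
      vr <- tapply(y[idx], g[idx], function(v) any(v == 0) && any(v == 1))
      bad <- names(vr)[!vr]
      if (length(bad)) {
        keep[idx[g[idx] %in% bad]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (sum(keep) == 0L)
    stop("outcome constant within every FE group; nothing identifiable",
         call. = FALSE)
  n_dropped <- sum(!keep)
  y <- y[keep]; w <- d$w[keep]; cl <- d$cl[keep]
  Xs <- d$X[keep, , drop = FALSE]
  fe <- lapply(d$fe, function(g) factor(g[keep]))

  blocks <- list(Matrix::Matrix(cbind(`(Intercept)` = 1, Xs), sparse = TRUE))
  for (j in seq_along(fe)) {
    f <- fe[[j]]
    contr <- Matrix::sparse.model.matrix(~ f - 1)
    colnames(contr) <- paste0("fe", j, "_", levels(f))
    # drop one reference level per dimension (intercept carries it)
    blocks[[j + 1L]] <- contr[, -1L, drop = FALSE]
  }
  X <- do.call(cbind, blocks)
  slopes <- c("(Intercept)", colnames(Xs))

  # deterministic rank selection (keep earliest independent columns; slopes
  # are listed first, so only redundant FE indicators are dropped)
  G <- as.matrix(Matrix::crossprod(X))
  keep_col <- greedy_chol_keep(G)
  dropped_cols <- colnames(X)[!keep_col]
  X <- X[, keep_col, drop = FALSE]

  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(100L)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    grad <- as.vector(Matrix::crossprod(X, w * (y - mu)))
    if (max(abs(grad)) < 1e-8) { converged <- TRUE; break }
    wirls <- w * mu * (1 - mu)
    H <- Matrix::crossprod(X * sqrt(wirls))
    step <- as.vector(Matrix::solve(H, grad))
    beta <- beta + step
    big <- which(abs(beta) > 15)
    if (length(big))
      stop("separation detected: coefficient diverging for term ",
           colnames(X)[big[1L]], call. = FALSE)
  }
  if (!converged)
    stop("IRLS did not converge in 100 iterations", call. = FALSE)
  names(beta) <- colnames(X)

  mu <- plogis(as.vector(X %*% beta))
  wirls <- w * mu * (1 - mu)
  bread <- solve(as.matrix(Matrix::crossprod(X * sqrt(wirls))))
  g <- as.integer(factor(cl))
  G <- max(g)
  if (G < 2L) stop("need at least 2 clusters for clustered SEs",
                   call. = FALSE)
  N <- length(y); K <- ncol(X)
  # cluster-summed score vectors, kept sparse until the G x K collapse
  agg <- Matrix::sparseMatrix(i = g, j = seq_len(N), x = w * (y - mu),
                              dims = c(G, N))
  S <- as.matrix(agg %*% X)
  adj <- G / (G - 1) * (N - 1) / (N - K)
  V <- adj * bread %*% crossprod(S) %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))

  rep_terms <- setdiff(slopes, "(Intercept)")
  out <- fit_result(beta[rep_terms], V[rep_terms, rep_terms, drop = FALSE],
                    n_obs = N, n_clusters = length(unique(cl)),
                    n_dropped_singletons = n_dropped,
                    family = "logistic", dropped = dropped_cols,
                    converged = converged)
  out$odds_ratio <- exp(out$coefficients)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  out$all_coefficients <- beta
  out
}

#' Female-male contrast of the exposure effect
#'
#' Fits one pooled model in which every treatment, control and FE dimension
#' is interacted with sex (numerically equivalent to separate by-sex fits)
#' so that standard errors clustered on the survey cluster honour the
#' covariance of estimates sharing clusters, then reports the female minus
#' male effect for each treatment.
#'
#' @param spec A linear [edu_spec()].
#' @param female_sample,male_sample Samples sharing the spec's columns
#'   (`edu_sample` or data tables).
#' @return List with `contrast` (a `data.table`: term, estimate, se, CI, p),
#'   `fit` (the pooled `edu_fit`), and the per-sex coefficient vectors.
#' @export
sex_contrast <- function(spec, female_sample, male_sample) {
  stopifnot(spec$family == "linear")
  fdat <- if (inherits(female_sample, "edu_sample")) female_sample$data else
    as.data.table(female_sample)
  mdat <- if (inherits(male_sample, "edu_sample")) male_sample$data else
    as.data.table(male_sample)
  need <- c(spec$outcome, spec$treatments, spec$controls, spec$fixed_effects,
            spec$cluster_se_on, spec$weights)
  if (!all(need %in% names(fdat)) || !all(need %in% names(mdat)))
    stop("samples do not share the specification's columns", call. = FALSE)
  pooled <- rbind(fdat[, need, with = FALSE], mdat[, need, with = FALSE])
  sexv <- rep(c("F", "M"), c(nrow(fdat), nrow(mdat)))

  vars <- c(spec$treatments, spec$controls)
  for (v in vars) {
    pooled[, paste0(v, ":F") := as.numeric(get(v)) * (sexv == "F")]
    pooled[, paste0(v, ":M") := as.numeric(get(v)) * (sexv == "M")]
  }
  for (f in spec$fixed_effects)
    pooled[, (f) := paste(get(f), sexv, sep = ":")]

  ctrl2 <- if (length(spec$controls))
    c(paste0(spec$controls, ":F"), paste0(spec$controls, ":M")) else
      character()
  spec2 <- edu_spec(outcome = spec$outcome,
                    treatments = c(paste0(spec$treatments, ":F"),
                                   paste0(spec$treatments, ":M")),
                    controls = ctrl2,
                    fixed_effects = spec$fixed_effects,
                    weights = spec$weights,
                    cluster_se_on = spec$cluster_se_on,
                    family = "linear")
  fit <- fe_fit(pooled, spec2)

  contrast <- rbindlist(lapply(spec$treatments, function(tr) {
    tf <- paste0(tr, ":F"); tm <- paste0(tr, ":M")
    if (!all(c(tf, tm) %in% names(fit$coefficients)))
      return(data.table(term = tr, estimate = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_))
    est <- fit$coefficients[tf] - fit$coefficients[tm]
    v <- fit$vcov[tf, tf] + fit$vcov[tm, tm] - 2 * fit$vcov[tf, tm]
    se <- sqrt(v)
    data.table(term = tr, estimate = unname(est), se = se,
               ci_low = unname(est - qnorm(0.975) * se),
               ci_high = unname(est + qnorm(0.975) * se),
               p = unname(2 * pnorm(-abs(est / se))))
  }))
  list(contrast = contrast, fit = fit,
       female = fit$coefficients[paste0(spec$treatments, ":F")],
       male = fit$coefficients[paste0(spec$treatments, ":M")])
}
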