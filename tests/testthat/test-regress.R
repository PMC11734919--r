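test_that("absorption is a projection: zero group means, idempotent", {
  d <- rand_fe_fixture(1)
  ab <- absorb_fixed_effects(as.matrix(d[, .(y, x1, x2)]), list(d$g1), d$w)
  dd <- as.data.table(ab$X)[, g := d$g1[ab$keep]][, w := d$w[ab$keep]]
  gm <- dd[, lapply(.SD, function(v) sum(v * w) / sum(w)), by = g,
           .SDcols = c("y", "x1", "x2")]
  expect_lt(max(abs(as.matrix(gm[, -1]))), 1e-12)
  ab2 <- absorb_fixed_effects(ab$X, list(d$g1[ab$keep]), d$w[ab$keep])
  expect_equal(ab2$X, ab$X, tolerance = 1e-10)
})

test_that("absorbed WLS equals full dummy-variable WLS on crossed FEs", {
  for (seed in 1:3) {
    d <- rand_fe_fixture(seed)
    spec <- edu_spec("y", c("x1", "x2"), fixed_effects = c("g1", "g2", "g3"),
                     weights = "w", cluster_se_on = "g1")
    fit <- fe_fit(d, spec)
    m <- lm(y ~ x1 + x2 + factor(g1) + factor(g2) + factor(g3), data = d,
            weights = w)
    expect_equal(fit$coefficients[c("x1", "x2")],
                 coef(m)[c("x1", "x2")], tolerance = 1e-6)
  }
})

test_that("weighted least squares matches the normal-equations oracle", {
  set.seed(4)
  n <- 100
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- X %*% c(1, -2, 0.5) + rnorm(n)
  w <- runif(n, 0.2, 3)
  fit <- wls_fit(as.vector(y), X, w)
  oracle <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
  expect_equal(unname(fit$coef), as.vector(oracle), tolerance = 1e-10)
  # outcome equal to a regressor: unit coefficient, zero residuals
  fit2 <- wls_fit(X[, 1], X[, 1, drop = FALSE], w)
  expect_equal(unname(fit2$coef), 1)
  expect_lt(max(abs(fit2$residuals)), 1e-12)
  # equal weights match unweighted OLS
  fit3 <- wls_fit(as.vector(y), X, rep(2, n))
  expect_equal(unname(fit3$coef), unname(coef(lm(y ~ X - 1))),
               tolerance = 1e-10, ignore_attr = TRUE)
  # deterministic drop of the later-listed collinear column
  Xc <- cbind(X, dup = X[, "a"])
  fit4 <- wls_fit(as.vector(y), Xc, w)
  expect_equal(fit4$dropped, "dup")
  expect_equal(fit4$coef[c("a", "b", "c")], fit$coef, tolerance = 1e-10)
})

test_that("cluster-robust covariance matches the loop-summed sandwich", {
  set.seed(5)
  n <- 50
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  w <- runif(n, 0.5, 2)
  cl <- sample(paste0("g", 1:8), n, TRUE)
  y <- X %*% c(1, -1) + rnorm(n)
  fit <- wls_fit(as.vector(y), X, w)
  K <- ncol(X)
  V <- cluster_robust_vcov(X, fit$residuals, w, cl, K)
  # explicit per-cluster loop
  bread <- solve(t(X) %*% (X * w))
  meat <- matrix(0, K, K)
  for (g in unique(cl)) {
    i <- cl == g
    s <- t(X[i, , drop = FALSE]) %*% (w[i] * fit$residuals[i])
    meat <- meat + s %*% t(s)
  }
  G <- length(unique(cl))
  adj <- G / (G - 1) * (n - 1) / (n - K)
  expect_equal(V, adj * bread %*% meat %*% bread, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("one observation per cluster degrades to HC1", {
  set.seed(6)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- X %*% c(0.5, 1) + rnorm(n)
  fit <- wls_fit(as.vector(y), X, rep(1, n))
  V <- cluster_robust_vcov(X, fit$residuals, rep(1, n),
                           paste0("u", seq_len(n)), ncol(X))
  m <- lm(y ~ X - 1)
  Vhc1 <- sandwich::vcovHC(m, type = "HC1")
  # CR1 with G = N: adj = N/(N-1) * (N-1)/(N-K) = N/(N-K), same as HC1
  expect_equal(unname(V), unname(Vhc1), tolerance = 1e-8)
})

test_that("duplicating every cluster with halved weights leaves SEs alone", {
  d <- rand_fe_fixture(7)
  spec <- edu_spec("y", c("x1", "x2"), fixed_effects = "g2",
                   weights = "w", cluster_se_on = "g1")
  f1 <- fe_fit(d, spec)
  d2 <- rbind(copy(d), copy(d))[, w := w / 2]
  f2 <- fe_fit(d2, spec)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  # dof factor differs only through N; estimates and meat/bread identical
  ratio <- f2$se / f1$se
  expect_lt(max(abs(ratio - ratio[1])), 1e-10)  # uniform scale shift only
  expect_lt(abs(ratio[1] - 1), 0.01)
})

test_that("fit matches lm + sandwich::vcovCL with dummy encoding", {
  d <- rand_fe_fixture(8)
  spec <- edu_spec("y", c("x1", "x2"), fixed_effects = c("g1", "g2"),
                   weights = "w", cluster_se_on = "g1")
  fit <- fe_fit(d, spec)
  m <- lm(y ~ x1 + x2 + factor(g1) + factor(g2), data = d, weights = w)
  V <- sandwich::vcovCL(m, cluster = d$g1, type = "HC1")
  expect_equal(fit$coefficients[c("x1", "x2")], coef(m)[c("x1", "x2")],
               tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(V))[c("x1", "x2")]),
               tolerance = 1e-8)
  expect_true(all(fit$ci_low < fit$coefficients &
                    fit$coefficients < fit$ci_high))
  expect_equal(unname(fit$se), unname(sqrt(diag(fit$vcov))))
})

test_that("Frisch-Waugh: an absorbed indicator added as control is inert", {
  d <- rand_fe_fixture(9)
  d[, ind := as.numeric(g1 == "a3")]
  spec0 <- edu_spec("y", c("x1", "x2"), fixed_effects = c("g1", "g2"),
                    weights = "w", cluster_se_on = "g1")
  spec1 <- edu_spec("y", c("x1", "x2"), controls = "ind",
                    fixed_effects = c("g1", "g2"), weights = "w",
                    cluster_se_on = "g1")
  f0 <- fe_fit(d, spec0)
  f1 <- fe_fit(d, spec1)
  expect_equal(f0$coefficients[c("x1", "x2")],
               f1$coefficients[c("x1", "x2")], tolerance = 1e-6)
  expect_true("ind" %in% f1$dropped_collinear)
})

test_that("weights are scale invariant; treatments without variation drop", {
  d <- rand_fe_fixture(10)
  spec <- edu_spec("y", c("x1", "x2"), fixed_effects = "g1",
                   weights = "w", cluster_se_on = "g1")
  f1 <- fe_fit(d, spec)
  d2 <- copy(d)[, w := w * 37.5]
  f2 <- fe_fit(d2, spec)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  # a treatment that is constant within every FE group is dropped with a note
  d3 <- copy(d)[, x2 := as.numeric(g1 == "a1")]
  spec3 <- edu_spec("y", c("x1", "x2"), fixed_effects = "g1",
                    weights = "w", cluster_se_on = "g1")
  f3 <- fe_fit(d3, spec3)
  expect_false("x2" %in% names(f3$coefficients))
  expect_true("x2" %in% f3$dropped_collinear)
})

test_that("logistic fit equals a glm oracle with identical encoding", {
  set.seed(11)
  n <- 250
  d <- data.table(g = sample(paste0("g", 1:6), n, TRUE),
                  x1 = rnorm(n), x2 = rnorm(n), w = runif(n, 0.5, 2))
  d[, y := rbinom(n, 1, plogis(-0.4 + 0.9 * x1 - 0.5 * x2))]
  spec <- edu_spec("y", c("x1", "x2"), fixed_effects = "g", weights = "w",
                   cluster_se_on = "g", family = "logistic")
  fit <- fit_logistic(d, spec)
  m <- suppressWarnings(glm(y ~ x1 + x2 + factor(g), data = d, weights = w,
                            family = binomial))
  expect_equal(unname(fit$coefficients[c("x1", "x2")]),
               unname(coef(m)[c("x1", "x2")]), tolerance = 1e-6)
  expect_equal(unname(fit$odds_ratio),
               unname(exp(coef(m)[c("x1", "x2")])), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("logistic degeneracies raise informative errors", {
  # outcome constant within every FE group: nothing identifiable
  d <- data.table(g = rep(c("a", "b"), each = 10),
                  x = rnorm(20), w = 1,
                  y = rep(c(0L, 1L), each = 10))
  spec <- edu_spec("y", "x", fixed_effects = "g", weights = "w",
                   cluster_se_on = "g", family = "logistic")
  expect_error(fit_logistic(d, spec), "nothing identifiable")
  # complete separation on a slope
  set.seed(12)
  d2 <- data.table(g = sample(c("a", "b"), 60, TRUE), x = rnorm(60), w = 1)
  d2[, y := as.integer(x > 0)]
  spec2 <- edu_spec("y", "x", fixed_effects = "g", weights = "w",
                    cluster_se_on = "g", family = "logistic")
  expect_error(fit_logistic(d2, spec2), "separation")
})

test_that("pooled sex-interacted model reproduces separate fits", {
  dF <- rand_fe_fixture(13)
  dM <- rand_fe_fixture(14)
  dF[, cluster_id := g1]; dM[, cluster_id := g1]
  spec <- edu_spec("y", c("x1", "x2"), fixed_effects = c("g1", "g2"),
                   weights = "w", cluster_se_on = "cluster_id")
  sc <- sex_contrast(spec, dF, dM)
  fF <- fe_fit(dF, spec)
  fM <- fe_fit(dM, spec)
  expect_equal(unname(sc$female[paste0(c("x1", "x2"), ":F")]),
               unname(fF$coefficients[c("x1", "x2")]), tolerance = 1e-8)
  expect_equal(unname(sc$male[paste0(c("x1", "x2"), ":M")]),
               unname(fM$coefficients[c("x1", "x2")]), tolerance = 1e-8)
  expect_equal(sc$contrast$estimate,
               unname(fF$coefficients[c("x1", "x2")] -
                        fM$coefficients[c("x1", "x2")]), tolerance = 1e-8)
  # identical samples relabelled F/M: contrast exactly zero
  sc0 <- sex_contrast(spec, dF, copy(dF))
  expect_equal(sc0$contrast$estimate, c(0, 0), tolerance = 1e-7)
})

test_that("tidy output carries one labelled row per reported term", {
  d <- rand_fe_fixture(15)
  fit <- fe_fit(d, edu_spec("y", c("x1", "x2"), fixed_effects = "g1",
                            weights = "w", cluster_se_on = "g1"))
  td <- tidy_fit(fit)
  expect_equal(td$term, c("x1", "x2"))
  expect_equal(td$estimate, unname(fit$coefficients))
  expect_true(all(td$ci_low < td$estimate & td$estimate < td$ci_high))
})
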