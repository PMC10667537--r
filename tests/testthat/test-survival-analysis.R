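test_that("stratified split allocates events proportionally and is deterministic", {
  co <- tibble::tibble(
    patient_id = 1:100,
    time_months = runif(100, 1, 100),
    event = rep(c(TRUE, FALSE), c(20, 80))
  )
  sp <- stratified_split(co, test_fraction = 0.3, seed = 5)
  expect_equal(sum(sp$event & sp$split_label == "test"), 6)
  expect_equal(sum(!sp$event & sp$split_label == "test"), 24)
  sp2 <- stratified_split(co, test_fraction = 0.3, seed = 5)
  expect_identical(sp$split_label, sp2$split_label)
  sp3 <- stratified_split(co, test_fraction = 0.3, seed = 6)
  expect_false(identical(sp$split_label, sp3$split_label))
  expect_error(stratified_split(co, test_fraction = 0, seed = 1), "between")
})

test_that("KM estimator: no events, no censoring, and a hand product-limit table", {
  k0 <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(k0$surv == 1))

  # n distinct event times, no censoring: S(t_(k)) = (n-k)/n
  k1 <- km_estimate(c(2, 4, 6, 8), c(1, 1, 1, 1))
  expect_equal(k1$surv, c(1, 3 / 4, 2 / 4, 1 / 4, 0))

  # mixed censoring, n = 6: events at 1, 3, 5; censored at 2, 4, 6
  # S(1) = 5/6; S(3) = 5/6 * 3/4; S(5) = 5/6 * 3/4 * 1/2
  k2 <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 0))
  ev <- k2[k2$n_event > 0, ]
  expect_equal(ev$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2))

  # invariant to subject ordering; S non-increasing
  set.seed(10)
  t <- rexp(40, 0.1) + 0.1
  e <- rbinom(40, 1, 0.6)
  o <- sample(40)
  expect_equal(km_estimate(t, e), km_estimate(t[o], e[o]))
  expect_true(all(diff(km_estimate(t, e)$surv) <= 1e-12))
  # with no censoring, 1 - S is the empirical CDF of event times
  kf <- km_estimate(t, rep(1, 40))
  expect_equal(1 - kf$surv[-1], ecdf(t)(kf$time[-1]))
})

test_that("log-rank: exchangeable groups give 0; hand O-E table reproduced", {
  t <- c(2, 5, 7, 9)
  e <- c(1, 0, 1, 1)
  # group B duplicates group A
  lr <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # A events at 1, 2; B events at 3, 4; no censoring
  # per-time O-E and hypergeometric variance by hand:
  # t=1: O_A=1 E_A=2/4  V=(2*2*1*3)/(16*3)=1/4
  # t=2: O_A=1 E_A=1/3  V=(1*2*1*2)/(9*2)=2/9
  # t=3: O_A=0 E_A=0    V=0 ; t=4: single subject, V=0
  # U = (1-1/2)+(1-1/3) = 7/6 ; V = 1/4+2/9 = 17/36 ; X2 = U^2/V
  lr2 <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr2$chi_square, (7 / 6)^2 / (17 / 36), tolerance = 1e-10)

  # symmetric in group labels
  set.seed(3)
  t2 <- rexp(60, 0.05) + 0.5
  e2 <- rbinom(60, 1, 0.5)
  g <- rep(c("x", "y"), 30)
  a <- logrank_test(t2, e2, g)
  b <- logrank_test(t2, e2, ifelse(g == "x", "y", "x"))
  expect_equal(a$chi_square, b$chi_square)

  expect_error(logrank_test(t2, e2, rep("x", 60)), "two nonempty")
  expect_warning(z <- logrank_test(t2, rep(0, 60), g), "No events")
  expect_true(is.na(z$chi_square))
})

test_that("optimal cut-point: forced binary choice, strict-greater labels, caveat", {
  set.seed(14)
  n <- 200
  f <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.01 * ifelse(f > 0, 2, 1))
  e <- t <= 120
  t <- pmin(t, 120)
  cp <- optimal_cutpoint(f, t, e, grid_policy = "unique")
  expect_equal(cp$cutoff, 0)  # the single admissible cut
  expect_equal(cp$n_low + cp$n_high, n)
  expect_match(cp$caveat, "maximally selected")
  expect_equal(cp$derived_on, "discovery")

  lab <- apply_cutpoint(c(1, 2, 3), 2)
  expect_equal(as.character(lab), c("low", "low", "high"))
  expect_warning(apply_cutpoint(c(1, 2), 5), "Degenerate")
})

test_that("optimal cut-point is invariant to strictly monotone feature transforms", {
  set.seed(23)
  n <- 300
  f <- rlnorm(n)
  step <- f > quantile(f, 0.5)
  t <- rexp(n, 0.004 * ifelse(step, 2.5, 1))
  e <- t <= 240
  t <- pmin(t, 240)
  cp1 <- optimal_cutpoint(f, t, e)
  cp2 <- optimal_cutpoint(log(f), t, e)
  expect_identical(f > cp1$cutoff, log(f) > cp2$cutoff)  # same partition
  expect_equal(cp1$chi_square_at_cutoff, cp2$chi_square_at_cutoff)
})

test_that("Cox fit matches a 1-D grid search of the partial likelihood", {
  set.seed(6)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(0.6 * x))
  e <- rep(1, n)  # no censoring, continuous times -> no ties
  fit <- cox_fit(data.frame(x = x), "x", t, e)
  grid <- seq(-1, 2, by = 1e-4)
  ll <- vapply(grid, log_partial_lik, numeric(1), time = t, event = e, x = x)
  beta_grid <- grid[which.max(ll)]
  expect_equal(fit$table$beta, beta_grid, tolerance = 1e-3)
  expect_true(fit$table$ci_low <= fit$table$hr &&
                fit$table$hr <= fit$table$ci_high)
})

test_that("Cox null covariate: HR near 1 with covering CI; errors are informative", {
  set.seed(44)
  n <- 800
  x <- rnorm(n)
  t <- rexp(n, 0.02)
  e <- rbinom(n, 1, 0.8)
  fit <- cox_fit(data.frame(x = x), "x", t, e)
  expect_lt(abs(fit$table$beta), 0.15)
  expect_true(fit$table$ci_low < 1 && 1 < fit$table$ci_high)
  expect_error(cox_fit(data.frame(x = rep(1, n)), "x", t, e), "Constant")
  expect_error(cox_fit(data.frame(z = x), "x", t, e), "not found")
})

test_that("Cox score test (Breslow) equals the log-rank chi-square", {
  set.seed(77)
  for (i in 1:5) {
    n <- 80
    g <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.03 * exp(0.4 * g))
    e <- as.integer(t <= quantile(t, 0.8))
    t <- pmin(t, quantile(t, 0.8))
    fit <- cox_fit(data.frame(g = g), "g", t, e, ties = "breslow")
    sc <- summary(fit$fit)$sctest[["test"]]
    lr <- logrank_test(t, e, g)$chi_square
    expect_equal(sc, lr, tolerance = 1e-8)
  }
})

test_that("per-1000-unit rescaling inverts the reporting convention", {
  expect_equal(hr_per_k_units(log(1.2) / 1000, k = 1000)$hr, 1.2)
  expect_equal(hr_per_k_units(0, k = 1000)$hr, 1)
  expect_equal(hr_per_k_units(0.3, k = 1)$hr, exp(0.3))
  # via a fitted model: CI endpoints transform identically
  set.seed(15)
  n <- 300
  x <- rpois(n, 500)
  t <- rexp(n, 0.01 * exp(0.001 * x))
  e <- t <= 100
  t <- pmin(t, 100)
  fit <- cox_fit(data.frame(x = x), "x", t, e)
  h <- hr_per_k_units(fit, k = 1000, term = "x")
  expect_equal(h$hr, exp(1000 * fit$table$beta))
  expect_equal(h$ci_low, exp(1000 * (fit$table$beta - qnorm(0.975) * fit$table$se)))
})
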