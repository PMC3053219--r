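test_that("the product-limit estimate matches the hand-computed example", {
  fit <- worked_fit()
  expect_equal(fit$times, c(1, 2, 3, 4))
  expect_equal(fit$n_risk, c(4L, 3L, 2L, 1L))
  expect_equal(fit$n_event, c(1L, 0L, 1L, 0L))
  expect_equal(fit$n_censor, c(0L, 1L, 0L, 1L))
  # S(1) = 3/4; S(3) = 3/4 * 1/2 = 3/8
  expect_equal(fit$survival, c(3/4, 3/4, 3/8, 3/8))
  # Greenwood: S^2 * sum d/(n(n-d)) -> (3/4)^2/12 = 3/64; (3/8)^2 * 7/12 = 21/256
  expect_equal(fit$variance, c(3/64, 3/64, 21/256, 21/256))
  expect_equal(median_survival(fit), 3)
  expect_equal(median(fit), 3)
})

test_that("step-function evaluation is right-continuous with flat extension", {
  fit <- worked_fit()
  expect_equal(survival_at(fit, 0)$survival, 1)
  expect_equal(survival_at(fit, 2)$survival, 3/4)   # carried from t = 1
  expect_equal(survival_at(fit, 2.999)$survival, 3/4)
  expect_equal(survival_at(fit, 3)$survival, 3/8)
  expect_equal(survival_at(fit, 100)$survival, 3/8)
  expect_error(survival_at(fit, -1), "non-negative")
  expect_equal(predict(fit, c(0.5, 3.5))$survival, c(1, 3/8))
})

test_that("numbers at risk count observations not yet ended", {
  fit <- worked_fit()
  expect_equal(numbers_at_risk(fit, 0), 4L)
  expect_equal(numbers_at_risk(fit, 2.5), 2L)
  expect_equal(numbers_at_risk(fit, 99), 0L)
  expect_equal(numbers_at_risk(c(1, 2, 3, 4), c(0, 1, 2.5, 4.1)),
               c(4L, 4L, 2L, 0L))
})

test_that("without censoring the estimate is the empirical survivor function", {
  set.seed(101)
  for (i in 1:20) {
    t <- round(rexp(sample(10:80, 1), 0.3), 3)
    fit <- km_fit(t, rep(1L, length(t)))
    expect_equal(fit$survival, empirical_survivor(t, fit$times))
  }
})

test_that("degenerate inputs are handled explicitly", {
  # all censored: S identically 1, zero variance
  fit <- km_fit(c(1, 2, 5), c(0, 0, 0))
  expect_equal(fit$survival, c(1, 1, 1))
  expect_equal(fit$variance, c(0, 0, 0))
  expect_true(is.na(median_survival(fit)))
  # all times zero, no events
  fit0 <- km_fit(c(0, 0), c(0, 0))
  expect_equal(fit0$survival, 1)
  expect_error(km_fit(numeric(0), integer(0)), "no observations")
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
  expect_error(km_fit(c(1, 2), c(1, 2)), "event")
})

test_that("curve invariants hold on random censored samples", {
  set.seed(202)
  for (i in 1:15) {
    n <- sample(20:120, 1)
    fit <- km_fit(round(rexp(n, 0.2), 2), rbinom(n, 1, 0.7))
    expect_true(all(diff(fit$survival) <= 1e-12))
    expect_true(all(diff(fit$n_risk) <= 0))
    expect_equal(fit$n_risk[-1],
                 (fit$n_risk - fit$n_event - fit$n_censor)[-length(fit$n_risk)])
    ok <- !is.na(fit$ci_low) & !is.na(fit$ci_high)
    expect_true(all(fit$ci_low[ok] >= 0 & fit$ci_high[ok] <= 1))
    expect_true(all(fit$ci_low[ok] <= fit$survival[ok] + 1e-12))
    expect_true(all(fit$ci_high[ok] >= fit$survival[ok] - 1e-12))
    # Greenwood variance starts at 0 and never decreases
    expect_true(all(diff(fit$variance / fit$survival^2)[fit$survival[-1] > 0] >= -1e-12))
  }
})

test_that("rescaling time rescales the curve but not the estimates", {
  set.seed(7)
  t <- rexp(60, 0.1); ev <- rbinom(60, 1, 0.5)
  f1 <- km_fit(t, ev)
  f2 <- km_fit(3.5 * t, ev)
  expect_equal(f2$times, 3.5 * f1$times)
  expect_equal(f2$survival, f1$survival)
  expect_equal(f2$variance, f1$variance)
  expect_equal(median_survival(f2), 3.5 * median_survival(f1))
})

test_that("confidence transforms agree with the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(33)
  t <- round(rexp(120, 0.15), 3); ev <- rbinom(120, 1, 0.6)
  for (ct in c("log", "log-log", "plain")) {
    fit <- km_fit(t, ev, conf_type = ct)
    sf <- summary(survival::survfit(
      survival::Surv(t, ev) ~ 1,
      conf.type = ifelse(ct == "plain", "plain", ifelse(ct == "log", "log", "log-log"))),
      times = fit$times)
    ok <- !is.na(sf$lower) & !is.na(fit$ci_low) & sf$surv > 0 & sf$surv < 1
    expect_lt(max(abs(fit$ci_low[ok] - sf$lower[ok])), 1e-9)
    expect_lt(max(abs(fit$ci_high[ok] - pmin(1, sf$upper)[ok])), 1e-9)
  }
})

test_that("median recovers the exponential closed form at scale", {
  set.seed(404)
  n <- 5000
  t <- rexp(n, 0.1); cens <- runif(n, 0, 18)
  fit <- km_fit(pmin(t, cens), as.integer(t <= cens))
  expect_lt(abs(median_survival(fit) - log(2) / 0.1) / (log(2) / 0.1), 0.05)
})

test_that("endpoint selection reads the record schema", {
  rec <- data.frame(time_years = c(5, 8), os_event = c(1L, 0L),
                    efs_time_years = c(3, 8), efs_event = c(1L, 0L))
  expect_equal(km_fit(rec, endpoint = "os")$times, c(5, 8))
  expect_equal(km_fit(rec, endpoint = "efs")$times, c(3, 8))
  expect_equal(km_fit(rec, endpoint = "efs")$endpoint, "efs")
  expect_output(print(km_fit(rec)), "Kaplan-Meier")
  expect_output(print(summary(worked_fit())), "median", ignore.case = TRUE)
})
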