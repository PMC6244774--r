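test_that("cox_fit matches a brute-force partial-likelihood maximizer", {
  # small untied uncensored instances; oracle maximizes the explicit
  # Breslow log partial likelihood over a coefficient grid
  set.seed(31)
  for (rep in 1:4) {
    n <- 8
    x <- rnorm(n)
    time <- rexp(n, exp(0.4 * x))
    event <- rep(1L, n)
    fit <- cox_fit(time, event, x)
    oracle <- optimize(function(b) brute_cox_loglik(b, time, event, x),
                       c(-10, 10), maximum = TRUE, tol = 1e-10)
    expect_equal(fit$coef[[1]], oracle$maximum, tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$objective, tolerance = 1e-8)
  }
})

test_that("cox_fit agrees with survival::coxph on tied data (both tie methods)", {
  skip_if_not_installed("survival")
  d <- toy_surv(seed = 32, n = 40, tie = TRUE)
  expect_gt(max(table(d$time[d$event == 1])), 1) # ties present
  for (ties in c("breslow", "efron")) {
    mine <- cox_fit(d$time, d$event, d$x, tie_method = ties)
    ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x,
                           ties = ties)
    expect_equal(mine$coef[[1]], unname(coef(ref)), tolerance = 1e-7)
    expect_equal(mine$se[[1]],
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-7)
  }
  # two covariates
  set.seed(33)
  x2 <- rnorm(40)
  mine2 <- cox_fit(d$time, d$event, cbind(a = d$x, b = x2))
  ref2 <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x + x2,
                          ties = "breslow")
  expect_equal(unname(mine2$coef), unname(coef(ref2)), tolerance = 1e-7)
})

test_that("Breslow and Efron agree exactly without tied event times", {
  set.seed(34)
  n <- 25
  x <- rnorm(n)
  time <- rexp(n, exp(0.5 * x)) # continuous: no ties a.s.
  event <- rbinom(n, 1, 0.8)
  if (sum(event) == 0) event[1] <- 1L
  fb <- cox_fit(time, event, x, tie_method = "breslow")
  fe <- cox_fit(time, event, x, tie_method = "efron")
  expect_equal(fb$coef, fe$coef, tolerance = 1e-12)
  expect_equal(fb$loglik, fe$loglik, tolerance = 1e-12)
})

test_that("HR is invariant to covariate shifts and scales as exp(c beta)", {
  d <- toy_surv(seed = 35)
  f0 <- cox_fit(d$time, d$event, d$x)
  fshift <- cox_fit(d$time, d$event, d$x + 100)
  expect_equal(fshift$coef[[1]], f0$coef[[1]], tolerance = 1e-7)
  fscale <- cox_fit(d$time, d$event, d$x / 2)
  expect_equal(fscale$coef[[1]], 2 * f0$coef[[1]], tolerance = 1e-7)
})

test_that("Wald, likelihood-ratio and score tests agree at large n", {
  set.seed(36)
  n <- 2000
  x <- rnorm(n)
  cfg <- synth_config(n_patients = n, log_hr_per_sd = 0.2,
                      censor_rate = 0.2, seed = 36)
  sv <- generate_survival(cfg, x)
  fit <- cox_fit(sv$time_weeks, sv$event, x)
  wald <- (fit$coef[[1]] / fit$se[[1]])^2
  lr <- 2 * (fit$loglik - fit$loglik_null)
  pl0 <- oscillomark:::.cox_pl(0, cbind(x), sv$time_weeks, sv$event,
                               "breslow")
  score <- pl0$grad^2 / (-pl0$hess)
  expect_lt(abs(wald - lr) / lr, 0.1)
  expect_lt(abs(score - lr) / lr, 0.1)
})

test_that("degenerate Cox inputs raise informative errors", {
  d <- toy_surv(seed = 37)
  expect_error(cox_fit(d$time, d$event, rep(1, length(d$time))),
               "constant covariate")
  expect_error(cox_fit(d$time, rep(0L, length(d$time)), d$x),
               "at least one")
  expect_error(cox_fit_bivariate(d$time, d$event, d$x, d$x),
               "collinear")
  # monotone likelihood: the covariate perfectly orders the event times
  t_sep <- 1:10
  x_sep <- 1:10
  expect_error(cox_fit(t_sep, rep(1L, 10), x_sep), "converge")
})

test_that("null covariates recover a zero coefficient on average", {
  set.seed(38)
  coefs <- replicate(40, {
    cfg <- synth_config(n_patients = 60, log_hr_per_sd = 0,
                        censor_rate = 0.2, seed = sample.int(1e6, 1))
    z <- rnorm(60)
    sv <- generate_survival(cfg, z)
    cox_fit(sv$time_weeks, sv$event, z)$coef[[1]]
  })
  expect_lt(abs(mean(coefs)), 3 * sd(coefs) / sqrt(length(coefs)) + 0.02)
})

test_that("Kaplan-Meier matches the product-limit oracle and survfit", {
  skip_if_not_installed("survival")
  set.seed(39)
  time <- sample(1:20, 15, replace = TRUE)
  event <- rbinom(15, 1, 0.7)
  km <- km_estimate(time, event)
  oracle <- brute_km(time, event)
  expect_equal(km$times, oracle$times)
  expect_equal(km$survival, oracle$survival)
  ref <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km$survival[km$times %in% ref$time],
               ref$surv[ref$time %in% km$times], tolerance = 1e-12)
  # survival starts at <= 1, non-increasing, drops only at event times
  expect_true(all(diff(km$survival) <= 1e-12))
  drops <- km$times[c(km$survival[1] < 1, diff(km$survival) < 0)]
  expect_true(all(drops %in% time[event == 1]))
})

test_that("KM handles the no-censoring and all-censored corners", {
  # no censoring: survival at t equals the empirical fraction above t
  t_all <- c(3, 1, 4, 2, 6)
  km <- km_estimate(t_all, rep(1L, 5))
  expect_equal(km$survival, 1 - ecdf(t_all)(km$times))
  expect_equal(km$median_time, 3)
  # all censored: flat at 1, median undefined
  km0 <- km_estimate(t_all, rep(0L, 5))
  expect_true(all(km0$survival == 1))
  expect_true(is.na(km0$median_time))
  expect_equal(km_table(km0)$n_censor, rep(1L, 5))
})

test_that("median split and median event time follow their tie rules", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 3)), c("low", "low", "high"))
  expect_error(median_split(rep(1, 4)), "degenerate")
  coh <- glioma_cohort()
  expect_equal(as.vector(table(median_split(coh$oba_global_z))),
               c(12, 12))

  expect_equal(median_event_time(c(8, 29, 39), c(1, 1, 1))$median_weeks, 29)
  expect_equal(median_event_time(c(10, 50), c(0, 1))$median_weeks, 50)
  expect_error(median_event_time(c(10, 50), c(0, 0)), "no observed events")
})
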