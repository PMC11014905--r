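test_that("the partial-likelihood maximum matches a grid-search oracle", {
  time <- c(2, 4, 5, 7, 9)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  x <- c(1, 0, 1, 1, 0)
  fit <- cox_fit(time, event, x)
  grid <- seq(-4, 4, by = 0.001)
  ll <- vapply(grid, cox_loglik_oracle, numeric(1), time, event, x)
  expect_equal(fit$coef[[1]], grid[which.max(ll)], tolerance = 2e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-5)
  expect_gte(fit$loglik, fit$loglik0)
})

test_that("coefficients and standard errors match survival::coxph for both tie rules", {
  skip_if_not_installed("survival")
  set.seed(14)
  n <- 120
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  time <- round(rexp(n, 0.05 * exp(0.4 * x[, "a"] - 0.6 * x[, "b"])), 1)
  event <- runif(n) < 0.75
  for (tie in c("efron", "breslow")) {
    fit <- cox_fit(time, event, x, ties = tie)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = tie)
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
    expect_true(all(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper))
  }
})

test_that("degenerate inputs are rejected or reported", {
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0), c(0, 0, 0)), "constant")
  expect_error(cox_fit(c(1, 2), c(0, 0), c(0, 1)), "event")
  # perfectly separating covariate drives a monotone likelihood
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- rep(TRUE, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(fit <- cox_fit(time, event, x), "monotone")
  expect_true(fit$monotone)
})

test_that("the score test at the null equals the log-rank statistic", {
  set.seed(17)
  n <- 80
  group <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.08 * exp(0.5 * group))   # continuous: no ties
  event <- runif(n) < 0.8
  fit <- cox_fit(time, event, group, ties = "breslow")
  lr <- logrank_test(time, event, group)
  expect_equal(fit$score_chisq, lr$chisq, tolerance = 1e-8)
})

test_that("a true hazard ratio of 2 is recovered with nominal coverage", {
  set.seed(23)
  covered <- logical(100)
  est <- numeric(100)
  for (r in seq_len(100)) {
    x <- rbinom(200, 1, 0.5)
    time <- rexp(200, 0.05 * exp(log(2) * x))
    cens <- runif(200, 5, 60)
    fit <- cox_fit(pmin(time, cens), time <= cens, x)
    est[r] <- fit$hr[1]
    covered[r] <- fit$ci_lower[1] <= 2 && 2 <= fit$ci_upper[1]
  }
  expect_equal(mean(est), 2, tolerance = 0.15)
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 0.995)
})

test_that("counting-process episodes reproduce the time-fixed fit", {
  skip_if_not_installed("survival")
  set.seed(29)
  n <- 60
  x <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.3 * x))
  event <- runif(n) < 0.8
  # artificial episode split at half-time must leave the estimate unchanged
  half <- time / 2
  start <- c(rep(0, n), half)
  stop_t <- c(half, time)
  ev <- c(rep(FALSE, n), event)
  xx <- c(x, x)
  fit0 <- cox_fit(time, event, x)
  fit1 <- cox_fit(stop_t, ev, xx, start = start)
  expect_equal(fit1$coef, fit0$coef, tolerance = 1e-8)
})

test_that("Mantel-Byar treats exposure as a time-dependent state", {
  # nobody enters the state: undefined, flagged
  res <- mantel_byar_test(c(5, 8, 10), c(1, 0, 1), c(NA, NA, NA))
  expect_false(res$defined)
  expect_error(mantel_byar_test(10, TRUE, 12), "entry after")

  skip_if_not_installed("survival")
  set.seed(37)
  n <- 150
  entry <- ifelse(runif(n) < 0.5, runif(n, 1, 6), NA)
  base <- rexp(n, 0.04)
  time <- pmin(base, runif(n, 20, 80))
  event <- base <= time
  entry[!is.na(entry) & entry >= time] <- NA
  res <- mantel_byar_test(time, event, entry)
  # oracle: time-dependent coxph on the same episode split
  entered <- !is.na(entry)
  df <- rbind(data.frame(start = 0, stop = ifelse(entered, entry, time),
                         ev = ifelse(entered, FALSE, event), z = 0),
              data.frame(start = entry[entered], stop = time[entered],
                         ev = event[entered], z = 1))
  df <- df[df$stop > df$start, ]
  ref <- survival::coxph(survival::Surv(start, stop, ev) ~ z, data = df)
  expect_equal(unname(res$fit$coef), unname(coef(ref)), tolerance = 1e-6)
  # the test statistic is the score test of that model
  sref <- summary(ref)
  expect_equal(res$chisq, unname(sref$sctest["test"]), tolerance = 0.05)
})

test_that("a protective post-entry hazard is recovered by the companion fit", {
  set.seed(41)
  hrs <- numeric(10)
  for (r in seq_len(10)) {
    n <- 400
    lam <- 0.05
    entry <- ifelse(runif(n) < 0.6, runif(n, 1, 8), NA)
    t1 <- rexp(n, lam)                      # pre-entry death time
    time <- ifelse(!is.na(entry) & t1 > entry,
                   entry + rexp(n, lam * 0.5), t1)
    entry[!is.na(entry) & t1 <= entry] <- NA
    cens <- runif(n, 30, 90)
    event <- time <= cens
    time <- pmin(time, cens)
    hrs[r] <- mantel_byar_test(time, event, entry)$fit$hr[1]
  }
  expect_equal(mean(hrs), 0.5, tolerance = 0.1)
})
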