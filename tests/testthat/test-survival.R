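# Follow-up filter, Kaplan-Meier, log-rank, maximally selected cutpoint,
# Cox fit and concordance.

clin4 <- data.frame(sample_id = c("a", "b", "c", "d"),
                    time = c(5, 8, 10, 12), event = c(1, 1, 0, 0),
                    stringsAsFactors = FALSE)

test_that("follow-up filter is strict at the 90-day boundary", {
  clin <- data.frame(sample_id = letters[1:4], time = c(30, 90, 91, 400),
                     event = c(1, 0, 1, 0), stringsAsFactors = FALSE)
  expect_message(kept <- filter_followup(clin), "kept 2 of 4")
  expect_equal(kept$time, c(91, 400))
  expect_equal(nrow(suppressMessages(filter_followup(clin[0, ]))), 0)
  set.seed(41)
  big <- rand_clin(500)
  expect_equal(suppressMessages(filter_followup(big))$sample_id,
               big$sample_id[big$time > 90])
})

test_that("follow-up truncation censors at the horizon", {
  tr <- truncate_followup(data.frame(time = c(100, 2000), event = c(1, 1)),
                          days = 1825)
  expect_equal(tr$time, c(100, 1825))
  expect_equal(tr$event, c(1, 0))
})

test_that("Kaplan-Meier matches the hand product-limit table", {
  km <- km_estimate(clin4)
  expect_equal(km_survival_at(km, c(0, 5, 8, 12)), c(1, 0.75, 0.5, 0.5))
  allc <- km_estimate(data.frame(time = c(3, 7, 9), event = c(0, 0, 0)))
  expect_true(all(allc$survival == 1))
  set.seed(42)
  big <- rand_clin(200)
  km2 <- km_estimate(big)
  expect_true(all(diff(km2$survival) <= 1e-12))
  expect_true(all(km2$survival >= 0 & km2$survival <= 1))
  expect_equal(km2, km_estimate(big[sample(nrow(big)), ]))  # order-invariant
})

test_that("log-rank matches the hand hypergeometric tally on a 2+2 toy", {
  a <- data.frame(time = c(1, 2), event = c(1, 1))
  b <- data.frame(time = c(3, 4), event = c(1, 1))
  lr <- logrank_test(a, b)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6)         # 2/4 + 1/3
  expect_equal(lr$variance, 17 / 36)       # 1/4 + 2/9
  expect_equal(lr$standardized, (7 / 6) / sqrt(17 / 36))
  expect_equal(lr$chisq, lr$standardized^2)
  # symmetry up to the sign of the standardized statistic
  expect_equal(logrank_test(b, a)$standardized, -lr$standardized)
  # identical groups: null
  g <- data.frame(time = c(2, 5, 9), event = c(1, 0, 1))
  same <- logrank_test(g, g)
  expect_lt(abs(same$standardized), 1e-10)
  expect_gt(same$p.value, 0.99)
  expect_error(logrank_test(data.frame(time = 1, event = 0),
                            data.frame(time = 2, event = 0)), "no events")
})

test_that("log-rank agrees with survdiff on 100 random datasets", {
  set.seed(43)
  for (k in 1:100) {
    a <- rand_clin(sample(5:30, 1))
    b <- rand_clin(sample(5:30, 1))
    if (sum(a$event) + sum(b$event) == 0) next
    lr <- logrank_test(a, b)
    df <- data.frame(time = c(a$time, b$time), event = c(a$event, b$event),
                     g = rep(1:2, c(nrow(a), nrow(b))))
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-6)
  }
})

test_that("optimal cutpoint equals the exhaustive survdiff oracle", {
  set.seed(44)
  for (k in 1:100) {
    n <- sample(25:45, 1)
    clin <- rand_clin(n)
    vals <- round(rnorm(n), 2)
    got <- tryCatch(optimal_cutoff(vals, clin), error = function(e) NULL)
    want <- oracle_cutoff(vals, clin)
    if (is.null(want)) { expect_null(got); next }
    expect_equal(got$cutpoint, want$cutpoint)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-6)
    expect_true(got$selection_biased)
    expect_true(all(got$group_sizes >= 0.1 * n))
  }
})

test_that("cutpoint lands on a separation boundary and rejects degenerates", {
  # low covariate values die early, high values are censored late
  clin <- data.frame(time = c(10, 20, 30, 40, 500, 600, 700, 800),
                     event = c(1, 1, 1, 1, 0, 0, 0, 0))
  vals <- c(1, 2, 3, 4, 11, 12, 13, 14)
  cut <- optimal_cutoff(vals, clin)
  # maximal selection picks a split inside the early-event value cluster
  # (the hypergeometric variance can favour an interior split over the
  # exact boundary); the grouping still separates early from late subjects
  expect_lte(cut$cutpoint, 4)
  expect_equal(cut$cutpoint, oracle_cutoff(vals, clin)$cutpoint)
  expect_error(optimal_cutoff(rep(1, 8), clin), "no admissible")
  expect_error(optimal_cutoff(vals, transform(clin, event = 0)),
               "no admissible")
})

test_that("Cox fit recovers a planted log-hazard ratio and is invariant", {
  set.seed(45)
  n <- 500
  x <- rnorm(n)
  t_ev <- rexp(n, rate = 0.002 * exp(0.7 * x))
  t_c <- rexp(n, rate = 0.001)
  clin <- data.frame(time = pmin(t_ev, t_c),
                     event = as.integer(t_ev <= t_c), x = x)
  fit <- cox_fit(clin, "x")
  expect_lt(abs(unname(fit$coef["x"]) - 0.7), 0.15)
  expect_gt(fit$c_index, 0.6)
  # invariance: time-unit rescaling and covariate shift leave beta alone
  clin2 <- transform(clin, time = time / 365.25)
  expect_equal(unname(cox_fit(clin2, "x")$coef), unname(fit$coef),
               tolerance = 1e-6)
  clin3 <- transform(clin, x = x + 100)
  expect_equal(unname(cox_fit(clin3, "x")$coef), unname(fit$coef),
               tolerance = 1e-6)
})

test_that("null covariates give beta near 0 and chance-level concordance", {
  set.seed(46)
  cvals <- replicate(20, {
    clin <- rand_clin(120)
    noise <- rnorm(120)
    harrell_c(noise, clin)
  })
  expect_lt(abs(mean(cvals) - 0.5), 0.03)
  clin <- rand_clin(200)
  clin$grp <- rep(0:1, 100)                 # binary covariate, no effect
  fit <- cox_fit(clin, "grp")
  expect_lt(abs(unname(fit$coef)), 2.5 * fit$se)
  expect_error(cox_fit(transform(clin, event = 0), "grp"), "no events")
})
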