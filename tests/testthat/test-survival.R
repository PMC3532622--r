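test_that("Kaplan-Meier estimates match the hand product-limit calculation", {
  # three subjects, all events
  d <- tibble::tibble(time = c(1, 2, 3), event = c(1L, 1L, 1L))
  km <- km_curve(d, time, event)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_identical(km$n_risk, c(3, 2, 1))

  # no events: flat at one
  flat <- km_curve(tibble::tibble(time = c(2, 5), event = c(0L, 0L)),
                   time, event)
  expect_true(all(flat$survival == 1))

  # censoring after the last event leaves earlier survival unchanged
  d2 <- tibble::tibble(time = c(1, 2, 3, 10), event = c(1L, 1L, 1L, 0L))
  km2 <- km_curve(d2, time, event)
  expect_equal(km2$survival[km2$time <= 3], c(3 / 4, 2 / 4, 1 / 4),
               tolerance = 1e-12)

  # hand-computable mixed fixtures with ties and censoring
  withr::local_seed(26)
  for (i in 1:10) {
    t <- sample(1:4, 5, replace = TRUE)
    e <- rbinom(5, 1, 0.7)
    if (sum(e) == 0) next
    got <- km_curve(tibble::tibble(time = t, event = e), time, event)
    ref <- brute_km(t, e)
    at_events <- got[got$n_event > 0, ]
    expect_equal(at_events$survival,
                 ref$survival[match(at_events$time, ref$time)],
                 tolerance = 1e-12)
  }

  expect_error(km_curve(tibble::tibble(time = -1, event = 1L), time, event),
               "non-negative")
})

test_that("log-rank agrees with the contingency-ledger oracle on 2 and 3 strata", {
  # identical strata: no signal
  d <- tibble::tibble(time = rep(c(1, 2, 3, 4), 2), event = rep(1L, 8),
                      g = rep(c("a", "b"), each = 4))
  out <- logrank_test(d, time, event, g)
  expect_gt(out$p_value, 0.99)

  # 12-subject toy, 3 strata, hand-coded 2-df oracle
  toy <- tibble::tibble(
    time = c(1, 2, 2, 3, 5, 6, 1, 4, 4, 7, 8, 9),
    event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 1L),
    g = rep(c("a", "b", "c"), each = 4)
  )
  got <- logrank_test(toy, time, event, g)
  expect_identical(got$df, 2L)
  expect_equal(got$statistic, brute_logrank(toy$time, toy$event, toy$g),
               tolerance = 1e-8)

  # two-stratum random fixtures against the same oracle
  withr::local_seed(27)
  for (i in 1:5) {
    t <- round(rexp(30, 0.2), 1)
    e <- rbinom(30, 1, 0.6)
    g <- rep(c("a", "b"), 15)
    if (sum(e) == 0) next
    got <- logrank_test(tibble::tibble(time = t, event = e, g = g),
                        time, event, g)
    expect_equal(got$statistic, brute_logrank(t, e, g), tolerance = 1e-8)
  }

  expect_error(logrank_test(dplyr::mutate(toy, event = 0L), time, event, g),
               "all censored")
  expect_error(logrank_test(dplyr::mutate(toy, g = "a"), time, event, g),
               "at least 2 strata")
})

test_that("log-rank detects a hazard-ratio-4 difference at the expected power", {
  withr::local_seed(28)
  rejects <- vapply(1:40, function(i) {
    t1 <- rexp(100, 0.05)
    t2 <- rexp(100, 0.2)
    cens <- runif(200, 0, 12)
    t <- pmin(c(t1, t2), cens)
    e <- as.integer(c(t1, t2) <= cens)
    d <- tibble::tibble(time = t, event = e, g = rep(c("a", "b"), each = 100))
    logrank_test(d, time, event, g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejects), 0.95)
})

test_that("Cox HR is horizon-censored, unit-invariant and warns on no-event groups", {
  withr::local_seed(29)
  n <- 200
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  t_event <- rexp(n, ifelse(pos, 0.02, 0.08))
  cens <- runif(n, 2, 15)
  d <- tibble::tibble(time = pmin(t_event, cens),
                      event = as.integer(t_event <= cens),
                      pos = pos)
  fit <- cox_hr(d, time, event, pos, horizon = 10)
  expect_lt(fit$hr, 1)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # time unit change leaves the HR untouched (horizon scaled along)
  d2 <- dplyr::mutate(d, time = time * 2)
  fit2 <- cox_hr(d2, time, event, pos, horizon = 20)
  expect_equal(fit2$hr, fit$hr, tolerance = 1e-8)

  # no events in one group: degenerate, warn but report
  d3 <- dplyr::mutate(d, event = ifelse(pos, 0L, event))
  expect_warning(cox_hr(d3, time, event, pos), "degenerate")

  expect_error(cox_hr(dplyr::mutate(d, pos = TRUE), time, event, pos),
               "both groups")
})

test_that("TYMS comparison recovers the generated shifts with the right sign", {
  withr::local_seed(30)
  ok <- vapply(1:20, function(i) {
    sim <- simulate_cohort(sim_config(n_samples = 200, seed = 300 + i))
    calls <- tibble::tibble(sample_id = sim$truth$sample_id,
                            call = sim$truth$latent_class)
    out <- tyms_comparison(sim$expression, calls)
    all(out$mean_case > out$mean_mss)
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  # permuted calls kill the signal
  sim <- simulate_cohort(sim_config(n_samples = 200, seed = 999))
  calls <- tibble::tibble(sample_id = sim$truth$sample_id,
                          call = sample(sim$truth$latent_class))
  out <- tyms_comparison(sim$expression, calls)
  expect_true(all(out$p_value > 1e-6, na.rm = TRUE))

  expect_error(tyms_comparison(dplyr::select(sim$expression, -TYMS), calls),
               "TYMS absent")
})

test_that("horizon censoring truncates times and clears late events", {
  out <- censor_at_horizon(c(3, 12, 10), c(1L, 1L, 1L), horizon = 10)
  expect_equal(out$time, c(3, 10, 10))
  expect_identical(out$event, c(1L, 0L, 1L))
  expect_error(censor_at_horizon(-1, 1L), "non-negative")
})
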