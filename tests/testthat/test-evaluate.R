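test_that("primary threshold optimisation matches exhaustive enumeration", {
  # worked example: interleaved labels, optimum in the first gap
  d <- tibble::tibble(index = c(0.1, 0.2, 0.3, 0.4),
                      msi = c(FALSE, TRUE, FALSE, TRUE))
  got <- optimize_primary_threshold(d, index, msi)
  expect_equal(got$threshold, 0.15)
  expect_equal(got$sum_sens_spec, 1.5)

  # perfectly separated: gap midpoint, sens = spec = 1
  d2 <- tibble::tibble(index = c(-0.5, -0.2, 0.4, 0.9),
                       msi = c(FALSE, FALSE, TRUE, TRUE))
  got2 <- optimize_primary_threshold(d2, index, msi)
  expect_equal(got2$threshold, 0.1)
  expect_equal(got2$sensitivity, 1)
  expect_equal(got2$specificity, 1)

  # random instances agree with the long-hand search, with and without floor
  withr::local_seed(14)
  for (i in 1:20) {
    n <- sample(10:120, 1)
    idx <- round(rnorm(n), 2) # force ties
    lab <- runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    d <- tibble::tibble(index = idx, msi = lab)
    got <- optimize_primary_threshold(d, index, msi)
    ref <- brute_best_threshold(idx, lab)
    expect_equal(got$sum_sens_spec, ref$total, tolerance = 1e-12)
    expect_equal(got$threshold, ref$threshold)
    gotf <- optimize_primary_threshold(d, index, msi,
                                       rule = "max_sens_plus_spec_with_floor",
                                       sens_floor = 0.9)
    reff <- brute_best_threshold(idx, lab, sens_floor = 0.9)
    expect_equal(gotf$sum_sens_spec, reff$total, tolerance = 1e-12)
    expect_gte(gotf$sensitivity, 0.9)
  }

  # label-independent indices cannot beat chance by much
  withr::local_seed(15)
  nulls <- vapply(1:20, function(i) {
    d <- tibble::tibble(index = rnorm(200), msi = rep(c(TRUE, FALSE), 100))
    optimize_primary_threshold(d, index, msi)$sum_sens_spec
  }, numeric(1))
  expect_lt(mean(nulls), 1.25)
})

test_that("the secondary threshold separates hospital classes among positives", {
  # hospital-MSI indices all above hospital-MSS: cut in the separating gap
  pos <- tibble::tibble(index = c(0.2, 0.25, 0.6, 0.8),
                        msi = c(FALSE, FALSE, TRUE, TRUE))
  got <- optimize_secondary_threshold(pos, index, msi)
  expect_equal(got$threshold, (0.25 + 0.6) / 2)
  expect_equal(got$sum_sens_spec, 2)

  withr::local_seed(16)
  for (i in 1:10) {
    idx <- rnorm(40)
    lab <- runif(40) < 0.5
    if (!any(lab) || all(lab)) next
    got <- optimize_secondary_threshold(tibble::tibble(index = idx, msi = lab),
                                        index, msi)
    expect_equal(got$sum_sens_spec, brute_best_threshold(idx, lab)$total,
                 tolerance = 1e-12)
  }
  expect_error(
    optimize_secondary_threshold(tibble::tibble(index = 1:3, msi = TRUE),
                                 index, msi),
    "single hospital class"
  )
})

test_that("AUC equals the pairwise-comparison count, ties at one half", {
  d <- tibble::tibble(index = c(1, 2, 3, 4), lab = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc_auc(d, index, lab, n_boot = 10)$auc, 1.0)
  d$lab <- c(FALSE, TRUE, FALSE, TRUE)
  expect_equal(roc_auc(d, index, lab, n_boot = 10)$auc, 0.75)

  withr::local_seed(17)
  for (i in 1:10) {
    idx <- sample(round(rnorm(60), 1)) # ties present
    lab <- runif(60) < 0.3
    if (!any(lab) || all(lab)) next
    d <- tibble::tibble(index = idx, lab = lab)
    expect_equal(roc_auc(d, index, lab, n_boot = 10)$auc,
                 brute_auc(idx, lab), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    d2 <- tibble::tibble(index = exp(2 * idx), lab = lab)
    expect_equal(roc_auc(d2, index, lab, n_boot = 10)$auc,
                 brute_auc(idx, lab), tolerance = 1e-12)
  }
})

test_that("null AUC is near half and the bootstrap CI covers it", {
  withr::local_seed(18)
  cover <- vapply(1:40, function(i) {
    d <- tibble::tibble(index = rnorm(200), lab = rep(c(TRUE, FALSE), 100))
    out <- roc_auc(d, index, lab, n_boot = 200, seed = i)
    expect_lt(abs(out$auc - 0.5), 0.1)
    out$ci_low <= 0.5 && out$ci_high >= 0.5
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # DeLong interval behaves similarly on a separated instance
  d <- tibble::tibble(index = c(rnorm(50), rnorm(50, 2)),
                      lab = rep(c(FALSE, TRUE), each = 50))
  dl <- roc_auc(d, index, lab, ci_method = "delong")
  expect_true(dl$ci_low <= dl$auc && dl$auc <= dl$ci_high)
})

test_that("performance reports reproduce confusion arithmetic and the optimiser's claim", {
  # constructed confusion mirroring development-cohort rates:
  # 29 positive (27 called), 247 negative (30 called)
  idx <- c(rep(1, 27), rep(-1, 2), rep(1, 30), rep(-1, 217))
  lab <- c(rep(TRUE, 29), rep(FALSE, 247))
  d <- tibble::tibble(index = idx, lab = lab)
  rep_ <- performance_report(d, index, lab, threshold = 0)
  expect_identical(c(rep_$tp, rep_$fn, rep_$fp, rep_$tn),
                   c(27L, 2L, 30L, 217L))
  expect_equal(rep_$sensitivity, 27 / 29, tolerance = 1e-12) # 0.931
  expect_equal(rep_$specificity, 217 / 247, tolerance = 1e-12) # 0.879
  expect_equal(rep_$overall_accuracy, 244 / 276, tolerance = 1e-12)

  perfect <- tibble::tibble(index = c(-1, -1, 1, 1),
                            lab = c(FALSE, FALSE, TRUE, TRUE))
  allright <- performance_report(perfect, index, lab, 0)
  expect_equal(allright$sensitivity, 1)
  expect_equal(allright$specificity, 1)
  expect_equal(allright$overall_accuracy, 1)
  expect_error(performance_report(perfect[0, ], index, lab, 0), "empty")

  # the report at the optimised threshold achieves the optimiser's sens+spec
  withr::local_seed(19)
  idx <- rnorm(80) + rep(c(0, 1.5), 40)
  lab <- rep(c(FALSE, TRUE), 40)
  d <- tibble::tibble(index = idx, lab = lab)
  opt <- optimize_primary_threshold(d, index, lab)
  at <- performance_report(d, index, lab, opt$threshold)
  expect_equal(at$sensitivity + at$specificity, opt$sum_sens_spec,
               tolerance = 1e-12)
})

test_that("optimize_thresholds sets both cut-offs on the model consistently", {
  withr::local_seed(20)
  n <- 120
  latent <- sample(c("MSI", "MSI_LIKE", "MSS"), n, replace = TRUE,
                   prob = c(0.15, 0.1, 0.75))
  idx <- rnorm(n, mean = c(MSI = 1.2, MSI_LIKE = 0.7, MSS = 0)[latent],
               sd = 0.25)
  scores <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), index = idx)
  labels <- tibble::tibble(sample_id = scores$sample_id,
                           msi = latent == "MSI")
  mod <- msi_signature(c("gA", "gB"), c(1, 0), c(0, 1))
  mod <- optimize_thresholds(mod, scores, labels)
  expect_true(has_thresholds(mod))
  expect_gte(mod$threshold_secondary, mod$threshold_primary)
  calls <- classify_index(idx, mod)
  # MSI-like latent samples are enriched among MSI_LIKE calls
  like_rate <- mean(latent[calls == "MSI_LIKE"] == "MSI_LIKE")
  overall <- mean(latent == "MSI_LIKE")
  expect_gt(like_rate, 2 * overall)
})
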