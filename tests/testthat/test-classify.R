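two_gene_model <- function(tp = 0.0, ts = 0.3) {
  # orthogonal centroids in the plane
  msi_signature(c("gA", "gB"), centroid_msi = c(1, 0),
                centroid_mss = c(0, 1),
                threshold_primary = tp, threshold_secondary = ts)
}

test_that("centroids are class means, independent of sample order", {
  m <- matrix(c(1, 3, 0, 1, 3, 2), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("gA", "gB")))
  expr <- expr_from_matrix(m)
  labels <- tibble::tibble(sample_id = c("a", "b", "c"),
                           msi = c(TRUE, TRUE, FALSE))
  mod <- build_centroids(expr, labels, c("gA", "gB"))
  expect_equal(mod$centroid_msi, c(2, 2)) # mean of (1,1), (3,3)
  expect_equal(mod$centroid_mss, c(0, 2)) # the single MSS sample

  mod2 <- build_centroids(expr[c(3, 1, 2), ], labels, c("gA", "gB"))
  expect_equal(mod2$centroid_msi, mod$centroid_msi)

  expect_error(build_centroids(expr, labels, c("gA", "gZ")), "absent.*gZ")
  labels$msi <- TRUE
  expect_error(build_centroids(expr, labels, "gA"), "both classes")
})

test_that("the index is the difference of cosine correlations, matching brute force", {
  mod <- two_gene_model()
  # profile == MSI centroid, orthogonal centroids: corr_msi 1, index 1
  expr <- expr_from_matrix(matrix(c(1, 0), 1, dimnames = list("s1", c("gA", "gB"))))
  out <- msi_index(expr, mod)
  expect_equal(out$corr_msi, 1, tolerance = 1e-12)
  expect_equal(out$corr_mss, 0, tolerance = 1e-12)
  expect_equal(out$index, 1, tolerance = 1e-12)

  # profile == -MSS centroid: index 0 - (-1) = 1
  out <- msi_index(expr_from_matrix(matrix(c(0, -1), 1,
                                           dimnames = list("s1", c("gA", "gB")))), mod)
  expect_equal(out$index, 1, tolerance = 1e-12)

  # random 64-dim profiles equal the loop-coded oracle to 1e-12
  withr::local_seed(8)
  genes <- sprintf("g%02d", 1:64)
  mod64 <- msi_signature(genes, rnorm(64), rnorm(64), 0, 0.2)
  profiles <- matrix(rnorm(5 * 64), 5, dimnames = list(sprintf("s%d", 1:5), genes))
  got <- msi_index(expr_from_matrix(profiles), mod64)
  for (i in 1:5) {
    expect_equal(got$corr_msi[i], brute_cosine(profiles[i, ], mod64$centroid_msi),
                 tolerance = 1e-12)
    expect_equal(got$index[i],
                 brute_cosine(profiles[i, ], mod64$centroid_msi) -
                   brute_cosine(profiles[i, ], mod64$centroid_mss),
                 tolerance = 1e-12)
  }
  expect_true(all(got$index >= -2 & got$index <= 2))
  expect_equal(got$index, got$corr_msi - got$corr_mss, tolerance = 1e-12)

  expect_error(
    msi_index(expr_from_matrix(matrix(c(0, 0), 1,
                                      dimnames = list("s1", c("gA", "gB")))), mod),
    "zero-norm"
  )
})

test_that("the index is scale-invariant and antisymmetric in the centroids", {
  withr::local_seed(9)
  genes <- sprintf("g%02d", 1:20)
  c1 <- rnorm(20); c2 <- rnorm(20)
  mod <- msi_signature(genes, c1, c2)
  profiles <- matrix(rnorm(4 * 20), 4, dimnames = list(sprintf("s%d", 1:4), genes))
  base <- msi_index(expr_from_matrix(profiles), mod)
  scaled <- msi_index(expr_from_matrix(3.7 * profiles), mod)
  expect_equal(scaled$index, base$index, tolerance = 1e-12)

  swapped <- msi_index(expr_from_matrix(profiles),
                       msi_signature(genes, c2, c1))
  expect_equal(swapped$index, -base$index, tolerance = 1e-12)
})

test_that("three-way calls respect the inclusive-upper boundary convention", {
  mod <- two_gene_model(tp = 0.0, ts = 0.3)
  calls <- classify_index(c(-0.1, 0.1, 0.3, 0.0), mod)
  expect_identical(as.character(calls), c("MSS", "MSI_LIKE", "MSI", "MSI_LIKE"))

  unset <- msi_signature(c("gA", "gB"), c(1, 0), c(0, 1))
  expect_error(classify_index(0.5, unset), "unset")
})

test_that("samples drawn around each centroid separate by index", {
  withr::local_seed(10)
  genes <- sprintf("g%02d", 1:30)
  c_msi <- rnorm(30); c_mss <- rnorm(30)
  mod <- msi_signature(genes, c_msi, c_mss)
  ok <- vapply(1:50, function(i) {
    a <- c_msi + rnorm(30, sd = 0.5) # SNR 2
    b <- c_mss + rnorm(30, sd = 0.5)
    m <- rbind(a, b); rownames(m) <- c("pa", "pb"); colnames(m) <- genes
    out <- msi_index(expr_from_matrix(m), mod)
    out$index[1] > out$index[2]
  }, logical(1))
  expect_true(all(ok))
})

test_that("platform reduction drops genes, records them and stales the thresholds", {
  withr::local_seed(13)
  genes <- sprintf("g%02d", 1:64)
  mod <- msi_signature(genes, rnorm(64), rnorm(64), 0.05, 0.2)
  avail <- genes[-(1:6)] # 58 of 64 genes survive the platform mapping
  red <- reduce_to_platform(mod, avail)
  expect_identical(length(red$gene_ids), 58L)
  expect_identical(red$provenance$dropped_genes, genes[1:6])
  expect_true(red$thresholds_stale)
  expect_error(classify_index(0.5, red), "stale")

  # reduced-model index equals direct cosine on the 58-dim subvectors
  prof <- rnorm(64); names(prof) <- genes
  m <- matrix(prof[avail], 1, dimnames = list("s1", avail))
  got <- msi_index(expr_from_matrix(m), red)
  keep <- match(avail, genes)
  expect_equal(got$index,
               brute_cosine(prof[avail], mod$centroid_msi[keep]) -
                 brute_cosine(prof[avail], mod$centroid_mss[keep]),
               tolerance = 1e-12)

  # all genes available: unchanged, thresholds stay live
  full <- reduce_to_platform(mod, genes)
  expect_identical(full$gene_ids, genes)
  expect_false(full$thresholds_stale)
  expect_error(reduce_to_platform(mod, genes[1:40]), "below the floor")

  # re-optimisation clears the staleness flag
  relive <- set_thresholds(red, 0.0, 0.1)
  expect_false(relive$thresholds_stale)
  expect_identical(as.character(classify_index(0.05, relive)), "MSI_LIKE")
})
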