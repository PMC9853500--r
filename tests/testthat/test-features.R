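make_fm <- function(values, labels = rep(c("a", "b"),
                                         length.out = nrow(values))) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  feature_matrix(values, feature_mz = seq_len(ncol(values)) * 100,
                 feature_type = rep("ms", ncol(values)), labels = labels)
}

test_that("peak binning clusters across samples with hand-checkable
          centers", {
  pls <- list(peak_list(500.0, 10, "s1"), peak_list(500.3, 14, "s2"))
  fm <- bin_peaks(pls, tolerance = 0.5, labels = c(s1 = "a", s2 = "b"))
  expect_equal(ncol(fm$values), 1)
  expect_equal(fm$feature_mz, 500.15)
  expect_equal(unname(fm$values[, 1]), c(10, 14))

  # identical single peak: one feature, equal values
  pls2 <- list(peak_list(300, 7, "s1"), peak_list(300, 7, "s2"))
  fm2 <- bin_peaks(pls2, 0.5)
  expect_equal(dim(fm2$values), c(2L, 1L))
  expect_true(all(fm2$values == 7))

  # disjoint peaks: block structure with zeros off-block
  pls3 <- list(peak_list(300, 5, "s1"), peak_list(900, 9, "s2"))
  fm3 <- bin_peaks(pls3, 0.5)
  expect_equal(unname(fm3$values), matrix(c(5, 0, 0, 9), 2, 2))
  expect_error(bin_peaks(list(peak_list(1, 1, "x")), 0.5), "two samples")
})

test_that("variance filter keeps exactly the strictly-greater columns", {
  set.seed(4)
  mk <- function(target) {
    x <- rnorm(20)
    x * sqrt(target) / sd(x)
  }
  vals <- cbind(a = mk(0.5), b = mk(1.0), c = mk(2.0))
  fm <- make_fm(vals)
  kept <- variance_filter(fm, threshold = 1)
  expect_equal(colnames(kept$values), "c")  # 1.0 excluded: strict >
  # constant column removed
  fm2 <- make_fm(cbind(const = rep(5, 20), var = mk(3)))
  expect_equal(colnames(variance_filter(fm2)$values), "var")
  expect_error(variance_filter(make_fm(cbind(x = rep(1, 10)))),
               "review the threshold")
})

test_that("variance filter agrees with the direct per-column oracle and
          is idempotent", {
  set.seed(11)
  vals <- matrix(rnorm(20 * 50, sd = 1.1), 20, 50,
                 dimnames = list(NULL, sprintf("f%02d", 1:50)))
  fm <- make_fm(vals)
  kept <- variance_filter(fm, 1)
  oracle <- which(apply(vals, 2, var) > 1)
  expect_identical(colnames(kept$values), colnames(vals)[oracle])
  twice <- variance_filter(kept, 1)
  expect_identical(twice$values, kept$values)
})

test_that("z-scaling produces exact column moments and stores fold
          parameters", {
  fm <- make_fm(cbind(x = c(1, 2, 3), y = c(5, 9, 10)),
                labels = c("a", "a", "b"))
  z <- z_scale(fm)
  expect_equal(unname(z$values[, "x"]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values, 2, var) - 1) < 1e-9))
  expect_equal(z$scaling_state, "z_scaled")
  # held-out transform uses stored parameters, not its own statistics
  held <- apply_scaling(c(2, 9), z)
  expect_equal(unname(held[1, 1]), (2 - mean(c(1, 2, 3))) / 1)
  expect_error(z_scale(z), "already")
  expect_error(z_scale(make_fm(cbind(k = rep(1, 3)),
                               labels = c("a", "a", "b"))),
               "zero-variance")
})

test_that("behavioral fusion appends tagged PTD/VFD columns in order", {
  co <- small_cohort(seed = 13)
  prep <- preprocess_cohort(co$spectra, co$blanks)
  fm <- bin_peaks(prep$peaklists, 3, labels = unlist(co$truth$labels))
  expect_identical(fuse_behavior(fm, co$behavior, character(0)), fm)
  f1 <- fuse_behavior(fm, co$behavior, "PTD")
  expect_equal(ncol(f1$values), ncol(fm$values) + 1)
  expect_equal(tail(f1$feature_type, 1), "PTD")
  f2 <- fuse_behavior(fm, co$behavior, c("VFD", "PTD"))
  expect_equal(tail(f2$feature_type, 2), c("PTD", "VFD"))
  lat <- vapply(co$behavior, `[[`, numeric(1), "derived_latency_mean")
  ids <- vapply(co$behavior, `[[`, "", "sample_id")
  expect_equal(unname(f1$values[, "PTD"]),
               unname(lat[match(rownames(f1$values), ids)]))
  expect_error(fuse_behavior(fm, co$behavior[-1]), "missing behavioral")
})

test_that("PCA matches the brute-force covariance eigendecomposition", {
  set.seed(19)
  vals <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(sprintf("s%02d", 1:30),
                                 sprintf("f%02d", 1:10)))
  fm <- z_scale(make_fm(vals))
  pca <- pca_scores(fm, k = 3)
  eg <- eigen(cov(fm$values))
  centered <- sweep(fm$values, 2, colMeans(fm$values))
  for (j in 1:3) {
    v <- eg$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(pca$loadings[, j]), v, tolerance = 1e-8)
    expect_equal(unname(pca$scores[, j]), unname(centered %*% v)[, 1],
                 tolerance = 1e-8)
  }
  expect_equal(pca$explained_variance,
               (eg$values / sum(eg$values))[1:3], tolerance = 1e-8)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
})

test_that("rank-one data loads entirely on the first component", {
  t_vec <- seq(-1, 1, length.out = 12)
  dir <- c(2, -1, 0.5)
  vals <- outer(t_vec, dir)
  colnames(vals) <- c("f1", "f2", "f3")
  fm <- feature_matrix(vals, c(100, 200, 300), rep("ms", 3),
                       rep(c("a", "b"), 6), scaling_state = "z_scaled")
  pca <- pca_scores(fm, k = 2)
  expect_equal(pca$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca_scores(fm, k = 5), "k must be")
})

test_that("feature matrices survive a delimited round trip", {
  fm <- make_fm(cbind(a = c(1.25, 2.5), b = c(0, 7)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$a, c(1.25, 2.5))
  expect_equal(back$label, c("a", "b"))
})
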