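test_that("Savitzky-Golay reproduces low-degree polynomials and constants", {
  mz <- seq(100, 200, by = 1)
  poly <- 5 + 0.3 * seq_along(mz) + 0.01 * seq_along(mz)^2
  s <- mass_spectrum(mz, poly)
  sm <- smooth_savgol(s, window = 7, order = 2)
  expect_equal(sm$intensity, poly, tolerance = 1e-8)
  sc <- smooth_savgol(mass_spectrum(mz, rep(4, length(mz))), 9, 2)
  expect_equal(sc$intensity, rep(4, length(mz)), tolerance = 1e-12)
  expect_match(tail(sm$processing_log, 1), "savgol")
})

test_that("Savitzky-Golay equals the brute-force sliding-fit oracle", {
  set.seed(10)
  for (rep in 1:5) {
    y <- runif(101, 5, 10)
    s <- mass_spectrum(seq(100, 200, by = 1), y)
    sm <- smooth_savgol(s, window = 5, order = 2)
    oracle <- savgol_oracle(y, 5, 2)
    interior <- 3:99
    expect_equal(sm$intensity[interior], oracle[interior],
                 tolerance = 1e-8)
  }
  expect_error(smooth_savgol(s, window = 6, order = 2), "odd")
  expect_error(smooth_savgol(s, window = 5, order = 5), "order")
})

test_that("loess baseline recovers a smooth peak-free curve", {
  mz <- seq(100, 2000, by = 2)
  base <- 30 * exp(-(mz - 100) / 500)
  s <- mass_spectrum(mz, base)
  r <- subtract_baseline_loess(s, span = 0.1)
  expect_lt(max(r$intensity), 0.05 * max(base))
  z <- subtract_baseline_loess(mass_spectrum(mz, rep(0, length(mz))), 0.1)
  expect_true(all(z$intensity == 0))
  expect_error(subtract_baseline_loess(s, span = 0), "span")
})

test_that("loess baseline preserves narrow peak apexes on zero baseline", {
  s <- toy_peak_spectrum(c(300, 600, 850), c(40, 100, 60), sd = 2)
  r <- subtract_baseline_loess(s, span = 0.2)
  for (p in c(300, 600, 850)) {
    i <- which.min(abs(s$mz - p))
    expect_equal(r$intensity[i], s$intensity[i], tolerance = 0.1)
  }
})

test_that("normalization scales the base peak to exactly 100 and is
          idempotent", {
  s <- mass_spectrum(c(1, 2, 3), c(2, 4, 8))
  n1 <- normalize_max100(s)
  expect_equal(n1$intensity, c(25, 50, 100))
  n2 <- normalize_max100(n1)
  expect_equal(n2$intensity, n1$intensity)
  expect_error(normalize_max100(mass_spectrum(c(1, 2), c(0, 0))),
               "all-zero")
  set.seed(2)
  rnd <- mass_spectrum(1:50, runif(50, 0, 7))
  expect_equal(max(normalize_max100(rnd)$intensity), 100)
})

test_that("alignment recovers a constructed rigid shift", {
  ref <- toy_peak_spectrum(c(250, 480, 700, 910), c(80, 100, 60, 90),
                           noise_sd = 0.3, seed = 5, sample_id = "ref")
  shifted <- ref
  shifted$mz <- shifted$mz + 2.0
  shifted$sample_id <- "shifted"
  # give the reference an extra landmark so it wins reference selection
  ref2 <- toy_peak_spectrum(c(250, 480, 700, 910, 150),
                            c(80, 100, 60, 90, 70),
                            noise_sd = 0.3, seed = 5, sample_id = "ref")
  out <- align_spectra(list(ref2, shifted), tolerance = 3)
  rec <- out[[2]]$mz[1] - shifted$mz[1]
  expect_equal(rec, -2.0, tolerance = 1.0)
  # identical spectra: zero shifts
  out2 <- align_spectra(list(ref2, ref2), tolerance = 3)
  expect_equal(out2[[2]]$mz, ref2$mz)
  # shift beyond tolerance: identity + warning
  far <- ref
  far$mz <- far$mz + 10
  far$sample_id <- "far"
  expect_warning(out3 <- align_spectra(list(ref2, far), tolerance = 3),
                 "identity")
  expect_equal(out3[[2]]$mz, far$mz)
})

test_that("peak detection finds constructed peaks and nothing on flat
          input", {
  # at snr 3 the constructed apex is always found; isolated ~3-sigma
  # noise excursions may legitimately clear the bar, so exact counts are
  # asserted at snr 5 where the noise floor is unreachable
  s <- toy_peak_spectrum(500, 100, sd = 2, noise_sd = 1, seed = 8)
  pl <- detect_peaks(s, snr_threshold = 3)
  expect_true(any(abs(pl$mz - 500) <= 1))
  expect_lte(length(pl), 3)
  pl_strict <- detect_peaks(s, snr_threshold = 5)
  expect_equal(length(pl_strict), 1)
  expect_equal(pl_strict$mz, 500, tolerance = 1.01)

  two <- toy_peak_spectrum(c(400, 450), c(60, 90), sd = 2, noise_sd = 1,
                           seed = 9)
  pl2 <- detect_peaks(two, snr_threshold = 5)
  expect_equal(length(pl2), 2)
  expect_equal(pl2$mz, c(400, 450), tolerance = 1.01)
  expect_true(!is.unsorted(pl2$mz, strictly = TRUE))

  flat <- mass_spectrum(1:100, rep(0, 100))
  expect_equal(length(detect_peaks(flat, 3)), 0)
})

test_that("replicate merging averages matched peaks and applies the
          majority rule", {
  pl <- function(mz, it) peak_list(mz, it, sample_id = "s1")
  merged <- merge_replicates(list(pl(c(500.0, 800), c(10, 20)),
                                  pl(c(500.2, 800), c(12, 22)),
                                  pl(c(499.9, 800), c(14, 24))),
                             tolerance = 0.5)
  i <- which.min(abs(merged$mz - 500))
  expect_equal(merged$mz[i], mean(c(500.0, 500.2, 499.9)))
  expect_equal(merged$intensity[i], 12)
  expect_equal(merged$n_replicates_merged, 3L)

  # identical lists merge to themselves
  a <- pl(c(300, 600), c(5, 9))
  m2 <- merge_replicates(list(a, a, a), tolerance = 0.5)
  expect_equal(m2$mz, a$mz)
  expect_equal(m2$intensity, a$intensity)

  # peak present in 1 of 3 replicates is dropped
  m3 <- merge_replicates(list(pl(c(300, 600), c(5, 9)),
                              pl(300, 5), pl(300, 5)), tolerance = 0.5)
  expect_equal(m3$mz, 300)

  expect_error(merge_replicates(list(pl(300, 5),
                                     peak_list(300, 5, "other"))),
               "mixed sample_ids")
})

test_that("matrix-blank exclusion removes matched peaks and is idempotent", {
  sp <- peak_list(c(300, 600), c(10, 20), "s")
  bl <- peak_list(600.1, 50, "matrix_blank")
  out <- exclude_matrix_peaks(sp, bl, tolerance = 0.5)
  expect_equal(out$mz, 300)
  twice <- exclude_matrix_peaks(out, bl, tolerance = 0.5)
  expect_equal(twice$mz, out$mz)
  # disjoint blank: unchanged; identical blank: emptied
  expect_equal(exclude_matrix_peaks(sp, peak_list(1000, 5, "b"), 0.5)$mz,
               sp$mz)
  expect_length(exclude_matrix_peaks(sp, sp, 0.5)$mz, 0)
  expect_warning(exclude_matrix_peaks(sp, peak_list(numeric(0),
                                                    numeric(0), "b")),
                 "empty blank")
})

test_that("the preprocessing chain logs one entry per stage in order", {
  co <- small_cohort(seed = 17)
  s <- co$spectra[[1]]
  cfg <- preprocess_config()
  s1 <- smooth_savgol(s, cfg$savgol_window, cfg$savgol_order)
  s2 <- subtract_baseline_loess(s1, cfg$loess_span)
  s3 <- normalize_max100(s2)
  expect_equal(length(s3$processing_log), 3)
  expect_match(s3$processing_log[1], "savgol")
  expect_match(s3$processing_log[2], "loess")
  expect_match(s3$processing_log[3], "normalize")
})

test_that("ground-truth library peaks are recovered from a synthetic
          cohort", {
  co <- small_cohort(seed = 23)
  prep <- preprocess_cohort(co$spectra, co$blanks)
  truth_pos <- co$truth$library_peak_positions
  heights <- co$truth$library_base_heights
  # consider peaks clearly above noise on the raw scale
  strong <- truth_pos[heights > 10 * co$truth$config$noise_sd]
  found <- unlist(lapply(prep$peaklists, `[[`, "mz"))
  hit <- vapply(strong, function(p) any(abs(found - p) <= 3), logical(1))
  expect_gt(mean(hit), 0.9)
})
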