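# Shared fixtures, built in code.

# A small but complete synthetic cohort (2 groups x 4 samples x 3 reps).
small_cohort <- function(seed = 42, ...) {
  generate_cohort(cohort_config(n_per_group = 4, seed = seed, ...))
}

# A flat spectrum with isolated Gaussian peaks at known positions.
toy_peak_spectrum <- function(positions, heights, sd = 2,
                              mz = seq(100, 1000, by = 1),
                              noise_sd = 0, seed = 1,
                              sample_id = "toy") {
  set.seed(seed)
  y <- rep(0, length(mz))
  for (i in seq_along(positions))
    y <- y + heights[i] * exp(-(mz - positions[i])^2 / (2 * sd^2))
  if (noise_sd > 0) y <- y + rnorm(length(mz), 0, noise_sd)
  mass_spectrum(mz, pmax(y, 0), sample_id = sample_id)
}

# Brute-force Savitzky-Golay oracle: per-window polynomial least squares
# evaluated at the window center (interior points only).
savgol_oracle <- function(y, window, order) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- rep(NA_real_, n)
  x <- -h:h
  for (i in (h + 1):(n - h)) {
    fit <- lm.fit(outer(x, 0:order, "^"), y[(i - h):(i + h)])
    out[i] <- fit$coefficients[1]
  }
  out
}

# A linearly separable two-class toy feature set.
separable_toy <- function(n_per = 10, gap = 4, p = 2, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p, gap / 2), n_per, p),
             matrix(rnorm(n_per * p, -gap / 2), n_per, p))
  list(X = scale(X), y = rep(c("a", "b"), each = n_per))
}
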