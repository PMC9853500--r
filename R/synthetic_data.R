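#' Synthetic cohort configuration
#'
#' Parameters of the synthetic serum-fingerprint cohort generator. The
#' generator emulates linear-mode MALDI-TOF acquisitions over a 0--10,000
#' Da window: a shared peak library with class-dependent multiplicative
#' intensity effects concentrated in the low-mass region (< 1,000 Da),
#' matrix-ion peaks present in blanks and samples alike, a smooth
#' exponentially decaying baseline, additive Gaussian detector noise,
#' small rigid m/z calibration jitter, and triplicate spotting.
#'
#' @param n_per_group animals per group (default 15).
#' @param groups character vector of class labels. A group named
#'   `"control"` (case-insensitive) receives control-like behavioral
#'   latents; all other groups receive pain-model latents that overlap
#'   one another.
#' @param peak_library_size number of shared serum peaks (default 80).
#' @param mass_range acquisition window in Da, within \[0, 10000\].
#' @param low_mass_fraction fraction of class-informative peaks placed
#'   below 1,000 Da (default 0.7).
#' @param n_informative number of class-informative peaks (default 24,
#'   commensurate with the tens of discriminant m/z signals a serum
#'   fingerprint study typically selects).
#' @param effect_size multiplicative class separation on informative peak
#'   intensities (>= 1; 1 means no class signal, default 2).
#' @param noise_sd additive intensity noise SD, a.u. (default 0.5).
#' @param baseline_amplitude baseline height at the low-mass edge, a.u.
#' @param mz_jitter_sd SD of the per-acquisition rigid m/z calibration
#'   shift, Da (default 1.5).
#' @param n_replicates spots per sample (default 3).
#' @param n_matrix_peaks number of matrix-ion peaks (default 8).
#' @param n_blank_replicates matrix-blank acquisitions (default 3).
#' @param grid_step m/z grid spacing in Da (default 2).
#' @param bio_cv log-normal biological (per-animal) intensity CV.
#' @param tech_cv log-normal technical (per-spot) intensity CV.
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 15L,
                          groups = c("control", "model"),
                          peak_library_size = 80L,
                          mass_range = c(200, 10000),
                          low_mass_fraction = 0.7,
                          n_informative = 24L,
                          effect_size = 2,
                          noise_sd = 0.5,
                          baseline_amplitude = 20,
                          mz_jitter_sd = 1.5,
                          n_replicates = 3L,
                          n_matrix_peaks = 8L,
                          n_blank_replicates = 3L,
                          grid_step = 2,
                          bio_cv = 0.25,
                          tech_cv = 0.1,
                          seed = 1L) {
  if (!length(groups)) stop("groups must be nonempty", call. = FALSE)
  if (anyDuplicated(groups)) stop("duplicate group labels", call. = FALSE)
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (length(mass_range) != 2 || mass_range[1] >= mass_range[2] ||
      mass_range[1] < 0 || mass_range[2] > 10000)
    stop("mass_range must be an increasing interval within [0, 10000] Da",
         call. = FALSE)
  if (effect_size < 1) stop("effect_size must be >= 1", call. = FALSE)
  if (low_mass_fraction < 0 || low_mass_fraction > 1)
    stop("low_mass_fraction must be in [0, 1]", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (n_informative > peak_library_size)
    stop("n_informative cannot exceed peak_library_size", call. = FALSE)
  structure(list(
    n_per_group = as.integer(n_per_group), groups = as.character(groups),
    peak_library_size = as.integer(peak_library_size),
    mass_range = as.numeric(mass_range),
    low_mass_fraction = low_mass_fraction,
    n_informative = as.integer(n_informative),
    effect_size = effect_size, noise_sd = noise_sd,
    baseline_amplitude = baseline_amplitude, mz_jitter_sd = mz_jitter_sd,
    n_replicates = as.integer(n_replicates),
    n_matrix_peaks = as.integer(n_matrix_peaks),
    n_blank_replicates = as.integer(n_blank_replicates),
    grid_step = grid_step, bio_cv = bio_cv, tech_cv = tech_cv,
    seed = as.integer(seed)), class = "cohort_config")
}

# sample `n` positions in [lo, hi] at least `spacing` apart, greedily
sample_spaced <- function(n, lo, hi, spacing, avoid = numeric(0)) {
  accepted <- numeric(0)
  for (trial in seq_len(2000L)) {
    if (length(accepted) >= n) break
    cand <- runif(1, lo, hi)
    if (all(abs(c(accepted, avoid) - cand) >= spacing))
      accepted <- c(accepted, cand)
  }
  if (length(accepted) < n)
    stop("could not place ", n, " peaks with ", spacing,
         " Da spacing in [", lo, ", ", hi, "]", call. = FALSE)
  sort(accepted)
}

# TOF-like resolution: peak FWHM grows linearly with m/z
peak_fwhm <- function(mz) 3 + 0.0015 * mz

add_gaussians <- function(y, grid, positions, heights) {
  for (j in seq_along(positions)) {
    s <- peak_fwhm(positions[j]) / 2.3548
    lo <- findInterval(positions[j] - 4 * s, grid) + 1L
    hi <- findInterval(positions[j] + 4 * s, grid)
    if (hi < lo) next
    win <- lo:hi
    y[win] <- y[win] +
      heights[j] * exp(-((grid[win] - positions[j])^2) / (2 * s^2))
  }
  y
}

#' Generate a synthetic cohort
#'
#' Produces class-structured sample spectra (with replicate spotting),
#' matrix-blank spectra, behavioral records, and a ground-truth manifest.
#' Fully deterministic given `config$seed`.
#'
#' Class structure is multiplicative: each informative library peak is
#' assigned (round-robin) to one group whose members express it at
#' `effect_size` times the base intensity, with log-normal biological and
#' technical variation on top. At `effect_size = 1` the class labels carry
#' no spectral information by construction.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `spectra` (list of [mass_spectrum()]),
#'   `blanks`, `behavior` (list of [behavior_record()]) and `truth`
#'   (ground-truth manifest: labels, informative peak positions, per-class
#'   multipliers, matrix peak positions, latent behavioral parameters, and
#'   a config echo).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  lo <- config$mass_range[1]; hi <- config$mass_range[2]
  grid <- seq(lo, hi, by = config$grid_step)
  low_cut <- min(1000, hi)

  # matrix ions live in the low-mass region
  matrix_pos <- sample_spaced(config$n_matrix_peaks, lo + 20,
                              min(900, hi - 20), 30)
  matrix_height <- rlnorm(config$n_matrix_peaks, log(25), 0.5)

  # shared serum peak library; roughly a third sits below 1,000 Da where
  # TOF peaks are narrow, the rest spreads over the high-mass range
  n_low <- ceiling(0.35 * config$peak_library_size)
  lib_pos <- c(
    sample_spaced(n_low, lo + 20, low_cut, 12, avoid = matrix_pos),
    sample_spaced(config$peak_library_size - n_low, low_cut,
                  hi - 20, 25, avoid = matrix_pos))
  lib_height <- rlnorm(config$peak_library_size, log(15), 0.7)

  # informative subset, low_mass_fraction of it below 1,000 Da; the
  # class-informative species are drawn from the abundant, reproducibly
  # detected tier (discriminant m/z are selected from reliable peaks)
  is_low <- lib_pos < low_cut
  n_inf_low <- min(round(config$n_informative * config$low_mass_fraction),
                   sum(is_low))
  inf_idx <- c(sample(which(is_low), n_inf_low),
               sample(which(!is_low), config$n_informative - n_inf_low))
  inf_idx <- sort(inf_idx)
  lib_height[inf_idx] <- rlnorm(length(inf_idx), log(25), 0.4)

  n_groups <- length(config$groups)
  mult <- matrix(1, n_groups, config$peak_library_size,
                 dimnames = list(config$groups, NULL))
  assigned <- rep_len(seq_len(n_groups), length(inf_idx))
  for (j in seq_along(inf_idx))
    mult[assigned[j], inf_idx[j]] <- config$effect_size

  # behavioral latent parameters per group
  is_control <- tolower(config$groups) %in% c("control", "sham", "naive")
  model_rank <- cumsum(!is_control)
  lat_mu <- ifelse(is_control, 12, 6 + 0.4 * (model_rank - 1))
  thr_mu <- ifelse(is_control, 1.1, 0.35 + 0.03 * (model_rank - 1))

  samples <- expand.grid(i = seq_len(config$n_per_group),
                         g = seq_len(n_groups))
  sample_ids <- sprintf("%s_%02d", config$groups[samples$g], samples$i)
  labels <- setNames(as.list(config$groups[samples$g]), sample_ids)
  n_samples <- nrow(samples)

  lat_true <- pmin(pmax(rnorm(n_samples, lat_mu[samples$g], 1.5), 2), 20)
  thr_true <- pmin(pmax(rlnorm(n_samples, log(thr_mu[samples$g]), 0.25),
                        0.05), 2)

  baseline <- config$baseline_amplitude * exp(-(grid - lo) / 1500)

  make_spectrum <- function(heights, id, rep_id, role) {
    shift <- rnorm(1, 0, config$mz_jitter_sd)
    y <- baseline
    y <- add_gaussians(y, grid, c(matrix_pos, if (role == "sample") lib_pos) +
                         shift,
                       c(matrix_height *
                           rlnorm(config$n_matrix_peaks, 0, config$tech_cv),
                         heights))
    y <- y + rnorm(length(grid), 0, config$noise_sd)
    mass_spectrum(grid, pmax(y, 0), sample_id = id, replicate_id = rep_id,
                  role = role)
  }

  spectra <- vector("list", n_samples * config$n_replicates)
  k <- 0L
  for (s in seq_len(n_samples)) {
    g <- samples$g[s]
    sample_heights <- lib_height * mult[g, ] *
      rlnorm(config$peak_library_size, 0, config$bio_cv)
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      rep_heights <- sample_heights *
        rlnorm(config$peak_library_size, 0, config$tech_cv)
      spectra[[k]] <- make_spectrum(rep_heights, sample_ids[s], r, "sample")
    }
  }
  blanks <- lapply(seq_len(config$n_blank_replicates), function(r)
    make_spectrum(NULL, "matrix_blank", r, "matrix_blank"))

  truth <- list(
    labels = labels,
    library_peak_positions = lib_pos,
    library_base_heights = lib_height,
    informative_peak_positions = lib_pos[inf_idx],
    class_multipliers = as.data.frame(t(mult[, inf_idx, drop = FALSE])),
    matrix_peak_positions = matrix_pos,
    behavior = setNames(lapply(seq_len(n_samples), function(s)
      list(latency_mean = lat_true[s], threshold_50 = thr_true[s])),
      sample_ids),
    config = unclass(config))

  beh_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  behavior <- lapply(seq_len(n_samples), function(s)
    generate_behavior(sample_ids[s], truth, seed = beh_seeds[s]))

  list(spectra = spectra, blanks = blanks, behavior = behavior,
       truth = truth)
}

#' Generate one behavioral record from latent ground truth
#'
#' Draws latency trials from a normal law around the sample's latent mean
#' (truncated at the 25 s acquisition cut-off) and simulates a von Frey
#' up-down staircase from a logistic psychometric function centred on the
#' latent 50% threshold.
#'
#' @param sample_id sample identifier present in `truth$behavior`.
#' @param truth ground-truth manifest from [generate_cohort()].
#' @param params an [updown_params()].
#' @param n_trials number of latency trials (default 3).
#' @param latency_sd trial-to-trial latency SD in seconds (default 1).
#' @param slope psychometric slope per log10 unit (default 8).
#' @param cutoff latency cut-off in seconds (default 25).
#' @param seed RNG seed.
#' @return A [behavior_record()].
#' @export
generate_behavior <- function(sample_id, truth, params = updown_params(),
                              n_trials = 3L, latency_sd = 1, slope = 8,
                              cutoff = 25, seed = 1L) {
  lat <- truth$behavior[[sample_id]]
  if (is.null(lat))
    stop("no latent behavioral parameters for sample '", sample_id, "'",
         call. = FALSE)
  set.seed(as.integer(seed))
  trials <- pmin(pmax(rnorm(n_trials, lat$latency_mean, latency_sd), 0.5),
                 cutoff)
  vf_seed <- sample.int(.Machine$integer.max - 1L, 1)
  vf <- simulate_updown(lat$threshold_50, slope = slope, params = params,
                        seed = vf_seed)
  behavior_record(sample_id, trials, vf, params = params, cutoff = cutoff)
}
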