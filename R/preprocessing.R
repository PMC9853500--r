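#' Preprocessing configuration
#'
#' Parameters for the spectral preprocessing chain. The methods (smoothing,
#' loess baseline, alignment) follow standard linear-mode MALDI practice;
#' defaults are deliberately conservative and every value is exposed here.
#'
#' @param savgol_window odd number of grid points for the Savitzky-Golay
#'   smoother (default 9).
#' @param savgol_order polynomial degree of the smoother (default 2), must
#'   be `< savgol_window`.
#' @param loess_span span of the loess baseline fit as a fraction of the
#'   mass range (default 0.1).
#' @param align_tolerance maximum rigid m/z shift considered during
#'   alignment, in Da (default 6, about three standard deviations of the
#'   calibration offsets linear-mode acquisitions typically show).
#' @param snr_threshold signal-to-noise threshold for peak detection
#'   (default 3); see [detect_peaks()] for the noise estimator.
#' @param blank_match_tolerance m/z tolerance (Da) for matching sample
#'   peaks against matrix-blank peaks (default 2).
#' @param merge_tolerance m/z tolerance (Da) for matching peaks across
#'   replicates (default 2).
#' @param bin_tolerance m/z tolerance (Da) for cross-sample peak binning
#'   (default 3).
#' @param peak_halfwin half-width, in grid points, of the local-maximum
#'   window used by peak detection (default 5).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(savgol_window = 9L, savgol_order = 2L,
                              loess_span = 0.1, align_tolerance = 6,
                              snr_threshold = 3, blank_match_tolerance = 2,
                              merge_tolerance = 2, bin_tolerance = 3,
                              peak_halfwin = 5L) {
  if (savgol_window %% 2 == 0)
    stop("savgol_window must be odd", call. = FALSE)
  if (savgol_order >= savgol_window)
    stop("savgol_order must be < savgol_window", call. = FALSE)
  if (loess_span <= 0 || loess_span > 1)
    stop("loess_span must be in (0, 1]", call. = FALSE)
  stopifnot(align_tolerance > 0, snr_threshold > 0,
            blank_match_tolerance > 0, merge_tolerance > 0,
            bin_tolerance > 0, peak_halfwin >= 1)
  structure(list(savgol_window = as.integer(savgol_window),
                 savgol_order = as.integer(savgol_order),
                 loess_span = loess_span,
                 align_tolerance = align_tolerance,
                 snr_threshold = snr_threshold,
                 blank_match_tolerance = blank_match_tolerance,
                 merge_tolerance = merge_tolerance,
                 bin_tolerance = bin_tolerance,
                 peak_halfwin = as.integer(peak_halfwin)),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing on the intensity track. The
#' filter reproduces any polynomial of degree up to `order` exactly; small
#' negative excursions introduced at sharp features are clipped to zero so
#' the spectrum invariant (nonnegative intensities) is preserved.
#'
#' @param spectrum a [mass_spectrum()].
#' @param window odd window length in grid points.
#' @param order polynomial degree, `< window`.
#' @return The smoothed spectrum with a processing-log entry appended.
#' @export
smooth_savgol <- function(spectrum, window = 9L, order = 2L) {
  validate_spectrum(spectrum)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (order >= window) stop("order must be < window", call. = FALSE)
  if (length(spectrum$mz) < window)
    stop("spectrum shorter than smoothing window", call. = FALSE)
  sm <- signal::sgolayfilt(spectrum$intensity, p = order, n = window)
  spectrum$intensity <- pmax(sm, 0)
  log_step(spectrum, sprintf("savgol(window=%d,order=%d)", window, order))
}

#' Loess baseline subtraction
#'
#' Estimates the smooth chemical/background baseline by robust locally
#' weighted regression of intensity on m/z (robustness iterations
#' downweight the peaks, which sit above the baseline) and subtracts it.
#' Residual negatives are clipped to zero; this stage is also the
#' "background removal" of the pipeline.
#'
#' @param spectrum a [mass_spectrum()].
#' @param span loess span as a fraction of the mass range, in (0, 1].
#' @return The baseline-subtracted spectrum.
#' @export
subtract_baseline_loess <- function(spectrum, span = 0.1) {
  validate_spectrum(spectrum)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (length(spectrum$mz) < 10)
    stop("spectrum too short for baseline estimation", call. = FALSE)
  base <- lowess(spectrum$mz, spectrum$intensity, f = span, iter = 4L)$y
  spectrum$intensity <- pmax(spectrum$intensity - base, 0)
  log_step(spectrum, sprintf("loess_baseline(span=%g)", span))
}

#' Normalize a spectrum to 100% base peak
#'
#' Scales intensities so the maximum equals exactly 100, the convention
#' for relative-intensity fingerprint spectra. Idempotent.
#'
#' @param spectrum a [mass_spectrum()].
#' @return The normalized spectrum.
#' @export
normalize_max100 <- function(spectrum) {
  validate_spectrum(spectrum)
  m <- max(spectrum$intensity)
  if (m <= 0)
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  spectrum$intensity <- spectrum$intensity * (100 / m)
  log_step(spectrum, "normalize_max100")
}

#' Rigid m/z alignment of a spectrum set
#'
#' Chooses the spectrum with the most detected landmark peaks as reference
#' and shifts every other spectrum rigidly in m/z so that the number of
#' landmark peaks matching the reference (within roughly one grid step) is
#' maximal; candidate shifts are the observed peak-to-peak displacements
#' within `tolerance`. Ties prefer the smallest |shift|. If no landmarks
#' can be matched within tolerance the spectrum keeps an identity shift and
#' a warning is issued.
#'
#' @param spectra list of [mass_spectrum()] on comparable mass ranges.
#' @param tolerance maximum |shift| in Da.
#' @param snr_threshold signal-to-noise threshold for landmark detection.
#' @param peak_halfwin local-maximum half window (grid points).
#' @return The list of spectra, shifted, with the applied shift logged.
#' @export
align_spectra <- function(spectra, tolerance = 3, snr_threshold = 3,
                          peak_halfwin = 5L) {
  if (length(spectra) < 2)
    stop("alignment needs at least two spectra", call. = FALSE)
  landmarks <- lapply(spectra, function(s)
    detect_peaks(s, snr_threshold, peak_halfwin)$mz)
  ref_idx <- which.max(lengths(landmarks))
  ref <- landmarks[[ref_idx]]
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    step <- median(diff(s$mz))
    match_tol <- 1.5 * step
    shift <- 0
    if (i != ref_idx && length(ref) && length(landmarks[[i]])) {
      d <- outer(ref, landmarks[[i]], "-")
      cand <- unique(c(0, round(d[abs(d) <= tolerance] / (step / 4)) *
                         (step / 4)))
      if (length(cand) > 1) {
        score <- vapply(cand, function(sh) {
          shifted <- landmarks[[i]] + sh
          sum(vapply(ref, function(r)
            any(abs(shifted - r) <= match_tol), logical(1)))
        }, numeric(1))
        best <- which(score == max(score))
        shift <- cand[best[which.min(abs(cand[best]))]]
      }
      if (shift == 0 && max(if (length(cand) > 1) score else 0) == 0)
        warning("no landmarks matched for '", s$sample_id,
                "'; identity shift applied")
    }
    s$mz <- s$mz + shift
    out[[i]] <- log_step(s, sprintf("align(shift=%+.3f)", shift))
  }
  out
}

#' Peak detection
#'
#' Detects local maxima of the (preprocessed) intensity track that exceed
#' `snr_threshold` times the noise level. Noise is estimated robustly from
#' the running-median-detrended signal as the lower quartile of its
#' *positive* values rescaled to a Gaussian SD: baseline-subtracted
#' spectra are floor-clipped at zero, which deflates symmetric MAD-type
#' estimates, while peak structure contaminates only the upper quantiles —
#' the lower quartile of the positive excursions is insensitive to both.
#' A point qualifies only if it is the maximum within `peak_halfwin` grid
#' points on either side.
#'
#' @param spectrum a preprocessed [mass_spectrum()].
#' @param snr_threshold dimensionless signal-to-noise cutoff.
#' @param peak_halfwin local-maximum half window in grid points.
#' @return A [peak_list()]; possibly empty.
#' @export
detect_peaks <- function(spectrum, snr_threshold = 3, peak_halfwin = 5L) {
  validate_spectrum(spectrum)
  y <- spectrum$intensity
  n <- length(y)
  k <- min(2L * as.integer(peak_halfwin) * 4L + 1L, n - (1 - n %% 2))
  detr <- y - runmed(y, max(k, 3L))
  pos <- detr[detr > 0]
  noise <- if (length(pos) >= 10)
    quantile(pos, 0.25, names = FALSE) / qnorm(0.625) else 0
  if (noise <= 0) noise <- mad(diff(y)) / sqrt(2)
  if (noise <= 0) noise <- .Machine$double.eps
  thr <- snr_threshold * noise
  w <- as.integer(peak_halfwin)
  idx <- integer(0)
  if (n >= 3) {
    cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                    y[2:(n - 1)] >= y[3:n]) + 1L
    cand <- cand[y[cand] >= thr & y[cand] > 0]
    idx <- cand[vapply(cand, function(i) {
      lo <- max(1L, i - w); hi <- min(n, i + w)
      y[i] >= max(y[lo:hi])
    }, logical(1))]
  }
  # collapse plateau/adjacent picks closer than the window
  if (length(idx) > 1) {
    keep <- c(TRUE, diff(idx) > w)
    idx <- idx[keep]
  }
  peak_list(spectrum$mz[idx], spectrum$intensity[idx],
            sample_id = spectrum$sample_id)
}

#' Merge replicate peak lists
#'
#' Peaks from the same sample's replicate acquisitions are matched greedily
#' across replicates within `tolerance` (single-linkage on the pooled,
#' m/z-sorted peaks), matched intensities are averaged, and any peak seen
#' in fewer than half of the replicates is dropped (majority rule).
#'
#' @param peaklists list of [peak_list()] from the same sample.
#' @param tolerance matching tolerance in Da.
#' @return One merged [peak_list()] with `n_replicates_merged` set.
#' @export
merge_replicates <- function(peaklists, tolerance = 2) {
  if (!length(peaklists)) stop("no peak lists supplied", call. = FALSE)
  ids <- unique(vapply(peaklists, `[[`, "", "sample_id"))
  if (length(ids) != 1)
    stop("replicates from mixed sample_ids: ",
         paste(ids, collapse = ", "), call. = FALSE)
  k <- length(peaklists)
  mz <- unlist(lapply(peaklists, `[[`, "mz"))
  it <- unlist(lapply(peaklists, `[[`, "intensity"))
  rep <- rep(seq_len(k), times = vapply(peaklists, length, integer(1)))
  if (!length(mz))
    return(peak_list(numeric(0), numeric(0), ids, k))
  o <- order(mz)
  mz <- mz[o]; it <- it[o]; rep <- rep[o]
  grp <- cumsum(c(1, diff(mz) > tolerance))
  n_rep <- tapply(rep, grp, function(r) length(unique(r)))
  keep <- n_rep >= k / 2
  peak_list(as.numeric(tapply(mz, grp, mean))[keep],
            as.numeric(tapply(it, grp, mean))[keep],
            sample_id = ids, n_replicates_merged = k)
}

#' Exclude matrix peaks
#'
#' Removes sample peaks lying within `tolerance` of any peak detected in
#' the matrix-blank spectra (the ionization matrix contributes its own
#' low-mass ion series, present in blanks and samples alike). Idempotent.
#'
#' @param peaklist sample [peak_list()].
#' @param blank_peaklists one [peak_list()] or a list of them, from blanks
#'   preprocessed identically to the samples.
#' @param tolerance m/z match tolerance in Da.
#' @return The filtered [peak_list()].
#' @export
exclude_matrix_peaks <- function(peaklist, blank_peaklists, tolerance = 2) {
  if (inherits(blank_peaklists, "peak_list"))
    blank_peaklists <- list(blank_peaklists)
  blank_mz <- unlist(lapply(blank_peaklists, `[[`, "mz"))
  if (!length(blank_mz)) {
    warning("empty blank peak set; no matrix exclusion applied")
    return(peaklist)
  }
  keep <- vapply(peaklist$mz, function(m)
    all(abs(blank_mz - m) > tolerance), logical(1))
  peak_list(peaklist$mz[keep], peaklist$intensity[keep],
            sample_id = peaklist$sample_id,
            n_replicates_merged = peaklist$n_replicates_merged)
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in order: Savitzky-Golay smoothing, loess baseline subtraction,
#' base-peak normalization to 100%, rigid alignment (samples and blanks
#' together), peak detection, replicate merging per sample, and
#' matrix-blank exclusion.
#'
#' @param spectra list of sample [mass_spectrum()] (replicates included).
#' @param blanks list of matrix-blank spectra.
#' @param config a [preprocess_config()].
#' @return A list with `peaklists` (one merged, blank-filtered
#'   [peak_list()] per sample, named by sample_id) and `blank_peaks` (the
#'   merged blank peak list).
#' @export
preprocess_cohort <- function(spectra, blanks, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  stage1 <- function(s) {
    s <- smooth_savgol(s, config$savgol_window, config$savgol_order)
    s <- subtract_baseline_loess(s, config$loess_span)
    normalize_max100(s)
  }
  all_spec <- lapply(c(spectra, blanks), stage1)
  all_spec <- align_spectra(all_spec, config$align_tolerance,
                            config$snr_threshold, config$peak_halfwin)
  roles <- vapply(all_spec, `[[`, "", "role")
  pls <- lapply(all_spec, detect_peaks, snr_threshold = config$snr_threshold,
                peak_halfwin = config$peak_halfwin)
  sample_pls <- pls[roles == "sample"]
  blank_pls <- pls[roles == "matrix_blank"]
  ids <- vapply(sample_pls, `[[`, "", "sample_id")
  merged <- lapply(split(sample_pls, ids), merge_replicates,
                   tolerance = config$merge_tolerance)
  blank_merged <- if (length(blank_pls)) {
    bl <- lapply(blank_pls, function(p) { p$sample_id <- "matrix_blank"; p })
    merge_replicates(bl, tolerance = config$merge_tolerance)
  } else peak_list(numeric(0), numeric(0), "matrix_blank", 0L)
  cleaned <- lapply(merged, exclude_matrix_peaks,
                    blank_peaklists = blank_merged,
                    tolerance = config$blank_match_tolerance)
  list(peaklists = cleaned, blank_peaks = blank_merged)
}
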