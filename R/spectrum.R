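#' Construct a mass spectrum
#'
#' A `mass_spectrum` holds one acquisition: an ascending m/z grid with
#' nonnegative intensities plus acquisition metadata and an ordered log of
#' processing steps already applied.
#'
#' @param mz numeric vector of m/z values (Da), strictly increasing.
#' @param intensity numeric vector of intensities (arbitrary units or
#'   relative %), same length as `mz`, all nonnegative.
#' @param sample_id sample identifier.
#' @param replicate_id replicate (spot) number, a small positive integer.
#' @param role `"sample"` or `"matrix_blank"`.
#' @param processing_log character vector of applied-step descriptors.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, sample_id = "unknown",
                          replicate_id = 1L,
                          role = c("sample", "matrix_blank"),
                          processing_log = character()) {
  role <- match.arg(role)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  s <- structure(
    list(mz = mz, intensity = intensity,
         sample_id = as.character(sample_id),
         replicate_id = as.integer(replicate_id),
         role = role, processing_log = as.character(processing_log)),
    class = "mass_spectrum")
  validate_spectrum(s)
}

#' Validate a mass spectrum
#'
#' Enforces the class invariants: equal-length m/z and intensity vectors of
#' length at least 2, strictly increasing m/z, finite nonnegative
#' intensities.
#'
#' @param s a `mass_spectrum`.
#' @return `s`, invisibly unchanged, or an error.
#' @export
validate_spectrum <- function(s) {
  if (!inherits(s, "mass_spectrum"))
    stop("not a mass_spectrum object", call. = FALSE)
  if (length(s$mz) != length(s$intensity))
    stop("m/z and intensity lengths differ (", length(s$mz), " vs ",
         length(s$intensity), ")", call. = FALSE)
  if (length(s$mz) < 2L)
    stop("spectrum must contain at least 2 points", call. = FALSE)
  if (any(!is.finite(s$mz)) || any(!is.finite(s$intensity)))
    stop("non-finite m/z or intensity values", call. = FALSE)
  if (any(diff(s$mz) <= 0))
    stop("m/z values must be strictly increasing", call. = FALSE)
  if (any(s$intensity < 0))
    stop("negative intensities are not allowed", call. = FALSE)
  s
}

log_step <- function(s, msg) {
  s$processing_log <- c(s$processing_log, msg)
  s
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("mass_spectrum '%s' (rep %d, %s): %d points, m/z %.1f-%.1f\n",
              x$sample_id, x$replicate_id, x$role, length(x$mz),
              min(x$mz), max(x$mz)))
  if (length(x$processing_log))
    cat("  processing:", paste(x$processing_log, collapse = " -> "), "\n")
  invisible(x)
}

#' Construct a peak list
#'
#' Discrete detected peaks (m/z, intensity) for one spectrum or a merged
#' replicate set. After normalization intensities are relative (% of base
#' peak).
#'
#' @param mz numeric vector of peak m/z positions (Da), ascending.
#' @param intensity numeric vector of peak intensities, nonnegative.
#' @param sample_id source sample identifier.
#' @param n_replicates_merged number of replicate spectra merged into this
#'   list (1 for a single-acquisition list).
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(mz, intensity, sample_id = "unknown",
                      n_replicates_merged = 1L) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("peak m/z and intensity lengths differ", call. = FALSE)
  if (length(mz) && any(intensity < 0))
    stop("negative peak intensities are not allowed", call. = FALSE)
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o],
                 sample_id = as.character(sample_id),
                 n_replicates_merged = as.integer(n_replicates_merged)),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak_list '%s': %d peaks (%d replicate(s) merged)\n",
              x$sample_id, length(x$mz), x$n_replicates_merged))
  invisible(x)
}

#' @export
length.peak_list <- function(x) length(x$mz)
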