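#' Construct a feature matrix
#'
#' Samples x features container used between peak binning and
#' classification. Spectral columns are named `mz_<center>` and carry
#' their bin center; behavioral columns are tagged `PTD` (thermal
#' withdrawal latency, s) and `VFD` (von Frey 50% threshold, g).
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids).
#' @param feature_mz numeric vector of bin centers (Da), `NA` for
#'   behavioral columns.
#' @param feature_type character vector: `"ms"`, `"PTD"` or `"VFD"`.
#' @param labels factor (or character) of class labels, one per row.
#' @param scaling_state `"raw"` or `"z_scaled"`.
#' @param center,scale stored per-column scaling parameters (for applying
#'   a training-fold transform to held-out samples), or `NULL`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_mz, feature_type, labels,
                           scaling_state = "raw", center = NULL,
                           scale = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels))
    stop("one label per sample row is required", call. = FALSE)
  if (ncol(values) != length(feature_mz) ||
      ncol(values) != length(feature_type))
    stop("feature metadata length mismatch", call. = FALSE)
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- ifelse(feature_type == "ms",
                               sprintf("mz_%.2f", feature_mz),
                               feature_type)
  structure(list(values = values, feature_mz = feature_mz,
                 feature_type = feature_type,
                 labels = factor(labels),
                 scaling_state = scaling_state,
                 center = center, scale = scale),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d samples x %d features (%s; %d spectral, %d behavioral)\n",
    nrow(x$values), ncol(x$values), x$scaling_state,
    sum(x$feature_type == "ms"), sum(x$feature_type != "ms")))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Bin peaks across samples into a feature matrix
#'
#' Pools all detected peaks, sorts them by m/z and splits the pooled list
#' wherever consecutive peaks are further apart than `tolerance`
#' (single-linkage clustering). Each cluster becomes one m/z bin whose
#' center is the mean member m/z; the matrix holds each sample's intensity
#' in the bin (mean if a sample contributes several peaks) and 0 where the
#' sample has no peak.
#'
#' @param peaklists named list of merged [peak_list()], one per sample.
#' @param tolerance clustering gap in Da.
#' @param labels class labels, either named by sample id or in
#'   `peaklists` order.
#' @return A raw-state [feature_matrix()].
#' @export
bin_peaks <- function(peaklists, tolerance = 3, labels = NULL) {
  if (length(peaklists) < 2)
    stop("binning needs at least two samples", call. = FALSE)
  ids <- vapply(peaklists, `[[`, "", "sample_id")
  if (is.null(names(peaklists))) names(peaklists) <- ids
  mz <- unlist(lapply(peaklists, `[[`, "mz"), use.names = FALSE)
  it <- unlist(lapply(peaklists, `[[`, "intensity"), use.names = FALSE)
  src <- rep(seq_along(peaklists),
             times = vapply(peaklists, length, integer(1)))
  if (!length(mz)) stop("no peaks to bin", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]; it <- it[o]; src <- src[o]
  grp <- cumsum(c(1, diff(mz) > tolerance))
  centers <- as.numeric(tapply(mz, grp, mean))
  n_bins <- length(centers)
  vals <- matrix(0, length(peaklists), n_bins,
                 dimnames = list(ids, sprintf("mz_%.2f", centers)))
  agg <- tapply(it, list(grp, src), mean)
  present <- which(!is.na(agg), arr.ind = TRUE)
  vals[cbind(as.integer(colnames(agg)[present[, 2]]),
             as.integer(rownames(agg)[present[, 1]]))] <-
    agg[present]
  lab <- if (is.null(labels)) rep(NA_character_, length(ids))
         else if (!is.null(names(labels))) unname(labels[ids])
         else labels
  feature_matrix(vals, feature_mz = centers,
                 feature_type = rep("ms", n_bins), labels = lab)
}

#' Variance-threshold feature selection
#'
#' Keeps exactly the spectral columns whose sample variance (n-1
#' denominator) is strictly greater than `threshold`, preserving column
#' order; applied to raw relative intensities before Z-scaling. Behavioral
#' columns (PTD/VFD) are exempt from the filter and always retained.
#'
#' @param matrix a raw-state [feature_matrix()].
#' @param threshold variance cutoff (default 1, strict `>`).
#' @return The filtered [feature_matrix()].
#' @export
variance_filter <- function(matrix, threshold = 1) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$scaling_state != "raw")
    stop("variance filter must precede Z-scaling", call. = FALSE)
  v <- apply(matrix$values, 2, var)
  keep <- v > threshold | matrix$feature_type != "ms"
  if (!any(keep))
    stop("variance filter removed every feature; review the threshold (",
         threshold, ") against the intensity scale", call. = FALSE)
  feature_matrix(matrix$values[, keep, drop = FALSE],
                 matrix$feature_mz[keep], matrix$feature_type[keep],
                 matrix$labels, scaling_state = "raw")
}

#' Z-scale a feature matrix
#'
#' Centers every column and divides by its sample standard deviation
#' (n-1). The per-column parameters are stored in the result so held-out
#' samples can be transformed with the training-fold statistics instead of
#' their own.
#'
#' @param matrix a raw-state [feature_matrix()].
#' @return A z-scaled [feature_matrix()] with `center` and `scale` set.
#' @export
z_scale <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$scaling_state != "raw")
    stop("matrix is already z-scaled", call. = FALSE)
  ctr <- colMeans(matrix$values)
  scl <- apply(matrix$values, 2, sd)
  if (any(scl == 0))
    stop("zero-variance column(s) ",
         paste(colnames(matrix$values)[scl == 0], collapse = ", "),
         " cannot be Z-scaled; filter them first", call. = FALSE)
  vals <- sweep(sweep(matrix$values, 2, ctr), 2, scl, "/")
  feature_matrix(vals, matrix$feature_mz, matrix$feature_type,
                 matrix$labels, scaling_state = "z_scaled",
                 center = ctr, scale = scl)
}

#' Apply stored scaling parameters to new samples
#'
#' @param newdata numeric matrix (or vector, one sample) on the raw scale
#'   with the same columns as the training matrix.
#' @param matrix a z-scaled [feature_matrix()] carrying `center`/`scale`.
#' @return The transformed numeric matrix.
#' @export
apply_scaling <- function(newdata, matrix) {
  stopifnot(inherits(matrix, "feature_matrix"),
            matrix$scaling_state == "z_scaled")
  if (is.null(dim(newdata))) newdata <- t(newdata)
  if (ncol(newdata) != length(matrix$center))
    stop("column mismatch with stored scaling parameters", call. = FALSE)
  sweep(sweep(newdata, 2, matrix$center), 2, matrix$scale, "/")
}

#' Fuse behavioral endpoints into a feature matrix
#'
#' Appends the derived mean withdrawal latency (`PTD`) and/or von Frey 50%
#' threshold (`VFD`) as additional raw columns, in that order; they are
#' then Z-scaled together with the spectral columns.
#'
#' @param matrix a raw-state [feature_matrix()] with sample-id rownames.
#' @param behavior list of [behavior_record()] covering every sample.
#' @param include subset of `c("PTD", "VFD")`; empty means no change.
#' @return The fused [feature_matrix()].
#' @export
fuse_behavior <- function(matrix, behavior, include = c("PTD", "VFD")) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$scaling_state != "raw")
    stop("fuse before Z-scaling so fused columns share the transform",
         call. = FALSE)
  include <- intersect(c("PTD", "VFD"), include)  # canonical order
  if (!length(include)) return(matrix)
  ids <- vapply(behavior, `[[`, "", "sample_id")
  rows <- rownames(matrix$values)
  hit <- match(rows, ids)
  if (anyNA(hit))
    stop("missing behavioral record for sample(s): ",
         paste(rows[is.na(hit)], collapse = ", "), call. = FALSE)
  cols <- sapply(include, function(tag) vapply(behavior[hit], function(b)
    if (tag == "PTD") b$derived_latency_mean else b$derived_threshold_50,
    numeric(1)))
  cols <- as.matrix(cols)
  colnames(cols) <- include
  feature_matrix(cbind(matrix$values, cols),
                 c(matrix$feature_mz, rep(NA_real_, length(include))),
                 c(matrix$feature_type, include),
                 matrix$labels, scaling_state = "raw")
}

#' Principal component scores of a z-scaled feature matrix
#'
#' Singular-value decomposition of the centered (already scaled) data,
#' equivalent to eigendecomposition of the column covariance. Component
#' signs are fixed by making each component's largest-magnitude loading
#' positive, so results are fully deterministic.
#'
#' @param matrix a z-scaled [feature_matrix()].
#' @param k number of components to keep (default 3).
#' @return A list of class `pca_result` with `loadings` (features x k,
#'   orthonormal), `scores` (samples x k) and `explained_variance`
#'   (fractions, nonincreasing).
#' @export
pca_scores <- function(matrix, k = 3L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$scaling_state != "z_scaled")
    stop("PCA expects a z-scaled matrix", call. = FALSE)
  n <- nrow(matrix$values); p <- ncol(matrix$values)
  if (k > min(n - 1, p))
    stop("k must be <= min(samples - 1, features) = ", min(n - 1, p),
         call. = FALSE)
  pc <- prcomp(matrix$values, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = load, scores = scores,
                 explained_variance = ev[seq_len(k)],
                 labels = matrix$labels),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a feature matrix as a delimited table
#'
#' One row per sample with a leading `sample_id` column, a `label` column
#' and one column per feature (header = feature id).
#'
#' @param matrix a [feature_matrix()].
#' @param path destination CSV file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  df <- data.frame(sample_id = rownames(matrix$values),
                   label = as.character(matrix$labels),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
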