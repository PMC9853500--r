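#' Multilayer perceptron configuration
#'
#' A single hidden layer of logistic units (3 nodes by default), logistic
#' output units with one-hot targets, full-batch backpropagation on the
#' sum-of-squares loss with classical momentum, a 50,000-epoch training
#' cap, and a classification confidence level of 0.05 for the reject
#' ("unknown") rule.
#'
#' @param n_hidden hidden nodes (default 3).
#' @param max_epochs training-iteration cap (default 50000).
#' @param learning_rate step size on the per-sample mean gradient
#'   (default 0.5). Together with `momentum` this is chosen so that
#'   training reaches the sharp, confident minima the reject rule needs
#'   within the fixed iteration cap.
#' @param momentum classical momentum coefficient (default 0.95).
#' @param confidence_level alpha of the accept/reject rule, in (0, 0.5)
#'   (default 0.05): a class is assigned only when its activation is at
#'   least `1 - alpha` and every other activation is at most `alpha`.
#' @param tol early-stopping tolerance on the epoch-to-epoch RMSE change
#'   (default 1e-8); training stops once the change stays below `tol` for
#'   `patience` consecutive epochs or the cap is reached.
#' @param rmse_target RMSE convergence floor (default 0.005): training is
#'   declared converged once the weighted training RMSE drops below this
#'   value, at which point every output is already far inside the 0.05
#'   confidence margins and further epochs only polish memorization. Set
#'   to 0 to always train to `tol`/`max_epochs`.
#' @param patience consecutive stalled epochs before stopping (default 5).
#' @param init_range half-width of the uniform weight initialization.
#' @param class_weights `"balanced"` (default) weights each sample's loss
#'   by the inverse frequency of its class, so that small class-size
#'   differences (such as the one leave-one-out itself creates in every
#'   fold) do not bias the outputs toward the majority class; `"none"`
#'   uses the plain sum of squares.
#' @param seed RNG seed for weight initialization.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden = 3L, max_epochs = 50000L,
                       learning_rate = 0.5, momentum = 0.95,
                       confidence_level = 0.05, tol = 1e-8,
                       patience = 5L, init_range = 0.5,
                       class_weights = c("balanced", "none"),
                       rmse_target = 0.005, seed = 1L) {
  class_weights <- match.arg(class_weights)
  if (n_hidden < 1) stop("n_hidden must be >= 1", call. = FALSE)
  if (max_epochs < 1) stop("max_epochs must be >= 1", call. = FALSE)
  if (confidence_level <= 0 || confidence_level >= 0.5)
    stop("confidence_level must be in (0, 0.5)", call. = FALSE)
  structure(list(n_hidden = as.integer(n_hidden),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 confidence_level = confidence_level, tol = tol,
                 patience = as.integer(patience),
                 init_range = init_range, class_weights = class_weights,
                 rmse_target = rmse_target, seed = as.integer(seed)),
            class = "mlp_config")
}

one_hot <- function(y) {
  y <- factor(y)
  tgt <- matrix(0, length(y), nlevels(y),
                dimnames = list(NULL, levels(y)))
  tgt[cbind(seq_along(y), as.integer(y))] <- 1
  tgt
}

#' Train the multilayer perceptron
#'
#' Full-batch backpropagation with momentum on one-hot targets and
#' sum-of-squares loss; weights are initialized uniformly in
#' `[-init_range, init_range]` under the configured seed, so training is
#' fully deterministic.
#'
#' @param X numeric matrix of z-scaled features (samples x inputs), or a
#'   z-scaled [feature_matrix()].
#' @param y class labels (factor or character), at least two classes.
#' @param config an [mlp_config()].
#' @return An object of class `mlp_model` with weight matrices `W1`
#'   (inputs x hidden), `W2` (hidden x classes), biases `b1`, `b2`, the
#'   class levels, per-epoch training RMSE `history`, and the config.
#' @export
mlp_train <- function(X, y, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"))
  if (inherits(X, "feature_matrix")) {
    if (X$scaling_state != "z_scaled")
      stop("feature matrix must be z-scaled before training",
           call. = FALSE)
    y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in the input matrix", call. = FALSE)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop("training needs at least two classes", call. = FALSE)
  if (length(y) != nrow(X))
    stop("one label per sample row is required", call. = FALSE)
  p <- ncol(X); h <- config$n_hidden; k <- nlevels(y)
  set.seed(config$seed)
  W1 <- matrix(runif(p * h, -config$init_range, config$init_range), p, h)
  b1 <- runif(h, -config$init_range, config$init_range)
  W2 <- matrix(runif(h * k, -config$init_range, config$init_range), h, k)
  b2 <- runif(k, -config$init_range, config$init_range)
  w <- if (config$class_weights == "balanced") {
    freq <- table(y)
    as.numeric(length(y) / (nlevels(y) * freq[as.integer(y)]))
  } else rep(1, length(y))
  fit <- mlp_train_cpp(X, one_hot(y), w, W1, b1, W2, b2,
                       config$max_epochs, config$learning_rate,
                       config$momentum, config$tol, config$patience,
                       config$rmse_target)
  if (isTRUE(fit$diverged))
    stop("training diverged (non-finite loss); try a smaller learning ",
         "rate", call. = FALSE)
  structure(list(W1 = fit$W1, b1 = drop(fit$b1), W2 = fit$W2,
                 b2 = drop(fit$b2), classes = levels(y),
                 history = drop(fit$history), epochs = fit$epochs,
                 config = config),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "mlp_model: %d-%d-%d, %d epochs, final training RMSE %.4g\n",
    nrow(x$W1), ncol(x$W1), ncol(x$W2), x$epochs,
    tail(x$history, 1)))
  invisible(x)
}

#' Output activations of a trained network
#'
#' @param model an [mlp_train()] model.
#' @param x numeric matrix (samples x inputs) or a single input vector,
#'   on the training z-scale.
#' @return Matrix of per-class logistic activations in (0, 1).
#' @export
mlp_activations <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(dim(x))) x <- t(x)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$W1))
    stop("input has ", ncol(x), " features but the network expects ",
         nrow(model$W1), call. = FALSE)
  a <- mlp_forward_cpp(x, model$W1, model$b1, model$W2, model$b2)$output
  colnames(a) <- model$classes
  a
}

#' Classify with a confidence-based reject option
#'
#' A sample is assigned class `c` only when the activation of `c` is at
#' least `1 - confidence_level` and every other class activation is at
#' most `confidence_level`; otherwise the output is `"unknown"`.
#' Unknowns are counted as erroneous predictions downstream.
#'
#' @param model an [mlp_train()] model.
#' @param x input vector or matrix on the training z-scale.
#' @param confidence_level alpha of the rule; defaults to the value the
#'   model was configured with.
#' @return Character vector of class labels or `"unknown"`.
#' @export
predict_with_confidence <- function(model, x,
                                    confidence_level =
                                      model$config$confidence_level) {
  a <- mlp_activations(model, x)
  apply(a, 1, function(act) {
    accept <- act >= 1 - confidence_level
    others_low <- vapply(seq_along(act), function(i)
      all(act[-i] <= confidence_level), logical(1))
    ok <- which(accept & others_low)
    if (length(ok) == 1) model$classes[ok] else "unknown"
  })
}

#' Leave-one-out cross-validation of the full decision pipeline
#'
#' For every sample, the variance filter and Z-scaling are refit on the
#' remaining n-1 samples, a fresh network is trained on them (with a
#' per-fold seed derived from the master seed), and the held-out sample —
#' transformed with the training-fold scaling — is classified under the
#' confidence rule. The success percentage counts `"unknown"` as an
#' error. `global_prep = TRUE` instead fits the filter and scaling once
#' on all samples (the leakage-prone variant, for comparison only).
#'
#' @param matrix a raw-state [feature_matrix()] (post-binning, optionally
#'   post-fusion).
#' @param config an [mlp_config()]; its `seed` is the master seed.
#' @param variance_threshold cutoff for the per-fold variance filter
#'   (default 1).
#' @param global_prep fit preprocessing once on all data (default FALSE).
#' @return An object of class `cv_result`: per-sample `true` and
#'   `predicted` labels (including `"unknown"`), `success_percentage`,
#'   and a `confusion` table with an unknown column.
#' @export
loocv <- function(matrix, config = mlp_config(), variance_threshold = 1,
                  global_prep = FALSE) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$scaling_state != "raw")
    stop("loocv expects a raw-state matrix; scaling is refit per fold",
         call. = FALSE)
  y <- factor(matrix$labels)
  n <- nrow(matrix$values)
  if (n < 3) stop("LOOCV needs at least 3 samples", call. = FALSE)
  tab <- table(y)
  if (any(tab < 2))
    stop("every class needs >= 2 members for LOOCV; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  fold_seeds <- (as.numeric(config$seed) * 7919 + 104729 * seq_len(n)) %%
    2147483647
  global_fm <- if (global_prep)
    z_scale(variance_filter(matrix, variance_threshold)) else NULL
  predicted <- character(n)
  for (i in seq_len(n)) {
    fold_cfg <- config
    fold_cfg$seed <- as.integer(fold_seeds[i])
    if (global_prep) {
      train_vals <- global_fm$values[-i, , drop = FALSE]
      test_vals <- global_fm$values[i, , drop = FALSE]
      fold_labels <- y[-i]
    } else {
      train_raw <- feature_matrix(matrix$values[-i, , drop = FALSE],
                                  matrix$feature_mz, matrix$feature_type,
                                  y[-i], scaling_state = "raw")
      train_fm <- z_scale(variance_filter(train_raw, variance_threshold))
      keep <- match(colnames(train_fm$values), colnames(matrix$values))
      train_vals <- train_fm$values
      test_vals <- apply_scaling(
        matrix$values[i, keep, drop = FALSE], train_fm)
      fold_labels <- y[-i]
    }
    model <- mlp_train(train_vals, fold_labels, fold_cfg)
    predicted[i] <- predict_with_confidence(model, test_vals)
  }
  cv_result(as.character(y), predicted,
            sample_ids = rownames(matrix$values))
}

#' Construct a cross-validation result
#'
#' @param true character vector of true labels.
#' @param predicted character vector of predicted labels (may contain
#'   `"unknown"`).
#' @param sample_ids optional sample identifiers.
#' @return An object of class `cv_result`.
#' @export
cv_result <- function(true, predicted, sample_ids = NULL) {
  stopifnot(length(true) == length(predicted))
  classes <- sort(unique(true))
  confusion <- table(
    true = factor(true, levels = classes),
    predicted = factor(predicted, levels = c(classes, "unknown")))
  structure(list(true = true, predicted = predicted,
                 sample_ids = sample_ids,
                 success_percentage = 100 * mean(true == predicted),
                 n = length(true), confusion = confusion),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d samples, %.1f%% correct (%d unknown)\n",
              x$n, x$success_percentage,
              sum(x$predicted == "unknown")))
  print(x$confusion)
  invisible(x)
}

#' Plain-text classification report
#'
#' Per-class correct counts, unknown count and the overall success
#' percentage (unknowns counted as errors; the headline percentage is
#' also given rounded to the nearest integer, the convention used when
#' reporting fingerprint classification success).
#'
#' @param cvresult a `cv_result`.
#' @return A list with `text` (character vector of report lines) and
#'   `table` (per-class data frame), invisibly; the text is printed.
#' @export
classification_report <- function(cvresult) {
  stopifnot(inherits(cvresult, "cv_result"))
  classes <- rownames(cvresult$confusion)
  per_class <- data.frame(
    class = classes,
    n = as.integer(rowSums(cvresult$confusion)),
    correct = as.integer(diag(cvresult$confusion[, classes,
                                                 drop = FALSE])),
    unknown = as.integer(cvresult$confusion[, "unknown"]),
    stringsAsFactors = FALSE)
  per_class$percent <- ifelse(per_class$n > 0,
                              100 * per_class$correct / per_class$n, 0)
  lines <- c(
    sprintf("Samples: %d", cvresult$n),
    sprintf("Overall success: %.1f%% (%d%%)",
            cvresult$success_percentage,
            round(cvresult$success_percentage)),
    sprintf("Unknown (rejected, counted as errors): %d",
            sum(cvresult$predicted == "unknown")),
    sprintf("  %-12s %3d/%3d correct (%5.1f%%), %d unknown",
            per_class$class, per_class$correct, per_class$n,
            per_class$percent, per_class$unknown))
  cat(lines, sep = "\n")
  invisible(list(text = lines, table = per_class))
}
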