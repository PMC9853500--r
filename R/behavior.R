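#' Von Frey up-down protocol parameters
#'
#' Describes the filament ladder and stopping rule of the up-down
#' (staircase) estimation of the 50% paw-withdrawal threshold. Stimulus
#' spacing `delta` is the mean log10 spacing of the filament set and is
#' recomputed from `filament_set` rather than hard-coded. The correction
#' factor kappa is obtained from the terminal response pattern, either from
#' a user-supplied lookup table (`kappa_table`, columns `pattern`, `kappa`,
#' pattern written with `O` = no response, `X` = response) or, by default,
#' computed by maximum likelihood (see [kappa_updown()]).
#'
#' @param filament_set ordered filament bending forces in grams.
#' @param start_force starting filament (default 0.4 g).
#' @param stop_after_first_response number of additional measurements
#'   recorded after the first response before the staircase stops
#'   (default 4).
#' @param kappa_table optional data frame with columns `pattern`, `kappa`.
#' @return A list of class `updown_params`.
#' @export
updown_params <- function(filament_set = c(0.04, 0.07, 0.16, 0.4, 0.6,
                                           1.0, 1.4, 2.0),
                          start_force = 0.4,
                          stop_after_first_response = 4L,
                          kappa_table = NULL) {
  if (is.unsorted(filament_set, strictly = TRUE))
    stop("filament_set must be strictly increasing", call. = FALSE)
  if (!start_force %in% filament_set)
    stop("start_force must be one of filament_set", call. = FALSE)
  if (!is.null(kappa_table) &&
      !all(c("pattern", "kappa") %in% names(kappa_table)))
    stop("kappa_table needs columns 'pattern' and 'kappa'", call. = FALSE)
  delta <- mean(diff(log10(10000 * filament_set)))
  structure(list(filament_set = filament_set, start_force = start_force,
                 stop_after_first_response =
                   as.integer(stop_after_first_response),
                 delta = delta, kappa_table = kappa_table),
            class = "updown_params")
}

#' Mean thermal withdrawal latency (Hargreaves test)
#'
#' Latencies are capped at the cut-off imposed during acquisition to avoid
#' skin damage (25 s by default) and averaged over at least three trials.
#'
#' @param trials numeric vector of withdrawal latencies in seconds.
#' @param cutoff cut-off time in seconds (default 25).
#' @return Mean capped latency in seconds.
#' @export
mean_withdrawal_latency <- function(trials, cutoff = 25) {
  if (length(trials) < 3)
    stop("at least three latency trials are required", call. = FALSE)
  if (any(!is.finite(trials)) || any(trials <= 0))
    stop("latency trials must be positive and finite", call. = FALSE)
  mean(pmin(trials, cutoff))
}

#' Up-down correction factor kappa from a response pattern
#'
#' Given the sequence of responses (`FALSE` = no withdrawal, `TRUE` =
#' withdrawal), the up-down rule fixes the relative stimulus ladder: the
#' staircase steps one level up after a non-response and one level down
#' after a response. kappa is defined so that `x_final + kappa * delta`
#' estimates the 50% point; it is computed here by maximizing the
#' likelihood of the observed responses under a normal tolerance
#' distribution (in log-stimulus units) whose standard deviation equals
#' the stimulus spacing — the assumption under which the classical
#' small-sample up-down correction table was derived. The result depends
#' only on the response pattern.
#'
#' @param responses logical vector of responses in protocol order.
#' @return kappa (dimensionless).
#' @export
kappa_updown <- function(responses) {
  responses <- as.logical(responses)
  n <- length(responses)
  if (!n) stop("empty response sequence", call. = FALSE)
  # relative stimulus levels implied by the up-down rule (units of delta)
  lev <- numeric(n)
  for (i in seq_len(n)[-1])
    lev[i] <- lev[i - 1] + if (responses[i - 1]) -1 else 1
  if (all(responses) || all(!responses))
    stop("kappa undefined for a constant response pattern", call. = FALSE)
  nll <- function(m) {
    p <- pnorm(lev - m)  # sd = 1 in units of delta
    -sum(ifelse(responses, log(p), log1p(-p)))
  }
  fit <- optimize(nll, interval = range(lev) + c(-5, 5))
  unname(fit$minimum - lev[n])
}

pattern_string <- function(responses)
  paste(ifelse(responses, "X", "O"), collapse = "")

#' 50% paw-withdrawal threshold by the Dixon formula
#'
#' Evaluates `10^(Xf + kappa * delta) / 10000` grams, where
#' `Xf = log10(10000 * final filament force)` is the final stimulus in log
#' units, `kappa` the tabular correction for the observed response pattern
#' and `delta` the mean log10 stimulus spacing. The result is clamped to
#' the filament range. Boundary conventions: an animal that never responds
#' through the top filament is assigned the top force; one that responds
#' at every presentation down through the bottom filament is assigned the
#' bottom force.
#'
#' The sequence is validated against the protocol first: it must start at
#' `start_force`, step one filament up after each non-response and one
#' down after each response, and stop `stop_after_first_response`
#' measurements after the first response (or earlier at a ladder
#' boundary).
#'
#' @param sequence data frame with columns `force` (g) and `response`
#'   (logical), in protocol order.
#' @param params an [updown_params()].
#' @return The 50% withdrawal threshold in grams.
#' @export
updown_50pct_threshold <- function(sequence, params = updown_params()) {
  stopifnot(inherits(params, "updown_params"))
  validate_updown_sequence(sequence, params)
  fs <- params$filament_set
  resp <- as.logical(sequence$response)
  if (!any(resp)) return(fs[length(fs)])
  if (all(resp)) return(fs[1])
  kappa <- lookup_kappa(resp, params)
  xf <- log10(10000 * sequence$force[nrow(sequence)])
  thr <- 10^(xf + kappa * params$delta) / 10000
  min(max(thr, fs[1]), fs[length(fs)])
}

lookup_kappa <- function(responses, params) {
  if (!is.null(params$kappa_table)) {
    pat <- pattern_string(responses)
    hit <- match(pat, params$kappa_table$pattern)
    if (!is.na(hit)) return(params$kappa_table$kappa[hit])
    warning("pattern '", pat, "' not in kappa_table; ",
            "falling back to maximum-likelihood kappa")
  }
  kappa_updown(responses)
}

validate_updown_sequence <- function(sequence, params) {
  if (!is.data.frame(sequence) ||
      !all(c("force", "response") %in% names(sequence)))
    stop("sequence must be a data frame with columns force, response",
         call. = FALSE)
  if (!nrow(sequence)) stop("empty up-down sequence", call. = FALSE)
  fs <- params$filament_set
  idx <- match(sequence$force, fs)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("step ", bad, ": force ", sequence$force[bad],
         " g is not in the filament set", call. = FALSE)
  }
  if (sequence$force[1] != params$start_force)
    stop("step 1: protocol starts at ", params$start_force, " g, not ",
         sequence$force[1], " g", call. = FALSE)
  resp <- as.logical(sequence$response)
  n <- nrow(sequence)
  for (i in seq_len(n - 1)) {
    expected <- idx[i] + if (resp[i]) -1L else 1L
    expected <- min(max(expected, 1L), length(fs))
    if (idx[i + 1] != expected)
      stop("step ", i + 1, ": expected filament ", fs[expected],
           " g after a ", if (resp[i]) "response" else "non-response",
           " at ", fs[idx[i]], " g, got ", sequence$force[i + 1], " g",
           call. = FALSE)
  }
  first <- which(resp)[1]
  if (is.na(first)) {
    if (idx[n] != length(fs))
      stop("step ", n, ": sequence without any response must ascend to ",
           "the top filament before stopping", call. = FALSE)
  } else {
    n_after <- n - first
    hit_boundary <- idx[n] %in% c(1L, length(fs))
    if (n_after > params$stop_after_first_response)
      stop("sequence continues beyond ", params$stop_after_first_response,
           " measurements after the first response (step ",
           first + params$stop_after_first_response + 1, ")",
           call. = FALSE)
    if (n_after < params$stop_after_first_response && !hit_boundary)
      stop("sequence stops early at step ", n,
           " without reaching a ladder boundary", call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate an up-down staircase
#'
#' Generates a protocol-valid von Frey sequence for an animal whose
#' probability of withdrawing at log-force `x` follows a logistic
#' psychometric function centred on the latent 50% threshold:
#' `P(response) = plogis(slope * (x - log10(10000 * threshold)))`.
#'
#' @param latent_threshold latent 50% threshold in grams (> 0).
#' @param slope psychometric slope per log10 unit of force (default 8);
#'   `Inf` gives a deterministic step function.
#' @param params an [updown_params()].
#' @param seed RNG seed.
#' @return Data frame with columns `force` (g) and `response` (logical).
#' @export
simulate_updown <- function(latent_threshold, slope = 8,
                            params = updown_params(), seed = 1L) {
  stopifnot(latent_threshold > 0)
  set.seed(as.integer(seed))
  fs <- params$filament_set
  mu <- log10(10000 * latent_threshold)
  idx <- match(params$start_force, fs)
  force <- numeric(0); resp <- logical(0)
  n_after <- -1L  # becomes 0 at the first response
  repeat {
    x <- log10(10000 * fs[idx])
    p <- if (is.infinite(slope)) as.numeric(x > mu)
         else plogis(slope * (x - mu))
    r <- runif(1) < p
    force <- c(force, fs[idx]); resp <- c(resp, r)
    if (n_after >= 0L || r) n_after <- n_after + 1L
    if (n_after >= params$stop_after_first_response) break
    nxt <- idx + if (r) -1L else 1L
    if (nxt < 1L || nxt > length(fs)) break
    idx <- nxt
  }
  data.frame(force = force, response = resp)
}

#' Assemble a behavioral record
#'
#' Bundles raw latency trials and a von Frey sequence with their derived
#' endpoints (mean capped latency; Dixon 50% threshold).
#'
#' @param sample_id sample identifier.
#' @param latency_trials numeric vector of latencies (s), length >= 3.
#' @param vf_sequence data frame with columns `force`, `response`.
#' @param params an [updown_params()].
#' @param cutoff latency cut-off in seconds.
#' @return A list of class `behavior_record` with fields `sample_id`,
#'   `latency_trials`, `vf_sequence`, `derived_latency_mean`,
#'   `derived_threshold_50`.
#' @export
behavior_record <- function(sample_id, latency_trials, vf_sequence,
                            params = updown_params(), cutoff = 25) {
  structure(list(
    sample_id = as.character(sample_id),
    latency_trials = as.numeric(latency_trials),
    vf_sequence = vf_sequence,
    derived_latency_mean = mean_withdrawal_latency(latency_trials, cutoff),
    derived_threshold_50 = updown_50pct_threshold(vf_sequence, params)),
    class = "behavior_record")
}

#' @export
print.behavior_record <- function(x, ...) {
  cat(sprintf(
    "behavior_record '%s': latency %.2f s (%d trials), 50%% threshold %.3f g (%s)\n",
    x$sample_id, x$derived_latency_mean, length(x$latency_trials),
    x$derived_threshold_50, pattern_string(x$vf_sequence$response)))
  invisible(x)
}
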