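#' Synthetic study design
#'
#' Describes a two-condition electrodermal study to be simulated: each
#' subject contributes baseline and anticipation epochs of 60 s at 10 Hz.
#' The default layout mirrors a public-speaking anticipation protocol:
#' 40 subjects with four epochs each, the first two baseline and the last
#' two anticipation. In the `"within"` design the anticipation epochs of
#' every subject use `anticipation_rate`; in the `"between"` design only
#' the treatment half of the subjects does, the rest staying at
#' `baseline_rate` (and one epoch per subject is baseline). Default rates
#' (6 vs 12 bursts/min) lie inside the 3-22 bursts/min range reported for
#' sudomotor firing, with the anticipation condition doubling the burst
#' rate; amplitudes are uniform on 0.1-1 uS, measurement noise is white
#' with SD 0.05 uS, and a slow half-period sinusoidal drift of 0.1 uS
#' emulates tonic-level wander.
#'
#' @param n_subjects number of subjects
#' @param epochs_per_subject epochs per subject (>= 2)
#' @param n_baseline baseline epochs per subject (the first
#'   `n_baseline` epochs); default half of `epochs_per_subject` in the
#'   within design and 1 in the between design
#' @param design "within" or "between"
#' @param baseline_rate,anticipation_rate burst rates (bursts/min, <= 30)
#' @param amp_low,amp_high burst amplitude range (uS)
#' @param noise_sd white measurement noise SD (uS)
#' @param drift_amp amplitude of the slow sinusoidal drift (uS)
#' @param duration epoch length (s)
#' @param rate sampling rate (Hz)
#' @param seed master seed; every random quantity in the study derives
#'   from it
#' @return an object of class `study_design`
#' @export
study_design <- function(n_subjects = 40, epochs_per_subject = 4,
                         design = c("within", "between"),
                         n_baseline = NULL,
                         baseline_rate = 6, anticipation_rate = 12,
                         amp_low = 0.1, amp_high = 1,
                         noise_sd = 0.05, drift_amp = 0.1,
                         duration = 60, rate = 10, seed = 1L) {
  design <- match.arg(design)
  if (baseline_rate > 30 || anticipation_rate > 30) {
    stop("burst rates must not exceed 30 per minute", call. = FALSE)
  }
  if (!(amp_low > 0 && amp_low <= amp_high)) {
    stop("need 0 < amp_low <= amp_high", call. = FALSE)
  }
  if (epochs_per_subject < 2) {
    stop("epochs_per_subject must be >= 2 (at least one baseline and one anticipation epoch)",
         call. = FALSE)
  }
  if (is.null(n_baseline)) {
    n_baseline <- if (design == "within") {
      max(1L, floor(epochs_per_subject / 2))
    } else {
      1L
    }
  }
  if (n_baseline < 1 || n_baseline >= epochs_per_subject) {
    stop("n_baseline must leave at least one anticipation epoch",
         call. = FALSE)
  }
  structure(list(n_subjects = n_subjects,
                 epochs_per_subject = epochs_per_subject,
                 n_baseline = as.integer(n_baseline),
                 design = design,
                 baseline_rate = baseline_rate,
                 anticipation_rate = anticipation_rate,
                 amp_low = amp_low, amp_high = amp_high,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 duration = duration, rate = rate,
                 seed = as.integer(seed)),
            class = "study_design")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random sudomotor burst train
#'
#' Burst onsets follow a homogeneous Poisson process at the requested
#' rate, sequentially thinned so that consecutive kept onsets are at
#' least `min_spacing` seconds apart (so ground-truth bursts are
#' unambiguous for onset-matching metrics); amplitudes are i.i.d. uniform
#' on \[amp_low, amp_high\]. Deterministic given the seed.
#'
#' @param rate burst rate (bursts per minute), at most 30
#' @param amp_low,amp_high amplitude range (uS)
#' @param duration train duration (s)
#' @param seed integer seed (`NULL` uses the current RNG stream)
#' @param sigma Gaussian burst SD (s)
#' @param min_spacing minimum spacing between kept onsets (s)
#' @return a [burst_train()]
#' @export
generate_burst_train <- function(rate, amp_low = 0.1, amp_high = 1,
                                 duration = 60, seed = NULL, sigma = 0.3,
                                 min_spacing = 1) {
  if (!is.finite(rate) || rate < 0 || rate > 30) {
    stop("burst rate must lie in [0, 30] per minute", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be > 0")
  gen <- function() {
    n <- stats::rpois(1, rate * duration / 60)
    if (n == 0) return(burst_train(sigma = sigma))
    onsets <- sort(stats::runif(n, 0, duration))
    keep <- c(TRUE, rep(FALSE, n - 1))
    last <- onsets[1]
    for (i in seq_len(n)[-1]) {
      if (onsets[i] - last >= min_spacing) {
        keep[i] <- TRUE
        last <- onsets[i]
      }
    }
    onsets <- onsets[keep]
    amps <- stats::runif(length(onsets), amp_low, amp_high)
    burst_train(onsets, amps, sigma = sigma)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Generate one synthetic epoch from a burst train
#'
#' Forward-simulates the train through the calibrated kernel, adds white
#' Gaussian measurement noise and a slow half-period sinusoidal drift
#' (`drift_amp * sin(pi t / duration)`, emulating tonic-level wander that
#' the minimum-subtraction convention removes only partially), then
#' subtracts the epoch minimum, matching the processing convention applied
#' to recorded data.
#'
#' @param train a [burst_train()]
#' @param params a calibrated [kernel_params()]
#' @param noise_sd white noise SD (uS)
#' @param drift_amp drift amplitude (uS)
#' @param duration epoch length (s)
#' @param rate sampling rate (Hz)
#' @param seed integer seed (`NULL` uses the current RNG stream)
#' @param label,subject metadata attached to the epoch
#' @return an [sf_epoch()]
#' @export
generate_epoch <- function(train, params, noise_sd = 0.05, drift_amp = 0.1,
                           duration = 60, rate = 10, seed = NULL,
                           label = NA_character_, subject = NA_character_) {
  stopifnot(inherits(train, "burst_train"), inherits(params, "kernel_params"))
  clean <- sf_simulate(params, train, duration, rate)
  gen <- function() {
    n <- length(clean$samples)
    t <- (seq_len(n) - 1) / rate
    y <- clean$samples +
      stats::rnorm(n, 0, noise_sd) +
      drift_amp * sin(pi * t / duration)
    sf_epoch(baseline_subtract(conductance_series(y, rate = rate)),
             label = label, subject = subject)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Generate a full two-condition synthetic study
#'
#' Simulates every epoch of the design with known ground truth: per
#' subject, the first `n_baseline` epochs at the baseline burst rate and
#' the remaining epochs at the condition-appropriate rate. All randomness
#' derives from the design's master seed through per-epoch sub-seeds, so
#' two runs with the same design are identical.
#'
#' @param design a [study_design()]
#' @param params a calibrated [kernel_params()]
#' @return an object of class `sf_study`: a list with `epochs` (list of
#'   [sf_epoch()]), `labels` (data frame `subject`, `epoch`, `label`,
#'   `group`), `truth` (list of ground-truth [burst_train()]s), and
#'   `design`
#' @export
generate_study <- function(design, params) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "kernel_params"))
  n_ep <- design$n_subjects * design$epochs_per_subject
  seeds <- .with_seed(design$seed,
                      matrix(sample.int(.Machine$integer.max, 2 * n_ep),
                             nrow = 2))
  epochs <- vector("list", n_ep)
  truth <- vector("list", n_ep)
  lab <- data.frame(subject = character(n_ep), epoch = integer(n_ep),
                    label = character(n_ep), group = character(n_ep))
  idx <- 0L
  for (s in seq_len(design$n_subjects)) {
    sid <- sprintf("S%02d", s)
    group <- if (design$design == "between" && s > design$n_subjects / 2) {
      "control"
    } else {
      "treatment"
    }
    for (e in seq_len(design$epochs_per_subject)) {
      idx <- idx + 1L
      is_baseline <- e <= design$n_baseline
      rate_bpm <- if (is_baseline) {
        design$baseline_rate
      } else if (design$design == "between" && group == "control") {
        design$baseline_rate
      } else {
        design$anticipation_rate
      }
      label <- if (is_baseline) "baseline" else "anticipation"
      train <- generate_burst_train(rate_bpm, design$amp_low,
                                    design$amp_high, design$duration,
                                    seed = seeds[1, idx])
      epochs[[idx]] <- generate_epoch(train, params,
                                      noise_sd = design$noise_sd,
                                      drift_amp = design$drift_amp,
                                      duration = design$duration,
                                      rate = design$rate,
                                      seed = seeds[2, idx],
                                      label = label, subject = sid)
      truth[[idx]] <- train
      lab$subject[idx] <- sid
      lab$epoch[idx] <- e
      lab$label[idx] <- label
      lab$group[idx] <- group
    }
  }
  structure(list(epochs = epochs, labels = lab, truth = truth,
                 design = design),
            class = "sf_study")
}

#' @export
print.sf_study <- function(x, ...) {
  cat(sprintf(
    "<sf_study> %s design: %d subjects x %d epochs (%g vs %g bursts/min)\n",
    x$design$design, x$design$n_subjects, x$design$epochs_per_subject,
    x$design$baseline_rate, x$design$anticipation_rate))
  invisible(x)
}

#' Match estimated bursts to ground truth
#'
#' Greedily pairs each true burst with the nearest above-threshold
#' estimated burst within `max_dist` seconds (closest pairs first, each
#' estimate used once) and reports per-pair onset and amplitude errors.
#'
#' @param truth the true [burst_train()]
#' @param est the estimated [burst_train()] (e.g. `result$bursts`)
#' @param threshold estimated bursts below this amplitude are ignored (uS)
#' @param max_dist maximum onset distance for a match (s)
#' @return a data frame with one row per true burst: `onset`, `amplitude`,
#'   `matched`, `onset_err` (s, absolute), `amp_err` (uS, absolute)
#' @export
match_bursts <- function(truth, est, threshold = 0.1, max_dist = 1) {
  stopifnot(inherits(truth, "burst_train"), inherits(est, "burst_train"))
  est <- est[est$amplitude >= threshold, , drop = FALSE]
  nt <- nrow(truth)
  out <- data.frame(onset = truth$onset, amplitude = truth$amplitude,
                    matched = rep(FALSE, nt),
                    onset_err = rep(NA_real_, nt),
                    amp_err = rep(NA_real_, nt))
  if (!nt || !nrow(est)) return(out)
  d <- abs(outer(truth$onset, est$onset, "-"))
  d[d > max_dist] <- NA
  while (any(is.finite(d))) {
    ij <- arrayInd(which.min(d), dim(d))
    i <- ij[1]; j <- ij[2]
    out$matched[i] <- TRUE
    out$onset_err[i] <- abs(truth$onset[i] - est$onset[j])
    out$amp_err[i] <- abs(truth$amplitude[i] - est$amplitude[j])
    d[i, ] <- NA; d[, j] <- NA
  }
  out
}
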