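#' Sudomotor burst trains
#'
#' A burst train is an ordered set of (onset, amplitude) pairs describing
#' sudomotor nerve activity (SNA). Each burst is a Gaussian bump of standard
#' deviation `sigma` seconds; its amplitude is expressed in SF-equivalent
#' microsiemens, i.e. the peak skin-conductance deflection the burst alone
#' would produce under a gain-calibrated kernel (see [calibrate_gain()]).
#'
#' @param onset numeric vector of burst centres (s). Sorted internally.
#' @param amplitude numeric vector of non-negative burst amplitudes
#'   (SF-equivalent microsiemens), recycled against `onset`.
#' @param sigma Gaussian standard deviation of a burst (s). Default 0.3 s.
#' @return An object of class `burst_train`: a data frame with columns
#'   `onset` and `amplitude`, plus a `sigma` attribute.
#' @examples
#' burst_train(c(10, 30, 50), c(0.5, 1, 0.8))
#' @export
burst_train <- function(onset = numeric(0), amplitude = numeric(0),
                        sigma = 0.3) {
  onset <- as.numeric(onset)
  amplitude <- as.numeric(rep_len(amplitude, length(onset)))
  if (length(onset) && any(!is.finite(onset))) {
    stop("burst onsets must be finite", call. = FALSE)
  }
  if (length(amplitude) && any(!is.finite(amplitude) | amplitude < 0)) {
    stop("burst amplitudes must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive duration in seconds", call. = FALSE)
  }
  ord <- order(onset, -amplitude)
  out <- data.frame(onset = onset[ord], amplitude = amplitude[ord])
  attr(out, "sigma") <- sigma
  class(out) <- c("burst_train", "data.frame")
  out
}

#' @export
print.burst_train <- function(x, ...) {
  cat(sprintf("<burst_train> %d burst(s), sigma = %.3g s\n",
              nrow(x), attr(x, "sigma")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Number of bursts in a train
#' @param x a [burst_train()]
#' @return integer count
#' @export
n_bursts <- function(x) {
  stopifnot(inherits(x, "burst_train"))
  nrow(x)
}

#' Kernel parameters of the canonical SF response
#'
#' The skin-conductance response to a single sudomotor burst is modelled as
#' the impulse response of a stable third-order linear ODE,
#' \deqn{\dddot y + (k_1+k_2+k_3)\ddot y + (k_1 k_2 + k_1 k_3 + k_2 k_3)
#'   \dot y + k_1 k_2 k_3\, y = g\, u(t),}
#' i.e. a convolution kernel with three real poles \eqn{-k_1,-k_2,-k_3}.
#' The kernel decays with two visible exponential phases (a fast fall after
#' the peak and a slow late recovery), matching the biphasic decay of
#' empirically observed spontaneous fluctuations.
#'
#' @param k1,k2,k3 positive rate coefficients (1/s); the negated poles of
#'   the kernel. Order is irrelevant.
#' @param gain output scale (microsiemens per unit burst). Set by
#'   [calibrate_gain()] so a unit burst yields a 1 uS peak.
#' @return An object of class `kernel_params`.
#' @seealso [default_kernel_params()], [impulse_response()], [sf_simulate()]
#' @export
kernel_params <- function(k1, k2, k3, gain = 1) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3)
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("all rate coefficients must be finite and > 0 (stable kernel)",
         call. = FALSE)
  }
  if (!is.finite(gain) || gain <= 0) {
    stop("gain must be finite and > 0", call. = FALSE)
  }
  structure(list(k1 = unname(k1), k2 = unname(k2), k3 = unname(k3),
                 gain = unname(gain)),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("<kernel_params> rates (1/s): %.4g, %.4g, %.4g; gain %.4g uS\n",
              x$k1, x$k2, x$k3, x$gain))
  invisible(x)
}

#' Default canonical kernel
#'
#' A synthetic canonical parameter set for the SF kernel, chosen to
#' reproduce the qualitative shape of a spontaneous fluctuation: a rise to
#' peak in roughly 2 s, a fast post-peak decline with a time constant near
#' 1 s, and a slow late recovery with a time constant near 8 s. The gain is
#' calibrated at 10 Hz so that one unit-amplitude Gaussian burst (sigma
#' 0.3 s) produces a 1 uS peak. These values are a packaged default, not a
#' transcription of any laboratory estimate; fit your own kernel with
#' [estimate_crf_fir()] and [fit_ode_to_crf()] when a measured canonical
#' response function is available.
#'
#' @return a calibrated [kernel_params()] object
#' @export
default_kernel_params <- function() {
  kernel_params(k1 = 0.15, k2 = 1.2, k3 = 2.8,
                gain = .default_kernel_gain)
}

# calibrate_gain(kernel_params(0.15, 1.2, 2.8), rate = 10, sigma = 0.3)
.default_kernel_gain <- 6.1581945768869666

# state-space companion realization: x1 = y, input enters highest derivative
.kernel_state_space <- function(params) {
  k <- c(params$k1, params$k2, params$k3)
  a0 <- k[1] * k[2] * k[3]
  a1 <- k[1] * k[2] + k[1] * k[3] + k[2] * k[3]
  a2 <- sum(k)
  A <- matrix(c(0, 1, 0,
                0, 0, 1,
                -a0, -a1, -a2), nrow = 3, byrow = TRUE)
  list(A = A, B = c(0, 0, 1), C = c(1, 0, 0))
}

# exact zero-order-hold discretization of (A, B) over step dt
.discretize <- function(A, B, dt) {
  M <- rbind(cbind(A, B), 0)
  E <- as.matrix(Matrix::expm(M * dt))
  list(Ad = E[1:3, 1:3, drop = FALSE], Bd = E[1:3, 4])
}

#' Gaussian SNA input trace
#'
#' Evaluates the continuous sudomotor drive
#' \eqn{u(t) = \sum_i a_i \exp(-(t-\mu_i)^2 / 2\sigma^2)} on a uniform
#' sample grid. Each Gaussian bump has unit peak at its onset, so an
#' isolated burst of amplitude `a` attains `u = a` at its centre. Bumps are
#' evaluated over +/- 5 sigma only; beyond that the contribution is below
#' 4e-6 of the peak.
#'
#' @param train a [burst_train()]
#' @param duration trace length (s)
#' @param rate sampling rate (Hz)
#' @return numeric vector of length `round(duration * rate)`, sample k
#'   (1-based) at time `(k - 1) / rate`
#' @export
gaussian_input <- function(train, duration, rate) {
  stopifnot(inherits(train, "burst_train"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  n <- round(duration * rate)
  u <- numeric(n)
  if (!nrow(train)) return(u)
  sigma <- attr(train, "sigma")
  t <- (seq_len(n) - 1) / rate
  for (i in seq_len(nrow(train))) {
    mu <- train$onset[i]
    lo <- max(1L, ceiling((mu - 5 * sigma) * rate) + 1L)
    hi <- min(n, floor((mu + 5 * sigma) * rate) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    u[idx] <- u[idx] +
      train$amplitude[i] * exp(-(t[idx] - mu)^2 / (2 * sigma^2))
  }
  u
}

#' Impulse response of the SF kernel
#'
#' The response of the third-order system to a Dirac input with zero
#' initial conditions, sampled exactly at the grid times (the linear system
#' is propagated with the matrix exponential, so no solver tolerance is
#' involved). The system has relative degree three, hence `h[1] == 0` at
#' t = 0.
#'
#' @param params a [kernel_params()] object
#' @param duration length of the returned response (s)
#' @param rate sampling rate (Hz)
#' @return numeric vector, `h[k]` the response at `(k - 1) / rate` seconds
#' @export
impulse_response <- function(params, duration, rate) {
  stopifnot(inherits(params, "kernel_params"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  ss <- .kernel_state_space(params)
  n <- round(duration * rate)
  Ad <- as.matrix(Matrix::expm(ss$A / rate))
  h <- numeric(n)
  x <- ss$B
  # h(t) = C exp(A t) B; h[1] = C B = 0
  h[1] <- x[1]
  for (k in seq_len(n - 1L)) {
    x <- Ad %*% x
    h[k + 1L] <- x[1]
  }
  params$gain * h
}

#' Simulate skin conductance from a burst train
#'
#' Integrates the third-order ODE driven by the Gaussian burst input. The
#' linear system is stepped exactly (zero-order hold with the matrix
#' exponential) on an internal grid of at least 100 Hz, with the input
#' sampled at step midpoints, and the result decimated to the requested
#' output rate. The output equals, to numerical accuracy, the continuous
#' convolution of the Gaussian drive with the kernel's impulse response.
#'
#' @param params a calibrated [kernel_params()]
#' @param train a [burst_train()]
#' @param duration epoch length (s)
#' @param rate output sampling rate (Hz)
#' @return a [conductance_series()] of length `round(duration * rate)`
#' @export
sf_simulate <- function(params, train, duration, rate) {
  stopifnot(inherits(params, "kernel_params"), inherits(train, "burst_train"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  n_out <- round(duration * rate)
  if (!nrow(train)) {
    return(conductance_series(numeric(n_out), rate = rate))
  }
  over <- max(1L, as.integer(ceiling(100 / rate)))
  fine_rate <- rate * over
  dt <- 1 / fine_rate
  n_fine <- n_out * over
  sigma <- attr(train, "sigma")
  # input held constant over each step at its midpoint value
  t_mid <- (seq_len(n_fine) - 0.5) * dt
  u <- .gaussian_eval(train, t_mid, sigma)
  ss <- .kernel_state_space(params)
  zoh <- .discretize(ss$A, ss$B, dt)
  y_fine <- .lsim_zoh(zoh$Ad, zoh$Bd, u)
  # fine sample j is at time j * dt; keep multiples of `over`, prepend t = 0
  y <- c(0, y_fine[seq.int(over, n_fine, by = over)])[seq_len(n_out)]
  conductance_series(params$gain * y, rate = rate)
}

# raw Gaussian superposition at arbitrary times (with 5 sigma truncation)
.gaussian_eval <- function(train, t, sigma) {
  u <- numeric(length(t))
  for (i in seq_len(nrow(train))) {
    mu <- train$onset[i]
    idx <- which(abs(t - mu) <= 5 * sigma)
    if (length(idx)) {
      u[idx] <- u[idx] +
        train$amplitude[i] * exp(-(t[idx] - mu)^2 / (2 * sigma^2))
    }
  }
  u
}

# propagate x_{j} = Ad x_{j-1} + Bd u_j from x_0 = 0; returns first state
.lsim_zoh <- function(Ad, Bd, u) {
  n <- length(u)
  y <- numeric(n)
  x <- c(0, 0, 0)
  for (j in seq_len(n)) {
    x <- Ad %*% x + Bd * u[j]
    y[j] <- x[1]
  }
  y
}

#' Calibrate the kernel gain to the unit-burst convention
#'
#' Sets the output gain so that a single burst of unit amplitude (the
#' default 0.3 s Gaussian) placed at the centre of a 60 s epoch produces a
#' simulated spontaneous fluctuation with a peak of exactly 1 uS at the
#' given sampling rate. After calibration, burst amplitudes are directly
#' interpretable as SF-equivalent microsiemens, so counting thresholds such
#' as 0.1 uS apply to them without conversion.
#'
#' @param params a [kernel_params()] object (gain may be arbitrary)
#' @param rate sampling rate used for the calibration (Hz), default 10
#' @param sigma burst width used for the calibration (s), default 0.3
#' @return `params` with `gain` replaced; all rate coefficients unchanged
#' @export
calibrate_gain <- function(params, rate = 10, sigma = 0.3) {
  stopifnot(inherits(params, "kernel_params"))
  ref <- burst_train(30, 1, sigma = sigma)
  probe <- kernel_params(params$k1, params$k2, params$k3, gain = 1)
  peak <- max(sf_simulate(probe, ref, duration = 60, rate = rate)$samples)
  if (!is.finite(peak) || peak <= .Machine$double.eps) {
    stop("degenerate kernel: unit burst produced no response; cannot calibrate",
         call. = FALSE)
  }
  kernel_params(params$k1, params$k2, params$k3, gain = 1 / peak)
}

#' Read or write kernel parameters as flat key-value text
#'
#' The on-disk format is one `key = value` pair per line with keys `k1`,
#' `k2`, `k3`, `gain`, plus informational keys `sigma_s` and
#' `calibrated_at_rate_hz`.
#'
#' @param params a [kernel_params()] object
#' @param path file path
#' @param sigma_s,calibrated_at_rate_hz informational metadata to record
#' @return `read_kernel_params` returns a [kernel_params()];
#'   `write_kernel_params` returns `path` invisibly.
#' @export
write_kernel_params <- function(params, path, sigma_s = 0.3,
                                calibrated_at_rate_hz = 10) {
  stopifnot(inherits(params, "kernel_params"))
  lines <- c(
    sprintf("k1 = %.17g", params$k1),
    sprintf("k2 = %.17g", params$k2),
    sprintf("k3 = %.17g", params$k3),
    sprintf("gain = %.17g", params$gain),
    sprintf("sigma_s = %.17g", sigma_s),
    sprintf("calibrated_at_rate_hz = %.17g", calibrated_at_rate_hz)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kernel_params
#' @export
read_kernel_params <- function(path) {
  if (!file.exists(path)) stop("kernel parameter file not found: ", path,
                               call. = FALSE)
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
  vals <- as.numeric(trimws(kv[, 2]))
  names(vals) <- trimws(kv[, 1])
  need <- c("k1", "k2", "k3", "gain")
  if (!all(need %in% names(vals)) || any(!is.finite(vals[need]))) {
    stop("kernel parameter file must define numeric k1, k2, k3, gain",
         call. = FALSE)
  }
  kernel_params(vals[["k1"]], vals[["k2"]], vals[["k3"]], vals[["gain"]])
}
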