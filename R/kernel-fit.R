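#' Canonical response function container
#'
#' A sampled canonical response function (CRF): the stereotyped
#' skin-conductance waveform evoked by a single sudomotor burst, in
#' microsiemens per unit event.
#'
#' @param samples numeric vector (uS per unit event), first sample at t = 0
#' @param rate sampling rate (Hz)
#' @return an object of class `crf`
#' @export
crf <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("CRF samples must be finite")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  if (length(samples) / rate < 10) {
    stop("CRF window must be at least 10 s to cover the SF decay",
         call. = FALSE)
  }
  structure(list(samples = samples, rate = rate,
                 window = length(samples) / rate),
            class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf("<crf> %.1f s window @ %g Hz, peak %.4g uS at %.2f s\n",
              x$window, x$rate, max(x$samples),
              (which.max(x$samples) - 1) / x$rate))
  invisible(x)
}

#' Read/write a CRF as two-column CSV (t_s, value)
#' @param x a [crf()]
#' @param path file path
#' @return `read_crf` returns a [crf()]; `write_crf` returns `path`
#'   invisibly.
#' @export
write_crf <- function(x, path) {
  stopifnot(inherits(x, "crf"))
  utils::write.csv(data.frame(t_s = (seq_along(x$samples) - 1) / x$rate,
                              value = x$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  if (!file.exists(path)) stop("CRF file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("CRF file needs two columns (t_s, value)")
  dt <- diff(df[[1]])
  if (any(!is.finite(dt)) || any(abs(dt - dt[1]) > 1e-9)) {
    stop("CRF time column must be uniformly spaced")
  }
  crf(df[[2]], rate = 1 / dt[1])
}

#' Estimate a canonical response function by FIR deconvolution
#'
#' Given epochs and the onsets of the fluctuations inside them, solves the
#' ordinary-least-squares finite impulse response model: each trace is a
#' superposition of one shared kernel shifted to every onset (a design
#' matrix of lagged indicator regressors). All onsets within and across
#' epochs share one kernel, the linear-superposition assumption of the
#' forward model.
#'
#' @param epochs list of [sf_epoch()] objects at a common sampling rate
#' @param onsets list (parallel to `epochs`) of numeric onset vectors (s),
#'   in each epoch's own time frame (0 = first sample)
#' @param window FIR kernel length (s), default 30
#' @return a [crf()] holding the least-squares kernel estimate
#' @export
estimate_crf_fir <- function(epochs, onsets, window = 30) {
  if (!length(epochs)) stop("need at least one epoch")
  if (length(onsets) != length(epochs)) {
    stop("onsets must be a list parallel to epochs")
  }
  rate <- epochs[[1]]$series$rate
  p <- round(window * rate)
  rows <- vapply(epochs, function(e) length(e$series$samples), 0L)
  if (sum(rows) <= p) {
    stop("FIR design is not identifiable: use longer data or a shorter window",
         call. = FALSE)
  }
  Xs <- vector("list", length(epochs))
  for (e in seq_along(epochs)) {
    ne <- rows[e]
    X <- matrix(0, ne, p)
    for (o in onsets[[e]]) {
      j0 <- round(o * rate)  # 0-based lag of the onset sample
      idx <- seq.int(0, p - 1L)
      t_idx <- j0 + idx + 1L
      ok <- t_idx >= 1L & t_idx <= ne
      X[cbind(t_idx[ok], idx[ok] + 1L)] <-
        X[cbind(t_idx[ok], idx[ok] + 1L)] + 1
    }
    Xs[[e]] <- X
  }
  if (!sum(vapply(onsets, length, 0L))) stop("need at least one onset")
  X <- do.call(rbind, Xs)
  y <- unlist(lapply(epochs, function(e) e$series$samples))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    stop("rank-deficient FIR design: use longer data or a shorter window",
         call. = FALSE)
  }
  crf(unname(fit$coefficients), rate = rate)
}

# model CRF implied by kernel rates: impulse response, optionally
# convolved with the Gaussian burst shape (input_sigma > 0), unit gain
.crf_model <- function(logk, window, rate, input_sigma, fine_rate = 100) {
  k <- exp(logk)
  params <- kernel_params(k[1], k[2], k[3], gain = 1)
  if (input_sigma > 0) {
    bt <- .burst_response_table(params, input_sigma, window, fine_rate)
    tt <- (seq_len(round(window * rate)) - 1) / rate
    pos <- (tt - bt$t0) / bt$df + 1
    i <- floor(pos); fr <- pos - i
    bt$b[i] * (1 - fr) + bt$b[i + 1] * fr
  } else {
    impulse_response(params, window, rate)
  }
}

#' Fit ODE kernel parameters to a canonical response function
#'
#' Finds rate coefficients whose impulse response best matches a given
#' CRF, as a maximum-a-posteriori estimate: optimization runs in log-rate
#' space (guaranteeing positivity and stability) under independent
#' Gaussian priors on the log-rates centred at the initial values with SD
#' 1 log-unit, and the residual is weighted as if observed with an SD of
#' 1% of the CRF peak. The output gain is profiled analytically (ordinary
#' least squares given the shape). A deterministic start is followed by up
#' to `n_restarts` jittered restarts under a fixed seed; the best basin
#' wins.
#'
#' @param x a [crf()]
#' @param init initial [kernel_params()] (also the prior centre)
#' @param input_sigma if the CRF was estimated from onset indicators of
#'   Gaussian bursts (as [estimate_crf_fir()] produces on burst-model
#'   data), set this to the burst SD (s) so the fit deconvolves the known
#'   bump shape; 0 (default) fits the bare impulse response
#' @param n_restarts jittered restarts after the deterministic start
#' @param seed seed for the restart jitter
#' @return a [kernel_params()] with fitted rates and gain; attributes
#'   `rmse` (final root-mean-square misfit, uS), `objective_trace` (the
#'   accepted, non-increasing objective values), and `converged`
#' @export
fit_ode_to_crf <- function(x, init, input_sigma = 0, n_restarts = 5,
                           seed = 1L) {
  stopifnot(inherits(x, "crf"), inherits(init, "kernel_params"))
  y <- x$samples
  peak <- max(abs(y))
  if (peak <= 0) stop("degenerate CRF: all zero")
  s2 <- (0.01 * peak)^2
  logk0 <- log(c(init$k1, init$k2, init$k3))
  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  obj <- function(logk) {
    if (any(!is.finite(logk)) || any(abs(logk) > 12)) return(1e12)
    h <- .crf_model(logk, x$window, x$rate, input_sigma)
    hh <- sum(h^2)
    if (hh <= .Machine$double.eps) return(1e12)
    g <- sum(h * y) / hh
    val <- 0.5 * sum((g * h - y)^2) / s2 + 0.5 * sum((logk - logk0)^2)
    if (val < trace_env$best) {
      trace_env$best <- val
      trace_env$trace <- c(trace_env$trace, val)
    }
    val
  }
  starts <- list(logk0)
  if (n_restarts > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    for (i in seq_len(n_restarts)) {
      starts[[i + 1]] <- logk0 + stats::rnorm(3, 0, 0.3)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  logk <- best$par
  h <- .crf_model(logk, x$window, x$rate, input_sigma)
  g <- sum(h * y) / sum(h^2)
  rmse <- sqrt(mean((g * h - y)^2))
  converged <- best$convergence == 0
  out <- kernel_params(exp(logk[1]), exp(logk[2]), exp(logk[3]),
                       gain = abs(g))
  attr(out, "rmse") <- rmse
  attr(out, "objective_trace") <- trace_env$trace
  attr(out, "converged") <- converged
  if (!converged && rmse > 0.05 * peak) {
    stop(sprintf(
      "kernel fit did not converge (best RMSE %.3g uS); best-so-far rates: %.4g %.4g %.4g",
      rmse, exp(logk[1]), exp(logk[2]), exp(logk[3])), call. = FALSE)
  }
  out
}
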