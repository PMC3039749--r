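#' Inversion configuration
#'
#' Settings for variational Bayesian inversion of an epoch. The model
#' places one candidate burst per `60 / max_rate` seconds (30 candidates in
#' a 60 s epoch at the default 30 bursts/min cap). Each candidate has a
#' free onset with a Gaussian prior centred on its grid position (SD
#' `prior_onset_sd`, truncated to the epoch) and a free amplitude
#' parameterized as `exp(log-amplitude)` with a log-normal prior whose
#' default mean corresponds to a 0.01 uS spontaneous fluctuation; unused
#' candidates therefore shrink towards a negligible amplitude without an
#' explicit sparsity penalty. Observation noise is i.i.d. Gaussian with a
#' weakly informative Gamma prior on its precision.
#'
#' @param max_rate maximum burst frequency (bursts per minute), default 30
#' @param sigma Gaussian burst SD (s), default 0.3
#' @param prior_amp_mean,prior_amp_sd prior mean and SD of the per-burst
#'   log-amplitude (log uS)
#' @param prior_onset_sd prior SD of each onset around its grid position (s)
#' @param prior_prec_shape,prior_prec_rate Gamma prior on noise precision
#' @param tol free-energy convergence tolerance (nats), default 0.01
#' @param max_iter iteration cap, default 200
#' @param merge_window posterior bursts closer than this (s) are merged
#'   into one (amplitudes summed, onset amplitude-weighted), since
#'   coincident Gaussian bumps are indistinguishable under the linear model
#' @param fine_rate internal grid (Hz) on which the burst response and its
#'   derivative are tabulated
#' @param seed integer seed (reserved for stochastic extensions; the
#'   default scheme is deterministic)
#' @return an object of class `inversion_config`
#' @export
inversion_config <- function(max_rate = 30, sigma = 0.3,
                             prior_amp_mean = log(0.01), prior_amp_sd = 2,
                             prior_onset_sd = 1,
                             prior_prec_shape = 1e-2, prior_prec_rate = 1e-2,
                             tol = 1e-2, max_iter = 200,
                             merge_window = 0.5, fine_rate = 100,
                             seed = 1L) {
  if (!is.finite(max_rate) || max_rate <= 0) stop("max_rate must be > 0")
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(max_rate = max_rate, sigma = sigma,
                 prior_amp_mean = prior_amp_mean, prior_amp_sd = prior_amp_sd,
                 prior_onset_sd = prior_onset_sd,
                 prior_prec_shape = prior_prec_shape,
                 prior_prec_rate = prior_prec_rate,
                 tol = tol, max_iter = max_iter,
                 merge_window = merge_window, fine_rate = fine_rate,
                 seed = as.integer(seed)),
            class = "inversion_config")
}

# tabulated response of one unit burst: b(t) = (gauss_sigma * h)(t),
# with derivative, on a fine grid starting at -5 sigma
.burst_response_table <- function(params, sigma, t_max, fine_rate = 100) {
  df <- 1 / fine_rate
  sg <- seq(-5 * sigma, 5 * sigma, by = df)
  g <- exp(-sg^2 / (2 * sigma^2))
  h <- impulse_response(params, t_max + 5 * sigma + df, fine_rate)
  b <- stats::convolve(g, rev(h), type = "open")[seq_len(length(h))] * df
  db <- c(0, diff(b)) * fine_rate
  db[1] <- db[2]
  list(t0 = -5 * sigma, df = df, b = b, db = db)
}

# evaluate tabulated burst response (and derivative) at t - mu for every
# candidate; returns n x m matrices via vectorized linear interpolation
.basis_eval <- function(bt, tgrid, mu) {
  n <- length(tgrid); m <- length(mu)
  lag <- outer(tgrid, mu, "-")
  pos <- (lag - bt$t0) / bt$df + 1
  len <- length(bt$b)
  inside <- pos >= 1 & pos <= len - 1e-9
  i <- floor(pmin(pmax(pos, 1), len - 1))
  fr <- pos - i
  B <- (bt$b[i] * (1 - fr) + bt$b[i + 1] * fr) * inside
  DB <- (bt$db[i] * (1 - fr) + bt$db[i + 1] * fr) * inside
  dim(B) <- c(n, m); dim(DB) <- c(n, m)
  list(B = B, DB = DB)
}

# free energy pieces for a given linearization point
.fe_terms <- function(J, r, tau, m, m0, P0) {
  n <- length(r); d <- length(m)
  H <- tau * crossprod(J)
  diag(H) <- diag(H) + P0
  R <- chol(H)
  S <- chol2inv(R)
  logdetS <- -2 * sum(log(diag(R)))
  trJSJ <- sum((J %*% S) * J)
  rss <- sum(r^2)
  ell <- 0.5 * n * log(tau / (2 * pi)) - 0.5 * tau * (rss + trJSJ)
  kl <- 0.5 * (sum(P0 * diag(S)) + sum(P0 * (m - m0)^2) - d -
                 sum(log(P0)) - logdetS)
  list(fe = ell - kl, S = S, trJSJ = trJSJ, rss = rss)
}

#' Variational free energy of a Gaussian posterior
#'
#' Evaluates the evidence lower bound for an epoch under the burst model:
#' the expected log-likelihood of the data (Gaussian observation model,
#' with the model prediction linearized at the posterior mean) minus the
#' Kullback-Leibler divergence from the prior to the posterior. Noise
#' precision is treated as a point value. The bound is deterministic given
#' its inputs.
#'
#' @param epoch an [sf_epoch()] (pre-processed, minimum-subtracted)
#' @param params a calibrated [kernel_params()]
#' @param posterior a list with elements `mean` (length 2m: the m
#'   log-amplitudes followed by the m onsets), `cov` (2m x 2m matrix, or a
#'   vector of 2m variances), and `precision` (noise precision, 1/uS^2)
#' @param cfg an [inversion_config()]; supplies the priors
#' @return the free energy (nats)
#' @export
free_energy <- function(epoch, params, posterior, cfg = inversion_config()) {
  stopifnot(inherits(epoch, "sf_epoch"), inherits(params, "kernel_params"))
  y <- epoch$series$samples
  if (any(!is.finite(y))) stop("epoch contains non-finite samples")
  if (!is.finite(posterior$precision) || posterior$precision <= 0) {
    stop("noise precision must be finite and > 0")
  }
  n <- length(y); rate <- epoch$series$rate; duration <- n / rate
  mvec <- posterior$mean
  d <- length(mvec); m <- d / 2
  if (m != floor(m)) stop("posterior$mean must hold log-amplitudes then onsets")
  S <- posterior$cov
  if (is.null(dim(S))) S <- diag(as.numeric(S), d)
  if (any(!is.finite(mvec)) || any(!is.finite(S))) {
    stop("posterior moments must be finite")
  }
  grid <- (seq_len(m) - 0.5) * duration / m
  prior <- .inv_priors(m, grid, cfg)
  tgrid <- (seq_len(n) - 1) / rate
  bt <- .burst_response_table(params, cfg$sigma, duration, cfg$fine_rate)
  z <- mvec[seq_len(m)]; mu <- mvec[m + seq_len(m)]
  bas <- .basis_eval(bt, tgrid, mu)
  a <- exp(z)
  r <- y - drop(bas$B %*% a)
  J <- cbind(sweep(bas$B, 2, a, "*"), sweep(-bas$DB, 2, a, "*"))
  tau <- posterior$precision
  rss <- sum(r^2)
  trJSJ <- sum((J %*% S) * J)
  ell <- 0.5 * n * log(tau / (2 * pi)) - 0.5 * tau * (rss + trJSJ)
  P0 <- prior$prec
  Rs <- chol(S)
  logdetS <- 2 * sum(log(diag(Rs)))
  kl <- 0.5 * (sum(P0 * diag(S)) + sum(P0 * (mvec - prior$mean)^2) - d -
                 sum(log(P0)) - logdetS)
  ell - kl
}

.inv_priors <- function(m, grid, cfg) {
  list(mean = c(rep(cfg$prior_amp_mean, m), grid),
       prec = c(rep(1 / cfg$prior_amp_sd^2, m),
                rep(1 / cfg$prior_onset_sd^2, m)))
}

#' Invert one epoch: estimate SNA bursts from skin conductance
#'
#' Fits the burst model to a pre-processed epoch by variational Laplace:
#' a Gaussian posterior over all per-candidate log-amplitudes and onsets is
#' optimized by damped Gauss-Newton ascent on the free energy, alternating
#' with a closed-form noise-precision update (Gamma-prior posterior mean).
#' Both updates are accepted only when they do not decrease the free
#' energy, so the recorded free-energy trace is non-decreasing. Iteration
#' stops when one full sweep improves the bound by less than `cfg$tol`
#' nats, or at `cfg$max_iter` sweeps (then `converged = FALSE`, without an
#' error).
#'
#' Amplitudes are initialized from a non-negative ridge projection of the
#' data onto the candidate basis; onsets start on the candidate grid.
#' After convergence, posterior bursts closer than `cfg$merge_window`
#' seconds are merged (see [inversion_config()]) and the train is sorted
#' by onset.
#'
#' @param epoch an [sf_epoch()] (minimum-subtracted; see
#'   [baseline_subtract()])
#' @param params a calibrated [kernel_params()]
#' @param cfg an [inversion_config()]
#' @return an object of class `sf_inversion` with elements `bursts` (a
#'   [burst_train()] of posterior means), `amp_sd`, `onset_sd`,
#'   `noise_precision`, `free_energy`, `fe_trace`, `fitted` (a
#'   [conductance_series()] from the forward model at the posterior mean),
#'   `residual_sd`, `n_iter`, `converged`
#' @export
invert_epoch <- function(epoch, params, cfg = inversion_config()) {
  stopifnot(inherits(epoch, "sf_epoch"), inherits(params, "kernel_params"),
            inherits(cfg, "inversion_config"))
  y <- epoch$series$samples
  if (any(!is.finite(y))) stop("epoch contains non-finite samples")
  n <- length(y); rate <- epoch$series$rate; duration <- n / rate
  m <- as.integer(ceiling(duration * cfg$max_rate / 60))
  grid <- (seq_len(m) - 0.5) * duration / m
  prior <- .inv_priors(m, grid, cfg)
  m0 <- prior$mean; P0 <- prior$prec
  tgrid <- (seq_len(n) - 1) / rate
  bt <- .burst_response_table(params, cfg$sigma, duration, cfg$fine_rate)

  z_floor <- cfg$prior_amp_mean - 10
  z_ceil <- log(max(10, 4 * max(abs(y)) + 1))
  clamp <- function(v) {
    z <- pmin(pmax(v[seq_len(m)], z_floor), z_ceil)
    mu <- pmin(pmax(v[m + seq_len(m)], 0), duration)
    c(z, mu)
  }

  eval_state <- function(v, tau) {
    z <- v[seq_len(m)]; mu <- v[m + seq_len(m)]
    bas <- .basis_eval(bt, tgrid, mu)
    a <- exp(z)
    r <- y - drop(bas$B %*% a)
    J <- cbind(sweep(bas$B, 2, a, "*"), sweep(-bas$DB, 2, a, "*"))
    ft <- .fe_terms(J, r, tau, v, m0, P0)
    c(list(v = v, r = r, J = J), ft)
  }

  # initialization: ridge projection on the grid-fixed amplitude basis
  B0 <- .basis_eval(bt, tgrid, grid)$B
  G <- crossprod(B0); diag(G) <- diag(G) + 1
  a0 <- drop(solve(G, crossprod(B0, y)))
  v <- clamp(c(log(pmax(a0, exp(cfg$prior_amp_mean))), grid))
  a_shape <- cfg$prior_prec_shape; a_rate <- cfg$prior_prec_rate
  rss0 <- sum((y - drop(B0 %*% exp(v[seq_len(m)])))^2)
  tau <- (a_shape + n / 2) / (a_rate + rss0 / 2)

  st <- eval_state(v, tau)
  fe_trace <- st$fe
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    fe_before <- st$fe
    # Gauss-Newton ascent step with step-halving
    gvec <- tau * crossprod(st$J, st$r) - P0 * (st$v - m0)
    dir <- drop(st$S %*% gvec)
    step <- 1
    for (k in 1:8) {
      cand <- eval_state(clamp(st$v + step * dir), tau)
      if (cand$fe > st$fe) { st <- cand; break }
      step <- step / 2
    }
    # precision update (Gamma posterior mean), accepted if F does not drop
    tau_new <- (a_shape + n / 2) / (a_rate + 0.5 * (st$rss + st$trJSJ))
    cand <- eval_state(st$v, tau_new)
    if (cand$fe >= st$fe) { tau <- tau_new; st <- cand }
    fe_trace <- c(fe_trace, st$fe)
    if (st$fe - fe_before < cfg$tol) { converged <- TRUE; break }
  }

  z <- st$v[seq_len(m)]; mu <- st$v[m + seq_len(m)]
  sds <- sqrt(pmax(diag(st$S), 0))
  amp <- exp(z)
  amp_sd <- amp * sds[seq_len(m)]
  onset_sd <- sds[m + seq_len(m)]
  merged <- .merge_bursts(mu, amp, amp_sd, onset_sd, cfg$merge_window)
  train <- burst_train(merged$onset, merged$amp, sigma = cfg$sigma)
  fitted <- sf_simulate(params, train, duration, rate)
  structure(list(
    bursts = train,
    amp_sd = merged$amp_sd[order(merged$onset)],
    onset_sd = merged$onset_sd[order(merged$onset)],
    noise_precision = tau,
    free_energy = st$fe,
    fe_trace = fe_trace,
    fitted = fitted,
    residual_sd = stats::sd(y - fitted$samples),
    n_iter = iter,
    converged = converged
  ), class = "sf_inversion")
}

# merge near-coincident bursts: coincident Gaussian bumps are equivalent
# to one bump with the summed amplitude under the linear forward model
.merge_bursts <- function(onset, amp, amp_sd, onset_sd, window) {
  ord <- order(onset)
  onset <- onset[ord]; amp <- amp[ord]
  amp_sd <- amp_sd[ord]; onset_sd <- onset_sd[ord]
  repeat {
    if (length(onset) < 2) break
    gaps <- diff(onset)
    j <- which.min(gaps)
    if (gaps[j] >= window) break
    w <- amp[j:(j + 1)] / sum(amp[j:(j + 1)])
    onset[j] <- sum(w * onset[j:(j + 1)])
    onset_sd[j] <- sum(w * onset_sd[j:(j + 1)])
    amp[j] <- amp[j] + amp[j + 1]
    amp_sd[j] <- sqrt(amp_sd[j]^2 + amp_sd[j + 1]^2)
    keep <- setdiff(seq_along(onset), j + 1)
    onset <- onset[keep]; amp <- amp[keep]
    amp_sd <- amp_sd[keep]; onset_sd <- onset_sd[keep]
  }
  list(onset = onset, amp = amp, amp_sd = amp_sd, onset_sd = onset_sd)
}

#' @export
print.sf_inversion <- function(x, ...) {
  cat(sprintf(
    "<sf_inversion> %d candidate burst(s), %d with amplitude >= 0.1 uS\n",
    nrow(x$bursts), sum(x$bursts$amplitude >= 0.1)))
  cat(sprintf("  free energy %.2f nats after %d iteration(s)%s\n",
              x$free_energy, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  residual SD %.4g uS, noise precision %.4g 1/uS^2\n",
              x$residual_sd, x$noise_precision))
  invisible(x)
}

#' Continuous SNA trace from an inversion result
#'
#' Reconstructs the estimated sudomotor drive by evaluating the Gaussian
#' bump superposition at the posterior-mean onsets and amplitudes.
#'
#' @param result an [invert_epoch()] result
#' @param duration trace length (s)
#' @param rate sampling rate (Hz)
#' @return numeric vector of SNA values on the requested grid
#' @export
extract_sna <- function(result, duration, rate) {
  stopifnot(inherits(result, "sf_inversion"))
  gaussian_input(result$bursts, duration, rate)
}
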