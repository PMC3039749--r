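#' Count above-threshold bursts in an inversion result
#'
#' Counts posterior-mean bursts whose amplitude is at least `threshold`
#' (inclusive comparison, so a burst at exactly the threshold is counted).
#' Because amplitudes are SF-equivalent microsiemens, the conventional
#' 0.1 uS response threshold applies directly.
#'
#' @param result an [invert_epoch()] result
#' @param threshold amplitude threshold (uS), default 0.1
#' @return integer count
#' @export
count_bursts <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "sf_inversion"))
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a non-negative amplitude in uS", call. = FALSE)
  }
  sum(result$bursts$amplitude >= threshold)
}

#' Conventional trough-to-peak SF counting
#'
#' An automatic stand-in for semi-visual scoring: local maxima whose rise
#' from the preceding local minimum (the lowest trough since the previous
#' counted response) reaches `threshold` are counted as fluctuations, with
#' counted peaks at least `min_separation` seconds apart to avoid
#' double-counting wiggles that a human rater would score as one response.
#'
#' @param epoch an [sf_epoch()] (pre-processed)
#' @param threshold trough-to-peak amplitude criterion (uS), default 0.25
#' @param min_separation minimum spacing between counted peaks (s)
#' @return integer count of detected fluctuations
#' @export
count_sf_conventional <- function(epoch, threshold = 0.25,
                                  min_separation = 1) {
  stopifnot(inherits(epoch, "sf_epoch"))
  x <- epoch$series$samples
  rate <- epoch$series$rate
  n <- length(x)
  dx <- diff(x)
  s <- sign(dx)
  nz <- which(s != 0)
  if (length(nz) < 2) return(0L)
  count <- 0L
  last_peak_t <- -Inf
  run_min <- x[1]  # lowest trough seen since the last counted peak
  prev_sign <- s[nz[1]]
  for (i in nz[-1]) {
    if (s[i] == prev_sign) next
    if (prev_sign > 0 && s[i] < 0) {  # local maximum at sample i
      t_here <- (i - 1) / rate
      if (x[i] - run_min >= threshold &&
          t_here - last_peak_t >= min_separation) {
        count <- count + 1L
        last_peak_t <- t_here
        run_min <- Inf  # baseline restarts at the next trough
      }
    } else {  # local minimum at sample i
      run_min <- min(run_min, x[i])
    }
    prev_sign <- s[i]
  }
  count
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit validity checks; with a
#' binary second argument this is the point-biserial coefficient.
#'
#' @param x,y numeric vectors of equal length (>= 3) and non-zero variance
#' @return the correlation coefficient in \[-1, 1\]
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

.safe_r <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (length(u) < 2) {
    stop("both label classes must be present", call. = FALSE)
  }
  if (length(u) > 2) stop("labels must have exactly two classes",
                          call. = FALSE)
  # "baseline" is the reference class regardless of alphabetical order
  if (is.character(u) && any(tolower(u) == "baseline")) {
    return(as.integer(tolower(as.character(labels)) != "baseline"))
  }
  as.integer(labels == u[2])
}

#' Correlations as a function of the counting threshold
#'
#' Recomputes DCM burst counts at each threshold and reports, per row, the
#' Pearson correlation with the conventional counts (`r_methods`) and the
#' point-biserial correlation of each count vector with the binary
#' psychological state (`r_validity_dcm`, `r_validity_conv`). The
#' conventional counts are held fixed across rows. Correlations that are
#' undefined at a given threshold (zero count variance) are returned as
#' `NA`.
#'
#' @param results list of [invert_epoch()] results, one per epoch
#' @param conv_counts integer vector of conventional SF counts, parallel
#'   to `results`
#' @param labels binary condition labels, parallel to `results`
#' @param thresholds numeric vector of amplitude thresholds (uS)
#' @return a data frame with columns `threshold`, `r_methods`,
#'   `r_validity_dcm`, `r_validity_conv`
#' @export
threshold_sweep <- function(results, conv_counts, labels,
                            thresholds = seq(0, 0.5, by = 0.05)) {
  if (length(results) < 3) stop("need at least 3 epochs")
  if (length(conv_counts) != length(results) ||
      length(labels) != length(results)) {
    stop("results, conv_counts and labels must be parallel vectors")
  }
  state <- .as_binary(labels)
  if (length(unique(state)) < 2) {
    stop("both label classes must be present", call. = FALSE)
  }
  conv_counts <- as.numeric(conv_counts)
  r_conv <- .safe_r(conv_counts, state)
  rows <- lapply(thresholds, function(thr) {
    dcm <- vapply(results, count_bursts, 0L, threshold = thr)
    # identical count vectors agree perfectly even when degenerate
    r_m <- if (all(dcm == conv_counts)) 1 else .safe_r(dcm, conv_counts)
    data.frame(threshold = thr,
               r_methods = r_m,
               r_validity_dcm = .safe_r(dcm, state),
               r_validity_conv = r_conv)
  })
  do.call(rbind, rows)
}

#' ROC curve for predicting a binary state from counts
#'
#' Sweeps every integer cutoff c and classifies an epoch as "positive"
#' when its count is at least c; each cutoff yields one
#' (false-positive rate, sensitivity) point. The endpoints (0,0) and
#' (1,1) are always included and the area under the curve is computed by
#' the trapezoid rule over the sorted points, which equals the
#' Mann-Whitney U statistic scaled by the number of label pairs (ties
#' counted one half).
#'
#' @param counts numeric (typically integer) response counts
#' @param labels binary state labels, parallel to `counts`
#' @return a list with `points` (data frame `cutoff`, `fpr`, `sens`) and
#'   `auc`
#' @export
roc_curve <- function(counts, labels) {
  counts <- as.numeric(counts)
  state <- .as_binary(labels)
  if (length(counts) != length(state)) {
    stop("counts and labels must have equal length")
  }
  if (length(unique(state)) < 2) {
    stop("both label classes must be present", call. = FALSE)
  }
  cuts <- sort(unique(c(counts, max(counts) + 1)))
  pts <- data.frame(
    cutoff = cuts,
    fpr = vapply(cuts, function(c) mean(counts[state == 0] >= c), 0),
    sens = vapply(cuts, function(c) mean(counts[state == 1] >= c), 0)
  )
  if (!any(pts$fpr == 0 & pts$sens == 0)) {
    pts <- rbind(pts, data.frame(cutoff = NA, fpr = 0, sens = 0))
  }
  if (!any(pts$fpr == 1 & pts$sens == 1)) {
    pts <- rbind(pts, data.frame(cutoff = NA, fpr = 1, sens = 1))
  }
  pts <- pts[order(pts$fpr, pts$sens), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$sens, -1) +
                                utils::tail(pts$sens, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Nested-regression F-test of added predictive value
#'
#' Extra-sum-of-squares comparison of `state ~ pred_base` against
#' `state ~ pred_base + pred_add`: the F statistic measures the variance
#' in the state explained by the added predictor above and beyond the
#' base predictor, with 1 and n - 3 degrees of freedom.
#'
#' @param state numeric (or binary) outcome vector, length n >= 4
#' @param pred_base base predictor (e.g. conventional SF counts)
#' @param pred_add added predictor (e.g. DCM burst counts)
#' @return a list with `F`, `df1`, `df2`, `p`
#' @export
nested_f_test <- function(state, pred_base, pred_add) {
  state <- as.numeric(.maybe_binary(state))
  pred_base <- as.numeric(pred_base); pred_add <- as.numeric(pred_add)
  n <- length(state)
  if (length(pred_base) != n || length(pred_add) != n) {
    stop("all vectors must have equal length")
  }
  if (n < 4) stop("need at least 4 observations")
  aux <- stats::lm.fit(cbind(1, pred_base), pred_add)
  if (sqrt(mean(aux$residuals^2)) < 1e-10 * (stats::sd(pred_add) + 1e-30)) {
    warning("pred_add is collinear with pred_base; F set to 0")
    return(list(F = 0, df1 = 1L, df2 = n - 3L, p = 1))
  }
  m1 <- stats::lm(state ~ pred_base)
  m2 <- stats::lm(state ~ pred_base + pred_add)
  rss1 <- sum(stats::residuals(m1)^2)
  rss2 <- sum(stats::residuals(m2)^2)
  df2 <- n - 3L
  Fstat <- (rss1 - rss2) / (rss2 / df2)
  list(F = Fstat, df1 = 1L, df2 = df2,
       p = stats::pf(Fstat, 1, df2, lower.tail = FALSE))
}

.maybe_binary <- function(x) {
  if (is.numeric(x)) x else .as_binary(x)
}

#' Per-subject arousal scores for between-subject designs
#'
#' The subject-level arousal summary used when the condition varies
#' between subjects: the mean response count over anticipation epochs
#' minus the count in the baseline epoch.
#'
#' @param counts numeric response counts, one per epoch
#' @param labels epoch condition tags ("baseline" vs anything else)
#' @param subjects subject identifier per epoch
#' @return a data frame with one row per subject: `subject`, `score`
#' @export
arousal_scores <- function(counts, labels, subjects) {
  if (length(counts) != length(labels) ||
      length(counts) != length(subjects)) {
    stop("counts, labels and subjects must be parallel vectors")
  }
  base <- tolower(as.character(labels)) == "baseline"
  out <- lapply(split(seq_along(counts), subjects), function(idx) {
    b <- idx[base[idx]]; a <- idx[!base[idx]]
    if (!length(b) || !length(a)) return(NULL)
    data.frame(subject = subjects[idx[1]],
               score = mean(counts[a]) - mean(counts[b]))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Full validity report at one threshold
#'
#' Bundles the counting and validity statistics at a single amplitude
#' threshold: DCM and conventional counts, their Pearson correlation,
#' each method's point-biserial validity against the binary state, ROC
#' curves with AUC, and the nested F-test of whether DCM counts explain
#' state variance beyond the conventional counts.
#'
#' @param results list of [invert_epoch()] results
#' @param epochs list of matching [sf_epoch()] objects (for conventional
#'   counting), or `NULL` if `conv_counts` is given
#' @param labels binary condition labels per epoch
#' @param threshold DCM amplitude threshold (uS), default 0.1
#' @param conv_threshold conventional trough-to-peak threshold (uS),
#'   default 0.25
#' @param conv_counts optional precomputed conventional counts
#' @return an object of class `validity_report`
#' @export
validity_report <- function(results, epochs = NULL, labels,
                            threshold = 0.1, conv_threshold = 0.25,
                            conv_counts = NULL) {
  if (is.null(conv_counts)) {
    if (is.null(epochs)) stop("provide epochs or conv_counts")
    conv_counts <- vapply(epochs, count_sf_conventional, 0L,
                          threshold = conv_threshold)
  }
  state <- .as_binary(labels)
  dcm_counts <- vapply(results, count_bursts, 0L, threshold = threshold)
  ft <- nested_f_test(state, conv_counts, dcm_counts)
  structure(list(
    threshold = threshold,
    counts_dcm = dcm_counts,
    counts_conv = as.integer(conv_counts),
    r_methods = .safe_r(dcm_counts, conv_counts),
    r_validity_dcm = .safe_r(dcm_counts, state),
    r_validity_conv = .safe_r(conv_counts, state),
    roc_dcm = roc_curve(dcm_counts, state),
    roc_conv = roc_curve(conv_counts, state),
    f_stat = ft$F, f_df = c(ft$df1, ft$df2), p_value = ft$p
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> threshold %.3g uS over %d epochs\n",
              x$threshold, length(x$counts_dcm)))
  cat(sprintf("  method correspondence r = %.3f\n", x$r_methods))
  cat(sprintf("  validity: DCM r = %.3f (AUC %.3f), conventional r = %.3f (AUC %.3f)\n",
              x$r_validity_dcm, x$roc_dcm$auc,
              x$r_validity_conv, x$roc_conv$auc))
  cat(sprintf("  DCM beyond conventional: F(%d,%d) = %.2f, p = %.4g\n",
              x$f_df[1], x$f_df[2], x$f_stat, x$p_value))
  invisible(x)
}
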