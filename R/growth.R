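#' Construct a growth curve from raw vectors
#'
#' @param time_min Timepoints in minutes, strictly increasing.
#' @param od Optical density readings (same length).
#' @param strain,environment,run Labels.
#' @param blank OD baseline subtracted before log transforms (default 0).
#' @return An object of class `"growth_curve"`.
#' @export
growth_curve <- function(time_min, od, strain = "strain",
                         environment = "env", run = 1L, blank = 0) {
  time_min <- as.numeric(time_min); od <- as.numeric(od)
  if (length(time_min) != length(od))
    stop("growth_curve: time and OD lengths differ")
  if (any(diff(time_min) <= 0))
    stop("growth_curve: timepoints must be strictly increasing")
  structure(list(strain = strain, environment = environment, run = run,
                 time_min = time_min, od = od, blank = blank),
            class = "growth_curve")
}

#' Extract lag, doubling time and efficiency from a growth curve
#'
#' The blank-corrected OD series is floored at 0.001, log-transformed,
#' lightly smoothed with a running median (window `median_window`), and the
#' local slope of log(OD) estimated by least squares in a sliding window of
#' `slope_window` points.  The three mitotic fitness components are then
#' \describe{
#'   \item{doubling_h}{`ln(2) / max slope` — population doubling time.}
#'   \item{lag_h}{intersection of the maximum-slope tangent with the
#'     initial log-OD baseline — population adaptation time.}
#'   \item{efficiency}{`max OD - initial OD` — total change in population
#'     density.}
#' }
#' Curves with no positive slope are flagged as non-growers (components
#' `NA`, `grower = FALSE`) and should be excluded downstream.
#'
#' @param curve A `growth_curve` with >= 10 timepoints spanning >= 8 h.
#' @param median_window,slope_window Odd window sizes for the running
#'   median and the sliding slope fit (defaults 3 and 5, chosen for 20-min
#'   sampling).
#' @return An object of class `"growth_fit"`: components, their natural
#'   logs, and fitting detail for `plot()`.
#' @examples
#' gc <- simulate_growth_curve(growth_params(lag_h = 4, mu_max = 0.3465,
#'                                           noise_sd = 0, seed = 1))
#' coef(extract_fitness(gc))
#' @export
extract_fitness <- function(curve, median_window = 3L, slope_window = 5L) {
  stopifnot(inherits(curve, "growth_curve"))
  t_h <- curve$time_min / 60
  if (length(t_h) < 10L) stop("extract_fitness: need >= 10 timepoints")
  if (max(t_h) - min(t_h) < 8) stop("extract_fitness: need >= 8 h of data")
  od <- pmax(curve$od - curve$blank, 0.001)
  lod <- log(od)
  lod_s <- stats::runmed(lod, median_window, endrule = "keep")

  k <- slope_window
  npt <- length(t_h)
  nwin <- npt - k + 1L
  slopes <- numeric(nwin); mids_t <- numeric(nwin); mids_y <- numeric(nwin)
  mean_od <- numeric(nwin)
  for (i in seq_len(nwin)) {
    idx <- i:(i + k - 1L)
    tt <- t_h[idx]; yy <- lod_s[idx]
    slopes[i] <- stats::cov(tt, yy) / stats::var(tt)
    mids_t[i] <- mean(tt); mids_y[i] <- mean(yy)
    mean_od[i] <- mean(od[idx])
  }
  ## guard against noise-driven spurious slopes at baseline OD, where the
  ## log transform amplifies measurement noise: only windows whose OD has
  ## risen clearly above the starting level compete for the maximum slope
  nb <- min(5L, npt)
  baseline_od <- stats::median(od[seq_len(nb)])
  noise_od <- stats::sd(od[seq_len(nb)])
  qualified <- mean_od >= baseline_od + 3 * noise_od
  best <- if (any(qualified)) which(qualified)[which.max(slopes[qualified])]
          else NA_integer_
  mu <- if (is.na(best)) -Inf else slopes[best]
  if (is.finite(mu) && mu > 0) {
    ## a single short-window slope is noisy at low OD; refit one line over
    ## the exponential band -- the contiguous stretch around the best
    ## window where OD is clearly above baseline but below saturation
    od_s <- exp(lod_s)
    lo <- max(baseline_od + 3 * noise_od, 1.1 * baseline_od)
    hi <- 0.9 * max(od_s)
    in_band <- od_s >= lo & od_s <= hi
    mid_idx <- min(npt, best + (k - 1L) %/% 2L)
    if (in_band[mid_idx]) {
      i0 <- mid_idx; while (i0 > 1L && in_band[i0 - 1L]) i0 <- i0 - 1L
      i1 <- mid_idx; while (i1 < npt && in_band[i1 + 1L]) i1 <- i1 + 1L
      pts <- i0:i1
      if (length(pts) >= k) {
        fit <- stats::lm.fit(cbind(1, t_h[pts]), lod_s[pts])
        if (is.finite(fit$coefficients[2L]) && fit$coefficients[2L] > 0) {
          mu <- unname(fit$coefficients[2L])
          best <- max(1L, min(nwin, i0))
          mids_t[best] <- mean(t_h[pts])
          mids_y[best] <- unname(sum(fit$coefficients * c(1, mean(t_h[pts]))))
        }
      }
    }
  }
  baseline <- stats::median(lod_s[seq_len(min(3L, npt))])
  grower <- is.finite(mu) && mu > 1e-6
  if (grower) {
    doubling_h <- log(2) / mu
    lag_h <- max(0, mids_t[best] - (mids_y[best] - baseline) / mu)
    efficiency <- max(od) - exp(baseline)
  } else {
    doubling_h <- lag_h <- efficiency <- NA_real_
  }
  structure(list(strain = curve$strain, environment = curve$environment,
                 run = curve$run, grower = grower,
                 lag_h = lag_h, doubling_h = doubling_h,
                 efficiency = efficiency, mu_max = if (grower) mu else NA_real_,
                 ln_lag = if (grower && lag_h > 0) log(lag_h) else NA_real_,
                 ln_doubling = if (grower) log(doubling_h) else NA_real_,
                 ln_efficiency = if (grower && efficiency > 0)
                   log(efficiency) else NA_real_,
                 detail = list(t_h = t_h, lod = lod, lod_s = lod_s,
                               mids_t = mids_t, slopes = slopes,
                               best = best, baseline = baseline)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<growth_fit> %s / %s run %s\n", x$strain, x$environment, x$run))
  if (!x$grower) {
    cat("  non-grower (no positive slope)\n")
  } else {
    cat(sprintf("  lag %.*f h   doubling %.*f h   efficiency %.*f OD\n",
                digits, x$lag_h, digits, x$doubling_h, digits, x$efficiency))
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(lag_h = object$lag_h, doubling_h = object$doubling_h,
    efficiency = object$efficiency)
}

#' @export
plot.growth_fit <- function(x, ...) {
  d <- x$detail
  graphics::plot(d$t_h, d$lod, xlab = "time (h)", ylab = "log OD",
                 pch = 16, cex = 0.5, col = "grey40", ...)
  graphics::lines(d$t_h, d$lod_s, col = "steelblue")
  if (x$grower) {
    mu <- log(2) / x$doubling_h
    graphics::abline(a = d$baseline - mu * x$lag_h, b = mu,
                     col = "firebrick", lty = 2)
    graphics::abline(h = d$baseline, col = "grey60", lty = 3)
    graphics::abline(v = x$lag_h, col = "firebrick", lty = 3)
  }
  invisible(x)
}

#' Log-scale relative-fitness score (LSC)
#'
#' For strain i and trait j, summed over runs r:
#' `LSC_ij = sum_r [ mean_k(log wt_kjr) - log x_ijr ]^2`,
#' the squared deviation of the strain's log-scale measurement from the
#' mean of the reference (wild-type) replicates in the same run.  Zero iff
#' the strain matches the reference log-mean in every run; larger means
#' further from reference.
#'
#' @param x_logs Numeric vector: the strain's log measurement, one per run.
#' @param wt_logs List of numeric vectors: reference log measurements per
#'   run (same number of runs; typically 10 replicates per run).
#' @return An object of class `"lsc_score"`: list with `value`, `n_runs`,
#'   `n_wt` (reference replicates per run), `per_run` deviations.
#' @examples
#' lsc_score(c(1.5, 1.5), list(rep(1, 10), rep(1, 10)))$value  # 0.5
#' @export
lsc_score <- function(x_logs, wt_logs) {
  if (is.numeric(wt_logs)) wt_logs <- list(wt_logs)
  n_runs <- length(x_logs)
  if (n_runs < 1L) stop("lsc_score: need at least one run")
  if (length(wt_logs) != n_runs)
    stop("lsc_score: reference runs (", length(wt_logs),
         ") do not match strain runs (", n_runs, ")")
  if (any(!is.finite(x_logs)) || any(!vapply(wt_logs, function(v)
    all(is.finite(v)) && length(v) >= 1L, logical(1))))
    stop("lsc_score: non-finite or empty log measurements")
  dev <- vapply(seq_len(n_runs),
                function(r) mean(wt_logs[[r]]) - x_logs[r], numeric(1))
  structure(list(value = sum(dev^2), n_runs = n_runs,
                 n_wt = vapply(wt_logs, length, integer(1)),
                 per_run = dev),
            class = "lsc_score")
}

#' @export
print.lsc_score <- function(x, ...) {
  cat(sprintf("<lsc_score> %.4f over %d run(s)\n", x$value, x$n_runs))
  invisible(x)
}

#' Fitness components for a table of growth curves
#'
#' Runs `extract_fitness()` per (strain, environment, run) series of a long
#' curve table.  The efficiency component can be inverted (reciprocal
#' before log) so that larger always means worse than reference, keeping
#' directionality consistent across components when feeding `lsc_score()`.
#'
#' @param curves Data frame with columns `strain, environment, run,
#'   time_min, od` (long format).
#' @param blank OD baseline.
#' @param invert_efficiency Invert efficiency before the log columns?
#'   Default `TRUE`.
#' @param ... Passed to `extract_fitness()`.
#' @return Data frame, one row per strain x environment x run, with the
#'   three components, their log transforms, and a `grower` flag.
#' @export
fitness_components <- function(curves, blank = 0, invert_efficiency = TRUE,
                               ...) {
  need <- c("strain", "environment", "run", "time_min", "od")
  if (!all(need %in% names(curves)))
    stop("fitness_components: curves must have columns ",
         paste(need, collapse = ", "))
  key <- interaction(curves$strain, curves$environment, curves$run,
                     drop = TRUE)
  rows <- lapply(split(curves, key), function(d) {
    d <- d[order(d$time_min), ]
    fit <- tryCatch(
      extract_fitness(growth_curve(d$time_min, d$od, d$strain[1L],
                                   d$environment[1L], d$run[1L],
                                   blank = blank), ...),
      error = function(e) NULL)
    if (is.null(fit))
      return(NULL)
    eff_for_log <- if (isTRUE(invert_efficiency) && isTRUE(fit$grower) &&
                       !is.na(fit$efficiency) && fit$efficiency > 0)
      1 / fit$efficiency else fit$efficiency
    data.frame(strain = d$strain[1L], environment = d$environment[1L],
               run = d$run[1L], grower = fit$grower,
               lag_h = fit$lag_h, doubling_h = fit$doubling_h,
               efficiency = fit$efficiency,
               ln_lag = fit$ln_lag, ln_doubling = fit$ln_doubling,
               ln_efficiency = if (isTRUE(fit$grower) &&
                                   !is.na(eff_for_log) && eff_for_log > 0)
                 log(eff_for_log) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
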