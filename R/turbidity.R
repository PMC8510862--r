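## Turbidity-curve preprocessing and regime analysis.
##
## A turbidimetric clot-lysis assay starts at high signal, descends to a
## minimum as the clot forms (CFT), rises slowly and linearly while plasmin
## nibbles the fiber surface (slow lysis), then accelerates into a sigmoidal
## rise as lysis reaches the fiber volume (fast lysis).  All detectors below
## operate on the min-max normalized turbidity (NT) in [0, 1].

#' Construct a turbidity trace
#'
#' @param time Numeric vector of sampling times in minutes, strictly
#'   increasing (typically a uniform 1-minute grid).
#' @param intensity Numeric vector of raw sensor intensities (arbitrary
#'   units), finite, same length as `time`.
#' @param channel_id Optional channel label.
#' @return An object of class `turbidity_trace`.
#' @export
turbidity_trace <- function(time, intensity, channel_id = "ch1") {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity))
    stop("time and intensity must have the same length")
  if (length(time) < 20)
    stop("a turbidity trace needs at least 20 samples")
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop("intensity must be finite")
  structure(list(time = time, intensity = intensity,
                 channel_id = as.character(channel_id)),
            class = "turbidity_trace")
}

#' @export
print.turbidity_trace <- function(x, ...) {
  cat(sprintf("<turbidity_trace> channel %s: %d samples, t = [%g, %g] min\n",
              x$channel_id, length(x$time), x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' Decimate a trace, keeping one sample out of `keep_every`
#'
#' Retains samples at indices 1, 1+keep_every, 1+2*keep_every, ... to discard
#' sample-to-sample sensor fluctuation before smoothing.
#'
#' @param trace A [turbidity_trace()].
#' @param keep_every Positive integer decimation factor (default 3).
#' @return A decimated `turbidity_trace`.
#' @export
slice_trace <- function(trace, keep_every = 3L) {
  stopifnot(inherits(trace, "turbidity_trace"))
  keep_every <- as.integer(keep_every)
  if (is.na(keep_every) || keep_every < 1L)
    stop("keep_every must be a positive integer")
  idx <- seq(1L, length(trace$time), by = keep_every)
  if (length(idx) < 2L)
    stop("fewer than 2 samples survive slicing")
  out <- trace
  out$time <- trace$time[idx]
  out$intensity <- trace$intensity[idx]
  out
}

#' Savitzky-Golay smoothing of a trace
#'
#' Third-order Savitzky-Golay filter with a window of five points on each
#' side of the point of interest (window length 11).  The signal is
#' mirror-padded by five samples at each end before filtering so that the
#' clotting minimum near the boundary of the fitted window is not shrunk by
#' edge effects.
#'
#' @param trace A [turbidity_trace()] with at least 11 samples.
#' @return A smoothed `turbidity_trace` on the same time grid.
#' @export
smooth_trace <- function(trace) {
  stopifnot(inherits(trace, "turbidity_trace"))
  n <- length(trace$intensity)
  if (n < 11L) stop("trace too short for an 11-point Savitzky-Golay window")
  half <- 5L
  x <- trace$intensity
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  sm <- signal::sgolayfilt(padded, p = 3, n = 2L * half + 1L)
  out <- trace
  out$intensity <- sm[(half + 1L):(half + n)]
  out
}

#' Min-max normalization to normalized turbidity (NT)
#'
#' @param trace A [turbidity_trace()].
#' @return An object of class `normalized_trace` with fields `time`, `nt`
#'   (in \[0, 1\]), `channel_id` and `delta_turbidity` (max minus min of the
#'   input intensity, in sensor units).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "turbidity_trace"))
  lo <- min(trace$intensity)
  hi <- max(trace$intensity)
  if (hi <= lo) stop("degenerate trace: constant intensity cannot be normalized")
  structure(list(time = trace$time,
                 nt = (trace$intensity - lo) / (hi - lo),
                 channel_id = trace$channel_id,
                 delta_turbidity = hi - lo),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("<normalized_trace> channel %s: %d samples, delta turbidity %.4g\n",
              x$channel_id, length(x$time), x$delta_turbidity))
  invisible(x)
}

#' Clot formation time
#'
#' The CFT is the time needed to reach the minimum of turbidity, measured
#' from the start of the trace.  Ties are broken to the earliest time.  If
#' the minimum sits at the final sample the clot never started lysing and a
#' `no_lysis` warning condition is signalled.
#'
#' @param nt A [normalize_trace()] result.
#' @return CFT in minutes.
#' @export
detect_cft <- function(nt) {
  stopifnot(inherits(nt, "normalized_trace"))
  i <- which.min(nt$nt)
  if (i == length(nt$nt))
    warning("turbidity minimum at the final sample: no lysis observed",
            call. = FALSE)
  nt$time[i] - nt$time[1]
}

#' Linear fit of the slow-lysis regime
#'
#' Fits a least-squares line to the NT curve on the window bounded by the
#' first post-CFT crossings of NT = `low` and NT = `high` (defaults 0.01 and
#' 0.075).  The slow-lysis regime is linear in time, so its slope (NT/min)
#' characterizes it; its inverse is proportional to the slow-lysis duration.
#'
#' @param nt A [normalize_trace()] result.
#' @param low,high NT levels bounding the fit window.
#' @return A list with `slope`, `intercept`, `window` (time bounds, minutes
#'   from trace start) and `n_points`.
#' @export
fit_slow_regime <- function(nt, low = 0.01, high = 0.075) {
  stopifnot(inherits(nt, "normalized_trace"))
  cft_abs <- detect_cft(nt) + nt$time[1]
  post <- which(nt$time > cft_abs)
  i_lo <- post[which(nt$nt[post] >= low)[1]]
  i_hi <- post[which(nt$nt[post] >= high)[1]]
  if (is.na(i_lo) || is.na(i_hi))
    stop("no lysis: NT never crosses the fit window after the CFT")
  keep <- which(nt$time >= nt$time[i_lo] & nt$time <= nt$time[i_hi])
  if (length(keep) < 3L)
    stop("insufficient window: fewer than 3 samples between the NT crossings")
  fit <- stats::lm(y ~ t, data = data.frame(t = nt$time[keep], y = nt$nt[keep]))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       window = c(nt$time[i_lo], nt$time[i_hi]),
       n_points = length(keep))
}

#' Total lysis time
#'
#' TLT is the interval from the CFT to the point of fastest lysis: the time
#' at which the central-difference derivative of the (already smoothed) NT
#' curve, restricted to times after the CFT, is maximal.  Ties are broken to
#' the earliest time.
#'
#' @param nt A [normalize_trace()] result.
#' @return TLT in minutes (offset from the CFT).
#' @export
detect_tlt <- function(nt) {
  stopifnot(inherits(nt, "normalized_trace"))
  cft_abs <- detect_cft(nt) + nt$time[1]
  n <- length(nt$time)
  deriv <- rep(NA_real_, n)
  deriv[2:(n - 1)] <- (nt$nt[3:n] - nt$nt[1:(n - 2)]) /
    (nt$time[3:n] - nt$time[1:(n - 2)])
  cand <- which(nt$time > cft_abs & !is.na(deriv))
  if (length(cand) < 3L)
    stop("post-CFT segment too short to estimate a lysis derivative")
  i <- cand[which.max(deriv[cand])]
  if (i >= n - 1L)
    warning("lysis derivative still rising at the end of the trace: truncated lysis",
            call. = FALSE)
  nt$time[i] - cft_abs
}

#' Slow-lysis regime end by backward scan
#'
#' Starting from the TLT point and scanning backward in time, the end of the
#' slow-lysis regime (SLT, measured from the CFT) is the first point whose
#' deviation from the slow-regime line is at most `delta` -- i.e. the last
#' point still on the line.  Points close to the TLT deviate strongly, so
#' the first within-`delta` point met on the backward scan marks the regime
#' boundary.
#'
#' @param nt A [normalize_trace()] result.
#' @param fit A [fit_slow_regime()] result.
#' @param delta Deviation threshold in NT units (default 0.005).
#' @return SLT in minutes (offset from the CFT).
#' @export
detect_slow_regime_end <- function(nt, fit, delta = 0.005) {
  stopifnot(inherits(nt, "normalized_trace"))
  cft_abs <- detect_cft(nt) + nt$time[1]
  tlt_abs <- detect_tlt(nt) + cft_abs
  idx <- which(nt$time > cft_abs & nt$time <= tlt_abs)
  if (length(idx) == 0L) stop("no samples between CFT and TLT")
  pred <- fit$intercept + fit$slope * nt$time[idx]
  dev <- abs(nt$nt[idx] - pred)
  on_line <- rev(idx)[which(rev(dev) <= delta)[1]]
  if (is.na(on_line))
    stop("regime detection failed: no point within delta of the slow-regime line")
  nt$time[on_line] - cft_abs
}

#' Full timescale decomposition of a normalized trace
#'
#' Runs every detector and assembles the timescales of the assay: CFT (from
#' trace start), SLT and FLT (offsets from the CFT, with TLT = SLT + FLT),
#' end of lysis (first time after the TLT with NT >= 0.95, from trace
#' start), the slow-regime slope, and the regime ratios
#' R_SL = SLT/TLT and R_FL = 1 - R_SL.
#'
#' @param nt A [normalize_trace()] result.
#' @param delta Backward-scan threshold passed to [detect_slow_regime_end()].
#' @param fit_low,fit_high NT window passed to [fit_slow_regime()].
#' @return An object of class `lysis_timescales` (a named list).
#' @export
compute_timescales <- function(nt, delta = 0.005, fit_low = 0.01,
                               fit_high = 0.075) {
  stopifnot(inherits(nt, "normalized_trace"))
  cft <- detect_cft(nt)
  tlt <- detect_tlt(nt)
  fit <- fit_slow_regime(nt, low = fit_low, high = fit_high)
  slt <- detect_slow_regime_end(nt, fit, delta = delta)
  if (slt > tlt) stop("inconsistent regimes: SLT exceeds TLT")
  flt <- tlt - slt
  cft_abs <- cft + nt$time[1]
  after_tlt <- which(nt$time > cft_abs + tlt & nt$nt >= 0.95)
  end_of_lysis <- if (length(after_tlt)) nt$time[after_tlt[1]] - nt$time[1] else NA_real_
  structure(list(
    cft = cft, slt = slt, flt = flt, tlt = tlt,
    end_of_lysis = end_of_lysis,
    slow_slope = fit$slope,
    r_sl = slt / tlt, r_fl = flt / tlt,
    delta_turbidity = nt$delta_turbidity,
    fit_window = fit$window,
    channel_id = nt$channel_id
  ), class = "lysis_timescales")
}

#' @export
print.lysis_timescales <- function(x, ...) {
  cat(sprintf(
    paste0("<lysis_timescales> channel %s\n",
           "  CFT %.1f min | SLT %.1f | FLT %.1f | TLT %.1f | end of lysis %s\n",
           "  slow slope %.4g NT/min | R_SL %.3f | R_FL %.3f | delta turbidity %.4g\n"),
    x$channel_id, x$cft, x$slt, x$flt, x$tlt,
    if (is.na(x$end_of_lysis)) "NA" else sprintf("%.1f min", x$end_of_lysis),
    x$slow_slope, x$r_sl, x$r_fl, x$delta_turbidity))
  invisible(x)
}

#' Analyze one raw trace end to end
#'
#' Convenience wrapper: slice, smooth, normalize, then extract timescales.
#'
#' @param trace A [turbidity_trace()].
#' @param keep_every Decimation factor (default 3; use 1 to keep every
#'   sample).
#' @param delta,fit_low,fit_high Detector settings, see
#'   [compute_timescales()].
#' @return A `lysis_timescales` object.
#' @export
analyze_trace <- function(trace, keep_every = 3L, delta = 0.005,
                          fit_low = 0.01, fit_high = 0.075) {
  nt <- normalize_trace(smooth_trace(slice_trace(trace, keep_every)))
  compute_timescales(nt, delta = delta, fit_low = fit_low, fit_high = fit_high)
}

#' Read turbidity traces from a long-format CSV
#'
#' Expected columns: `time_min`, `channel`, `intensity` (header required).
#'
#' @param path CSV file path.
#' @return Named list of [turbidity_trace()] objects, one per channel.
#' @export
read_turbidity_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "channel", "intensity")
  if (!all(need %in% names(df)))
    stop("CSV must have columns time_min, channel, intensity")
  out <- lapply(split(df, df$channel), function(d) {
    d <- d[order(d$time_min), ]
    turbidity_trace(d$time_min, d$intensity, channel_id = d$channel[1])
  })
  out[order(names(out))]
}

#' Analyze every channel of a long-format turbidity CSV
#'
#' @param traces Either a path to a CSV (see [read_turbidity_csv()]) or a
#'   list of [turbidity_trace()] objects.
#' @param ... Passed to [analyze_trace()].
#' @return A data.frame with one row per channel (cft, slt, flt, tlt,
#'   end_of_lysis, slow_slope, r_sl, r_fl, delta_turbidity).
#' @export
analyze_channels <- function(traces, ...) {
  if (is.character(traces)) traces <- read_turbidity_csv(traces)
  rows <- lapply(traces, function(tr) {
    ts <- analyze_trace(tr, ...)
    data.frame(channel = ts$channel_id, cft = ts$cft, slt = ts$slt,
               flt = ts$flt, tlt = ts$tlt, end_of_lysis = ts$end_of_lysis,
               slow_slope = ts$slow_slope, r_sl = ts$r_sl, r_fl = ts$r_fl,
               delta_turbidity = ts$delta_turbidity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
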