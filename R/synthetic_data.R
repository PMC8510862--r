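## Synthetic turbidity assays with the statistical structure the analysis
## assumes: an eight-channel reader sampling once per minute, a sigmoidal
## clotting descent to the turbidity minimum, a linear slow-lysis ramp
## ending near NT = 0.1, and a sigmoidal fast-lysis rise, plus additive
## Gaussian sensor noise.

#' Experimental condition (protein concentrations)
#'
#' @param fibrinogen mg/mL.
#' @param tpa,pai1,pg ug/mL.
#' @param n_replicates Number of replicate channels.
#' @param label Condition label.
#' @return An object of class `experiment_condition`.
#' @export
experiment_condition <- function(fibrinogen = 3, tpa = 0.001, pai1 = 0.01,
                                 pg = 13, n_replicates = 1L, label = "control") {
  stopifnot(fibrinogen >= 0, tpa >= 0, pai1 >= 0, pg >= 0, n_replicates >= 1)
  structure(list(fibrinogen = fibrinogen, tpa = tpa, pai1 = pai1, pg = pg,
                 n_replicates = as.integer(n_replicates),
                 label = as.character(label)),
            class = "experiment_condition")
}

#' The packaged experimental-condition table
#'
#' The 19 assay conditions of the turbidimetric study: titrations of tPA,
#' PAI-1, plasminogen and fibrinogen around the control case
#' (fibrinogen 3 mg/mL, tPA 0.001, PAI-1 0.01, Pg 13 ug/mL), with their
#' replicate counts (74 usable experiments in total; the control case has
#' 18 replicates).
#'
#' @return Data.frame with columns `label`, `fibrinogen_mg_ml`,
#'   `tpa_ug_ml`, `pai1_ug_ml`, `pg_ug_ml`, `n_replicates`.
#' @export
table1_conditions <- function() {
  df <- data.frame(
    label = as.character(1:19),
    fibrinogen_mg_ml = c(rep(3, 13), 0.8, 1, 2, 4, 5, 6),
    tpa_ug_ml = c(0.0005, 0.001, 0.002, 0.004, 0.008, rep(0.001, 14)),
    pai1_ug_ml = c(rep(0.01, 5), 0.0025, 0.005, 0.02, 0.04, rep(0.01, 10)),
    pg_ug_ml = c(rep(13, 9), 2.6, 5.2, 26, 52, rep(13, 6)),
    n_replicates = c(4L, 18L, 4L, 4L, 4L, 4L, 4L, 4L, 2L, 3L, 4L, 4L, 4L,
                     2L, 2L, 2L, 2L, 1L, 2L)
  )
  df$label[2] <- "2 (control)"
  df
}

#' Synthetic assay configuration
#'
#' Defaults reproduce the average timescales of the turbidimetric assays:
#' clot formation at 19 min, a slow-lysis ramp of 73 min ending at
#' NT = 0.1 (slope 0.1/73 NT/min), a fast regime placing the maximal lysis
#' rate 67 min later, and 0.5% sensor noise.
#'
#' @param baseline Intensity at the start (sensor units).
#' @param delta_turbidity Max-min intensity span (sensor units).
#' @param cft Clot formation time, min.
#' @param slow_slope Slow-regime slope, NT/min.
#' @param slt Duration of the linear slow-lysis ramp, min.
#' @param flt Interval from ramp end to the maximal lysis rate, min.
#' @param fast_rate Logistic steepness of the fast regime, 1/min, or
#'   `NULL` (default) to choose the steepness at which the fast segment
#'   joins the slow ramp with matching slope: the curve then leaves the
#'   ramp line smoothly from above and its departure point (the
#'   ground-truth SLT) is unambiguous.
#' @param noise_sd Noise standard deviation as a fraction of
#'   `delta_turbidity`.
#' @param sampling Sampling interval, min.
#' @param duration Total duration, min (default: automatic, long enough to
#'   cross NT = 0.95).
#' @param channels Number of channels (max 8).
#' @param seed Integer seed.
#' @return An object of class `synthetic_assay_config`.
#' @export
synthetic_assay_config <- function(baseline = 1000, delta_turbidity = 700,
                                   cft = 19, slow_slope = 0.1 / 73,
                                   slt = 73, flt = 67, fast_rate = NULL,
                                   noise_sd = 0.005, sampling = 1,
                                   duration = NULL, channels = 1L,
                                   seed = 1L) {
  stopifnot(cft > 0, slt > 0, flt > 0, slow_slope > 0,
            noise_sd >= 0, channels >= 1, channels <= 8)
  y1 <- slow_slope * slt
  if (y1 >= 0.6) stop("inconsistent config: slow ramp ends above NT = 0.6")
  if (is.null(fast_rate)) {
    ## entry slope of the affine-normalized logistic at the ramp end is
    ## (1 - y1) * r * plogis(-r * flt); pick the larger r at which it
    ## equals the ramp slope (C1 joint, monotone departure)
    entry <- function(r) (1 - y1) * r * stats::plogis(-r * flt) - slow_slope
    r_peak <- 1.2785 / flt
    if (entry(r_peak) <= 0)
      stop("inconsistent config: no logistic steepness joins the ramp ",
           "smoothly; shorten flt or lower slow_slope")
    fast_rate <- stats::uniroot(entry, c(r_peak, 50 / flt), tol = 1e-10)$root
  }
  stopifnot(fast_rate > 0)
  cfg <- list(baseline = baseline, delta_turbidity = delta_turbidity,
              cft = cft, slow_slope = slow_slope, slt = slt, flt = flt,
              fast_rate = fast_rate, noise_sd = noise_sd,
              sampling = sampling, channels = as.integer(channels),
              seed = as.integer(seed))
  ## fast regime: affine-normalized logistic from the ramp end to 1, with
  ## the maximal derivative at cft + slt + flt
  t_infl <- cft + slt + flt
  s0 <- stats::plogis(-fast_rate * flt)
  s95 <- (0.95 - y1) / (1 - y1) * (1 - s0) + s0
  t95 <- t_infl + stats::qlogis(s95) / fast_rate
  cfg$duration <- if (is.null(duration)) ceiling(t95 + 10) else duration
  if (cfg$duration <= t_infl)
    stop("inconsistent config: duration shorter than cft + slt + flt")
  structure(cfg, class = "synthetic_assay_config")
}

## Continuous noise-free NT curve of a phenomenological assay.
pheno_nt <- function(t, cfg) {
  y1 <- cfg$slow_slope * cfg$slt
  t_ramp_end <- cfg$cft + cfg$slt
  t_infl <- t_ramp_end + cfg$flt
  s0 <- stats::plogis(cfg$fast_rate * (t_ramp_end - t_infl))
  nt <- numeric(length(t))
  ## smooth cosine descent: gentle curvature at the minimum keeps the
  ## Savitzky-Golay-smoothed minimum within one sample of the true CFT
  i1 <- t <= cfg$cft
  nt[i1] <- 0.5 * (1 + cos(pi * t[i1] / cfg$cft))
  i2 <- t > cfg$cft & t <= t_ramp_end
  nt[i2] <- cfg$slow_slope * (t[i2] - cfg$cft)
  i3 <- t > t_ramp_end
  s <- stats::plogis(cfg$fast_rate * (t[i3] - t_infl))
  nt[i3] <- y1 + (1 - y1) * (s - s0) / (1 - s0)
  nt
}

#' Generate a phenomenological synthetic assay
#'
#' Builds the piecewise noise-free curve (cosine clotting descent, linear
#' slow ramp, affine-normalized logistic fast rise), samples it on the
#' 1-minute grid for each channel with independent additive Gaussian
#' noise, and returns the ground-truth timescales.  The ground-truth SLT
#' is the point where the continuous curve departs from the slow-regime
#' line by the detection threshold delta (the same operational definition
#' the analysis uses); the end of the linear ramp is also reported as
#' `ramp_end`.
#'
#' @param cfg A [synthetic_assay_config()].
#' @param delta Departure threshold defining the ground-truth SLT.
#' @return List with `traces` (list of [turbidity_trace()]), `truth`
#'   (list: cft, slt, flt, tlt, ramp_end, end_of_lysis, slow_slope,
#'   delta_turbidity), and `config`.
#' @export
generate_phenomenological <- function(cfg = synthetic_assay_config(),
                                      delta = 0.005) {
  stopifnot(inherits(cfg, "synthetic_assay_config"))
  tt <- seq(0, cfg$duration, by = cfg$sampling)
  nt <- pheno_nt(tt, cfg)

  ## ground truth: TLT at the fast-logistic inflection; SLT where the
  ## continuous curve leaves the slow line by delta (backward-scan definition)
  t_ramp_end <- cfg$cft + cfg$slt
  t_infl <- t_ramp_end + cfg$flt
  dev <- function(t) {
    abs(pheno_nt(t, cfg) - cfg$slow_slope * (t - cfg$cft)) - delta
  }
  t_slt <- if (dev(t_infl) <= 0) t_infl else
    stats::uniroot(dev, c(t_ramp_end, t_infl), tol = 1e-8)$root
  fine <- seq(t_infl, cfg$duration, by = cfg$sampling / 100)
  t95 <- fine[which(pheno_nt(fine, cfg) >= 0.95)[1]]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  lo <- cfg$baseline - cfg$delta_turbidity
  traces <- lapply(seq_len(cfg$channels), function(ch) {
    noise <- stats::rnorm(length(tt), 0, cfg$noise_sd * cfg$delta_turbidity)
    turbidity_trace(tt, lo + cfg$delta_turbidity * nt + noise,
                    channel_id = sprintf("ch%d", ch))
  })
  list(traces = traces,
       truth = list(cft = cfg$cft,
                    slt = t_slt - cfg$cft,
                    flt = t_infl - t_slt,
                    tlt = t_infl - cfg$cft,
                    ramp_end = cfg$slt,
                    end_of_lysis = t95,
                    slow_slope = cfg$slow_slope,
                    delta_turbidity = cfg$delta_turbidity),
       config = cfg)
}

#' Generate a mechanistic synthetic assay
#'
#' Forward-composes clot formation and fibrinolysis: the clot-formation
#' model provides the initial conditions, lysis runs under the requested
#' shell schedule, and the lysed-fibrin fraction (a proxy for NT) is
#' mapped affinely to intensity, prefixed with a cosine clotting descent,
#' noised and downsampled to the 1-minute grid.
#'
#' @param condition An [experiment_condition()] (or list of lab
#'   concentrations).
#' @param schedule `"surface_bulk"` (surface shells while rf/rf0 > 0.9,
#'   full volume after), `"surface"`, or `"bulk"`.
#' @param noise_sd Noise s.d. as a fraction of the intensity span.
#' @param seed Integer seed.
#' @param baseline,delta_turbidity Intensity mapping (sensor units).
#' @param t_max Maximal simulated lysis time, s.
#' @param dt Integration step, s.
#' @param ... Passed to [run_clot_formation()].
#' @return List with `trace` (a [turbidity_trace()]), `truth` (cft and the
#'   rf-threshold crossing times slt/flt, minutes), `trajectory`, and
#'   `clot_state`.
#' @export
generate_mechanistic <- function(condition = experiment_condition(),
                                 schedule = c("surface_bulk", "surface",
                                              "bulk"),
                                 noise_sd = 0.005, seed = 1L,
                                 baseline = 1000, delta_turbidity = 700,
                                 t_max = 36000, dt = 0.1, ...) {
  schedule <- match.arg(schedule)
  cs <- run_clot_formation(list(fibrinogen = condition$fibrinogen,
                                tpa = condition$tpa, pai1 = condition$pai1,
                                pg = condition$pg), ...)
  constants <- clot_constants(cs)
  policy <- switch(schedule,
    surface = shell_policy("surface"),
    bulk = shell_policy("bulk"),
    surface_bulk = shell_policy("schedule", fun = function(t, rf, kmax) {
      if (rf > 0.9 * constants$rf0) 0L else kmax
    }))
  traj <- run_fibrinolysis(cs, policy, dt = dt, t_max = t_max,
                           record_every = round(60 / dt),
                           constants = constants)
  ts <- trajectory_timescales(traj)

  cft_min <- cs$t_clot / 60
  t_lysis_min <- traj$t / 60 + cft_min
  tt <- seq(0, max(t_lysis_min), by = 1)
  nt <- numeric(length(tt))
  clotting <- tt <= cft_min
  nt[clotting] <- 0.5 * (1 + cos(pi * tt[clotting] / cft_min))
  nt[!clotting] <- stats::approx(t_lysis_min, traj$percent,
                                 xout = tt[!clotting], rule = 2)$y
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  intensity <- (baseline - delta_turbidity) + delta_turbidity * nt +
    stats::rnorm(length(tt), 0, noise_sd * delta_turbidity)
  list(trace = turbidity_trace(tt, intensity, channel_id = condition$label),
       truth = list(cft = cft_min,
                    slt = ts$slt / 60, flt = ts$flt / 60,
                    t95 = ts$t95 / 60),
       trajectory = traj, clot_state = cs)
}
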