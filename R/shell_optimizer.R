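## Greedy per-step fit of the number of reacting shells against a target
## lysis curve, and shell-fraction aggregation over normalized regime time.
##
## At each 0.1 s step the lysis equations are advanced in trial for every
## admissible shell count kappa in {0, ..., kappa_max}; the kappa whose
## one-step-ahead lysed fraction is closest (squared error) to the target
## is committed.  The procedure is deliberately sequential: the slow/fast
## regime structure emerges from the fitted kappa(t), it is not imposed.

#' Resample a target curve onto the simulation grid
#'
#' Linear interpolation of (time, value) samples onto a uniform grid of
#' step `dt`, starting at time 0.
#'
#' @param time Sample times in seconds (must start at or before 0 and be
#'   increasing).
#' @param value Target values (lysed fraction / NT, in \[0, 1\]).
#' @param dt Grid step in seconds (default 0.1).
#' @return List with `time` and `value` on the dense grid.
#' @export
resample_target <- function(time, value, dt = 0.1) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (time[1] > 0) stop("target must cover the start of the lysis window")
  grid <- seq(0, max(time), by = dt)
  list(time = grid,
       value = stats::approx(time, value, xout = grid, rule = 1)$y)
}

#' Turn a normalized turbidity curve into a lysis target
#'
#' Takes the post-CFT portion of a [normalize_trace()] result (NT is used
#' as a proxy for the lysed-fibrin fraction), shifts time so lysis starts
#' at 0, converts minutes to seconds, and resamples to the simulation grid.
#'
#' @param nt A [normalize_trace()] result.
#' @param dt Grid step in seconds.
#' @return List with `time` (s) and `value` (lysed fraction target).
#' @export
nt_to_lysis_target <- function(nt, dt = 0.1) {
  cft_abs <- detect_cft(nt) + nt$time[1]
  keep <- nt$time >= cft_abs
  tt <- (nt$time[keep] - cft_abs) * 60
  vv <- pmin(pmax(nt$nt[keep], 0), 1)
  resample_target(tt, vv, dt)
}

## Trial one-step lysed fractions for all kappa candidates 0..kmax.
## Only the plasmin substrate Theta depends on kappa at fixed state, so the
## candidate sweep is a vectorized evaluation of the lysis rate.
candidate_percents <- function(l, pn_b, rf, eps, kmax, dt, constants, rates) {
  geom <- constants$geometry
  kappa <- 0:kmax
  m <- shell_protofibril_count(rf, kappa, geom$r0, geom$p0)
  th_pn <- constants$nu * constants$fr / N_AVOGADRO * 1e6 / (1 - eps) *
    m * constants$q_pn
  dl <- (1 - eps) * constants$gamma * rates$k_pn2 * pn_b * th_pn /
    (rates$K_pn_M + th_pn)
  (l + dt * dl) / constants$cfr0
}

#' Optimal shell count for one step
#'
#' Among kappa in {0, ..., kappa_max}, returns the one whose trial one-step
#' lysed fraction minimizes the squared error against `target_next`.  Ties
#' break to the smallest kappa (the most conservative reaction depth).
#'
#' @param state Named lysis state vector (see [lysis_rhs()]).
#' @param target_next Target lysed fraction at t + dt.
#' @param dt Step, s.
#' @param constants A [clot_constants()] object.
#' @param rates A [binding_rates()] object.
#' @return Integer shell count.
#' @export
optimal_kappa_step <- function(state, target_next, dt = 0.1, constants,
                               rates = binding_rates()) {
  rf <- update_radius(state[["l"]], constants)
  if (rf <= 0) stop("terminal state: no fiber left")
  eps <- porosity(rf, constants)
  kmax <- ceiling(rf / constants$geometry$r0)
  pc <- candidate_percents(state[["l"]], state[["pn_b"]], rf, eps, kmax, dt,
                           constants, rates)
  which.min((pc - target_next)^2) - 1L
}

#' Fit a time-varying shell schedule to a target lysis curve
#'
#' Greedy one-step-lookahead optimization: at every step the shell count
#' minimizing the next-step squared error between simulated lysed fraction
#' and the target is selected and committed, until the target is exhausted,
#' fibrin runs out, or `t_max` is reached.
#'
#' @param clot_state A [run_clot_formation()] result.
#' @param target A dense target from [resample_target()] /
#'   [nt_to_lysis_target()], or a (time, value) data.frame/list to be
#'   resampled.
#' @param dt Step, s (must match the target grid).
#' @param t_max Optional cap on simulated time, s.
#' @param constants,rates Optional overrides.
#' @return An object of class `shell_schedule`: a data.frame with columns
#'   `t`, `kappa_opt`, `kappa_max`, `phi`, `sqerr`, `percent`, `target`,
#'   plus attributes `mse` (time-averaged squared error), `constants` and
#'   `trajectory_tail` (final state).
#' @export
fit_shell_schedule <- function(clot_state, target, dt = 0.1, t_max = Inf,
                               constants = NULL, rates = NULL) {
  if (is.null(constants)) constants <- clot_constants(clot_state)
  if (is.null(rates)) rates <- clot_state$bind_rates
  if (is.null(rates)) rates <- binding_rates()
  if (is.data.frame(target) || (is.list(target) && is.null(target$value)))
    target <- resample_target(target[[1]], target[[2]], dt)
  tgt <- target$value
  if (abs(target$time[2] - target$time[1] - dt) > 1e-9)
    stop("target grid step does not match dt")

  geom <- constants$geometry
  gamma <- constants$gamma; cfr0 <- constants$cfr0
  rf0 <- constants$rf0; eps0 <- constants$eps0
  r0 <- geom$r0; p0 <- geom$p0
  theta_base <- constants$nu * constants$fr / N_AVOGADRO * 1e6
  q_tpa <- geom$q_tpa; q_pg <- geom$q_pg; q_pn <- constants$q_pn
  kf_tpa <- rates$kf_tpa; kr_tpa <- rates$kr_tpa
  kf_pg <- rates$kf_pg; kr_pg <- rates$kr_pg
  k2 <- rates$k_tpa_pg2; K2 <- rates$K_tpa_pg_M
  k_pn2 <- rates$k_pn2; K_pn <- rates$K_pn_M
  kr_pn <- rates$kr_pn; ki <- rates$ki_tpa_pai

  y <- initial_lysis_state(clot_state, constants)
  l <- y[["l"]]; tpa <- y[["tpa"]]; tpa_b <- y[["tpa_b"]]
  pg <- y[["pg"]]; pg_b <- y[["pg_b"]]; pn <- y[["pn"]]
  pn_b <- y[["pn_b"]]; pai1 <- y[["pai1"]]

  n_steps <- min(length(tgt) - 1L, floor(t_max / dt))
  out_k <- integer(n_steps); out_kmax <- integer(n_steps)
  out_err <- numeric(n_steps); out_pc <- numeric(n_steps)
  n_done <- 0L
  for (step in seq_len(n_steps)) {
    frac <- 1 - l / cfr0
    if (frac < 1e-6) break
    rf <- rf0 * sqrt(frac)
    eps <- 1 - (1 - eps0) * frac
    kmax <- ceiling(rf / r0)

    ## candidate sweep (vectorized over kappa)
    kappa_all <- 0:kmax
    m_all <- pi * p0 * (2 * r0 * rf * (1 + kappa_all) +
                          r0 * r0 * (1 - kappa_all^2))
    mtot <- pi * p0 * (rf + r0)^2
    m_all[m_all > mtot] <- mtot
    th_scale <- theta_base / (1 - eps)
    th_pn_all <- th_scale * m_all * q_pn
    dl_all <- (1 - eps) * gamma * k_pn2 * pn_b * th_pn_all /
      (K_pn + th_pn_all)
    pc_all <- (l + dt * dl_all) / cfr0
    err_all <- (pc_all - tgt[step + 1L])^2
    ik <- which.min(err_all)            # first minimum = smallest kappa
    kappa <- kappa_all[ik]

    ## committed step with the chosen kappa
    m <- m_all[ik]
    th_tpa <- th_scale * m * q_tpa
    th_pg <- th_scale * m * q_pg
    ads_tpa <- kf_tpa * tpa * (th_tpa - tpa_b)
    des_tpa <- kr_tpa * tpa_b
    ads_pg <- kf_pg * pg * (th_pg - pg_b - pn_b)
    des_pg <- kr_pg * pg_b
    act <- k2 * tpa_b * pg_b / (K2 + pg_b)
    des_pn <- kr_pn * pn_b
    inh <- ki * tpa * pai1
    cf <- (1 - eps) / eps
    l <- min(l + dt * dl_all[ik], cfr0)
    tpa <- max(0, tpa + dt * (-cf * (ads_tpa - des_tpa) - inh))
    tpa_b <- max(0, tpa_b + dt * (ads_tpa - des_tpa))
    pg <- max(0, pg + dt * (-cf * (ads_pg - des_pg)))
    pg_b <- max(0, pg_b + dt * (ads_pg - des_pg - act))
    pn <- pn + dt * cf * des_pn
    pn_b <- max(0, pn_b + dt * (act - des_pn))
    pai1 <- max(0, pai1 + dt * (-inh))

    n_done <- step
    out_k[step] <- kappa
    out_kmax[step] <- kmax
    out_err[step] <- err_all[ik]
    out_pc[step] <- l / cfr0
  }
  idx <- seq_len(n_done)
  sched <- data.frame(
    t = idx * dt,
    kappa_opt = out_k[idx], kappa_max = out_kmax[idx],
    phi = ifelse(out_kmax[idx] > 0, out_k[idx] / out_kmax[idx], 1),
    sqerr = out_err[idx], percent = out_pc[idx], target = tgt[idx + 1L])
  structure(sched, class = c("shell_schedule", "data.frame"),
            mse = mean(out_err[idx]), constants = constants,
            final_state = c(l = l, tpa = tpa, tpa_b = tpa_b, pg = pg,
                            pg_b = pg_b, pn = pn, pn_b = pn_b, pai1 = pai1))
}

#' @export
print.shell_schedule <- function(x, ...) {
  cat(sprintf(
    "<shell_schedule> %d steps of %.3g s, final lysis %.1f%%, mse %.3g\n",
    nrow(x), x$t[2] - x$t[1], 100 * x$percent[nrow(x)], attr(x, "mse")))
  invisible(x)
}

#' Time-averaged squared error of a fixed policy against a target
#'
#' Runs [run_fibrinolysis()] with the given policy over the target window
#' and returns the mean squared difference between the simulated lysed
#' fraction and the target (the same objective the fitted schedule
#' minimizes step-wise).
#'
#' @param clot_state A [run_clot_formation()] result.
#' @param target Dense target (see [fit_shell_schedule()]).
#' @param policy Policy passed to [run_fibrinolysis()].
#' @param dt Step, s.
#' @return Mean squared error (scalar).
#' @export
policy_mse <- function(clot_state, target, policy, dt = 0.1) {
  t_end <- max(target$time)
  traj <- run_fibrinolysis(clot_state, policy, dt = dt, t_max = t_end,
                           record_every = 1L)
  sim <- stats::approx(traj$t, traj$percent, xout = target$time,
                       rule = 2)$y
  mean((sim - target$value)^2)
}

#' Aggregate shell fractions over normalized regime time
#'
#' Each fitted schedule is split into three regions -- slow lysis
#' (0, SLT\], fast lysis (SLT, SLT+FLT\], end of lysis (SLT+FLT, end\] --
#' whose internal times are normalized to \[0, 1\] and binned into 10 bins;
#' the median and quartiles of the shell fraction phi are computed per bin
#' over all schedules pooled.
#'
#' @param schedules List of [fit_shell_schedule()] results (or data.frames
#'   with `t` and `phi`).
#' @param timescales List (same length) of lists with `slt`, `flt` and
#'   `end` in seconds (lysis-trajectory time).
#' @return Data.frame with columns `region` (slow/fast/end), `bin` (1..10),
#'   `phi_median`, `phi_q25`, `phi_q75`, `n`.
#' @export
aggregate_phi <- function(schedules, timescales) {
  stopifnot(length(schedules) == length(timescales))
  pool <- list()
  for (i in seq_along(schedules)) {
    s <- schedules[[i]]; ts <- timescales[[i]]
    if (is.null(ts$slt) || is.null(ts$flt) || is.null(ts$end) ||
        anyNA(c(ts$slt, ts$flt, ts$end))) {
      warning("schedule ", i, " misses regime boundaries; skipped")
      next
    }
    bounds <- list(slow = c(0, ts$slt),
                   fast = c(ts$slt, ts$slt + ts$flt),
                   end = c(ts$slt + ts$flt, ts$end))
    for (rg in names(bounds)) {
      b <- bounds[[rg]]
      if (b[2] <= b[1]) next
      in_rg <- s$t > b[1] & s$t <= b[2]
      if (!any(in_rg)) next
      u <- (s$t[in_rg] - b[1]) / (b[2] - b[1])   # normalized time in (0,1]
      bin <- pmin(pmax(ceiling(u * 10), 1L), 10L)
      pool[[length(pool) + 1L]] <-
        data.frame(region = rg, bin = bin, phi = s$phi[in_rg])
    }
  }
  if (!length(pool)) stop("no schedule had usable regime boundaries")
  pool <- do.call(rbind, pool)
  out <- do.call(rbind, lapply(split(pool, list(pool$region, pool$bin),
                                     drop = TRUE), function(d) {
    qs <- stats::quantile(d$phi, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(region = d$region[1], bin = d$bin[1], phi_median = qs[2],
               phi_q25 = qs[1], phi_q75 = qs[3], n = nrow(d))
  }))
  out$region <- factor(out$region, levels = c("slow", "fast", "end"))
  out <- out[order(out$region, out$bin), ]
  rownames(out) <- NULL
  out
}
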