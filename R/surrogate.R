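## Surrogate lysis model: instead of fitting the shell count against an
## experimental curve, the shell fraction is drawn from regime-specific
## empirical distributions, with the regime decided by the normalized
## fiber radius (slow while rf/rf0 > 0.9, fast below).

#' Build regime-specific shell-fraction distributions
#'
#' For each fitted schedule, computes the mean shell fraction phi in the
#' slow regime (t <= SLT) and in the fast regime (SLT < t <= SLT + FLT);
#' the per-simulation means form the two empirical distributions used by
#' the surrogate model.
#'
#' @param schedules List of [fit_shell_schedule()] results.
#' @param timescales List (same length) of lists with `slt` and `flt` in
#'   seconds.
#' @param r_tilde_slow,r_tilde_fast Normalized-radius thresholds marking
#'   the slow-to-fast transition and the end of the fast regime.
#' @return An object of class `phi_distributions` with fields `slow`,
#'   `fast` (numeric sample vectors in \[0, 1\]) and the thresholds.
#' @export
build_phi_distributions <- function(schedules, timescales,
                                    r_tilde_slow = 0.9, r_tilde_fast = 0.6) {
  stopifnot(length(schedules) == length(timescales))
  slow <- numeric(0); fast <- numeric(0)
  for (i in seq_along(schedules)) {
    s <- schedules[[i]]; ts <- timescales[[i]]
    if (is.null(ts$slt) || is.na(ts$slt)) {
      warning("schedule ", i, " has no slow-regime boundary; excluded")
      next
    }
    in_slow <- s$t <= ts$slt
    if (any(in_slow)) slow <- c(slow, mean(s$phi[in_slow]))
    if (!is.null(ts$flt) && !is.na(ts$flt)) {
      in_fast <- s$t > ts$slt & s$t <= ts$slt + ts$flt
      if (any(in_fast)) fast <- c(fast, mean(s$phi[in_fast]))
    }
  }
  if (!length(slow) || !length(fast))
    stop("empty phi distribution: no schedule covered both regimes")
  structure(list(slow = slow, fast = fast,
                 r_tilde_slow = r_tilde_slow, r_tilde_fast = r_tilde_fast),
            class = "phi_distributions")
}

#' @export
print.phi_distributions <- function(x, ...) {
  cat(sprintf(
    "<phi_distributions> slow: n=%d mean %.3f | fast: n=%d mean %.3f | thresholds %.2f/%.2f\n",
    length(x$slow), mean(x$slow), length(x$fast), mean(x$fast),
    x$r_tilde_slow, x$r_tilde_fast))
  invisible(x)
}

#' Run the surrogate lysis model
#'
#' At each step the normalized radius decides the regime (slow while
#' `rf/rf0 > r_tilde_slow`); the shell fraction phi is drawn from the
#' corresponding empirical distribution (uniformly, with replacement) and
#' `kappa = round(phi * kappa_max)`.  The draw cadence is every step by
#' default, configurable to every `n` steps or once per regime.  The SLT is
#' the first crossing of `r_tilde_slow` and the FLT the interval from there
#' to the first crossing of `r_tilde_fast`.
#'
#' @param clot_state A [run_clot_formation()] result.
#' @param dists A [build_phi_distributions()] result.
#' @param seed Integer seed for the draw stream (recorded in the output).
#' @param dt Step, s.
#' @param t_max Maximal simulated time, s.
#' @param cadence One of `"every_step"`, `"every_n"`, `"once_per_regime"`.
#' @param n Redraw period in steps for `"every_n"`.
#' @param record_every Snapshot recording period, steps.
#' @param stop_at_fast Stop once the fast threshold is crossed (the SLT
#'   and FLT are then already determined).
#' @return List with `trajectory` (a `lysis_trajectory`), `slt`, `flt`
#'   (seconds; `flt` is NA with a partial-result flag in `complete` when
#'   the fast threshold is not reached), `complete`, and `seed`.
#' @export
run_surrogate <- function(clot_state, dists, seed, dt = 0.1, t_max = 36000,
                          cadence = c("every_step", "every_n",
                                      "once_per_regime"),
                          n = 1L, record_every = 50L,
                          stop_at_fast = FALSE) {
  stopifnot(inherits(dists, "phi_distributions"))
  cadence <- match.arg(cadence)
  constants <- clot_constants(clot_state)
  rates <- clot_state$bind_rates
  if (is.null(rates)) rates <- binding_rates()
  rf0 <- constants$rf0

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  count <- 0L
  phi_cur <- NA_real_
  regime_cur <- ""
  draw_kappa <- function(t, rf, kmax) {
    regime <- if (rf > dists$r_tilde_slow * rf0) "slow" else "fast"
    redraw <- switch(cadence,
      every_step = TRUE,
      every_n = count %% n == 0L,
      once_per_regime = regime != regime_cur)
    count <<- count + 1L
    if (redraw || is.na(phi_cur)) {
      pool <- if (regime == "slow") dists$slow else dists$fast
      phi_cur <<- pool[sample.int(length(pool), 1L)]
      regime_cur <<- regime
    }
    round(phi_cur * kmax)
  }

  y <- initial_lysis_state(clot_state, constants)
  policy <- shell_policy("schedule", fun = draw_kappa)
  sim <- lysis_loop(y, policy, dt, t_max, record_every, constants, rates,
                    stop_at_fast = stop_at_fast)
  traj <- structure(sim$snapshots,
                    class = c("lysis_trajectory", "data.frame"),
                    constants = constants, exhausted = sim$exhausted,
                    t_slow = sim$t_slow, t_fast = sim$t_fast,
                    policy = "surrogate")
  ts <- trajectory_timescales(traj, dists$r_tilde_slow, dists$r_tilde_fast)
  list(trajectory = traj, slt = ts$slt, flt = ts$flt,
       complete = !is.na(ts$flt), seed = seed)
}
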