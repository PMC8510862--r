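## Plasmin-mediated fiber degradation under a pluggable shell policy.
##
## Lysis proceeds from the outside of the fibers inward: bound plasmin
## cleaves fibrin on the kappa outermost protofibril shells, the fiber
## radius shrinks in proportion to the cumulative lysis L, and the clot
## porosity rises accordingly.  Free species live in the fluid phase (uM),
## bound species in the fibrin phase (uM); the two exchange through the
## volume ratio (1 - eps)/eps.

#' Constants of a lysis run derived from a clot state
#'
#' Collapses the fiber-length / clot-volume / linear-density constants of
#' the radius-lysis relation into the normalization
#' `rf^2 = rf0^2 * (1 - L/cfr0)`, the unique form consistent with a radius
#' proportional to the amount of lysis, constant fiber length, and zero
#' radius at complete lysis.
#'
#' @param clot_state A [run_clot_formation()] result (or compatible list).
#' @param gamma Solubilization factor: fraction of fibrin returned to the
#'   plasma phase per plasmin cleavage (default 0.1).
#' @param q_pn Plasmin substrate sites per exposed fibrin monomer.
#' @return An object of class `clot_constants`.
#' @export
clot_constants <- function(clot_state, gamma = 0.1,
                           q_pn = clot_state$geometry$q_pn) {
  stopifnot(gamma > 0, gamma <= 1)
  geom <- clot_state$geometry
  poly <- clot_state$poly
  if (poly[["fr"]] <= 0 || poly[["fntot"]] <= 0)
    stop("clot state has no fibers: nothing to lyse")
  structure(list(
    gamma = gamma,
    cfr0 = clot_state$cfr0_uM,            # fibrin in fibers, uM (clot volume)
    rf0 = clot_state$rf0,                 # nm
    eps0 = clot_state$eps0,
    nu = poly[["cfr"]] / poly[["fntot"]], # monomers per protofibril
    fr = poly[["fr"]],                    # fibers/L
    geometry = geom,
    q_pn = q_pn
  ), class = "clot_constants")
}

#' Instantaneous lysis rate (Michaelis-Menten)
#'
#' `dL/dt = gamma * k_pn2 * pn_b * theta_pn / (K_pn_M + theta_pn)`:
#' bound plasmin cleaving the exposed fibrin substrate, with a fraction
#' `gamma` of each cleavage solubilized.
#'
#' @param pn_b Bound plasmin, uM.
#' @param theta_pn Exposed fibrin substrate, uM.
#' @param gamma Solubilization factor.
#' @param rates A [binding_rates()] object (uses `k_pn2`, `K_pn_M`).
#' @return Lysis rate in uM/s.
#' @export
lysis_rate <- function(pn_b, theta_pn, gamma = 0.1, rates = binding_rates()) {
  stopifnot(pn_b >= 0, theta_pn >= 0)
  gamma * rates$k_pn2 * pn_b * theta_pn / (rates$K_pn_M + theta_pn)
}

#' Fiber radius at a given cumulative lysis
#'
#' `rf^2 = rf0^2 * (1 - l/cfr0)`; the radius is exactly zero at complete
#' lysis.
#'
#' @param l Cumulative lysed fibrin, uM (clot volume).
#' @param constants A [clot_constants()] object.
#' @return Fiber radius in nm.
#' @export
update_radius <- function(l, constants) {
  if (any(l < 0)) stop("negative lysis")
  if (any(l > constants$cfr0 * (1 + 1e-12))) stop("over-lysis: l exceeds cfr0")
  constants$rf0 * sqrt(pmax(0, 1 - l / constants$cfr0))
}

#' Clot porosity at a given fiber radius
#'
#' `eps = 1 - (1 - eps0) * (rf/rf0)^2`: fiber length and number are
#' conserved during lysis, so the fiber volume fraction scales with the
#' cross-section area.
#'
#' @param rf Fiber radius, nm.
#' @param constants A [clot_constants()] object.
#' @return Porosity in (0, 1\].
#' @export
porosity <- function(rf, constants) {
  1 - (1 - constants$eps0) * (rf / constants$rf0)^2
}

## Binding-site concentrations (uM, fibrin phase) for a given radius and
## shell count. Vectorized over kappa.
lysis_thetas <- function(rf, kappa, constants, eps) {
  geom <- constants$geometry
  m <- shell_protofibril_count(rf, kappa, geom$r0, geom$p0)
  scale <- constants$nu * constants$fr / N_AVOGADRO * 1e6 / (1 - eps)
  list(tpa = scale * m * geom$q_tpa,
       pg = scale * m * geom$q_pg,
       pn = scale * m * constants$q_pn)
}

#' Time derivatives of the lysis system
#'
#' Bound-phase kinetics follow the clotting binding equations with sites
#' recomputed from the current radius and shell count; fluid-phase species
#' are coupled through the adsorption/desorption exchange fluxes scaled by
#' `(1 - eps)/eps`, PAI-1 keeps inhibiting free tPA, and free plasmin
#' accumulates from bound-plasmin desorption without rebinding.  The lysis
#' rate carries a `(1 - eps)` factor so `l` is expressed per clot volume
#' and comparable with `cfr0`.
#'
#' @param state Named numeric vector: `l` (uM, clot volume), fluid `tpa`,
#'   `pg`, `pn`, `pai1` (uM), bound `tpa_b`, `pg_b`, `pn_b` (uM, fibrin
#'   phase).
#' @param kappa Number of reacting shells.
#' @param constants A [clot_constants()] object.
#' @param rates A [binding_rates()] object.
#' @return Named numeric vector of derivatives (uM/s).
#' @export
lysis_rhs <- function(state, kappa, constants, rates = binding_rates()) {
  l <- state[["l"]]
  rf <- update_radius(l, constants)
  eps <- porosity(rf, constants)
  th <- lysis_thetas(rf, kappa, constants, eps)
  fl <- binding_fluxes(state[["tpa"]], state[["tpa_b"]], state[["pg"]],
                       state[["pg_b"]], state[["pai1"]], state[["pn_b"]],
                       th$tpa, th$pg, rates)
  cf <- (1 - eps) / eps
  dl <- (1 - eps) *
    lysis_rate(state[["pn_b"]], th$pn, constants$gamma, rates)
  c(l = dl,
    tpa = -cf * (fl$ads_tpa - fl$des_tpa) - fl$inh,
    tpa_b = fl$ads_tpa - fl$des_tpa,
    pg = -cf * (fl$ads_pg - fl$des_pg),
    pg_b = fl$ads_pg - fl$des_pg - fl$act,
    pn = cf * fl$des_pn,
    pn_b = fl$act - fl$des_pn,
    pai1 = -fl$inh)
}

#' Shell policies for lysis runs
#'
#' A policy decides the number of reacting shells at each time step:
#' `"surface"` keeps `kappa = 0`, `"bulk"` uses every available shell
#' (`kappa_max = ceiling(rf/r0)`, recomputed as the fiber shrinks),
#' `"fixed"` clamps a constant `kappa` to the available range, and
#' `"schedule"` evaluates `fun(t, rf, kappa_max)` each step.
#'
#' @param type One of `"surface"`, `"bulk"`, `"fixed"`, `"schedule"`.
#' @param kappa Shell count for `"fixed"`.
#' @param fun Function `(t, rf, kappa_max) -> kappa` for `"schedule"`.
#' @return An object of class `shell_policy`.
#' @export
shell_policy <- function(type = c("surface", "bulk", "fixed", "schedule"),
                         kappa = NULL, fun = NULL) {
  type <- match.arg(type)
  if (type == "fixed" && (is.null(kappa) || kappa < 0))
    stop("fixed policy needs a nonnegative kappa")
  if (type == "schedule" && !is.function(fun))
    stop("schedule policy needs a function (t, rf, kappa_max) -> kappa")
  structure(list(type = type, kappa = kappa, fun = fun),
            class = "shell_policy")
}

## Map the end-of-clotting binding state (per clot volume) to the lysis
## state vector (bound pools per fibrin phase).
initial_lysis_state <- function(clot_state, constants) {
  b <- clot_state$binding
  f <- 1 / (1 - constants$eps0)
  c(l = 0,
    tpa = b[["tpa"]], tpa_b = b[["tpa_b"]] * f,
    pg = b[["pg"]], pg_b = b[["pg_b"]] * f,
    pn = 0, pn_b = b[["pn_b"]] * f,
    pai1 = b[["pai1"]])
}

#' Simulate fibrinolysis under a shell policy
#'
#' Fixed-step integration at `dt` (default 0.1 s, the grid the shell
#' optimizer also uses) of the lysis system, with the available shell count
#' `kappa_max = ceiling(rf/r0)` recomputed every step.  The run stops at
#' exhaustion (`l >= (1 - 1e-6) * cfr0`) or at `t_max`.
#'
#' @param clot_state A [run_clot_formation()] result.
#' @param policy A [shell_policy()] (or one of its type strings).
#' @param dt Time step, s.
#' @param t_max Maximal simulated time, s.
#' @param record_every Record one snapshot every this many steps.
#' @param constants Optional [clot_constants()] override.
#' @param rates Optional [binding_rates()] override (defaults to the ones
#'   stored in the clot state).
#' @param stop_at_fast Stop as soon as the fast-regime threshold
#'   `rf/rf0 <= 0.6` is crossed (useful when only the slow/fast crossing
#'   times are needed).
#' @return An object of class `lysis_trajectory`: a data.frame with columns
#'   `t`, `l`, `percent`, `rf`, `eps`, `kappa` and the species, plus
#'   attributes `constants` and `exhausted`.
#' @export
run_fibrinolysis <- function(clot_state, policy = "surface", dt = 0.1,
                             t_max = 36000, record_every = 10L,
                             constants = NULL, rates = NULL,
                             stop_at_fast = FALSE) {
  if (is.character(policy)) policy <- shell_policy(policy)
  stopifnot(inherits(policy, "shell_policy"))
  if (is.null(constants)) constants <- clot_constants(clot_state)
  if (is.null(rates)) rates <- clot_state$bind_rates
  if (is.null(rates)) rates <- binding_rates()

  y <- initial_lysis_state(clot_state, constants)
  sim <- lysis_loop(y, policy, dt, t_max, record_every, constants, rates,
                    stop_at_fast = stop_at_fast)
  traj <- sim$snapshots
  structure(traj, class = c("lysis_trajectory", "data.frame"),
            constants = constants, exhausted = sim$exhausted,
            t_slow = sim$t_slow, t_fast = sim$t_fast,
            policy = policy$type)
}

## Core fixed-step loop, shared with the surrogate model.  `draw_kappa` is
## called with (t, rf, kappa_max) and must return an integer shell count.
lysis_loop <- function(y, policy, dt, t_max, record_every, constants, rates,
                       draw_kappa = NULL, stop_at_fast = FALSE) {
  geom <- constants$geometry
  gamma <- constants$gamma
  cfr0 <- constants$cfr0
  rf0 <- constants$rf0
  eps0 <- constants$eps0
  r0 <- geom$r0
  p0 <- geom$p0
  theta_base <- constants$nu * constants$fr / N_AVOGADRO * 1e6
  q_tpa <- geom$q_tpa; q_pg <- geom$q_pg; q_pn <- constants$q_pn
  kf_tpa <- rates$kf_tpa; kr_tpa <- rates$kr_tpa
  kf_pg <- rates$kf_pg; kr_pg <- rates$kr_pg
  k2 <- rates$k_tpa_pg2; K2 <- rates$K_tpa_pg_M
  k_pn2 <- rates$k_pn2; K_pn <- rates$K_pn_M
  kr_pn <- rates$kr_pn; ki <- rates$ki_tpa_pai

  n_steps <- ceiling(t_max / dt)
  n_rec <- floor(n_steps / record_every) + 1L
  rec <- matrix(NA_real_, n_rec, 14L)
  colnames(rec) <- c("t", "l", "percent", "rf", "eps", "kappa", "tpa",
                     "tpa_b", "pg", "pg_b", "pn", "pn_b", "pai1",
                     "kappa_max")
  l <- y[["l"]]; tpa <- y[["tpa"]]; tpa_b <- y[["tpa_b"]]
  pg <- y[["pg"]]; pg_b <- y[["pg_b"]]; pn <- y[["pn"]]
  pn_b <- y[["pn_b"]]; pai1 <- y[["pai1"]]
  exhausted <- FALSE
  irec <- 0L
  t <- 0
  t_slow <- NA_real_  # first crossing of rf/rf0 <= 0.9
  t_fast <- NA_real_  # first crossing of rf/rf0 <= 0.6
  for (step in 0:n_steps) {
    frac <- 1 - l / cfr0
    if (frac < 1e-6) { exhausted <- TRUE; frac <- 0 }
    rf <- rf0 * sqrt(frac)
    if (is.na(t_slow) && rf <= 0.9 * rf0) t_slow <- t
    if (is.na(t_fast) && rf <= 0.6 * rf0) {
      t_fast <- t
    }
    stop_now <- stop_at_fast && !is.na(t_fast)
    eps <- 1 - (1 - eps0) * frac
    kmax <- ceiling(rf / r0)
    kappa <- switch(policy$type,
      surface = 0L,
      bulk = kmax,
      fixed = min(policy$kappa, kmax),
      schedule = {
        k <- if (is.null(draw_kappa)) policy$fun(t, rf, kmax)
             else draw_kappa(t, rf, kmax)
        max(0L, min(as.integer(round(k)), kmax))
      })

    if (step %% record_every == 0L || exhausted || stop_now) {
      irec <- irec + 1L
      if (irec > nrow(rec)) rec <- rbind(rec, rec[1, , drop = FALSE] * NA)
      rec[irec, ] <- c(t, l, l / cfr0, rf, eps, kappa, tpa, tpa_b, pg,
                       pg_b, pn, pn_b, pai1, kmax)
    }
    if (exhausted || stop_now || step == n_steps) break

    m <- pi * p0 * (2 * r0 * rf * (1 + kappa) + r0 * r0 * (1 - kappa * kappa))
    mtot <- pi * p0 * (rf + r0)^2
    if (m > mtot) m <- mtot
    th_scale <- theta_base / (1 - eps)
    th_tpa <- th_scale * m * q_tpa
    th_pg <- th_scale * m * q_pg
    th_pn <- th_scale * m * q_pn

    ads_tpa <- kf_tpa * tpa * (th_tpa - tpa_b)
    des_tpa <- kr_tpa * tpa_b
    ads_pg <- kf_pg * pg * (th_pg - pg_b - pn_b)
    des_pg <- kr_pg * pg_b
    act <- k2 * tpa_b * pg_b / (K2 + pg_b)
    des_pn <- kr_pn * pn_b
    inh <- ki * tpa * pai1
    cf <- (1 - eps) / eps
    dl <- (1 - eps) * gamma * k_pn2 * pn_b * th_pn / (K_pn + th_pn)

    l <- min(l + dt * dl, cfr0)
    tpa <- max(0, tpa + dt * (-cf * (ads_tpa - des_tpa) - inh))
    tpa_b <- max(0, tpa_b + dt * (ads_tpa - des_tpa))
    pg <- max(0, pg + dt * (-cf * (ads_pg - des_pg)))
    pg_b <- max(0, pg_b + dt * (ads_pg - des_pg - act))
    pn <- pn + dt * cf * des_pn
    pn_b <- max(0, pn_b + dt * (act - des_pn))
    pai1 <- max(0, pai1 + dt * (-inh))
    t <- t + dt
  }
  list(snapshots = as.data.frame(rec[seq_len(irec), , drop = FALSE]),
       exhausted = exhausted, t_slow = t_slow, t_fast = t_fast)
}

#' @export
print.lysis_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lysis_trajectory> policy %s: %d snapshots, t = [0, %g] s, lysis %.1f%%%s\n",
    attr(x, "policy"), nrow(x), x$t[nrow(x)], 100 * x$percent[nrow(x)],
    if (isTRUE(attr(x, "exhausted"))) " (exhausted)" else ""))
  invisible(x)
}

#' Timescales of a simulated lysis trajectory
#'
#' Slow and fast lysis times are read off the normalized fiber radius:
#' SLT is the first time `rf/rf0 <= 0.9` and the fast regime ends at the
#' first time `rf/rf0 <= 0.6` (FLT is the interval between the two).  The
#' time of the maximal lysis-rate (max derivative of the lysed fraction)
#' and the time of 95% lysis are also reported.
#'
#' @param traj A [run_fibrinolysis()] trajectory.
#' @param slow_threshold,fast_threshold Normalized-radius thresholds.
#' @return List with `slt`, `flt`, `t_max_rate`, `t95` (seconds; NA when a
#'   crossing is not reached).
#' @export
trajectory_timescales <- function(traj, slow_threshold = 0.9,
                                  fast_threshold = 0.6) {
  constants <- attr(traj, "constants")
  rtil <- traj$rf / constants$rf0
  t_at <- function(th) {
    i <- which(rtil <= th)[1]
    if (is.na(i)) NA_real_ else traj$t[i]
  }
  ## exact crossing times tracked step-by-step by the integrator, when the
  ## default 0.9/0.6 thresholds are requested
  slt <- if (slow_threshold == 0.9 && !is.null(attr(traj, "t_slow")))
    attr(traj, "t_slow") else t_at(slow_threshold)
  t_fast <- if (fast_threshold == 0.6 && !is.null(attr(traj, "t_fast")))
    attr(traj, "t_fast") else t_at(fast_threshold)
  dl <- diff(traj$percent) / diff(traj$t)
  t_max_rate <- if (length(dl)) traj$t[which.max(dl)] else NA_real_
  i95 <- which(traj$percent >= 0.95)[1]
  list(slt = slt, flt = if (is.na(t_fast)) NA_real_ else t_fast - slt,
       t_max_rate = t_max_rate,
       t95 = if (is.na(i95)) NA_real_ else traj$t[i95])
}
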