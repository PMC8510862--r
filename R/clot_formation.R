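## Fibrin polymerization, fiber geometry and protein binding during clotting.
##
## Polymerization is tracked as a number density cascade (molecules/L):
## fibrinogen fa -> monomer f1 -> oligomers f2..f10 -> protofibrils fn ->
## fibers fr, with bookkeeping totals fntot (protofibrils in fibers),
## cfn (fibrin in protofibrils) and cfr (fibrin in fibers).  Rate constants
## are in 1/s (kA) and L/(molecules.s) (all others).  Protein binding runs
## in micromolar; the two unit systems meet in the binding-site
## concentration Theta.

#' Polymerization rate constants
#'
#' Defaults are the best-ranked parameter set from the grid search over the
#' polymerization cascade. `oligomer_threshold` is the oligomer length at
#' which protofibrils form (11 monomers).
#'
#' @param kA Fibrinopeptide-A cleavage rate, 1/s.
#' @param kPI Monomer addition to monomers/oligomers, L/(molecules.s).
#' @param kPG Monomer addition to protofibrils (protofibril growth),
#'   L/(molecules.s).
#' @param kFI Protofibril-protofibril aggregation (fiber initiation),
#'   L/(molecules.s).
#' @param kFG Protofibril addition to fibers (fiber growth), L/(molecules.s).
#' @param kFA Fiber-fiber aggregation, L/(molecules.s).
#' @param oligomer_threshold Minimal oligomer length for protofibril
#'   formation.
#' @return An object of class `polymerization_rates`.
#' @export
polymerization_rates <- function(kA = 0.02, kPI = 1e-17, kPG = 1e-15,
                                 kFI = 1e-18, kFG = 1e-16, kFA = 1e-18,
                                 oligomer_threshold = 11L) {
  r <- list(kA = kA, kPI = kPI, kPG = kPG, kFI = kFI, kFG = kFG, kFA = kFA,
            oligomer_threshold = as.integer(oligomer_threshold))
  if (any(unlist(r[1:6]) < 0)) stop("rate constants must be nonnegative")
  if (r$oligomer_threshold < 2L) stop("oligomer_threshold must be >= 2")
  structure(r, class = "polymerization_rates")
}

#' Binding and activation rate constants
#'
#' Reversible adsorption of tPA and plasminogen to fibrin binding sites,
#' Michaelis-Menten activation of bound plasminogen by bound tPA,
#' Michaelis-Menten fibrin cleavage by bound plasmin, and irreversible
#' inhibition of free tPA by PAI-1.
#'
#' @param kf_pg,kr_pg Plasminogen adsorption (1/(uM.s)) and desorption (1/s).
#' @param kf_tpa,kr_tpa tPA adsorption (1/(uM.s)) and desorption (1/s).
#' @param k_tpa_pg2,K_tpa_pg_M Catalytic rate (1/s) and Michaelis constant
#'   (uM) for plasmin generation from bound plasminogen.
#' @param k_pn2,K_pn_M Catalytic rate (1/s) and Michaelis constant (uM) for
#'   fibrin cleavage by bound plasmin.
#' @param kr_pn Bound-plasmin desorption, 1/s.
#' @param ki_tpa_pai tPA/PAI-1 inhibition, 1/(uM.s).
#' @return An object of class `binding_rates`.
#' @export
binding_rates <- function(kf_pg = 1.087e-4, kr_pg = 5.435e-5,
                          kf_tpa = 1.148e-4, kr_tpa = 6.658e-5,
                          k_tpa_pg2 = 0.2, K_tpa_pg_M = 0.02,
                          k_pn2 = 25, K_pn_M = 250,
                          kr_pn = 5.435e-5, ki_tpa_pai = 25) {
  r <- list(kf_pg = kf_pg, kr_pg = kr_pg, kf_tpa = kf_tpa, kr_tpa = kr_tpa,
            k_tpa_pg2 = k_tpa_pg2, K_tpa_pg_M = K_tpa_pg_M,
            k_pn2 = k_pn2, K_pn_M = K_pn_M, kr_pn = kr_pn,
            ki_tpa_pai = ki_tpa_pai)
  if (any(unlist(r) <= 0)) stop("binding rate constants must be positive")
  structure(r, class = "binding_rates")
}

#' Fiber cross-section geometry
#'
#' The default protofibril radius (2.5 nm, i.e. a ~5 nm protofibril
#' diameter) is the one consistent with the packing density `p0`: at
#' `p0 = 0.01116` protofibrils/nm^2 each protofibril occupies 89.6 nm^2 of
#' cross-section, so `r0 = 2.5` nm gives a ~22% protein packing fraction,
#' matching the known protein content of hydrated fibrin fibers.
#'
#' @param p0 Areal packing density of protofibrils in a fiber cross-section,
#'   protofibrils/nm^2.
#' @param r0 Protofibril radius, nm.
#' @param q_tpa,q_pg,q_pn Binding sites per fibrin monomer for tPA,
#'   plasminogen, and plasmin substrate.
#' @param lambda_p Fibrin monomers per nm of protofibril length (default
#'   1/22.5: one monomer per half-staggered 22.5 nm repeat).
#' @return An object of class `fiber_geometry`.
#' @export
fiber_geometry <- function(p0 = 0.01116, r0 = 2.5, q_tpa = 1.5, q_pg = 2.4,
                           q_pn = 1.0, lambda_p = 1 / 22.5) {
  stopifnot(p0 > 0, r0 > 0, q_tpa > 0, q_pg > 0, q_pn > 0, lambda_p > 0)
  structure(list(p0 = p0, r0 = r0, q_tpa = q_tpa, q_pg = q_pg, q_pn = q_pn,
                 lambda_p = lambda_p),
            class = "fiber_geometry")
}

#' Time derivatives of the polymerization cascade
#'
#' The monomer pool feeds oligomers of sizes 2..10 one monomer at a time;
#' an oligomer of size 10 receiving a monomer becomes a protofibril
#' (11 monomers).  Protofibrils aggregate pairwise into fibers, add to
#' existing fibers, and grow in length by monomer addition; fibers also
#' aggregate pairwise.  Total fibrin
#' `fa + f1 + sum(j * fj) + cfn + cfr` is conserved exactly.
#'
#' @param state Named numeric vector with entries `fa`, `f1`..`f10`, `fn`,
#'   `fr`, `fntot`, `cfn`, `cfr` (molecules/L).
#' @param rates A [polymerization_rates()] object.
#' @return Named numeric vector of time derivatives (molecules/(L.s)).
#' @export
polymerization_rhs <- function(state, rates) {
  if (any(state < 0)) stop("invalid state: negative concentration")
  fa <- state[["fa"]]
  f <- unname(state[paste0("f", 1:10)])
  fn <- state[["fn"]]
  fr <- state[["fr"]]
  cfn <- state[["cfn"]]
  kA <- rates$kA; kPI <- rates$kPI; kPG <- rates$kPG
  kFI <- rates$kFI; kFG <- rates$kFG; kFA <- rates$kFA

  d <- numeric(length(state))
  names(d) <- names(state)
  d[["fa"]] <- -kA * fa
  d[["f1"]] <- kA * fa - kPI * f[1] * (f[1] + sum(f)) - kPG * f[1] * fn
  for (j in 2:10)
    d[[paste0("f", j)]] <- kPI * f[1] * (f[j - 1] - f[j])
  d[["fn"]] <- kPI * f[1] * f[10] - 2 * kFI * fn * fn - kFG * fr * fn
  d[["fr"]] <- kFI * fn * fn - kFA * fr * fr
  d[["fntot"]] <- 2 * kFI * fn * fn + kFG * fr * fn + kFA * fr * fr
  d[["cfn"]] <- 11 * kPI * f[1] * f[10] + kPG * f[1] * fn -
    2 * kFI * fn * cfn - kFG * fr * cfn
  d[["cfr"]] <- 2 * kFI * fn * cfn + kFG * fr * cfn
  d
}

#' Total fibrin content of a polymerization state
#'
#' @param state Named numeric vector as in [polymerization_rhs()].
#' @return Total fibrin `fa + f1 + sum(j*fj, j=2..10) + cfn + cfr`
#'   (molecules/L), a conserved quantity.
#' @export
total_fibrin <- function(state) {
  state[["fa"]] + state[["f1"]] +
    sum((2:10) * unname(state[paste0("f", 2:10)])) +
    state[["cfn"]] + state[["cfr"]]
}

#' Average fiber radius from protofibril content
#'
#' `rf = sqrt((fntot/fr) / (pi * p0))`: the radius of a cylinder packing
#' `fntot/fr` protofibrils per fiber at areal density `p0`.
#'
#' @param fntot Protofibrils incorporated in fibers, per liter.
#' @param fr Fiber number concentration, per liter.
#' @param p0 Packing density, protofibrils/nm^2.
#' @return Fiber radius in nm.
#' @export
fiber_radius <- function(fntot, fr, p0 = 0.01116) {
  if (fr <= 0) stop("undefined radius: no fibers (fr = 0)")
  if (fntot < 0) stop("fntot must be nonnegative")
  sqrt((fntot / fr) / (pi * p0))
}

#' Protofibril count in the kappa outer shells of a fiber
#'
#' Closed form of the annulus integral of the packing density over radii
#' `[rf - kappa*r0, rf + r0]`:
#' `m = pi*p0*(2*r0*rf*(1 + kappa) + r0^2*(1 - kappa^2))`.
#' `kappa = 0` exposes only the outermost annulus; `kappa = rf/r0` recovers
#' the whole cross-section `pi*p0*(rf + r0)^2`.  The result is clamped to
#' the fiber's total protofibril count.
#'
#' @param rf Fiber radius, nm.
#' @param kappa Number of reacting shells (nonnegative).
#' @param r0 Protofibril radius, nm.
#' @param p0 Packing density, protofibrils/nm^2.
#' @return Protofibril count (vectorized over `kappa`).
#' @export
shell_protofibril_count <- function(rf, kappa, r0 = 2.5, p0 = 0.01116) {
  if (any(kappa < 0)) stop("invalid argument: kappa must be nonnegative")
  m <- pi * p0 * (2 * r0 * rf * (1 + kappa) + r0^2 * (1 - kappa^2))
  pmin(m, pi * p0 * (rf + r0)^2)
}

#' Binding-site concentration on the reacting shells
#'
#' Sites per fiber are `(cfr/fntot) * m * q`: fibrin monomers per
#' protofibril, times protofibrils in the reacting shells, times sites per
#' monomer.  By default this is converted to a molar concentration by
#' multiplying with the fiber number concentration and dividing by
#' Avogadro's number (`theta_literal = TRUE` returns raw sites per fiber).
#'
#' @param cfr Fibrin in fibers, molecules/L.
#' @param fntot Protofibrils in fibers, per liter.
#' @param fr Fiber number concentration, per liter.
#' @param geometry A [fiber_geometry()].
#' @param q Binding sites per fibrin monomer.
#' @param kappa Number of reacting shells.
#' @param theta_literal If TRUE, return sites per fiber instead of uM.
#' @return Theta in uM (or sites/fiber).
#' @export
binding_sites <- function(cfr, fntot, fr, geometry = fiber_geometry(),
                          q = geometry$q_tpa, kappa = 0,
                          theta_literal = FALSE) {
  if (fntot <= 0) {
    if (cfr > 0) stop("inconsistent state: fibrin in fibers but fntot = 0")
    return(0)
  }
  if (fr <= 0) return(0)
  rf <- fiber_radius(fntot, fr, geometry$p0)
  m <- shell_protofibril_count(rf, kappa, geometry$r0, geometry$p0)
  sites_per_fiber <- (cfr / fntot) * m * q
  if (theta_literal) return(sites_per_fiber)
  sites_per_fiber * fr / N_AVOGADRO * 1e6
}

## Elementary binding fluxes (uM/s) shared by the clotting and lysis models.
## theta_* and bound species must be expressed in the same phase volume.
binding_fluxes <- function(tpa, tpa_b, pg, pg_b, pai1, pn_b,
                           theta_tpa, theta_pg, r) {
  list(
    ads_tpa = r$kf_tpa * tpa * (theta_tpa - tpa_b),
    des_tpa = r$kr_tpa * tpa_b,
    ads_pg  = r$kf_pg * pg * (theta_pg - pg_b - pn_b),
    des_pg  = r$kr_pg * pg_b,
    act     = r$k_tpa_pg2 * tpa_b * pg_b / (r$K_tpa_pg_M + pg_b),
    des_pn  = r$kr_pn * pn_b,
    inh     = r$ki_tpa_pai * tpa * pai1
  )
}

#' Time derivatives of the protein binding system during clotting
#'
#' Mass-action adsorption to free sites, first-order desorption,
#' Michaelis-Menten activation of bound plasminogen by bound tPA
#' (plasmin competes with plasminogen for the same sites), and
#' irreversible inhibition of free tPA by PAI-1.
#'
#' @param bstate Named numeric vector with entries `tpa`, `tpa_b`, `pg`,
#'   `pg_b`, `pai1`, `pn_b` (uM).
#' @param theta_tpa,theta_pg Binding-site concentrations, uM.
#' @param rates A [binding_rates()] object.
#' @return Named numeric vector of derivatives (uM/s).
#' @export
binding_rhs <- function(bstate, theta_tpa, theta_pg, rates = binding_rates()) {
  fl <- binding_fluxes(bstate[["tpa"]], bstate[["tpa_b"]], bstate[["pg"]],
                       bstate[["pg_b"]], bstate[["pai1"]], bstate[["pn_b"]],
                       theta_tpa, theta_pg, rates)
  c(tpa   = -fl$ads_tpa + fl$des_tpa - fl$inh,
    tpa_b = fl$ads_tpa - fl$des_tpa,
    pg    = -fl$ads_pg + fl$des_pg,
    pg_b  = fl$ads_pg - fl$des_pg - fl$act,
    pai1  = -fl$inh,
    pn_b  = -fl$des_pn + fl$act)
}

#' Simulate clot formation
#'
#' Integrates the polymerization cascade coupled to protein binding from
#' t = 0 to `t_clot` (default 1000 s, comparable with the average clot
#' formation time) with a stiff adaptive solver.  Binding sites are
#' recomputed at every evaluation from the current fibrin-in-fibers,
#' protofibril and fiber concentrations; during formation only adsorption
#' to the outer fiber surface is considered (`kappa = 0` by default).
#'
#' @param conditions Named list or vector of laboratory concentrations:
#'   `fibrinogen` (mg/mL), `tpa`, `pai1`, `pg` (ug/mL).
#' @param poly_rates A [polymerization_rates()] object.
#' @param bind_rates A [binding_rates()] object.
#' @param geometry A [fiber_geometry()] object.
#' @param t_clot Clotting time in seconds.
#' @param kappa Shell count used for Theta during formation (default 0,
#'   surface adsorption only).
#' @param dt_report Reporting interval of the returned time course, s.
#' @param mw Molecular weights (kDa), see [default_molecular_weights()].
#' @param rtol,atol_uM Solver tolerances; absolute tolerance for the
#'   molecules/L block is scaled by Avogadro's number.
#' @return An object of class `clot_state`: final polymerization and
#'   binding states, initial fiber radius `rf0` (nm), binding-site
#'   concentrations, fibrinogen incorporation fraction, initial porosity
#'   `eps0`, and the reported time course (`$timecourse`).
#' @export
run_clot_formation <- function(conditions,
                               poly_rates = polymerization_rates(),
                               bind_rates = binding_rates(),
                               geometry = fiber_geometry(),
                               t_clot = 1000, kappa = 0, dt_report = 10,
                               mw = default_molecular_weights(),
                               rtol = 1e-8, atol_uM = 1e-12) {
  conditions <- as.list(conditions)
  fa0 <- convert_units(conditions$fibrinogen, "mg_ml", "molecules_l",
                       "fibrinogen", mw)
  tpa0 <- convert_units(conditions$tpa, "ug_ml", "uM", "tpa", mw)
  pg0 <- convert_units(conditions$pg, "ug_ml", "uM", "pg", mw)
  pai0 <- convert_units(conditions$pai1, "ug_ml", "uM", "pai1", mw)

  poly_names <- c("fa", paste0("f", 1:10), "fn", "fr", "fntot", "cfn", "cfr")
  y0 <- c(stats::setNames(c(fa0, rep(0, 15)), poly_names),
          tpa = tpa0, tpa_b = 0, pg = pg0, pg_b = 0, pai1 = pai0, pn_b = 0,
          tpa_i = 0)  # accumulated inhibited tPA, for mass bookkeeping

  np <- length(poly_names)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)  # guard against solver undershoot below zero
    poly <- y[seq_len(np)]
    dpoly <- polymerization_rhs(poly, poly_rates)
    th_tpa <- binding_sites(poly[["cfr"]], poly[["fntot"]], poly[["fr"]],
                            geometry, geometry$q_tpa, kappa)
    th_pg <- binding_sites(poly[["cfr"]], poly[["fntot"]], poly[["fr"]],
                           geometry, geometry$q_pg, kappa)
    db <- binding_rhs(y[np + 1:6], th_tpa, th_pg, bind_rates)
    fl_inh <- bind_rates$ki_tpa_pai * y[["tpa"]] * y[["pai1"]]
    list(c(dpoly, db, tpa_i = fl_inh))
  }

  times <- unique(c(seq(0, t_clot, by = dt_report), t_clot))
  atol <- c(rep(atol_uM * N_AVOGADRO * 1e-6, np), rep(atol_uM, 7))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed: lsoda istate = ", attr(sol, "istate")[1])
  final <- sol[nrow(sol), -1]
  final[final < 0] <- 0

  poly <- final[poly_names]
  has_fibers <- poly[["fr"]] > 0 && poly[["fntot"]] > 0
  rf0 <- if (has_fibers) fiber_radius(poly[["fntot"]], poly[["fr"]], geometry$p0) else NA_real_
  th_tpa <- binding_sites(poly[["cfr"]], poly[["fntot"]], poly[["fr"]],
                          geometry, geometry$q_tpa, kappa)
  th_pg <- binding_sites(poly[["cfr"]], poly[["fntot"]], poly[["fr"]],
                         geometry, geometry$q_pg, kappa)
  cfr0_uM <- poly[["cfr"]] / N_AVOGADRO * 1e6
  ## fiber volume fraction: monomer footprint 1/(lambda_p*p0) nm^3,
  ## 1 nm^3 = 1e-24 L
  fibrin_vol_frac <- poly[["cfr"]] * (1 / (geometry$lambda_p * geometry$p0)) * 1e-24
  eps0 <- 1 - fibrin_vol_frac

  structure(list(
    poly = poly,
    binding = final[c("tpa", "tpa_b", "pg", "pg_b", "pai1", "pn_b")],
    tpa_inhibited = final[["tpa_i"]],
    rf0 = rf0,
    theta_tpa = th_tpa, theta_pg = th_pg,
    incorporation = poly[["cfr"]] / fa0,
    cfr0_uM = cfr0_uM,
    eps0 = eps0,
    initial = c(fa = fa0, tpa = tpa0, pg = pg0, pai1 = pai0),
    conditions = conditions,
    geometry = geometry, bind_rates = bind_rates, poly_rates = poly_rates,
    kappa_formation = kappa, t_clot = t_clot,
    timecourse = as.data.frame(sol)
  ), class = "clot_state")
}

#' @export
print.clot_state <- function(x, ...) {
  cat(sprintf(
    paste0("<clot_state> after %g s of clotting\n",
           "  rf0 %.1f nm | incorporation %.1f%% | eps0 %.6f\n",
           "  tPA bound %.3g uM (%.2f%% of initial) | Pg bound %.3g uM\n"),
    x$t_clot, x$rf0, 100 * x$incorporation, x$eps0,
    x$binding[["tpa_b"]], 100 * x$binding[["tpa_b"]] / x$initial[["tpa"]],
    x$binding[["pg_b"]]))
  invisible(x)
}
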