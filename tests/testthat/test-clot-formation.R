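## Polymerization cascade, fiber geometry and binding kinetics.

test_that("quiescent and single-reaction limits of the cascade", {
  rates0 <- polymerization_rates(kA = 0, kPI = 0, kPG = 0, kFI = 0,
                                 kFG = 0, kFA = 0)
  st <- random_poly_state() * 0
  st[["fa"]] <- 1e18
  expect_true(all(polymerization_rhs(st, rates0) == 0))
  r <- polymerization_rates(kA = 0.05, kPI = 0, kPG = 0, kFI = 0,
                            kFG = 0, kFA = 0)
  d <- polymerization_rhs(st, r)
  expect_equal(d[["fa"]], -0.05 * 1e18)
  expect_equal(d[["f1"]], 0.05 * 1e18)
  expect_true(all(d[setdiff(names(d), c("fa", "f1"))] == 0))
  st[["f1"]] <- -1
  expect_error(polymerization_rhs(st, r), "negative")
})

test_that("the cascade conserves total fibrin and matches the stoichiometry oracle", {
  set.seed(7)
  rates <- polymerization_rates()
  for (i in 1:25) {
    st <- random_poly_state()
    d <- polymerization_rhs(st, rates)
    dM <- d[["fa"]] + d[["f1"]] +
      sum((2:10) * d[paste0("f", 2:10)]) + d[["cfn"]] + d[["cfr"]]
    expect_lt(abs(dM) / max(abs(d)), 1e-10)
    oracle <- poly_rhs_oracle(st, rates)
    expect_equal(unname(d), unname(oracle),
                 tolerance = 1e-12)
  }
})

test_that("fiber radius inverts the packing relation", {
  p0 <- 0.01116
  expect_equal(fiber_radius(pi * p0 * 100^2 * 5, 5, p0), 100)
  expect_equal(fiber_radius(0, 3), 0)
  expect_equal(fiber_radius(350 * 2, 2, p0), sqrt(350 / (pi * p0)),
               tolerance = 1e-12)  # ~99.9 nm
  expect_equal(fiber_radius(350 * 2, 2, p0), 99.9, tolerance = 1e-3)
  expect_error(fiber_radius(10, 0), "no fibers")
})

test_that("shell protofibril count matches the annulus quadrature oracle", {
  quad <- function(rf, kappa, r0, p0) {
    2 * pi * stats::integrate(function(r) p0 * r,
                              lower = rf - kappa * r0, upper = rf + r0,
                              rel.tol = 1e-12)$value
  }
  set.seed(11)
  for (i in 1:20) {
    rf <- runif(1, 20, 200)
    r0 <- runif(1, 1, 6)
    kappa <- sample(0:floor(rf / r0), 1)
    p0 <- 0.01116
    m <- shell_protofibril_count(rf, kappa, r0, p0)
    expect_equal(m, quad(rf, kappa, r0, p0), tolerance = 1e-9)
  }
  ## kappa = rf/r0 closes the square: the whole cross-section
  expect_equal(shell_protofibril_count(100, 100 / 5, 5, 0.01116),
               pi * 0.01116 * 105^2, tolerance = 1e-12)
  ## kappa = 0: outermost annulus only
  expect_equal(shell_protofibril_count(100, 0, 5, 0.01116),
               pi * 0.01116 * (2 * 5 * 100 + 25), tolerance = 1e-12)
  ## clamping: m never exceeds the fiber total
  expect_lte(shell_protofibril_count(10, 4, 5, 0.01116),
             pi * 0.01116 * 15^2)
  expect_error(shell_protofibril_count(100, -1), "kappa")
})

test_that("binding-site concentrations scale with q and shell depth", {
  geom <- fiber_geometry()
  expect_equal(binding_sites(0, 1e17, 1e15, geom, kappa = 0), 0)
  th_tpa <- binding_sites(4e18, 1e17, 1e15, geom, geom$q_tpa, kappa = 0)
  th_pg <- binding_sites(4e18, 1e17, 1e15, geom, geom$q_pg, kappa = 0)
  expect_equal(th_pg / th_tpa, 2.4 / 1.5, tolerance = 1e-12)
  ## full-bulk vs surface ratio from the closed form, rf = 100, r0 = 5
  g5 <- fiber_geometry(r0 = 5)
  fntot <- pi * 0.01116 * 100^2 * 1e15  # rf = 100 nm at fr = 1e15
  kmax <- 100 / 5
  th_bulk <- binding_sites(4e18, fntot, 1e15, g5, kappa = kmax)
  th_surf <- binding_sites(4e18, fntot, 1e15, g5, kappa = 0)
  expect_equal(th_bulk / th_surf, 105^2 / (2 * 5 * 100 + 25),
               tolerance = 1e-9)
  expect_error(binding_sites(1, 0, 1e15), "inconsistent")
  ## the literal (sites-per-fiber) form differs by fr/N_av * 1e6
  lit <- binding_sites(4e18, 1e17, 1e15, geom, kappa = 0,
                       theta_literal = TRUE)
  expect_equal(lit * 1e15 / 6.02214076e23 * 1e6, th_tpa, tolerance = 1e-12)
})

test_that("binding kinetics respect their limiting regimes", {
  r <- binding_rates()
  b <- c(tpa = 1e-5, tpa_b = 0, pg = 0.1, pg_b = 0, pai1 = 2e-4, pn_b = 0)
  ## no fibers: only inhibition and desorption act
  d <- binding_rhs(b, 0, 0, r)
  expect_equal(d[["tpa"]], -r$ki_tpa_pai * 1e-5 * 2e-4)
  expect_equal(d[["pg"]], 0)
  expect_equal(d[["pg_b"]], 0)
  ## saturation fixed point: without PAI-1, desorption and activation,
  ## bound tPA relaxes to Theta
  b2 <- c(tpa = 1e-3, tpa_b = 0.5, pg = 0, pg_b = 0, pai1 = 0, pn_b = 0)
  d2 <- binding_rhs(b2, theta_tpa = 0.5, theta_pg = 1, r)
  expect_equal(d2[["tpa_b"]], -r$kr_tpa * 0.5)  # only desorption remains
  b3 <- c(tpa = 10, tpa_b = 0.2, pg = 0, pg_b = 0, pai1 = 0, pn_b = 0)
  d3 <- binding_rhs(b3, theta_tpa = 0.5, theta_pg = 1, r)
  expect_gt(d3[["tpa_b"]], 0)                   # below Theta: net adsorption
})

test_that("total tPA mass is conserved through binding and inhibition", {
  cs <- control_clot_state()
  tc <- cs$timecourse
  total <- tc$tpa + tc$tpa_b + tc$tpa_i
  expect_equal(total, rep(cs$initial[["tpa"]], nrow(tc)), tolerance = 1e-8)
})

test_that("clot formation reproduces the control-state geometry and binding", {
  cs <- control_clot_state()
  expect_gt(cs$incorporation, 0.8)
  expect_true(cs$rf0 > 20 && cs$rf0 < 200)
  ## bound tPA about 2% of the initial tPA with the best-ranked rates
  frac <- cs$binding[["tpa_b"]] / cs$initial[["tpa"]]
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.03)
  ## bound pools never exceed their capacities along the run
  tc <- cs$timecourse
  for (i in seq(1, nrow(tc), by = 10)) {
    if (tc$fntot[i] <= 0 || tc$fr[i] <= 0) next
    th_t <- binding_sites(tc$cfr[i], tc$fntot[i], tc$fr[i], cs$geometry,
                          cs$geometry$q_tpa, kappa = 0)
    th_p <- binding_sites(tc$cfr[i], tc$fntot[i], tc$fr[i], cs$geometry,
                          cs$geometry$q_pg, kappa = 0)
    expect_lte(tc$tpa_b[i], th_t + 1e-9)
    expect_lte(tc$pg_b[i] + tc$pn_b[i], th_p + 1e-9)
  }
  ## fiber radius nondecreasing once fibers exist
  rf <- with(tc, ifelse(fr > 0 & fntot > 0, sqrt((fntot / fr) / (pi * 0.01116)), NA))
  rf <- rf[!is.na(rf) & tc$time > 100]
  expect_true(all(diff(rf) > -1e-9))
})

test_that("quiescent rates leave the proteins to PAI-1 only", {
  cs0 <- run_clot_formation(control_conditions(),
                            poly_rates = polymerization_rates(
                              kA = 0, kPI = 0, kPG = 0, kFI = 0, kFG = 0,
                              kFA = 0))
  expect_true(is.na(cs0$rf0))
  expect_equal(cs0$theta_tpa, 0)
  expect_equal(cs0$binding[["tpa_b"]], 0)
  expect_lt(cs0$binding[["tpa"]], cs0$initial[["tpa"]])  # inhibited away
  expect_equal(cs0$binding[["pg"]], cs0$initial[["pg"]], tolerance = 1e-8)
})

test_that("more fibrinogen means more fibrin in fibers", {
  cfr <- vapply(c(1, 2, 3, 4), function(fg) {
    run_clot_formation(list(fibrinogen = fg, tpa = 0.001, pai1 = 0.01,
                            pg = 13))$cfr0_uM
  }, numeric(1))
  expect_true(all(diff(cfr) > 0))
})
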