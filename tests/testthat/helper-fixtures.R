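## Shared fixtures, memoized across test files.
##
## Tests that exercise lysis dynamics use a clot formed with tPA boosted to
## 0.1 ug/mL (100x the control assay): plasmin generation scales with bound
## tPA, so lysis completes in ~20 simulated minutes instead of many hours
## while leaving every mechanism (binding, activation, shell geometry,
## porosity coupling) untouched.

.fixture_cache <- new.env(parent = emptyenv())

memoized <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

## control assay concentrations (fibrinogen mg/mL, others ug/mL)
control_conditions <- function() {
  list(fibrinogen = 3, tpa = 0.001, pai1 = 0.01, pg = 13)
}

control_clot_state <- function() {
  memoized("control_clot", run_clot_formation(control_conditions()))
}

fast_clot_state <- function() {
  memoized("fast_clot",
           run_clot_formation(list(fibrinogen = 3, tpa = 0.1,
                                   pai1 = 0.01, pg = 13)))
}

## fast clot with pre-formed bound plasmin: makes the shell candidates
## distinguishable from the first optimizer step
fast_clot_state_with_plasmin <- function(pn_b = 1e-4) {
  cs <- fast_clot_state()
  cs$binding[["pn_b"]] <- pn_b
  cs
}

## a valid random polymerization state (molecules/L)
random_poly_state <- function(scale = 1e18) {
  nm <- c("fa", paste0("f", 1:10), "fn", "fr", "fntot", "cfn", "cfr")
  stats::setNames(stats::runif(length(nm), 0, scale), nm)
}

## Independent reaction-by-reaction oracle for the polymerization cascade:
## every elementary reaction is listed with its rate and its per-species
## stoichiometric change (fibrin carried by a protofibril is cfn/fn per
## protofibril).  Summing rate * delta over reactions rebuilds the full
## derivative vector without the telescoped algebra of the closed form.
poly_rhs_oracle <- function(state, rates) {
  f <- unname(state[paste0("f", 1:10)])
  fn <- state[["fn"]]; fr <- state[["fr"]]; cfn <- state[["cfn"]]
  d <- stats::setNames(numeric(length(state)), names(state))
  add <- function(rate, deltas) {
    for (sp in names(deltas)) d[[sp]] <<- d[[sp]] + rate * deltas[[sp]]
  }
  ## fibrinopeptide cleavage: fa -> f1
  add(rates$kA * state[["fa"]], c(fa = -1, f1 = 1))
  ## chain elongation: f1 + fj -> f(j+1), j = 1..9 (j = 1 consumes two f1)
  add(rates$kPI * f[1] * f[1], c(f1 = -2, f2 = 1))
  for (j in 2:9) {
    deltas <- stats::setNames(c(-1, -1, 1),
                              c("f1", paste0("f", j), paste0("f", j + 1)))
    add(rates$kPI * f[1] * f[j], deltas)
  }
  ## protofibril creation: f1 + f10 -> protofibril of 11 monomers
  add(rates$kPI * f[1] * f[10], c(f1 = -1, f10 = -1, fn = 1, cfn = 11))
  ## protofibril elongation: f1 + fn -> fn (one more monomer in cfn)
  add(rates$kPG * f[1] * fn, c(f1 = -1, cfn = 1))
  mass_per_proto <- if (fn > 0) cfn / fn else 0
  ## fiber initiation: fn + fn -> fr
  add(rates$kFI * fn * fn,
      c(fn = -2, fr = 1, fntot = 2, cfn = -2 * mass_per_proto,
        cfr = 2 * mass_per_proto))
  ## fiber growth: fr + fn -> fr
  add(rates$kFG * fr * fn,
      c(fn = -1, fntot = 1, cfn = -mass_per_proto, cfr = mass_per_proto))
  ## fiber-fiber aggregation: fr + fr -> fr (books one protofibril in)
  add(rates$kFA * fr * fr, c(fr = -1, fntot = 1))
  d
}
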