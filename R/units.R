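#' @keywords internal
"_PACKAGE"

## Avogadro's number, mol^-1
N_AVOGADRO <- 6.02214076e23

#' Default molecular weights (kDa)
#'
#' Literature-standard molecular weights used to convert between laboratory
#' mass concentrations and molar concentrations. All values are configurable:
#' pass a modified copy to [convert_units()] or to the simulation front-ends.
#'
#' @return Named numeric vector of molecular weights in kDa for
#'   `fibrinogen`, `tpa`, `pg` (plasminogen), `pai1` and `plasmin`.
#' @export
#' @examples
#' default_molecular_weights()
default_molecular_weights <- function() {
  c(fibrinogen = 340, tpa = 68, pg = 92, pai1 = 43, plasmin = 85)
}

#' Convert protein concentrations between unit systems
#'
#' Converts between laboratory mass units (`mg_ml`, `ug_ml`), micromolar
#' (`uM`) and number density (`molecules_l`). Conversions go through the
#' molar concentration, so round-trips are exact to floating-point precision.
#'
#' @param value Numeric vector of concentrations.
#' @param from,to One of `"mg_ml"`, `"ug_ml"`, `"uM"`, `"molecules_l"`.
#' @param species Species name used to look up the molecular weight; required
#'   whenever the conversion crosses between mass and molar/number units.
#' @param mw Named vector of molecular weights in kDa
#'   (default [default_molecular_weights()]).
#' @return Numeric vector in the target units.
#' @export
#' @examples
#' convert_units(3, "mg_ml", "uM", "fibrinogen")  # ~8.82 uM
convert_units <- function(value, from, to, species = NULL,
                          mw = default_molecular_weights()) {
  units <- c("mg_ml", "ug_ml", "uM", "molecules_l")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(value)

  mass <- c("mg_ml", "ug_ml")
  if (from %in% mass && to %in% mass) {
    return(value * if (from == "mg_ml") 1e3 else 1e-3)
  }
  w <- NA_real_
  if (from %in% mass || to %in% mass) {
    if (is.null(species) || !(species %in% names(mw)))
      stop("unknown species '", species, "': no molecular weight available")
    w <- mw[[species]] * 1000  # g/mol
  }

  ## to molar (M)
  molar <- switch(from,
    mg_ml = (value * 1) / w,          # mg/mL = g/L; g/L / (g/mol) = mol/L
    ug_ml = (value * 1e-3) / w,       # ug/mL = mg/L
    uM = value * 1e-6,
    molecules_l = value / N_AVOGADRO
  )
  switch(to,
    mg_ml = molar * w,
    ug_ml = molar * w * 1e3,
    uM = molar * 1e6,
    molecules_l = molar * N_AVOGADRO
  )
}
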