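#' Standard atomic weight of cadmium
#'
#' Molar mass used for all mass/molar concentration conversions involving
#' cadmium, in g/mol.  Every conversion function takes a `molar_mass`
#' argument defaulting to this constant, so a different value (e.g. for an
#' isotopically enriched spike) can be supplied without touching the code.
#'
#' @export
cd_molar_mass <- 112.41

.conc_units <- c("mg_per_kg", "mg_per_L", "mM", "uM", "M")

#' Convert between concentration units
#'
#' Converts solution concentrations among mg/L, mM, uM and M.  Mass/molar
#' conversions require the molar mass of the solute.  `mg_per_kg` (mass of
#' metal per dry soil mass) has no defined conversion path to any solution
#' unit here because it depends on the solution volume basis; use
#' [added_cd_to_solution()] for the dose-to-solution step.
#'
#' @param value numeric vector of concentrations.
#' @param from,to unit names, one of `"mg_per_kg"`, `"mg_per_L"`, `"mM"`,
#'   `"uM"`, `"M"`.
#' @param molar_mass solute molar mass in g/mol; defaults to [cd_molar_mass].
#' @return numeric vector in the target unit.
#' @examples
#' convert_conc(2155, "mg_per_L", "mM")  # ~19.2 mM Cd
#' convert_conc(1, "mM", "uM")           # 1000
#' @export
convert_conc <- function(value, from, to, molar_mass = cd_molar_mass) {
  from <- match.arg(from, .conc_units)
  to <- match.arg(to, .conc_units)
  stopifnot(is.numeric(value), is.numeric(molar_mass), molar_mass > 0)
  if (from == to) {
    return(value)
  }
  if (from == "mg_per_kg" || to == "mg_per_kg") {
    stop("unsupported conversion: 'mg_per_kg' has no solution-volume basis; ",
         "use added_cd_to_solution() for the dose-to-solution step",
         call. = FALSE)
  }
  # route every conversion through mol/L
  to_molar <- switch(from,
    mg_per_L = value / molar_mass / 1000,
    mM = value / 1e3,
    uM = value / 1e6,
    M = value
  )
  switch(to,
    mg_per_L = to_molar * molar_mass * 1000,
    mM = to_molar * 1e3,
    uM = to_molar * 1e6,
    M = to_molar
  )
}
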