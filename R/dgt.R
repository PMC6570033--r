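#' DGT device configuration
#'
#' Physical constants of the diffusive gradients in thin-films (DGT)
#' sampler and the elution protocol.  Defaults are for a standard Chelex
#' sampler deployed for 24 h at 25 C with a 1 mL 1-M HNO3 elution:
#' diffusive gel 0.082 cm plus filter membrane 0.014 cm, Cd diffusion
#' coefficient in the gel 6.09e-6 cm2/s, gel volume 0.16 mL, exposure area
#' 3.14 cm2, elution factor 0.8.
#'
#' @param delta_g_gel diffusive gel thickness, cm.
#' @param delta_g_filter filter membrane thickness, cm.
#' @param D diffusion coefficient of the metal in the gel, cm2/s.
#' @param t deployment time, s.
#' @param v_hno3 eluent volume, mL.
#' @param v_gel resin gel volume, mL.
#' @param area exposure area, cm2.
#' @param f_e elution factor (fraction of resin-bound metal recovered).
#' @return list of class `dgt_config`.
#' @export
dgt_config <- function(delta_g_gel = 0.082, delta_g_filter = 0.014,
                       D = 6.09e-6, t = 86400, v_hno3 = 1, v_gel = 0.16,
                       area = 3.14, f_e = 0.8) {
  cfg <- list(delta_g_gel = delta_g_gel, delta_g_filter = delta_g_filter,
              D = D, t = t, v_hno3 = v_hno3, v_gel = v_gel,
              area = area, f_e = f_e)
  bad <- names(cfg)[!vapply(cfg, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    stop("dgt_config: field(s) must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "dgt_config")
}

#' @export
print.dgt_config <- function(x, ...) {
  cat("DGT configuration (Delta g =", x$delta_g_gel + x$delta_g_filter,
      "cm, D =", format(x$D), "cm2/s, t =", x$t, "s)\n")
  invisible(x)
}

#' Metal mass accumulated per unit sampler area
#'
#' M_DGT = C_Cd * (V_HNO3 + V_gel) / (A * f_e), with eluate concentration
#' C_Cd in ug/L and volumes in mL (converted to litres internally), giving
#' ug/cm2.
#'
#' @param c_cd measured eluate concentration, ug/L; vectorized.
#' @param cfg a [dgt_config()].
#' @return accumulated mass, ug/cm2.
#' @export
mass_accumulated <- function(c_cd, cfg = dgt_config()) {
  stopifnot(inherits(cfg, "dgt_config"))
  if (any(c_cd < 0)) stop("eluate concentration must be >= 0", call. = FALSE)
  volume_L <- (cfg$v_hno3 + cfg$v_gel) / 1000
  c_cd * volume_L / (cfg$area * cfg$f_e)
}

#' Time-averaged DGT-measured concentration
#'
#' [Cd_DGT] = M_DGT * Delta g / (D * t).  M_DGT in ug/cm2, Delta g in cm, D
#' in cm2/s and t in s give ug/cm3; the result is converted to ug/L
#' (x 1000).  The concentration is not corrected by the soil-specific
#' diffusion ratio R_diff (the distribution coefficient needed for it is
#' concentration dependent, so no single correction is defensible).
#'
#' @param m_dgt accumulated mass, ug/cm2; vectorized.
#' @param cfg a [dgt_config()].
#' @return time-averaged concentration at the sampler face, ug/L.
#' @export
dgt_concentration <- function(m_dgt, cfg = dgt_config()) {
  stopifnot(inherits(cfg, "dgt_config"))
  if (any(m_dgt < 0)) stop("accumulated mass must be >= 0", call. = FALSE)
  delta_g <- cfg$delta_g_gel + cfg$delta_g_filter
  m_dgt * delta_g / (cfg$D * cfg$t) * 1000
}

#' Eluate concentration to DGT concentration, end to end
#'
#' Composition of [mass_accumulated()] and [dgt_concentration()]; linear in
#' the eluate concentration with a constant that depends only on the device
#' configuration (0.0843 ug/L per ug/L eluate at the defaults).
#'
#' @inheritParams mass_accumulated
#' @return [Cd_DGT] in ug/L.
#' @export
cd_dgt_from_eluate <- function(c_cd, cfg = dgt_config()) {
  dgt_concentration(mass_accumulated(c_cd, cfg), cfg)
}
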