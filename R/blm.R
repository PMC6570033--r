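#' @title Biotic ligand model for cadmium in soil solution
#' @description A single-ligand, mass-action competition model.  Each
#'   cation M (Cd2+, Ca2+, Mg2+, H+) binds a common soil ligand L,
#'   `M + L <-> ML`, with affinity constant `K_M = [ML]/([M][L])` (1/M).
#'   The ligand site is divalent, so two protons occupy one site: the
#'   proton terms carry a stoichiometric factor of 2 throughout.
#'
#'   Parameters are estimated per soil in two stages from a Cd-spiking
#'   series.  Stage 1 linearizes the competition isotherm for each cation:
#'   `1/[M] = 1/[M]0 * (1 + (K_M/K_Cd) * ([Cd]0 - [Cd])/[Cd])`, an OLS
#'   straight line whose intercept gives the cation total `[M]0` and whose
#'   slope/intercept ratio gives the affinity ratio `K_M/K_Cd`.  Stage 2
#'   fits the remaining two parameters (total ligand `[L]0` and `K_Cd`) by
#'   least squares on the bound-Cd isotherm
#'   `[CdL] = [Cd][L]0 / (1/K_Cd + [Cd] + (K_Ca/K_Cd)[Ca] +
#'   (K_Mg/K_Cd)[Mg] + 2(K_H/K_Cd)[H])`, where the observed bound Cd is
#'   the added Cd minus the free Cd.  The DGT-measured concentration
#'   stands in for the free Cd ion; that equivalence is an approximation
#'   (DGT integrates all labile species).
#'
#'   All solution concentrations are handled in mM on a 100%-WHC volume
#'   basis; affinity constants are in 1/M, so dimensionless binding terms
#'   are `K * c/1000`.
#' @name blm
NULL

.blm_cations <- c("cd", "ca", "mg", "h")
.blm_stoich <- c(cd = 1, ca = 1, mg = 1, h = 2)

#' Convert a soil Cd dose to a solution concentration
#'
#' Assumes all added CdCl2 dissolves into the water added at
#' `whc_multiple` times the soil's water-holding capacity:
#' `cd_add / (whc * whc_multiple)` mg/L.  At the default multiple of 2
#' (water added at 200% WHC) the result is already on the 100%-WHC basis
#' used by the rest of the model after the measured concentrations are
#' doubled.
#'
#' @param cd_add dose, mg Cd per kg dry soil; vectorized.
#' @param whc water-holding capacity as a fraction of dry mass (L water
#'   per kg soil at 100% WHC), e.g. 0.232 for 23.2%.
#' @param whc_multiple water addition as a multiple of WHC.
#' @return solution concentration, mg/L.
#' @examples
#' added_cd_to_solution(1000, 0.232)  # 2155 mg/L
#' @export
added_cd_to_solution <- function(cd_add, whc, whc_multiple = 2) {
  if (!(whc > 0)) stop("whc must be > 0", call. = FALSE)
  if (any(cd_add < 0)) stop("cd_add must be >= 0", call. = FALSE)
  cd_add / (whc * whc_multiple)
}

#' Proton concentration from solution pH
#'
#' `[H+] = whc_multiple * 10^-pH` in M: the measured pH of the 200%-WHC
#' slurry is converted to a 100%-WHC-basis proton concentration by the
#' same doubling applied to the other cations.
#'
#' @param ph_solution measured solution pH, in (0, 14); vectorized.
#' @param whc_multiple water addition as a multiple of WHC.
#' @return proton concentration, M.
#' @export
proton_concentration <- function(ph_solution, whc_multiple = 2) {
  if (any(ph_solution <= 0 | ph_solution >= 14)) {
    stop("ph_solution must lie in (0, 14)", call. = FALSE)
  }
  whc_multiple * 10^(-ph_solution)
}

#' Biotic ligand model parameter set
#'
#' @param k_cd,k_ca,k_mg,k_h affinity constants, 1/M.
#' @param ca0,mg0,h0 total (free + ligand-bound) cation concentrations, mM.
#' @param l0 total ligand concentration, mM.
#' @return list of class `blm_parameters`; all entries must be strictly
#'   positive.
#' @export
blm_parameters <- function(k_cd, k_ca, k_mg, k_h, ca0, mg0, h0, l0) {
  p <- list(k_cd = k_cd, k_ca = k_ca, k_mg = k_mg, k_h = k_h,
            ca0 = ca0, mg0 = mg0, h0 = h0, l0 = l0)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    stop("blm_parameters must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "blm_parameters")
}

#' @export
print.blm_parameters <- function(x, ...) {
  cat("BLM parameters: K_Cd =", signif(x$k_cd, 4), "K_Ca =",
      signif(x$k_ca, 4), "K_Mg =", signif(x$k_mg, 4), "K_H =",
      signif(x$k_h, 4), "(1/M)\n  totals (mM): Ca0 =", signif(x$ca0, 4),
      "Mg0 =", signif(x$mg0, 4), "H0 =", signif(x$h0, 4), "L0 =",
      signif(x$l0, 4), "\n")
  invisible(x)
}

.spiked_rows_for_stage <- function(obs) {
  keep <- obs$cd_add > 0 & obs$cd_dgt > 0
  obs[keep, , drop = FALSE]
}

#' Stage-1 cation fit
#'
#' OLS of `1/[cation]` on `x = ([Cd]0 - [Cd])/[Cd]` over the spiked levels
#' of one soil, where `[Cd]0` is the added Cd as a solution concentration
#' (mM) and `[Cd]` is the DGT-measured free Cd (converted from uM to mM).
#' The intercept estimates `1/[M]0` and the slope/intercept ratio
#' estimates `K_M/K_Cd`.  Zero-addition rows are excluded (x is 0/0
#' there).
#'
#' A fit with non-positive intercept or slope has no physical parameter
#' interpretation; it is returned with `admissible = FALSE` and `NA`
#' derived parameters rather than raised, so that a screening loop over
#' soils can proceed.
#'
#' @param obs spiked observations for a single soil: columns `cd_add`,
#'   `cd_add_solution` (mM), `cd_dgt` (uM), and the cation columns `ca`,
#'   `mg`, `h` (mM).
#' @param cation one of `"ca"`, `"mg"`, `"h"`.
#' @return object of class `blm_stage1`: `slope`, `intercept`, `total0`
#'   (mM), `k_ratio` (`K_cation/K_Cd`), `n_points`, `admissible`.
#' @export
stage1_cation_fit <- function(obs, cation = c("ca", "mg", "h")) {
  cation <- match.arg(cation)
  d <- .spiked_rows_for_stage(obs)
  if (nrow(d) < 2) {
    stop("stage 1 needs >= 2 spiked observations with positive cd_dgt",
         call. = FALSE)
  }
  cd_free <- convert_conc(d$cd_dgt, "uM", "mM")
  x <- (d$cd_add_solution - cd_free) / cd_free
  y <- 1 / d[[cation]]
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  admissible <- is.finite(b[1]) && is.finite(b[2]) && b[1] > 0 && b[2] > 0
  # the proton line has slope 2*K_H/K_Cd (two protons occupy one divalent
  # site), so the stoichiometric factor is divided out of the ratio
  s <- .blm_stoich[[cation]]
  structure(list(
    cation = cation,
    slope = unname(b[2]),
    intercept = unname(b[1]),
    total0 = if (admissible) unname(1 / b[1]) else NA_real_,
    k_ratio = if (admissible) unname(b[2] / b[1] / s) else NA_real_,
    n_points = nrow(d),
    admissible = admissible,
    lm = fit
  ), class = "blm_stage1")
}

# Bound Cd predicted by the competition isotherm; two algebraically
# identical forms kept separate so tests can assert their equivalence.
# Concentrations in mM, affinity constants in 1/M.
.cdl_ratio_form <- function(cd, ca, mg, h, k_cd, r_ca, r_mg, r_h, l0) {
  cd * l0 / (1000 / k_cd + cd + r_ca * ca + r_mg * mg + 2 * r_h * h)
}

.cdl_direct_form <- function(cd, ca, mg, h, k_cd, k_ca, k_mg, k_h, l0) {
  k_cd / 1000 * cd * l0 /
    (1 + (k_cd * cd + k_ca * ca + k_mg * mg + 2 * k_h * h) / 1000)
}

#' Stage-2 fit of total ligand and the cadmium affinity constant
#'
#' Minimizes the sum of squared differences between the observed bound Cd,
#' `[CdL] = [Cd]0 - [Cd]`, and the competition-isotherm prediction over
#' the spiked levels, with the stage-1 affinity ratios held fixed.
#' Positivity of both parameters is enforced by optimizing on the log10
#' scale; a coarse log-space grid scan supplies the starting point for a
#' Nelder-Mead refinement, making the optimum deterministic for a given
#' configuration.
#'
#' @param obs spiked observations for one soil (as in
#'   [stage1_cation_fit()]).
#' @param k_ratios named numeric, affinity ratios `K_M/K_Cd` for `ca`,
#'   `mg`, `h`.
#' @param weights residual weighting: `"none"` (default, plain squared
#'   error), `"relative"` (residuals divided by the observed [CdL]; the
#'   spiked levels span four orders of magnitude, so relative weighting
#'   prevents the top level from dominating), or `"inverse_cd"` (residuals
#'   divided by the free Cd concentration -- the inverse-variance choice
#'   when measurement error is proportional to the measured free-ion
#'   concentration, as it is for multiplicative instrument noise).
#' @param grid_points grid resolution per parameter for the initial scan.
#' @param l0_range,k_cd_range log10 search ranges (mM and 1/M).
#' @return object of class `blm_stage2`: `l0` (mM), `k_cd` (1/M),
#'   `objective`, `convergence` (0 = converged), `identifiable` (`FALSE`,
#'   with a warning, when fewer levels than parameters).
#' @export
stage2_fit <- function(obs, k_ratios,
                       weights = c("none", "relative", "inverse_cd"),
                       grid_points = 60, l0_range = c(-3, 3),
                       k_cd_range = c(0, 7)) {
  weights <- match.arg(weights)
  stopifnot(all(c("ca", "mg", "h") %in% names(k_ratios)))
  d <- .spiked_rows_for_stage(obs)
  if (nrow(d) < 1) stop("no usable spiked observations", call. = FALSE)
  identifiable <- nrow(d) >= 2
  if (!identifiable) {
    warning("only one spiked level for two free parameters; the optimum ",
            "is not identifiable", call. = FALSE)
  }
  cd_free <- convert_conc(d$cd_dgt, "uM", "mM")
  cdl_obs <- d$cd_add_solution - cd_free
  w <- switch(weights,
    none = rep(1, length(cdl_obs)),
    relative = 1 / pmax(abs(cdl_obs), 1e-12),
    inverse_cd = 1 / pmax(cd_free, 1e-12))

  objective <- function(par) {  # par = log10(l0), log10(k_cd)
    pred <- .cdl_ratio_form(cd_free, d$ca, d$mg, d$h,
                            k_cd = 10^par[2],
                            r_ca = k_ratios[["ca"]], r_mg = k_ratios[["mg"]],
                            r_h = k_ratios[["h"]], l0 = 10^par[1])
    sum((w * (cdl_obs - pred))^2)
  }

  grid_l0 <- seq(l0_range[1], l0_range[2], length.out = grid_points)
  grid_k <- seq(k_cd_range[1], k_cd_range[2], length.out = grid_points)
  vals <- outer(grid_l0, grid_k,
                Vectorize(function(a, b) objective(c(a, b))))
  start_idx <- arrayInd(which.min(vals), dim(vals))
  start <- c(grid_l0[start_idx[1]], grid_k[start_idx[2]])

  opt <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("stage-2 optimization did not converge (code ", opt$convergence,
         ") after 2000 iterations; objective = ", opt$value, call. = FALSE)
  }
  structure(list(
    l0 = 10^opt$par[1],
    k_cd = 10^opt$par[2],
    objective = opt$value,
    convergence = opt$convergence,
    n_levels = nrow(d),
    identifiable = identifiable,
    weights = weights
  ), class = "blm_stage2")
}

#' Two-stage biotic ligand model fit for one soil
#'
#' Runs [stage1_cation_fit()] for Ca, Mg and H, then [stage2_fit()], and
#' assembles the full parameter set (absolute affinity constants are the
#' stage-1 ratios times the stage-2 `K_Cd`).
#'
#' @inheritParams stage2_fit
#' @param ... passed on to [stage2_fit()].
#' @return list of class `blm_fit`: `parameters` (a [blm_parameters()]),
#'   `stage1` (per-cation fits), `stage2`.
#' @export
fit_blm <- function(obs, weights = c("none", "relative", "inverse_cd"),
                    ...) {
  weights <- match.arg(weights)
  stage1 <- lapply(stats::setNames(nm = c("ca", "mg", "h")),
                   function(ct) stage1_cation_fit(obs, ct))
  inadmissible <- names(stage1)[!vapply(stage1, `[[`, logical(1),
                                        "admissible")]
  if (length(inadmissible) > 0) {
    stop("stage-1 fit inadmissible (non-positive slope or intercept) for: ",
         paste(inadmissible, collapse = ", "), call. = FALSE)
  }
  k_ratios <- vapply(stage1, `[[`, numeric(1), "k_ratio")
  totals <- vapply(stage1, `[[`, numeric(1), "total0")
  stage2 <- stage2_fit(obs, k_ratios, weights = weights, ...)
  params <- blm_parameters(
    k_cd = stage2$k_cd,
    k_ca = k_ratios[["ca"]] * stage2$k_cd,
    k_mg = k_ratios[["mg"]] * stage2$k_cd,
    k_h = k_ratios[["h"]] * stage2$k_cd,
    ca0 = totals[["ca"]], mg0 = totals[["mg"]], h0 = totals[["h"]],
    l0 = stage2$l0)
  structure(list(parameters = params, stage1 = stage1, stage2 = stage2),
            class = "blm_fit")
}

#' @export
print.blm_fit <- function(x, ...) {
  cat("Two-stage biotic ligand model fit (", x$stage2$n_levels,
      " spiked levels; stage-2 objective ", signif(x$stage2$objective, 4),
      ")\n", sep = "")
  print(x$parameters)
  invisible(x)
}

#' Solve the multi-cation speciation equilibrium
#'
#' Given total concentrations of Cd, Ca, Mg and H and a parameter set,
#' finds the free ligand concentration `[L]` from the ligand balance
#' `l0 = [L] * (1 + sum_i s_i K_i [M_i])` with
#' `[M_i] = total_i / (1 + s_i K_i [L])` and stoichiometric factor
#' `s = 2` for the proton, 1 otherwise.  The balance is strictly
#' increasing in `[L]`, zero at 0 and at least `l0` at `[L] = l0`, so the
#' root is bracketed in `(0, l0]` and located by [stats::uniroot()] to
#' near machine precision.
#'
#' @param totals named numeric: total concentrations `cd`, `ca`, `mg`,
#'   `h` in mM (non-negative).
#' @param params a [blm_parameters()]; its `ca0`, `mg0`, `h0` fields are
#'   ignored here (the `totals` argument governs), only the affinity
#'   constants and `l0` are used.
#' @param tol relative convergence tolerance for the root.
#' @return object of class `speciation`: `free`, `bound` (named mM
#'   vectors over the four cations, `free + bound = total`), and
#'   `free_ligand` (mM).
#' @export
speciate <- function(totals, params, tol = 1e-12) {
  stopifnot(inherits(params, "blm_parameters"))
  if (!all(.blm_cations %in% names(totals))) {
    stop("totals must be named with: ", paste(.blm_cations, collapse = ", "),
         call. = FALSE)
  }
  totals <- unlist(totals)[.blm_cations]
  if (any(totals < 0)) stop("totals must be >= 0", call. = FALSE)
  k <- c(cd = params$k_cd, ca = params$k_ca, mg = params$k_mg,
         h = params$k_h)
  s <- .blm_stoich
  l0 <- params$l0

  free_at <- function(L) totals / (1 + s * k * L / 1000)
  balance <- function(L) L * (1 + sum(s * k * free_at(L) / 1000)) - l0

  if (balance(l0) < -l0 * 1e-9) {
    stop("speciation solver: ligand balance root not bracketed in (0, l0]; ",
         "balance(l0) = ", balance(l0), call. = FALSE)
  }
  root <- stats::uniroot(balance, interval = c(0, l0), tol = l0 * tol,
                         extendInt = "no")
  L <- root$root
  free <- free_at(L)
  structure(list(
    free = free,
    bound = totals - free,
    free_ligand = L,
    totals = totals
  ), class = "speciation")
}

#' @export
print.speciation <- function(x, digits = 4, ...) {
  cat("Speciation state (mM): free ligand =", signif(x$free_ligand, digits),
      "\n")
  print(round(rbind(total = x$totals, free = x$free, bound = x$bound),
              digits))
  invisible(x)
}

#' Predict free Cd across addition levels and compare with observation
#'
#' Runs [speciate()] at each total Cd level with the parameter set's own
#' cation totals, and, when observations are supplied, reports the
#' observed/predicted ratio and whether each level falls within a factor
#' of 2 (the conventional goodness band for speciation models).  Levels
#' with a missing observation are kept in the output with `NA` comparison
#' columns and counted in the `n_skipped` attribute.
#'
#' @param params a [blm_parameters()].
#' @param cd0 total Cd concentrations, mM (e.g. the spiking series
#'   converted by [added_cd_to_solution()] and [convert_conc()]).
#' @param observed optional observed free Cd at the same levels, uM
#'   (typically the DGT-measured concentration).
#' @return data frame: `cd0_mM`, `free_cd_uM`, and with observations
#'   `observed_uM`, `ratio` (observed/predicted), `within_factor_2`.
#' @export
predict_free_cd <- function(params, cd0, observed = NULL) {
  free <- vapply(cd0, function(c0) {
    sp <- speciate(c(cd = c0, ca = params$ca0, mg = params$mg0,
                     h = params$h0), params)
    sp$free[["cd"]]
  }, numeric(1))
  out <- data.frame(cd0_mM = cd0,
                    free_cd_uM = convert_conc(free, "mM", "uM"))
  if (!is.null(observed)) {
    stopifnot(length(observed) == length(cd0))
    ratio <- observed / out$free_cd_uM
    out$observed_uM <- observed
    out$ratio <- ratio
    out$within_factor_2 <- ifelse(is.finite(ratio),
                                  ratio >= 0.5 & ratio <= 2, NA)
    attr(out, "n_skipped") <- sum(!is.finite(ratio))
  }
  out
}
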