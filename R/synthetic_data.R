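#' @title Synthetic soil and spiking data
#' @description Generators that emulate the statistical structure of the
#'   study design: a soil-property table whose four soil types and
#'   two-factor correlation pattern mirror the field data, dose-response
#'   observations following the interaction regression model, and
#'   equilibrium cation-exchange observations produced by the forward
#'   speciation solver from a known biotic ligand parameterization.  Every
#'   generator is deterministic given its configuration, so fitted
#'   estimates can be compared against known truth in tests.
#' @name synthetic_data
NULL

#' Default biotic ligand model truth per soil type
#'
#' Reads the per-type parameter presets shipped with the package
#' (`blm_type_presets.yaml`).
#'
#' @return named list of [blm_parameters()], one per soil type.
#' @export
default_blm_truth <- function() {
  raw <- yaml::read_yaml(cadsoil_file("blm_type_presets.yaml"))
  lapply(raw, function(p) do.call(blm_parameters, p))
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 17 soils split 5 sandy, 4
#' andosol, 3 brown-forest and 5 cohesive; spiking design 1.5, 15, 150 and
#' 1000 mg/kg; regression truth equal to the fitted interaction-model
#' coefficients; residual noise 0.2 log10 units; 5% CV multiplicative
#' noise on simulated concentrations.
#'
#' @param seed integer seed recorded in, and governing, every generator.
#' @param n_soils_per_type named counts for the four soil types.
#' @param regression_truth named coefficients `b1_cec`, `b2_ph`,
#'   `b3_logcd`, `b4_interaction`, `intercept` of the interaction model.
#' @param noise_sd_log10 SD of the additive Gaussian noise on
#'   log10 [Cd_DGT].
#' @param blm_truth named list of [blm_parameters()] per soil type.
#' @param cd_levels spiking doses, mg/kg (strictly positive).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise on simulated solution concentrations.
#' @param whc water-holding capacity (fraction) used for dose-to-solution
#'   conversion in the spiking simulation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_soils_per_type = c(sandy = 5, andosol = 4,
                                            brown_forest = 3, cohesive = 5),
                       regression_truth = c(b1_cec = -0.041, b2_ph = -0.655,
                                            b3_logcd = 0.562,
                                            b4_interaction = 0.147,
                                            intercept = 4.364),
                       noise_sd_log10 = 0.2,
                       blm_truth = default_blm_truth(),
                       cd_levels = c(1.5, 15, 150, 1000),
                       noise_cv = 0.05,
                       whc = 0.232) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (any(n_soils_per_type < 0) || sum(n_soils_per_type) < 1) {
    stop("need at least one soil overall and no negative type counts",
         call. = FALSE)
  }
  if (noise_sd_log10 < 0 || noise_cv < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  need <- c("b1_cec", "b2_ph", "b3_logcd", "b4_interaction", "intercept")
  if (!all(need %in% names(regression_truth))) {
    stop("regression_truth must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_soils_per_type = n_soils_per_type,
                 regression_truth = regression_truth,
                 noise_sd_log10 = noise_sd_log10,
                 blm_truth = blm_truth,
                 cd_levels = cd_levels,
                 noise_cv = noise_cv,
                 whc = whc),
            class = "sim_config")
}

.type_prefix <- c(sandy = "S", andosol = "A", brown_forest = "B",
                  cohesive = "C")

# latent factor means per type: f1 = sorption/organic axis (CEC, WHC,
# AREA, total C, ignition loss), f2 = coarseness axis (sand, pH vs clay)
.type_latent_mean <- list(sandy = c(-1.2, 1.2),
                          andosol = c(1.5, -0.2),
                          brown_forest = c(-0.1, -1.0),
                          cohesive = c(0.5, -0.3))

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic soil-property table
#'
#' Draws each soil's properties from a common two-latent-factor model with
#' type-specific factor means, then clips to physical ranges and
#' renormalizes the texture fractions to sum to 100.  The construction
#' reproduces the qualitative correlation pattern of the field data
#' (CEC-WHC strongly positive, pH-sand positive, CEC-pH negative across
#' types) and the type contrasts (sandy: high sand, low CEC, high pH;
#' andosol: high CEC, organic-rich; cohesive: intermediate, clay-rich).
#'
#' @param cfg a [sim_config()].
#' @return a `soil_table` passing [validate_soil_table()], with the seed
#'   recorded in the `"seed"` attribute.
#' @export
generate_soil_table <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (sum(cfg$n_soils_per_type) < 1) stop("no soils requested", call. = FALSE)
  set.seed(cfg$seed)
  rows <- list()
  for (type in names(cfg$n_soils_per_type)) {
    n <- cfg$n_soils_per_type[[type]]
    if (n == 0) next
    mu <- .type_latent_mean[[type]]
    f1 <- stats::rnorm(n, mu[1], 0.5)
    f2 <- stats::rnorm(n, mu[2], 0.5)
    cec <- exp(2.3 + 1.0 * f1 + stats::rnorm(n, 0, 0.15))
    whc <- .clip(52 + 22 * f1 - 6 * f2 + stats::rnorm(n, 0, 5), 12, 130)
    ph <- .clip(5.7 - 0.35 * f1 + 0.55 * f2 + stats::rnorm(n, 0, 0.25),
                3.5, 8.5)
    total_c <- .clip(exp(0.4 + 1.2 * f1) - 0.5 + stats::rnorm(n, 0, 0.3),
                     0, 12)
    ignition_loss <- .clip(1.5 + 2.0 * total_c + stats::rnorm(n, 0, 1),
                           0.2, 30)
    area <- .clip(50 + 18 * f1 - 10 * f2 + stats::rnorm(n, 0, 8), 5, 130)
    sand <- .clip(48 + 28 * f2 - 10 * f1 + stats::rnorm(n, 0, 6), 1, 99)
    clay <- .clip(25 - 12 * f2 + 4 * f1 + stats::rnorm(n, 0, 6), 0.5, 70)
    silt <- .clip(100 - sand - clay, 0.5, 98)
    total <- sand + silt + clay
    rows[[type]] <- data.frame(
      sample_id = sprintf("%s-%d", .type_prefix[[type]], seq_len(n)),
      location = "synthetic",
      sand = 100 * sand / total, silt = 100 * silt / total,
      clay = 100 * clay / total,
      cec = cec, area = area, whc = whc, ph = ph, total_c = total_c,
      ignition_loss = ignition_loss, soil_type = type,
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d$soil_type <- .normalize_soil_type(d$soil_type)
  validate_soil_table(d)
  attr(d, "seed") <- cfg$seed
  class(d) <- c("soil_table", "data.frame")
  d
}

#' Generate dose-response observations from the interaction model
#'
#' For every soil x addition level, draws
#' `log10(cd_dgt) = b1*cec + b2*ph + b3*log10(cd_add) +
#' b4*(ph*log10(cd_add)) + intercept + N(0, noise_sd_log10)`.
#'
#' @param soils a soil table (real or from [generate_soil_table()]).
#' @param cfg a [sim_config()]; `cd_levels` must be strictly positive.
#' @return data frame with columns `sample_id`, `cec`, `ph`, `cd_add`,
#'   `cd_dgt` (ug/L); seed and truth recorded as attributes.
#' @export
generate_regression_dataset <- function(soils, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$cd_levels <= 0)) {
    stop("cd_levels must be strictly positive (the model is defined on ",
         "log10 dose)", call. = FALSE)
  }
  set.seed(cfg$seed + 1L)
  b <- cfg$regression_truth
  d <- expand.grid(sample_id = soils$sample_id, cd_add = cfg$cd_levels,
                   stringsAsFactors = FALSE)
  idx <- match(d$sample_id, soils$sample_id)
  d$cec <- soils$cec[idx]
  d$ph <- soils$ph[idx]
  lp <- b[["b1_cec"]] * d$cec + b[["b2_ph"]] * d$ph +
    b[["b3_logcd"]] * log10(d$cd_add) +
    b[["b4_interaction"]] * d$ph * log10(d$cd_add) + b[["intercept"]]
  d$cd_dgt <- 10^(lp + stats::rnorm(nrow(d), 0, cfg$noise_sd_log10))
  attr(d, "seed") <- cfg$seed
  attr(d, "truth") <- b
  d
}

#' Generate equilibrium spiking observations from a known BLM
#'
#' The independent forward model that the two-stage fitters must invert:
#' for each addition level the dose is converted to a total solution Cd
#' (mM) via [added_cd_to_solution()] and the molar mass, the speciation
#' equilibrium is solved by [speciate()] with the truth's cation totals,
#' and the free Ca, Mg, H and Cd concentrations are reported, optionally
#' perturbed by multiplicative lognormal noise with coefficient of
#' variation `noise_cv` (mean-one, so noise does not bias the level).
#'
#' @param blm_truth a [blm_parameters()].
#' @param cd_levels doses in mg/kg (may include 0: the unspiked control).
#' @param cfg a [sim_config()] supplying `whc`, `noise_cv` and the seed.
#' @return a `spiked_table` (columns as in [read_spiked_table()];
#'   `cd_dgt` in uM), with `truth` and `seed` attributes.
#' @export
generate_blm_dataset <- function(blm_truth, cd_levels = NULL,
                                 cfg = sim_config()) {
  stopifnot(inherits(blm_truth, "blm_parameters"),
            inherits(cfg, "sim_config"))
  if (is.null(cd_levels)) cd_levels <- cfg$cd_levels
  set.seed(cfg$seed + 2L)
  cd0 <- convert_conc(added_cd_to_solution(cd_levels, cfg$whc),
                      "mg_per_L", "mM")
  sp <- lapply(cd0, function(c0)
    speciate(c(cd = c0, ca = blm_truth$ca0, mg = blm_truth$mg0,
               h = blm_truth$h0), blm_truth))
  free <- t(vapply(sp, `[[`, numeric(4), "free"))
  d <- data.frame(sample_id = "SYN-1", cd_add = cd_levels,
                  cd_add_solution = cd0,
                  cd_dgt = convert_conc(free[, "cd"], "mM", "uM"),
                  ca = free[, "ca"], mg = free[, "mg"], h = free[, "h"],
                  stringsAsFactors = FALSE)
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    jitter <- function(x) x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
    for (col in c("cd_dgt", "ca", "mg", "h")) d[[col]] <- jitter(d[[col]])
  }
  attr(d, "cd_dgt_unit") <- "uM"
  attr(d, "truth") <- blm_truth
  attr(d, "seed") <- cfg$seed
  class(d) <- c("spiked_table", "data.frame")
  d
}
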