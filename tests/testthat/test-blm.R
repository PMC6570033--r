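test_that("dose-to-solution conversion reproduces the worked example", {
  # 1000 mg/kg into water at 200% of a 23.2% WHC
  expect_equal(round(added_cd_to_solution(1000, 0.232)), 2155)
  expect_equal(added_cd_to_solution(0, 0.232), 0)
  # 150 mg/kg gives ~323 mg/L, i.e. ~2.9 mM after molar conversion
  mgL <- added_cd_to_solution(150, 0.232)
  expect_equal(round(mgL), 323)
  expect_equal(round(convert_conc(mgL, "mg_per_L", "mM"), 1), 2.9)
  expect_error(added_cd_to_solution(10, 0), "whc")
})

test_that("proton concentration applies the WHC-basis factor", {
  expect_equal(proton_concentration(7), 2e-7)
  expect_equal(proton_concentration(0.0001), 2 * 10^-0.0001)
  expect_equal(proton_concentration(7, whc_multiple = 1), 1e-7)
  expect_error(proton_concentration(14.5), "\\(0, 14\\)")
})

test_that("stage-1 fit equals the closed-form two-point OLS on printed data", {
  d <- load_table3()
  s1 <- d[d$sample_id == "S-1", ]
  fit <- stage1_cation_fit(s1, "ca")
  # independent normal-equations fit on the three spiked rows
  sp <- s1[s1$cd_add > 0, ]
  cd <- sp$cd_dgt / 1000
  beta <- ols_oracle(data.frame(x = (sp$cd_add_solution - cd) / cd),
                     1 / sp$ca)
  expect_equal(fit$intercept, beta[["intercept"]], tolerance = 1e-10)
  expect_equal(fit$slope, beta[["x"]], tolerance = 1e-10)
  expect_equal(fit$total0, 1 / beta[["intercept"]], tolerance = 1e-10)
  expect_true(fit$admissible)
  expect_equal(fit$n_points, 3)
})

test_that("stage-1 inverts noiseless synthetic competition data", {
  truth <- canonical_blm_truth()
  syn <- generate_blm_dataset(truth, cfg = sim_config(seed = 3,
                                                      noise_cv = 0))
  for (ct in c("ca", "mg", "h")) {
    fit <- stage1_cation_fit(syn, ct)
    total_truth <- truth[[paste0(ct, "0")]]
    ratio_truth <- truth[[paste0("k_", ct)]] / truth$k_cd
    expect_equal(fit$total0, total_truth, tolerance = 1e-9)
    expect_equal(fit$k_ratio, ratio_truth, tolerance = 1e-9)
  }
  expect_error(stage1_cation_fit(syn[1, ], "ca"), ">= 2")
})

test_that("inadmissible stage-1 fits are flagged, not raised", {
  d <- data.frame(sample_id = "X", cd_add = c(10, 100, 1000),
                  cd_add_solution = c(0.1, 1, 10),
                  cd_dgt = c(50, 500, 5000),
                  ca = c(1, 2, 4), mg = 1, h = 1)  # 1/[Ca] falls with x
  fit <- stage1_cation_fit(d, "ca")
  expect_false(fit$admissible)
  expect_true(is.na(fit$total0))
  expect_true(is.na(fit$k_ratio))
})

test_that("the two isotherm forms are algebraically identical", {
  set.seed(99)
  for (i in 1:50) {
    k <- 10^runif(4, 0, 5)
    conc <- 10^runif(4, -4, 1)
    l0 <- 10^runif(1, -2, 2)
    a <- cadsoil:::.cdl_ratio_form(conc[1], conc[2], conc[3], conc[4],
                                   k_cd = k[1], r_ca = k[2] / k[1],
                                   r_mg = k[3] / k[1], r_h = k[4] / k[1],
                                   l0 = l0)
    b <- cadsoil:::.cdl_direct_form(conc[1], conc[2], conc[3], conc[4],
                                    k[1], k[2], k[3], k[4], l0)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("stage-2 recovers noiseless parameters and matches a grid search", {
  truth <- blm_parameters(k_cd = 2000, k_ca = 600, k_mg = 400, k_h = 150,
                          ca0 = 1, mg0 = 0.5, h0 = 0.1, l0 = 5)
  syn <- generate_blm_dataset(truth, cfg = sim_config(seed = 8,
                                                      noise_cv = 0))
  ratios <- c(ca = 600 / 2000, mg = 400 / 2000, h = 150 / 2000)
  fit <- stage2_fit(syn, ratios)
  expect_equal(fit$l0, 5, tolerance = 1e-6)
  expect_equal(fit$k_cd, 2000, tolerance = 1e-6)
  expect_equal(fit$convergence, 0)

  # brute-force 400 x 400 log grid around the admissible region
  d <- syn[syn$cd_add > 0, ]
  cd <- d$cd_dgt / 1000
  cdl <- d$cd_add_solution - cd
  obj <- function(l0, k_cd) {
    pred <- cd * l0 / (1000 / k_cd + cd + ratios[["ca"]] * d$ca +
                         ratios[["mg"]] * d$mg + 2 * ratios[["h"]] * d$h)
    sum((cdl - pred)^2)
  }
  g_l0 <- 10^seq(-1, 2, length.out = 400)
  g_k <- 10^seq(1, 5, length.out = 400)
  vals <- outer(g_l0, g_k, Vectorize(obj))
  best <- arrayInd(which.min(vals), dim(vals))
  # optimum within one grid cell of the grid-search argmin
  expect_lt(abs(log10(fit$l0) - log10(g_l0[best[1]])), 3 / 399 + 1e-9)
  expect_lt(abs(log10(fit$k_cd) - log10(g_k[best[2]])), 4 / 399 + 1e-9)
})

test_that("stage-2 warns when underdetermined", {
  truth <- canonical_blm_truth()
  syn <- generate_blm_dataset(truth, cd_levels = c(150),
                              cfg = sim_config(seed = 8, noise_cv = 0))
  expect_warning(fit <- stage2_fit(syn, c(ca = 0.3, mg = 0.3, h = 0.3)),
                 "identifiable")
  expect_false(fit$identifiable)
})

test_that("speciation closes mass balances and matches the grid oracle", {
  set.seed(21)
  for (i in 1:10) {
    params <- blm_parameters(k_cd = 10^runif(1, 2, 4.5),
                             k_ca = 10^runif(1, 1, 3.5),
                             k_mg = 10^runif(1, 1, 3.5),
                             k_h = 10^runif(1, 1, 3.5),
                             ca0 = 10^runif(1, -2, 1),
                             mg0 = 10^runif(1, -2, 1),
                             h0 = 10^runif(1, -4, 0),
                             l0 = 10^runif(1, -1, 1.2))
    totals <- c(cd = 10^runif(1, -3, 1.3), ca = params$ca0,
                mg = params$mg0, h = params$h0)
    sp <- speciate(totals, params)
    # mass balance per cation and for the ligand
    expect_equal(sp$free + sp$bound, sp$totals, tolerance = 1e-8)
    k <- c(params$k_cd, params$k_ca, params$k_mg, params$k_h)
    expect_equal(sp$free_ligand + sum(sp$bound), params$l0,
                 tolerance = 1e-8 * params$l0)
    expect_true(all(sp$free >= 0) && all(sp$bound >= 0))
    # independent grid-refinement oracle for the free ligand
    L_oracle <- speciate_grid_oracle(totals, params, n_grid = 1e5)
    expect_equal(sp$free_ligand, L_oracle, tolerance = 1e-8)
  }
})

test_that("speciation limits behave physically", {
  params <- blm_parameters(k_cd = 1e3, k_ca = 1e2, k_mg = 1e2, k_h = 1e2,
                           ca0 = 1, mg0 = 1, h0 = 0.1, l0 = 1e-10)
  totals <- c(cd = 2, ca = 1, mg = 1, h = 0.1)
  sp <- speciate(totals, params)
  expect_equal(sp$free, sp$totals, tolerance = 1e-6)

  weak <- blm_parameters(k_cd = 1e-9, k_ca = 1e-9, k_mg = 1e-9,
                         k_h = 1e-9, ca0 = 1, mg0 = 1, h0 = 0.1, l0 = 5)
  sp2 <- speciate(totals, weak)
  expect_equal(sp2$free_ligand, 5, tolerance = 1e-9)
  expect_equal(unname(sp2$bound), rep(0, 4), tolerance = 1e-9)
})

test_that("free cadmium responds monotonically to drivers", {
  base <- canonical_blm_truth()
  free_cd <- function(params, cd0) {
    speciate(c(cd = cd0, ca = params$ca0, mg = params$mg0, h = params$h0),
             params)$free[["cd"]]
  }
  # non-decreasing in total Cd
  cd0s <- 10^seq(-3, 1.3, length.out = 12)
  expect_true(all(diff(vapply(cd0s, free_cd, numeric(1),
                              params = base)) >= 0))
  set.seed(31)
  for (i in 1:15) {
    cd0 <- 10^runif(1, -2, 1)
    p_hi_l0 <- blm_parameters(base$k_cd, base$k_ca, base$k_mg, base$k_h,
                              base$ca0, base$mg0, base$h0, base$l0 * 2)
    expect_lte(free_cd(p_hi_l0, cd0), free_cd(base, cd0) + 1e-12)
    scale <- 10^runif(1, 0.1, 1)
    p_hi_ca <- blm_parameters(base$k_cd, base$k_ca * scale, base$k_mg,
                              base$k_h, base$ca0, base$mg0, base$h0,
                              base$l0)
    expect_gte(free_cd(p_hi_ca, cd0), free_cd(base, cd0) - 1e-12)
  }
})

test_that("the full two-stage fit round-trips the generator", {
  truth <- canonical_blm_truth()
  syn <- generate_blm_dataset(truth, cfg = sim_config(seed = 13,
                                                      noise_cv = 0))
  fit <- fit_blm(syn, weights = "inverse_cd")
  err <- blm_recovery_errors(fit, truth,
                             c(ca = 0.3, mg = 0.3, h = 0.3))
  expect_lt(max(err), 1e-6)
  est <- fit$parameters
  for (nm in names(est)) {
    expect_equal(est[[nm]], truth[[nm]], tolerance = 1e-5)
  }
})

test_that("forward prediction reports factor-of-2 agreement per level", {
  truth <- canonical_blm_truth()
  cfg <- sim_config(seed = 17, noise_cv = 0)
  syn <- generate_blm_dataset(truth, cfg = cfg)
  pred <- predict_free_cd(truth, syn$cd_add_solution, observed = syn$cd_dgt)
  expect_equal(pred$ratio, rep(1, nrow(pred)), tolerance = 1e-9)
  expect_true(all(pred$within_factor_2))
  # missing observations are skipped with a count, not an error
  obs <- syn$cd_dgt
  obs[2] <- NA
  pred2 <- predict_free_cd(truth, syn$cd_add_solution, observed = obs)
  expect_equal(attr(pred2, "n_skipped"), 1)
  expect_true(is.na(pred2$within_factor_2[2]))
})

test_that("published-scale parameters give finite positive predictions", {
  # forward solver driven by a fitted-parameter table of the field study:
  # sandy-soil row, four spiking levels
  params <- blm_parameters(k_cd = 2387.81, k_ca = 24.48, k_mg = 23.66,
                           k_h = 38.71, ca0 = 2.24, mg0 = 1.04,
                           h0 = 0.00037, l0 = 11.14)
  d <- load_table3()
  s1 <- d[d$sample_id == "S-1" & d$cd_add > 0, ]
  pred <- predict_free_cd(params, s1$cd_add_solution,
                          observed = s1$cd_dgt)
  expect_true(all(is.finite(pred$free_cd_uM)))
  expect_true(all(pred$free_cd_uM > 0))
})
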