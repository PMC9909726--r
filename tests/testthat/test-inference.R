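# Constrained and unconstrained fitting, identifiability diagnostics, and
# species calibration.

human_ref <- function() species_reference("human")

shared_f_albumin <- function() {
  physiological_params(0.167, 0.73, 0.73, 0.87, 2.00, 2800, 3640, 1120)
}

test_that("noiseless albumin data return the generating parameters", {
  truth <- shared_f_albumin()
  des <- make_design("iv_bolus", "albumin")
  obs <- generate_dataset(truth, des$schedule, des$sample_times,
                          noise_spec(cv = 0))
  fit <- fit_protein(obs, human_ref())
  expect_lt(abs(fit$estimates$Cl_p - 0.167) / 0.167, 1e-6)
  expect_lt(abs(fit$estimates$f_1 - 0.73) / 0.73, 1e-6)
  expect_true(fit$converged)
  expect_false(any(fit$bound_hit))
})

test_that("clearance-only refits recover only the clearance change", {
  ref <- human_ref()
  f_mab <- c(0.367, 0.361)
  sched <- dose_schedule("plasma", "bolus", 1)
  tt <- 10^seq(1, log10(120000), length.out = 14)
  make_obs <- function(clp) {
    pp <- physiological_params(clp, f_mab[1], f_mab[2], 0.87, 2.00,
                               2800, 3640, 1120)
    generate_dataset(pp, sched, tt, noise_spec(cv = 0))
  }
  fit1 <- fit_protein(make_obs(0.132), ref, mode = "clp_only", fixed_f = f_mab)
  expect_lt(abs(fit1$estimates$Cl_p - 0.132) / 0.132, 1e-6)
  # second protein, identical structure, different clearance
  fit2 <- fit_protein(make_obs(0.23), ref, mode = "clp_only", fixed_f = f_mab)
  expect_lt(abs(fit2$estimates$Cl_p - 0.23) / 0.23, 1e-6)
  expect_identical(fit1$estimates$f_1, fit2$estimates$f_1)
})

test_that("optimiser beats a brute-force grid on a noisy replicate", {
  truth <- shared_f_albumin()
  des <- make_design("iv_bolus", "albumin", n_samples = 12)
  obs <- generate_dataset(truth, des$schedule, des$sample_times,
                          noise_spec(cv = 0.10, seed = 303))
  fit <- fit_protein(obs, human_ref())
  loss_at <- function(clp, f) {
    pp <- physiological_params(clp, f, f, 0.87, 2.00, 2800, 3640, 1120)
    pred <- protpk:::.predict_obs(obs, pp)
    sum((log(pred) - log(obs$concentration))^2)
  }
  cls <- 10^seq(log10(0.02), log10(1.5), length.out = 15)
  fs <- seq(0.15, 1, length.out = 15)
  grid <- outer(cls, fs, Vectorize(loss_at))
  expect_lte(fit$loss, min(grid) + 1e-10)
  # and sits at a local minimum: small perturbations only increase the loss
  for (d in list(c(1.03, 1), c(1 / 1.03, 1), c(1, 1.03), c(1, 1 / 1.03))) {
    expect_gte(loss_at(fit$estimates$Cl_p * d[1],
                       min(fit$estimates$f_1 * d[2], 1)), fit$loss)
  }
})

test_that("noisy replicates recover parameters within the study thresholds", {
  truth <- shared_f_albumin()
  des <- make_design("iv_bolus", "albumin", n_samples = 12)
  obs <- generate_dataset(truth, des$schedule, des$sample_times,
                          noise_spec(cv = 0.10, seed = 71), n_replicates = 5)
  errs <- sapply(1:5, function(r) {
    f <- fit_protein(one_replicate(obs, r), human_ref())
    c(cl = abs(f$estimates$Cl_p - 0.167) / 0.167,
      f = abs(f$estimates$f_1 - 0.73) / 0.73)
  })
  expect_lt(stats::median(errs["cl", ]), 0.10)
  expect_lt(stats::median(errs["f", ]), 0.15)
})

test_that("fits are invariant to joint rescaling of dose and concentrations", {
  truth <- shared_f_albumin()
  tt <- 10^seq(1, log10(150000), length.out = 13)
  obs1 <- generate_dataset(truth, dose_schedule("plasma", "bolus", 1), tt,
                           noise_spec(cv = 0.1, seed = 5))
  obs2 <- observed_dataset(obs1$time, obs1$concentration * 1000,
                           schedule = dose_schedule("plasma", "bolus", 1000))
  f1 <- fit_protein(obs1, human_ref())
  f2 <- fit_protein(obs2, human_ref())
  expect_equal(f1$estimates$Cl_p, f2$estimates$Cl_p, tolerance = 1e-4)
  expect_equal(f1$estimates$f_1, f2$estimates$f_1, tolerance = 1e-4)
  expect_equal(f1$loss, f2$loss, tolerance = 1e-6)
})

test_that("unconstrained 5-parameter fit recovers the albumin time constants", {
  truth_cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
  pp <- compartmental_to_physiological(truth_cp, species_constants("human"))
  des <- make_design("iv_bolus", "albumin", n_samples = 24)
  obs <- generate_dataset(pp, des$schedule, des$sample_times, noise_spec(cv = 0))
  cf <- fit_compartmental(obs, V_p = 2800, n_starts = 16, seed = 1)
  rel <- abs(unlist(unclass(cf$cp)) - unlist(unclass(truth_cp))) /
    unlist(unclass(truth_cp))
  expect_lt(max(rel), 1e-4)
  # three eigen-modes; slowest within 5 % of the generator's terminal mode
  expect_identical(length(cf$eigen_time_constants), 3L)
  expect_equal(max(cf$eigen_time_constants),
               terminal_time_constant(truth_cp, "eigen"), tolerance = 0.05)

  # nesting: the constrained 2-parameter fit can never do better
  fit2 <- fit_protein(obs, human_ref())
  expect_gte(fit2$loss, cf$loss)
  cmp <- compare_nested_fits(fit2, cf)
  expect_gte(cmp$F, 0)
  expect_identical(cmp$df1, 3L)
})

test_that("sparse designs flag weakly identified time constants", {
  truth_cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
  pp <- compartmental_to_physiological(truth_cp, species_constants("human"))
  tt <- 10^seq(1, log10(60000), length.out = 6)
  obs <- generate_dataset(pp, dose_schedule("plasma", "bolus", 1), tt,
                          noise_spec(cv = 0))
  prof <- suppressWarnings(
    profile_identifiability(obs, truth_cp, V_p = 2800))
  expect_identical(nrow(prof), 5L)
  expect_gte(sum(prof$weakly_identified), 1L)
})

test_that("co-estimated assay baseline is recovered on clean data", {
  truth <- shared_f_albumin()
  tt <- 10^seq(1, log10(150000), length.out = 14)
  obs <- generate_dataset(truth, dose_schedule("plasma", "bolus", 1), tt,
                          noise_spec(cv = 0, baseline = 2e-5))
  fit <- fit_protein(obs, human_ref(), baseline = "estimate",
                     baseline_value = 1e-5)
  expect_lt(abs(fit$estimates$Cl_p - 0.167) / 0.167, 1e-3)
  expect_lt(abs(fit$estimates$baseline - 2e-5) / 2e-5, 0.02)
})

test_that("insufficient data are rejected up front", {
  truth <- shared_f_albumin()
  tt <- c(10, 100, 1000)
  obs <- generate_dataset(truth, dose_schedule("plasma", "bolus", 1), tt,
                          noise_spec(cv = 0))
  expect_error(fit_protein(obs, human_ref()), "insufficient")
  expect_error(fit_protein(obs, human_ref(), mode = "clp_only"), "fixed_f")
})

test_that("calibration solves the three-target system exactly on shared-f parameters", {
  pp0 <- shared_f_albumin()
  cp0 <- physiological_to_compartmental(pp0)
  ss <- steady_state_summary(pp0)
  sc <- calibrate_species(cp0, list(lymph_ratio = ss$lymph_plasma_ratio,
                                    V_ECF = ss$V_ECF, L_total = ss$L_total),
                          V_p = 2800)
  expect_equal(sc$V_1, 3640, tolerance = 1e-8)
  expect_equal(sc$V_2, 1120, tolerance = 1e-8)
  expect_equal(attr(sc, "shared_f"), 0.73, tolerance = 1e-8)
})

test_that("two albumin targets reproduce the human volume ratios", {
  cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
  expect_warning(
    sc <- calibrate_species(cp, list(lymph_ratio = 0.725, V_ECF = 3479),
                            V_p = 2800),
    "underdetermined")
  expect_equal(sc$v1_ratio, 1.3, tolerance = 0.02)
  expect_equal(sc$v2_ratio, 0.4, tolerance = 0.02)
})

test_that("inflating the V_ECF target moves both volume ratios upward", {
  cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
  get <- function(vecf) suppressWarnings(
    calibrate_species(cp, list(lymph_ratio = 0.725, V_ECF = vecf), V_p = 2800))
  base <- get(3479)
  up <- get(3479 * 1.1)
  expect_gt(up$v1_ratio, base$v1_ratio)
  expect_gt(up$v2_ratio, base$v2_ratio)
})

test_that("infeasible targets raise a classed calibration error", {
  cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
  expect_error(
    calibrate_species(cp, list(lymph_ratio = 0.725, V_ECF = 50000,
                               L_total = 2.8), V_p = 2800),
    class = "protpk_calibration_infeasible")
  expect_error(calibrate_species(cp, list(lymph_ratio = 0.7), V_p = 2800),
               "at least two")
})
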