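# ODE simulator: rate-system structure, closed-form oracle equivalence,
# conservation, half-time and the single-exponential limit.

test_that("rate matrix is Metzler with clearance-only volume-weighted leakage", {
  pp <- physiological_params(0, 1, 1, 0.87, 2.0, 2800, 3640, 1120)
  sys <- build_rate_system(pp)
  wcs <- colSums(sys$A * sys$volumes) # volume-weighted column sums
  expect_equal(unname(wcs), c(0, 0, 0), tolerance = 1e-14)
  pp2 <- protein_params("albumin")
  sys2 <- build_rate_system(pp2)
  off <- sys2$A[row(sys2$A) != col(sys2$A)]
  expect_true(all(off >= 0))
  wcs2 <- colSums(sys2$A * sys2$volumes)
  expect_equal(unname(wcs2), c(-pp2$Cl_p, 0, 0), tolerance = 1e-12)
})

test_that("albumin eigenvalues are real, negative, distinct; slowest is the terminal mode", {
  sys <- build_rate_system(protein_params("albumin"))
  ev <- eigen(sys$A, only.values = TRUE)$values
  expect_true(all(abs(Im(ev)) < 1e-12))
  ev <- Re(ev)
  expect_true(all(ev < 0))
  expect_identical(length(unique(signif(ev, 10))), 3L)
  slowest <- 1 / min(abs(ev))
  expect_equal(slowest, 39520.72, tolerance = 1e-5)
  expect_lt(abs(slowest - 37561.15) / 37561.15, 0.06)
})

test_that("solution matches the matrix-exponential closed form on all routes", {
  # plasma bolus, albumin
  pp <- protein_params("albumin")
  tt <- c(0, 10^seq(0, log10(40000), length.out = 25))
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1),
                     t_end = 40000, times = tt)
  orc <- oracle_simulate(pp, tt, boluses = data.frame(time = 0, state = 1,
                                                      amount = 1))
  scale <- max(orc$conc)
  expect_lt(max(abs(as.matrix(sim[, c("C_p", "C_1", "C_2")]) - orc$conc)) /
              scale, 1e-8)
  expect_lt(max(abs(sim$eliminated - orc$eliminated)), 1e-8)

  # tissue-1 bolus, mepolizumab
  ppm <- protein_params("mepolizumab")
  ttm <- seq(0, 20000, length.out = 40)
  simm <- simulate_pk(ppm, dose_schedule("tissue1", "bolus", 5),
                      t_end = 20000, times = ttm)
  orcm <- oracle_simulate(ppm, ttm, boluses = data.frame(time = 0, state = 2,
                                                         amount = 5))
  expect_lt(max(abs(as.matrix(simm[, c("C_p", "C_1", "C_2")]) - orcm$conc)) /
              max(orcm$conc), 1e-8)

  # repeated 60-min infusions, dog ALT (tests event handling at boundaries)
  ppd <- protein_params("ALT")
  ttd <- seq(0, 2000, length.out = 81)
  sched <- dose_schedule("plasma", "infusion", amount = 100, duration = 60,
                         period = 600, n_repeats = 3)
  simd <- simulate_pk(ppd, sched, t_end = 2000, times = ttd)
  inf <- data.frame(start = c(0, 600, 1200), end = c(60, 660, 1260),
                    state = 1, rate = 100 / 60)
  orcd <- oracle_simulate(ppd, ttd, infusions = inf)
  expect_lt(max(abs(as.matrix(simd[, c("C_p", "C_1", "C_2")]) - orcd$conc)) /
              max(orcd$conc), 1e-8)
  expect_lt(max(abs(simd$eliminated - orcd$eliminated)) /
              max(orcd$eliminated), 1e-8)
})

test_that("bolus initial conditions mix instantaneously into the route compartment", {
  pp <- protein_params("albumin")
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 7), t_end = 100,
                     n_points = 11)
  expect_equal(sim$C_p[1], 7 / 2800, tolerance = 1e-12)
  expect_identical(sim$C_1[1], 0)
  expect_identical(sim$C_2[1], 0)
  expect_identical(sim$C_lymph[1], 0)
  sim2 <- simulate_pk(pp, dose_schedule("tissue2", "bolus", 3), t_end = 100,
                      n_points = 11)
  expect_equal(sim2$C_2[1], 3 / 1120, tolerance = 1e-12)
  expect_identical(sim2$C_p[1], 0)
})

test_that("without clearance the total amount is conserved indefinitely", {
  pp <- physiological_params(0, 0.73, 0.72, 0.87, 2.0, 2800, 3640, 1120)
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 50000,
                     n_points = 200)
  total <- 2800 * sim$C_p + 3640 * sim$C_1 + 1120 * sim$C_2
  expect_lt(max(abs(total - 1)), 1e-8)
  expect_true(all(sim$eliminated == 0))
  expect_lt(mass_balance_residual(sim), 1e-8)
})

test_that("mass balance holds to 1e-6 for every catalog protein and dosing kind", {
  cat13 <- load_catalog()
  for (nm in cat13$name) {
    rec <- protein_record(nm)
    lp <- rec$liver
    pp <- if (rec$is_liver_recycled) rec$physiological else
      compartmental_to_physiological(rec$compartmental, rec$species_constants)
    horizon <- 2 * terminal_time_constant(rec$compartmental)
    sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1),
                       t_end = horizon, n_points = 120, lp = lp)
    expect_lt(mass_balance_residual(sim), 1e-6)
  }
  # repeated-infusion schedule across period boundaries
  pp <- protein_params("ALT")
  sim <- simulate_pk(pp, dose_schedule("tissue1", "infusion", amount = 10,
                                       duration = 120, period = 720,
                                       n_repeats = 3),
                     t_end = 4000, n_points = 300)
  expect_lt(mass_balance_residual(sim), 1e-6)
  expect_true(all(diff(sim$eliminated) >= -1e-12))
  expect_true(all(as.matrix(sim[, c("C_p", "C_1", "C_2")]) >= 0))
})

test_that("constant infusion approaches the analytic steady state", {
  pp <- protein_params("ALT")
  ss <- steady_state_summary(pp)
  horizon <- 10 * terminal_time_constant(
    physiological_to_compartmental(pp), method = "eigen")
  R <- 0.5 # amount/min
  sim <- simulate_pk(pp, dose_schedule("plasma", "infusion",
                                       amount = R * horizon,
                                       duration = horizon),
                     t_end = horizon, n_points = 200)
  n <- nrow(sim)
  expect_equal(sim$C_p[n], R / pp$Cl_p, tolerance = 1e-3)
  expect_equal(sim$C_1[n] / sim$C_p[n], pp$f_1, tolerance = 1e-3)
  expect_equal(sim$C_2[n] / sim$C_p[n], pp$f_2, tolerance = 1e-3)
  expect_equal(sim$C_lymph[n] / sim$C_p[n], ss$lymph_plasma_ratio,
               tolerance = 1e-3)
})

test_that("albumin IV bolus half-time is about two days", {
  pp <- protein_params("albumin")
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 10000,
                     n_points = 400)
  ht <- half_time(sim)
  expect_gt(ht / 1440, 1.5)
  expect_lt(ht / 1440, 2.5)
  # grid convergence: 10x refinement moves the estimate < 0.1 %
  sim10 <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 10000,
                       n_points = 4000)
  expect_lt(abs(half_time(sim10) - ht) / ht, 1e-3)
})

test_that("without tissue exchange the half-time is T_M log(2) exactly", {
  pp <- physiological_params(2.8, 0, 0, 0.87, 2.0, 2800, 3640, 1120)
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 5000,
                     n_points = 500)
  expect_equal(half_time(sim), 1000 * log(2), tolerance = 1e-6)
})

test_that("half-time signals explicitly when the curve never falls to half", {
  pp <- physiological_params(0, 0.73, 0.72, 0.87, 2.0, 2800, 3640, 1120)
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 100,
                     n_points = 50)
  expect_error(half_time(sim), class = "protpk_half_time_not_reached")
})

test_that("subcutaneous and IV AUC both equal dose over clearance", {
  pp <- protein_params("ALT")
  cp <- physiological_to_compartmental(pp)
  horizon <- 20 * terminal_time_constant(cp, "eigen")
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  auc <- sapply(c("plasma", "tissue1"), function(route) {
    sim <- simulate_pk(pp, dose_schedule(route, "bolus", 1),
                       t_end = horizon, n_points = 3000, grid = "log",
                       t_min = 0.01)
    trapz(sim$t, sim$C_p)
  })
  expect_equal(unname(auc[["plasma"]]), 1 / pp$Cl_p, tolerance = 5e-3)
  expect_equal(unname(auc[["tissue1"]]), 1 / pp$Cl_p, tolerance = 5e-3)
  expect_equal(unname(auc[["tissue1"]] / auc[["plasma"]]), 1, tolerance = 5e-3)
})

test_that("short-T_M proteins decay as a single exponential near the metabolic rate", {
  pp <- protein_params("amylase") # T_M of 100 min versus ~2000-min exchange
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 200,
                     n_points = 100)
  fitl <- stats::lm(log(sim$C_p) ~ sim$t)
  # mono-exponential over the first 2 T_M: log residuals stay tiny
  expect_lt(max(abs(stats::residuals(fitl))), 0.02)
  lambda <- -stats::coef(fitl)[[2]]
  expect_equal(lambda, pp$Cl_p / pp$V_p, tolerance = 0.10)
  # the early decay also carries the sieved filtration outflux, so the
  # fitted rate sits much closer to (Cl_p + f_1 L_1 + f_2 L_2)/V_p
  lam_out <- (pp$Cl_p + pp$f_1 * pp$L_1 + pp$f_2 * pp$L_2) / pp$V_p
  expect_equal(lambda, lam_out, tolerance = 0.02)
})

test_that("pooled lymph matches direct recomputation and the dog ALT shape", {
  pp <- protein_params("ALT")
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 15000,
                     n_points = 500)
  expect_identical(sim$C_lymph, lymph_concentration(sim, pp))
  expect_identical(sim$C_lymph[1], 0)
  ipk <- which.max(sim$C_lymph)
  expect_gt(ipk, 1L) # rises from zero ...
  expect_lt(ipk, nrow(sim)) # ... peaks ...
  expect_lt(sim$C_lymph[nrow(sim)], sim$C_lymph[ipk]) # ... then declines
  # late decline parallel to plasma: the lymph/plasma ratio settles to a
  # constant (the terminal eigenvector's, above the infusion steady-state
  # value)
  late <- sim$t > 10000
  ratio <- sim$C_lymph[late] / sim$C_p[late]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.01)
  expect_gt(mean(ratio), steady_state_summary(pp)$lymph_plasma_ratio)
})

test_that("simulation input validation catches malformed requests", {
  pp <- protein_params("albumin")
  expect_error(simulate_pk(pp, dose_schedule("plasma", "bolus", 1),
                           t_end = -5), "> 0")
  expect_error(dose_schedule("intrathecal", "bolus", 1))
  expect_error(dose_schedule("plasma", "infusion", 1), "duration")
  expect_error(dose_schedule("plasma", "infusion", 1, duration = 120,
                             period = 60, n_repeats = 3), "exceed")
  expect_error(simulate_pk(pp, dose_schedule("plasma", "bolus", 1),
                           t_end = 10, times = c(-1, 5)), "non-negative")
})

test_that("tidy CSV export round-trips with its metadata sidecar", {
  pp <- protein_params("albumin")
  sim <- simulate_pk(pp, dose_schedule("plasma", "bolus", 1), t_end = 1000,
                     n_points = 20)
  path <- file.path(tempdir(), "sim.csv")
  write_simulation(sim, path)
  long <- utils::read.csv(path)
  expect_setequal(unique(long$compartment),
                  c("plasma", "tissue1", "tissue2", "lymph"))
  expect_equal(long$concentration[long$compartment == "plasma"], sim$C_p,
               tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  expect_identical(meta$package, "protpk")
  expect_equal(meta$parameters$Cl_p, pp$Cl_p)
  expect_identical(meta$schedule[[1]]$route, "plasma")
  unlink(c(path, paste0(path, ".json")))
})
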