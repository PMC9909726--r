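# Parameter estimation under the physiological constraints: species-level
# lymph flows and tissue volumes are fixed, the capillary "pore" is shared
# between the two tissues (f_1 = f_2 = f), and the clearance is free. A
# 5-parameter unconstrained compartmental fit is provided for comparison,
# together with species calibration of the tissue volumes from steady-state
# observations.
#
# All losses are sums of squared log-concentration residuals (proportional
# error), matching the multi-decade semilog character of protein PK data.

#' Observed concentration-time dataset
#'
#' @param time sampling times, min (non-negative, strictly increasing within
#'   a replicate and matrix).
#' @param concentration measured concentrations, amount/ml (> 0; fitting is
#'   carried out on the log scale).
#' @param matrix `"plasma"` or `"lymph"` per record.
#' @param replicate replicate identifier per record.
#' @param status optional per-record status (`"ok"` / `"blq"` for values at
#'   or below the quantification limit).
#' @param schedule the [dose_schedule()] (or list) under which the data were
#'   collected; required for fitting.
#' @param species optional species label.
#' @param baseline known additive background level (e.g. basal enzyme
#'   activity), amount/ml.
#' @return Data frame of class `observed_dataset` with the schedule,
#'   species and baseline carried as attributes.
#' @export
observed_dataset <- function(time, concentration, matrix = "plasma",
                             replicate = 1L, status = NULL, schedule = NULL,
                             species = NULL, baseline = 0) {
  n <- length(time)
  stopifnot(length(concentration) == n)
  matrix <- rep_len(as.character(matrix), n)
  replicate <- rep_len(replicate, n)
  if (is.null(status)) status <- rep_len("ok", n)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(concentration <= 0)) {
    stop("concentrations must be > 0 for log-space fitting", call. = FALSE)
  }
  if (!all(matrix %in% c("plasma", "lymph"))) {
    stop("matrix must be 'plasma' or 'lymph'", call. = FALSE)
  }
  for (key in split(seq_len(n), list(matrix, replicate), drop = TRUE)) {
    if (is.unsorted(time[key], strictly = TRUE)) {
      stop("times must be strictly increasing within a replicate", call. = FALSE)
    }
  }
  out <- data.frame(time = time, concentration = concentration,
                    matrix = matrix, replicate = replicate, status = status)
  attr(out, "schedule") <- schedule
  attr(out, "species") <- species
  attr(out, "baseline") <- baseline
  class(out) <- c("observed_dataset", "data.frame")
  out
}

#' Read / write observed datasets as CSV
#'
#' The CSV dialect has columns `time_min, concentration, matrix, replicate`
#' (plus optional `status`); dose and species travel in an optional JSON
#' sidecar `<path>.json` written by [write_observed_csv()].
#'
#' @param path CSV path.
#' @param schedule optional [dose_schedule()] to attach (otherwise read from
#'   the sidecar when present).
#' @param species optional species label.
#' @return An [observed_dataset()].
#' @export
read_observed_csv <- function(path, schedule = NULL, species = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "concentration", "matrix", "replicate")
  if (!all(need %in% names(x))) {
    stop("observed CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  side <- paste0(path, ".json")
  baseline <- 0
  if (is.null(schedule) && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$schedule)) {
      schedule <- do.call(dose_schedule, meta$schedule)
    }
    if (!is.null(meta$species)) species <- meta$species
    if (!is.null(meta$baseline)) baseline <- meta$baseline
  }
  observed_dataset(x$time_min, x$concentration, x$matrix, x$replicate,
                   status = x$status, schedule = schedule, species = species,
                   baseline = baseline)
}

#' @rdname read_observed_csv
#' @param data an [observed_dataset()].
#' @param sidecar write the JSON sidecar (default TRUE).
#' @export
write_observed_csv <- function(data, path, sidecar = TRUE) {
  stopifnot(inherits(data, "observed_dataset"))
  out <- data.frame(time_min = data$time, concentration = data$concentration,
                    matrix = data$matrix, replicate = data$replicate,
                    status = data$status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    sched <- attr(data, "schedule")
    if (inherits(sched, "dose_schedule")) {
      meta <- list(schedule = Filter(Negate(is.null), unclass(sched)),
                   species = attr(data, "species"),
                   baseline = attr(data, "baseline"))
      jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                           digits = NA, null = "null")
    }
  }
  invisible(path)
}

#' Species-level reference parameters from the catalog
#'
#' Within a species every protein shares the same lymph flows and tissue
#' volumes; this helper extracts them (from the first catalog row of the
#' species) for use as the fixed scaffold of constrained fits.
#'
#' @param species species label present in the catalog.
#' @param catalog catalog data frame.
#' @return List of class `species_reference`: `species_constants`, `L_1`,
#'   `L_2`.
#' @export
species_reference <- function(species, catalog = load_catalog()) {
  rows <- catalog[catalog$species == species, ]
  if (!nrow(rows)) stop("no catalog entries for species '", species, "'",
                        call. = FALSE)
  structure(
    list(species_constants = species_constants(species),
         L_1 = rows$L1_ml_min[1], L_2 = rows$L2_ml_min[1]),
    class = "species_reference"
  )
}

# Build the physiological set implied by (Cl_p, f) on a species scaffold.
.pp_from_ref <- function(ref, Cl_p, f_1, f_2 = f_1) {
  sc <- ref$species_constants
  physiological_params(Cl_p, f_1, f_2, ref$L_1, ref$L_2,
                       sc$V_p, sc$V_1, sc$V_2)
}

# Model predictions at the observation rows of `data`.
.predict_obs <- function(data, pp, lp = NULL, baseline = 0, rtol = 1e-11) {
  sched <- attr(data, "schedule")
  if (is.null(sched)) stop("dataset carries no dose schedule", call. = FALSE)
  tt <- sort(unique(data$time))
  sim <- simulate_pk(pp, sched, t_end = max(tt), times = tt, lp = lp,
                     rtol = rtol)
  i <- match(data$time, sim$t)
  pred <- ifelse(data$matrix == "plasma", sim$C_p[i], sim$C_lymph[i])
  pred + baseline
}

#' Fit a protein under the physiological constraints
#'
#' Estimates the plasma clearance, and optionally a shared sieving factor,
#' on a fixed species scaffold (lymph flows and volumes from
#' [species_reference()]), by bounded nonlinear least squares
#' (`minpack.lm::nls.lm`) on log-concentration residuals. Lymph
#' observations, when present, are predicted through the pooled-lymph
#' relation and enter the loss with equal weight after the log transform.
#' With a [liver_params()] object supplied the four-compartment model is
#' used and the free clearance is the liver clearance `Cl_L`.
#'
#' @param data an [observed_dataset()] carrying its dose schedule.
#' @param ref a [species_reference()] (or a list with `species_constants`,
#'   `L_1`, `L_2`).
#' @param mode `"clp_and_f"` (default): clearance plus one shared sieving
#'   factor; `"clp_only"`: clearance only, sieving fixed at `fixed_f`.
#' @param fixed_f sieving factor(s) used in `clp_only` mode: a single shared
#'   value or `c(f_1, f_2)`.
#' @param lp optional [liver_params()]; switches to the liver-recycling
#'   model with `Cl_L` as the free clearance (its `Cl_L` field seeds the
#'   start value).
#' @param start optional named start values (`Cl_p`, `f`).
#' @param t_first first valid sample time, min: observations earlier than
#'   this (pre-mixing samples) are excluded (default 0, pure model).
#' @param baseline `"none"` (default), `"fixed"` (subtract/add
#'   `baseline_value`), or `"estimate"` (co-estimate an additive
#'   background).
#' @param baseline_value background level for `baseline = "fixed"` or the
#'   start value for `"estimate"`.
#' @param control a `minpack.lm::nls.lm.control` list.
#' @return Object of class `protein_fit`: `estimates` (list with `Cl_p` or
#'   `Cl_L`, `f_1`, `f_2`, `baseline`), `loss` (sum of squared log
#'   residuals), `residuals`, `converged`, `bound_hit`, `n_obs`, and the
#'   underlying `nls.lm` object.
#' @examples
#' ref <- species_reference("human")
#' des <- make_design("iv_bolus", "albumin")
#' obs <- generate_dataset(protein_params("albumin"), des$schedule,
#'                         des$sample_times, noise_spec(cv = 0))
#' fit <- fit_protein(obs, ref)
#' fit$estimates$Cl_p # recovers 0.167 ml/min
#' @export
fit_protein <- function(data, ref, mode = c("clp_and_f", "clp_only"),
                        fixed_f = NULL, lp = NULL, start = NULL, t_first = 0,
                        baseline = c("none", "fixed", "estimate"),
                        baseline_value = 0,
                        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-12)) {
  stopifnot(inherits(data, "observed_dataset"))
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  keep <- data$time >= t_first & data$status == "ok"
  dfit <- data[keep, ]
  attr(dfit, "schedule") <- attr(data, "schedule")
  class(dfit) <- class(data)
  est_f <- mode == "clp_and_f"
  est_b <- baseline == "estimate"
  n_par <- 1L + est_f + est_b
  if (nrow(dfit) < 3L * n_par) {
    stop("insufficient data: need at least 3 distinct points per free ",
         "parameter", call. = FALSE)
  }
  if (mode == "clp_only") {
    if (is.null(fixed_f)) stop("clp_only mode requires 'fixed_f'", call. = FALSE)
    f_fix <- rep_len(fixed_f, 2L)
  }
  b_fix <- if (baseline == "fixed") baseline_value else 0

  # crude clearance start: dose over trapezoidal AUC of the plasma points
  if (is.null(start)) {
    pl <- dfit[dfit$matrix == "plasma", ]
    auc <- sum(diff(pl$time) * (utils::head(pl$concentration, -1) +
                                  utils::tail(pl$concentration, -1)) / 2)
    doses <- .expand_doses(attr(data, "schedule"), max(dfit$time))
    total_dose <- sum(doses$boluses$amount) +
      sum(doses$infusions$rate * (doses$infusions$end - doses$infusions$start))
    cl0 <- if (auc > 0 && total_dose > 0) total_dose / auc else 1
    start <- list(Cl_p = cl0, f = 0.5)
  }

  par0 <- log(start$Cl_p)
  lower <- log(1e-8)
  upper <- log(1e6)
  if (est_f) {
    par0 <- c(par0, log(start$f))
    lower <- c(lower, log(1e-6))
    upper <- c(upper, 0)
  }
  if (est_b) {
    b0 <- max(baseline_value, 1e-8 * max(dfit$concentration))
    par0 <- c(par0, log(b0))
    lower <- c(lower, log(1e-12 * max(dfit$concentration)))
    upper <- c(upper, log(10 * max(dfit$concentration)))
  }

  resid_fn <- function(par) {
    cl <- exp(par[1])
    ff <- if (est_f) rep(exp(par[2]), 2L) else f_fix
    bb <- if (est_b) exp(par[length(par)]) else b_fix
    if (is.null(lp)) {
      pp <- .pp_from_ref(ref, cl, ff[1], ff[2])
      lpi <- NULL
    } else {
      pp <- .pp_from_ref(ref, 0, ff[1], ff[2])
      lpi <- liver_params(lp$k, lp$V_L, cl)
    }
    pred <- .predict_obs(dfit, pp, lp = lpi, baseline = bb)
    log(pred) - log(dfit$concentration)
  }

  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn, control = control)
  par_hat <- fit$par
  cl_hat <- exp(par_hat[1])
  f_hat <- if (est_f) rep(exp(par_hat[2]), 2L) else f_fix
  b_hat <- if (est_b) exp(par_hat[length(par_hat)]) else b_fix
  bound_hit <- abs(par_hat - lower) < 1e-8 | abs(par_hat - upper) < 1e-8
  if (any(bound_hit)) {
    warning("fit converged at a parameter bound; estimates are not interior",
            call. = FALSE)
  }
  estimates <- list(f_1 = f_hat[1], f_2 = f_hat[2], baseline = b_hat)
  estimates[[if (is.null(lp)) "Cl_p" else "Cl_L"]] <- cl_hat
  structure(
    list(estimates = estimates, mode = mode, loss = sum(fit$fvec^2),
         residuals = data.frame(time = dfit$time, matrix = dfit$matrix,
                                log_residual = fit$fvec),
         converged = fit$info %in% 1:3, info = fit$info,
         bound_hit = bound_hit, n_obs = nrow(dfit), n_par = n_par,
         nls = fit, ref = ref, liver = !is.null(lp)),
    class = "protein_fit"
  )
}

#' Unconstrained five-parameter compartmental fit
#'
#' Fits all five time constants to a plasma bolus dataset by multi-start
#' bounded least squares in log-parameter space: one moment-based heuristic
#' start (terminal and initial log-slopes) plus Latin-hypercube starts over
#' the bounds, under a fixed seed. Plasma concentrations depend only on the
#' time constants and `V_p`, so no tissue volumes are needed.
#'
#' @param data an [observed_dataset()] of plasma observations carrying its
#'   schedule.
#' @param V_p plasma volume, ml.
#' @param n_starts number of starts (default 16; the first is the
#'   heuristic).
#' @param seed RNG seed for the Latin hypercube.
#' @param bounds_log10 lower/upper bounds for all five constants,
#'   log10 minutes (default `c(0.5, 6)`).
#' @param t_first first valid sample time (as in [fit_protein()]).
#' @param control a `minpack.lm::nls.lm.control` list.
#' @return List of class `compartmental_fit`: `cp` (best
#'   [compartmental_params()]), `loss`, `fit` (best `nls.lm` object),
#'   `start_losses` (loss per start), `eigen_time_constants` (the three
#'   eigen-mode time constants of the fitted system), `converged`, `n_obs`.
#' @export
fit_compartmental <- function(data, V_p, n_starts = 16, seed = 1,
                              bounds_log10 = c(0.5, 6), t_first = 0,
                              control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-14, ptol = 1e-12)) {
  stopifnot(inherits(data, "observed_dataset"))
  keep <- data$time >= t_first & data$status == "ok" & data$matrix == "plasma"
  dfit <- data[keep, ]
  attr(dfit, "schedule") <- attr(data, "schedule")
  class(dfit) <- class(data)
  if (nrow(dfit) < 15L) {
    stop("unconstrained 5-parameter fits need at least 15 plasma points",
         call. = FALSE)
  }
  sc1 <- species_constants("internal", V_p = V_p, v1_ratio = 1, v2_ratio = 1)
  resid_fn <- function(par) {
    cp <- compartmental_params(exp(par[1]), exp(par[2]), exp(par[3]),
                               exp(par[4]), exp(par[5]))
    pp <- suppressWarnings(compartmental_to_physiological(cp, sc1))
    pred <- .predict_obs(dfit, pp)
    log(pred) - log(dfit$concentration)
  }

  # heuristic start from the terminal and initial log-slopes
  tt <- dfit$time
  lc <- log(dfit$concentration)
  n <- length(tt)
  tail_i <- max(1L, n - 3L):n
  sl_tail <- stats::coef(stats::lm(lc[tail_i] ~ tt[tail_i]))[2]
  head_i <- 1:min(4L, n)
  sl_head <- stats::coef(stats::lm(lc[head_i] ~ tt[head_i]))[2]
  t_slow <- if (is.finite(sl_tail) && sl_tail < 0) -1 / sl_tail else max(tt)
  t_fast <- if (is.finite(sl_head) && sl_head < 0) -1 / sl_head else max(tt) / 50
  h <- log(pmin(pmax(c(t_slow / 2, 4 * t_fast, 1.5 * t_fast,
                       4 * t_fast, 1.5 * t_fast),
                     10^bounds_log10[1]), 10^bounds_log10[2]))

  lo <- rep(log(10^bounds_log10[1]), 5)
  up <- rep(log(10^bounds_log10[2]), 5)
  set.seed(seed)
  starts <- rbind(h,
                  matrix(lo, n_starts - 1L, 5, byrow = TRUE) +
                    lhs::randomLHS(n_starts - 1L, 5) *
                      matrix(up - lo, n_starts - 1L, 5, byrow = TRUE))
  fits <- vector("list", nrow(starts))
  losses <- rep(Inf, nrow(starts))
  for (i in seq_len(nrow(starts))) {
    f <- try(minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = up,
                                fn = resid_fn, control = control),
             silent = TRUE)
    if (!inherits(f, "try-error")) {
      fits[[i]] <- f
      losses[i] <- sum(f$fvec^2)
    }
  }
  best <- which.min(losses)
  fit <- fits[[best]]
  cp <- compartmental_params(exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3]),
                             exp(fit$par[4]), exp(fit$par[5]))
  ev <- eigen(.amounts_matrix(cp), only.values = TRUE)$values
  structure(
    list(cp = cp, loss = losses[best], fit = fit, start_losses = losses,
         eigen_time_constants = sort(1 / abs(Re(ev))),
         converged = fit$info %in% 1:3, n_obs = nrow(dfit), n_par = 5L),
    class = "compartmental_fit"
  )
}

#' Profile-likelihood flatness scan
#'
#' For each time constant of a fitted compartmental model, fixes it at
#' `factor` times its estimate, refits the remaining four, and reports
#' whether the data can still be described essentially as well (root mean
#' square log residual below `flat_tol`): a flat direction indicates a
#' weakly identified parameter under the sampling design.
#'
#' @param data the [observed_dataset()] that was fitted.
#' @param cp the fitted [compartmental_params()].
#' @param V_p plasma volume, ml.
#' @param factor displacement factor applied to each constant (default 4).
#' @param flat_tol RMS log-residual threshold below which the displaced fit
#'   counts as indistinguishable (default 0.05, i.e. 5 % on concentrations).
#' @param control a `minpack.lm::nls.lm.control` list.
#' @return Data frame with one row per time constant: displaced value,
#'   achieved RMS log residual, and logical `weakly_identified`.
#' @export
profile_identifiability <- function(data, cp, V_p, factor = 4,
                                    flat_tol = 0.05,
                                    control = minpack.lm::nls.lm.control(maxiter = 80)) {
  stopifnot(inherits(cp, "compartmental_params"))
  keep <- data$status == "ok" & data$matrix == "plasma"
  dfit <- data[keep, ]
  attr(dfit, "schedule") <- attr(data, "schedule")
  class(dfit) <- class(data)
  sc1 <- species_constants("internal", V_p = V_p, v1_ratio = 1, v2_ratio = 1)
  nms <- names(unclass(cp))
  theta <- log(unlist(unclass(cp)))
  out <- lapply(seq_along(nms), function(i) {
    fixed_val <- theta[i] + log(factor)
    resid_fn <- function(par) {
      full <- theta
      full[-i] <- par
      full[i] <- fixed_val
      cpi <- compartmental_params(exp(full[1]), exp(full[2]), exp(full[3]),
                                  exp(full[4]), exp(full[5]))
      pp <- suppressWarnings(compartmental_to_physiological(cpi, sc1))
      log(.predict_obs(dfit, pp)) - log(dfit$concentration)
    }
    f <- minpack.lm::nls.lm(par = theta[-i], lower = rep(log(1e-2), 4),
                            upper = rep(log(1e7), 4), fn = resid_fn,
                            control = control)
    rms <- sqrt(mean(f$fvec^2))
    data.frame(parameter = nms[i], displaced_to = exp(fixed_val),
               rms_log_residual = rms, weakly_identified = rms < flat_tol)
  })
  do.call(rbind, out)
}

#' F-ratio comparison of nested fits
#'
#' Tests whether the unconstrained fit improves significantly on the
#' physiologically constrained one:
#' `F = ((SSR_r - SSR_f)/(p_f - p_r)) / (SSR_f/(n - p_f))`.
#'
#' @param fit_reduced the constrained fit (e.g. a [fit_protein()] result).
#' @param fit_full the richer fit (e.g. a [fit_compartmental()] result).
#' @return List: `F`, `df1`, `df2`, `p_value`, and the two losses.
#' @export
compare_nested_fits <- function(fit_reduced, fit_full) {
  ssr_r <- fit_reduced$loss
  ssr_f <- fit_full$loss
  p_r <- fit_reduced$n_par
  p_f <- fit_full$n_par
  n <- fit_full$n_obs
  df1 <- p_f - p_r
  df2 <- n - p_f
  if (df1 <= 0 || df2 <= 0) stop("fits are not nested with spare degrees of freedom",
                                 call. = FALSE)
  Fstat <- ((ssr_r - ssr_f) / df1) / (ssr_f / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       loss_reduced = ssr_r, loss_full = ssr_f)
}

#' Calibrate species tissue volumes from steady-state observations
#'
#' Solves for the lumped tissue volumes `(V_1, V_2)` given a protein's time
#' constants and up to three steady-state targets: the pooled lymph/plasma
#' concentration ratio, the extravascular distribution volume `V_ECF`, and
#' the total lymph flow. The solver treats the shared sieving factor `f`
#' (capillary-pore equality, `f_1 = f_2 = f`) as part of the unknowns:
#' `f = ratio`, `V_1 + V_2 = V_ECF / f`, `V_1/T_T1 + V_2/T_T2 = L_total` -
#' three equations in `(V_1, V_2, f)`, solved exactly when all three targets
#' are supplied. With a target missing the system is underdetermined and
#' the missing piece is filled from the time constants themselves (the
#' equal-sieving volume split `V_2/V_1 = T_T2 T_P1 / (T_T1 T_P2)`), with a
#' warning.
#'
#' @param cp [compartmental_params()] of the calibration protein (albumin
#'   for the human).
#' @param targets named list with any of `lymph_ratio`, `V_ECF` (ml),
#'   `L_total` (ml/min).
#' @param V_p plasma volume, ml.
#' @param species label for the returned constants.
#' @return A [species_constants()] object with attributes `shared_f` (the
#'   implied sieving factor) and `achieved` (the steady-state summary at the
#'   solution).
#' @examples
#' cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
#' calibrate_species(cp, list(lymph_ratio = 0.725, V_ECF = 3479),
#'                   V_p = 2800) # ratios near 1.3 and 0.4
#' @export
calibrate_species <- function(cp, targets, V_p = 2800, species = "calibrated") {
  stopifnot(inherits(cp, "compartmental_params"))
  known <- intersect(names(targets), c("lymph_ratio", "V_ECF", "L_total"))
  if (length(known) < 2L) {
    stop("at least two of lymph_ratio, V_ECF, L_total are required",
         call. = FALSE)
  }
  r_eq <- cp$T_T2 * cp$T_P1 / (cp$T_T1 * cp$T_P2) # equal-sieving V_2/V_1
  f <- targets$lymph_ratio
  if (is.null(f)) {
    warning("lymph_ratio target missing: sieving factor taken from the ",
            "time constants (underdetermined)", call. = FALSE)
    # equal-sieving value implied by cp at the V solving L_total alone
    f <- NA_real_
  }
  a <- 1 / cp$T_T1
  b <- 1 / cp$T_T2
  if (!is.null(targets$L_total) && !is.null(targets$V_ECF) && !is.null(f) &&
      !is.na(f)) {
    S <- targets$V_ECF / f
    V_1 <- (targets$L_total - b * S) / (a - b)
    V_2 <- S - V_1
  } else if (!is.null(targets$V_ECF) && !is.na(f)) {
    warning("L_total target missing: volume split taken from the ",
            "equal-sieving rule (underdetermined)", call. = FALSE)
    S <- targets$V_ECF / f
    V_1 <- S / (1 + r_eq)
    V_2 <- S - V_1
  } else if (!is.null(targets$L_total)) {
    if (!is.na(f) && is.null(targets$V_ECF)) {
      warning("V_ECF target missing: volume split taken from the ",
              "equal-sieving rule (underdetermined)", call. = FALSE)
    }
    V_1 <- targets$L_total / (a + r_eq * b)
    V_2 <- r_eq * V_1
    if (is.na(f)) f <- V_p * cp$T_T1 / (V_1 * cp$T_P1)
  } else {
    stop("unsupported target combination", call. = FALSE)
  }
  if (!is.finite(V_1) || !is.finite(V_2) || V_1 <= 0 || V_2 <= 0) {
    stop(errorCondition(
      sprintf("no positive tissue-volume solution (V_1 = %.4g, V_2 = %.4g ml)",
              V_1, V_2),
      class = c("protpk_calibration_infeasible", "error", "condition")))
  }
  sc <- species_constants(species, V_p = V_p,
                          v1_ratio = V_1 / V_p, v2_ratio = V_2 / V_p)
  pp <- suppressWarnings(compartmental_to_physiological(cp, sc))
  attr(sc, "shared_f") <- f
  attr(sc, "achieved") <- steady_state_summary(pp)
  sc
}

#' @export
print.protein_fit <- function(x, ...) {
  cl_name <- if (x$liver) "Cl_L" else "Cl_p"
  cat(sprintf("Constrained protein fit (%s), %d observations\n", x$mode, x$n_obs))
  cat(sprintf("  %s = %.5g ml/min, f_1 = %.4g, f_2 = %.4g",
              cl_name, x$estimates[[cl_name]], x$estimates$f_1, x$estimates$f_2))
  if (x$estimates$baseline > 0) cat(sprintf(", baseline = %.4g", x$estimates$baseline))
  cat(sprintf("\n  loss (sum sq log-resid) = %.6g; converged: %s\n",
              x$loss, x$converged))
  invisible(x)
}

#' @export
print.compartmental_fit <- function(x, ...) {
  cat(sprintf("Unconstrained compartmental fit, %d observations\n", x$n_obs))
  print(x$cp)
  cat(sprintf("  loss = %.6g; eigen time constants (min): %s\n",
              x$loss, paste(signif(x$eigen_time_constants, 5), collapse = ", ")))
  invisible(x)
}
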