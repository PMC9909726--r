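# Parameter algebra for the lumped convective protein PK model.
#
# Two equivalent parameterisations are supported:
#  * compartmental: five steady-state time constants (T_M, T_P1, T_P2,
#    T_T1, T_T2), all in minutes, which fully determine the plasma kinetics;
#  * physiological: plasma clearance Cl_p (ml/min), sieving factors f_1, f_2,
#    lymph flows L_1, L_2 (ml/min) and the three volumes (ml), which in
#    addition determine tissue and lymph concentrations.
#
# Units are fixed package-wide: minutes, ml, amounts in caller-chosen units
# (mg, IU, fraction of dose), concentrations in amount/ml.

.SPECIES_RATIOS <- list(
  human  = c(v1 = 1.3, v2 = 0.4),
  baboon = c(v1 = 1.3, v2 = 0.4),
  dog    = c(v1 = 1.0, v2 = 0.3),
  lamb   = c(v1 = 1.0, v2 = 0.3)
)

.check_pos <- function(x, what, finite = TRUE, strict = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("'%s' must be a single numeric value", what), call. = FALSE)
  }
  if (strict && x <= 0) stop(sprintf("'%s' must be > 0", what), call. = FALSE)
  if (!strict && x < 0) stop(sprintf("'%s' must be >= 0", what), call. = FALSE)
  if (finite && !is.finite(x)) stop(sprintf("'%s' must be finite", what), call. = FALSE)
  invisible(x)
}

#' Species-level constants: plasma volume and tissue volume ratios
#'
#' The tissue volumes of the lumped model are tied to the plasma volume
#' through species-specific ratios. All packaged values are scaled to a
#' 70 kg human with `V_p` = 2800 ml: human and baboon use
#' `V_1/V_p` = 1.3, `V_2/V_p` = 0.4; dog and lamb use 1.0 and 0.3. The
#' baboon ratios are an assumption carried over from the human (flagged in
#' the `assumed` attribute), not an independent estimate.
#'
#' @param species one of `"human"`, `"baboon"`, `"dog"`, `"lamb"`, or any
#'   other label provided both ratios are given explicitly.
#' @param V_p plasma volume, ml.
#' @param v1_ratio,v2_ratio tissue-to-plasma volume ratios `V_1/V_p` and
#'   `V_2/V_p`; defaults looked up from the packaged species table.
#' @return An object of class `species_constants` with fields `species`,
#'   `V_p`, `v1_ratio`, `v2_ratio`, `V_1`, `V_2`.
#' @examples
#' species_constants("human")
#' species_constants("dog")
#' @export
species_constants <- function(species = c("human", "baboon", "dog", "lamb"),
                              V_p = 2800, v1_ratio = NULL, v2_ratio = NULL) {
  if (length(species) > 1L) species <- match.arg(species)
  if (is.null(v1_ratio) || is.null(v2_ratio)) {
    if (!species %in% names(.SPECIES_RATIOS)) {
      stop("unknown species '", species,
           "': supply v1_ratio and v2_ratio explicitly", call. = FALSE)
    }
    r <- .SPECIES_RATIOS[[species]]
    if (is.null(v1_ratio)) v1_ratio <- unname(r["v1"])
    if (is.null(v2_ratio)) v2_ratio <- unname(r["v2"])
  }
  .check_pos(V_p, "V_p")
  .check_pos(v1_ratio, "v1_ratio")
  .check_pos(v2_ratio, "v2_ratio")
  structure(
    list(species = species, V_p = V_p,
         v1_ratio = v1_ratio, v2_ratio = v2_ratio,
         V_1 = v1_ratio * V_p, V_2 = v2_ratio * V_p,
         assumed = identical(species, "baboon")),
    class = "species_constants"
  )
}

#' Compartmental parameterisation: the five time constants
#'
#' `T_M` is the metabolic time constant (`V_p/Cl_p`): the time for a
#' mono-exponential plasma decay to 1/e in the absence of tissue exchange.
#' `T_P1` and `T_P2` are the time constants for the fall in plasma
#' concentration produced by filtration into each tissue, and `T_T1`,
#' `T_T2` are the tissue washout time constants. All in minutes.
#'
#' @param T_M,T_P1,T_P2,T_T1,T_T2 time constants, minutes; all strictly
#'   positive and finite.
#' @return Object of class `compartmental_params`.
#' @examples
#' compartmental_params(16750, 4385, 1929, 4182, 557) # human albumin
#' @export
compartmental_params <- function(T_M, T_P1, T_P2, T_T1, T_T2) {
  cp <- list(T_M = T_M, T_P1 = T_P1, T_P2 = T_P2, T_T1 = T_T1, T_T2 = T_T2)
  for (nm in names(cp)) .check_pos(cp[[nm]], nm)
  structure(cp, class = "compartmental_params")
}

#' Physiological parameterisation: clearance, sieving factors, lymph flows
#'
#' Protein leaves the plasma by sieved convection at rate `f_i * L_i * C_p`
#' into tissue i and returns unsieved with the lymph at rate `L_i * C_i`;
#' catabolism removes plasma protein at rate `Cl_p * C_p`. A sieving factor
#' of 1 means the capillary filtrate carries the full plasma concentration;
#' 0 means the protein is fully reflected. Values above 1 are not
#' physiologically plausible and trigger a warning but are representable so
#' that unconstrained conversions can be inspected.
#'
#' @param Cl_p plasma metabolic clearance, ml/min (>= 0).
#' @param f_1,f_2 sieving factors, dimensionless, in `[0, 1]` for plausible
#'   parameter sets.
#' @param L_1,L_2 lymph flows, ml/min (> 0).
#' @param V_p,V_1,V_2 plasma and tissue volumes, ml (> 0).
#' @return Object of class `physiological_params`.
#' @examples
#' physiological_params(Cl_p = 0.167, f_1 = 0.734, f_2 = 0.722,
#'                      L_1 = 0.87, L_2 = 2.0,
#'                      V_p = 2800, V_1 = 3640, V_2 = 1120)
#' @export
physiological_params <- function(Cl_p, f_1, f_2, L_1, L_2, V_p, V_1, V_2) {
  .check_pos(Cl_p, "Cl_p", strict = FALSE)
  .check_pos(f_1, "f_1", strict = FALSE)
  .check_pos(f_2, "f_2", strict = FALSE)
  .check_pos(L_1, "L_1")
  .check_pos(L_2, "L_2")
  .check_pos(V_p, "V_p")
  .check_pos(V_1, "V_1")
  .check_pos(V_2, "V_2")
  if (f_1 > 1 || f_2 > 1) {
    warning("sieving factor exceeds 1: physiologically implausible ",
            sprintf("(f_1 = %.4g, f_2 = %.4g)", f_1, f_2), call. = FALSE)
  }
  structure(
    list(Cl_p = Cl_p, f_1 = f_1, f_2 = f_2, L_1 = L_1, L_2 = L_2,
         V_p = V_p, V_1 = V_1, V_2 = V_2),
    class = "physiological_params"
  )
}

#' Convert compartmental time constants to physiological parameters
#'
#' The exact algebra is `Cl_p = V_p/T_M`, `L_i = V_i/T_Ti` and
#' `f_i = (V_p * T_Ti) / (V_i * T_Pi)`, with the tissue volumes taken from
#' the species constants. Sieving factors above 1 indicate a physiologically
#' implausible combination and raise a warning (not an error).
#'
#' @param cp a [compartmental_params()] object.
#' @param sc a [species_constants()] object supplying `V_p`, `V_1`, `V_2`.
#' @return A [physiological_params()] object.
#' @examples
#' cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
#' compartmental_to_physiological(cp, species_constants("human"))
#' @export
compartmental_to_physiological <- function(cp, sc) {
  stopifnot(inherits(cp, "compartmental_params"),
            inherits(sc, "species_constants"))
  physiological_params(
    Cl_p = sc$V_p / cp$T_M,
    f_1 = sc$V_p * cp$T_T1 / (sc$V_1 * cp$T_P1),
    f_2 = sc$V_p * cp$T_T2 / (sc$V_2 * cp$T_P2),
    L_1 = sc$V_1 / cp$T_T1,
    L_2 = sc$V_2 / cp$T_T2,
    V_p = sc$V_p, V_1 = sc$V_1, V_2 = sc$V_2
  )
}

#' Convert physiological parameters back to compartmental time constants
#'
#' Algebraic inverse of [compartmental_to_physiological()]:
#' `T_M = V_p/Cl_p`, `T_Ti = V_i/L_i`, `T_Pi = V_p * T_Ti / (V_i * f_i)`.
#' The round trip through both conversions is the identity to machine
#' precision.
#'
#' @param pp a [physiological_params()] object with `Cl_p > 0` and both
#'   sieving factors strictly positive.
#' @param clp_zero what to do when `Cl_p = 0` (the metabolic time constant
#'   is then undefined): `"error"` (default) or `"infinite"`, which returns
#'   `T_M = Inf` in a plain list (an infinite time constant is not a valid
#'   `compartmental_params` object).
#' @return A [compartmental_params()] object (or a plain list when
#'   `clp_zero = "infinite"` applies).
#' @export
physiological_to_compartmental <- function(pp, clp_zero = c("error", "infinite")) {
  stopifnot(inherits(pp, "physiological_params"))
  clp_zero <- match.arg(clp_zero)
  if (pp$f_1 <= 0 || pp$f_2 <= 0) {
    stop("sieving factors must be > 0 to recover finite plasma-to-tissue ",
         "time constants", call. = FALSE)
  }
  T_T1 <- pp$V_1 / pp$L_1
  T_T2 <- pp$V_2 / pp$L_2
  T_P1 <- pp$V_p * T_T1 / (pp$V_1 * pp$f_1)
  T_P2 <- pp$V_p * T_T2 / (pp$V_2 * pp$f_2)
  if (pp$Cl_p == 0) {
    if (clp_zero == "error") {
      stop("Cl_p = 0: metabolic time constant T_M is undefined (infinite); ",
           "use clp_zero = \"infinite\" for an explicit sentinel", call. = FALSE)
    }
    return(list(T_M = Inf, T_P1 = T_P1, T_P2 = T_P2, T_T1 = T_T1, T_T2 = T_T2))
  }
  compartmental_params(pp$V_p / pp$Cl_p, T_P1, T_P2, T_T1, T_T2)
}

#' Steady-state summary relations of the convective model
#'
#' Under a constant input the model settles to `C_i/C_p = f_i`, from which
#' three experimentally anchored quantities follow: total lymph flow
#' `L_1 + L_2`; the flow-weighted pooled lymph/plasma concentration ratio
#' `(f_1 L_1 + f_2 L_2) / (L_1 + L_2)`; and the extravascular distribution
#' volume `V_ECF = f_1 V_1 + f_2 V_2`. The amount ratios
#' `a_i = f_i V_i / V_p` give the steady-state tissue/plasma amount split.
#'
#' @param pp a [physiological_params()] object.
#' @return Object of class `steady_state_summary` with fields `L_total`
#'   (ml/min), `lymph_plasma_ratio`, `V_ECF` (ml), `a1_over_ap`,
#'   `a2_over_ap`.
#' @examples
#' cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
#' pp <- compartmental_to_physiological(cp, species_constants("human"))
#' steady_state_summary(pp) # ratio ~0.725, V_ECF ~3479 ml
#' @export
steady_state_summary <- function(pp) {
  stopifnot(inherits(pp, "physiological_params"))
  L_total <- pp$L_1 + pp$L_2
  structure(
    list(
      L_total = L_total,
      lymph_plasma_ratio = (pp$f_1 * pp$L_1 + pp$f_2 * pp$L_2) / L_total,
      V_ECF = pp$f_1 * pp$V_1 + pp$f_2 * pp$V_2,
      a1_over_ap = pp$f_1 * pp$V_1 / pp$V_p,
      a2_over_ap = pp$f_2 * pp$V_2 / pp$V_p
    ),
    class = "steady_state_summary"
  )
}

#' Terminal (slowest) plasma time constant
#'
#' When the metabolic time constant dominates the exchange constants, the
#' late log-linear plasma decay has time constant
#' `T_M * (1 + T_T1/T_P1 + T_T2/T_P2)` (total equilibrated amount over the
#' catabolic rate). `method = "eigen"` instead returns the exact slowest
#' eigen-mode, `1/|lambda_min|`, of the amounts-space rate matrix; the two
#' agree closely whenever `T_M` is much larger than the exchange constants.
#'
#' @param cp a [compartmental_params()] object.
#' @param method `"approximate"` (equilibrated-pool formula, default) or
#'   `"eigen"` (exact slowest eigen-mode).
#' @return Time constant in minutes.
#' @examples
#' cp <- compartmental_params(16750, 4385, 1929, 4182, 557)
#' terminal_time_constant(cp) / 1440        # ~26 days
#' terminal_time_constant(cp, "eigen") / 1440
#' @export
terminal_time_constant <- function(cp, method = c("approximate", "eigen")) {
  stopifnot(inherits(cp, "compartmental_params"))
  method <- match.arg(method)
  if (method == "approximate") {
    return(cp$T_M * (1 + cp$T_T1 / cp$T_P1 + cp$T_T2 / cp$T_P2))
  }
  A <- .amounts_matrix(cp)
  ev <- eigen(A, only.values = TRUE)$values
  re <- Re(ev)
  if (any(re >= 0)) stop("rate matrix has a non-negative eigenvalue", call. = FALSE)
  1 / min(abs(re))
}

# Rate matrix acting on compartment amounts (A_p, A_1, A_2); depends only on
# the five time constants.
.amounts_matrix <- function(cp) {
  matrix(c(
    -(1 / cp$T_M + 1 / cp$T_P1 + 1 / cp$T_P2), 1 / cp$T_T1, 1 / cp$T_T2,
    1 / cp$T_P1, -1 / cp$T_T1, 0,
    1 / cp$T_P2, 0, -1 / cp$T_T2
  ), nrow = 3, byrow = TRUE)
}

#' Load the packaged 13-protein kinetic catalog
#'
#' One row per protein with both parameterisations: name, species, molecular
#' weight, catabolic organ, the five time constants, and the printed
#' physiological parameters (clearance, sieving factors, lymph flows). The
#' two parameterisations were rounded independently at source and agree
#' under [compartmental_to_physiological()] to within 1 % relative error for
#' every protein except recAP, whose `T_M`/`Cl` entries are liver-compartment
#' quantities (see [check_catalog()] and [liver_params()]).
#'
#' @param path optional path to an alternative catalog CSV with the same
#'   schema; defaults to the packaged file.
#' @return A data frame of class `protein_catalog`, 13 rows when packaged.
#' @examples
#' cat13 <- load_catalog()
#' nrow(cat13)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "protein_catalog.csv", package = "protpk",
                        mustWork = TRUE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- c("name", "species", "mw_da", "catabolic_organ",
              "T_M_min", "T_P1_min", "T_P2_min", "T_T1_min", "T_T2_min",
              "Cl_p_ml_min", "f1", "f2", "L1_ml_min", "L2_ml_min",
              "liver_recycled")
  if (!identical(names(x), schema)) {
    stop("catalog file does not match the expected schema; found columns: ",
         paste(names(x), collapse = ", "), call. = FALSE)
  }
  num <- c("mw_da", "T_M_min", "T_P1_min", "T_P2_min", "T_T1_min", "T_T2_min",
           "Cl_p_ml_min", "f1", "f2", "L1_ml_min", "L2_ml_min")
  bad <- vapply(x[num], function(col) !is.numeric(col) || any(!is.finite(col)) ||
                  any(col <= 0), logical(1))
  if (any(bad)) {
    stop("catalog columns corrupted (non-numeric or non-positive): ",
         paste(num[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.logical(x$liver_recycled)) {
    stop("catalog column 'liver_recycled' must be logical", call. = FALSE)
  }
  class(x) <- c("protein_catalog", "data.frame")
  x
}

#' Retrieve one catalog protein with both parameterisations
#'
#' @param name catalog protein name (e.g. `"albumin"`, `"mepolizumab"`,
#'   `"ALT"`, `"recAP"`).
#' @param catalog a catalog data frame from [load_catalog()].
#' @return A list of class `protein_record` with fields `name`, `species`,
#'   `mw`, `catabolic_organ`, `is_liver_recycled`, `species_constants`,
#'   `compartmental` (from the time-constant columns), `physiological` (from
#'   the printed clearance/sieving/lymph columns), and, for liver-recycled
#'   proteins, `liver` ([liver_params()]) plus a `physiological` set with
#'   plasma clearance zero (all catabolism acts on the liver compartment).
#' @export
protein_record <- function(name, catalog = load_catalog()) {
  i <- match(name, catalog$name)
  if (is.na(i)) {
    stop("unknown catalog protein '", name, "'; available: ",
         paste(catalog$name, collapse = ", "), call. = FALSE)
  }
  row <- catalog[i, ]
  sc <- species_constants(row$species)
  cp <- compartmental_params(row$T_M_min, row$T_P1_min, row$T_P2_min,
                             row$T_T1_min, row$T_T2_min)
  liver <- NULL
  if (row$liver_recycled) {
    # Catalog Cl entry is the liver clearance; plasma clearance is zero and
    # all elimination proceeds through the recycling compartment.
    pp <- physiological_params(0, row$f1, row$f2, row$L1_ml_min, row$L2_ml_min,
                               sc$V_p, sc$V_1, sc$V_2)
    liver <- liver_params(
      k = 50 * (row$f1 * row$L1_ml_min + row$f2 * row$L2_ml_min),
      V_L = 26 * sc$V_p,
      Cl_L = row$Cl_p_ml_min
    )
  } else {
    pp <- physiological_params(row$Cl_p_ml_min, row$f1, row$f2,
                               row$L1_ml_min, row$L2_ml_min,
                               sc$V_p, sc$V_1, sc$V_2)
  }
  structure(
    list(name = row$name, species = row$species, mw = row$mw_da,
         catabolic_organ = row$catabolic_organ,
         is_liver_recycled = row$liver_recycled,
         species_constants = sc, compartmental = cp, physiological = pp,
         liver = liver),
    class = "protein_record"
  )
}

#' Simulation-ready physiological parameters for a catalog protein
#'
#' @param name catalog protein name.
#' @param source `"compartmental"` (default) derives the physiological set
#'   exactly from the time-constant columns via
#'   [compartmental_to_physiological()]; `"physiological"` uses the printed
#'   clearance/sieving/lymph columns directly. The two differ only by the
#'   independent rounding of the source tables (< 1 %).
#' @param catalog a catalog data frame from [load_catalog()].
#' @return A [physiological_params()] object. For liver-recycled proteins
#'   the plasma clearance is zero under either source; pair with the
#'   record's [liver_params()].
#' @export
protein_params <- function(name, source = c("compartmental", "physiological"),
                           catalog = load_catalog()) {
  source <- match.arg(source)
  rec <- protein_record(name, catalog)
  if (source == "physiological" || rec$is_liver_recycled) {
    return(rec$physiological)
  }
  compartmental_to_physiological(rec$compartmental, rec$species_constants)
}

#' Cross-table consistency audit of the catalog
#'
#' Recomputes clearance, sieving factors and lymph flows from the time
#' constants and species volumes and compares them with the printed
#' physiological columns. For liver-recycled proteins (recAP) the clearance
#' check is replaced by the liver identity `T_M = V_L / Cl_L` with
#' `V_L = 26 V_p`.
#'
#' An entry passes if its relative mismatch is below `tol` or if the
#' recomputed value rounds to the printed one at its printed precision
#' (some entries, e.g. a clearance printed to two significant digits, are
#' coarser than 1 %).
#'
#' @param catalog a catalog data frame from [load_catalog()].
#' @param tol maximum tolerated relative mismatch (default 0.01, the
#'   independent rounding allowance of the source tables).
#' @return Data frame with one row per protein: relative errors for each
#'   physiological quantity, the maximum, and a `pass` flag.
#' @examples
#' all(check_catalog()$pass)
#' @export
check_catalog <- function(catalog = load_catalog(), tol = 0.01) {
  rel <- function(a, b) abs(a - b) / abs(b)
  n_dec <- function(b) {
    s <- sub("0+$", "", format(b, scientific = FALSE))
    if (!grepl("\\.", s)) 0L else nchar(sub(".*\\.", "", s))
  }
  entry_ok <- function(a, b) {
    rel(a, b) <= tol || abs(a - b) <= 0.5 * 10^-n_dec(b) + 1e-12
  }
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    sc <- species_constants(row$species)
    cp <- compartmental_params(row$T_M_min, row$T_P1_min, row$T_P2_min,
                               row$T_T1_min, row$T_T2_min)
    pp <- compartmental_to_physiological(cp, sc)
    if (row$liver_recycled) {
      e_cl <- rel(26 * sc$V_p / row$Cl_p_ml_min, row$T_M_min) # V_L/Cl_L vs T_M
      ok_cl <- e_cl <= tol
    } else {
      e_cl <- rel(pp$Cl_p, row$Cl_p_ml_min)
      ok_cl <- entry_ok(pp$Cl_p, row$Cl_p_ml_min)
    }
    errs <- c(cl = e_cl,
              f1 = rel(pp$f_1, row$f1), f2 = rel(pp$f_2, row$f2),
              L1 = rel(pp$L_1, row$L1_ml_min), L2 = rel(pp$L_2, row$L2_ml_min))
    pass <- ok_cl && entry_ok(pp$f_1, row$f1) && entry_ok(pp$f_2, row$f2) &&
      entry_ok(pp$L_1, row$L1_ml_min) && entry_ok(pp$L_2, row$L2_ml_min)
    data.frame(name = row$name, species = row$species,
               check = if (row$liver_recycled) "liver" else "plasma",
               rel_err_cl = errs[["cl"]],
               rel_err_f1 = errs[["f1"]], rel_err_f2 = errs[["f2"]],
               rel_err_L1 = errs[["L1"]], rel_err_L2 = errs[["L2"]],
               max_rel_err = max(errs), pass = pass)
  })
  do.call(rbind, out)
}

#' @export
print.species_constants <- function(x, ...) {
  cat(sprintf("Species constants: %s%s\n", x$species,
              if (isTRUE(x$assumed)) " (volume ratios assumed)" else ""))
  cat(sprintf("  V_p = %g ml, V_1 = %g ml (%.2f V_p), V_2 = %g ml (%.2f V_p)\n",
              x$V_p, x$V_1, x$v1_ratio, x$V_2, x$v2_ratio))
  invisible(x)
}

#' @export
print.compartmental_params <- function(x, ...) {
  cat("Compartmental time constants (min):\n")
  cat(sprintf("  T_M = %g, T_P1 = %g, T_P2 = %g, T_T1 = %g, T_T2 = %g\n",
              x$T_M, x$T_P1, x$T_P2, x$T_T1, x$T_T2))
  invisible(x)
}

#' @export
print.physiological_params <- function(x, ...) {
  cat("Physiological parameters:\n")
  cat(sprintf("  Cl_p = %.4g ml/min, f_1 = %.4g, f_2 = %.4g\n",
              x$Cl_p, x$f_1, x$f_2))
  cat(sprintf("  L_1 = %.4g, L_2 = %.4g ml/min; V_p = %g, V_1 = %g, V_2 = %g ml\n",
              x$L_1, x$L_2, x$V_p, x$V_1, x$V_2))
  invisible(x)
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat("Steady-state summary:\n")
  cat(sprintf("  total lymph flow      %.4g ml/min\n", x$L_total))
  cat(sprintf("  lymph/plasma ratio    %.4g\n", x$lymph_plasma_ratio))
  cat(sprintf("  V_ECF                 %.4g ml\n", x$V_ECF))
  cat(sprintf("  tissue/plasma amounts %.4g, %.4g\n", x$a1_over_ap, x$a2_over_ap))
  invisible(x)
}
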