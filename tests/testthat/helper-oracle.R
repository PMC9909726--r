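# Independent closed-form oracle for the linear compartment system, built on
# Matrix::expm with an augmented-matrix formulation (never on the package's
# solver): states [concentrations, cumulative eliminated amount, 1], so that
# piecewise-constant inputs and clearance bookkeeping are exact.

oracle_matrix <- function(pp, lp = NULL) {
  if (is.null(lp)) {
    A <- rbind(
      c(-(pp$Cl_p + pp$f_1 * pp$L_1 + pp$f_2 * pp$L_2) / pp$V_p,
        pp$L_1 / pp$V_p, pp$L_2 / pp$V_p),
      c(pp$f_1 * pp$L_1 / pp$V_1, -pp$L_1 / pp$V_1, 0),
      c(pp$f_2 * pp$L_2 / pp$V_2, 0, -pp$L_2 / pp$V_2))
    list(A = A, V = c(pp$V_p, pp$V_1, pp$V_2), Cl = c(pp$Cl_p, 0, 0))
  } else {
    A <- rbind(
      c(-(pp$Cl_p + pp$f_1 * pp$L_1 + pp$f_2 * pp$L_2 + lp$k) / pp$V_p,
        pp$L_1 / pp$V_p, pp$L_2 / pp$V_p, lp$k / pp$V_p),
      c(pp$f_1 * pp$L_1 / pp$V_1, -pp$L_1 / pp$V_1, 0, 0),
      c(pp$f_2 * pp$L_2 / pp$V_2, 0, -pp$L_2 / pp$V_2, 0),
      c(lp$k / lp$V_L, 0, 0, -(lp$k + lp$Cl_L) / lp$V_L))
    list(A = A, V = c(pp$V_p, pp$V_1, pp$V_2, lp$V_L),
         Cl = c(pp$Cl_p, 0, 0, lp$Cl_L))
  }
}

# propagate [x, e, 1] over dt under constant input u (conc/min per state)
oracle_step <- function(A, Cl, x, e, u, dt) {
  n <- nrow(A)
  M <- matrix(0, n + 2L, n + 2L)
  M[1:n, 1:n] <- A
  M[1:n, n + 2L] <- u
  M[n + 1L, 1:n] <- Cl
  y <- as.numeric(Matrix::expm(M * dt) %*% c(x, e, 1))
  list(x = y[1:n], e = y[n + 1L])
}

# boluses: data.frame(time, state, amount); infusions: data.frame(start, end,
# state, rate). Returns concentrations and eliminated at `times`.
oracle_simulate <- function(pp, times, boluses = NULL, infusions = NULL,
                            lp = NULL) {
  sys <- oracle_matrix(pp, lp)
  n <- nrow(sys$A)
  if (is.null(boluses)) boluses <- data.frame(time = numeric(),
                                              state = integer(),
                                              amount = numeric())
  if (is.null(infusions)) infusions <- data.frame(start = numeric(),
                                                  end = numeric(),
                                                  state = integer(),
                                                  rate = numeric())
  t_end <- max(times)
  cuts <- sort(unique(c(0, t_end, boluses$time, infusions$start,
                        infusions$end)))
  cuts <- cuts[cuts >= 0 & cuts <= t_end]
  x <- numeric(n)
  e <- 0
  out <- matrix(NA_real_, length(times), n)
  elim <- numeric(length(times))
  for (s in seq_len(length(cuts) - 1L)) {
    t0 <- cuts[s]
    t1 <- cuts[s + 1L]
    for (j in which(boluses$time == t0)) {
      x[boluses$state[j]] <- x[boluses$state[j]] +
        boluses$amount[j] / sys$V[boluses$state[j]]
    }
    u <- numeric(n)
    for (j in which(infusions$start <= t0 & infusions$end >= t1)) {
      u[infusions$state[j]] <- u[infusions$state[j]] +
        infusions$rate[j] / sys$V[infusions$state[j]]
    }
    at <- which(times >= t0 & times < t1)
    for (i in at) {
      st <- oracle_step(sys$A, sys$Cl, x, e, u, times[i] - t0)
      out[i, ] <- st$x
      elim[i] <- st$e
    }
    st <- oracle_step(sys$A, sys$Cl, x, e, u, t1 - t0)
    x <- st$x
    e <- st$e
  }
  for (j in which(boluses$time == t_end)) {
    x[boluses$state[j]] <- x[boluses$state[j]] +
      boluses$amount[j] / sys$V[boluses$state[j]]
  }
  i_end <- which(times == t_end)
  if (length(i_end)) {
    out[i_end, ] <- matrix(x, length(i_end), n, byrow = TRUE)
    elim[i_end] <- e
  }
  list(conc = out, eliminated = elim)
}

# random valid compartmental parameter sets (log-uniform over 1..1e5 min)
random_cp <- function(n, seed = 42) {
  set.seed(seed)
  replicate(n, {
    v <- 10^stats::runif(5, 0, 5)
    compartmental_params(v[1], v[2], v[3], v[4], v[5])
  }, simplify = FALSE)
}

# extract one replicate of an observed_dataset, keeping attributes
one_replicate <- function(data, r) {
  d <- data[data$replicate == r, ]
  attr(d, "schedule") <- attr(data, "schedule")
  attr(d, "baseline") <- attr(data, "baseline")
  class(d) <- class(data)
  d
}
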