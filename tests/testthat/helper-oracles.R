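# Independent oracles used across the suite.

# Exact solution of the two-compartment mass-balance ODE system
#   dA1/dt = -(k10 + k12) A1 + k21 A2 + R(t)
#   dA2/dt =  k12 A1 - k21 A2
# by matrix-exponential propagation across the piecewise-constant-input
# event grid. Returns central concentrations at `times`; with
# `mass_balance = TRUE` also the cumulative eliminated amount (third state,
# dE/dt = k10 A1).
ode_oracle <- function(times, doses, sp, mass_balance = FALSE) {
  k <- micro_to_macro(sp)
  A <- matrix(c(-(k$k10 + k$k12), k$k12, k$k10,
                k$k21, -k$k21, 0,
                0, 0, 0), 3, 3)
  evs <- sort(unique(c(0, doses$start, doses$start + doses$duration, times)))
  x <- c(0, 0, 0)
  out <- matrix(NA_real_, length(times), 3)
  tprev <- evs[1]
  for (tt in evs) {
    h <- tt - tprev
    if (h > 0) {
      R <- 0
      for (j in seq_len(nrow(doses)))
        if (tprev >= doses$start[j] - 1e-12 &&
            tt <= doses$start[j] + doses$duration[j] + 1e-12)
          R <- R + doses$amount[j] / doses$duration[j]
      # augmented exponential handles the (singular) constant-input system
      Aug <- rbind(cbind(A * h, c(R, 0, 0) * h), 0)
      M <- as.matrix(Matrix::expm(Matrix::Matrix(Aug)))
      x <- as.numeric(M[1:3, 1:3] %*% x + M[1:3, 4])
    }
    hit <- which(abs(times - tt) < 1e-12)
    if (length(hit)) out[hit, ] <- matrix(x, length(hit), 3, byrow = TRUE)
    tprev <- tt
  }
  if (mass_balance) out else out[, 1] / sp$V1
}

# Exact marginal -2 log likelihood (2*pi constant omitted, matching the
# engine's convention) for the linear-in-eta fixture: one subject, lnY =
# mu - eta + W eps, eta ~ N(0, om2) -> Y ~ N(mu, om2 + W^2).
linear_marginal_m2ll <- function(lny, mu, om2, W) {
  s2 <- om2 + W^2
  sum(log(s2) + (lny - mu)^2 / s2)
}

# Fixture: subjects observed once shortly after the start of a slow
# infusion, so ln F = log(rate * t / V1) = const - eta_V1 exactly (CL ~ 0
# and the infusion has barely begun). Linear in eta with slope -1.
make_linear_eta_dataset <- function(n, TVV1 = 3, om2 = 0.09, W = 0.2,
                                    seed = 1) {
  set.seed(seed)
  eta <- stats::rnorm(n, 0, sqrt(om2))
  eps <- stats::rnorm(n)
  tobs <- 1e-3
  mu <- log(100 * tobs / TVV1)
  lny <- mu - eta + W * eps
  rows <- lapply(seq_len(n), function(i)
    data.frame(ID = i, TIME = c(0, tobs), AMT = c(100, NA),
               RATE = c(100, NA), DV = c(NA, exp(lny[i])),
               EVID = c(1L, 0L), MDV = c(1L, 0L)))
  list(ds = pk_dataset(do.call(rbind, rows)), lny = lny, mu = mu,
       om2 = om2, W = W, TVV1 = TVV1)
}

# Small rich-design trial for fast engine tests: few subjects, few cycles.
sim_small_trial <- function(n = 30, n_cycles = 6, seed = 1,
                            pop = bev_final_params(),
                            spec = bev_final_spec(),
                            dist = cov_distribution()) {
  ds <- simulate_trial(trial_design(n_subjects = n, n_cycles = n_cycles),
                       dist = dist, pop = pop, spec = spec, seed = seed)
  apply_exclusions(ds, 0.25)$dataset
}

# Reduced one-random-effect truth used by the cheaper recovery/bootstrap
# tests: IIV on CL only, no covariates.
reduced_pop <- function() {
  pop_params(CL = 0.0113, V1 = 2.99, Q = 0.269, V2 = 6.09,
             omega2 = c(CL = 0.0871, V1 = 0), W = 0.284)
}

sim_reduced_trial <- function(n = 30, n_cycles = 6, seed = 1) {
  dist <- cov_distribution()
  spec <- cov_model_spec()
  ds <- simulate_trial(trial_design(n_subjects = n, n_cycles = n_cycles),
                       dist = dist, pop = reduced_pop(), spec = spec,
                       seed = seed)
  apply_exclusions(ds, 0.25)$dataset
}

fit_reduced <- function(ds, init = reduced_pop(), ...) {
  fit_foce(ds, cov_model_spec(), init = init,
           fixed = c("Q", "V2", "omega2_V1"), estimate_se = FALSE, ...)
}
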