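sp_ref <- structural_params(CL = 0.0113, V1 = 2.99, Q = 0.269, V2 = 6.09)

test_that("micro_to_macro reproduces the rate-constant arithmetic", {
  k <- micro_to_macro(sp_ref)
  expect_equal(k$k10, 0.0113 / 2.99, tolerance = 1e-12)
  expect_equal(k$k12, 0.269 / 2.99, tolerance = 1e-12)
  expect_equal(k$k21, 0.269 / 6.09, tolerance = 1e-12)
  # frozen values computed from the quadratic
  expect_equal(k$k10, 0.003779, tolerance = 1e-3)
  expect_equal(k$k12, 0.089967, tolerance = 1e-4)
  expect_equal(k$k21, 0.044171, tolerance = 1e-4)
  expect_equal(k$beta, 0.001221, tolerance = 1e-3)
  # Vieta identities
  expect_equal(k$alpha * k$beta, k$k10 * k$k21, tolerance = 1e-12)
  expect_equal(k$alpha + k$beta, k$k10 + k$k12 + k$k21, tolerance = 1e-12)
  expect_gte(k$alpha, k$beta)
})

test_that("micro_to_macro degenerates cleanly at Q = 0 and rejects bad input", {
  k <- micro_to_macro(structural_params(0.0113, 2.99, 0, 6.09))
  expect_equal(k$alpha, 0.0113 / 2.99, tolerance = 1e-12)
  expect_equal(k$beta, 0)
  expect_error(structural_params(-1, 2.99, 0.269, 6.09), "positive|> 0")
  expect_error(structural_params(0.0113, 0, 0.269, 6.09))
})

test_that("Vieta identities hold across random parameter draws", {
  set.seed(42)
  for (i in 1:25) {
    sp <- structural_params(runif(1, 1e-3, 1), runif(1, 0.5, 10),
                            runif(1, 1e-3, 2), runif(1, 0.5, 20))
    k <- micro_to_macro(sp)
    expect_equal(k$alpha + k$beta, k$k10 + k$k12 + k$k21,
                 tolerance = 1e-12)
    expect_equal(k$alpha * k$beta, k$k10 * k$k21, tolerance = 1e-10)
  }
})

test_that("one-compartment limit matches the closed form at end of infusion", {
  sp <- structural_params(0.0113, 2.99, 0, 6.09)
  d <- dose_events(0, 1065, 1.5)
  # (R/CL)(1 - exp(-(CL/V1) * 1.5)) with R = 710 mg/h
  expected <- (710 / 0.0113) * (1 - exp(-(0.0113 / 2.99) * 1.5))
  expect_equal(concentration(1.5, d, sp), expected, tolerance = 1e-10)
  expect_equal(expected, 355.2, tolerance = 1e-3)
})

test_that("concentration is zero before dosing and errors on negative time", {
  d <- dose_events(10, 1065, 1.5)
  expect_equal(concentration(c(0, 5, 9.99), d, sp_ref), c(0, 0, 0))
  expect_error(concentration(-1, d, sp_ref), "non-negative")
})

test_that("closed form agrees with the matrix-exponential ODE oracle", {
  set.seed(7)
  for (rep in 1:3) {
    nd <- sample(2:5, 1)
    doses <- dose_events(start = sort(runif(nd, 0, 800)),
                         amount = runif(nd, 200, 1500),
                         duration = runif(nd, 0.25, 2))
    sp <- structural_params(runif(1, 0.005, 0.05), runif(1, 1, 6),
                            runif(1, 0.05, 0.6), runif(1, 2, 12))
    tt <- sort(runif(50, 0, 1200))
    ora <- ode_oracle(tt, doses, sp)
    cf <- concentration(tt, doses, sp)
    expect_lt(max(abs(cf - ora) / pmax(abs(ora), 1e-9)), 1e-8)
  }
})

test_that("production regimen (equally spaced maintenance run) matches the oracle", {
  # 16 q21d doses, durations stepping 1.5/1.0/0.5 h: the last 14 doses form
  # an equally spaced identical run, exercising the geometric fast path
  starts <- (0:15) * 504
  durs <- c(1.5, 1.0, rep(0.5, 14))
  doses <- dose_events(starts, rep(1065, 16), durs)
  tt <- sort(c(starts[-1], 2.5, 4 * 504 + 1.5, starts[16] + 504, 8000.25))
  ora <- ode_oracle(tt, doses, sp_ref)
  cf <- concentration(tt, doses, sp_ref)
  expect_lt(max(abs(cf - ora) / pmax(abs(ora), 1e-9)), 1e-8)
})

test_that("mass balance: compartments plus eliminated equals infused", {
  doses <- dose_events(c(0, 504), c(1065, 1065), c(1.5, 1.0))
  tt <- c(1, 10, 503, 600, 2000)
  st <- ode_oracle(tt, doses, sp_ref, mass_balance = TRUE)
  infused <- vapply(tt, function(t)
    sum(pmin(pmax(t - doses$start, 0), doses$duration) *
          doses$amount / doses$duration), numeric(1))
  expect_lt(max(abs(rowSums(st) - infused) / infused), 1e-6)
})

test_that("superposition and post-infusion monotonic decline", {
  d1 <- dose_events(0, 1065, 1.5)
  d2 <- dose_events(504, 1065, 1.0)
  both <- dose_events(c(0, 504), c(1065, 1065), c(1.5, 1.0))
  tt <- seq(0, 2000, by = 7)
  expect_equal(concentration(tt, both, sp_ref),
               concentration(tt, d1, sp_ref) + concentration(tt, d2, sp_ref),
               tolerance = 1e-12)
  # strictly decreasing after the last infusion ends
  tpost <- seq(505.1, 5000, length.out = 300)
  cpost <- concentration(tpost, both, sp_ref)
  expect_true(all(diff(cpost) < 0))
})

test_that("terminal log-slope tends to -beta", {
  k <- micro_to_macro(sp_ref)
  d <- dose_events(0, 1065, 1.5)
  t1 <- 4000; t2 <- 4100
  slope <- (log(concentration(t2, d, sp_ref)) -
              log(concentration(t1, d, sp_ref))) / (t2 - t1)
  expect_equal(slope, -k$beta, tolerance = 1e-4)
})

test_that("near-degenerate alpha ~ beta stays accurate and continuous", {
  # k10 == k21 = 0.1 with k12 -> 0 drives alpha - beta towards zero
  d <- dose_events(0, 100, 1)
  tt <- c(0.5, 1, 5, 20, 60)
  prev <- NULL
  for (k12 in c(1e-3, 1e-6, 1e-9)) {
    sp <- structural_params(0.1, 1, k12, k12 / 0.1)  # k21 = Q/V2 = 0.1
    cc <- concentration(tt, d, sp)
    expect_true(all(is.finite(cc)))
    expect_lt(max(abs(cc - ode_oracle(tt, d, sp)) / cc), 1e-7)
    if (!is.null(prev)) expect_equal(cc, prev, tolerance = 0.02)
    prev <- cc
  }
  # and the k12 -> 0 limit coincides with the one-compartment model
  one <- concentration(tt, d, structural_params(0.1, 1, 0, 1))
  expect_equal(prev, one, tolerance = 1e-4)
})

test_that("typical values reproduce the published worked examples", {
  pop <- bev_final_params(); spec <- bev_final_spec()
  f <- typical_values(pop, spec, list(BWT = 71, SEXM = 0, DRUG = 0))
  expect_equal(f$CL, 0.0113, tolerance = 1e-12)
  expect_equal(f$V1, 2.99, tolerance = 1e-12)
  m <- typical_values(pop, spec, list(BWT = 71, SEXM = 1, DRUG = 0))
  expect_equal(signif(m$CL, 3), 0.0143)
  expect_equal(signif(m$V1, 3), 3.73)
  big <- typical_values(pop, spec, list(BWT = 100, SEXM = 1, DRUG = 1))
  expect_equal(big$CL, 0.0113 * (100 / 71)^0.354 * 1.262 * 1.02,
               tolerance = 1e-12)
})

test_that("weight factor is exactly 1 at the reference weight for any theta", {
  spec <- cov_model_spec(list(cov_term("CL", "BWT", "power", ref = 71)))
  for (th in c(-1, 0, 0.354, 2)) {
    pop <- pop_params(0.0113, 2.99, 0.269, 6.09, theta = c("CL~BWT" = th))
    expect_equal(typical_values(pop, spec, list(BWT = 71))$CL, 0.0113,
                 tolerance = 1e-15)
  }
})

test_that("missing covariates raise a named error, never a silent default", {
  pop <- bev_final_params(); spec <- bev_final_spec()
  expect_error(typical_values(pop, spec, list(BWT = 71, SEXM = 1)), "DRUG")
  expect_error(typical_values(pop, spec, list(SEXM = 1, DRUG = 0)), "BWT")
})

test_that("individual_params applies exponential random effects", {
  tvp <- structural_params(0.0113, 2.99, 0.269, 6.09)
  expect_equal(unclass(individual_params(tvp)), unclass(tvp))
  dbl <- individual_params(tvp, c(CL = log(2)))
  expect_equal(dbl$CL, 2 * tvp$CL, tolerance = 1e-12)
  expect_equal(dbl$V1, tvp$V1)
  # log-normal median property
  set.seed(11)
  draws <- tvp$CL * exp(rnorm(1e5, 0, sqrt(0.0871)))
  expect_equal(median(draws), tvp$CL, tolerance = 0.01)
})
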