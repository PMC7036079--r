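test_that("FOCE-I OFV equals the closed-form marginal -2LL when the model is linear in eta", {
  for (seed in c(1, 5)) {
    fx <- make_linear_eta_dataset(40, seed = seed)
    pop <- pop_params(CL = 1e-6, V1 = fx$TVV1, Q = 0, V2 = 1,
                      omega2 = c(CL = 0, V1 = fx$om2), W = fx$W)
    got <- foce_objective(pop, fx$ds, cov_model_spec())
    exact <- linear_marginal_m2ll(fx$lny, fx$mu, fx$om2, fx$W)
    expect_equal(got$ofv, exact, tolerance = 1e-6)
    expect_true(all(got$ok))
  }
})

test_that("omega^2 = 0 collapses to fixed-effects log-normal regression", {
  fx <- make_linear_eta_dataset(25, seed = 3)
  pop <- pop_params(CL = 1e-6, V1 = fx$TVV1, Q = 0, V2 = 1,
                    omega2 = c(CL = 0, V1 = 0), W = fx$W)
  got <- foce_objective(pop, fx$ds, cov_model_spec())
  r <- fx$lny - fx$mu
  expect_equal(got$ofv, sum(log(fx$W^2) + r^2 / fx$W^2), tolerance = 1e-7)
})

test_that("OFV is invariant to subject ordering and ID relabeling", {
  ds <- sim_reduced_trial(n = 12, n_cycles = 4, seed = 8)
  pop <- reduced_pop()
  base <- foce_objective(pop, ds, cov_model_spec())$ofv
  df <- as.data.frame(ds)
  ids <- unique(df$ID)
  perm <- rev(ids)
  df2 <- do.call(rbind, lapply(perm, function(id) df[df$ID == id, ]))
  expect_equal(foce_objective(pop, pk_dataset(df2), cov_model_spec())$ofv,
               base, tolerance = 1e-10)
  df3 <- df; df3$ID <- df3$ID * 1000L + 7L
  expect_equal(foce_objective(pop, pk_dataset(df3), cov_model_spec())$ofv,
               base, tolerance = 1e-10)
})

test_that("OFV at the truth beats 2x-perturbed parameters in most trials", {
  wins <- 0L
  nseed <- 12L
  for (s in seq_len(nseed)) {
    ds <- sim_reduced_trial(n = 25, n_cycles = 4, seed = 300 + s)
    truth <- reduced_pop()
    pert <- pop_params(truth$CL * 2, truth$V1 * 2, truth$Q, truth$V2,
                       omega2 = truth$omega2, W = truth$W)
    o1 <- foce_objective(truth, ds, cov_model_spec())$ofv
    o2 <- foce_objective(pert, ds, cov_model_spec())$ofv
    wins <- wins + (o1 < o2)
  }
  expect_gte(wins, nseed - 1L)
})

test_that("noise-free data inverts to the typical values within 0.1%", {
  pop0 <- pop_params(0.0113, 2.99, 0.269, 6.09,
                     omega2 = c(CL = 0, V1 = 0), W = 1e-9)
  ds <- simulate_trial(trial_design(n_subjects = 15, n_cycles = 6),
                       pop = pop0, spec = cov_model_spec(), seed = 44)
  init <- pop_params(0.02, 4, 0.2, 4, omega2 = c(CL = 0, V1 = 0), W = 1e-9)
  fit <- fit_foce(ds, cov_model_spec(), init = init,
                  fixed = c("omega2_CL", "omega2_V1", "W"),
                  estimate_se = FALSE)
  expect_true(fit$convergence$ok)
  for (p in c("CL", "V1", "Q", "V2"))
    expect_equal(fit$estimates[[p]], pop0[[p]],
                 tolerance = 1e-3)
})

test_that("adding a null covariate moves the OFV like chi-square(1)", {
  # linear-in-eta fixture, where FOCE is exact: the likelihood-ratio
  # statistic for a permuted binary covariate with true theta = 0 must be
  # chi-square(1) distributed (Wilks) -- scaled-down replicate count
  nsim <- 40
  d_ofv <- numeric(nsim)
  for (s in seq_len(nsim)) {
    fx <- make_linear_eta_dataset(60, seed = 900 + s)
    df <- as.data.frame(fx$ds)
    set.seed(s)
    nullcov <- data.frame(ID = unique(df$ID),
                          GRP = sample(rep(0:1, length.out = 60)))
    df$GRP <- nullcov$GRP[match(df$ID, nullcov$ID)]
    ds <- pk_dataset(df)
    init0 <- pop_params(1e-6, 3, 1e-9, 1, omega2 = c(CL = 0, V1 = 0.09),
                        W = 0.2)
    fixed <- c("CL", "Q", "V2", "omega2_CL")
    f0 <- fit_foce(ds, cov_model_spec(), init = init0, fixed = fixed,
                   estimate_se = FALSE)
    spec1 <- cov_model_spec(list(cov_term("V1", "GRP", "fractional")))
    init1 <- pop_params(1e-6, 3, 1e-9, 1,
                        theta = c("V1~GRP" = 0),
                        omega2 = c(CL = 0, V1 = 0.09), W = 0.2)
    f1 <- fit_foce(ds, spec1, init = init1, fixed = fixed,
                   estimate_se = FALSE)
    d_ofv[s] <- f0$ofv - f1$ofv
  }
  expect_gt(mean(d_ofv), 0.4)
  expect_lt(mean(d_ofv), 2.2)
  expect_gte(mean(d_ofv < qchisq(0.95, 1)), 0.85)
})

test_that("shrinkage formulas behave at the boundaries", {
  fake <- list(eta = cbind(rep(0, 50), rep(0, 50)),
               pop = pop_params(1, 1, 1, 1, omega2 = c(CL = 0.09, V1 = 0.09),
                                W = 0.1),
               diag = data.frame(IWRES = rnorm(200)))
  sh <- compute_shrinkage(fake)
  expect_equal(sh[["eta_CL"]], 100)
  expect_equal(sh[["eta_V1"]], 100)
  set.seed(2)
  eta <- rnorm(4000, 0, 0.3)
  fake$eta <- cbind(eta, eta)
  fake$pop$omega2 <- c(CL = 0.09, V1 = 0.09)
  sh <- compute_shrinkage(fake)
  expect_equal(sh[["eta_CL"]], 100 * (1 - sd(eta) / 0.3), tolerance = 1e-9)
  fake$pop$omega2 <- c(CL = 0, V1 = 0.09)
  expect_true(is.na(compute_shrinkage(fake)[["eta_CL"]]))
})

test_that("richer sampling lowers eta shrinkage at the same truth", {
  rich <- fit_reduced(sim_reduced_trial(n = 25, n_cycles = 8, seed = 60))
  sparse <- fit_reduced(sim_reduced_trial(n = 25, n_cycles = 2, seed = 60))
  expect_lt(rich$shrinkage[["eta_CL"]], sparse$shrinkage[["eta_CL"]])
})

test_that("cv_percent matches the published worked values", {
  expect_equal(signif(cv_percent(0.0871), 3), 29.5)
  expect_equal(signif(cv_percent(0.117), 3), 34.2)
  expect_equal(cv_percent(0), 0)
  expect_error(cv_percent(-0.1), "non-negative")
})

test_that("pre-first-dose observations are rejected by the engine", {
  df <- data.frame(ID = 1, TIME = c(0, 0, 10), AMT = c(NA, 100, NA),
                   RATE = c(NA, 100, NA), DV = c(5, NA, 3),
                   EVID = c(0L, 1L, 0L), MDV = c(0L, 1L, 0L))
  expect_error(foce_objective(reduced_pop(), pk_dataset(df),
                              cov_model_spec()),
               "first dose")
})

test_that("fit serialises to JSON", {
  fit <- fit_reduced(sim_reduced_trial(n = 10, n_cycles = 3, seed = 77))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$ofv, fit$ofv, tolerance = 1e-12)
  expect_equal(back$estimates$CL, fit$estimates[["CL"]], tolerance = 1e-12)
})

test_that("sandwich standard errors are computable and comparable", {
  ds <- sim_reduced_trial(n = 30, n_cycles = 4, seed = 91)
  f_h <- fit_foce(ds, cov_model_spec(), init = reduced_pop(),
                  fixed = c("Q", "V2", "omega2_V1"))
  f_s <- fit_foce(ds, cov_model_spec(), init = reduced_pop(),
                  fixed = c("Q", "V2", "omega2_V1"),
                  se_method = "sandwich")
  for (p in c("CL", "V1", "W")) {
    expect_gt(f_s$se[[p]], 0)
    # at the true model both estimators target the same quantity
    expect_lt(abs(log(f_s$se[[p]] / f_h$se[[p]])), log(3))
  }
})
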