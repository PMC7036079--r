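test_that("outlier flags follow the |residual| > 6 rule exactly", {
  fit <- fit_reduced(sim_reduced_trial(n = 10, n_cycles = 3, seed = 5))
  fit$diag$CWRES[] <- 0
  fit$diag$IWRES[] <- 0
  fit$diag$IWRES[1] <- 6.1
  fit$diag$IWRES[2] <- 5.9
  fit$diag$CWRES[3] <- -6.2
  tab <- compute_residuals(fit)
  expect_equal(which(tab$outlier), c(1L, 3L))
})

test_that("CWRES is approximately standard normal at the truth", {
  pop <- bev_final_params()
  ds <- simulate_trial(trial_design(n_subjects = 300, n_cycles = 8),
                       pop = pop, seed = 77)
  ds <- apply_exclusions(ds, 0.25)$dataset
  r <- foce_objective(pop, ds, bev_final_spec(), want_diag = TRUE)
  expect_gte(length(r$cwres), 3000)
  expect_lt(abs(mean(r$cwres)), 0.1)
  expect_gt(sd(r$cwres), 0.9)
  expect_lt(sd(r$cwres), 1.1)
  # IWRES at eta-hat is shrunk, but centred
  expect_lt(abs(mean(r$iwres)), 0.1)
})

test_that("influence_check is a no-op without flagged rows", {
  fit <- fit_reduced(sim_reduced_trial(n = 10, n_cycles = 3, seed = 6))
  res <- compute_residuals(fit)
  expect_equal(sum(res$outlier), 0)
  rep <- influence_check(NULL, fit, res)
  expect_false(rep$influential)
  expect_identical(rep$final_fit, fit)
})

test_that("gross-error points are flagged and influential by construction", {
  # contamination kept small relative to the dataset so the estimated W is
  # not inflated past the point where |IWRES| = ln(factor)/W drops below 6
  ds <- sim_reduced_trial(n = 60, n_cycles = 6, seed = 31)
  df <- as.data.frame(ds)
  obs_idx <- which(df$EVID == 0)
  bad <- obs_idx[seq(3, by = 151, length.out = 3)]
  df$DV[bad] <- df$DV[bad] * 50
  ds2 <- pk_dataset(df)
  fit <- fit_reduced(ds2)
  res <- compute_residuals(fit)
  expect_gte(sum(res$outlier), 3)
  rep <- influence_check(ds2, fit, res, fixed = c("Q", "V2", "omega2_V1"))
  expect_true(rep$influential)
  expect_false(is.null(rep$refit))
  # the adopted fit is the no-outlier refit, and W returns towards truth
  expect_lt(rep$final_fit$estimates[["W"]], fit$estimates[["W"]])
})

test_that("removing one typical observation barely moves the estimates", {
  ds <- sim_reduced_trial(n = 40, n_cycles = 6, seed = 32)
  fit <- fit_reduced(ds)
  res <- compute_residuals(fit)
  med <- which.min(abs(res$CWRES - median(res$CWRES)))
  df <- as.data.frame(ds)
  drop <- df$EVID == 0 & df$ID == res$ID[med] & df$TIME == res$TIME[med]
  fit2 <- fit_reduced(pk_dataset(df[!drop, ]), init = fit$pop)
  for (p in c("CL", "V1", "omega2_CL", "W"))
    expect_equal(fit2$estimates[[p]], fit$estimates[[p]], tolerance = 0.01)
})

test_that("single bootstrap replicate is deterministic given the seed", {
  ds <- sim_reduced_trial(n = 12, n_cycles = 3, seed = 41)
  b1 <- bootstrap_ci(ds, cov_model_spec(), init = reduced_pop(), n_reps = 1,
                     seed = 9, fixed = c("Q", "V2", "omega2_V1"))
  b2 <- bootstrap_ci(ds, cov_model_spec(), init = reduced_pop(), n_reps = 1,
                     seed = 9, fixed = c("Q", "V2", "omega2_V1"))
  expect_identical(b1$table, b2$table)
  expect_equal(b1$n_converged, 1)
})

test_that("bootstrap percentile CI matches the analytic CI on a linear toy model", {
  # estimating only V1 in the linear-in-eta fixture, the MLE is a monotone
  # transform of the subject-mean log-observation, so the bootstrap
  # percentile CI must match the resampled-mean quantiles analytically
  fx <- make_linear_eta_dataset(40, seed = 12)
  init <- pop_params(1e-6, 3, 1e-9, 1, omega2 = c(CL = 0, V1 = 0.09),
                     W = 0.2)
  fixed <- c("CL", "Q", "V2", "omega2_CL", "omega2_V1", "W")
  b <- bootstrap_ci(fx$ds, cov_model_spec(), init = init, n_reps = 400,
                    seed = 3, fixed = fixed)
  expect_equal(b$n_converged, 400)
  ci <- b$table[b$table$parameter == "V1", ]
  # analytic: V1-hat = exp(const - mean(lny)); normal-approx CI of the mean
  s <- sd(fx$lny) / sqrt(40)
  mu <- mean(fx$lny)
  const <- log(100 * 1e-3)
  lo <- exp(const - (mu + 1.96 * s))
  hi <- exp(const - (mu - 1.96 * s))
  expect_equal(ci$median, exp(const - mu), tolerance = 0.01)
  expect_equal(ci$lower, lo, tolerance = 0.02)
  expect_equal(ci$upper, hi, tolerance = 0.02)
})

test_that("bootstrap medians track the point estimate as replicates grow", {
  ds <- sim_reduced_trial(n = 20, n_cycles = 3, seed = 48)
  fit <- fit_reduced(ds)
  b_small <- bootstrap_ci(ds, cov_model_spec(), init = fit$pop, n_reps = 10,
                          seed = 1, fixed = c("Q", "V2", "omega2_V1"))
  b_big <- bootstrap_ci(ds, cov_model_spec(), init = fit$pop, n_reps = 60,
                        seed = 1, fixed = c("Q", "V2", "omega2_V1"))
  gap <- function(b) abs(b$table$median[b$table$parameter == "CL"] -
                           fit$estimates[["CL"]])
  expect_lt(gap(b_big), gap(b_small) + 0.0005)
})

test_that("vpc collapses to the single replicate at n_trials = 1 and is seed-stable", {
  ds <- sim_reduced_trial(n = 15, n_cycles = 4, seed = 51)
  v1 <- vpc(ds, cov_model_spec(), reduced_pop(), n_trials = 1, seed = 4)
  expect_equal(v1$table$sim_p50, v1$table$sim_p50_lo)
  expect_equal(v1$table$sim_p50, v1$table$sim_p50_hi)
  v2 <- vpc(ds, cov_model_spec(), reduced_pop(), n_trials = 5, seed = 8)
  v3 <- vpc(ds, cov_model_spec(), reduced_pop(), n_trials = 5, seed = 8)
  expect_identical(v2$table, v3$table)
})

test_that("vpc is self-consistent when the model is true", {
  pop <- reduced_pop()
  ds <- sim_reduced_trial(n = 120, n_cycles = 8, seed = 61)
  v <- vpc(ds, cov_model_spec(), pop, n_trials = 60, seed = 14)
  tab <- v$table
  inside <- tab$obs_p50 >= tab$sim_p50_lo & tab$obs_p50 <= tab$sim_p50_hi
  expect_gte(mean(inside), 0.8)
  # pooled fraction of observations below the simulated bin median ~ 1/2
  obs <- as.data.frame(ds)[as.data.frame(ds)$EVID == 0, ]
  med <- tab$sim_p50[match(obs$TAG, tab$bin)]
  expect_equal(mean(obs$DV < med), 0.5, tolerance = 0.08)
})
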