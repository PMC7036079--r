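# Model qualification: conditional/individual weighted residuals and the
# outlier rule, case-deletion influence, subject-resampling bootstrap, and
# the visual predictive check.

#' Residual table with outlier flags
#'
#' IWRES is the individual weighted residual
#' `(ln Y - ln F_ind) / W` with `F_ind` evaluated at the empirical Bayes
#' modes. CWRES is the conditional weighted residual from the FOCE
#' linearisation about `eta-hat`: the whitened marginal residual
#' `L^-1 (ln Y - ln F(eta-hat) + G eta-hat)` where
#' `G Omega G' + W^2 I = L L'`. Observations with `|CWRES| > threshold` or
#' `|IWRES| > threshold` are flagged as potential outliers.
#'
#' @param fit a `pk_fit`.
#' @param threshold outlier threshold on either residual (default 6).
#' @return A data.frame of class `residual_table`: `ID`, `TIME`, `DV`,
#'   `PRED`, `IPRED` (log scale predictions), `IWRES`, `CWRES`, `outlier`.
#' @export
compute_residuals <- function(fit, threshold = 6) {
  stopifnot(inherits(fit, "pk_fit"))
  tab <- fit$diag
  tab$outlier <- abs(tab$CWRES) > threshold | abs(tab$IWRES) > threshold
  attr(tab, "threshold") <- threshold
  class(tab) <- c("residual_table", "data.frame")
  tab
}

#' @export
print.residual_table <- function(x, ...) {
  cat(sprintf("%d observations, %d flagged (|CWRES| or |IWRES| > %g)\n",
              nrow(x), sum(x$outlier), attr(x, "threshold")))
  invisible(x)
}

#' Influence of flagged outliers on the parameter estimates
#'
#' Refits the model without the flagged observations and reports the
#' relative change in each key parameter. The outliers are influential if
#' any key parameter changes by more than `influence_threshold` (default
#' 20%); in that case the refit without outliers is returned as the
#' recommended final fit.
#'
#' @param ds the fitted [pk_dataset()].
#' @param fit the `pk_fit` on all data.
#' @param residuals a [compute_residuals()] table (or any data.frame with
#'   `ID`, `TIME`, `outlier`).
#' @param influence_threshold relative-change cutoff (fraction, 0.2).
#' @param fixed,control passed to [fit_foce()].
#' @return A list of class `influence_report`: `n_flagged`, `changes`
#'   (named relative changes), `influential`, `refit` (the no-outlier fit,
#'   or `NULL` when nothing was flagged or the refit failed), and
#'   `final_fit` (the fit the procedure keeps).
#' @export
influence_check <- function(ds, fit, residuals,
                            influence_threshold = 0.2,
                            fixed = fit$fixed, control = list()) {
  flagged <- residuals[residuals$outlier, c("ID", "TIME")]
  if (!nrow(flagged)) {
    return(structure(list(n_flagged = 0L, changes = NULL,
                          influential = FALSE, refit = NULL,
                          final_fit = fit), class = "influence_report"))
  }
  df <- as.data.frame(ds)
  key <- paste(df$ID, df$TIME, df$EVID)
  drop <- key %in% paste(flagged$ID, flagged$TIME, 0)
  ds2 <- pk_dataset(df[!drop, , drop = FALSE])
  refit <- try(fit_foce(ds2, fit$spec, init = fit$pop, fixed = fixed,
                        estimate_se = FALSE, control = control),
               silent = TRUE)
  if (inherits(refit, "try-error") || !refit$convergence$ok) {
    return(structure(list(n_flagged = nrow(flagged), changes = NULL,
                          influential = NA, refit = NULL, final_fit = fit,
                          note = "refit without outliers did not converge"),
                     class = "influence_report"))
  }
  keys <- c("CL", "V1", "Q", "V2", "omega2_CL", "omega2_V1", "W")
  keys <- setdiff(keys, fit$fixed)
  changes <- abs(refit$estimates[keys] - fit$estimates[keys]) /
    abs(fit$estimates[keys])
  infl <- any(changes > influence_threshold, na.rm = TRUE)
  structure(list(n_flagged = nrow(flagged), changes = changes,
                 influential = infl, refit = refit,
                 final_fit = if (infl) refit else fit),
            class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf("flagged observations: %d\n", x$n_flagged))
  if (!is.null(x$changes)) {
    cat("relative parameter changes on removal:\n")
    print(signif(x$changes, 3))
    cat(sprintf("influential (> 20%% change): %s\n",
                ifelse(isTRUE(x$influential), "yes -- no-outlier fit adopted",
                       "no")))
  }
  invisible(x)
}

#' Non-parametric bootstrap confidence intervals
#'
#' Resamples subjects (the exchangeable unit) with replacement to the
#' original subject count, refits every replicate from `init`, and reports
#' percentile confidence intervals over the converged replicates.
#'
#' @param ds a [pk_dataset()].
#' @param spec a [cov_model_spec()].
#' @param init initial [pop_params()] (typically the point estimates).
#' @param n_reps number of bootstrap datasets (1000 at production scale).
#' @param seed integer seed.
#' @param stratify optional covariate column name; resampling is then done
#'   within each level (e.g. `"DRUG"`).
#' @param fixed,control passed to [fit_foce()].
#' @param probs percentile probabilities of the interval.
#' @return An object of class `bootstrap_result`: `table` (per parameter:
#'   median, lower, upper), `n_converged`, `n_total`, `estimates` (matrix
#'   of replicate estimates).
#' @export
bootstrap_ci <- function(ds, spec, init, n_reps = 1000, seed = 1,
                         stratify = NULL, fixed = character(),
                         control = list(), probs = c(0.025, 0.5, 0.975)) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  df <- as.data.frame(ds)
  ids <- unique(df$ID)
  rows_by_id <- split(seq_len(nrow(df)), factor(df$ID, levels = ids))
  strat <- if (is.null(stratify)) rep(1L, length(ids)) else
    df[[stratify]][match(ids, df$ID)]
  set.seed(as.integer(seed))
  est_mat <- NULL
  n_conv <- 0L
  for (b in seq_len(n_reps)) {
    pick <- unlist(lapply(unique(strat), function(s) {
      pool <- which(strat == s)
      sample(pool, length(pool), replace = TRUE)
    }), use.names = FALSE)
    parts <- lapply(seq_along(pick), function(j) {
      rec <- df[rows_by_id[[pick[j]]], , drop = FALSE]
      rec$ID <- j
      rec
    })
    bs <- pk_dataset(do.call(rbind, parts))
    fit <- try(fit_foce(bs, spec, init = init, fixed = fixed,
                        estimate_se = FALSE, control = control),
               silent = TRUE)
    ok <- !inherits(fit, "try-error") && fit$convergence$ok
    if (ok) {
      if (is.null(est_mat))
        est_mat <- matrix(NA_real_, n_reps, length(fit$estimates),
                          dimnames = list(NULL, names(fit$estimates)))
      est_mat[b, ] <- fit$estimates
      n_conv <- n_conv + 1L
    }
  }
  if (is.null(est_mat)) stop("no bootstrap replicate converged")
  keep <- stats::complete.cases(est_mat)
  qs <- apply(est_mat[keep, , drop = FALSE], 2, stats::quantile,
              probs = probs, names = FALSE)
  tab <- data.frame(parameter = colnames(est_mat),
                    lower = qs[1, ], median = qs[2, ], upper = qs[3, ])
  rownames(tab) <- NULL
  structure(list(table = tab, n_converged = n_conv, n_total = n_reps,
                 probs = probs, estimates = est_mat[keep, , drop = FALSE]),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %d of %d replicates converged\n",
              x$n_converged, x$n_total))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_trials` replicates of the study using the original dataset's
#' design (dose records, observation times, covariate values) and the
#' estimated parameters, then compares observed percentiles per nominal-time
#' bin with the distribution of the same percentiles across simulated
#' replicates. Bins default to the nominal sample tags (`TAG` column); a
#' numeric binning on nominal time is used when tags are absent. Simulated
#' values below `lloq` are excluded from the percentile computation (M1
#' convention) with the simulated BLQ fraction reported; set
#' `drop_sim_blq = FALSE` to keep them.
#'
#' @param ds the [pk_dataset()] that was fitted.
#' @param spec a [cov_model_spec()].
#' @param pop estimated [pop_params()] used for simulation.
#' @param n_trials number of simulated replicates (1000 at production
#'   scale).
#' @param seed integer seed.
#' @param lloq lower limit of quantification (mg/L); `NULL` disables BLQ
#'   handling.
#' @param drop_sim_blq exclude simulated below-LLOQ values from percentiles.
#' @param probs percentiles compared (default 2.5/50/97.5).
#' @param n_bins number of quantile-spaced time bins when `TAG` is absent.
#' @return An object of class `vpc_result`: per-bin observed percentiles,
#'   simulated percentile point estimates (medians across replicates) with
#'   95% CIs, bin sizes, and the simulated BLQ fraction.
#' @export
vpc <- function(ds, spec, pop, n_trials = 1000, seed = 1, lloq = 0.25,
                drop_sim_blq = TRUE, probs = c(0.025, 0.5, 0.975),
                n_bins = 8) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  df <- as.data.frame(ds)
  blq <- if (!is.null(df$BLQ)) df$BLQ %in% TRUE else rep(FALSE, nrow(df))
  obs <- df[df$EVID == 0 & df$MDV == 0 & !is.na(df$DV) & !blq, , drop = FALSE]
  dose <- df[df$EVID == 1, , drop = FALSE]
  ids <- unique(obs$ID)
  if (!is.null(obs$TAG) && !anyNA(obs$TAG)) {
    bins <- factor(obs$TAG, levels = unique(obs$TAG[order(
      if (!is.null(obs$NTIM)) obs$NTIM else obs$TIME)]))
  } else {
    nt <- if (!is.null(obs$NTIM)) obs$NTIM else obs$TIME
    br <- unique(stats::quantile(nt, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(nt, breaks = br, include.lowest = TRUE)
  }

  cov_df <- obs[match(ids, obs$ID), , drop = FALSE]
  sp_by_id <- lapply(seq_along(ids), function(i)
    typical_values(pop, spec, as.list(cov_df[i, , drop = FALSE])))
  dose_by_id <- split(dose, factor(dose$ID, levels = ids))
  obs_idx_by_id <- split(seq_len(nrow(obs)), factor(obs$ID, levels = ids))

  set.seed(as.integer(seed))
  nb <- nlevels(bins)
  np <- length(probs)
  sim_pct <- array(NA_real_, c(n_trials, nb, np))
  blq_frac <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    simdv <- numeric(nrow(obs))
    for (i in seq_along(ids)) {
      eta <- c(CL = stats::rnorm(1, 0, sqrt(pop$omega2[["CL"]])),
               V1 = stats::rnorm(1, 0, sqrt(pop$omega2[["V1"]])))
      spi <- individual_params(sp_by_id[[i]], eta)
      d <- dose_by_id[[i]]
      idx <- obs_idx_by_id[[i]]
      f <- cpp_conc(obs$TIME[idx], d$TIME, d$AMT, d$AMT / d$RATE,
                    spi$CL, spi$V1, spi$Q, spi$V2)
      simdv[idx] <- exp(log(f) + pop$W * stats::rnorm(length(idx)))
    }
    isblq <- if (!is.null(lloq)) simdv < lloq else rep(FALSE, length(simdv))
    blq_frac[tr] <- mean(isblq)
    use <- if (drop_sim_blq) !isblq else rep(TRUE, length(simdv))
    for (bkt in seq_len(nb)) {
      sel <- use & as.integer(bins) == bkt
      if (any(sel))
        sim_pct[tr, bkt, ] <- stats::quantile(simdv[sel], probs = probs,
                                              names = FALSE)
    }
  }

  obs_tab <- data.frame(bin = levels(bins),
                        n = as.integer(table(bins)),
                        t(vapply(seq_len(nb), function(bkt)
                          stats::quantile(obs$DV[as.integer(bins) == bkt],
                                          probs = probs, names = FALSE),
                          numeric(np))))
  names(obs_tab)[3:(2 + np)] <- paste0("obs_p", 100 * probs)
  sim_cols <- list()
  for (j in seq_len(np)) {
    m <- sim_pct[, , j, drop = FALSE]
    dim(m) <- c(n_trials, nb)
    sim_cols[[paste0("sim_p", 100 * probs[j])]] <-
      apply(m, 2, stats::median, na.rm = TRUE)
    sim_cols[[paste0("sim_p", 100 * probs[j], "_lo")]] <-
      apply(m, 2, stats::quantile, probs = 0.025, na.rm = TRUE, names = FALSE)
    sim_cols[[paste0("sim_p", 100 * probs[j], "_hi")]] <-
      apply(m, 2, stats::quantile, probs = 0.975, na.rm = TRUE, names = FALSE)
  }
  out <- cbind(obs_tab, as.data.frame(sim_cols))
  structure(list(table = out, probs = probs, n_trials = n_trials,
                 sim_blq_fraction = mean(blq_frac),
                 drop_sim_blq = drop_sim_blq),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC over %d simulated trials (simulated BLQ fraction %.3g%s)\n",
              x$n_trials, x$sim_blq_fraction,
              if (x$drop_sim_blq) ", excluded" else ", retained"))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
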