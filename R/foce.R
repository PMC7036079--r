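# Nonlinear mixed-effects estimation by FOCE with eta-eps interaction.
# The per-subject inner problem (empirical Bayes modes, linearised marginal
# likelihood) is compiled (src/pkcore.cpp); this file owns data preparation,
# the outer quasi-Newton minimisation, standard errors and shrinkage.

# Flatten a pk_dataset into the arrays the compiled objective consumes.
nlme_prep <- function(ds, spec) {
  df <- as.data.frame(ds)
  blq <- if (!is.null(df$BLQ)) df$BLQ %in% TRUE else rep(FALSE, nrow(df))
  obs <- df[df$EVID == 0 & df$MDV == 0 & !is.na(df$DV) & !blq, , drop = FALSE]
  dose <- df[df$EVID == 1, , drop = FALSE]
  if (!nrow(obs)) stop("no usable observations in dataset")
  ids <- unique(obs$ID)
  dose <- dose[dose$ID %in% ids, , drop = FALSE]
  obs <- obs[order(match(obs$ID, ids), obs$TIME), , drop = FALSE]
  dose <- dose[order(match(dose$ID, ids), dose$TIME), , drop = FALSE]
  first_dose <- tapply(dose$TIME, dose$ID, min)[as.character(ids)]
  if (any(is.na(first_dose)))
    stop("subject(s) with observations but no dose records")
  fd_obs <- as.numeric(first_dose[match(obs$ID, ids)])
  if (any(obs$TIME <= fd_obs))
    stop("observations at or before the first dose cannot be fitted on the ",
         "log scale; apply_exclusions() or remove pre-first-dose samples")
  obs_n <- as.integer(table(factor(obs$ID, levels = ids)))
  dose_n <- as.integer(table(factor(dose$ID, levels = ids)))
  covnames <- unique(c("BWT", "SEXM", "DRUG",
                       vapply(spec$terms, function(tr) tr$cov, character(1))))
  covnames <- intersect(covnames, names(obs))
  cov_df <- obs[match(ids, obs$ID), covnames, drop = FALSE]
  rownames(cov_df) <- NULL
  list(ids = ids,
       lny = log(obs$DV), obs_t = obs$TIME,
       obs_ptr = c(0L, cumsum(obs_n)),
       dose_t = dose$TIME, dose_amt = dose$AMT,
       dose_dur = dose$AMT / dose$RATE,
       dose_ptr = c(0L, cumsum(dose_n)),
       cov_df = cov_df, obs = obs, n_obs = nrow(obs))
}

#' FOCE-I objective function value and empirical Bayes modes
#'
#' Evaluates the approximate marginal -2 log-likelihood of the population
#' model on a dataset. Per subject, the empirical Bayes mode `eta-hat`
#' maximises the joint density of the data and the random effects; the
#' marginal contribution is the first-order conditional (linearised)
#' approximation `log det(Sigma) + r' Sigma^-1 r` with
#' `Sigma = G Omega G' + W^2 I` and `r_i = ln(y) - ln(F(eta-hat)) + G eta-hat`,
#' where `G` is the Jacobian of the log-predictions at `eta-hat`. With the
#' log-additive residual model the residual variance does not depend on
#' `eta`, so the eta-eps interaction term is exact by construction. The
#' additive constant `n log(2 pi)` is omitted, as is conventional for
#' reported objective function values; only differences in OFV between
#' nested models are interpretable.
#'
#' @param pop a [pop_params()] at which to evaluate.
#' @param ds a [pk_dataset()] (already past exclusions).
#' @param spec a [cov_model_spec()].
#' @param eta_start optional matrix of starting eta values (subjects x 2).
#' @param want_diag also return predictions and residuals.
#' @return A list with `ofv`, per-subject `ofv_i`, `eta` (empirical Bayes
#'   modes), `ok` (per-subject inner convergence), and when `want_diag`
#'   also `pred`, `ipred`, `cwres`, `iwres` on the log scale, aligned with
#'   the fitted observation rows (`obs`).
#' @export
foce_objective <- function(pop, ds, spec, eta_start = NULL,
                           want_diag = FALSE) {
  prep <- if (is.list(ds) && !is.null(ds$obs_ptr)) ds else nlme_prep(ds, spec)
  tv <- tv_matrix(pop, spec, prep$cov_df)
  ns <- length(prep$ids)
  if (is.null(eta_start)) eta_start <- matrix(0, ns, 2)
  res <- cpp_foce(prep$lny, prep$obs_t, prep$obs_ptr,
                  prep$dose_t, prep$dose_amt, prep$dose_dur, prep$dose_ptr,
                  tv$CL, tv$V1, tv$Q, tv$V2,
                  pop$omega2[["CL"]], pop$omega2[["V1"]], pop$W,
                  eta_start, want_diag)
  res$ids <- prep$ids
  if (want_diag) res$obs <- prep$obs
  res
}

# ---- parameter transform table ----------------------------------------

par_table <- function(init, spec, fixed = character()) {
  nm <- c("CL", "V1", "Q", "V2")
  trans <- rep("log", 4)
  vals <- c(init$CL, init$V1, init$Q, init$V2)
  for (tr in spec$terms) {
    nm <- c(nm, tr$id)
    trans <- c(trans, if (tr$form == "ratio") "log" else "identity")
    th <- unname(init$theta[match(tr$id, names(init$theta))])
    if (is.na(th)) th <- switch(tr$form, power = 0.5, fractional = 0,
                                ratio = 1)
    vals <- c(vals, th)
  }
  nm <- c(nm, "omega2_CL", "omega2_V1", "W")
  trans <- c(trans, "log", "log", "log")
  vals <- c(vals, init$omega2[["CL"]], init$omega2[["V1"]], init$W)
  est <- !(nm %in% fixed)
  bad <- setdiff(fixed, nm)
  if (length(bad)) stop("unknown parameter(s) in 'fixed': ",
                        paste(bad, collapse = ", "))
  zero_om <- nm %in% c("omega2_CL", "omega2_V1") & vals == 0
  if (any(zero_om & est))
    stop("omega^2 initialised at 0 must be listed in 'fixed' ",
         "(no random effect) or given a positive initial value")
  data.frame(name = nm, trans = trans, value = vals, est = est,
             stringsAsFactors = FALSE)
}

to_trans <- function(v, trans) ifelse(trans == "log", log(v), v)
from_trans <- function(x, trans) ifelse(trans == "log", exp(x), x)

pop_from_values <- function(vals, spec) {
  theta <- vals[vapply(spec$terms, function(tr) tr$id, character(1))]
  pop_params(CL = vals[["CL"]], V1 = vals[["V1"]], Q = vals[["Q"]],
             V2 = vals[["V2"]],
             theta = theta,
             omega2 = c(CL = vals[["omega2_CL"]], V1 = vals[["omega2_V1"]]),
             W = vals[["W"]])
}

#' Default initial estimates
#'
#' Literature-scale starting values for an IgG-type antibody: CL 0.01 L/h,
#' V1 3 L, Q 0.3 L/h, V2 6 L, omega^2 0.1, W 0.3; power coefficients start
#' at 0.5, fractional at 0, ratio at 1.
#'
#' @param spec a [cov_model_spec()] (supplies the coefficient slots).
#' @return A [pop_params()] object.
#' @export
default_init <- function(spec = cov_model_spec()) {
  theta <- vapply(spec$terms, function(tr)
    switch(tr$form, power = 0.5, fractional = 0, ratio = 1), numeric(1))
  names(theta) <- vapply(spec$terms, function(tr) tr$id, character(1))
  pop_params(CL = 0.01, V1 = 3, Q = 0.3, V2 = 6, theta = theta,
             omega2 = c(CL = 0.1, V1 = 0.1), W = 0.3)
}

fd_hessian <- function(fn, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hs <- pmax(abs(x) * h, h)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, hs[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hs[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, hs[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * hs[i] * hs[j])
    }
  }
  H
}

#' Fit the population model by FOCE-I
#'
#' Outer quasi-Newton (PORT) minimisation of the FOCE-I objective over
#' transformed parameters: typical values, ratio-form coefficients, random
#' effect variances and the residual scale on the log scale; power and
#' fractional coefficients unconstrained. Standard errors come from the
#' inverse of the numerical Hessian of `OFV/2` with a delta-method
#' back-transform to the natural scale; the condition number is the
#' eigenvalue ratio of the correlation matrix of the estimates.
#'
#' @param ds a [pk_dataset()] that has passed [apply_exclusions()].
#' @param spec a [cov_model_spec()].
#' @param init initial [pop_params()]; defaults to [default_init()].
#' @param fixed character vector of parameter names held at their initial
#'   values (`"CL"`, `"V1"`, `"Q"`, `"V2"`, term ids, `"omega2_CL"`,
#'   `"omega2_V1"`, `"W"`). An `omega^2` fixed at zero removes that random
#'   effect.
#' @param estimate_se compute the covariance step (adds ~2 p^2 objective
#'   evaluations).
#' @param se_method `"hessian"` (inverse Hessian of OFV/2, the default) or
#'   `"sandwich"` (H^-1 B H^-1 with B the cross-product of per-subject
#'   score vectors; robust to mild model misspecification).
#' @param control list: `iter.max` (default 500), `eval.max` (4000),
#'   `rel.tol` (1e-10), `se_h` (Hessian step, 1e-3), `trace` (0).
#' @return An object of class `pk_fit`: estimates (`pop`), `se` and `rse`
#'   on the natural scale, `ofv`, empirical Bayes `eta` modes, `shrinkage`,
#'   `condition_number`, `convergence` metadata, and a residual table
#'   (`diag`).
#' @examples
#' \donttest{
#' ds <- simulate_trial(trial_design(n_subjects = 30, n_cycles = 6), seed = 7)
#' fit <- fit_foce(ds, bev_final_spec(), init = bev_final_params(),
#'                 estimate_se = FALSE)
#' coef(fit)
#' }
#' @export
fit_foce <- function(ds, spec, init = default_init(spec),
                     fixed = character(), estimate_se = TRUE,
                     se_method = c("hessian", "sandwich"),
                     control = list()) {
  se_method <- match.arg(se_method)
  ctl <- utils::modifyList(list(iter.max = 500, eval.max = 4000,
                                rel.tol = 1e-10, se_h = 1e-3, trace = 0),
                           control)
  prep <- nlme_prep(ds, spec)
  pt <- par_table(init, spec, fixed)
  ns <- length(prep$ids)
  state <- new.env(parent = emptyenv())
  state$eta <- matrix(0, ns, 2)
  state$neval <- 0L
  full_trans <- to_trans(pt$value, pt$trans)

  obj <- function(x_est) {
    xt <- full_trans
    xt[pt$est] <- x_est
    vals <- from_trans(xt, pt$trans)
    names(vals) <- pt$name
    pop <- pop_from_values(vals, spec)
    r <- foce_objective(pop, prep, spec, eta_start = state$eta)
    state$neval <- state$neval + 1L
    if (!all(r$ok)) return(1e10)
    state$eta <- r$eta
    if (!is.finite(r$ofv)) return(1e10)
    r$ofv
  }

  start <- full_trans[pt$est]
  nlctl <- list(iter.max = ctl$iter.max, eval.max = ctl$eval.max,
                rel.tol = ctl$rel.tol, trace = ctl$trace)
  opt <- stats::nlminb(start, obj, control = nlctl)
  # PORT's "false convergence" is common with finite-difference gradients on
  # a conditionally-optimised objective; restart from the candidate optimum
  # and accept when a restart no longer moves the OFV.
  restarts <- 0L
  while (opt$convergence != 0 && restarts < 2L) {
    opt2 <- stats::nlminb(opt$par, obj, control = nlctl)
    improved <- opt$objective - opt2$objective
    stalled <- improved < 1e-3 + 1e-8 * abs(opt$objective)
    if (opt2$objective <= opt$objective) opt <- opt2
    restarts <- restarts + 1L
    if (stalled) { opt$convergence <- 0L
                   opt$message <- paste0(opt$message, " [stationary restart]")
                   break }
    if (opt2$convergence == 0) break
  }
  xt <- full_trans
  xt[pt$est] <- opt$par
  vals <- from_trans(xt, pt$trans)
  names(vals) <- pt$name
  pop <- pop_from_values(vals, spec)
  final <- foce_objective(pop, prep, spec, eta_start = state$eta,
                          want_diag = TRUE)
  converged <- opt$convergence == 0 && all(final$ok)

  se_nat <- rep(NA_real_, nrow(pt))
  names(se_nat) <- pt$name
  vcov_t <- NULL
  condno <- NA_real_
  cov_ok <- FALSE
  if (estimate_se) {
    H <- try(fd_hessian(function(x) obj(x) / 2, opt$par, h = ctl$se_h),
             silent = TRUE)
    if (!inherits(H, "try-error") && all(is.finite(H))) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0) {
        vcov_t <- solve(H)
        if (se_method == "sandwich") {
          # B = cross-product of per-subject scores (central differences of
          # the subject-level OFV contributions)
          obj_i <- function(x_est) {
            xt <- full_trans
            xt[pt$est] <- x_est
            v <- from_trans(xt, pt$trans)
            names(v) <- pt$name
            foce_objective(pop_from_values(v, spec), prep, spec,
                           eta_start = state$eta)$ofv_i
          }
          p <- length(opt$par)
          hs <- pmax(abs(opt$par) * ctl$se_h, ctl$se_h)
          scores <- matrix(0, ns, p)
          for (j in seq_len(p)) {
            e <- replace(numeric(p), j, hs[j])
            scores[, j] <- -0.5 * (obj_i(opt$par + e) - obj_i(opt$par - e)) /
              (2 * hs[j])
          }
          vcov_t <- vcov_t %*% crossprod(scores) %*% vcov_t
        }
        set <- sqrt(diag(vcov_t))
        deriv <- ifelse(pt$trans[pt$est] == "log", vals[pt$est], 1)
        se_nat[pt$est] <- set * abs(deriv)
        cr <- stats::cov2cor(vcov_t)
        evc <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
        condno <- max(evc) / min(evc)
        cov_ok <- TRUE
      }
    }
  }

  est <- vals
  eta <- final$eta
  rownames(eta) <- as.character(final$ids)
  fit <- structure(list(
    pop = pop, spec = spec, estimates = est, se = se_nat,
    rse = 100 * se_nat / abs(est),
    fixed = pt$name[!pt$est], par_table = pt, vcov_trans = vcov_t,
    ofv = final$ofv, ofv_i = final$ofv_i, eta = eta,
    condition_number = condno, cov_step_ok = cov_ok,
    convergence = list(code = opt$convergence, message = opt$message,
                       ok = converged, inner_ok = all(final$ok),
                       n_eval = state$neval, iterations = opt$iterations),
    diag = data.frame(ID = final$obs$ID, TIME = final$obs$TIME,
                      NTIM = if (!is.null(final$obs$NTIM)) final$obs$NTIM
                             else final$obs$TIME,
                      TAG = if (!is.null(final$obs$TAG)) final$obs$TAG
                            else NA_character_,
                      DV = final$obs$DV,
                      PRED = final$pred, IPRED = final$ipred,
                      IWRES = final$iwres, CWRES = final$cwres),
    n_subjects = ns, n_obs = prep$n_obs), class = "pk_fit")
  fit$shrinkage <- compute_shrinkage(fit)
  fit
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE-I fit: %d subjects, %d observations, OFV = %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  cat(sprintf("convergence: %s (%d objective evaluations)\n",
              if (x$convergence$ok) "ok" else "NOT converged",
              x$convergence$n_eval))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    se = signif(x$se, 3),
                    `rse%` = signif(x$rse, 3), check.names = FALSE)
  fixed <- rownames(tab) %in% x$fixed
  rownames(tab)[fixed] <- paste0(rownames(tab)[fixed], " (fix)")
  print(tab)
  if (!is.na(x$condition_number))
    cat(sprintf("condition number: %.4g\n", x$condition_number))
  sh <- x$shrinkage
  cat(sprintf("shrinkage%%: eta_CL %.3g, eta_V1 %.3g, eps %.3g\n",
              sh[["eta_CL"]], sh[["eta_V1"]], sh[["eps"]]))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) object$estimates

#' Eta and epsilon shrinkage of a fit
#'
#' `eta`-shrinkage per random effect is `100 * (1 - SD(eta-hat) / omega)`;
#' `eps`-shrinkage is `100 * (1 - SD(IWRES))`. A variance of zero gives
#' `NA` (undefined).
#'
#' @param fit a `pk_fit`.
#' @return Named vector `eta_CL`, `eta_V1`, `eps` (percent).
#' @export
compute_shrinkage <- function(fit) {
  om <- fit$pop$omega2
  sh <- c(eta_CL = NA_real_, eta_V1 = NA_real_, eps = NA_real_)
  if (om[["CL"]] > 0)
    sh[["eta_CL"]] <- 100 * (1 - stats::sd(fit$eta[, 1]) / sqrt(om[["CL"]]))
  if (om[["V1"]] > 0)
    sh[["eta_V1"]] <- 100 * (1 - stats::sd(fit$eta[, 2]) / sqrt(om[["V1"]]))
  sh[["eps"]] <- 100 * (1 - stats::sd(fit$diag$IWRES))
  sh
}

#' Coefficient of variation of a log-normal random effect
#'
#' Reports inter-individual variability as `CV% = 100 * sqrt(omega^2)`, the
#' convention under which variances of 0.0871 and 0.117 read as 29.5% and
#' 34.2%.
#'
#' @param omega2 non-negative variance(s) of `eta`.
#' @return CV in percent.
#' @examples
#' cv_percent(c(0.0871, 0.117))
#' @export
cv_percent <- function(omega2) {
  if (any(omega2 < 0)) stop("omega^2 must be non-negative")
  100 * sqrt(omega2)
}

#' Serialise a fit to JSON
#'
#' @param fit a `pk_fit`.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  out <- list(estimates = as.list(fit$estimates), se = as.list(fit$se),
              ofv = fit$ofv, condition_number = fit$condition_number,
              shrinkage = as.list(fit$shrinkage),
              convergence = fit$convergence,
              fixed = fit$fixed,
              eta = list(ID = rownames(fit$eta),
                         CL = unname(fit$eta[, 1]),
                         V1 = unname(fit$eta[, 2])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
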