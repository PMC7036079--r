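# Stepwise covariate modeling: forward inclusion / backward elimination by
# likelihood-ratio testing on the FOCE-I objective.

#' Likelihood-ratio decision for nested models
#'
#' Accepts the larger model iff the OFV improvement exceeds the chi-square
#' critical value at level `alpha` with `df` degrees of freedom.
#'
#' @param delta_ofv OFV(reduced) - OFV(full), improvement convention
#'   (>= 0 when the larger model fits better; negative values never accept).
#' @param df degrees of freedom added, >= 1.
#' @param alpha significance level.
#' @return A list with `accept`, `p` and the critical `threshold`.
#' @examples
#' lrt_decision(3.9, 1, 0.05)
#' @export
lrt_decision <- function(delta_ofv, df, alpha) {
  if (df < 1) stop("df must be >= 1")
  thr <- stats::qchisq(1 - alpha, df)
  p <- stats::pchisq(max(delta_ofv, 0), df, lower.tail = FALSE)
  list(accept = delta_ofv > thr, p = p, threshold = thr)
}

scm_fit <- function(ds, terms, init_pop, fixed, control, base_spec_ids) {
  spec <- cov_model_spec(terms)
  theta <- as.list(init_pop$theta)
  for (tr in terms) if (is.null(theta[[tr$id]]) || is.na(theta[[tr$id]]))
    theta[[tr$id]] <- switch(tr$form, power = 0, fractional = 0, ratio = 1)
  ids <- vapply(terms, function(tr) tr$id, character(1))
  theta <- unlist(theta[ids])
  init <- pop_params(init_pop$CL, init_pop$V1, init_pop$Q, init_pop$V2,
                     theta = theta, omega2 = init_pop$omega2, W = init_pop$W)
  fit <- try(fit_foce(ds, spec, init = init, fixed = fixed,
                      estimate_se = FALSE, control = control), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$convergence$ok) return(NULL)
  fit
}

#' Stepwise covariate model building
#'
#' Forward inclusion: at each round every remaining candidate term is added
#' to the working model and refitted; the candidate with the largest
#' significant OFV drop (LRT at `alpha_forward`) enters. Backward
#' elimination: terms are removed one at a time, dropping the
#' least-significant term whose removal is not rejected at
#' `alpha_backward`. Terms in `forced` are always present and exempt from
#' elimination (used for the drug-product effect, which is retained to
#' quantify its ratio regardless of significance). The final model is
#' refitted with the covariance step and flagged as overparameterised when
#' the condition number exceeds 1000.
#'
#' Ties among equally significant candidates break by largest OFV drop,
#' then lexicographic `(parameter, covariate)`.
#'
#' @param ds a [pk_dataset()].
#' @param base_spec [cov_model_spec()] of the base (structural) model.
#' @param candidates list of [cov_term()] candidates (df = 1 each).
#' @param forced list of [cov_term()] always kept in the model.
#' @param init initial [pop_params()] for the base fit.
#' @param alpha_forward,alpha_backward significance levels (0.05 / 0.001).
#' @param fixed,control passed to [fit_foce()].
#' @return An object of class `scm_trace`: `steps` (data.frame of every
#'   decision), `final_spec`, `final_fit`, `overparameterized`.
#' @export
run_scm <- function(ds, base_spec, candidates, forced = list(),
                    init = default_init(base_spec),
                    alpha_forward = 0.05, alpha_backward = 0.001,
                    fixed = character(), control = list()) {
  base_ids <- vapply(base_spec$terms, function(tr) tr$id, character(1))
  work <- c(base_spec$terms, forced)
  steps <- data.frame()
  log_step <- function(direction, id, delta, p, accepted, note = "") {
    steps <<- rbind(steps, data.frame(
      direction = direction, term = id, delta_ofv = delta, df = 1L,
      p = p, accepted = accepted, note = note))
  }

  fit0 <- scm_fit(ds, work, init, fixed, control, base_ids)
  if (is.null(fit0)) stop("base model fit failed")
  pool <- candidates

  repeat {
    if (!length(pool)) break
    best <- NULL
    keep_pool <- logical(length(pool))
    for (k in seq_along(pool)) {
      cand <- pool[[k]]
      if (cand$id %in% vapply(work, function(tr) tr$id, character(1))) next
      fit1 <- scm_fit(ds, c(work, list(cand)), fit0$pop, fixed, control,
                      base_ids)
      if (is.null(fit1)) {
        log_step("forward", cand$id, NA, NA, FALSE, "fit failed, skipped")
        keep_pool[k] <- TRUE
        next
      }
      delta <- fit0$ofv - fit1$ofv
      dec <- lrt_decision(delta, 1, alpha_forward)
      keep_pool[k] <- TRUE
      if (dec$accept &&
          (is.null(best) || delta > best$delta + 1e-9 ||
           (abs(delta - best$delta) <= 1e-9 &&
            paste(cand$param, cand$cov) < paste(best$cand$param, best$cand$cov)))) {
        best <- list(cand = cand, fit = fit1, delta = delta, p = dec$p,
                     k = k)
      }
      log_step("forward", cand$id, delta, dec$p, FALSE)
    }
    if (is.null(best)) break
    steps$accepted[steps$direction == "forward" &
                     steps$term == best$cand$id &
                     !is.na(steps$delta_ofv) &
                     abs(steps$delta_ofv - best$delta) < 1e-12] <- TRUE
    work <- c(work, list(best$cand))
    fit0 <- best$fit
    pool <- pool[-best$k]
  }

  # backward elimination over non-base, non-forced terms
  forced_ids <- vapply(forced, function(tr) tr$id, character(1))
  repeat {
    removable <- Filter(function(tr)
      !(tr$id %in% base_ids) && !(tr$id %in% forced_ids), work)
    if (!length(removable)) break
    worst <- NULL
    for (cand in removable) {
      reduced <- Filter(function(tr) tr$id != cand$id, work)
      fitr <- scm_fit(ds, reduced, fit0$pop, fixed, control, base_ids)
      if (is.null(fitr)) {
        log_step("backward", cand$id, NA, NA, FALSE, "fit failed, skipped")
        next
      }
      delta <- fitr$ofv - fit0$ofv  # cost of removal
      dec <- lrt_decision(delta, 1, alpha_backward)
      if (!dec$accept &&
          (is.null(worst) || delta < worst$delta - 1e-9 ||
           (abs(delta - worst$delta) <= 1e-9 &&
            paste(cand$param, cand$cov) < paste(worst$cand$param, worst$cand$cov)))) {
        worst <- list(cand = cand, fit = fitr, delta = delta, p = dec$p)
      }
      log_step("backward", cand$id, delta, dec$p, FALSE)
    }
    if (is.null(worst)) break
    steps$accepted[steps$direction == "backward" &
                     steps$term == worst$cand$id &
                     !is.na(steps$delta_ofv) &
                     abs(steps$delta_ofv - worst$delta) < 1e-12] <- TRUE
    work <- Filter(function(tr) tr$id != worst$cand$id, work)
    fit0 <- worst$fit
  }

  final_spec <- cov_model_spec(work)
  final_fit <- fit_foce(ds, final_spec, init = fit0$pop, fixed = fixed,
                        estimate_se = TRUE, control = control)
  over <- isTRUE(final_fit$condition_number > 1000) || !final_fit$cov_step_ok
  structure(list(steps = steps, final_spec = final_spec,
                 final_fit = final_fit, overparameterized = over,
                 alpha_forward = alpha_forward,
                 alpha_backward = alpha_backward),
            class = "scm_trace")
}

#' @export
print.scm_trace <- function(x, ...) {
  cat(sprintf("SCM trace (forward alpha %g, backward alpha %g)\n",
              x$alpha_forward, x$alpha_backward))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE) else cat("  no steps\n")
  cat("final model terms:\n")
  print(x$final_spec)
  if (x$overparameterized)
    cat("WARNING: final model flagged as overparameterized\n")
  invisible(x)
}

#' Screening statistics of empirical Bayes etas against covariates
#'
#' Automates the usual visual eta-vs-covariate screening: Pearson
#' correlation tests for continuous covariates and one-way ANOVA for
#' categorical ones, for each random effect. The SCM candidate list remains
#' user-supplied; this report only ranks covariates worth testing.
#'
#' @param fit a `pk_fit`.
#' @param ds the fitted [pk_dataset()].
#' @param covariates character vector of covariate column names.
#' @param categorical names within `covariates` to treat as categorical.
#' @return A data.frame with one row per (eta, covariate): statistic and p.
#' @export
eta_screen <- function(fit, ds, covariates,
                       categorical = intersect(covariates,
                                               c("SEXM", "DRUG", "ECOG"))) {
  df <- as.data.frame(ds)
  ids <- rownames(fit$eta)
  cov_rows <- df[match(ids, as.character(df$ID)), covariates, drop = FALSE]
  out <- data.frame()
  for (j in c(1, 2)) {
    if (fit$pop$omega2[[c("CL", "V1")[j]]] <= 0) next
    eta <- fit$eta[, j]
    for (cv in covariates) {
      v <- cov_rows[[cv]]
      if (cv %in% categorical) {
        fitaov <- stats::aov(eta ~ factor(v))
        p <- summary(fitaov)[[1]][["Pr(>F)"]][1]
        stat <- summary(fitaov)[[1]][["F value"]][1]
        kind <- "anova-F"
      } else {
        ct <- stats::cor.test(eta, v)
        p <- ct$p.value
        stat <- unname(ct$estimate)
        kind <- "pearson-r"
      }
      out <- rbind(out, data.frame(eta = paste0("eta_", c("CL", "V1")[j]),
                                   covariate = cv, statistic = stat,
                                   kind = kind, p = p))
    }
  }
  out[order(out$p), , drop = FALSE]
}

#' Serialise an SCM trace to JSON
#'
#' @param trace an `scm_trace`.
#' @param path output path.
#' @export
write_scm_trace <- function(trace, path) {
  out <- list(steps = trace$steps,
              final_terms = vapply(trace$final_spec$terms,
                                   function(tr) tr$id, character(1)),
              final_ofv = trace$final_fit$ofv,
              overparameterized = trace$overparameterized)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
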