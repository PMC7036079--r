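#' Two-compartment disposition parameters
#'
#' Container for the structural parameters of a two-compartment disposition
#' model with first-order elimination from the central compartment: systemic
#' clearance `CL` (L/h), central volume `V1` (L), intercompartmental
#' clearance `Q` (L/h) and peripheral volume `V2` (L).
#'
#' `Q = 0` is accepted and collapses the model to one compartment; all other
#' parameters must be strictly positive.
#'
#' @param CL,V1,Q,V2 numeric scalars (L/h, L, L/h, L).
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(CL = 0.0113, V1 = 2.99, Q = 0.269, V2 = 6.09)
#' @export
structural_params <- function(CL, V1, Q, V2) {
  vals <- c(CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (any(!is.finite(vals))) stop("structural parameters must be finite")
  if (CL <= 0 || V1 <= 0 || V2 <= 0 || Q < 0)
    stop("CL, V1, V2 must be > 0 and Q >= 0")
  structure(as.list(vals), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("CL = %g L/h, V1 = %g L, Q = %g L/h, V2 = %g L\n",
              x$CL, x$V1, x$Q, x$V2))
  invisible(x)
}

#' Micro and hybrid rate constants of the two-compartment model
#'
#' Converts `(CL, V1, Q, V2)` to the micro constants `k10 = CL/V1`,
#' `k12 = Q/V1`, `k21 = Q/V2` and the hybrid disposition constants
#' `alpha >= beta`, the roots of
#' `lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0`.
#'
#' @param sp a [structural_params()] object.
#' @return A list with `k10`, `k12`, `k21`, `alpha`, `beta` (1/h).
#' @examples
#' micro_to_macro(structural_params(0.0113, 2.99, 0.269, 6.09))
#' @export
micro_to_macro <- function(sp) {
  stopifnot(inherits(sp, "structural_params"))
  k10 <- sp$CL / sp$V1
  k12 <- sp$Q / sp$V1
  k21 <- if (sp$Q > 0) sp$Q / sp$V2 else 0
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- if (alpha > 0) p / alpha else 0
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Dosing events
#'
#' One row per zero-order (constant-rate) intravenous infusion.
#'
#' @param start infusion start times (h).
#' @param amount dose amounts (mg), strictly positive.
#' @param duration infusion durations (h), strictly positive.
#' @return A `data.frame` of class `dose_events`.
#' @export
dose_events <- function(start, amount, duration) {
  if (any(amount <= 0)) stop("dose amounts must be > 0")
  if (any(duration <= 0)) stop("infusion durations must be > 0")
  if (any(start < 0)) stop("dose start times must be >= 0")
  structure(data.frame(start = start, amount = amount, duration = duration),
            class = c("dose_events", "data.frame"))
}

#' Central-compartment concentration under superposed infusions
#'
#' Closed-form (bi-exponential) central concentration of the two-compartment
#' IV-infusion model, superposed over a dosing history. The during-infusion
#' and post-infusion branches are handled by representing each finite
#' infusion as the difference of two never-ending infusions; the
#' concentration is continuous in `t` and zero before the first dose.
#'
#' @param t numeric vector of times (h), non-negative.
#' @param doses a [dose_events()] data frame.
#' @param sp a [structural_params()] object.
#' @return Central concentrations (mg/L) at `t`.
#' @examples
#' sp <- structural_params(0.0113, 2.99, 0.269, 6.09)
#' d <- dose_events(0, 1065, 1.5)
#' concentration(c(0, 1.5, 24, 504), d, sp)
#' @export
concentration <- function(t, doses, sp) {
  stopifnot(inherits(sp, "structural_params"))
  if (any(t < 0)) stop("times must be non-negative")
  doses <- as.data.frame(doses)
  cpp_conc(as.numeric(t), as.numeric(doses$start), as.numeric(doses$amount),
           as.numeric(doses$duration), sp$CL, sp$V1, sp$Q, sp$V2)
}

# ---- covariate model ---------------------------------------------------

#' Covariate model specification
#'
#' A covariate model is a list of multiplicative terms on the typical values
#' of the structural parameters. Three functional forms are supported, all
#' evaluating to a factor of 1 at the reference covariate value:
#'
#' * `power`: `(COV / ref)^theta` for a continuous covariate with reference
#'   (median) value `ref`;
#' * `fractional`: `1 + theta` when the categorical covariate equals
#'   `level`, 1 otherwise (multi-level categories contribute one term per
#'   non-reference level);
#' * `ratio`: `theta^COV` for a 0/1-coded covariate, so `theta` is the
#'   multiplicative ratio of the non-reference group (used for the
#'   drug-product effect, numerically stabler near 1).
#'
#' Coefficients `theta` live in [pop_params()], keyed by the term id
#' `"<param>~<cov>"` (plus `"==<level>"` for extra factor levels), so the
#' same specification can be re-evaluated along an optimisation path.
#'
#' @param terms a list of terms created by [cov_term()].
#' @return An object of class `cov_model_spec`.
#' @seealso [typical_values()], [pop_params()]
#' @export
cov_model_spec <- function(terms = list()) {
  ids <- vapply(terms, function(tr) tr$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate covariate terms: ", paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(terms = terms), class = "cov_model_spec")
}

#' @rdname cov_model_spec
#' @param param structural parameter name (`"CL"`, `"V1"`, `"Q"`, `"V2"`).
#' @param cov covariate column name.
#' @param form `"power"`, `"fractional"` or `"ratio"`.
#' @param ref reference value for `power` terms (> 0).
#' @param level non-reference level (numeric code) for `fractional` terms.
#' @export
cov_term <- function(param, cov, form = c("power", "fractional", "ratio"),
                     ref = NULL, level = 1) {
  form <- match.arg(form)
  param <- match.arg(param, c("CL", "V1", "Q", "V2"))
  if (form == "power") {
    if (is.null(ref) || ref <= 0)
      stop("power terms need a positive reference value")
  }
  id <- paste0(param, "~", cov)
  if (form == "fractional" && level != 1)
    id <- paste0(id, "==", level)
  structure(list(param = param, cov = cov, form = form, ref = ref,
                 level = level, id = id), class = "cov_term")
}

#' @export
print.cov_model_spec <- function(x, ...) {
  if (!length(x$terms)) {
    cat("covariate model: (none)\n")
    return(invisible(x))
  }
  for (tr in x$terms)
    cat(sprintf("  %-12s %-10s on %s%s\n", tr$id, tr$form, tr$param,
                if (tr$form == "power") sprintf(" (ref %g)", tr$ref) else ""))
  invisible(x)
}

#' Population parameters
#'
#' Fixed effects, covariate coefficients, random-effect variances and the
#' residual scale of the mixed-effects model. Inter-individual variability
#' is exponential (`P_j = TVP * exp(eta_j)`, `eta_j ~ N(0, omega^2)`) and is
#' carried on CL and V1 only; the residual model is additive on the log
#' scale, `ln Y = ln F + W * eps` with `eps ~ N(0, 1)`.
#'
#' @param CL,V1,Q,V2 typical values at the reference covariates.
#' @param theta named numeric vector of covariate coefficients, names being
#'   term ids of the accompanying [cov_model_spec()].
#' @param omega2 named numeric vector `c(CL =, V1 =)` of eta variances.
#' @param W residual scale on the log-concentration scale.
#' @return An object of class `pop_params`.
#' @export
pop_params <- function(CL, V1, Q, V2, theta = numeric(0),
                       omega2 = c(CL = 0, V1 = 0), W = 0.3) {
  if (any(c(CL, V1, V2) <= 0) || Q < 0) stop("typical values must be positive")
  if (W <= 0) stop("W must be > 0")
  om <- c(CL = 0, V1 = 0)
  om[names(omega2)] <- omega2
  if (any(om < 0)) stop("omega^2 must be >= 0")
  structure(list(CL = CL, V1 = V1, Q = Q, V2 = V2,
                 theta = theta, omega2 = om, W = W),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat(sprintf("typicals: CL %g L/h, V1 %g L, Q %g L/h, V2 %g L\n",
              x$CL, x$V1, x$Q, x$V2))
  if (length(x$theta)) {
    cat("covariate coefficients:\n")
    for (nm in names(x$theta)) cat(sprintf("  %-14s %g\n", nm, x$theta[[nm]]))
  }
  cat(sprintf("omega^2: CL %g, V1 %g;  residual W: %g\n",
              x$omega2[["CL"]], x$omega2[["V1"]], x$W))
  invisible(x)
}

cov_factor <- function(tr, theta, covs) {
  if (!tr$cov %in% names(covs))
    stop("missing covariate '", tr$cov, "' required by term ", tr$id)
  v <- covs[[tr$cov]]
  if (is.na(v)) stop("covariate '", tr$cov, "' is NA")
  switch(tr$form,
         power = (v / tr$ref)^theta,
         fractional = ifelse(v == tr$level, 1 + theta, 1),
         ratio = theta^v)
}

#' Typical parameter values for a covariate vector
#'
#' Applies the multiplicative covariate model to the population typical
#' values. Order-independent; a missing covariate raises an error naming it.
#'
#' @param pop a [pop_params()] object carrying the coefficients.
#' @param spec a [cov_model_spec()].
#' @param cov named list/vector of covariate values for one subject (e.g.
#'   `list(BWT = 71, SEXM = 1, DRUG = 0)`).
#' @return A [structural_params()] object with the subject's typical values.
#' @examples
#' pop <- bev_final_params()
#' spec <- bev_final_spec()
#' typical_values(pop, spec, list(BWT = 71, SEXM = 0, DRUG = 0))
#' @export
typical_values <- function(pop, spec, cov) {
  stopifnot(inherits(pop, "pop_params"), inherits(spec, "cov_model_spec"))
  cov <- as.list(cov)
  vals <- c(CL = pop$CL, V1 = pop$V1, Q = pop$Q, V2 = pop$V2)
  for (tr in spec$terms) {
    th <- unname(pop$theta[match(tr$id, names(pop$theta))])
    if (is.na(th)) stop("no coefficient for term ", tr$id, " in pop_params")
    vals[[tr$param]] <- vals[[tr$param]] * cov_factor(tr, th, cov)
  }
  structural_params(vals[["CL"]], vals[["V1"]], vals[["Q"]], vals[["V2"]])
}

# Vectorised typical values over a covariate data.frame (one row per
# subject); returns a list of numeric vectors. Engine-internal fast path.
tv_matrix <- function(pop, spec, cov_df) {
  n <- nrow(cov_df)
  out <- list(CL = rep(pop$CL, n), V1 = rep(pop$V1, n),
              Q = rep(pop$Q, n), V2 = rep(pop$V2, n))
  for (tr in spec$terms) {
    th <- unname(pop$theta[match(tr$id, names(pop$theta))])
    if (is.na(th)) stop("no coefficient for term ", tr$id, " in pop_params")
    if (!tr$cov %in% names(cov_df))
      stop("missing covariate '", tr$cov, "' required by term ", tr$id)
    v <- cov_df[[tr$cov]]
    fac <- switch(tr$form,
                  power = (v / tr$ref)^th,
                  fractional = ifelse(v == tr$level, 1 + th, 1),
                  ratio = th^v)
    out[[tr$param]] <- out[[tr$param]] * fac
  }
  out
}

#' Individual parameters from typical values and random effects
#'
#' `P_j = TVP * exp(eta_j)`; `eta` defaults to zero for parameters without
#' inter-individual variability (Q, V2).
#'
#' @param tvp a [structural_params()] object of subject typical values.
#' @param eta named numeric vector of random effects (`CL`, `V1`).
#' @return A [structural_params()] object of realised individual parameters.
#' @export
individual_params <- function(tvp, eta = c(CL = 0, V1 = 0)) {
  stopifnot(inherits(tvp, "structural_params"))
  e <- c(CL = 0, V1 = 0, Q = 0, V2 = 0)
  e[names(eta)] <- eta
  structural_params(tvp$CL * exp(e[["CL"]]), tvp$V1 * exp(e[["V1"]]),
                    tvp$Q * exp(e[["Q"]]), tvp$V2 * exp(e[["V2"]]))
}

# ---- published bevacizumab final model --------------------------------

#' Published bevacizumab population-PK final model
#'
#' Convenience constructors for the final covariate model reported for the
#' bevacizumab biosimilar comparison in non-squamous NSCLC: body-weight
#' power terms on CL and V1 (reference 71 kg), fractional sex effects, and
#' ratio-form drug-product effects (reference product coded `DRUG = 0`).
#' `bev_final_params()` carries the published estimates, e.g.
#' `CL = 0.0113 * (BWT/71)^0.354 * 1.262^[male] * 1.02^[test product]` L/h.
#'
#' @return `bev_final_spec()`: a [cov_model_spec()]; `bev_final_params()`:
#'   a [pop_params()] object.
#' @examples
#' typical_values(bev_final_params(), bev_final_spec(),
#'                list(BWT = 71, SEXM = 1, DRUG = 0))
#' @export
bev_final_spec <- function() {
  cov_model_spec(list(
    cov_term("CL", "BWT", "power", ref = 71),
    cov_term("V1", "BWT", "power", ref = 71),
    cov_term("CL", "SEXM", "fractional"),
    cov_term("V1", "SEXM", "fractional"),
    cov_term("CL", "DRUG", "ratio"),
    cov_term("V1", "DRUG", "ratio")))
}

#' @rdname bev_final_spec
#' @export
bev_final_params <- function() {
  pop_params(CL = 0.0113, V1 = 2.99, Q = 0.269, V2 = 6.09,
             theta = c("CL~BWT" = 0.354, "V1~BWT" = 0.468,
                       "CL~SEXM" = 0.262, "V1~SEXM" = 0.247,
                       "CL~DRUG" = 1.02, "V1~DRUG" = 1.07),
             omega2 = c(CL = 0.0871, V1 = 0.117), W = 0.284)
}
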