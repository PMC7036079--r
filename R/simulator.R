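#' Trial design for the synthetic two-product antibody study
#'
#' Encodes the sampling and dosing design of a parallel-group 21-day-cycle
#' study of a body-weight-dosed (15 mg/kg) intravenous antibody: infusion
#' durations stepping down 90 -> 60 -> 30 min over the first three cycles,
#' pre-dose trough samples at every cycle from cycle 2 on, samples 1 h after
#' the end of infusion at cycles 1 and 5, and an end-of-treatment sample one
#' cycle after the last dose. The cycle-1 pre-dose sample is not generated:
#' its model value is exactly zero in a simulation (no carryover), whereas
#' discordant real-world baseline samples are the subject of the exclusion
#' rule in [apply_exclusions()].
#'
#' @param n_subjects number of subjects.
#' @param p_test allocation probability of the test drug product.
#' @param n_cycles number of 21-day dosing cycles (default 16, roughly one
#'   year of treatment).
#' @param cycle_h cycle length in hours (21 d = 504 h).
#' @param dose_per_kg dose in mg per kg baseline body weight.
#' @param inf_dur_h infusion durations (h) for cycles 1, 2 and >= 3.
#' @param peak_cycles cycles with a post-infusion sample.
#' @param peak_offset_h sample time after end of infusion (h).
#' @param peak_jitter_sd SD (h) of optional jitter on the post-infusion
#'   sampling time (0 = nominal times, the default).
#' @param eot_offset_h end-of-treatment sample time after the last dose (h).
#' @param lloq lower limit of quantification (mg/L).
#' @param dropout per-cycle probability of discontinuation after cycle 6
#'   (0 = everyone completes all cycles).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 705, p_test = 0.5, n_cycles = 16,
                         cycle_h = 504, dose_per_kg = 15,
                         inf_dur_h = c(1.5, 1.0, 0.5),
                         peak_cycles = c(1, 5), peak_offset_h = 1,
                         peak_jitter_sd = 0, eot_offset_h = 504,
                         lloq = 0.25, dropout = 0) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (lloq <= 0) stop("lloq must be > 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(n_subjects = n_subjects, p_test = p_test,
                 n_cycles = n_cycles, cycle_h = cycle_h,
                 dose_per_kg = dose_per_kg, inf_dur_h = inf_dur_h,
                 peak_cycles = peak_cycles, peak_offset_h = peak_offset_h,
                 peak_jitter_sd = peak_jitter_sd,
                 eot_offset_h = eot_offset_h, lloq = lloq,
                 dropout = dropout),
            class = "trial_design")
}

#' Baseline covariate distribution
#'
#' Samplers matched to the published baseline table of the emulated study:
#' body weight log-normal with median 71 kg (log-SD 0.2) truncated to the
#' printed 28-135 kg range, 64.8% male, 1:1 drug product. Optional extra
#' continuous covariates (albumin, ALT, alkaline phosphatase, longest tumor
#' diameter) are log-normal around the printed medians truncated to the
#' printed ranges; optional "null" covariates are permuted copies of body
#' weight, carrying no signal, for covariate-selection power checks.
#'
#' @param wt_median,wt_logsd,wt_range body-weight sampler parameters.
#' @param p_male probability of male sex.
#' @param extras logical; sample the extra continuous covariates.
#' @param n_null number of permuted null covariates (`NULL1`, ...).
#' @return An object of class `cov_distribution`.
#' @export
cov_distribution <- function(wt_median = 71, wt_logsd = 0.2,
                             wt_range = c(28, 135), p_male = 0.648,
                             extras = FALSE, n_null = 0) {
  if (wt_median <= 0 || wt_logsd <= 0) stop("invalid weight sampler")
  if (wt_range[1] <= 0 || wt_range[2] <= wt_range[1])
    stop("invalid weight range")
  if (p_male < 0 || p_male > 1) stop("p_male must be in [0, 1]")
  structure(list(wt_median = wt_median, wt_logsd = wt_logsd,
                 wt_range = wt_range, p_male = p_male, extras = extras,
                 n_null = n_null),
            class = "cov_distribution")
}

rlnorm_trunc <- function(n, median, logsd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 10, log(median), logsd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Sample a baseline covariate table
#'
#' @param dist a [cov_distribution()].
#' @param n number of subjects (0 allowed, giving an empty table).
#' @param seed integer seed; given the seed the output is reproducible.
#' @param p_test drug-product allocation probability.
#' @return A data.frame with columns `ID`, `BWT`, `SEXM` (1 = male),
#'   `DRUG` (1 = test product) and any optional covariates.
#' @export
sample_population <- function(dist, n, seed, p_test = 0.5) {
  stopifnot(inherits(dist, "cov_distribution"))
  if (n == 0)
    return(data.frame(ID = integer(0), BWT = numeric(0),
                      SEXM = integer(0), DRUG = integer(0)))
  set.seed(as.integer(seed))
  out <- data.frame(
    ID = seq_len(n),
    BWT = rlnorm_trunc(n, dist$wt_median, dist$wt_logsd, dist$wt_range),
    SEXM = stats::rbinom(n, 1, dist$p_male),
    DRUG = stats::rbinom(n, 1, p_test))
  if (isTRUE(dist$extras)) {
    out$ALB <- rlnorm_trunc(n, 4.05, 0.12, c(2.10, 5.80))
    out$ALT <- rlnorm_trunc(n, 19.0, 0.50, c(3.00, 119))
    out$ALP <- rlnorm_trunc(n, 114, 0.45, c(30.0, 999))
    out$LTD <- rlnorm_trunc(n, 60.0, 0.55, c(10.0, 297))
  }
  if (dist$n_null > 0)
    for (k in seq_len(dist$n_null))
      out[[paste0("NULL", k)]] <- sample(out$BWT)
  out
}

subject_regimen <- function(cov, design) {
  ncyc <- design$n_cycles
  starts <- (seq_len(ncyc) - 1) * design$cycle_h
  dur <- design$inf_dur_h[pmin(seq_len(ncyc), length(design$inf_dur_h))]
  amt <- design$dose_per_kg * cov$BWT  # baseline weight, fixed across cycles
  dose_events(starts, rep(amt, ncyc), dur)
}

subject_sample_times <- function(doses, design, ncyc) {
  starts <- doses$start
  tab <- data.frame(NTIM = numeric(0), CYCLE = integer(0),
                    TAG = character(0))
  pk <- intersect(design$peak_cycles, seq_len(ncyc))
  for (cy in pk) {
    t0 <- starts[cy] + doses$duration[cy] + design$peak_offset_h
    tab <- rbind(tab, data.frame(NTIM = t0, CYCLE = cy,
                                 TAG = sprintf("C%dP", cy)))
  }
  if (ncyc >= 2)
    tab <- rbind(tab, data.frame(NTIM = starts[2:ncyc], CYCLE = 2:ncyc,
                                 TAG = sprintf("C%dT", 2:ncyc)))
  tab <- rbind(tab, data.frame(NTIM = starts[ncyc] + design$eot_offset_h,
                               CYCLE = ncyc, TAG = "EOT"))
  tab[order(tab$NTIM), , drop = FALSE]
}

#' Simulate one subject's event records
#'
#' Draws the subject's random effects (`eta_CL`, `eta_V1`, each once per
#' subject), builds the regimen from the design and the subject's baseline
#' weight, evaluates the noise-free closed-form concentrations, and applies
#' the log-additive residual model `ln Y = ln F + W * eps`, `eps ~ N(0,1)`
#' independently per sample.
#'
#' @param cov one-row data.frame (or named list) of baseline covariates,
#'   including `ID`.
#' @param design a [trial_design()].
#' @param pop a [pop_params()] (truth used for simulation).
#' @param spec a [cov_model_spec()].
#' @param seed integer seed for this subject's stream.
#' @return A data.frame of event records for one subject (dose rows and
#'   observation rows with `DV`, `NTIM`, `CYCLE`, `TAG`, covariates).
#' @export
simulate_subject <- function(cov, design, pop, spec, seed) {
  cov <- as.list(cov)
  set.seed(as.integer(seed))
  ncyc <- design$n_cycles
  if (design$dropout > 0 && ncyc > 6) {
    extra <- stats::rgeom(1, design$dropout)
    ncyc <- min(ncyc, 6 + extra)
    ncyc <- max(ncyc, 1)
  }
  doses <- subject_regimen(cov, design)[seq_len(ncyc), , drop = FALSE]
  eta <- c(CL = stats::rnorm(1, 0, sqrt(pop$omega2[["CL"]])),
           V1 = stats::rnorm(1, 0, sqrt(pop$omega2[["V1"]])))
  sp <- individual_params(typical_values(pop, spec, cov), eta)
  st <- subject_sample_times(doses, design, ncyc)
  st$TIME <- st$NTIM
  if (design$peak_jitter_sd > 0) {
    pk <- grepl("P$", st$TAG)
    st$TIME[pk] <- st$TIME[pk] + stats::rnorm(sum(pk), 0, design$peak_jitter_sd)
  }
  f <- concentration(st$TIME, doses, sp)
  eps <- stats::rnorm(nrow(st))
  dv <- exp(log(f) + pop$W * eps)
  doserows <- data.frame(ID = cov$ID, TIME = doses$start, NTIM = doses$start,
                         AMT = doses$amount,
                         RATE = doses$amount / doses$duration,
                         DV = NA_real_, EVID = 1L, MDV = 1L,
                         CYCLE = seq_len(ncyc), TAG = "DOSE")
  obsrows <- data.frame(ID = cov$ID, TIME = st$TIME, NTIM = st$NTIM,
                        AMT = NA_real_, RATE = NA_real_, DV = dv,
                        EVID = 0L, MDV = 0L, CYCLE = st$CYCLE, TAG = st$TAG)
  rec <- rbind(doserows, obsrows)
  # troughs sort before the same-time dose row (pre-dose samples)
  rec <- rec[order(rec$TIME, -rec$EVID), , drop = FALSE]
  for (nm in setdiff(names(cov), "ID")) rec[[nm]] <- cov[[nm]]
  rownames(rec) <- NULL
  rec
}

#' Simulate a full trial
#'
#' Samples a baseline population, then simulates every subject on an
#' independent seed substream (records do not depend on `n_subjects`
#' ordering), flags below-LLOQ samples, and returns the assembled
#' [pk_dataset()].
#'
#' @param design a [trial_design()].
#' @param dist a [cov_distribution()].
#' @param pop,spec simulation truth; default the published bevacizumab
#'   final model ([bev_final_params()], [bev_final_spec()]).
#' @param seed master integer seed.
#' @return A [pk_dataset()] with `BLQ` flags.
#' @examples
#' \donttest{
#' ds <- simulate_trial(trial_design(n_subjects = 10), seed = 42)
#' print(ds)
#' }
#' @export
simulate_trial <- function(design, dist = cov_distribution(),
                           pop = bev_final_params(), spec = bev_final_spec(),
                           seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  covs <- sample_population(dist, design$n_subjects, seed = seed,
                            p_test = design$p_test)
  recs <- lapply(seq_len(nrow(covs)), function(i) {
    sseed <- (as.integer(seed) %% 100000L) * 20011L + 7919L * i
    simulate_subject(covs[i, , drop = FALSE], design, pop, spec,
                     seed = sseed %% 2147483647L)
  })
  ds <- pk_dataset(do.call(rbind, recs))
  apply_lloq_censoring(ds, design$lloq)
}
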