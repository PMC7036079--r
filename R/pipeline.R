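# End-to-end workflow: simulate -> assemble -> base fit -> SCM -> final fit
# -> outlier/influence -> bootstrap -> VPC -> report. Configuration comes
# from a YAML (or JSON) file; sizes can be overridden by a named profile.

profile_sizes <- list(
  smoke = list(n_subjects = 20, n_cycles = 6, n_boot = 20, n_vpc = 20),
  recovery = list(n_subjects = 100, n_cycles = 16, n_boot = 100, n_vpc = 100),
  `paper-scale` = list(n_subjects = 705, n_cycles = 16, n_boot = 1000,
                       n_vpc = 1000))

#' Read a pipeline configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON. Any omitted section falls back to the
#' built-in defaults (the published-model truth, the standard design, the
#' sex + drug-product covariate candidates).
#'
#' @param path config file path, or `NULL` for all-defaults.
#' @return A named list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list()
  else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(
    design = list(), distribution = list(extras = FALSE, n_null = 0),
    fixed = character(),
    scm = list(enable = TRUE,
               candidates = list(
                 list(param = "CL", cov = "SEXM", form = "fractional"),
                 list(param = "V1", cov = "SEXM", form = "fractional")),
               forced = list(
                 list(param = "CL", cov = "DRUG", form = "ratio"),
                 list(param = "V1", cov = "DRUG", form = "ratio"))),
    fit = list(enable = TRUE),
    bootstrap = list(enable = TRUE), vpc = list(enable = TRUE))
  utils::modifyList(defaults, cfg)
}

terms_from_config <- function(lst) {
  lapply(lst, function(x)
    cov_term(x$param, x$cov, x$form,
             ref = if (!is.null(x$ref)) x$ref else NULL,
             level = if (!is.null(x$level)) x$level else 1))
}

pipeline_log <- function(dir, ...) {
  msg <- sprintf(...)
  message(msg)
  cat(msg, "\n", file = file.path(dir, "run.log"), append = TRUE)
}

#' Run the full analysis pipeline on a synthetic trial
#'
#' Deterministic given `seed`: simulates a trial at the configured truth,
#' applies the exclusion rules, fits the weight-based base model, runs
#' stepwise covariate modeling, qualifies the final model
#' (outliers/influence, bootstrap, VPC) and writes every stage's artifact
#' into `out_dir` together with a `report.json` that cross-links them and
#' records the config hash.
#'
#' @param config a list (see [read_pipeline_config()]) or a path to a
#'   YAML/JSON config file.
#' @param seed master integer seed.
#' @param profile `"smoke"`, `"recovery"` or `"paper-scale"`; controls
#'   subject count, cycle count, bootstrap replicates and VPC trials unless
#'   overridden in the config.
#' @param out_dir run directory (created; default a fresh directory under
#'   `tempdir()`).
#' @return Invisibly, a list with the final fit, stage artifacts and
#'   `status` (0 = success and convergence).
#' @export
run_pipeline <- function(config = NULL, seed = 1, profile = "smoke",
                         out_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
  else utils::modifyList(read_pipeline_config(NULL),
                         if (is.null(config)) list() else config)
  if (!profile %in% names(profile_sizes))
    stop("unknown profile '", profile, "'")
  sz <- profile_sizes[[profile]]
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(),
                         paste0("mabpk-run-", format(Sys.time(), "%Y%m%d-%H%M%S")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  pipeline_log(out_dir, "[config] hash %s, profile %s, seed %d",
               cfg_hash, profile, as.integer(seed))

  design_args <- utils::modifyList(
    list(n_subjects = sz$n_subjects, n_cycles = sz$n_cycles), cfg$design)
  design <- do.call(trial_design, design_args)
  dist <- do.call(cov_distribution, cfg$distribution)
  truth <- bev_final_params()
  truth_spec <- bev_final_spec()

  run_stage <- function(name, expr) {
    pipeline_log(out_dir, "[%s] start", name)
    r <- try(expr, silent = TRUE)
    if (inherits(r, "try-error"))
      stop("pipeline stage '", name, "' failed: ", attr(r, "condition")$message)
    pipeline_log(out_dir, "[%s] done", name)
    r
  }

  ds <- run_stage("simulate", {
    d <- simulate_trial(design, dist, truth, truth_spec, seed = seed)
    write_pk_dataset(d, file.path(out_dir, "data.csv"))
    d
  })
  excl <- run_stage("exclusions", {
    e <- apply_exclusions(ds, design$lloq)
    write_pk_dataset(e$dataset, file.path(out_dir, "data-analysis.csv"))
    write_exclusion_report(e$report, file.path(out_dir, "exclusions.json"))
    e
  })
  dsa <- excl$dataset

  if (!isTRUE(cfg$fit$enable)) {
    report <- list(config_hash = cfg_hash, seed = as.integer(seed),
                   profile = profile, artifacts = list.files(out_dir),
                   exclusions = excl$report[c("n_predose_high", "n_blq")])
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(list(out_dir = out_dir, dataset = ds,
                          analysis_dataset = dsa, config_hash = cfg_hash,
                          status = 0L)))
  }

  base_spec <- cov_model_spec(list(cov_term("CL", "BWT", "power", ref = 71),
                                   cov_term("V1", "BWT", "power", ref = 71)))
  base_fit <- run_stage("fit-base", {
    f <- fit_foce(dsa, base_spec, estimate_se = FALSE)
    write_fit(f, file.path(out_dir, "fit-base.json"))
    f
  })

  if (isTRUE(cfg$scm$enable)) {
    trace <- run_stage("scm", {
      tr <- run_scm(dsa, base_spec,
                    candidates = terms_from_config(cfg$scm$candidates),
                    forced = terms_from_config(cfg$scm$forced),
                    init = base_fit$pop)
      write_scm_trace(tr, file.path(out_dir, "scm-trace.json"))
      tr
    })
    final_fit <- trace$final_fit
    final_spec <- trace$final_spec
  } else {
    trace <- NULL
    final_fit <- run_stage("fit-final", fit_foce(dsa, truth_spec,
                                                 init = truth))
    final_spec <- truth_spec
  }

  qual <- run_stage("outliers", {
    res <- compute_residuals(final_fit)
    infl <- influence_check(dsa, final_fit, res)
    utils::write.csv(as.data.frame(res),
                     file.path(out_dir, "residuals.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_flagged = infl$n_flagged, influential = infl$influential,
           changes = as.list(infl$changes)),
      file.path(out_dir, "influence.json"), auto_unbox = TRUE, digits = NA)
    list(residuals = res, influence = infl)
  })
  final_fit <- qual$influence$final_fit
  write_fit(final_fit, file.path(out_dir, "fit-final.json"))
  diagnostic_plots(final_fit, file.path(out_dir, "figures"))

  boot <- NULL
  if (isTRUE(cfg$bootstrap$enable))
    boot <- run_stage("bootstrap", {
      b <- bootstrap_ci(dsa, final_spec, init = final_fit$pop,
                        n_reps = if (!is.null(cfg$bootstrap$n_reps))
                          cfg$bootstrap$n_reps else sz$n_boot,
                        seed = seed + 1L)
      utils::write.csv(b$table, file.path(out_dir, "bootstrap.csv"),
                       row.names = FALSE)
      b
    })

  vpc_res <- NULL
  if (isTRUE(cfg$vpc$enable))
    vpc_res <- run_stage("vpc", {
      v <- vpc(dsa, final_spec, final_fit$pop,
               n_trials = if (!is.null(cfg$vpc$n_trials))
                 cfg$vpc$n_trials else sz$n_vpc,
               seed = seed + 2L, lloq = design$lloq)
      utils::write.csv(v$table, file.path(out_dir, "vpc.csv"),
                       row.names = FALSE)
      vpc_plot(v, file.path(out_dir, "figures", "vpc.png"))
      v
    })

  # recovery comparison against the configured truth
  truth_vals <- unlist(list(CL = truth$CL, V1 = truth$V1, Q = truth$Q,
                            V2 = truth$V2))
  comp <- run_stage("report", {
    common <- intersect(names(final_fit$estimates),
                        c(names(truth_vals), names(truth$theta),
                          "omega2_CL", "omega2_V1", "W"))
    tv <- c(truth_vals, truth$theta,
            omega2_CL = unname(truth$omega2[["CL"]]),
            omega2_V1 = unname(truth$omega2[["V1"]]), W = truth$W)
    cmp <- data.frame(parameter = common,
                      truth = unname(tv[common]),
                      estimate = unname(final_fit$estimates[common]))
    cmp$rel_error <- (cmp$estimate - cmp$truth) / cmp$truth
    utils::write.csv(cmp, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
    report <- list(config_hash = cfg_hash, seed = as.integer(seed),
                   profile = profile,
                   artifacts = list.files(out_dir),
                   ofv = final_fit$ofv,
                   converged = final_fit$convergence$ok,
                   exclusions = excl$report[c("n_predose_high", "n_blq")],
                   scm_final_terms = vapply(final_spec$terms,
                                            function(tr) tr$id, character(1)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cmp
  })

  status <- if (final_fit$convergence$ok) 0L else 1L
  invisible(list(out_dir = out_dir, dataset = ds, analysis_dataset = dsa,
                 base_fit = base_fit, scm = trace, final_fit = final_fit,
                 qualification = qual, bootstrap = boot, vpc = vpc_res,
                 recovery = comp, config_hash = cfg_hash, status = status))
}

#' Command-line entry point
#'
#' `mabpk_cli(c("all", "--profile", "smoke", "--seed", "1", "--out", dir))`
#' runs the pipeline; the subcommands `simulate`, `fit`, `scm`, `outliers`,
#' `bootstrap`, `vpc` and `report` rerun individual stages (all stages up
#' to and including the requested one, reusing the run directory). Returns
#' the exit status (0 on success with convergence) rather than quitting, so
#' wrapper scripts decide the process exit.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
mabpk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- if (length(args)) args[[1]] else "all"
  known <- c("simulate", "fit", "scm", "outliers", "bootstrap", "vpc",
             "report", "all")
  if (!sub %in% known) {
    message("usage: mabpk <", paste(known, collapse = "|"),
            "> [--config PATH] [--seed INT] [--profile NAME] [--out DIR]")
    return(invisible(2L))
  }
  opts <- list(config = NULL, seed = 1L, profile = "smoke", out = NULL)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opts)) stop("unknown option ", rest[i])
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  cfg <- opts$config
  stages <- c(simulate = 1, fit = 3, scm = 4, outliers = 5, bootstrap = 6,
              vpc = 7, report = 8, all = 8)
  cfg_list <- read_pipeline_config(cfg)
  want <- stages[[sub]]
  if (want < 3) cfg_list$fit$enable <- FALSE
  if (want < 4) cfg_list$scm$enable <- FALSE
  if (want < 6) cfg_list$bootstrap$enable <- FALSE
  if (want < 7) cfg_list$vpc$enable <- FALSE
  res <- try(run_pipeline(cfg_list, seed = as.integer(opts$seed),
                          profile = opts$profile, out_dir = opts$out),
             silent = TRUE)
  if (inherits(res, "try-error")) {
    message(attr(res, "condition")$message)
    return(invisible(1L))
  }
  invisible(res$status)
}
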