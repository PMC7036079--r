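# Diagnostic figures written to image files. Base graphics only; every
# device call is guarded so a headless library without png support degrades
# to a warning rather than a failed pipeline.

save_png <- function(path, expr, width = 900, height = 700) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    TRUE
  }, error = function(e) {
    warning("could not write ", path, ": ", conditionMessage(e))
    FALSE
  })
  if (ok) path else character(0)
}

#' Goodness-of-fit and random-effect diagnostic figures
#'
#' Writes the standard panels to PNG files in `dir`: observed vs population
#' and individual predictions (log scale), CWRES against time and against
#' prediction, and histograms of the empirical Bayes etas. Returns the
#' paths written (invisibly); on a headless system without a usable png
#' device it warns and writes nothing.
#'
#' @param fit a `pk_fit`.
#' @param dir output directory (created).
#' @param prefix filename prefix.
#' @return Invisibly, the written file paths.
#' @export
diagnostic_plots <- function(fit, dir, prefix = "gof") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- fit$diag
  out <- character(0)
  out <- c(out, save_png(file.path(dir, paste0(prefix, "-obs-pred.png")), {
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    lobs <- log(d$DV)
    for (col in c("PRED", "IPRED")) {
      graphics::plot(d[[col]], lobs, pch = 16, cex = 0.5,
                     col = "#00000060",
                     xlab = paste0("ln ", col), ylab = "ln observed",
                     main = paste("Observed vs", col))
      graphics::abline(0, 1)
      graphics::abline(stats::lm(lobs ~ d[[col]]), lty = 2, col = "red")
    }
  }))
  out <- c(out, save_png(file.path(dir, paste0(prefix, "-cwres.png")), {
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    graphics::plot(d$TIME, d$CWRES, pch = 16, cex = 0.5, col = "#00000060",
                   xlab = "time (h)", ylab = "CWRES", main = "CWRES vs time")
    graphics::abline(h = 0); graphics::abline(h = c(-6, 6), lty = 3)
    graphics::plot(d$PRED, d$CWRES, pch = 16, cex = 0.5, col = "#00000060",
                   xlab = "ln population prediction", ylab = "CWRES",
                   main = "CWRES vs prediction")
    graphics::abline(h = 0); graphics::abline(h = c(-6, 6), lty = 3)
  }))
  out <- c(out, save_png(file.path(dir, paste0(prefix, "-eta.png")), {
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    for (j in 1:2) {
      nm <- c("eta_CL", "eta_V1")[j]
      if (fit$pop$omega2[[c("CL", "V1")[j]]] > 0)
        graphics::hist(fit$eta[, j], breaks = 20, main = nm, xlab = nm)
      else {
        graphics::plot.new(); graphics::title(paste(nm, "(no IIV)"))
      }
    }
  }))
  invisible(out)
}

#' Visual predictive check figure
#'
#' Observed percentiles (points/lines) over the simulated percentile bands
#' per bin, on the log scale.
#'
#' @param v a [vpc()] result.
#' @param path output PNG path.
#' @return Invisibly, the path (or `character(0)` if no device).
#' @export
vpc_plot <- function(v, path) {
  tab <- v$table
  x <- seq_len(nrow(tab))
  invisible(save_png(path, {
    graphics::par(mar = c(7, 4, 2, 1))
    rng <- range(c(tab$obs_p2.5, tab$obs_p97.5, tab$sim_p2.5_lo,
                   tab$sim_p97.5_hi), na.rm = TRUE)
    graphics::plot(x, tab$obs_p50, log = "y", ylim = rng, type = "n",
                   xaxt = "n", xlab = "", ylab = "concentration (mg/L)",
                   main = sprintf("VPC (%d simulated trials)", v$n_trials))
    graphics::axis(1, at = x, labels = tab$bin, las = 2, cex.axis = 0.8)
    poly <- function(lo, hi, col)
      graphics::polygon(c(x, rev(x)), c(lo, rev(hi)), border = NA, col = col)
    poly(tab$sim_p2.5_lo, tab$sim_p2.5_hi, "#87cefa66")
    poly(tab$sim_p50_lo, tab$sim_p50_hi, "#ffb6c166")
    poly(tab$sim_p97.5_lo, tab$sim_p97.5_hi, "#87cefa66")
    graphics::lines(x, tab$sim_p50, col = "black")
    graphics::lines(x, tab$sim_p2.5, col = "black", lty = 2)
    graphics::lines(x, tab$sim_p97.5, col = "black", lty = 2)
    graphics::lines(x, tab$obs_p50, col = "red", lwd = 2)
    graphics::lines(x, tab$obs_p2.5, col = "red", lty = 2)
    graphics::lines(x, tab$obs_p97.5, col = "red", lty = 2)
    graphics::points(x, tab$obs_p50, col = "red", pch = 16)
  }))
}
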