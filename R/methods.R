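#' @export
print.gformula <- function(x, digits = 7L, all_times = FALSE, ...) {
  survival <- x$outcome_type == "survival"
  cat("PREDICTED RISK UNDER MULTIPLE INTERVENTIONS\n\n")
  descs <- vapply(x$interventions, `[[`, "", "description")
  legend <- data.frame(Intervention = seq_along(descs) - 1L,
                       Description = descs)
  print(legend, row.names = FALSE, right = FALSE)
  cat("\nSample size = ", x$header$n,
      ", Monte Carlo sample size = ", x$header$nsimul, "\n", sep = "")
  cat("Number of bootstrap samples = ", x$header$nsamples, "\n", sep = "")
  if (x$header$boot_failed > 0L) {
    cat("Failed bootstrap replicates = ", x$header$boot_failed, "\n",
        sep = "")
  }
  ref <- x$header$ref_int
  refdesc <- if (ref == 0L) "natural course" else descs[ref + 1L]
  cat("Reference intervention = ", refdesc, " (", ref, ")\n\n", sep = "")
  res <- x$result
  if (survival && !all_times) {
    res <- res[res$k == x$header$time_points - 1L, , drop = FALSE]
  }
  est_lab <- if (survival) "risk" else "mean"
  labels <- c(k = "k", interv = "Interv.",
              np_estimate = paste("NP", est_lab),
              estimate = paste("g-form", est_lab),
              ratio = if (survival) "Risk ratio" else "Mean ratio",
              difference = if (survival) "Risk difference" else
                "Mean difference",
              se = paste(toupper(substring(est_lab, 1, 1)),
                         "SE"),
              ci_lower = "lower 95% CI", ci_upper = "upper 95% CI",
              ratio_se = "Ratio SE", ratio_ci_lower = "Ratio lower 95% CI",
              ratio_ci_upper = "Ratio upper 95% CI",
              difference_se = "Diff SE",
              difference_ci_lower = "Diff lower 95% CI",
              difference_ci_upper = "Diff upper 95% CI")
  shown <- res[, intersect(names(labels), names(res)), drop = FALSE]
  for (nm in names(shown)) {
    if (is.numeric(shown[[nm]]) && !nm %in% c("k", "interv")) {
      shown[[nm]] <- signif(shown[[nm]], digits)
    }
  }
  names(shown) <- labels[names(shown)]
  print(shown, row.names = FALSE)
  invisible(x)
}

#' @export
summary.gformula <- function(object, ...) {
  structure(list(fit = object), class = "summary.gformula")
}

#' @export
print.summary.gformula <- function(x, ...) {
  print(x$fit, ...)
  cat("\nFitted models (step 1):\n")
  rm <- data.frame(model = names(x$fit$rmses), rmse = unname(x$fit$rmses))
  print(rm, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gformula <- function(object, ...) object$coefs

#' @export
vcov.gformula <- function(object, ...) object$vcovs

#' Diagnostic plot: nonparametric versus parametric natural-course estimates
#'
#' One panel per time-varying covariate comparing the nonparametric mean by
#' follow-up time with the mean over the simulated natural-course histories,
#' plus, for survival outcomes, a panel comparing the nonparametric and
#' parametric risk curves. Close agreement supports (but does not guarantee)
#' the absence of gross misspecification of the covariate and outcome
#' models.
#'
#' @param x a `gformula` object.
#' @param ... passed to [graphics::matplot()].
#' @return (invisibly) a data.frame of the plotted series, with columns `k`,
#'   `panel`, `np` and `parametric`.
#' @export
plot.gformula <- function(x, ...) {
  np <- x$np_cov_means
  sims <- x$sim_cov_means
  panels <- intersect(names(sims), names(np))
  survival <- x$outcome_type == "survival"
  n_panel <- length(panels) + as.integer(survival)
  mf <- grDevices::n2mfrow(n_panel)
  old <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  plotted <- list()
  for (v in panels) {
    ks <- np$k
    m <- cbind(np[[v]], sims[[v]][seq_along(ks)])
    graphics::matplot(ks, m, type = "b", pch = c(1, 2), lty = c(1, 2),
                      col = c("black", "firebrick"), xlab = "k",
                      ylab = "mean", main = v, ...)
    graphics::legend("topright", legend = c("nonparametric", "parametric"),
                     pch = c(1, 2), lty = c(1, 2),
                     col = c("black", "firebrick"), bty = "n", cex = 0.8)
    plotted[[v]] <- data.frame(k = ks, panel = v, np = m[, 1],
                               parametric = m[, 2])
  }
  if (survival) {
    ks <- seq.int(0L, x$header$time_points - 1L)
    m <- cbind(x$np_estimate, x$estimates[1L, ])
    graphics::matplot(ks, m, type = "b", pch = c(1, 2), lty = c(1, 2),
                      col = c("black", "firebrick"), xlab = "k",
                      ylab = "risk", main = "risk", ...)
    graphics::legend("topleft", legend = c("nonparametric", "parametric"),
                     pch = c(1, 2), lty = c(1, 2),
                     col = c("black", "firebrick"), bty = "n", cex = 0.8)
    plotted[["risk"]] <- data.frame(k = ks, panel = "risk", np = m[, 1],
                                    parametric = m[, 2])
  }
  invisible(do.call(rbind, c(plotted, list(make.row.names = FALSE))))
}
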