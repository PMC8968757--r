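# Log-probit reduction of gravimetric impactor data to (MMAD, GSD).
#
# A lognormal mass distribution plots as a straight line in probit-vs-ln(d)
# space: probit(F(d)) = [ln d - ln MMAD] / ln GSD. Fitting that line by least
# squares to the cumulative undersize fractions observed at the stage
# cut-points gives MMAD = exp(-intercept/slope) and GSD = exp(1/slope).

#' Fit a lognormal PSD to impactor data by log-probit regression
#'
#' Reduces the gravimetric record of a cascade-impactor trial to a mass
#' median aerodynamic diameter (MMAD) and geometric standard deviation (GSD).
#' The cumulative mass fraction smaller than each stage cut-point
#' (accumulated from the backup filter upward, the standard undersize
#' convention) is probit-transformed and regressed on the log cut-point by
#' unweighted least squares. Cut-points where the cumulative fraction is
#' exactly 0 or 1 carry no probit information and are excluded; at least
#' three informative points are required.
#'
#' @param trial An [impactor_trial()].
#'
#' @return An object of class `"psd_fit"` with components `mmad`, `gsd`,
#'   `intercept`, `slope`, `r_squared`, `n_points_used`, and a `points` data
#'   frame of the cumulative fractions used. Standard methods are available:
#'   [coef()], [predict()], [fitted()], [residuals()], `plot()`, `summary()`.
#'
#' @section Degenerate trials: Trials with all mass on a single stage, fewer
#'   than three informative cut-points, or a non-positive fitted slope raise
#'   a condition of class `"aerodose_degenerate_fit"` carrying the cumulative
#'   points as diagnostics.
#'
#' @examples
#' psd <- lognormal_psd(0.93, 1.43)
#' tr <- simulate_impactor_trial(psd, total_mass = 7, balance_resolution = 0)
#' fit <- fit_probit_psd(tr)
#' coef(fit)
#' @export
fit_probit_psd <- function(trial) {
  stopifnot(inherits(trial, "impactor_trial"))
  cum <- cumulative_undersize(trial)
  ok <- cum$fraction > 0 & cum$fraction < 1
  if (sum(cum$mass > 0) <= 1L) {
    abort_degenerate("all collected mass on a single stage; spread undefined", cum)
  }
  if (sum(ok) < 3L) {
    abort_degenerate("fewer than 3 cut-points with cumulative fraction in (0,1)", cum)
  }
  x <- log(cum$d50[ok])
  y <- stats::qnorm(cum$fraction[ok])
  fit <- stats::lm.fit(cbind(intercept = 1, log_d50 = x), y)
  a <- fit$coefficients[["intercept"]]
  b <- fit$coefficients[["log_d50"]]
  if (!is.finite(b) || b <= 0) {
    abort_degenerate("non-positive probit slope; mass not increasing with size", cum)
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(mmad = exp(-a / b), gsd = exp(1 / b),
         intercept = a, slope = b,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         n_points_used = sum(ok),
         points = transform(cum, used = ok),
         trial_id = trial$id),
    class = "psd_fit"
  )
}

abort_degenerate <- function(message, points) {
  stop(structure(
    class = c("aerodose_degenerate_fit", "aerodose_error", "error", "condition"),
    list(message = message, call = NULL, points = points)
  ))
}

# Cumulative mass fraction smaller than each cut-point. The stage with
# cut-point d50_j ideally collects everything >= d50_j that reaches it, so
# the mass smaller than d50_j is the backup filter plus all stages with
# smaller cut-points.
cumulative_undersize <- function(trial) {
  m <- stage_masses(trial)
  m <- m[order(m$d50), ]          # ascending cut-point
  backup <- if (is.na(trial$backup_filter_mass)) 0 else max(trial$backup_filter_mass, 0)
  total <- sum(m$mass) + backup
  if (total <= 0) abort_degenerate("no mass collected", m)
  below <- backup + c(0, cumsum(m$mass))[seq_len(nrow(m))]
  data.frame(d50 = m$d50, mass = m$mass, fraction = below / total)
}

#' @export
print.psd_fit <- function(x, ...) {
  cat("Log-probit lognormal PSD fit\n")
  cat(sprintf("  MMAD = %.3f um, GSD = %.3f  (n = %d cut-points, R^2 = %.4f)\n",
              x$mmad, x$gsd, x$n_points_used, x$r_squared))
  invisible(x)
}

#' @export
summary.psd_fit <- function(object, ...) {
  cat("Log-probit lognormal PSD fit")
  if (!is.null(object$trial_id)) cat(" for trial ", object$trial_id, sep = "")
  cat("\n\n")
  cat(sprintf("  MMAD      %.4f um\n", object$mmad))
  cat(sprintf("  GSD       %.4f\n", object$gsd))
  cat(sprintf("  probit(F) = %.4f + %.4f ln(d)   R^2 = %.4f\n",
              object$intercept, object$slope, object$r_squared))
  cat(sprintf("  %d of %d cut-points informative\n\n",
              object$n_points_used, nrow(object$points)))
  print(object$points, row.names = FALSE)
  invisible(object)
}

#' @export
coef.psd_fit <- function(object, ...) {
  c(mmad = object$mmad, gsd = object$gsd,
    intercept = object$intercept, slope = object$slope)
}

#' Predicted cumulative undersize fraction
#'
#' @param object A `"psd_fit"`.
#' @param newdata Diameters (um) at which to evaluate the fitted cumulative
#'   mass fraction; defaults to the trial cut-points.
#' @param ... Unused.
#' @return Cumulative mass fraction smaller than each diameter.
#' @export
predict.psd_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$points$d50 else newdata
  stats::pnorm(object$intercept + object$slope * log(d))
}

#' @export
fitted.psd_fit <- function(object, ...) {
  predict(object)[object$points$used]
}

#' @export
residuals.psd_fit <- function(object, ...) {
  obs <- object$points$fraction[object$points$used]
  stats::qnorm(obs) - stats::qnorm(fitted(object))
}

#' Probit plot of an impactor PSD fit
#'
#' Plots the probit-transformed cumulative undersize fractions against the
#' log cut-point, with the fitted line; the classic impactor data-reduction
#' diagnostic.
#'
#' @param x A `"psd_fit"`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.psd_fit <- function(x, ...) {
  p <- x$points[x$points$used, ]
  plot(log(p$d50), stats::qnorm(p$fraction),
       xlab = "ln d50 (um)", ylab = "probit cumulative mass fraction",
       main = sprintf("MMAD %.2f um, GSD %.2f", x$mmad, x$gsd), ...)
  graphics::abline(a = x$intercept, b = x$slope, lty = 2)
  invisible(x)
}

#' Extract the fitted distribution as a lognormal PSD object
#'
#' @param fit A `"psd_fit"`.
#' @return A mass-basis aerodynamic [lognormal_psd()].
#' @export
as_lognormal_psd <- function(fit) {
  stopifnot(inherits(fit, "psd_fit"))
  lognormal_psd(fit$mmad, max(fit$gsd, 1),
                basis = "mass", diameter_kind = "aerodynamic")
}
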