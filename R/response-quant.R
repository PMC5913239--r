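#' Four-parameter logistic fit of a concentration-response curve
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^(hill (log10EC50 - log10[A])))`
#' by least squares on the log10-concentration scale. Intra-experiment
#' replicates are averaged per concentration before fitting. The Hill slope
#' is bounded in [0.2, 5] for stability on sparse grids. Flat data (no
#' concentration-dependent response beyond the replicate noise) is flagged
#' `no_response` and no parameters are reported.
#'
#' @param conc Concentrations, molar (> 0, >= 4 distinct values). May also be
#'   a data.frame with columns `concentration_M` and `response` (then
#'   `response` is ignored).
#' @param response Responses, same length as `conc`.
#' @param average_replicates Average responses per concentration first?
#'   Default `TRUE`.
#' @return Object of class `fourpl`: coefficients `bottom`, `top`,
#'   `log10_EC50`, `hill`, their SEs, `converged` and `no_response` flags.
#' @export
fit_4pl <- function(conc, response = NULL, average_replicates = TRUE) {
  if (is.data.frame(conc)) {
    check_columns(conc, c("concentration_M", "response"), "conc")
    response <- conc$response
    conc <- conc$concentration_M
  }
  check_positive(conc, "concentrations")
  if (length(unique(conc)) < 4) {
    stop_input("4PL fit needs >= 4 distinct concentrations")
  }
  if (length(conc) != length(response)) {
    stop_input("conc and response lengths differ")
  }
  rep_sd <- if (anyDuplicated(conc)) {
    stats::sd(unlist(tapply(response, conc, function(v) v - mean(v))))
  } else NA_real_
  if (average_replicates && anyDuplicated(conc)) {
    m <- tapply(response, conc, mean)
    conc <- as.numeric(names(m))
    response <- as.numeric(m)
  }
  o <- order(conc)
  conc <- conc[o]; response <- response[o]
  lx <- log10(conc)
  span <- max(response) - min(response)
  flat <- span == 0 ||
    (is.finite(rep_sd) && span < 3 * rep_sd)
  if (flat) {
    return(structure(list(coefficients = c(bottom = NA, top = NA,
                                           log10_EC50 = NA, hill = NA),
                          se = c(bottom = NA, top = NA, log10_EC50 = NA,
                                 hill = NA),
                          converged = FALSE, no_response = TRUE),
                     class = "fourpl"))
  }
  half <- (max(response) + min(response)) / 2
  ec50_0 <- lx[which.min(abs(response - half))]
  fit <- try(minpack.lm::nlsLM(
    response ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lx))),
    start = list(bottom = min(response), top = max(response),
                 lec50 = ec50_0, hill = 1),
    lower = c(-Inf, -Inf, min(lx) - 3, 0.2),
    upper = c(Inf, Inf, max(lx) + 3, 5),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(coefficients = c(bottom = NA, top = NA,
                                           log10_EC50 = NA, hill = NA),
                          se = c(bottom = NA, top = NA, log10_EC50 = NA,
                                 hill = NA),
                          converged = FALSE, no_response = FALSE),
                     class = "fourpl"))
  }
  cf <- stats::coef(fit)
  ses <- summary(fit)$coefficients[, "Std. Error"]
  ec50_outside <- cf[["lec50"]] < min(lx) | cf[["lec50"]] > max(lx)
  structure(list(
    coefficients = c(bottom = cf[["bottom"]], top = cf[["top"]],
                     log10_EC50 = cf[["lec50"]], hill = cf[["hill"]]),
    se = c(bottom = ses[["bottom"]], top = ses[["top"]],
           log10_EC50 = ses[["lec50"]], hill = ses[["hill"]]),
    ec50_outside_range = ec50_outside,
    converged = TRUE, no_response = FALSE, fit = fit
  ), class = "fourpl")
}

#' @export
print.fourpl <- function(x, ...) {
  if (x$no_response) {
    cat("4PL fit: no concentration-dependent response detected\n")
  } else if (!x$converged) {
    cat("4PL fit: did not converge\n")
  } else {
    cf <- x$coefficients
    cat(sprintf(
      "4PL fit: bottom %.3g, top %.3g, pEC50 %.3g, hill %.3g%s\n",
      cf[["bottom"]], cf[["top"]], -cf[["log10_EC50"]], cf[["hill"]],
      if (isTRUE(x$ec50_outside_range)) "  [EC50 outside tested range]" else ""))
  }
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
predict.fourpl <- function(object, conc, ...) {
  if (!object$converged) stop_input("cannot predict from a non-converged fit")
  cf <- object$coefficients
  cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
    (1 + 10^(cf[["hill"]] * (cf[["log10_EC50"]] - log10(conc))))
}

#' Normalize responses to the assay maximum of a reference curve
#'
#' Expresses responses as percent of the reference agonist's fitted span, so
#' that the reference fitted `top` maps to 100% and its fitted `bottom` to
#' 0%. Used to put curves from different plates/assays on a common percent
#' scale before operational-model analysis.
#'
#' @param response Responses (vector or data.frame with a `response` column).
#' @param reference_fit A converged [fit_4pl()] of the reference agonist.
#' @return Same shape as `response`, in percent of the reference maximum.
#' @export
normalize_to_assay_max <- function(response, reference_fit) {
  stopifnot(inherits(reference_fit, "fourpl"))
  if (reference_fit$no_response || !reference_fit$converged) {
    stop_input("reference curve is flat or unconverged; cannot normalize")
  }
  cf <- reference_fit$coefficients
  scale_one <- function(v) 100 * (v - cf[["bottom"]]) / (cf[["top"]] - cf[["bottom"]])
  if (is.data.frame(response)) {
    check_columns(response, "response")
    response$response <- scale_one(response$response)
    response
  } else {
    scale_one(response)
  }
}

#' Insulin stimulation index
#'
#' Fold increase of secretion (or percent release) over the glucose-only
#' control: `ISI = mean(condition) / mean(control)`. The control condition's
#' ISI is 1 by construction.
#'
#' @param value Secretion measure per sample (secreted amount or percent
#'   release).
#' @param condition Condition label per sample.
#' @param is_control Logical per sample; at least one control required.
#' @return Named numeric of ISI per condition.
#' @export
insulin_stimulation_index <- function(value, condition, is_control) {
  if (!any(is_control)) stop_input("at least one control sample required")
  ctrl <- mean(value[is_control])
  if (!is.finite(ctrl) || ctrl == 0) {
    stop_input("control mean is zero; ISI undefined")
  }
  m <- tapply(value, condition, mean)
  out <- as.numeric(m) / ctrl
  names(out) <- names(m)
  out
}

#' Percent of insulin released
#'
#' `100 * secreted / (secreted + residual)`: secretion as a percentage of the
#' total (secreted + residual cellular content) pool.
#'
#' @param secreted Secreted amount (>= 0).
#' @param residual Residual cellular content, same units (>= 0).
#' @return Percentage in [0, 100].
#' @export
percent_release <- function(secreted, residual) {
  check_nonnegative(secreted, "secreted")
  check_nonnegative(residual, "residual")
  if (any(secreted + residual == 0)) {
    stop_input("secreted and residual are both zero; percent release undefined")
  }
  100 * secreted / (secreted + residual)
}

#' Baseline-normalize a response trace (F / F_baseline)
#'
#' Divides a signal trace by its mean over a baseline window, so the
#' normalized signal averages 1 over that window.
#'
#' @param time Strictly increasing times, minutes.
#' @param signal Signal values.
#' @param window Baseline window `c(t_a, t_b)` in minutes; must lie within
#'   the trace and contain at least 2 samples.
#' @return Normalized signal vector.
#' @export
baseline_normalize <- function(time, signal, window) {
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  if (window[1] < min(time) || window[2] > max(time)) {
    stop_input("baseline window outside trace")
  }
  idx <- time >= window[1] & time <= window[2]
  if (sum(idx) < 2) stop_input("baseline window contains < 2 samples")
  b <- mean(signal[idx])
  if (b == 0) stop_input("baseline mean is zero")
  signal / b
}

#' Trapezoidal area under a trace relative to a baseline
#'
#' Integrates `signal - baseline_value` between `t_start` and `t_end` by the
#' trapezoid rule, interpolating the signal at the window bounds; may be
#' negative.
#'
#' @param time Strictly increasing times, minutes.
#' @param signal Signal values.
#' @param t_start,t_end Integration window, minutes (within the trace).
#' @param baseline_value Baseline to subtract (e.g. pre-agonist mean or the
#'   value at agonist addition).
#' @return AUC in signal x minutes.
#' @export
trace_auc <- function(time, signal, t_start = min(time), t_end = max(time),
                      baseline_value = 0) {
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  if (t_start >= t_end) stop_input("t_start must be < t_end")
  if (t_start < min(time) || t_end > max(time)) {
    stop_input("integration window outside trace")
  }
  grid <- sort(unique(c(t_start, t_end, time[time > t_start & time < t_end])))
  y <- stats::approx(time, signal, xout = grid)$y - baseline_value
  sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
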