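#' Specific binding by nonspecific subtraction
#'
#' Subtracts the nonspecific-binding trace (excess unlabelled agonist) from
#' the total-binding trace, pointwise. If the two traces are on different
#' time grids the nonspecific trace is linearly interpolated onto the total
#' grid; disjoint time ranges are an error.
#'
#' @param total,nonspecific data.frames with columns `time_min` and `signal`,
#'   or numeric signal vectors on a shared grid (then supply `time`).
#' @param time Time grid when vectors are given.
#' @param clip Clip negative specific binding at 0? Default `FALSE`.
#' @return data.frame with `time_min` and `signal` (specific binding).
#' @export
specific_binding <- function(total, nonspecific, time = NULL, clip = FALSE) {
  as_trace <- function(x, nm) {
    if (is.data.frame(x)) {
      check_columns(x, c("time_min", "signal"), nm)
      x[, c("time_min", "signal")]
    } else {
      if (is.null(time)) stop_input("supply `time` with vector inputs")
      data.frame(time_min = time, signal = as.numeric(x))
    }
  }
  tot <- as_trace(total, "total")
  ns <- as_trace(nonspecific, "nonspecific")
  if (min(ns$time_min) > max(tot$time_min) ||
      max(ns$time_min) < min(tot$time_min)) {
    stop_input("total and nonspecific traces cover disjoint time ranges")
  }
  ns_on_grid <- if (length(ns$time_min) == length(tot$time_min) &&
                    all(ns$time_min == tot$time_min)) {
    ns$signal
  } else {
    stats::approx(ns$time_min, ns$signal, xout = tot$time_min, rule = 2)$y
  }
  out <- data.frame(time_min = tot$time_min, signal = tot$signal - ns_on_grid)
  if (clip) out$signal <- pmax(out$signal, 0)
  out
}

#' Fit a one-phase exponential dissociation
#'
#' Fits `B(t) = B0 exp(-k_off t)` to a specific-binding trace recorded after
#' washout/blockade, with the plateau fixed at 0 (specific binding must decay
#' to zero under complete blockade). A non-decreasing trace is flagged as
#' "no dissociation detected" rather than fitted.
#'
#' @param time Time since washout, minutes.
#' @param signal Specific binding (nonspecific already subtracted).
#' @return Object of class `decay_fit`: `k_off` (1/min), `B0`, standard
#'   errors, `half_life` (min), `converged`, `no_dissociation` flags.
#' @export
fit_dissociation <- function(time, signal) {
  if (length(time) != length(signal) || length(time) < 3) {
    stop_input("need >= 3 matched (time, signal) points")
  }
  slope0 <- stats::coef(stats::lm(log(pmax(signal, max(signal) * 1e-6)) ~ time))[2]
  if (!is.finite(slope0) || slope0 >= 0) {
    return(structure(list(k_off = NA_real_, B0 = NA_real_, se = c(k_off = NA, B0 = NA),
                          half_life = NA_real_, converged = FALSE,
                          no_dissociation = TRUE),
                     class = "decay_fit"))
  }
  fit <- try(minpack.lm::nlsLM(signal ~ B0 * exp(-k * time),
                               start = list(B0 = max(signal),
                                            k = as.numeric(-slope0)),
                               lower = c(0, 0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error") || stats::coef(fit)[["k"]] <= 0) {
    return(structure(list(k_off = NA_real_, B0 = NA_real_,
                          se = c(k_off = NA, B0 = NA),
                          half_life = NA_real_, converged = FALSE,
                          no_dissociation = FALSE),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(k_off = cf[["k"]], B0 = cf[["B0"]],
                 se = c(k_off = se[["k"]], B0 = se[["B0"]]),
                 half_life = log(2) / cf[["k"]],
                 converged = TRUE, no_dissociation = FALSE,
                 fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (isTRUE(x$no_dissociation)) {
    cat("One-phase dissociation: no dissociation detected\n")
  } else if (!x$converged) {
    cat("One-phase dissociation: fit did not converge\n")
  } else {
    cat(sprintf(
      "One-phase dissociation: k_off = %.4g /min (SE %.2g), t1/2 = %.3g min\n",
      x$k_off, x$se[["k_off"]], x$half_life))
  }
  invisible(x)
}

#' Motulsky-Mahan predicted specific binding under competition
#'
#' Closed-form tracer-receptor occupancy when a labelled tracer at
#' concentration `L` and an unlabelled competitor at concentration `I`
#' associate simultaneously with free receptor, with `RL(0) = 0`:
#' `KA = k1 L + k2`, `KB = k3 I + k4`,
#' `S = sqrt((KA - KB)^2 + 4 k1 k3 L I)`, `KF = (KA + KB + S)/2`,
#' `KS = (KA + KB - S)/2`, and
#' `RL(t) = Q [ k4 (KF - KS)/(KF KS) + (k4 - KF)/KF e^{-KF t}
#'            - (k4 - KS)/KS e^{-KS t} ]` with `Q = Bmax k1 L/(KF - KS)`.
#' When the exponents coincide (`|KF - KS|/KF < 1e-9`) the series-expanded
#' repeated-root limit is used instead of the difference quotient.
#'
#' @param times Times, minutes.
#' @param L Tracer concentration, molar.
#' @param I Competitor concentration, molar.
#' @param k1,k2 Tracer association (1/(M min)) and dissociation (1/min) rates.
#' @param k3,k4 Competitor association and dissociation rates (same units).
#' @param Bmax Maximal tracer binding, signal units.
#' @return Predicted specific binding at `times`.
#' @export
mm_predict <- function(times, L, I, k1, k2, k3, k4, Bmax) {
  check_nonnegative(c(L, I, k1, k2, k3, k4), "rates and concentrations")
  KA <- k1 * L + k2
  KB <- k3 * I + k4
  S <- sqrt((KA - KB)^2 + 4 * k1 * k3 * L * I)
  KF <- (KA + KB + S) / 2
  KS <- (KA + KB - S) / 2
  if ((KF - KS) / KF >= 1e-9) {
    Q <- Bmax * k1 * L / (KF - KS)
    Q * (k4 * (KF - KS) / (KF * KS) +
           (k4 - KF) / KF * exp(-KF * times) -
           (k4 - KS) / KS * exp(-KS * times))
  } else {
    # repeated-root limit KF -> KS = m:
    # RL = Bmax k1 L [ k4/m^2 (1 - e^{-m t}) - (k4 - m) t e^{-m t} / m ]
    m <- (KF + KS) / 2
    Bmax * k1 * L * (k4 / m^2 * (1 - exp(-m * times)) -
                       (k4 - m) * times * exp(-m * times) / m)
  }
}

#' Global Motulsky-Mahan fit of competitive-association traces
#'
#' Fits the competitor's association and dissociation rate constants (`k3`,
#' `k4`, reported as `k_on`, `k_off`) by least squares across traces recorded
#' at four or more competitor concentrations with a shared tracer
#' concentration, using [mm_predict()] as the model. Tracer `k1`, `k2` and
#' `Bmax` are taken as known (estimated beforehand from competitor-free
#' traces) or co-fit (`fit_bmax = TRUE` re-estimates `Bmax`, shared across
#' traces). Rates are optimized on the log10 scale.
#'
#' @param traces data.frame with columns `competitor_M`, `time_min`, `signal`
#'   (specific binding).
#' @param tracer Named list with `k1`, `k2`, `Bmax`.
#' @param L Tracer concentration, molar.
#' @param fit_bmax Also fit a shared `Bmax`? Default `FALSE`.
#' @param start Optional starting values `c(log10_k3, log10_k4)`.
#' @return Object of class `mm_fit`: `k_on`, `k_off` with SEs,
#'   `residence_time` (= 1/k_off), `K_d` (= k_off/k_on), `Bmax`, `converged`,
#'   and the residual sum of squares.
#' @export
fit_competitive <- function(traces, tracer, L, fit_bmax = FALSE,
                            start = NULL) {
  check_columns(traces, c("competitor_M", "time_min", "signal"), "traces")
  concs <- sort(unique(traces$competitor_M[traces$competitor_M > 0]))
  if (length(concs) < 4) {
    stop_input("competitive fit needs >= 4 non-zero competitor concentrations")
  }
  tt <- traces$time_min
  obs <- traces$signal
  conc_of_row <- traces$competitor_M
  predict_all <- function(k3, k4, Bmax) {
    out <- numeric(length(obs))
    for (I in unique(conc_of_row)) {
      idx <- conc_of_row == I
      out[idx] <- mm_predict(tt[idx], L, I, tracer$k1, tracer$k2,
                             k3, k4, Bmax)
    }
    out
  }
  if (is.null(start)) {
    start <- c(log10(tracer$k1), log10(tracer$k2))
  }
  par0 <- if (fit_bmax) c(start, log10(tracer$Bmax)) else start
  obj <- function(p) {
    pr <- predict_all(10^p[1], 10^p[2],
                      if (fit_bmax) 10^p[3] else tracer$Bmax)
    sum((obs - pr)^2)
  }
  lower <- c(2, -6, if (fit_bmax) -6)
  upper <- c(13, 2, if (fit_bmax) 12)
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e7))
  converged <- opt$convergence == 0
  p <- opt$par
  # SEs on the log10 scale from the Gauss-Newton approximation, then delta
  # method back to the natural scale.
  n_obs <- length(obs)
  n_par <- length(p)
  sigma2 <- opt$value / max(n_obs - n_par, 1)
  H <- try(stats::optimHess(p, obj), silent = TRUE)
  se_log <- rep(NA_real_, n_par)
  if (!inherits(H, "try-error")) {
    cov_try <- try(solve(H / 2) * sigma2, silent = TRUE)
    if (!inherits(cov_try, "try-error")) {
      d <- diag(cov_try)
      d[!is.finite(d) | d <= 0] <- NA_real_
      se_log <- sqrt(d)
    }
  }
  k_on <- 10^p[1]; k_off <- 10^p[2]
  derived <- derive_constants(k_on, k_off)
  structure(list(
    k_on = k_on, k_off = k_off,
    se = c(k_on = k_on * log(10) * se_log[1],
           k_off = k_off * log(10) * se_log[2]),
    residence_time = derived$residence_time,
    K_d = derived$K_d,
    Bmax = if (fit_bmax) 10^p[3] else tracer$Bmax,
    tracer = tracer, L = L,
    rss = opt$value, converged = converged,
    n_concentrations = length(concs)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Competitive-association (Motulsky-Mahan) fit",
      if (!x$converged) "[NOT CONVERGED]", "\n")
  cat(sprintf("  k_on  = %.4g /(M min)  (SE %.2g)\n", x$k_on, x$se[["k_on"]]))
  cat(sprintf("  k_off = %.4g /min      (SE %.2g)\n", x$k_off, x$se[["k_off"]]))
  cat(sprintf("  residence time = %.4g min; K_d = %.4g M\n",
              x$residence_time, x$K_d))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off,
    residence_time = object$residence_time, K_d = object$K_d)
}

#' @export
predict.mm_fit <- function(object, times, I, ...) {
  mm_predict(times, object$L, I, object$tracer$k1, object$tracer$k2,
             object$k_on, object$k_off, object$Bmax)
}

#' Residence time and equilibrium dissociation constant from rate constants
#'
#' Exact identities: residence time `= 1/k_off` (minutes) and
#' `K_d = k_off/k_on` (molar).
#'
#' @param k_on Association rate constant, 1/(M min).
#' @param k_off Dissociation rate constant, 1/min.
#' @return List with `residence_time` and `K_d`.
#' @export
derive_constants <- function(k_on, k_off) {
  check_positive(k_on, "k_on")
  check_positive(k_off, "k_off")
  list(residence_time = 1 / k_off, K_d = k_off / k_on)
}
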