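#' Global operational-model fit for one pathway
#'
#' Fits the operational model of agonism, parameterized directly in the log
#' transduction coefficient, jointly across all agonists measured in one
#' pathway (and experiment):
#' `E([A]) = basal + (Em - basal) / (1 + ((1 + [A]/KA) / (R [A]))^n)` with
#' `R = 10^log10(tau/KA)`. `Em`, `basal` and the transducer slope `n` are
#' shared across agonists; `log10(KA)` and `log10(tau/KA)` are per agonist.
#' Agonists whose responses never rise above the noise floor are flagged
#' `quantifiable = FALSE` and excluded from the fit (no estimates are
#' invented for them).
#'
#' Intra-experiment replicates are averaged per concentration before fitting.
#'
#' @param data data.frame with columns `agonist`, `concentration_M`,
#'   `response` (optionally `replicate`; other columns ignored). One pathway
#'   and one experiment at a time.
#' @param reference_agonist Id of the reference agonist; must be present and
#'   quantifiable.
#' @param n_fixed Fix the transducer slope at this value (e.g. 1), or `NULL`
#'   to estimate it (bounded in [0.2, 5]).
#' @param noise_floor Absolute response span below which an agonist is
#'   deemed unquantifiable. Default: `3 x` the pooled replicate SD when
#'   replicates exist, else 5% of the global response span.
#' @param compute_se Compute standard errors from the numerical Hessian?
#' @param pathway,experiment Optional labels carried into the result.
#' @return Object of class `operational_fit`: data.frame `agonists` with
#'   per-agonist `log10_KA`, `log10_tau_over_KA`, SEs and `quantifiable`;
#'   shared `Em`, `basal`, `n`; `converged`; residual sum of squares.
#' @export
fit_operational_model <- function(data, reference_agonist,
                                  n_fixed = NULL, noise_floor = NULL,
                                  compute_se = TRUE,
                                  pathway = NULL, experiment = NULL) {
  check_columns(data, c("agonist", "concentration_M", "response"), "data")
  check_positive(data$concentration_M, "concentrations")
  if (!reference_agonist %in% data$agonist) {
    stop_input("reference agonist '", reference_agonist, "' absent from data")
  }
  pathway <- pathway %||% (if ("pathway" %in% names(data))
    as.character(data$pathway[1]) else NA_character_)
  experiment <- experiment %||% (if ("experiment" %in% names(data))
    data$experiment[1] else NA)

  # replicate-average per agonist x concentration
  key <- interaction(data$agonist, data$concentration_M, drop = TRUE)
  rep_res <- unlist(tapply(data$response, key, function(v) v - mean(v)))
  pooled_sd <- if (length(rep_res) > length(levels(key)))
    stats::sd(rep_res) else NA_real_
  agg <- stats::aggregate(response ~ agonist + concentration_M, data, mean)
  agg$agonist <- as.character(agg$agonist)

  global_span <- diff(range(agg$response))
  if (is.null(noise_floor)) {
    noise_floor <- if (is.finite(pooled_sd)) 3 * pooled_sd
                   else 0.05 * global_span
  }
  spans <- tapply(agg$response, agg$agonist, function(v) diff(range(v)))
  quantifiable <- spans > noise_floor
  ids <- names(spans)
  if (!quantifiable[[reference_agonist]]) {
    stop_input("reference agonist is not quantifiable in this data")
  }
  fit_ids <- ids[quantifiable[ids]]
  sub <- agg[agg$agonist %in% fit_ids, ]
  conc <- sub$concentration_M
  y <- sub$response
  aidx <- match(sub$agonist, fit_ids)
  m <- length(fit_ids)

  # starting values from a crude per-agonist EC50 / span read-off
  ymin <- min(y); span0 <- max(y) - ymin
  lka0 <- lr0 <- numeric(m)
  for (j in seq_len(m)) {
    cj <- conc[aidx == j]; yj <- y[aidx == j]
    o <- order(cj); cj <- cj[o]; yj <- yj[o]
    f <- min(max((max(yj) - ymin) / span0, 0.05), 0.95)
    half <- ymin + (max(yj) - ymin) / 2
    above <- which(yj >= half)
    ec50 <- if (length(above)) cj[above[1]] else exp(mean(log(cj)))
    lr0[j] <- log10(f) - log10(ec50)
    lka0[j] <- log10(ec50) - log10(1 - f)
  }
  fix_n <- !is.null(n_fixed)
  par0 <- c(basal = ymin, span = span0,
            if (!fix_n) c(n = 1), lka0, lr0)
  n_shared_par <- if (fix_n) 2L else 3L
  lower <- c(ymin - span0, 0.05 * span0, if (!fix_n) 0.2,
             rep(-13, m), rep(0, m))
  upper <- c(ymin + 0.5 * span0, 3 * span0, if (!fix_n) 5,
             rep(-2, m), rep(15, m))
  par0 <- pmin(pmax(par0, lower), upper)

  obj <- function(p) {
    basal <- p[1]; span <- p[2]
    n <- if (fix_n) n_fixed else p[3]
    lka <- p[n_shared_par + seq_len(m)]
    lr <- p[n_shared_par + m + seq_len(m)]
    KA <- 10^lka[aidx]; R <- 10^lr[aidx]
    pred <- basal + span / (1 + ((1 + conc / KA) / (R * conc))^n)
    sum((y - pred)^2)
  }
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000, factr = 1e3))
  # polish with a second pass from the first optimum (the Em/tau ridge is
  # shallow; a restart escapes premature termination on it)
  opt2 <- stats::optim(opt$par, obj, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 1000, factr = 1e3))
  if (opt2$value <= opt$value) opt <- opt2
  p <- opt$par
  se_full <- rep(NA_real_, length(p))
  if (compute_se) {
    H <- try(stats::optimHess(p, obj), silent = TRUE)
    if (!inherits(H, "try-error")) {
      sigma2 <- opt$value / max(length(y) - length(p), 1)
      cv <- try(solve(H / 2) * sigma2, silent = TRUE)
      if (!inherits(cv, "try-error")) {
        d <- diag(cv)
        d[!is.finite(d) | d <= 0] <- NA_real_
        se_full <- sqrt(d)
      }
    }
  }
  lka <- p[n_shared_par + seq_len(m)]
  lr <- p[n_shared_par + m + seq_len(m)]
  se_lka <- se_full[n_shared_par + seq_len(m)]
  se_lr <- se_full[n_shared_par + m + seq_len(m)]
  agonists <- data.frame(
    agonist = ids,
    quantifiable = as.logical(quantifiable[ids]),
    log10_KA = NA_real_, log10_tau_over_KA = NA_real_,
    se_log10_KA = NA_real_, se_log10_tau_over_KA = NA_real_,
    stringsAsFactors = FALSE)
  pos <- match(fit_ids, agonists$agonist)
  agonists$log10_KA[pos] <- lka
  agonists$log10_tau_over_KA[pos] <- lr
  agonists$se_log10_KA[pos] <- se_lka
  agonists$se_log10_tau_over_KA[pos] <- se_lr
  structure(list(
    agonists = agonists,
    Em = p[1] + p[2], basal = p[1],
    n = if (fix_n) n_fixed else p[3],
    n_fixed = fix_n,
    reference_agonist = reference_agonist,
    pathway = pathway, experiment = experiment,
    rss = opt$value, converged = opt$convergence == 0,
    equation = "E = basal + (Em-basal)/(1 + ((1 + A/KA)/(10^logR * A))^n)"
  ), class = "operational_fit")
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("Operational-model fit (%s%s)%s\n",
              x$pathway %||% "pathway ?",
              if (!is.na(x$experiment)) paste0(", experiment ", x$experiment) else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cat(sprintf("  shared: Em = %.3g, basal = %.3g, n = %.3g%s\n",
              x$Em, x$basal, x$n, if (x$n_fixed) " (fixed)" else ""))
  for (i in seq_len(nrow(x$agonists))) {
    a <- x$agonists[i, ]
    if (a$quantifiable) {
      cat(sprintf("  %-12s log10(tau/KA) = %6.3f (SE %.3g), log10 KA = %6.2f\n",
                  a$agonist, a$log10_tau_over_KA, a$se_log10_tau_over_KA,
                  a$log10_KA))
    } else {
      cat(sprintf("  %-12s not quantifiable (no detectable response)\n",
                  a$agonist))
    }
  }
  invisible(x)
}

#' @export
coef.operational_fit <- function(object, ...) {
  stats::setNames(object$agonists$log10_tau_over_KA, object$agonists$agonist)
}

#' Fit the operational model for every pathway x experiment in a panel
#'
#' Convenience wrapper looping [fit_operational_model()] over the `pathway`
#' and `experiment` columns of a tidy concentration-response table.
#'
#' @param data Tidy data.frame with `agonist`, `pathway`, `experiment`,
#'   `concentration_M`, `response`.
#' @param reference_agonist Reference agonist id.
#' @param ... Passed on to [fit_operational_model()].
#' @return List of `operational_fit` objects.
#' @export
fit_operational_panel <- function(data, reference_agonist, ...) {
  check_columns(data, c("agonist", "pathway", "experiment",
                        "concentration_M", "response"), "data")
  fits <- list()
  for (pw in unique(data$pathway)) {
    for (ex in unique(data$experiment)) {
      sub <- data[data$pathway == pw & data$experiment == ex, ]
      if (!nrow(sub)) next
      fits[[length(fits) + 1L]] <-
        fit_operational_model(sub, reference_agonist,
                              pathway = as.character(pw), experiment = ex, ...)
    }
  }
  fits
}

#' Within-experiment normalized transduction coefficients
#'
#' Computes `Delta log10(tau/KA)` for every agonist by subtracting the
#' reference agonist's `log10(tau/KA)` within the same pathway and
#' experiment. Experiments where the reference is unquantifiable are dropped
#' with a warning. Cells where an agonist is unquantifiable are `NA` (never
#' imputed).
#'
#' @param fits A list of [fit_operational_model()] results (one per pathway x
#'   experiment), e.g. from [fit_operational_panel()].
#' @param reference_agonist Reference agonist id; defaults to the one stored
#'   in the fits.
#' @return A `bias_table` data.frame: `agonist`, `pathway`, `experiment`,
#'   `delta_log_tka`, `quantifiable`. Summarize across experiments with
#'   [summary.bias_table()].
#' @export
delta_log_tka <- function(fits, reference_agonist = NULL) {
  if (inherits(fits, "operational_fit")) fits <- list(fits)
  rows <- list()
  for (f in fits) {
    stopifnot(inherits(f, "operational_fit"))
    ref <- reference_agonist %||% f$reference_agonist
    a <- f$agonists
    iref <- match(ref, a$agonist)
    if (is.na(iref)) stop_input("reference agonist '", ref, "' absent from fit")
    if (!a$quantifiable[iref] || is.na(a$log10_tau_over_KA[iref])) {
      warning("reference agonist unquantifiable in pathway ", f$pathway,
              ", experiment ", f$experiment, "; experiment excluded")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      agonist = a$agonist,
      pathway = f$pathway,
      experiment = f$experiment,
      delta_log_tka = a$log10_tau_over_KA - a$log10_tau_over_KA[iref],
      quantifiable = a$quantifiable,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_input("no experiment had a quantifiable reference")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_agonist") <- reference_agonist %||%
    fits[[1]]$reference_agonist
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Summarize a bias table across experiments
#'
#' @param object A `bias_table` from [delta_log_tka()].
#' @param ... Unused.
#' @return data.frame with per agonist x pathway: `mean_delta`, `sem`,
#'   `n_experiments`.
#' @export
summary.bias_table <- function(object, ...) {
  sp <- split(object, list(object$agonist, object$pathway), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d$delta_log_tka[d$quantifiable & !is.na(d$delta_log_tka)]
    data.frame(agonist = d$agonist[1], pathway = d$pathway[1],
               mean_delta = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else if (length(v) == 1) 0 else NA_real_,
               n_experiments = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pathway-bias contrast: delta-delta log(tau/KA)
#'
#' Contrasts the normalized transduction coefficients between two pathways:
#' `DDlog(tau/KA) = Dlog(tau/KA)_A - Dlog(tau/KA)_B`, with standard error
#' `sqrt(SEM_A^2 + SEM_B^2)` propagated from the cross-experiment SEMs, a
#' 95% confidence interval, and a significance call when the CI excludes
#' zero. The bias factor is `10^DD`.
#'
#' @param bias_table A `bias_table` from [delta_log_tka()] containing both
#'   pathways.
#' @param pathway_a,pathway_b Pathway ids to contrast (A minus B).
#' @param ci `"z"` (default; multiplier 1.96) or `"t"` (Student-t with
#'   Welch-Satterthwaite degrees of freedom).
#' @param conf Confidence level, default 0.95.
#' @return A `bias_contrast` data.frame: per agonist `ddelta_log_tka`, `se`,
#'   `ci_lo`, `ci_hi`, `significant`, `bias_factor`.
#' @export
ddelta_log_tka <- function(bias_table, pathway_a, pathway_b,
                           ci = c("z", "t"), conf = 0.95) {
  ci <- match.arg(ci)
  s <- summary(bias_table)
  A <- s[s$pathway == pathway_a, ]
  B <- s[s$pathway == pathway_b, ]
  if (!nrow(A) || !nrow(B)) {
    stop_input("pathway(s) not present in the bias table")
  }
  mg <- merge(A, B, by = "agonist", suffixes = c("_a", "_b"))
  dd <- mg$mean_delta_a - mg$mean_delta_b
  se <- sqrt(mg$sem_a^2 + mg$sem_b^2)
  alpha <- 1 - conf
  mult <- if (ci == "z") {
    rep(stats::qnorm(1 - alpha / 2), length(se))
  } else {
    df <- (mg$sem_a^2 + mg$sem_b^2)^2 /
      (mg$sem_a^4 / pmax(mg$n_experiments_a - 1, 1) +
         mg$sem_b^4 / pmax(mg$n_experiments_b - 1, 1))
    ifelse(is.finite(df) & df > 0, stats::qt(1 - alpha / 2, df),
           stats::qnorm(1 - alpha / 2))
  }
  lo <- dd - mult * se
  hi <- dd + mult * se
  out <- data.frame(
    agonist = mg$agonist,
    pathway_a = pathway_a, pathway_b = pathway_b,
    ddelta_log_tka = dd, se = se, ci_lo = lo, ci_hi = hi,
    significant = !is.na(lo) & !is.na(hi) & (lo > 0 | hi < 0),
    bias_factor = 10^dd,
    n_a = mg$n_experiments_a, n_b = mg$n_experiments_b,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ci_type") <- ci
  class(out) <- c("bias_contrast", "data.frame")
  out
}

#' Web-of-bias radial coordinates
#'
#' Per agonist x pathway coordinate `10^(Dlog(tau/KA) - Dlog(tau/KA) at the
#' reference pathway)`: the inverse logarithm of the transduction coefficient
#' normalized to both the reference agonist (already done in the bias table)
#' and a reference pathway. The reference agonist maps to 1 on every pathway
#' and every agonist maps to 1 on the reference pathway. Unquantifiable cells
#' are `NA`, not zero.
#'
#' @param bias_table A `bias_table` from [delta_log_tka()].
#' @param reference_pathway Pathway to normalize against.
#' @return data.frame: `agonist`, `pathway`, `coordinate` (unitless),
#'   suitable for radar plotting.
#' @export
web_of_bias <- function(bias_table, reference_pathway) {
  s <- summary(bias_table)
  if (!reference_pathway %in% s$pathway) {
    stop_input("reference pathway '", reference_pathway, "' not present")
  }
  refd <- s[s$pathway == reference_pathway,
            c("agonist", "mean_delta")]
  names(refd)[2] <- "ref_delta"
  mg <- merge(s, refd, by = "agonist")
  mg$coordinate <- 10^(mg$mean_delta - mg$ref_delta)
  out <- mg[order(mg$pathway, mg$agonist),
            c("agonist", "pathway", "coordinate")]
  rownames(out) <- NULL
  out
}
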