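#' Ground-truth panel of agonist parameters for simulation
#'
#' Bundles, for each agonist, the operational-model parameters per signalling
#' pathway, binding rate constants, trafficking (endocytosis / recycling /
#' degradation) rate constants, a secretion coupling coefficient and a planted
#' endosomal pH. Every synthetic dataset the package can generate is derived
#' from one of these panels, so downstream fits can always be compared with
#' known truth.
#'
#' @param agonists Named list of agonist records. Each record is a list with
#'   elements:
#'   \describe{
#'     \item{operational}{data.frame with columns `pathway`, `Em`, `basal`,
#'       `n`, `log10_KA` (log10 molar) and `log10_tau_over_KA` (the log
#'       transduction coefficient, log10 1/M).}
#'     \item{binding}{named numeric with `k_on` (1/(M min)) and `k_off`
#'       (1/min).}
#'     \item{trafficking}{named numeric with `k_e`, `k_r`, `k_d` (1/min):
#'       endocytosis, recycling and degradation rate constants.}
#'     \item{secretion_coupling}{unitless coupling of receptor occupancy at
#'       the cell surface to insulin secretion.}
#'     \item{endosomal_ph}{planted pH of the endosomal compartment the ligand
#'       occupies after internalization.}
#'   }
#' @param reference Id (name) of the reference agonist; must be present.
#'
#' @return An object of class `ground_truth_panel`.
#' @seealso [demo_truth()] for a ready-made six-agonist panel.
#' @export
ground_truth_panel <- function(agonists, reference) {
  if (!length(agonists)) stop_input("agonist list must not be empty")
  if (is.null(names(agonists)) || any(!nzchar(names(agonists)))) {
    stop_input("agonists must be a named list")
  }
  if (!reference %in% names(agonists)) {
    stop_input("reference agonist '", reference, "' not in panel")
  }
  for (id in names(agonists)) {
    a <- agonists[[id]]
    op <- a$operational
    check_columns(op, c("pathway", "Em", "basal", "n",
                        "log10_KA", "log10_tau_over_KA"),
                  paste0("operational table for ", id))
    if (any(op$Em <= op$basal)) stop_input(id, ": Em must exceed basal")
    if (any(op$n <= 0)) stop_input(id, ": slope n must be > 0")
    check_nonnegative(unlist(a$binding), paste0(id, " binding rates"))
    check_nonnegative(unlist(a$trafficking), paste0(id, " trafficking rates"))
  }
  structure(list(agonists = agonists, reference = reference),
            class = "ground_truth_panel")
}

#' @export
print.ground_truth_panel <- function(x, ...) {
  cat("Ground-truth panel:", length(x$agonists), "agonists (reference:",
      x$reference, ")\n")
  for (id in names(x$agonists)) {
    a <- x$agonists[[id]]
    cat(sprintf("  %-12s pathways: %s | k_off %.3g /min | k_e %.3g /min\n",
                id, paste(a$operational$pathway, collapse = ", "),
                a$binding[["k_off"]], a$trafficking[["k_e"]]))
  }
  invisible(x)
}

#' Build one agonist record for a ground-truth panel
#'
#' Convenience constructor for the per-agonist entry of
#' [ground_truth_panel()]: one row of operational parameters per pathway
#' named in `log_tka`, plus binding, trafficking, secretion-coupling and
#' endosomal-pH truth.
#'
#' @param log_tka Named numeric: log10(tau/KA) per pathway (names are
#'   pathway ids).
#' @param log_ka log10 functional affinity (molar), shared across pathways.
#' @param Em,basal,n Shared operational parameters.
#' @param k_on,k_off Binding rate constants (1/(M min), 1/min).
#' @param k_e,k_r,k_d Trafficking rate constants (1/min).
#' @param coupling Secretion coupling coefficient (unitless).
#' @param endosomal_ph Planted endosomal pH.
#' @return List suitable as one element of the `agonists` argument of
#'   [ground_truth_panel()].
#' @export
agonist_record <- function(log_tka, log_ka = -7.2, Em = 100, basal = 0, n = 1,
                           k_on, k_off, k_e, k_r, k_d,
                           coupling = 1, endosomal_ph = 6.0) {
  list(
    operational = data.frame(
      pathway = names(log_tka),
      Em = Em, basal = basal, n = n,
      log10_KA = log_ka,
      log10_tau_over_KA = as.numeric(log_tka),
      stringsAsFactors = FALSE
    ),
    binding = c(k_on = k_on, k_off = k_off),
    trafficking = c(k_e = k_e, k_r = k_r, k_d = k_d),
    secretion_coupling = coupling,
    endosomal_ph = endosomal_ph
  )
}

#' Demonstration ground truth: a six-agonist GLP-1R-like panel
#'
#' A panel emulating the pharmacology of exendin-4 and congeners at the
#' GLP-1R: the reference agonist `ex4`; `exF1`, a G-protein-biased,
#' fast-dissociating, weakly internalizing, fast-recycling analog (its
#' beta-arrestin-1 response is planted below the noise floor); `exD3`, a
#' beta-arrestin-biased, slowly dissociating, strongly internalizing,
#' slow-recycling analog; and three licensed-drug-like agonists with
#' intermediate profiles. Rate constants are in 1/min and 1/(M min);
#' transduction coefficients in log10(1/M). Trafficking is coupled to
#' secretion with a shared positive coupling so that stronger net
#' internalization yields lower prolonged secretion.
#'
#' @return A [ground_truth_panel()].
#' @export
demo_truth <- function() {
  p <- c("cAMP", "barr1", "barr2")
  ground_truth_panel(reference = "ex4", agonists = list(
    ex4 = agonist_record(
      log_tka = c(cAMP = 9.0, barr1 = 7.4, barr2 = 7.5),
      k_on = 5e7, k_off = 0.05,
      k_e = 0.030, k_r = 0.010, k_d = 0.004,
      coupling = 1, endosomal_ph = 5.9),
    exF1 = agonist_record(
      log_tka = c(cAMP = 8.6, barr1 = -2, barr2 = 6.8),
      k_on = 3e7, k_off = 0.20,
      k_e = 0.008, k_r = 0.030, k_d = 0.002,
      coupling = 1, endosomal_ph = 6.6),
    exD3 = agonist_record(
      log_tka = c(cAMP = 8.4, barr1 = 7.5, barr2 = 7.8),
      k_on = 4e7, k_off = 0.018,
      k_e = 0.034, k_r = 0.004, k_d = 0.006,
      coupling = 1, endosomal_ph = 5.4),
    lixi = agonist_record(
      log_tka = c(cAMP = 8.9, barr1 = 7.3, barr2 = 7.45),
      k_on = 4.5e7, k_off = 0.035,
      k_e = 0.028, k_r = 0.007, k_d = 0.004,
      coupling = 1, endosomal_ph = 5.8),
    sema = agonist_record(
      log_tka = c(cAMP = 8.8, barr1 = 7.2, barr2 = 7.3),
      k_on = 4e7, k_off = 0.08,
      k_e = 0.024, k_r = 0.014, k_d = 0.003,
      coupling = 1, endosomal_ph = 6.1),
    dula = agonist_record(
      log_tka = c(cAMP = 8.7, barr1 = 7.15, barr2 = 7.25),
      k_on = 3.5e7, k_off = 0.09,
      k_e = 0.022, k_r = 0.015, k_d = 0.003,
      coupling = 1, endosomal_ph = 6.1)
  ))
}

#' Assay design: concentration grids, time grids and replication
#'
#' @param concentrations Agonist concentration grid in molar (log-spaced by
#'   default); at least 4 required for dose-response fitting.
#' @param times Time grid in minutes for kinetic and trafficking readouts.
#' @param n_replicates Intra-experiment replicates per condition.
#' @param n_experiments Independent experimental repeats.
#' @param tracer_conc Labelled-tracer concentration in molar (competitive
#'   kinetics).
#' @param competitor_concs Unlabelled competitor concentrations in molar; at
#'   least 4 required, mirroring the competitive-kinetics design.
#' @param facs_times Time points (min) at which stripping-based
#'   internalization is read.
#'
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(concentrations = 10^seq(-11.5, -6.5, length.out = 8),
                         times = seq(0, 60, by = 2),
                         n_replicates = 3,
                         n_experiments = 5,
                         tracer_conc = 1e-8,
                         competitor_concs = c(3e-9, 1e-8, 3e-8, 1e-7),
                         facs_times = c(15, 30, 60)) {
  check_positive(concentrations, "concentrations")
  if (length(concentrations) < 4) {
    stop_input("dose-response design needs >= 4 concentrations")
  }
  if (length(competitor_concs) < 4) {
    stop_input("competitive-kinetics design needs >= 4 competitor concentrations")
  }
  check_nonnegative(times, "times")
  check_positive(tracer_conc, "tracer_conc")
  check_positive(competitor_concs, "competitor_concs")
  structure(list(concentrations = sort(concentrations), times = sort(times),
                 n_replicates = as.integer(n_replicates),
                 n_experiments = as.integer(n_experiments),
                 tracer_conc = tracer_conc,
                 competitor_concs = sort(competitor_concs),
                 facs_times = sort(facs_times)),
            class = "assay_design")
}

#' Gaussian measurement-noise model
#'
#' Noise is Gaussian on the linear response scale. With `cv` set, the standard
#' deviation is `cv * |mean|` (plus `sd_floor`, so flat-zero signals still
#' scatter); with `sd` set it is absolute. Readouts that are physically
#' non-negative are truncated at 0.
#'
#' @param cv Coefficient of variation (fraction of the mean), or `NULL`.
#' @param sd Absolute standard deviation in response units, or `NULL`.
#' @param sd_floor Additive sd floor used with `cv` (response units).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.1, sd = NULL, sd_floor = 0) {
  if (is.null(cv) && is.null(sd)) stop_input("give one of cv or sd")
  if (!is.null(cv)) check_nonnegative(cv, "cv")
  if (!is.null(sd)) check_nonnegative(sd, "sd")
  structure(list(cv = cv, sd = sd, sd_floor = sd_floor), class = "noise_model")
}

# Apply a noise model to a vector of mean signals.
apply_noise <- function(mean_signal, noise, nonneg = TRUE) {
  s <- if (!is.null(noise$sd)) rep(noise$sd, length(mean_signal))
       else noise$cv * abs(mean_signal) + noise$sd_floor
  out <- mean_signal + stats::rnorm(length(mean_signal), 0, s)
  if (nonneg) out <- pmax(out, 0)
  out
}

#' Simulate concentration-response panels from operational-model truth
#'
#' Draws replicate responses around the operational-model mean for every
#' agonist x pathway x concentration x experiment. The reference agonist's
#' rows are flagged `is_reference`.
#'
#' @param truth A [ground_truth_panel()].
#' @param design An [assay_design()].
#' @param noise A [noise_model()].
#' @param seed Integer seed (fans out to a dedicated stream).
#' @return Tidy data.frame with columns `agonist`, `pathway`, `experiment`,
#'   `concentration_M`, `replicate`, `response`, `is_reference`.
#' @export
generate_dose_response_panel <- function(truth, design = assay_design(),
                                         noise = noise_model(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth_panel"))
  if (!length(design$concentrations)) stop_input("empty concentration grid")
  grids <- list()
  for (id in names(truth$agonists)) {
    op <- truth$agonists[[id]]$operational
    for (i in seq_len(nrow(op))) {
      g <- expand.grid(experiment = seq_len(design$n_experiments),
                       concentration_M = design$concentrations,
                       replicate = seq_len(design$n_replicates),
                       KEEP.OUT.ATTRS = FALSE)
      g$agonist <- id
      g$pathway <- op$pathway[i]
      g$mean <- operational_response(g$concentration_M,
                                     Em = op$Em[i], basal = op$basal[i],
                                     n = op$n[i],
                                     log10_KA = op$log10_KA[i],
                                     log10_tau_over_KA = op$log10_tau_over_KA[i])
      grids[[length(grids) + 1L]] <- g
    }
  }
  out <- do.call(rbind, grids)
  out$response <- with_seed(stream_seed(seed, "dose_response"),
                            apply_noise(out$mean, noise))
  out$is_reference <- out$agonist == truth$reference
  out$mean <- NULL
  rownames(out) <- NULL
  out[, c("agonist", "pathway", "experiment", "concentration_M",
          "replicate", "response", "is_reference")]
}

#' Mean response under the operational model of agonism
#'
#' `E([A]) = basal + (Em - basal) / (1 + ((1 + [A]/KA) / (R [A]))^n)` with
#' `R = 10^log10_tau_over_KA`, the transduction-coefficient parameterization
#' in which tau/KA is a direct fit parameter.
#'
#' @param conc Agonist concentration(s), molar.
#' @param Em,basal System maximal and basal response (response units).
#' @param n Unitless transducer slope.
#' @param log10_KA log10 functional affinity (molar).
#' @param log10_tau_over_KA log10 transduction coefficient (1/M).
#' @return Mean response, same length as `conc`.
#' @export
operational_response <- function(conc, Em, basal, n, log10_KA,
                                 log10_tau_over_KA) {
  KA <- 10^log10_KA
  R <- 10^log10_tau_over_KA
  basal + (Em - basal) / (1 + ((1 + conc / KA) / (R * conc))^n)
}

#' Simulate time-resolved competitive-binding traces
#'
#' Forward-simulates the Motulsky-Mahan mean for each unlabelled agonist at
#' the design's competitor concentrations, plus a competitor-free trace and an
#' excess-competitor (nonspecific, 10 uM) trace. A constant nonspecific
#' background is added to all "total" traces.
#'
#' @inheritParams generate_dose_response_panel
#' @param tracer Named list/vector with tracer `k1` (1/(M min)), `k2` (1/min)
#'   and `Bmax` (signal units).
#' @param ns_level Constant nonspecific background (signal units).
#' @param agonists Which agonists to simulate (default all in `truth`).
#' @return Tidy data.frame: `agonist`, `competitor_M`, `condition`
#'   (`"total"` or `"nonspecific"`), `time_min`, `signal`.
#' @export
generate_kinetic_traces <- function(truth, design = assay_design(),
                                    noise = noise_model(cv = 0.01),
                                    seed = 1,
                                    tracer = list(k1 = 5e7, k2 = 0.05,
                                                  Bmax = 1000),
                                    ns_level = 50,
                                    agonists = names(truth$agonists)) {
  stopifnot(inherits(truth, "ground_truth_panel"))
  check_positive(c(tracer$k1, tracer$k2, tracer$Bmax), "tracer parameters")
  if (any(design$competitor_concs < 0) || design$tracer_conc < 0) {
    stop_input("concentrations must be non-negative")
  }
  rows <- list()
  L <- design$tracer_conc
  tt <- design$times
  for (id in agonists) {
    b <- truth$agonists[[id]]$binding
    for (I in c(0, design$competitor_concs, 1e-5)) {
      spec <- mm_predict(tt, L = L, I = I,
                         k1 = tracer$k1, k2 = tracer$k2,
                         k3 = b[["k_on"]], k4 = b[["k_off"]],
                         Bmax = tracer$Bmax)
      rows[[length(rows) + 1L]] <- data.frame(
        agonist = id, competitor_M = I,
        condition = if (I >= 1e-5) "nonspecific" else "total",
        time_min = tt, mean = spec + ns_level,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$signal <- with_seed(stream_seed(seed, "kinetics"),
                          apply_noise(out$mean, noise))
  out$mean <- NULL
  rownames(out) <- NULL
  out
}

#' Analytic solution of the surface/endosome/degraded compartment model
#'
#' Solves `dS/dt = -k_e S + k_r I`, `dI/dt = k_e S - (k_r + k_d) I`, with the
#' degraded pool `D` accumulating the balance, from `S(0) = 1, I(0) = D(0) =
#' 0`. The 2x2 linear system is solved in closed form via its eigenvalues
#' (with the repeated-root limit handled analytically), so no numerical
#' integrator tolerance enters round-trip tests.
#'
#' @param times Times, minutes.
#' @param k_e,k_r,k_d Endocytosis, recycling, degradation rates (1/min).
#' @return data.frame with columns `time`, `S`, `I`, `D` (fractions of the
#'   initially labelled pool; `S + I + D = 1`).
#' @export
compartment_trajectory <- function(times, k_e, k_r, k_d) {
  check_nonnegative(c(k_e, k_r, k_d), "trafficking rates")
  check_nonnegative(times, "times")
  tr <- -(k_e + k_r + k_d)
  det <- k_e * k_d
  disc <- tr^2 - 4 * det   # = (k_e - k_r - k_d)^2 + 4 k_e k_r >= 0
  sq <- sqrt(max(disc, 0))
  l1 <- (tr + sq) / 2
  l2 <- (tr - sq) / 2
  if (sq > 1e-12 * abs(tr + (tr == 0))) {
    # S(t) = a1 e^{l1 t} + a2 e^{l2 t}; S(0)=1, S'(0) = -k_e
    a1 <- (-k_e - l2) / (l1 - l2)
    a2 <- 1 - a1
    S <- a1 * exp(l1 * times) + a2 * exp(l2 * times)
    # I(t) = (S' + k_e S)/k_r if k_r > 0, else direct form
    if (k_r > 0) {
      Sp <- a1 * l1 * exp(l1 * times) + a2 * l2 * exp(l2 * times)
      I <- (Sp + k_e * S) / k_r
    } else {
      # one-way cascade: I' = k_e e^{-k_e t} - (k_d) I with l1/l2 = -k_e,-(k_d)
      kI <- k_r + k_d
      I <- if (abs(k_e - kI) > 1e-12) {
        k_e / (kI - k_e) * (exp(-k_e * times) - exp(-kI * times))
      } else {
        k_e * times * exp(-k_e * times)
      }
    }
  } else {
    # repeated eigenvalue l = tr/2
    l <- tr / 2
    S <- exp(l * times) * (1 + (-k_e - l) * times)
    I <- k_e * times * exp(l * times)
  }
  data.frame(time = times, S = S, I = I, D = pmax(1 - S - I, 0))
}

#' Simulate trafficking readouts (FACS stripping, DERET, surface plates)
#'
#' Generates, from the compartment model, (i) FACS median fluorescences with
#' and without surface-label stripping at the design's trafficking time
#' points, including paired t0 values and a 15-min internalization +
#' recycling measurement; (ii) DERET donor/acceptor time courses for agonist
#' and vehicle wells; (iii) plate-reader surface signals for the
#' vehicle / internalized / recycled stages. The latent `S, I, D` trajectory
#' is returned for round-trip tests. Degraded receptor is modelled as
#' non-fluorescent, so the stripping readout reports the internalized
#' (endosomal) pool.
#'
#' @inheritParams generate_dose_response_panel
#' @param strip_residual Fraction of surface label surviving stripping
#'   (1 - stripping efficiency); default 0.1, i.e. 90% efficiency.
#' @param label_units Total label per cell (arbitrary fluorescence units).
#' @param recycle_period Recycling chase duration after the 15-min
#'   internalization, minutes.
#' @param internalize_time Internalization time for the plate recycling
#'   protocol, minutes.
#' @return List with data.frames `facs`, `recycling`, `deret`, `plate`,
#'   `latent`.
#' @export
generate_trafficking_measurements <- function(truth, design = assay_design(),
                                              noise = noise_model(cv = 0.03),
                                              seed = 1,
                                              strip_residual = 0.1,
                                              label_units = 1000,
                                              recycle_period = 30,
                                              internalize_time = 30) {
  stopifnot(inherits(truth, "ground_truth_panel"))
  facs <- list(); recyc <- list(); deret <- list(); plate <- list()
  latent <- list()
  tt <- design$times
  for (id in names(truth$agonists)) {
    k <- truth$agonists[[id]]$trafficking
    traj <- compartment_trajectory(unique(sort(c(0, tt, design$facs_times,
                                                 internalize_time, 15))),
                                   k[["k_e"]], k[["k_r"]], k[["k_d"]])
    latent[[id]] <- cbind(agonist = id, traj)
    at <- function(t) traj[match(t, traj$time), ]
    # FACS: F_minusMe = (S+I) * label (degraded pool dark);
    # F_plusMe = (strip_residual*S + I) * label
    for (tx in c(0, design$facs_times)) {
      z <- at(tx)
      facs[[length(facs) + 1L]] <- data.frame(
        agonist = id, time_min = tx,
        F_plusMe = (strip_residual * z$S + z$I) * label_units,
        F_minusMe = (z$S + z$I) * label_units, stringsAsFactors = FALSE)
    }
    # Recycling: internalize 15 min, strip, chase with no re-internalization,
    # second strip; remaining internal label decays at k_r + k_d.
    z15 <- at(15)
    F_int15 <- z15$I * label_units
    F_rec <- F_int15 * exp(-(k[["k_r"]] + k[["k_d"]]) * recycle_period)
    recyc[[length(recyc) + 1L]] <- data.frame(
      agonist = id, F_int15 = F_int15, F_rec = F_rec,
      internalized_percent_15 = 100 * z15$I / (z15$S + z15$I),
      stringsAsFactors = FALSE)
    # DERET: donor (620) dequenches as receptor leaves the fluorescein bath
    trj <- at(tt)
    deret[[length(deret) + 1L]] <- data.frame(
      agonist = id, condition = "agonist", time_min = tt,
      A620 = 200 * (1 + 1.5 * (1 - trj$S)), A520 = 2000,
      stringsAsFactors = FALSE)
    # Plate: surface signal at stages vehicle / internalized / recycled
    zi <- at(internalize_time)
    kout <- k[["k_r"]] + k[["k_d"]]
    recovered <- if (kout > 0) {
      zi$I * k[["k_r"]] / kout * (1 - exp(-kout * recycle_period))
    } else 0
    plate[[length(plate) + 1L]] <- data.frame(
      agonist = id,
      stage = c("vehicle", "internalized", "recycled"),
      mean = label_units * c(1, zi$S, zi$S + recovered),
      stringsAsFactors = FALSE)
  }
  deret[[length(deret) + 1L]] <- data.frame(
    agonist = "vehicle", condition = "vehicle", time_min = tt,
    A620 = 200, A520 = 2000, stringsAsFactors = FALSE)
  facs <- do.call(rbind, facs); recyc <- do.call(rbind, recyc)
  deret <- do.call(rbind, deret); plate <- do.call(rbind, plate)
  with_seed(stream_seed(seed, "trafficking"), {
    facs$F_plusMe <- apply_noise(facs$F_plusMe, noise)
    facs$F_minusMe <- apply_noise(facs$F_minusMe, noise)
    recyc$F_int15 <- apply_noise(recyc$F_int15, noise)
    recyc$F_rec <- apply_noise(recyc$F_rec, noise)
    deret$A620 <- apply_noise(deret$A620, noise)
    deret$A520 <- apply_noise(deret$A520, noise)
    plate$signal <- apply_noise(plate$mean, noise)
  })
  plate$mean <- NULL
  rownames(facs) <- rownames(recyc) <- rownames(deret) <- rownames(plate) <- NULL
  list(facs = facs, recycling = recyc, deret = deret, plate = plate,
       latent = do.call(rbind, latent))
}

#' Simulate endosomal-pH calibration and cell measurements
#'
#' For each agonist a ligand-specific linear fluorescence-vs-pH calibration is
#' generated, together with paired cellular intensities without (control) and
#' with bafilomycin. Bafilomycin collapses the endosomal pH gradient, so its
#' intensities are generated at pH 7.4; control intensities at the planted
#' endosomal pH. A random per-condition loading factor cancels in the
#' ratio-based estimator.
#'
#' Cellular intensities mimic the assay's repeated fluorescence reads over
#' the measurement window: each reported value is the mean of `n_reads`
#' noisy reads.
#'
#' @inheritParams generate_dose_response_panel
#' @param ph_grid Calibration pH values (>= 3 distinct values required).
#' @param n_reads Number of serial reads averaged per cellular intensity.
#' @return List with data.frames `calibration` (`ligand`, `pH`, `intensity`)
#'   and `cells` (`ligand`, `F_control`, `F_bafilomycin`, `true_ph`).
#' @export
generate_ph_dataset <- function(truth, noise = noise_model(cv = 0.01),
                                seed = 1,
                                ph_grid = seq(4.5, 8, by = 0.5),
                                n_reads = 8) {
  stopifnot(inherits(truth, "ground_truth_panel"))
  if (diff(range(ph_grid)) <= 0) stop_input("calibration pH range has zero width")
  ids <- names(truth$agonists)
  with_seed(stream_seed(seed, "ph"), {
    calib <- list(); cells <- list()
    for (id in ids) {
      ph <- truth$agonists[[id]]$endosomal_ph %||% 6.0
      if (ph < min(ph_grid) || ph > max(ph_grid)) {
        stop_input("planted pH for ", id, " outside the calibration range")
      }
      slope <- stats::runif(1, 120, 220)        # AU per pH unit (fluorescein-like)
      intercept <- stats::runif(1, -300, -100)  # AU
      calib[[id]] <- data.frame(
        ligand = id, pH = ph_grid,
        intensity = apply_noise(intercept + slope * ph_grid, noise),
        stringsAsFactors = FALSE)
      loading <- stats::runif(1, 0.5, 2)  # cancels in the ratio estimator
      cells[[id]] <- data.frame(
        ligand = id,
        F_control = mean(apply_noise(
          rep(loading * (intercept + slope * ph), n_reads), noise)),
        F_bafilomycin = mean(apply_noise(
          rep(loading * (intercept + slope * 7.4), n_reads), noise)),
        true_ph = ph, stringsAsFactors = FALSE)
    }
    list(calibration = do.call(rbind, calib),
         cells = do.call(rbind, cells))
  })
}

#' Simulate prolonged insulin-secretion samples
#'
#' Cumulative secretion over the incubation is modelled as a baseline rate
#' plus `coupling * occupancy * integral of S(t)/S(0) dt`: receptor signalling
#' proportional to the surface receptor remaining, so strong net
#' internalization with slow recycling depresses prolonged secretion. Control
#' (glucose-only) samples are included so the insulin stimulation index is
#' computable. This coupling law is an explicit generator convention, not a
#' mechanistic model.
#'
#' @inheritParams generate_dose_response_panel
#' @param duration Incubation length, minutes (default 960 = 16 h).
#' @param agonist_conc Applied agonist concentration, molar (default 100 nM).
#' @param baseline_rate Baseline secretion rate, units/min.
#' @param gain Global secretion gain multiplying the agonist coupling
#'   coefficient, units/min.
#' @param total_content Total insulin content per sample (units).
#' @return data.frame: `condition`, `replicate`, `secreted`, `content`,
#'   `is_control`.
#' @export
generate_secretion_timecourse <- function(truth, design = assay_design(),
                                          noise = noise_model(cv = 0.05),
                                          seed = 1, duration = 960,
                                          agonist_conc = 1e-7,
                                          baseline_rate = 0.02,
                                          gain = 0.10,
                                          total_content = 1000) {
  stopifnot(inherits(truth, "ground_truth_panel"))
  rows <- list()
  grid <- seq(0, duration, length.out = 481)
  for (id in names(truth$agonists)) {
    a <- truth$agonists[[id]]
    k <- a$trafficking
    if (is.null(a$trafficking)) stop_input("no trafficking truth for ", id)
    Kd <- a$binding[["k_off"]] / a$binding[["k_on"]]
    occ <- agonist_conc / (agonist_conc + Kd)
    traj <- compartment_trajectory(grid, k[["k_e"]], k[["k_r"]], k[["k_d"]])
    intS <- sum(diff(grid) * (utils::head(traj$S, -1) + utils::tail(traj$S, -1)) / 2)
    mean_sec <- baseline_rate * duration +
      gain * a$secretion_coupling * occ * intS
    rows[[id]] <- data.frame(condition = id,
                             replicate = seq_len(design$n_replicates),
                             mean = mean_sec, is_control = FALSE,
                             stringsAsFactors = FALSE)
  }
  rows[["control"]] <- data.frame(condition = "control",
                                  replicate = seq_len(design$n_replicates),
                                  mean = baseline_rate * duration,
                                  is_control = TRUE, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$secreted <- with_seed(stream_seed(seed, "secretion"),
                            apply_noise(out$mean, noise))
  out$content <- pmax(total_content - out$secreted, 0)
  out$mean <- NULL
  rownames(out) <- NULL
  out[, c("condition", "replicate", "secreted", "content", "is_control")]
}
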