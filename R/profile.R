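#' Assemble the per-agonist multi-readout feature matrix
#'
#' Joins, per agonist: the dissociation rate constant `k_off` normalized to
#' the reference agonist within each assay (then averaged across assays),
#' the pathway-normalized transduction coefficients `Dlog(tau/KA)` for two
#' pathways, and internalization and recycling percentages at a fixed time
#' point. Missing cells stay `NA` (masked), never imputed or zero-filled.
#'
#' @param bias_table A `bias_table` from [delta_log_tka()] covering the two
#'   pathways.
#' @param kinetics data.frame with `agonist`, `k_off` and optionally `assay`
#'   (per-assay normalization to the reference before averaging).
#' @param trafficking data.frame with `agonist`, `internalization_pct`,
#'   `recycling_pct`.
#' @param reference_agonist Reference agonist id for per-assay
#'   normalization.
#' @param pathways Two pathway ids whose `Dlog(tau/KA)` enter the matrix.
#' @return Numeric matrix (rows = agonists, columns = features) with an
#'   attached `"units"` attribute; `NA` marks masked cells.
#' @export
assemble_features <- function(bias_table, kinetics, trafficking,
                              reference_agonist,
                              pathways = c("cAMP", "barr2")) {
  check_columns(kinetics, c("agonist", "k_off"), "kinetics")
  check_columns(trafficking,
                c("agonist", "internalization_pct", "recycling_pct"),
                "trafficking")
  ids <- sort(unique(c(kinetics$agonist, trafficking$agonist,
                       unique(bias_table$agonist))))
  # per-assay normalization of k_off to the reference agonist
  if (!"assay" %in% names(kinetics)) kinetics$assay <- 1L
  norm_k <- lapply(split(kinetics, kinetics$assay), function(d) {
    refk <- d$k_off[d$agonist == reference_agonist]
    if (!length(refk) || !is.finite(refk[1]) || refk[1] <= 0) {
      warning("reference agonist missing from a kinetics assay; assay dropped")
      return(NULL)
    }
    data.frame(agonist = d$agonist, rel = d$k_off / refk[1])
  })
  norm_k <- do.call(rbind, norm_k)
  koff_rel <- if (!is.null(norm_k)) {
    tapply(norm_k$rel, norm_k$agonist, mean)
  } else NULL
  s <- summary(bias_table)
  feat <- matrix(NA_real_, nrow = length(ids), ncol = 5,
                 dimnames = list(ids, c(
                   "k_off_rel",
                   paste0("dlog_tka_", pathways[1]),
                   paste0("dlog_tka_", pathways[2]),
                   "internalization_pct", "recycling_pct")))
  for (id in ids) {
    if (!is.null(koff_rel) && id %in% names(koff_rel)) {
      feat[id, 1] <- koff_rel[[id]]
    }
    for (j in 1:2) {
      v <- s$mean_delta[s$agonist == id & s$pathway == pathways[j]]
      if (length(v) == 1 && is.finite(v)) feat[id, 1 + j] <- v
    }
    ti <- trafficking[trafficking$agonist == id, ]
    if (nrow(ti) == 1) {
      feat[id, 4] <- ti$internalization_pct
      feat[id, 5] <- ti$recycling_pct
    }
  }
  if (anyNA(feat)) {
    missing_rows <- rownames(feat)[apply(feat, 1, anyNA)]
    warning("masked (missing) features for: ",
            paste(missing_rows, collapse = ", "))
  }
  attr(feat, "units") <- c(
    k_off_rel = "fold of reference k_off",
    stats::setNames("log10 units", paste0("dlog_tka_", pathways[1])),
    stats::setNames("log10 units", paste0("dlog_tka_", pathways[2])),
    internalization_pct = "%", recycling_pct = "%")
  feat
}

#' Principal component analysis of agonist profiles
#'
#' Standardizes each feature column (mean 0, SD 1) and decomposes the
#' agonist x feature matrix. Masked (`NA`) cells are an error: drop the
#' incomplete rows (`drop_incomplete = TRUE`) or complete the matrix first —
#' values are never imputed.
#'
#' @param features Matrix from [assemble_features()] (>= 3 complete rows).
#' @param drop_incomplete Drop rows containing `NA` (with a message) instead
#'   of erroring.
#' @return Object of class `pca_profile`: `scores` (agonists x components),
#'   `loadings` (features x components, orthonormal), `variance_explained`
#'   (%; sums to 100 over all components).
#' @export
pca_profile <- function(features, drop_incomplete = FALSE) {
  if (anyNA(features)) {
    if (!drop_incomplete) {
      stop_input("feature matrix has masked cells; drop or complete those ",
                 "rows (see drop_incomplete) - values are not imputed")
    }
    keep <- !apply(features, 1, anyNA)
    message("dropping incomplete rows: ",
            paste(rownames(features)[!keep], collapse = ", "))
    features <- features[keep, , drop = FALSE]
  }
  if (nrow(features) < 3) stop_input("need >= 3 complete agonist rows for PCA")
  pc <- stats::prcomp(features, center = TRUE, scale. = TRUE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, prcomp = pc),
            class = "pca_profile")
}

#' @export
print.pca_profile <- function(x, ...) {
  cat("Agonist-profile PCA:",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                     x$variance_explained), collapse = ", "), "\n")
  print(round(x$scores[, seq_len(min(3, ncol(x$scores))), drop = FALSE], 3))
  invisible(x)
}

#' Linear relationship between two per-agonist quantities
#'
#' Ordinary least-squares regression of `y` on `x` across agonists, as used
#' to relate internalization to prolonged insulin secretion and to glucose
#' AUC. The headline output is the slope and its sign.
#'
#' @param x,y Paired per-agonist values (>= 3 points, `x` not constant).
#' @param labels Optional `c(x_label, y_label)`.
#' @return Object of class `relationship_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
regress_relationship <- function(x, y, labels = c("x", "y")) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_input("need >= 3 paired points")
  if (stats::var(x) == 0) stop_input("x has zero variance; slope undefined")
  if (stats::var(y) == 0) {
    # constant response: flat line, no explained variance
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = 1, n = length(x), labels = labels,
                          fit = NULL),
                     class = "relationship_fit"))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = stats::coef(fit)[["x"]],
                 intercept = stats::coef(fit)[[1]],
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 n = length(x), labels = labels, fit = fit),
            class = "relationship_fit")
}

#' @export
print.relationship_fit <- function(x, ...) {
  cat(sprintf("%s vs %s: slope %.4g (p = %.3g), r^2 = %.3f, n = %d\n",
              x$labels[2], x$labels[1], x$slope, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates every assay from a ground-truth panel, runs all fitting stages
#' (dose-response and operational-model bias, competitive binding kinetics,
#' trafficking metrics, endosomal pH, secretion indices), assembles the
#' agonist feature matrix, and runs the profile PCA and the
#' internalization-vs-secretion regression. All tables, a JSON run manifest
#' (seed, parameters) and the result bundle are written to `output_dir` as
#' plain CSV/JSON when it is given.
#'
#' @param config List (or path to a YAML file, read with the yaml package)
#'   with optional entries `seed`, `output_dir`, `reference_agonist`,
#'   `reference_pathway`, `pathway_contrast` (2 pathway ids), `ci`
#'   (`"z"`/`"t"`), `design` (arguments to [assay_design()]), `noise_cv`.
#' @param truth A [ground_truth_panel()]; default [demo_truth()].
#' @return Invisibly, a list with all intermediate and final results
#'   (`dose_response`, `operational_fits`, `bias_table`, `bias_contrast`,
#'   `web`, `kinetics`, `trafficking`, `ph`, `secretion`, `isi`, `features`,
#'   `pca`, `regression`, `manifest`).
#' @export
run_pipeline <- function(config = list(), truth = demo_truth()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  ref <- config$reference_agonist %||% truth$reference
  if (!ref %in% names(truth$agonists)) {
    stop_input("reference agonist '", ref, "' not in ground truth")
  }
  ref_pathway <- config$reference_pathway %||% "cAMP"
  contrast <- config$pathway_contrast %||% c("cAMP", "barr2")
  ci <- config$ci %||% "t"
  design <- do.call(assay_design, config$design %||% list())
  noise <- noise_model(cv = config$noise_cv %||% 0.1)

  # --- simulate -------------------------------------------------------------
  dr <- generate_dose_response_panel(truth, design, noise, seed = seed)
  kin <- generate_kinetic_traces(truth, design,
                                 noise = noise_model(cv = 0.01,
                                                     sd_floor = 0.5),
                                 seed = seed)
  trf <- generate_trafficking_measurements(truth, design,
                                           noise = noise_model(cv = 0.03),
                                           seed = seed)
  ph <- generate_ph_dataset(truth, noise = noise_model(cv = 0.01),
                            seed = seed)
  secr <- generate_secretion_timecourse(truth, design,
                                        noise = noise_model(cv = 0.05),
                                        seed = seed)

  # --- signal bias ----------------------------------------------------------
  fits <- fit_operational_panel(dr, reference_agonist = ref,
                                compute_se = FALSE)
  bt <- delta_log_tka(fits, reference_agonist = ref)
  contrast_tab <- ddelta_log_tka(bt, contrast[1], contrast[2], ci = ci)
  web <- web_of_bias(bt, ref_pathway)

  # --- binding kinetics -----------------------------------------------------
  tracer <- list(k1 = 5e7, k2 = 0.05, Bmax = 1000)
  kin_rows <- list()
  for (id in unique(kin$agonist)) {
    sub <- kin[kin$agonist == id, ]
    ns <- sub[sub$condition == "nonspecific", ]
    spec_rows <- lapply(split(sub[sub$condition == "total", ],
                              sub$competitor_M[sub$condition == "total"]),
                        function(d) {
      sp <- specific_binding(data.frame(time_min = d$time_min,
                                        signal = d$signal),
                             data.frame(time_min = ns$time_min,
                                        signal = ns$signal))
      data.frame(competitor_M = d$competitor_M[1],
                 time_min = sp$time_min, signal = sp$signal)
    })
    spec <- do.call(rbind, spec_rows)
    fit <- fit_competitive(spec[spec$competitor_M > 0, ], tracer = tracer,
                           L = design$tracer_conc)
    kin_rows[[id]] <- data.frame(
      agonist = id, k_on = fit$k_on, k_off = fit$k_off,
      residence_time = fit$residence_time, K_d = fit$K_d,
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  kinetics_tab <- do.call(rbind, kin_rows)
  rownames(kinetics_tab) <- NULL

  # --- trafficking ----------------------------------------------------------
  trf_rows <- list()
  tx <- max(design$facs_times)
  for (id in unique(trf$facs$agonist)) {
    f <- trf$facs[trf$facs$agonist == id, ]
    f0 <- f[f$time_min == 0, ]
    fx <- f[f$time_min == tx, ]
    internal <- facs_internalized_percent(fx$F_plusMe, fx$F_minusMe,
                                          f0$F_plusMe, f0$F_minusMe)
    r <- trf$recycling[trf$recycling$agonist == id, ]
    rec <- facs_recycled_percent(r$F_int15, r$F_rec,
                                 r$internalized_percent_15)
    trf_rows[[id]] <- data.frame(
      agonist = id,
      internalization_pct = as.numeric(internal),
      recycling_pct = rec$recycled_percent_of_internalized,
      stringsAsFactors = FALSE)
  }
  trafficking_tab <- do.call(rbind, trf_rows)
  rownames(trafficking_tab) <- NULL

  # --- endosomal pH ---------------------------------------------------------
  ph_rows <- list()
  for (id in unique(ph$calibration$ligand)) {
    cal <- ph$calibration[ph$calibration$ligand == id, ]
    calib <- fit_ph_calibration(cal$pH, cal$intensity, ligand = id)
    cells <- ph$cells[ph$cells$ligand == id, ]
    est <- estimate_endosomal_ph(cells$F_control, cells$F_bafilomycin, calib)
    ph_rows[[id]] <- data.frame(ligand = id, ph = est$ph,
                                extrapolated = est$extrapolated,
                                true_ph = cells$true_ph,
                                stringsAsFactors = FALSE)
  }
  ph_tab <- do.call(rbind, ph_rows)
  rownames(ph_tab) <- NULL

  # --- secretion index ------------------------------------------------------
  rel <- percent_release(secr$secreted, secr$content)
  isi <- insulin_stimulation_index(rel, secr$condition, secr$is_control)

  # --- profile --------------------------------------------------------------
  features <- assemble_features(bt, kinetics_tab, trafficking_tab,
                                reference_agonist = ref,
                                pathways = contrast)
  pca <- pca_profile(features, drop_incomplete = TRUE)
  agonist_isi <- isi[rownames(features)]
  reg <- regress_relationship(features[, "internalization_pct"],
                              as.numeric(agonist_isi),
                              labels = c("internalization_pct", "ISI"))

  manifest <- list(seed = seed, reference_agonist = ref,
                   reference_pathway = ref_pathway,
                   pathway_contrast = contrast, ci = ci,
                   n_experiments = design$n_experiments,
                   noise_cv = noise$cv,
                   package_version = as.character(utils::packageVersion("gpcrtraffic")))
  bundle <- list(dose_response = dr, operational_fits = fits,
                 bias_table = bt, bias_contrast = contrast_tab, web = web,
                 kinetic_traces = kin, kinetics = kinetics_tab,
                 trafficking_raw = trf, trafficking = trafficking_tab,
                 ph = ph_tab, secretion = secr, isi = isi,
                 features = features, pca = pca, regression = reg,
                 manifest = manifest)

  outdir <- config$output_dir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, f) utils::write.csv(d, file.path(outdir, f),
                                          row.names = FALSE)
    wr(dr, "dose_response.csv")
    wr(as.data.frame(bt), "bias_table.csv")
    wr(as.data.frame(contrast_tab), "bias_contrast.csv")
    wr(web, "web_of_bias.csv")
    wr(kinetics_tab, "kinetics.csv")
    wr(trafficking_tab, "trafficking.csv")
    wr(ph_tab, "endosomal_ph.csv")
    wr(secr, "secretion.csv")
    wr(data.frame(condition = names(isi), isi = as.numeric(isi)), "isi.csv")
    wr(data.frame(agonist = rownames(features), features,
                  check.names = FALSE), "features.csv")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(bundle)
}
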