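#' Internalized receptor percentage from stripping-based flow cytometry
#'
#' Computes the percentage of internalized receptor from median
#' fluorescences measured with (`F_plusMe`) and without (`F_minusMe`)
#' surface-label stripping, at the measurement time `t_x` and at time zero:
#' `100 * (r(t_x) - r(t_0)) / (1 - r(t_0))` with `r(t) =
#' F_plusMe(t) / F_minusMe(t)`. The `t_0` term corrects for imperfect
#' stripping; the result is invariant to a common rescaling of all
#' fluorescences.
#'
#' @param f_plus,f_minus Median fluorescence with / without stripping at the
#'   measurement time (> 0).
#' @param f_plus0,f_minus0 Paired values at time zero.
#' @param tolerance Percentage-point tolerance outside [0, 100] beyond which
#'   values are flagged (returned as-is, never clipped).
#' @return Numeric percentage(s) with attribute `flagged` marking values
#'   outside `[-tolerance, 100 + tolerance]`.
#' @export
facs_internalized_percent <- function(f_plus, f_minus, f_plus0, f_minus0,
                                      tolerance = 2) {
  check_positive(f_minus, "F_minusMe")
  check_positive(f_minus0, "F_minusMe(t0)")
  r0 <- f_plus0 / f_minus0
  if (any(r0 >= 1)) {
    stop_input("t0 stripped/unstripped ratio >= 1: stripping failed")
  }
  rt <- f_plus / f_minus
  out <- 100 * (rt - r0) / (1 - r0)
  attr(out, "flagged") <- out < -tolerance | out > 100 + tolerance
  out
}

#' Recycled receptor percentage from the two-strip protocol
#'
#' After 15 min of internalization and a first strip, the remaining
#' fluorescence `F_int15` marks the internalized pool; after a recycling
#' chase and a second strip, `F_rec` marks what stayed inside. The fraction
#' of the internalized pool that returned to the surface is
#' `100 * (F_int15 - F_rec) / F_int15`. With `internalized_percent_15`
#' supplied, the alternative convention — absolute percentage points of total
#' receptor recycled, i.e. the fraction above times the percent internalized
#' at 15 min — is returned alongside.
#'
#' @param f_int15 Median fluorescence after internalization + first strip
#'   (> 0).
#' @param f_rec Median fluorescence after the recycling chase + second strip.
#' @param internalized_percent_15 Optional percent internalized at 15 min.
#' @param tolerance Percentage points of `f_rec > f_int15` excess tolerated
#'   before flagging.
#' @return data.frame with `recycled_percent_of_internalized`, optionally
#'   `recycled_percent_of_total`, and a `flagged` column.
#' @export
facs_recycled_percent <- function(f_int15, f_rec,
                                  internalized_percent_15 = NULL,
                                  tolerance = 2) {
  check_positive(f_int15, "F_int15")
  check_nonnegative(f_rec, "F_rec")
  pct <- 100 * (f_int15 - f_rec) / f_int15
  out <- data.frame(recycled_percent_of_internalized = pct,
                    flagged = pct < -tolerance)
  if (!is.null(internalized_percent_15)) {
    out$recycled_percent_of_total <- pct * internalized_percent_15 / 100
  }
  out
}

#' Surface-receptor loss from plate-reader surface labelling
#'
#' Residual surface expression in agonist- vs. vehicle-treated wells,
#' expressed as percent surface loss: `100 * (1 - agonist / vehicle)`.
#'
#' @param signal_agonist Surface signal after agonist treatment.
#' @param signal_vehicle Surface signal in vehicle wells (> 0).
#' @return Percentage surface loss.
#' @export
plate_internalization_percent <- function(signal_agonist, signal_vehicle) {
  check_positive(signal_vehicle, "vehicle signal")
  100 * (1 - signal_agonist / signal_vehicle)
}

#' Percent recovery of surface receptor after a recycling chase
#'
#' `100 * (S_recycled - S_internalized) / (S_vehicle - S_internalized)`: the
#' recovered surface signal as a percentage of the surface receptor lost
#' during the internalization step.
#'
#' @param s_vehicle Vehicle (no-internalization) surface signal.
#' @param s_internalized Surface signal immediately after internalization.
#' @param s_recycled Surface signal after the recycling chase.
#' @return Percentage recovery.
#' @export
plate_recycling_percent <- function(s_vehicle, s_internalized, s_recycled) {
  denom <- s_vehicle - s_internalized
  if (any(denom <= 0)) {
    stop_input("no surface loss to recover from (vehicle <= internalized)")
  }
  100 * (s_recycled - s_internalized) / denom
}

#' Surface-receptor loss time course from a DERET assay
#'
#' In diffusion-enhanced RET, surface receptors labelled with a terbium donor
#' are quenched by extracellular fluorescein; internalization removes the
#' receptor from the fluorescein bath and the 620 nm donor signal recovers,
#' so surface loss rises with the 620/520 ratio. Each well's ratio
#' `R(t) = A620/A520` is anchored to its own `t0` (removing labelling
#' variation) and expressed relative to the vehicle time course:
#' `loss(t) = R(t)/R(0) - R_veh(t)/R_veh(0)`.
#'
#' @param series data.frame for the agonist well: `time_min`, `A620`, `A520`.
#' @param vehicle data.frame for the vehicle well, same columns and time
#'   grid.
#' @return data.frame `time_min`, `surface_loss` (unitless, 0 at t0).
#' @export
deret_surface_loss <- function(series, vehicle) {
  check_columns(series, c("time_min", "A620", "A520"), "series")
  check_columns(vehicle, c("time_min", "A620", "A520"), "vehicle")
  if (any(series$A520 == 0) || any(vehicle$A520 == 0)) {
    stop_input("A520 signal of zero; ratio undefined")
  }
  if (nrow(series) != nrow(vehicle) ||
      any(series$time_min != vehicle$time_min)) {
    stop_input("agonist and vehicle series must share one time grid")
  }
  o <- order(series$time_min)
  r <- (series$A620 / series$A520)[o]
  rv <- (vehicle$A620 / vehicle$A520)[o]
  data.frame(time_min = series$time_min[o],
             surface_loss = r / r[1] - rv / rv[1])
}

#' Surface downregulation as percent of vehicle
#'
#' Residual surface fluorescence after treatment, normalized to the vehicle
#' control: `100 * agonist / vehicle`.
#'
#' @param fluor_agonist Surface fluorescence after agonist.
#' @param fluor_vehicle Vehicle surface fluorescence (> 0).
#' @return Percent of vehicle.
#' @export
surface_downregulation_percent <- function(fluor_agonist, fluor_vehicle) {
  check_positive(fluor_vehicle, "vehicle fluorescence")
  100 * fluor_agonist / fluor_vehicle
}

#' Linear fluorescence-vs-pH calibration for one ligand
#'
#' Ordinary least-squares line through (pH, intensity) calibration points for
#' a fluorescein-conjugated ligand. Calibration is ligand-specific: the
#' conjugate's pH sensitivity depends on its environment, so lines must not
#' be mixed between ligands.
#'
#' @param ph Calibration pH values (>= 3 distinct).
#' @param intensity Measured fluorescence intensities.
#' @param ligand Optional ligand id carried into the result.
#' @return Object of class `ph_calibration`: `slope` (AU/pH), `intercept`
#'   (AU), `r_squared`, `range` (pH range covered), `usable` flag (FALSE when
#'   the slope is indistinguishable from 0).
#' @export
fit_ph_calibration <- function(ph, intensity, ligand = NA_character_) {
  if (length(unique(ph)) < 3) stop_input("need >= 3 distinct calibration pH values")
  fit <- stats::lm(intensity ~ ph)
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- cf[["ph"]]
  usable <- is.finite(slope) && abs(slope) > 0 &&
    (stats::var(intensity) > 0)
  structure(list(ligand = ligand, slope = slope, intercept = cf[[1]],
                 r_squared = r2, range = range(ph), usable = usable,
                 fit = fit),
            class = "ph_calibration")
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf(
    "pH calibration%s: intensity = %.4g %+.4g * pH (R^2 %.3f, pH %.1f-%.1f)%s\n",
    if (!is.na(x$ligand)) paste0(" [", x$ligand, "]") else "",
    x$intercept, x$slope, x$r_squared, x$range[1], x$range[2],
    if (!x$usable) "  [UNUSABLE: flat]" else ""))
  invisible(x)
}

#' @export
predict.ph_calibration <- function(object, ph, ...) {
  object$intercept + object$slope * ph
}

#' Estimate endosomal pH from the bafilomycin ratio method
#'
#' Bafilomycin collapses the endosomal proton gradient, so the bafilomycin
#' condition is anchored at pH 7.4. The expected intensity at the unknown pH
#' is `F_control / F_bafilomycin * calibration(7.4)` — using the relative
#' signal change cancels ligand loading — and the calibration line is
#' inverted to yield pH. Estimates outside the calibration range carry an
#' `extrapolated` flag.
#'
#' @param f_control Intensity without bafilomycin.
#' @param f_bafilomycin Intensity with bafilomycin (> 0).
#' @param calib A usable [fit_ph_calibration()].
#' @param neutral_ph pH assumed under bafilomycin (default 7.4).
#' @return List: `ph`, `extrapolated`.
#' @export
estimate_endosomal_ph <- function(f_control, f_bafilomycin, calib,
                                  neutral_ph = 7.4) {
  stopifnot(inherits(calib, "ph_calibration"))
  if (!calib$usable) stop_input("calibration slope is zero; cannot estimate pH")
  check_positive(f_bafilomycin, "F_bafilomycin")
  target <- f_control / f_bafilomycin * predict(calib, neutral_ph)
  ph <- (target - calib$intercept) / calib$slope
  list(ph = ph,
       extrapolated = ph < calib$range[1] | ph > calib$range[2])
}
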