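# Small ground-truth panels and independent oracles shared across tests.

# Three-agonist, one-pathway panel with transducer slope 1.5: with n != 1 the
# operational model is fully identified (no Em/tau ridge), so absolute
# log10(tau/KA) recovery can be asserted.
identified_truth <- function() {
  ground_truth_panel(reference = "ref", agonists = list(
    ref = agonist_record(log_tka = c(cAMP = 9.0), n = 1.5, k_on = 5e7,
                         k_off = 0.05, k_e = 0.03, k_r = 0.01, k_d = 0.004),
    a2 = agonist_record(log_tka = c(cAMP = 8.2), n = 1.5, k_on = 5e7,
                        k_off = 0.05, k_e = 0.03, k_r = 0.01, k_d = 0.004),
    a3 = agonist_record(log_tka = c(cAMP = 7.6), n = 1.5, k_on = 5e7,
                        k_off = 0.05, k_e = 0.03, k_r = 0.01, k_d = 0.004)))
}

# Two identical agonists in two pathways: a null panel for calibration tests.
null_truth <- function() {
  ground_truth_panel(reference = "ref", agonists = list(
    ref = agonist_record(log_tka = c(cAMP = 9.0, barr2 = 7.5), k_on = 5e7,
                         k_off = 0.05, k_e = 0.03, k_r = 0.01, k_d = 0.004),
    tst = agonist_record(log_tka = c(cAMP = 9.0, barr2 = 7.5), k_on = 5e7,
                         k_off = 0.05, k_e = 0.03, k_r = 0.01, k_d = 0.004)))
}

# Independent numerical oracle for competitive binding: integrate the
# two-ligand mass-action ODE system (tracer RL, competitor RI, free receptor
# by balance) with a strict-tolerance solver.
mm_ode_oracle <- function(times, L, I, k1, k2, k3, k4, Bmax) {
  deriv <- function(t, y, p) {
    free <- Bmax - y[1] - y[2]
    list(c(k1 * L * free - k2 * y[1],
           k3 * I * free - k4 * y[2]))
  }
  out <- deSolve::lsoda(c(RL = 0, RI = 0), times, deriv, parms = NULL,
                        rtol = 1e-11, atol = 1e-11 * Bmax)
  as.numeric(out[, "RL"])
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected)) /
              max(abs(expected), .Machine$double.eps), rel_tol)
}
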