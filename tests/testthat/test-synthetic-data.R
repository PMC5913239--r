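test_that("noiseless dose-response generation reproduces the operational mean", {
  truth <- identified_truth()
  des <- assay_design(n_experiments = 1, n_replicates = 2)
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0), seed = 1)
  a <- truth$agonists$a2$operational
  sub <- dr[dr$agonist == "a2", ]
  expect_equal(sub$response,
               operational_response(sub$concentration_M, a$Em, a$basal, a$n,
                                    a$log10_KA, a$log10_tau_over_KA))
  expect_true(all(dr$is_reference == (dr$agonist == "ref")))
})

test_that("generators are deterministic under a fixed seed", {
  truth <- demo_truth()
  des <- assay_design(n_experiments = 2)
  expect_identical(generate_dose_response_panel(truth, des, seed = 42),
                   generate_dose_response_panel(truth, des, seed = 42))
  expect_identical(generate_kinetic_traces(truth, des, seed = 42),
                   generate_kinetic_traces(truth, des, seed = 42))
  expect_identical(generate_trafficking_measurements(truth, des, seed = 42),
                   generate_trafficking_measurements(truth, des, seed = 42))
  expect_identical(generate_ph_dataset(truth, seed = 42),
                   generate_ph_dataset(truth, seed = 42))
  expect_identical(generate_secretion_timecourse(truth, des, seed = 42),
                   generate_secretion_timecourse(truth, des, seed = 42))
  # different seeds differ
  expect_false(identical(
    generate_dose_response_panel(truth, des, seed = 42),
    generate_dose_response_panel(truth, des, seed = 43)))
})

test_that("replicate scatter matches the planted coefficient of variation", {
  truth <- identified_truth()
  des <- assay_design(n_experiments = 1, n_replicates = 5)
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0.1),
                                     seed = 11)
  # mid-curve points for the reference agonist, pooled over many seeds
  cvs <- unlist(lapply(1:40, function(s) {
    d <- generate_dose_response_panel(truth, des, noise_model(cv = 0.1),
                                      seed = s)
    d <- d[d$agonist == "ref", ]
    m <- tapply(d$response, d$concentration_M, mean)
    s_ <- tapply(d$response, d$concentration_M, sd)
    mid <- m > 0.25 * max(m) & m < 0.9 * max(m)
    (s_ / m)[mid]
  }))
  expect_gt(median(cvs), 0.05)
  expect_lt(median(cvs), 0.2)
})

test_that("empty agonist list and bad designs are rejected", {
  expect_error(ground_truth_panel(list(), "x"), "empty")
  expect_error(assay_design(concentrations = c(1e-9, 1e-8, 1e-7)), ">= 4")
  expect_error(assay_design(competitor_concs = c(1e-9, 1e-8)), ">= 4")
  des <- assay_design()
  des$tracer_conc <- -1
  expect_error(generate_kinetic_traces(demo_truth(), des), "non-negative")
})

test_that("competitor-free kinetic trace equals the one-phase association form", {
  truth <- null_truth()
  des <- assay_design(n_experiments = 1)
  tr <- list(k1 = 5e7, k2 = 0.05, Bmax = 1000)
  kin <- generate_kinetic_traces(truth, des, noise_model(sd = 0), seed = 1,
                                 tracer = tr, ns_level = 0,
                                 agonists = "ref")
  free <- kin[kin$competitor_M == 0, ]
  kobs <- tr$k1 * des$tracer_conc + tr$k2
  expected <- tr$Bmax * tr$k1 * des$tracer_conc / kobs *
    (1 - exp(-kobs * free$time_min))
  expect_equal(free$signal, expected, tolerance = 1e-12)
  # excess competitor: specific binding ~ 0 at all t
  ns <- kin[kin$condition == "nonspecific", ]
  expect_lt(max(ns$signal) / tr$Bmax, 0.01)
})

test_that("compartment trajectories conserve mass and obey closed-form limits", {
  tt <- seq(0, 120, by = 1)
  for (k in list(c(0.03, 0.01, 0.004), c(0.05, 0, 0), c(0, 0.02, 0.01),
                 c(0.04, 0, 0.04), c(0.02, 0.03, 0))) {
    traj <- compartment_trajectory(tt, k[1], k[2], k[3])
    expect_lt(max(abs(traj$S + traj$I + traj$D - 1)), 1e-9)
  }
  # k_r = k_d = 0: internalized fraction 1 - exp(-k_e t)
  traj <- compartment_trajectory(tt, 0.05, 0, 0)
  expect_equal(traj$I, 1 - exp(-0.05 * tt), tolerance = 1e-10)
  # k_e = 0: nothing internalizes
  traj0 <- compartment_trajectory(tt, 0, 0.02, 0.01)
  expect_equal(traj0$I, rep(0, length(tt)))
  # against an independent ODE integration, general rates
  deriv <- function(t, y, p) list(c(-p[1] * y[1] + p[2] * y[2],
                                    p[1] * y[1] - (p[2] + p[3]) * y[2]))
  ode <- deSolve::lsoda(c(S = 1, I = 0), tt, deriv, c(0.03, 0.01, 0.004),
                        rtol = 1e-11, atol = 1e-12)
  traj <- compartment_trajectory(tt, 0.03, 0.01, 0.004)
  expect_equal(traj$S, as.numeric(ode[, "S"]), tolerance = 1e-7)
  expect_equal(traj$I, as.numeric(ode[, "I"]), tolerance = 1e-7)
})

test_that("trafficking generator encodes the stated stripping efficiency", {
  truth <- demo_truth()
  trf <- generate_trafficking_measurements(truth, assay_design(),
                                           noise_model(cv = 0), seed = 1,
                                           strip_residual = 0.1)
  f0 <- trf$facs[trf$facs$time_min == 0, ]
  expect_equal(f0$F_plusMe / f0$F_minusMe, rep(0.1, nrow(f0)),
               tolerance = 1e-12)
})

test_that("pH generator anchors: planted 7.4 makes control equal bafilomycin", {
  truth <- ground_truth_panel(reference = "x", agonists = list(
    x = agonist_record(log_tka = c(cAMP = 9), k_on = 5e7, k_off = 0.05,
                       k_e = 0.03, k_r = 0.01, k_d = 0.004,
                       endosomal_ph = 7.4)))
  ph <- generate_ph_dataset(truth, noise_model(cv = 0), seed = 1)
  expect_equal(ph$cells$F_control, ph$cells$F_bafilomycin, tolerance = 1e-12)
  expect_error(
    generate_ph_dataset(truth, noise_model(cv = 0), seed = 1,
                        ph_grid = rep(7, 5)), "zero width")
})

test_that("zero secretion coupling gives ISI exactly 1; faster endocytosis lowers secretion", {
  base <- list(log_tka = c(cAMP = 9), k_on = 5e7, k_off = 0.05,
               k_e = 0.02, k_r = 0.005, k_d = 0.002)
  t0 <- ground_truth_panel(reference = "a", agonists = list(
    a = do.call(agonist_record, c(base, coupling = 0)),
    b = do.call(agonist_record, c(modifyList(base, list(k_e = 0.04)),
                                  coupling = 0))))
  s <- generate_secretion_timecourse(t0, assay_design(), noise_model(cv = 0),
                                     seed = 1)
  isi <- insulin_stimulation_index(percent_release(s$secreted, s$content),
                                   s$condition, s$is_control)
  expect_equal(as.numeric(isi), rep(1, 3))
  # doubled k_e, same otherwise -> lower cumulative secretion at 16 h
  t1 <- ground_truth_panel(reference = "a", agonists = list(
    a = do.call(agonist_record, c(base, coupling = 1)),
    b = do.call(agonist_record, c(modifyList(base, list(k_e = 0.04)),
                                  coupling = 1))))
  s1 <- generate_secretion_timecourse(t1, assay_design(), noise_model(cv = 0),
                                      seed = 1)
  expect_lt(mean(s1$secreted[s1$condition == "b"]),
            mean(s1$secreted[s1$condition == "a"]))
})
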