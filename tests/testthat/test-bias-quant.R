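test_that("noiseless operational fit recovers planted log(tau/KA) on an identified panel", {
  truth <- identified_truth()
  des <- assay_design(n_experiments = 1, n_replicates = 1,
                      concentrations = 10^seq(-11.5, -6, length.out = 10))
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0), seed = 1)
  f <- fit_operational_model(dr, "ref")
  planted <- c(a2 = 8.2, a3 = 7.6, ref = 9.0)
  expect_lt(max(abs(f$agonists$log10_tau_over_KA -
                      planted[f$agonists$agonist])), 1e-4)
  expect_true(all(f$agonists$quantifiable))
})

test_that("an agonist below the noise floor is unquantifiable, never imputed", {
  truth <- ground_truth_panel(reference = "ref", agonists = list(
    ref = agonist_record(log_tka = c(barr1 = 7.5), k_on = 5e7, k_off = 0.05,
                         k_e = 0.03, k_r = 0.01, k_d = 0.004),
    dead = agonist_record(log_tka = c(barr1 = -2), k_on = 5e7, k_off = 0.05,
                          k_e = 0.03, k_r = 0.01, k_d = 0.004)))
  des <- assay_design(n_experiments = 1)
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0.1),
                                     seed = 3)
  f <- fit_operational_model(dr, "ref")
  dead <- f$agonists[f$agonists$agonist == "dead", ]
  expect_false(dead$quantifiable)
  expect_true(is.na(dead$log10_tau_over_KA))
  # and the flag propagates: delta is NA, web coordinate is NA (absent)
  bt <- delta_log_tka(list(f))
  expect_true(is.na(bt$delta_log_tka[bt$agonist == "dead"]))
  expect_error(fit_operational_model(dr, "nosuch"), "absent")
})

test_that("a 10-fold potency shift between full agonists gives delta = -1, matching a grid-search oracle", {
  # two full agonists identical except for a 10x EC50 shift (log(tau/KA)
  # differs by exactly -1)
  truth <- ground_truth_panel(reference = "ref", agonists = list(
    ref = agonist_record(log_tka = c(cAMP = 9.0), k_on = 5e7, k_off = 0.05,
                         k_e = 0.03, k_r = 0.01, k_d = 0.004),
    shifted = agonist_record(log_tka = c(cAMP = 8.0), k_on = 5e7,
                             k_off = 0.05, k_e = 0.03, k_r = 0.01,
                             k_d = 0.004)))
  des <- assay_design(n_experiments = 1, n_replicates = 1)
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0), seed = 1)
  f <- fit_operational_model(dr, "ref")
  a <- f$agonists
  delta <- a$log10_tau_over_KA[a$agonist == "shifted"] -
    a$log10_tau_over_KA[a$agonist == "ref"]
  expect_equal(delta, -1, tolerance = 1e-3)

  # exhaustive grid-search refit (Em, basal, n fixed at truth; per-agonist
  # logKA and logR on grids) as an independent oracle for the same delta
  agg <- aggregate(response ~ agonist + concentration_M, dr, mean)
  grid_fit <- function(sub) {
    lka <- seq(-8.5, -6, by = 0.05)
    lr <- seq(7, 10, by = 0.005)
    g <- expand.grid(lka = lka, lr = lr)
    sse <- vapply(seq_len(nrow(g)), function(i) {
      pred <- operational_response(sub$concentration_M, 100, 0, 1,
                                   g$lka[i], g$lr[i])
      sum((sub$response - pred)^2)
    }, numeric(1))
    g$lr[which.min(sse)]
  }
  lr_ref <- grid_fit(agg[agg$agonist == "ref", ])
  lr_sh <- grid_fit(agg[agg$agonist == "shifted", ])
  expect_equal(lr_sh - lr_ref, -1, tolerance = 0.011)
  expect_equal(delta, lr_sh - lr_ref, tolerance = 0.011)
})

test_that("delta log(tau/KA) is zero for the reference and shift-invariant", {
  truth <- identified_truth()
  des <- assay_design(n_experiments = 3)
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0.05),
                                     seed = 9)
  fits <- fit_operational_panel(dr, "ref", compute_se = FALSE)
  bt <- delta_log_tka(fits)
  refrows <- bt[bt$agonist == "ref", ]
  expect_equal(refrows$delta_log_tka, rep(0, nrow(refrows)))
  s <- summary(bt)
  expect_equal(s$sem[s$agonist == "ref"], 0)
  # direct subtraction: 8.5 vs 8.0 -> +0.5
  f1 <- fits[[1]]
  f1$agonists$log10_tau_over_KA <- c(8.5, 8.3, 8.0)[
    match(f1$agonists$agonist, c("a2", "a3", "ref"))]
  b1 <- delta_log_tka(list(f1))
  expect_equal(b1$delta_log_tka[b1$agonist == "a2"], 0.5)
  # adding a constant within an experiment changes no delta
  f2 <- f1
  f2$agonists$log10_tau_over_KA <- f1$agonists$log10_tau_over_KA + 0.73
  expect_equal(delta_log_tka(list(f2))$delta_log_tka, b1$delta_log_tka)
})

test_that("ddelta propagation matches the hand-computed example and is antisymmetric", {
  # per-experiment deltas engineered to mean 0.5 (SEM 0.10) and -0.3 (SEM 0.10)
  dA <- 0.5 + 0.1 * sqrt(5) * scale(c(-2, -1, 0, 1, 2))[, 1]
  dB <- -0.3 + 0.1 * sqrt(5) * scale(c(2, 1, 0, -1, -2))[, 1]
  bt <- data.frame(
    agonist = rep("x", 10),
    pathway = rep(c("A", "B"), each = 5),
    experiment = rep(1:5, 2),
    delta_log_tka = c(dA, dB),
    quantifiable = TRUE)
  class(bt) <- c("bias_table", "data.frame")
  s <- summary(bt)
  expect_equal(s$mean_delta, c(0.5, -0.3))
  expect_equal(s$sem, c(0.1, 0.1))
  dd <- ddelta_log_tka(bt, "A", "B", ci = "z")
  expect_equal(dd$ddelta_log_tka, 0.8)
  expect_equal(dd$se, sqrt(0.02), tolerance = 1e-12)
  expect_equal(dd$ci_lo, 0.8 - qnorm(0.975) * sqrt(0.02))
  expect_equal(dd$ci_hi, 0.8 + qnorm(0.975) * sqrt(0.02))
  expect_equal(round(c(dd$ci_lo, dd$ci_hi), 3), c(0.523, 1.077))
  expect_true(dd$significant)
  expect_equal(dd$bias_factor, 10^0.8)
  # antisymmetry: swapping pathways negates the contrast and mirrors the CI
  rev <- ddelta_log_tka(bt, "B", "A", ci = "z")
  expect_equal(rev$ddelta_log_tka, -dd$ddelta_log_tka)
  expect_equal(rev$ci_lo, -dd$ci_hi)
  expect_equal(rev$ci_hi, -dd$ci_lo)
})

test_that("web-of-bias coordinates anchor at 1 and are response-unit invariant", {
  truth <- null_truth()
  des <- assay_design(n_experiments = 2)
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0.05),
                                     seed = 17)
  fits <- fit_operational_panel(dr, "ref", compute_se = FALSE)
  bt <- delta_log_tka(fits)
  web <- web_of_bias(bt, "cAMP")
  expect_equal(web$coordinate[web$agonist == "ref"], c(1, 1))
  expect_equal(web$coordinate[web$pathway == "cAMP"], c(1, 1))
  # a delta of +1 relative to the reference pathway maps to 10
  bt2 <- data.frame(agonist = rep(c("r", "t"), each = 2),
                    pathway = rep(c("P", "Q"), 2),
                    experiment = 1,
                    delta_log_tka = c(0, 0, 0, 1),
                    quantifiable = TRUE)
  class(bt2) <- c("bias_table", "data.frame")
  w2 <- web_of_bias(bt2, "P")
  expect_equal(w2$coordinate[w2$agonist == "t" & w2$pathway == "Q"], 10)
  # invariance to response units: rescale all responses 7.3x
  dr2 <- dr
  dr2$response <- dr2$response * 7.3
  bt_s <- delta_log_tka(fit_operational_panel(dr2, "ref", compute_se = FALSE))
  expect_equal(web_of_bias(bt_s, "cAMP")$coordinate, web$coordinate,
               tolerance = 1e-4)
})

test_that("for full agonists with n = 1, delta log(tau/KA) equals delta pEC50", {
  truth <- ground_truth_panel(reference = "ref", agonists = list(
    ref = agonist_record(log_tka = c(cAMP = 9.2), k_on = 5e7, k_off = 0.05,
                         k_e = 0.03, k_r = 0.01, k_d = 0.004),
    t1 = agonist_record(log_tka = c(cAMP = 8.6), k_on = 5e7, k_off = 0.05,
                        k_e = 0.03, k_r = 0.01, k_d = 0.004)))
  des <- assay_design(n_experiments = 1, n_replicates = 1)
  dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0), seed = 1)
  f <- fit_operational_model(dr, "ref")
  bt <- delta_log_tka(list(f))
  dd <- bt$delta_log_tka[bt$agonist == "t1"]
  p1 <- fit_4pl(dr[dr$agonist == "ref", c("concentration_M", "response")])
  p2 <- fit_4pl(dr[dr$agonist == "t1", c("concentration_M", "response")])
  dpec50 <- coef(p1)[["log10_EC50"]] - coef(p2)[["log10_EC50"]]
  expect_lt(abs(dd - dpec50), 0.05)
})

test_that("ddelta estimates cover their planted truth at the nominal rate", {
  # biased two-pathway panel at experimental scale: n = 5 experiments,
  # 10% response noise; planted ddelta(cAMP - barr2) = -0.5
  truth <- ground_truth_panel(reference = "ref", agonists = list(
    ref = agonist_record(log_tka = c(cAMP = 9.0, barr2 = 7.5), k_on = 5e7,
                         k_off = 0.05, k_e = 0.03, k_r = 0.01, k_d = 0.004),
    tst = agonist_record(log_tka = c(cAMP = 8.7, barr2 = 7.7), k_on = 5e7,
                         k_off = 0.05, k_e = 0.03, k_r = 0.01, k_d = 0.004)))
  des <- assay_design(n_experiments = 5)
  truth_dd <- (8.7 - 9.0) - (7.7 - 7.5)
  covered <- vapply(1:50, function(s) {
    dr <- generate_dose_response_panel(truth, des, noise_model(cv = 0.1),
                                       seed = 1000 + s)
    bt <- delta_log_tka(fit_operational_panel(dr, "ref", compute_se = FALSE))
    dd <- ddelta_log_tka(bt, "cAMP", "barr2", ci = "t")
    dd <- dd[dd$agonist == "tst", ]
    dd$ci_lo <= truth_dd && truth_dd <= dd$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
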