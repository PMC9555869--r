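test_that("mean residue ellipticity follows the conversion formula", {
  expect_equal(mean_residue_ellipticity(0, 110, 0.1, 0.2), 0)
  expect_equal(mean_residue_ellipticity(-20, 110, 0.1, 0.2), -11000)
  # linearity: doubling the concentration halves the result
  expect_equal(mean_residue_ellipticity(-20, 110, 0.1, 0.4), -5500)
  expect_error(mean_residue_ellipticity(1, 110, 0, 0.2), "positive")
})

test_that("fraction denatured is the two-state lever rule", {
  expect_equal(fraction_denatured(-11000, -11000, -3000), 0)
  expect_equal(fraction_denatured(-3000, -11000, -3000), 1)
  expect_equal(fraction_denatured(-7000, -11000, -3000), 0.5)
  expect_error(fraction_denatured(1, 5, 5), "differ")
})

test_that("two-state melt fit recovers the generator on noiseless data", {
  mc <- make_melting_curve(Tm = 320, dHm = 100,
                           baselines = list(yN = c(-11000, -5),
                                            yD = c(-3000, -2)))
  fit <- fit_two_state_melt(mc)
  expect_lt(abs(fit$Tm_K - 320), 0.2)
  expect_lt(abs(fit$dHm - 100) / 100, 0.03)

  # symmetric sigmoid with flat baselines: Tm at the signal midpoint
  flat <- make_melting_curve(Tm = 315, dHm = 80,
                             baselines = list(yN = c(-11000, 0),
                                              yD = c(-3000, 0)))
  fit2 <- fit_two_state_melt(flat)
  mid_T <- flat$T_C[which.min(abs(flat$theta_mdeg - (-7000)))]
  expect_lt(abs(fit2$Tm_C - mid_T), 0.5)

  # a transition-free curve cannot be fit
  no_trans <- data.frame(T_C = seq(20, 70, 0.5),
                         theta_mdeg = -11000 + 5 * seq(20, 70, 0.5))
  expect_error(fit_two_state_melt(no_trans))
})

test_that("melt fit degrades gracefully with noise", {
  errs <- vapply(1:20, function(s) {
    mc <- make_melting_curve(Tm = 320, dHm = 100,
                             baselines = list(yN = c(-11000, -5),
                                              yD = c(-3000, -2)),
                             noise_sd = 0.02 * 8000, seed = 1000 + s)
    fit <- tryCatch(fit_two_state_melt(mc), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$Tm_K - 320)
  }, numeric(1))
  expect_lt(stats::median(errs, na.rm = TRUE), 0.5)
})

test_that("saturation binding fit recovers Kd", {
  sat <- make_saturation_curve(Kd = 180)
  fit <- fit_saturation_binding(sat)
  expect_lt(abs(fit$Kd - 180) / 180, 0.001)
  # model identity: signal at the fitted Kd is the fitted midpoint
  mid <- fit$mP_free + (fit$mP_bound - fit$mP_free) / 2
  pred <- fit$mP_free + (fit$mP_bound - fit$mP_free) * fit$Kd /
    (fit$Kd + fit$Kd)
  expect_equal(pred, mid, tolerance = 1e-9)
  expect_error(fit_saturation_binding(sat[1:3, ]), "at least 5")
})

test_that("competition fit recovers Ki via Cheng-Prusoff", {
  comp <- make_competition_curve(Ki = 33, probe_conc = 10, probe_kd = 180)
  fit <- fit_competition_ki(comp, probe_conc = 10, probe_kd = 180)
  expect_lt(abs(fit$Ki - 33) / 33, 0.01)
  expect_equal(fit$IC50, cheng_prusoff_ic50(33, 10, 180), tolerance = 1e-3)
  # IC50 = 35, probe 10 nM, probe Kd 180 nM -> Ki = 35 * 18/19 = 33.16
  expect_equal(cheng_prusoff_ki(35, 10, 180), 33.15789, tolerance = 1e-5)

  rising <- comp
  rising$mP <- rev(rising$mP)
  expect_error(fit_competition_ki(rising, 10, 180), "not decreasing")
})

test_that("dose-response fit recovers Hill parameters and flags flat curves", {
  dr <- make_dose_response(EC50 = 1, Emax = 11, bottom = 1, hill_n = 1)
  fit <- fit_dose_response(dr)
  expect_lt(abs(fit$EC50 - 1), 0.001)
  expect_lt(abs(fit$Emax - 11) / 11, 0.001)
  expect_lt(abs(fit$bottom - 1), 0.01)
  expect_lt(abs(fit$hill_n - 1), 0.01)
  # response at the fitted EC50 equals the midpoint of bottom and Emax
  mid <- fit$bottom + (fit$Emax - fit$bottom) / 2
  pred <- fit$bottom + (fit$Emax - fit$bottom) /
    (1 + (fit$EC50 / fit$EC50)^fit$hill_n)
  expect_equal(pred, mid, tolerance = 1e-9)

  flat <- make_dose_response(EC50 = 1, Emax = 11, noise_sd = 0.05, seed = 2)
  flat$fold_activation <- 1 + rnorm(nrow(flat), sd = 0.05)
  res <- fit_dose_response(flat)
  expect_false(res$activated)
  expect_true(is.na(res$EC50))
})

test_that("binding and dose fits stay accurate under 5% noise", {
  rel_err <- function(est, truth) abs(est - truth) / truth
  kd_errs <- ki_errs <- ec_errs <- numeric(30)
  for (s in 1:30) {
    sat <- make_saturation_curve(Kd = 180, noise_sd = 0.05 * 150,
                                 seed = 2000 + s)
    kd_errs[s] <- rel_err(fit_saturation_binding(sat)$Kd, 180)
    comp <- make_competition_curve(Ki = 33, noise_sd = 0.05 * 150,
                                   seed = 3000 + s)
    ki_errs[s] <- rel_err(fit_competition_ki(comp, 10, 180)$Ki, 33)
    dr <- make_dose_response(EC50 = 1, Emax = 11, noise_sd = 0.05 * 10,
                             seed = 4000 + s)
    ec_errs[s] <- rel_err(fit_dose_response(dr)$EC50, 1)
  }
  expect_lt(stats::median(kd_errs), 0.10)
  expect_lt(stats::median(ki_errs), 0.10)
  expect_lt(stats::median(ec_errs), 0.10)
})

test_that("HDX differences apply the 0.5 Da threshold and antisymmetry", {
  pep <- data.frame(peptide = c("p1", "p2", "p3"),
                    start = c(1, 11, 21), end = c(10, 20, 30),
                    length = c(10, 10, 10), n_prolines = c(0, 1, 0))
  hd <- make_hdx_table(pep, uptake_a = c(4.5, 3.6, 2.0),
                       uptake_b = c(4.5, 3.0, 1.6))
  d <- delta_rfu(hd)
  # length 10, no prolines: 9 exchangeable amides; uptake 4.5 Da -> RFU 0.5
  expect_equal(d$rfu_a[d$peptide == "p1"], 0.5)
  expect_equal(d$n_exchangeable[d$peptide == "p1"], 9)
  # +0.6 Da shift is significant, +0.4 Da is not
  expect_true(d$significant[d$peptide == "p2"])
  expect_false(d$significant[d$peptide == "p3"])
  expect_equal(d$delta_centroid_Da, c(0, 0.6, 0.4), tolerance = 1e-12)

  # swapping states negates both differences
  rev <- delta_rfu(hd, state_a = "B", state_b = "A")
  expect_equal(rev$delta_rfu, -d$delta_rfu)
  expect_equal(rev$delta_centroid_Da, -d$delta_centroid_Da)
})
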