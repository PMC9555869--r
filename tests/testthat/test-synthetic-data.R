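test_that("helix topology has 5 atoms per residue and uniform CA spacing", {
  h <- make_helix_topology(3)
  expect_equal(n_atoms(h), 15L)
  expect_equal(length(unique(h$topology$residue_index)), 3L)
  expect_error(make_helix_topology(2), "at least 3")

  h10 <- make_helix_topology(10)
  ca <- which(h10$topology$atom_name == "CA")
  co <- frame_coords(h10, 1)[ca, ]
  steps <- sqrt(rowSums(diff(co)^2))
  expect_lt(max(steps) - min(steps), 1e-9)

  # end-to-end CA distance from the parametric formula: chord + rise
  chord <- 2 * 2.3 * abs(sin(9 * (100 * pi / 180) / 2))
  expected <- sqrt(chord^2 + (9 * 1.5)^2)
  expect_equal(sqrt(sum((co[10, ] - co[1, ])^2)), expected, tolerance = 1e-9)
  expect_lt(expected, 9 * 3.8)
})

test_that("substate sampling is reproducible and respects weights", {
  h <- make_helix_topology(5)
  a <- n_atoms(h)
  zero <- matrix(0, a, 3)
  shift <- matrix(1, a, 3)

  # single substate, zero noise: frames identical to reference + field
  e <- sample_substate_ensemble(h, list(substate_spec("s", shift, 1)),
                                n_frames = 4, noise_sigma = 0, seed = 1)
  ref <- frame_coords(h, 1)
  for (f in 1:4) expect_equal(frame_coords(e, f), ref + shift)

  # identical seeds give bitwise-identical coordinates
  e1 <- sample_substate_ensemble(h, list(substate_spec("s", zero, 0.5),
                                         substate_spec("t", shift, 0.5)),
                                 1000, 0.3, seed = 42)
  e2 <- sample_substate_ensemble(h, list(substate_spec("s", zero, 0.5),
                                         substate_spec("t", shift, 0.5)),
                                 1000, 0.3, seed = 42)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$labels$substate, e2$labels$substate)

  # two equal-weight substates, n = 10000: counts within binomial 3 sigma
  e3 <- sample_substate_ensemble(h, list(substate_spec("s", zero, 0.5),
                                         substate_spec("t", shift, 0.5)),
                                 10000, 0, seed = 7)
  n_s <- sum(e3$labels$substate == "s")
  expect_lt(abs(n_s - 5000), 150)

  # weight validation
  expect_error(
    sample_substate_ensemble(h, list(substate_spec("s", zero, 0.7)), 10, 0.1),
    "sum to 1")
})

test_that("apo/liganded pair design controls substate sharing and labels", {
  d1 <- ensemble_pair_design(1, n_frames_apo = 200, n_frames_liganded = 150,
                             seed = 3)
  p1 <- make_apo_liganded_pair(d1)
  expect_equal(sum(p1$apo$labels$group == "APO"), 200L)
  expect_equal(sum(p1$liganded$labels$group == "LIGANDED"), 150L)
  # w = 1: every apo substate is also populated by liganded frames
  expect_true(all(unique(p1$apo$labels$substate) %in%
                    unique(p1$liganded$labels$substate)))

  d0 <- ensemble_pair_design(0, n_frames_apo = 200, n_frames_liganded = 200,
                             seed = 3)
  p0 <- make_apo_liganded_pair(d0)
  expect_length(intersect(unique(p0$apo$labels$substate),
                          unique(p0$liganded$labels$substate)), 0)
})

test_that("melting curve generator follows the two-state forward model", {
  flat <- list(yN = c(-11000, 0), yD = c(-3000, 0))
  tm_k <- 320
  mc <- make_melting_curve(Tm = tm_k, dHm = 100, baselines = flat,
                           T_grid = seq(20, 70, by = 0.1))
  # at T = Tm the signal is the exact baseline midpoint (fD = 0.5)
  i <- which.min(abs(mc$T_C - (tm_k - 273.15)))
  expect_equal(mc$theta_mdeg[i], -7000, tolerance = 1)
  # far below Tm the signal sits on the native baseline
  expect_equal(mc$theta_mdeg[1], -11000, tolerance = 1e-6)
  expect_error(make_melting_curve(Tm = 320, dHm = -5), "positive")
  expect_error(make_melting_curve(Tm = 400, dHm = 100), "inside")
})

test_that("binding curve generators hit their analytic midpoints", {
  sat <- make_saturation_curve(Kd = 180, conc_nM = c(1, 180, 1e6))
  expect_equal(sat$mP[2], (50 + 200) / 2)     # x = Kd -> midpoint
  expect_equal(sat$mP[3], 200, tolerance = 0.1)  # x >> Kd -> mP_bound
  expect_error(make_saturation_curve(Kd = -1), "positive")

  # Cheng-Prusoff: Ki 33 nM, probe 10 nM, probe Kd 180 nM -> IC50 34.83 nM
  ic50 <- cheng_prusoff_ic50(33, 10, 180)
  expect_equal(ic50, 34.83, tolerance = 1e-3)
  comp <- make_competition_curve(Ki = 33, conc_nM = c(ic50))
  expect_equal(comp$mP, (200 + 50) / 2)
  expect_equal(cheng_prusoff_ki(ic50, 10, 180), 33)
})

test_that("dose-response generator matches the Hill equation", {
  dr <- make_dose_response(EC50 = 1, Emax = 11, bottom = 1, hill_n = 1,
                           dose_nM = c(1e-6, 1))
  expect_equal(dr$fold_activation[1], 1, tolerance = 1e-5)  # d -> 0: bottom
  expect_equal(dr$fold_activation[2], 6.0)                  # d = EC50
  expect_error(make_dose_response(EC50 = 0, Emax = 5), "positive")
})

test_that("HDX table generator validates uptake against exchangeable amides", {
  pep <- data.frame(peptide = "p1", start = 1, end = 9, length = 9,
                    n_prolines = 0)
  expect_error(make_hdx_table(pep, uptake_a = 9, uptake_b = 1),
               "exceeds exchangeable")
  hd <- make_hdx_table(pep, uptake_a = 4.5, uptake_b = 4.5)
  expect_equal(nrow(hd), 2L)
  expect_equal(delta_rfu(hd)$delta_rfu, 0)
})
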