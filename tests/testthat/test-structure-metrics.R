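two_residue_ensemble <- function(res1_atoms, res2_atoms,
                                 elements1 = NULL, elements2 = NULL) {
  n1 <- nrow(res1_atoms)
  n2 <- nrow(res2_atoms)
  if (is.null(elements1)) elements1 <- rep("C", n1)
  if (is.null(elements2)) elements2 <- rep("C", n2)
  top <- data.frame(
    serial = seq_len(n1 + n2),
    atom_name = c(paste0("A", seq_len(n1)), paste0("B", seq_len(n2))),
    element = c(elements1, elements2),
    residue_index = rep(1:2, c(n1, n2)),
    residue_name = "XXX", chain_id = "A", stringsAsFactors = FALSE)
  ensemble(top, rbind(res1_atoms, res2_atoms))
}

test_that("minimum heavy-atom distance excludes hydrogens", {
  e <- two_residue_ensemble(rbind(c(0, 0, 0), c(3, 0, 0)),
                            rbind(c(6, 0, 0)))
  expect_equal(min_heavy_atom_distance(e, 1, 2), 3.0)

  # an H atom closer than any heavy pair is ignored
  eh <- two_residue_ensemble(rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0)),
                             rbind(c(6, 0, 0)),
                             elements1 = c("C", "C", "H"))
  expect_equal(min_heavy_atom_distance(eh, 1, 2), 3.0)

  # all-hydrogen residue errors
  hh <- two_residue_ensemble(rbind(c(0, 0, 0)), rbind(c(1, 0, 0)),
                             elements1 = "H")
  expect_error(min_heavy_atom_distance(hh, 1, 2), "no heavy atoms")
})

test_that("minimum distance equals exhaustive pair enumeration", {
  set.seed(3)
  for (rep in 1:5) {
    a <- matrix(rnorm(24, sd = 3), 8, 3)
    b <- matrix(rnorm(24, mean = 5, sd = 3), 8, 3)
    e <- two_residue_ensemble(a, b)
    brute <- min(vapply(1:8, function(i) {
      min(sqrt(colSums((t(b) - a[i, ])^2)))
    }, numeric(1)))
    expect_equal(min_heavy_atom_distance(e, 1, 2), brute, tolerance = 1e-12)
    # symmetric in argument order
    expect_equal(min_heavy_atom_distance(e, 2, 1),
                 min_heavy_atom_distance(e, 1, 2))
  }
})

test_that("van der Waals contact uses a strict 4.5 A cutoff", {
  expect_true(is_vdw_contact(4.49))
  expect_false(is_vdw_contact(4.50))
  expect_false(is_vdw_contact(10))
  expect_error(is_vdw_contact(3, cutoff = 0), "positive")
  expect_error(is_vdw_contact(-1), "non-negative")
})

test_that("CA distance series reports per-frame values with mean and sd", {
  h <- make_helix_topology(6)
  a <- n_atoms(h)
  # two frames where CA(1)-CA(6) distances are forced to 4 and 6
  co1 <- frame_coords(h, 1)
  ca1 <- which(h$topology$residue_index == 1 & h$topology$atom_name == "CA")
  ca6 <- which(h$topology$residue_index == 6 & h$topology$atom_name == "CA")
  dir <- co1[ca6, ] - co1[ca1, ]
  dir <- dir / sqrt(sum(dir^2))
  co_a <- co1
  co_a[ca6, ] <- co1[ca1, ] + 4 * dir
  co_b <- co1
  co_b[ca6, ] <- co1[ca1, ] + 6 * dir
  arr <- array(0, dim = c(2, a, 3))
  arr[1, , ] <- co_a
  arr[2, , ] <- co_b
  e <- ensemble(h$topology, arr)
  ds <- ca_distance_series(e, 1, 6)
  expect_equal(ds$distance, c(4, 6))
  expect_equal(attr(ds, "mean"), 5.0)

  # identical frames: sd = 0
  e0 <- copies_ensemble(h$topology, co1, 3)
  expect_equal(attr(ca_distance_series(e0, 1, 6), "sd"), 0)

  # mean equals brute-force average over frames
  expect_equal(attr(ds, "mean"), mean(ds$distance))
  expect_error(ca_distance_series(e, 1, 99), "no unique CA")
})

ring_ensemble <- function(offset, tilt_deg = 0) {
  # two 6-atom rings in residue 1 and 2
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(cos(ang), sin(ang), 0)
  ring2 <- ring
  if (tilt_deg != 0) {
    t <- tilt_deg * pi / 180
    R <- matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3,
                byrow = TRUE)
    ring2 <- ring %*% t(R)
  }
  ring2 <- sweep(ring2, 2, offset, `+`)
  top <- data.frame(
    serial = 1:12,
    atom_name = rep(paste0("C", 1:6), 2),
    element = "C",
    residue_index = rep(1:2, each = 6),
    residue_name = c(rep("TRP", 6), rep("PHE", 6)),
    chain_id = "A", stringsAsFactors = FALSE)
  ensemble(top, rbind(ring, ring2))
}

test_that("pi-stacking occupancy applies distance and angle criteria", {
  ra <- ring_spec(1, paste0("C", 1:6))
  rb <- ring_spec(2, paste0("C", 1:6))
  expect_equal(pi_stacking_occupancy(ring_ensemble(c(0, 0, 3.5)), ra, rb),
               1, ignore_attr = TRUE)
  expect_equal(pi_stacking_occupancy(ring_ensemble(c(0, 0, 8)), ra, rb),
               0, ignore_attr = TRUE)
  expect_equal(
    pi_stacking_occupancy(ring_ensemble(c(0, 0, 4), tilt_deg = 90), ra, rb),
    0, ignore_attr = TRUE)
  # 20-degree tilt at 4 A still stacks under the 30-degree default
  expect_equal(
    pi_stacking_occupancy(ring_ensemble(c(0, 0, 4), tilt_deg = 20), ra, rb),
    1, ignore_attr = TRUE)
})

test_that("per-cluster RMSF matches hand arithmetic and is order-invariant", {
  h <- make_helix_topology(30)
  co <- frame_coords(h, 1)
  ca3 <- which(h$topology$residue_index == 3 & h$topology$atom_name == "CA")
  co_up <- co
  co_up[ca3, 3] <- co[ca3, 3] + 0.3
  co_dn <- co
  co_dn[ca3, 3] <- co[ca3, 3] - 0.3
  arr <- array(0, dim = c(2, n_atoms(h), 3))
  arr[1, , ] <- co_up
  arr[2, , ] <- co_dn
  e <- ensemble(h$topology, arr)
  cl <- cluster_fixed_radius(e, radius = 2.4)
  r <- rmsf_per_cluster(e, cl)
  # the displaced residue fluctuates by ~0.3; the CA superposition can
  # redistribute a sliver of motion onto the rigid residues
  expect_equal(r$rmsf[r$residue_index == 3], 0.3, tolerance = 0.05)
  expect_true(all(r$rmsf[r$residue_index != 3] < 0.05))

  # identical frames: all-zero RMSF
  e0 <- copies_ensemble(h$topology, co, 4)
  cl0 <- cluster_fixed_radius(e0, radius = 2.4)
  r0 <- rmsf_per_cluster(e0, cl0)
  expect_true(all(r0$rmsf < 1e-9))

  # frame order does not change RMSF
  e_rev <- keep_frames(e, 2:1)
  cl_rev <- cluster_fixed_radius(e_rev, radius = 2.4)
  r_rev <- rmsf_per_cluster(e_rev, cl_rev)
  expect_equal(r_rev$rmsf, r$rmsf, tolerance = 1e-9)

  # singleton clusters are skipped with a warning
  e1 <- keep_frames(e, 1)
  cl1 <- cluster_fixed_radius(e1, radius = 2.4)
  expect_warning(rmsf_per_cluster(e1, cl1), "fewer than 2")
})
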