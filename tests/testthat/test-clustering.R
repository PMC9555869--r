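test_that("superposition removes rigid-body differences", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  same <- superpose(P, P)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)

  Q <- apply_rigid(P, random_proper_rotation(), rnorm(3, sd = 5))
  fit <- superpose(P, Q)
  expect_lt(fit$rmsd, 1e-6)
  expect_lt(max(abs(fit$transform(P) - Q)), 1e-6)

  expect_error(superpose(P, Q, sel_idx = 1:2), "at least 3")
})

test_that("superposition RMSD is symmetric and matches the rotation-grid oracle", {
  set.seed(42)
  for (rep in 1:3) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    r_pq <- superpose(P, Q)$rmsd
    r_qp <- superpose(Q, P)$rmsd
    expect_lt(abs(r_pq - r_qp), 1e-9)
    expect_lt(abs(r_pq - grid_rmsd_oracle(P, Q)), 1e-3)
    expect_equal(rmsd_pair(P, Q), r_pq, tolerance = 1e-9)
  }
})

make_two_group_ensemble <- function(n1, n2, sep = 10, sigma = 0.15,
                                    seed = 5) {
  h <- make_helix_topology(8)
  a <- n_atoms(h)
  # displace alternating residues in opposite z so superposition cannot
  # remove the difference (a uniform translation would be fitted away)
  shift <- matrix(0, a, 3)
  res <- h$topology$residue_index
  shift[, 3] <- ifelse(res %% 2 == 0, sep, -sep)
  specs <- list(substate_spec("g1", matrix(0, a, 3), n1 / (n1 + n2)),
                substate_spec("g2", shift, n2 / (n1 + n2)))
  sample_substate_ensemble(h, specs, n1 + n2, sigma, seed = seed)
}

test_that("fixed-radius clustering recovers well-separated substates", {
  e <- make_two_group_ensemble(20, 20)
  cl <- cluster_fixed_radius(e, radius = 2.4)
  expect_equal(length(cl$centroids), 2L)
  # memberships match the generating substates exactly
  expect_equal(length(unique(paste(cl$cluster_id, e$labels$substate))), 2L)
  # radius invariant holds exactly
  expect_true(all(cl$rmsd_to_centroid <= cl$radius))
  # sizes sum to F
  expect_equal(sum(cl$sizes), n_frames(e))
})

test_that("clustering memberships equal thresholded RMSD graph components", {
  e <- make_two_group_ensemble(25, 20, seed = 9)
  cl <- cluster_fixed_radius(e, radius = 2.4)
  comp <- bio3d_component_clusters(e, radius = 2.4)
  # identical partitions (up to label permutation)
  expect_equal(length(unique(paste(cl$cluster_id, comp))),
               length(unique(comp)))
  expect_equal(length(unique(cl$cluster_id)), length(unique(comp)))
})

test_that("degenerate clustering cases behave as expected", {
  h <- make_helix_topology(5)
  e <- copies_ensemble(h$topology, frame_coords(h, 1), 6)
  cl <- cluster_fixed_radius(e, radius = 2.4)
  expect_equal(length(cl$centroids), 1L)
  expect_equal(cl$sizes, 6L)

  # radius larger than the max pairwise RMSD -> one cluster
  e2 <- make_two_group_ensemble(10, 10, sep = 3, sigma = 0.1)
  cl2 <- cluster_fixed_radius(e2, radius = 100)
  expect_equal(length(cl2$centroids), 1L)

  expect_error(cluster_fixed_radius(e, radius = -1), "positive")
})

test_that("clustering is deterministic for a fixed frame order", {
  e <- make_two_group_ensemble(15, 15, seed = 13)
  a <- cluster_fixed_radius(e, radius = 2.4)
  b <- cluster_fixed_radius(e, radius = 2.4)
  expect_identical(a$cluster_id, b$cluster_id)
})

test_that("combined clustering tallies provenance and conserves totals", {
  d <- ensemble_pair_design(0.5, n_frames_apo = 60, n_frames_liganded = 40,
                            seed = 21)
  pair <- make_apo_liganded_pair(d)
  cc <- combined_cluster(pair$apo, pair$liganded, radius = 2.4)
  expect_equal(sum(cc$table$count_a), 60L)
  expect_equal(sum(cc$table$count_b), 40L)
  expect_true(all(cc$table$count_a + cc$table$count_b >= 1L))

  # identical copies of one ensemble: every cluster balanced
  sym <- combined_cluster(pair$apo, pair$apo, radius = 2.4)
  expect_equal(sym$table$count_a, sym$table$count_b)

  # disjoint substates: no cluster holds both provenances
  d0 <- ensemble_pair_design(0, n_frames_apo = 50, n_frames_liganded = 50,
                             seed = 22)
  p0 <- make_apo_liganded_pair(d0)
  cc0 <- combined_cluster(p0$apo, p0$liganded, radius = 2.4)
  expect_true(all(cc0$table$count_a == 0 | cc0$table$count_b == 0))
})

test_that("representative selection ranks by centroid RMSD with index tie-break", {
  h <- make_helix_topology(5)
  e <- copies_ensemble(h$topology, frame_coords(h, 1), 5)
  cl <- cluster_fixed_radius(e, radius = 2.4)
  reps <- select_representatives(e, cl, 1L, n = 3)
  expect_equal(reps$labels$source_index, 1:3)  # ties -> lowest frame index

  all_reps <- select_representatives(e, cl, 1L, n = 5)
  expect_equal(n_frames(all_reps), 5L)
  expect_error(select_representatives(e, cl, 1L, n = 6), "exceeds")

  # a frame sitting exactly at the centroid ranks first
  e2 <- make_two_group_ensemble(12, 12, seed = 30)
  cl2 <- cluster_fixed_radius(e2, radius = 2.4)
  k <- 1L
  members <- which(cl2$cluster_id == k)
  sel <- atom_selection(e2, "CA")
  d <- vapply(members, function(f) {
    rmsd_pair(frame_coords(e2, f)[sel, ], cl2$centroids[[k]])
  }, numeric(1))
  best <- members[which.min(d)]
  top1 <- select_representatives(e2, cl2, k, n = 1)
  expect_equal(top1$labels$source_index, best)
})
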