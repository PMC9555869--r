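# Shared fixtures: tiny ensembles, rigid transforms, and the brute-force
# superposition oracle used to cross-check the Kabsch implementation.

# Single-atom-per-frame ensemble on the z axis (for DI hand cases).
point_ensemble <- function(z_values) {
  top <- data.frame(serial = 1L, atom_name = "CA", element = "C",
                    residue_index = 1L, residue_name = "ALA",
                    chain_id = "A", stringsAsFactors = FALSE)
  co <- array(0, dim = c(length(z_values), 1L, 3L))
  co[, 1, 3] <- z_values
  ensemble(top, co)
}

# Ensemble of repeated copies of one A x 3 coordinate matrix.
copies_ensemble <- function(topology, coords, n) {
  arr <- array(0, dim = c(n, nrow(coords), 3L))
  for (k in seq_len(n)) arr[k, , ] <- coords
  ensemble(topology, arr)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# A proper random rotation (determinant +1).
random_proper_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

apply_rigid <- function(coords, R, t) {
  sweep(coords %*% t(R), 2, t, `+`)
}

# Rotate `move_idx` atoms about the axis through p0 along `axis` by `ang`.
rotate_about_axis <- function(coords, p0, axis, ang, move_idx) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  coords[move_idx, ] <- sweep(
    sweep(coords[move_idx, , drop = FALSE], 2, p0) %*% t(R), 2, p0, `+`)
  coords
}

# Brute-force minimum RMSD over a rotation grid (ZYZ Euler angles):
# coarse 3-degree global scan plus a 0.1-degree local box around the best
# cell. Uses only the closed form rmsd^2 = (|P|^2 + |Q|^2 - 2 tr(R H)) / n,
# independent of the SVD route under test.
grid_rmsd_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Pc, Qc)  # tr(R' H) is the objective
  const <- sum(Pc^2) + sum(Qc^2)
  n <- nrow(P)
  best_tr <- function(alphas, betas, gammas) {
    best <- -Inf
    arg <- c(0, 0, 0)
    for (b in betas) {
      cb <- cos(b); sb <- sin(b)
      for (a in alphas) {
        ca <- cos(a); sa <- sin(a)
        Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
        Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
        M <- Rz1 %*% Ry
        for (g in gammas) {
          cg <- cos(g); sg <- sin(g)
          Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3,
                        byrow = TRUE)
          tr <- sum(t(M %*% Rz2) * H)
          if (tr > best) {
            best <- tr
            arg <- c(a, b, g)
          }
        }
      }
    }
    list(tr = best, arg = arg)
  }
  step <- 3 * pi / 180
  coarse <- best_tr(seq(0, 2 * pi, by = step), seq(0, pi, by = step),
                    seq(0, 2 * pi, by = step))
  fine_step <- 0.1 * pi / 180
  rng <- function(center) seq(center - step, center + step, by = fine_step)
  fine <- best_tr(rng(coarse$arg[1]), rng(coarse$arg[2]), rng(coarse$arg[3]))
  sqrt(max((const - 2 * fine$tr) / n, 0))
}

# Connected components of the thresholded pairwise min-RMSD graph, with the
# pairwise RMSDs computed by bio3d (independent of the package kernels).
bio3d_component_clusters <- function(x, radius, selection = "CA") {
  sel <- atom_selection(x, selection)
  f <- n_frames(x)
  xyz <- matrix(0, nrow = f, ncol = 3L * length(sel))
  for (k in 1:3)

    xyz[, seq(k, by = 3L, length.out = length(sel))] <- x$coords[, sel, k]
  rd <- matrix(0, f, f)
  for (i in seq_len(f - 1)) {
    rd[i, (i + 1):f] <- bio3d::rmsd(xyz[i, ], xyz[(i + 1):f, , drop = FALSE],
                                    fit = TRUE)
    rd[(i + 1):f, i] <- rd[i, (i + 1):f]
  }
  adj <- rd <= radius
  comp <- rep(NA_integer_, f)
  cur <- 0L
  for (s in seq_len(f)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
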