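#' Minimum heavy-atom distance between two residues
#'
#' For one frame, the minimum Euclidean distance over all pairs of heavy
#' (non-hydrogen) atoms, one from each residue. This is the per-frame
#' quantity behind van der Waals contact calls.
#'
#' @param x an [ensemble()]
#' @param residue_a,residue_b residue indices (1-based, as in the topology)
#' @param frame frame index (default 1)
#' @return distance in Angstrom
#' @export
min_heavy_atom_distance <- function(x, residue_a, residue_b, frame = 1L) {
  ia <- heavy_atoms_of(x, residue_a)
  ib <- heavy_atoms_of(x, residue_b)
  co <- frame_coords(x, frame)
  min(cross_distances(co[ia, , drop = FALSE], co[ib, , drop = FALSE]))
}

heavy_atoms_of <- function(x, residue) {
  idx <- which(x$topology$residue_index == residue & x$topology$is_heavy)
  if (length(idx) == 0L) {
    stop("residue ", residue, " has no heavy atoms")
  }
  idx
}

cross_distances <- function(a, b) {
  # |a_i - b_j| for all pairs; a, b are n x 3 matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Per-frame minimum heavy-atom distance series
#'
#' @inheritParams min_heavy_atom_distance
#' @return data.frame with columns `frame`, `distance`, plus `mean`/`sd`
#'   attributes
#' @export
min_distance_series <- function(x, residue_a, residue_b) {
  v <- vapply(seq_len(n_frames(x)), function(f) {
    min_heavy_atom_distance(x, residue_a, residue_b, frame = f)
  }, numeric(1))
  distance_series(v, sprintf("min heavy-atom %d-%d", residue_a, residue_b))
}

distance_series <- function(values, definition) {
  out <- data.frame(frame = seq_along(values), distance = values)
  attr(out, "mean") <- mean(values)
  attr(out, "sd") <- stats::sd(values)
  attr(out, "definition") <- definition
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Van der Waals contact predicate
#'
#' Two residues are in contact when some heavy-atom pair distance is
#' strictly below the cutoff (default 4.5 Angstrom).
#'
#' @param distance minimum heavy-atom distance, Angstrom (>= 0)
#' @param cutoff contact cutoff, Angstrom (default 4.5)
#' @return logical
#' @export
is_vdw_contact <- function(distance, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (any(distance < 0)) stop("distance must be non-negative")
  distance < cutoff
}

#' C-alpha to C-alpha distance series between two residues
#'
#' @param x an [ensemble()]
#' @param res_a,res_b residue indices
#' @return a `distance_series` data.frame (`frame`, `distance`), with
#'   `mean` and `sd` attributes
#' @export
ca_distance_series <- function(x, res_a, res_b) {
  ca <- function(res) {
    i <- which(x$topology$residue_index == res & x$topology$atom_name == "CA")
    if (length(i) != 1L) stop("residue ", res, " has no unique CA atom")
    i
  }
  ia <- ca(res_a)
  ib <- ca(res_b)
  d <- sqrt(rowSums((x$coords[, ia, , drop = TRUE] -
                       x$coords[, ib, , drop = TRUE])^2))
  if (n_frames(x) == 1L) d <- sqrt(sum((x$coords[1, ia, ] - x$coords[1, ib, ])^2))
  distance_series(d, sprintf("CA %d - CA %d", res_a, res_b))
}

#' Aromatic ring specification
#'
#' @param residue residue index carrying the ring
#' @param atom_names at least 5 atom names forming the ring
#' @return list of class `ring_spec`
#' @export
ring_spec <- function(residue, atom_names) {
  if (length(atom_names) < 5L) stop("a ring needs at least 5 atoms")
  structure(list(residue = residue, atom_names = atom_names),
            class = "ring_spec")
}

ring_atom_indices <- function(x, ring) {
  idx <- vapply(ring$atom_names, function(nm) {
    i <- which(x$topology$residue_index == ring$residue &
                 x$topology$atom_name == nm)
    if (length(i) != 1L) {
      stop("ring atom ", nm, " not found in residue ", ring$residue)
    }
    i
  }, integer(1))
  unname(idx)
}

# Ring centroid and unit plane normal (smallest principal axis).
ring_geometry <- function(coords) {
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-6) stop("degenerate ring: atoms are collinear")
  list(centroid = centroid, normal = sv$v[, 3])
}

#' Pi-stacking occupancy of two aromatic rings across an ensemble
#'
#' A frame counts as stacked when the ring-centroid distance is at most
#' `d_max` and the angle between the ring-plane normals (sign-disambiguated
#' to \[0, 90\] degrees) is at most `angle_max`. Ring planes are fit by
#' principal axes. Returns the stacked fraction of frames.
#'
#' @param x an [ensemble()]
#' @param ring_a,ring_b [ring_spec()] objects
#' @param d_max centroid distance cutoff, Angstrom (default 5.0)
#' @param angle_max normal-angle cutoff, degrees (default 30)
#' @return fraction in \[0, 1\]; per-frame flags in the `stacked` attribute
#' @export
pi_stacking_occupancy <- function(x, ring_a, ring_b, d_max = 5.0,
                                  angle_max = 30) {
  ia <- ring_atom_indices(x, ring_a)
  ib <- ring_atom_indices(x, ring_b)
  stacked <- vapply(seq_len(n_frames(x)), function(f) {
    co <- frame_coords(x, f)
    ga <- ring_geometry(co[ia, , drop = FALSE])
    gb <- ring_geometry(co[ib, , drop = FALSE])
    d <- sqrt(sum((ga$centroid - gb$centroid)^2))
    cosang <- abs(sum(ga$normal * gb$normal))
    ang <- acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
    d <= d_max && ang <= angle_max
  }, logical(1))
  out <- mean(stacked)
  attr(out, "stacked") <- stacked
  out
}

#' Per-cluster, per-residue C-alpha RMSF
#'
#' Within each cluster, frames are superposed (over CA atoms) onto the
#' iteratively refined cluster mean structure; the RMSF of residue `i` is
#' the root mean square displacement of its CA from the cluster-mean
#' position. Singleton clusters are skipped with a warning (RMSF undefined).
#'
#' @param x the clustered [ensemble()]
#' @param assignment a `cluster_assignment` from [cluster_fixed_radius()]
#' @return data.frame with columns `cluster_id`, `residue_index`, `rmsf`
#' @export
rmsf_per_cluster <- function(x, assignment) {
  ca_idx <- atom_selection(x, "CA")
  res <- x$topology$residue_index[ca_idx]
  out <- list()
  for (k in sort(unique(assignment$cluster_id))) {
    members <- which(assignment$cluster_id == k)
    if (length(members) < 2L) {
      warning("cluster ", k, " has fewer than 2 frames; RMSF skipped")
      next
    }
    sub <- keep_frames(x, members)
    aligned <- global_overlay(sub, selection = "CA")
    ca <- aligned$coords[, ca_idx, , drop = FALSE]
    mean_pos <- apply(ca, c(2, 3), mean)
    disp2 <- sweep(ca, c(2, 3), mean_pos)^2
    rmsf <- sqrt(apply(disp2, 2, sum) / dim(ca)[1])
    out[[length(out) + 1L]] <- data.frame(cluster_id = k,
                                          residue_index = res, rmsf = rmsf)
  }
  if (length(out) == 0L) {
    return(data.frame(cluster_id = integer(), residue_index = integer(),
                      rmsf = numeric()))
  }
  do.call(rbind, out)
}
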