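#' Optimal least-squares superposition of two coordinate sets
#'
#' Computes the rigid transform (rotation + translation) minimizing the RMSD
#' of `mobile` onto `reference` over a selection, by the Kabsch/SVD method
#' with reflection correction.
#'
#' @param mobile,reference numeric `A x 3` matrices (Angstrom)
#' @param sel_idx integer atom indices used to compute the transform
#'   (default: all atoms); at least 3 atoms are required.
#' @return list with `rotation` (3x3), `center_mobile`, `center_reference`
#'   (the selection centroids), `rmsd` (minimized, over the selection), and
#'   `transform(coords)`, a function applying the transform to any `A x 3`
#'   matrix in the mobile frame.
#' @export
superpose <- function(mobile, reference, sel_idx = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L)
  if (is.null(sel_idx)) sel_idx <- seq_len(nrow(mobile))
  if (length(sel_idx) < 3L) {
    stop("superposition needs at least 3 selected atoms")
  }
  P <- mobile[sel_idx, , drop = FALSE]
  Q <- reference[sel_idx, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selections differ in atom count")
  pc <- colMeans(P)
  qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc)
  Qc <- sweep(Q, 2, qc)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  D <- diag(3)
  if (det(sv$v %*% t(sv$u)) < 0) D[3, 3] <- -1
  R <- sv$v %*% D %*% t(sv$u)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(max(sum((aligned - Qc)^2) / nrow(P), 0))
  transform <- function(coords) {
    sweep(sweep(coords, 2, pc) %*% t(R), 2, qc, `+`)
  }
  list(rotation = R, center_mobile = pc, center_reference = qc,
       rmsd = rmsd, transform = transform)
}

#' Minimized pairwise RMSD
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom after optimal superposition over the selection
#' @export
rmsd_pair <- function(mobile, reference, sel_idx = NULL) {
  if (is.null(sel_idx)) sel_idx <- seq_len(nrow(mobile))
  rmsd_pair_cpp(mobile[sel_idx, , drop = FALSE],
                reference[sel_idx, , drop = FALSE])
}

#' Fixed-radius RMSD clustering of an ensemble
#'
#' Clusters frames so that every frame lies within `radius` (RMSD over the
#' selection, after optimal superposition) of its cluster centroid. The
#' algorithm is a deterministic leader pass in frame order (assign to the
#' first centroid within the radius, else the frame seeds a new cluster),
#' followed by centroid refinement: each centroid is recomputed as the
#' average of its members after superposition onto the previous centroid,
#' all frames are reassigned to their nearest centroid (spawning a new
#' cluster for any frame farther than `radius` from every centroid), and
#' the process repeats until assignments are stable or `max_iter` rounds.
#' A final assignment-only pass guarantees the radius invariant. Cluster ids
#' are dense `1..K` in order of first appearance; empty clusters are dropped.
#'
#' @param x an [ensemble()]
#' @param radius clustering radius in Angstrom (default 2.4)
#' @param selection atom selection for the RMSD (default `"CA"`);
#'   see [atom_selection()]
#' @param max_iter maximum refinement rounds (default 10); a warning is
#'   emitted if refinement has not converged by then
#' @return object of class `cluster_assignment`: list with `cluster_id`
#'   (integer per frame), `centroids` (list of `A_sel x 3` matrices),
#'   `rmsd_to_centroid` (per frame), `radius`, `selection`, `sizes`.
#' @export
cluster_fixed_radius <- function(x, radius = 2.4, selection = "CA",
                                 max_iter = 10L) {
  if (radius <= 0) stop("radius must be positive")
  sel_idx <- atom_selection(x, selection)
  if (length(sel_idx) < 3L) stop("selection must contain at least 3 atoms")
  cube <- selection_cube(x, sel_idx)
  f <- n_frames(x)

  lead <- leader_cluster_cpp(cube, radius)
  assign <- lead$assign
  centroids <- lapply(lead$seeds, function(i) cube[, , i])

  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # refine centroids as superposed member means
    for (k in seq_along(centroids)) {
      members <- which(assign == k)
      if (length(members) == 0L) next
      centroids[[k]] <- superposed_mean_cpp(cube, members, centroids[[k]])
    }
    res <- reassign_with_spawning(cube, centroids, radius)
    centroids <- res$centroids
    if (identical(res$assign, assign)) {
      assign <- res$assign
      converged <- TRUE
      break
    }
    assign <- res$assign
  }
  if (!converged && max_iter > 0L) {
    warning("fixed-radius refinement did not converge in ", max_iter,
            " iterations; applying final assignment pass")
  }
  # final assignment-only pass: guarantees the radius invariant
  res <- reassign_with_spawning(cube, centroids, radius)
  assign <- res$assign
  centroids <- res$centroids

  # compact ids in order of first appearance, drop empty clusters
  first_seen <- unique(assign)
  remap <- match(assign, first_seen)
  centroids <- centroids[first_seen]
  out <- list(cluster_id = remap,
              centroids = centroids,
              rmsd_to_centroid = rmsd_per_frame(cube, centroids, remap),
              radius = radius, selection = selection, sel_idx = sel_idx,
              sizes = as.integer(table(factor(remap,
                                              levels = seq_along(centroids)))))
  class(out) <- "cluster_assignment"
  out
}

# Assign every frame to the nearest centroid; frames beyond `radius` of all
# centroids spawn new clusters sequentially (each new centroid is available
# to later frames).
reassign_with_spawning <- function(cube, centroids, radius) {
  res <- assign_nearest_cpp(cube, cube_from_list(centroids))
  assign <- res$id
  far <- which(res$rmsd > radius)
  for (f in far) {
    cur <- cube[, , f]
    hit <- NA_integer_
    # re-check all centroids, including ones spawned earlier in this pass
    for (k in seq_along(centroids)) {
      if (rmsd_pair_cpp(cur, centroids[[k]]) <= radius) {
        hit <- k
        break
      }
    }
    if (is.na(hit)) {
      centroids[[length(centroids) + 1L]] <- cur
      hit <- length(centroids)
    }
    assign[f] <- hit
  }
  list(assign = assign, centroids = centroids)
}

cube_from_list <- function(mats) {
  a <- nrow(mats[[1]])
  arr <- array(0, dim = c(a, 3L, length(mats)))
  for (k in seq_along(mats)) arr[, , k] <- mats[[k]]
  arr
}

rmsd_per_frame <- function(cube, centroids, assign) {
  out <- numeric(dim(cube)[3])
  for (k in seq_along(centroids)) {
    members <- which(assign == k)
    if (length(members) == 0L) next
    out[members] <- rmsd_to_ref_cpp(
      cube[, , members, drop = FALSE], centroids[[k]])
  }
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d frames, %d clusters, radius %.2f A\n",
              length(x$cluster_id), length(x$centroids), x$radius))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Combined clustering of two labeled ensembles
#'
#' Concatenates the frames of two ensembles (group A first), clusters them
#' with [cluster_fixed_radius()], and tallies per-cluster counts of frames
#' from each group. This is the entry point for apo-vs-liganded (or
#' WT-vs-mutant) population comparison.
#'
#' @param a,b ensembles with identical topologies over the selection
#' @param radius clustering radius in Angstrom (default 2.4)
#' @param selection atom selection (default `"CA"`)
#' @param group_names length-2 character, names for the two groups
#'   (default `c("apo", "liganded")`)
#' @param ... passed to [cluster_fixed_radius()]
#' @return list with `assignment` (a `cluster_assignment` over the combined
#'   frames) and `table` (a `cluster_table`: data.frame with `cluster_id`,
#'   `count_a`, `count_b` and group names as attributes)
#' @export
combined_cluster <- function(a, b, radius = 2.4, selection = "CA",
                             group_names = c("apo", "liganded"), ...) {
  sel_a <- atom_selection(a, selection)
  sel_b <- atom_selection(b, selection)
  if (!identical(sel_a, sel_b)) stop("selection resolves differently in a and b")
  check_same_topology(a, b, sel_idx = sel_a)
  combined <- concat_ensembles(a, b)
  assignment <- cluster_fixed_radius(combined, radius = radius,
                                     selection = selection, ...)
  from_a <- seq_len(n_frames(combined)) <= n_frames(a)
  tab <- cluster_table(assignment$cluster_id, from_a, group_names)
  list(assignment = assignment, table = tab)
}

#' Build a per-cluster provenance count table
#'
#' @param cluster_id integer cluster id per frame
#' @param from_a logical per frame, `TRUE` for group-A frames
#' @param group_names length-2 character
#' @return a `cluster_table` data.frame with columns `cluster_id`,
#'   `count_a`, `count_b`
#' @export
cluster_table <- function(cluster_id, from_a,
                          group_names = c("apo", "liganded")) {
  stopifnot(length(cluster_id) == length(from_a))
  ids <- sort(unique(cluster_id))
  tab <- data.frame(
    cluster_id = ids,
    count_a = as.integer(tapply(from_a, factor(cluster_id, ids), sum)),
    count_b = as.integer(tapply(!from_a, factor(cluster_id, ids), sum)))
  attr(tab, "group_names") <- group_names
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' Select representative frames of a cluster
#'
#' Returns the `n` member frames with the smallest RMSD (over the clustering
#' selection) to the cluster centroid; ties are broken by lower frame index.
#'
#' @param x the clustered [ensemble()]
#' @param assignment a `cluster_assignment` from [cluster_fixed_radius()]
#' @param cluster_id which cluster to draw from
#' @param n number of representatives (default 100)
#' @return an [ensemble()] of `n` frames, ordered by increasing RMSD to the
#'   centroid
#' @export
select_representatives <- function(x, assignment, cluster_id, n = 100L) {
  members <- which(assignment$cluster_id == cluster_id)
  if (length(members) == 0L) stop("cluster ", cluster_id, " is empty")
  if (n > length(members)) {
    stop("n (", n, ") exceeds cluster size (", length(members), ")")
  }
  cube <- selection_cube(x, assignment$sel_idx)
  d <- rmsd_to_ref_cpp(cube[, , members, drop = FALSE],
                       assignment$centroids[[cluster_id]])
  ord <- order(d, members)  # ties -> lower frame index
  keep_frames(x, members[ord[seq_len(n)]])
}
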