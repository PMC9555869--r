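#' Global least-squares overlay of an ensemble
#'
#' Iteratively superposes every frame (over the selection) onto the running
#' mean structure until the mean moves less than `tol` (RMS over selected
#' atoms) or `max_iter` rounds. The transform computed on the selection is
#' applied to all atoms. Overlay is idempotent to within `tol`.
#'
#' @param x an [ensemble()] with at least 2 frames
#' @param selection atom selection used for the overlay (default `"CA"`)
#' @param tol convergence tolerance on the mean structure, Angstrom
#'   (default 1e-6)
#' @param max_iter maximum iterations (default 50)
#' @return the [ensemble()] with coordinates in the common frame
#' @export
global_overlay <- function(x, selection = "CA", tol = 1e-6, max_iter = 50L) {
  if (n_frames(x) < 2L) stop("overlay needs at least 2 frames")
  sel_idx <- atom_selection(x, selection)
  coords <- x$coords
  f <- n_frames(x)
  mean_sel <- apply(coords[, sel_idx, , drop = FALSE], c(2, 3), mean)
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(f)) {
      fit <- superpose(matrix(coords[i, sel_idx, ], ncol = 3), mean_sel)
      coords[i, , ] <- fit$transform(matrix(coords[i, , ], ncol = 3))
    }
    new_mean <- apply(coords[, sel_idx, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(mean(rowSums((new_mean - mean_sel)^2)))
    mean_sel <- new_mean
    if (shift < tol) break
  }
  ensemble(x$topology, coords, x$labels)
}

#' Per-atom discrimination index between two structure subgroups
#'
#' For each atom, with all structures already in a common frame (see
#' [global_overlay()]): `m_between` is the mean positional distance over all
#' inter-group structure pairs, `m_within` the mean over intra-group pairs
#' pooled from both groups (0 when neither group has 2 structures), and
#' `DI = (m_between - m_within) / max(m_between, m_within)`, clamped to
#' \[0, 1\], with `DI = 0` when both means are 0. DI near 0 means the groups
#' are indistinguishable at that atom; DI near 1 means they are structurally
#' distinct.
#'
#' @param group_a,group_b ensembles sharing a topology, in a common frame
#' @return numeric vector, one DI in \[0, 1\] per atom
#' @export
discrimination_index <- function(group_a, group_b) {
  if (n_frames(group_a) < 1L || n_frames(group_b) < 1L) {
    stop("both groups need at least one structure")
  }
  check_same_topology(group_a, group_b)
  di_from_distances(pairwise_atom_distances(group_a, group_b))
}

# All pairwise per-atom distances, split into inter- and pooled intra-group
# pairs. Returns list(between = P1 x A matrix, within = P2 x A matrix).
pairwise_atom_distances <- function(group_a, group_b) {
  na <- n_frames(group_a)
  nb <- n_frames(group_b)
  a <- n_atoms(group_a)
  frame_of <- function(g, i) matrix(g$coords[i, , ], ncol = 3)
  dist_pair <- function(p, q) sqrt(rowSums((p - q)^2))
  between <- matrix(0, nrow = na * nb, ncol = a)
  r <- 0L
  for (i in seq_len(na)) {
    pi_ <- frame_of(group_a, i)
    for (j in seq_len(nb)) {
      r <- r + 1L
      between[r, ] <- dist_pair(pi_, frame_of(group_b, j))
    }
  }
  intra <- function(g) {
    n <- n_frames(g)
    if (n < 2L) return(NULL)
    out <- matrix(0, nrow = n * (n - 1L) / 2L, ncol = a)
    r <- 0L
    for (i in seq_len(n - 1L)) {
      pi_ <- frame_of(g, i)
      for (j in (i + 1L):n) {
        r <- r + 1L
        out[r, ] <- dist_pair(pi_, frame_of(g, j))
      }
    }
    out
  }
  list(between = between, within = rbind(intra(group_a), intra(group_b)))
}

# Distances below this floor (Angstrom) are numerical round-off from the
# superposition, not structure; both means under it give DI = 0.
DI_EPS <- 1e-8

di_from_distances <- function(d) {
  m_between <- colMeans(d$between)
  m_within <- if (is.null(d$within)) {
    rep(0, length(m_between))
  } else {
    colMeans(d$within)
  }
  hi <- pmax(m_between, m_within)
  di <- ifelse(hi < DI_EPS, 0, (m_between - m_within) / hi)
  pmin(pmax(di, 0), 1)
}

#' Local overlaid dipeptide residual (LODR) at one residue
#'
#' Measures residue-level backbone dissimilarity between two structures:
#' the structures are superposed on the peptide unit preceding residue `i`
#' (atoms `C(i-1)`, `O(i-1)`, `N(i)`, `CA(i)`), and the LODR is the RMS
#' distance over the following unit (`C(i)`, `O(i)`, `N(i+1)`, `CA(i+1)`).
#' Rigid-body differences cancel; only local backbone changes register.
#' Chain-terminal residues are undefined and return `NA` with a warning.
#'
#' @param coords_x,coords_y `A x 3` coordinate matrices of the two
#'   structures
#' @param topology shared topology data.frame
#' @param residue_i residue index (needs residues `i-1` and `i+1` with
#'   backbone atoms N, CA, C, O)
#' @return LODR in Angstrom, or `NA` for terminal residues
#' @export
lodr <- function(coords_x, coords_y, topology, residue_i) {
  sets <- lodr_atom_sets(topology, residue_i)
  if (is.null(sets)) {
    warning("LODR undefined for chain-terminal residue ", residue_i)
    return(NA_real_)
  }
  fit <- superpose(coords_x, coords_y, sel_idx = sets$overlay)
  moved <- fit$transform(coords_x)
  sqrt(mean(rowSums((moved[sets$measure, , drop = FALSE] -
                       coords_y[sets$measure, , drop = FALSE])^2)))
}

lodr_atom_sets <- function(topology, residue_i) {
  find <- function(res, name) {
    i <- which(topology$residue_index == res & topology$atom_name == name)
    if (length(i) == 1L) i else NA_integer_
  }
  overlay <- c(find(residue_i - 1L, "C"), find(residue_i - 1L, "O"),
               find(residue_i, "N"), find(residue_i, "CA"))
  measure <- c(find(residue_i, "C"), find(residue_i, "O"),
               find(residue_i + 1L, "N"), find(residue_i + 1L, "CA"))
  if (anyNA(overlay) || anyNA(measure)) return(NULL)
  list(overlay = overlay, measure = measure)
}

#' Per-residue local discrimination index profile
#'
#' Applies the [discrimination_index()] formula per residue, with pairwise
#' [lodr()] values as the distances: inter-group LODR pairs versus pooled
#' intra-group pairs. Peaks localize backbone conformational differences
#' between the groups. Terminal residues are `NA`.
#'
#' @param group_a,group_b ensembles sharing a topology (no overlay needed;
#'   LODR is superposition-local)
#' @return data.frame with columns `residue_index`, `local_di`
#' @export
local_di_profile <- function(group_a, group_b) {
  check_same_topology(group_a, group_b)
  top <- group_a$topology
  residues <- sort(unique(top$residue_index))
  na <- n_frames(group_a)
  nb <- n_frames(group_b)
  frame_of <- function(g, i) matrix(g$coords[i, , ], ncol = 3)
  frames_a <- lapply(seq_len(na), frame_of, g = group_a)
  frames_b <- lapply(seq_len(nb), frame_of, g = group_b)
  di <- vapply(residues, function(res) {
    sets <- lodr_atom_sets(top, res)
    if (is.null(sets)) return(NA_real_)
    pair_lodr <- function(p, q) {
      fit <- superpose(p, q, sel_idx = sets$overlay)
      moved <- fit$transform(p)
      sqrt(mean(rowSums((moved[sets$measure, , drop = FALSE] -
                           q[sets$measure, , drop = FALSE])^2)))
    }
    between <- as.vector(vapply(frames_a, function(p) {
      vapply(frames_b, pair_lodr, numeric(1), p = p)
    }, numeric(nb)))
    intra <- function(frames) {
      n <- length(frames)
      if (n < 2L) return(numeric(0))
      unlist(lapply(seq_len(n - 1L), function(i) {
        vapply((i + 1L):n, function(j) pair_lodr(frames[[i]], frames[[j]]),
               numeric(1))
      }))
    }
    within <- c(intra(frames_a), intra(frames_b))
    m_between <- mean(between)
    m_within <- if (length(within) == 0L) 0 else mean(within)
    hi <- max(m_between, m_within)
    if (hi < DI_EPS) return(0)
    min(max((m_between - m_within) / hi, 0), 1)
  }, numeric(1))
  data.frame(residue_index = residues, local_di = di)
}
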