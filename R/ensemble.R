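#' Conformational ensemble container
#'
#' An `ensemble` bundles a topology (one row per atom), a coordinate array of
#' `F` frames by `A` atoms by 3 (Angstrom), and per-frame provenance labels.
#' It is the object clustered and measured throughout the package.
#'
#' @param topology data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_index` (1-based), `residue_name`, `chain_id`. A logical
#'   `is_heavy` column is derived from `element` (everything but H/D).
#' @param coords numeric array of dimension `c(F, A, 3)`, or an `A x 3`
#'   matrix for a single frame. All values must be finite.
#' @param labels optional data.frame with `F` rows carrying per-frame
#'   provenance; missing columns among `variant`, `ligand`, `group`,
#'   `substate`, `source_index` are filled with defaults.
#'
#' @return An object of class `ensemble` with elements `topology`, `coords`
#'   and `labels`.
#' @export
ensemble <- function(topology, coords, labels = NULL) {
  stopifnot(is.data.frame(topology))
  need <- c("serial", "atom_name", "element", "residue_index",
            "residue_name", "chain_id")
  missing_cols <- setdiff(need, names(topology))
  if (length(missing_cols) > 0L) {
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be an F x A x 3 array")
  }
  if (dim(coords)[2] != nrow(topology)) {
    stop("coords has ", dim(coords)[2], " atoms but topology has ",
         nrow(topology))
  }
  if (dim(coords)[1] < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(coords))) stop("coords contains non-finite values")
  key <- paste(topology$chain_id, topology$residue_index, topology$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom_name) in topology: ",
         key[which(duplicated(key))[1]])
  }
  topology$is_heavy <- !toupper(topology$element) %in% c("H", "D")
  nf <- dim(coords)[1]
  labels <- normalize_labels(labels, nf)
  structure(list(topology = topology, coords = coords, labels = labels),
            class = "ensemble")
}

normalize_labels <- function(labels, n_frames) {
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(n_frames))
  if (nrow(labels) == 0L && n_frames > 0L) {
    labels <- data.frame(row.names = seq_len(n_frames))
  }
  if (nrow(labels) != n_frames) {
    stop("labels has ", nrow(labels), " rows but ensemble has ", n_frames,
         " frames")
  }
  defaults <- list(variant = "WT", ligand = "APO", group = "APO",
                   substate = NA_character_,
                   source_index = seq_len(n_frames))
  for (nm in names(defaults)) {
    if (is.null(labels[[nm]])) labels[[nm]] <- defaults[[nm]]
  }
  labels
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<ensemble> %d frame(s), %d atoms, %d residue(s)\n",
              d[1], d[2], length(unique(x$topology$residue_index))))
  grp <- table(x$labels$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param x an `ensemble`
#' @return integer count
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' Extract one frame as an A x 3 coordinate matrix
#' @param x an `ensemble`
#' @param i frame index (1-based)
#' @return numeric matrix `A x 3`
#' @export
frame_coords <- function(x, i) {
  stopifnot(i >= 1L, i <= n_frames(x))
  matrix(x$coords[i, , ], ncol = 3L)
}

#' Resolve an atom selection to topology row indices
#'
#' @param x an `ensemble`
#' @param selection either a character vector of atom names (e.g. `"CA"`),
#'   or an integer vector of atom indices.
#' @return integer vector of atom indices
#' @export
atom_selection <- function(x, selection = "CA") {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > n_atoms(x))) stop("selection index out of range")
    return(idx)
  }
  idx <- which(x$topology$atom_name %in% selection)
  if (length(idx) == 0L) {
    stop("selection matched no atoms: ", paste(selection, collapse = ","))
  }
  idx
}

# Coordinates of a selection as an A_sel x 3 x F cube (for the C++ kernels).
selection_cube <- function(x, sel_idx) {
  aperm(x$coords[, sel_idx, , drop = FALSE], c(2, 3, 1))
}

#' Keep a subset of frames
#' @param x an `ensemble`
#' @param idx integer frame indices (1-based, in the order to keep)
#' @return an `ensemble`
#' @export
keep_frames <- function(x, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= n_frames(x)))
  ensemble(x$topology, x$coords[idx, , , drop = FALSE],
           x$labels[idx, , drop = FALSE])
}

#' Concatenate two ensembles sharing a topology
#'
#' Frames of `a` come first; labels are carried along. Topologies must match
#' in atom name, order, and residue numbering.
#'
#' @param a,b ensembles with identical topologies
#' @return an `ensemble` with `n_frames(a) + n_frames(b)` frames
#' @export
concat_ensembles <- function(a, b) {
  check_same_topology(a, b)
  coords <- array(0, dim = c(n_frames(a) + n_frames(b), n_atoms(a), 3L))
  coords[seq_len(n_frames(a)), , ] <- a$coords
  coords[n_frames(a) + seq_len(n_frames(b)), , ] <- b$coords
  labs <- rbind(a$labels[names(a$labels)], b$labels[names(a$labels)])
  ensemble(a$topology, coords, labs)
}

check_same_topology <- function(a, b, sel_idx = NULL) {
  ta <- a$topology
  tb <- b$topology
  if (!is.null(sel_idx)) {
    ta <- ta[sel_idx, , drop = FALSE]
    tb <- tb[sel_idx, , drop = FALSE]
  }
  if (nrow(ta) != nrow(tb)) {
    stop("topology mismatch: ", nrow(ta), " vs ", nrow(tb), " atoms")
  }
  same <- ta$atom_name == tb$atom_name & ta$residue_index == tb$residue_index
  if (!all(same)) {
    i <- which(!same)[1]
    stop(sprintf(
      "topology mismatch at atom %d: %s/%d vs %s/%d", i,
      ta$atom_name[i], ta$residue_index[i], tb$atom_name[i],
      tb$residue_index[i]))
  }
  invisible(TRUE)
}
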