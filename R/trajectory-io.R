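#' Read a multi-model PDB file as an ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a bare `ATOM` block is a
#' single frame. The topology is taken from the first model, and all models
#' must share its atom count and ordering. Parsing of the fixed-column
#' records is delegated to \pkg{bio3d}.
#'
#' @param path path to a PDB file
#' @return an [ensemble()]
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_model_atom_counts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- infer_element(at$elety[blank])
  topology <- data.frame(
    serial = at$eleno,
    atom_name = trimws(at$elety),
    element = trimws(elem),
    residue_index = at$resno,
    residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  f <- nrow(xyz)
  a <- ncol(xyz) / 3L
  coords <- array(0, dim = c(f, a, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3L, length.out = a),
                                      drop = FALSE]
  ensemble(topology, coords)
}

# Fail early, naming the model, if models disagree in atom count.
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  if (!any(model_starts)) return(invisible(TRUE))
  model_id <- cumsum(model_starts)
  counts <- table(model_id[is_atom & model_id > 0L])
  if (length(unique(as.integer(counts))) > 1L) {
    ref <- as.integer(counts[1])
    bad <- names(counts)[as.integer(counts) != ref][1]
    stop(sprintf(
      "inconsistent atom counts across models: model %s has %d atoms, model 1 has %d",
      bad, as.integer(counts[bad]), ref))
  }
  invisible(TRUE)
}

# Element from the leading alphabetic characters of a PDB atom name.
infer_element <- function(atom_name) {
  nm <- gsub("[0-9'\"]", "", trimws(atom_name))
  el <- toupper(substr(nm, 1, 1))
  el[el == ""] <- "X"
  el
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard `MODEL`/`ATOM`/`ENDMDL` records (one `MODEL` per frame).
#' Optional per-atom scalars (e.g. a discrimination index for structure
#' coloring) are stored in the B-factor column, clipped to \[0, 999.99\].
#'
#' @param x an [ensemble()]
#' @param path output path
#' @param bfactor_values optional numeric vector, one value per atom
#' @return `path`, invisibly
#' @export
write_multimodel_pdb <- function(x, path, bfactor_values = NULL) {
  a <- n_atoms(x)
  if (is.null(bfactor_values)) {
    b <- rep(0, a)
  } else {
    if (length(bfactor_values) != a) {
      stop("bfactor_values must have one value per atom (", a, ")")
    }
    b <- pmin(pmax(bfactor_values, 0), 999.99)
  }
  f <- n_frames(x)
  xyz <- matrix(0, nrow = f, ncol = 3L * a)
  for (k in 1:3) xyz[, seq(k, by = 3L, length.out = a)] <- x$coords[, , k]
  top <- x$topology
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$residue_index, resid = top$residue_name,
                   eleno = top$serial, elety = top$atom_name,
                   chain = top$chain_id, elesy = top$element,
                   b = b, end = TRUE)
  invisible(path)
}

#' Evenly spaced frame subsampling
#'
#' Keeps `n` frames at indices `floor(k * (F - 1) / (n - 1) + 0.5)` for
#' `k = 0..n-1` (0-based; `n = 1` keeps the first frame). Endpoints are
#' always included and duplicates are impossible for `n <= F`. Frame labels
#' are carried along.
#'
#' @param x an [ensemble()]
#' @param n number of frames to keep, `1 <= n <= n_frames(x)`
#' @return an [ensemble()] with `n` frames
#' @export
subsample_frames <- function(x, n) {
  f <- n_frames(x)
  n <- as.integer(n)
  if (n < 1L || n > f) stop("n must be between 1 and the frame count (", f, ")")
  if (n == 1L) return(keep_frames(x, 1L))
  k <- 0:(n - 1L)
  idx <- floor(k * (f - 1) / (n - 1) + 0.5) + 1L
  keep_frames(x, idx)
}

#' Read a receptor-ligand activity table
#'
#' Expects columns `variant`, `ligand`, `ec50_nM`, `emax`, `fold_10nM`,
#' `fold_100nM`. A blank `ec50_nM` marks a ligand with no measurable
#' activation and is returned as `NA`.
#'
#' @param path path to a CSV file
#' @return data.frame with one row per receptor-ligand complex
#' @export
read_activity_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("variant", "ligand", "ec50_nM", "emax", "fold_10nM", "fold_100nM")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("activity table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("malformed number in column %s, row %d: '%s'",
                   col, bad[1], v[bad[1]]))
    }
    out
  }
  out <- data.frame(variant = raw$variant, ligand = raw$ligand,
                    ec50 = num("ec50_nM"), emax = num("emax"),
                    fold_10nM = num("fold_10nM"),
                    fold_100nM = num("fold_100nM"),
                    stringsAsFactors = FALSE)
  neg <- which(!is.na(out$ec50) & out$ec50 <= 0)
  if (length(neg) > 0L) {
    stop("non-positive ec50_nM in row ", neg[1])
  }
  out
}
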