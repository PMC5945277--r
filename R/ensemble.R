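#' Structure ensembles
#'
#' A `structure_ensemble` holds an ordered set of conformations (frames) of
#' the same molecule: an `F x N x 3` coordinate array in nanometres, per-atom
#' labels, per-frame labels, the index of the alignment reference frame and
#' an atom mask selecting the subset used for analysis (by default all
#' atoms; PDB readers default to backbone atoms).
#'
#' @param coords numeric array `F x N x 3` (nm), or an `F x 3N` matrix which
#'   is reshaped.
#' @param atom_labels optional data frame with one row per atom (columns such
#'   as `name`, `resid`, `chain`).
#' @param frame_labels optional character vector, one entry per frame.
#' @param reference_index index of the alignment reference frame (default 1).
#' @param mask integer vector of atom indices used for analysis (default all).
#' @return an object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(coords, atom_labels = NULL, frame_labels = NULL,
                               reference_index = 1L, mask = NULL) {
  if (is.matrix(coords)) {
    if (ncol(coords) %% 3 != 0)
      stop_input("flat coordinate matrix must have 3N columns")
    n_atoms <- ncol(coords) / 3
    arr <- array(NA_real_, c(nrow(coords), n_atoms, 3))
    for (f in seq_len(nrow(coords)))
      arr[f, , ] <- matrix(coords[f, ], ncol = 3, byrow = TRUE)
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (is.null(mask)) mask <- seq_len(n_atoms)
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) == 0 || any(mask < 1) || any(mask > n_atoms))
    stop_input("mask must be a non-empty subset of atom indices")
  if (reference_index < 1 || reference_index > n_frames)
    stop_input("reference_index must address an existing frame")
  if (is.null(frame_labels)) frame_labels <- as.character(seq_len(n_frames))
  structure(list(coords = coords,
                 atom_labels = atom_labels,
                 frame_labels = as.character(frame_labels),
                 reference_index = as.integer(reference_index),
                 mask = mask),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d frames, %d atoms (%d masked), ref frame %d\n",
              dim(x$coords)[1], dim(x$coords)[2], length(x$mask),
              x$reference_index))
  invisible(x)
}

n_frames <- function(ens) dim(ens$coords)[1]
n_atoms <- function(ens) dim(ens$coords)[2]

resolve_mask_spec <- function(pdb, mask_spec) {
  if (is.numeric(mask_spec)) return(as.integer(mask_spec))
  sel <- switch(mask_spec,
    backbone = bio3d::atom.select(pdb, elety = c("N", "CA", "C", "O"),
                                  verbose = FALSE),
    calpha = bio3d::atom.select(pdb, elety = "CA", verbose = FALSE),
    all = bio3d::atom.select(pdb, "all", verbose = FALSE),
    stop_input("unknown mask_spec: ", mask_spec))
  sel$atom
}

#' Read an ensemble of PDB structures
#'
#' Reads one frame per single-model file, or all models of a single
#' multi-model file. Coordinates are converted from Angstrom to nm. All
#' files must yield identical atom counts after selection.
#'
#' @param paths character vector of PDB file paths.
#' @param mask_spec `"backbone"` (default: N, CA, C, O atoms), `"calpha"`,
#'   `"all"`, or an integer vector of atom indices applied after reading.
#'   The selection defines the retained atom set; the ensemble mask then
#'   covers all retained atoms.
#' @return a [structure_ensemble] with `frame_labels` taken from file names
#'   (or model numbers for a multi-model file).
#' @export
read_pdb_ensemble <- function(paths, mask_spec = "backbone") {
  if (length(paths) == 0) stop_input("no PDB paths given")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop_input("unreadable PDB file(s): ", paste(missing, collapse = ", "))

  frames <- list()
  labels <- character()
  atom_tab <- NULL
  counts <- integer()
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    sel <- resolve_mask_spec(pdb, mask_spec)
    if (length(sel) == 0)
      stop_input("atom selection yields 0 atoms for file: ", p)
    xyz_idx <- bio3d::atom2xyz(sel)
    xyz <- pdb$xyz
    n_models <- nrow(xyz)
    for (m in seq_len(n_models)) {
      v <- xyz[m, xyz_idx]
      frames[[length(frames) + 1L]] <- matrix(v, ncol = 3, byrow = TRUE) / 10
      labels <- c(labels,
                  if (n_models > 1) sprintf("%s#%d", basename(p), m)
                  else basename(p))
      counts <- c(counts, length(sel))
    }
    if (is.null(atom_tab))
      atom_tab <- pdb$atom[sel, c("elety", "resid", "resno", "chain")]
  }
  if (length(unique(counts)) > 1) {
    bad <- unique(labels[counts != counts[1]])
    stop_input("atom-count mismatch across files: ",
               paste(bad, collapse = ", "))
  }
  n_at <- counts[1]
  arr <- array(NA_real_, c(length(frames), n_at, 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  names(atom_tab) <- c("name", "resid", "resno", "chain")
  structure_ensemble(arr, atom_labels = atom_tab, frame_labels = labels)
}

#' Write a structure ensemble to a multi-model PDB file
#'
#' Coordinates are converted from nm back to Angstrom. One MODEL record per
#' frame.
#'
#' @param ens a [structure_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lab <- ens$atom_labels
  na <- n_atoms(ens)
  name <- if (!is.null(lab)) lab$name else rep("CA", na)
  resid <- if (!is.null(lab)) lab$resid else rep("GLY", na)
  resno <- if (!is.null(lab) && !is.null(lab$resno)) lab$resno else seq_len(na)
  chain <- if (!is.null(lab) && !is.null(lab$chain)) lab$chain else rep("A", na)
  chain[is.na(chain)] <- "A"
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$coords[f, , , drop = TRUE] * 10
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    for (a in seq_len(na)) {
      nm <- name[a]
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                         a, nm_fmt, resid[a], chain[a], resno[a],
                         xyz[a, 1], xyz[a, 2], xyz[a, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Optimal rotation (Kabsch, via SVD) mapping centered P onto centered Q.
# P, Q: N x 3, already centered. Returns 3x3 matrix R with P %*% R ~ Q.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose every frame onto the reference frame
#'
#' Least-squares rigid-body (Kabsch) superposition over the masked atoms,
#' unweighted. The rotation is determined on the mask and applied to all
#' atoms. The reference frame itself is returned unchanged.
#'
#' @param ens a [structure_ensemble] with at least one frame and a mask of
#'   at least 3 non-collinear atoms.
#' @return the superposed [structure_ensemble].
#' @export
superpose <- function(ens) {
  ref <- ens$coords[ens$reference_index, , , drop = TRUE]
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
  refm <- ref[ens$mask, , drop = FALSE]
  ref_cen <- colMeans(refm)
  refm_c <- sweep(refm, 2, ref_cen)
  sv <- svd(refm_c)$d
  if (length(ens$mask) < 3 || sum(sv > 1e-10) < 2)
    stop_input("mask atoms are collinear or degenerate; rotation is underdetermined")
  out <- ens
  for (f in seq_len(n_frames(ens))) {
    if (f == ens$reference_index) next
    fr <- ens$coords[f, , , drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
    frm <- fr[ens$mask, , drop = FALSE]
    cen <- colMeans(frm)
    R <- kabsch_rotation(sweep(frm, 2, cen), refm_c)
    moved <- sweep(fr, 2, cen) %*% R
    out$coords[f, , ] <- sweep(moved, 2, ref_cen, `+`)
  }
  out
}

#' Root-mean-square deviation between two conformations
#'
#' RMSD over the atoms of two 3N coordinate vectors (or N x 3 matrices),
#' optionally after optimal rigid-body superposition (translation +
#' Kabsch rotation).
#'
#' @param frame_a,frame_b 3N numeric vectors (x1,y1,z1,x2,...) or N x 3
#'   matrices, in nm.
#' @param fit superpose `frame_a` onto `frame_b` first (default `TRUE`).
#' @return RMSD in nm.
#' @export
rmsd <- function(frame_a, frame_b, fit = TRUE) {
  A <- if (is.matrix(frame_a)) frame_a else matrix(frame_a, ncol = 3, byrow = TRUE)
  B <- if (is.matrix(frame_b)) frame_b else matrix(frame_b, ncol = 3, byrow = TRUE)
  if (!all(dim(A) == dim(B)))
    stop_input("coordinate length mismatch: ", nrow(A), " vs ", nrow(B), " atoms")
  if (fit) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
    if (nrow(A) >= 2) {
      sv <- svd(A)$d
      # 1- or 2-point or collinear sets: rotation is still well-defined for
      # the least-squares objective; kabsch handles rank deficiency via SVD
      A <- A %*% kabsch_rotation(A, B)
    }
  }
  sqrt(mean(rowSums((A - B)^2)))
}

#' Flatten a superposed ensemble into an F x 3N matrix
#'
#' Masked coordinates are concatenated per frame in atom order
#' (x1, y1, z1, x2, ...). The ensemble is assumed to be superposed already
#' (see [superpose]); flattening does not change coordinates.
#'
#' @param ens a [structure_ensemble].
#' @return an object of class `flat_ensemble` with fields `X` (F x 3N
#'   matrix, nm), `mean` (column means), `mask` and `frame_labels`.
#' @export
flatten <- function(ens) {
  Fn <- n_frames(ens)
  m <- ens$mask
  X <- matrix(NA_real_, Fn, 3 * length(m))
  for (f in seq_len(Fn)) {
    fr <- ens$coords[f, m, , drop = FALSE]
    X[f, ] <- as.vector(t(fr[1, , ]))
  }
  if (length(m) == 1) {
    for (f in seq_len(Fn)) X[f, ] <- ens$coords[f, m, ]
  }
  structure(list(X = X, mean = colMeans(X), mask = m,
                 frame_labels = ens$frame_labels),
            class = "flat_ensemble")
}

#' Construct a flat ensemble directly from a coordinate matrix
#'
#' Convenience constructor for analyses that start from plain matrices
#' (e.g. synthetic ensembles) rather than PDB files.
#'
#' @param X numeric F x 3N matrix (nm).
#' @param frame_labels optional frame labels.
#' @return a `flat_ensemble`.
#' @export
flat_ensemble <- function(X, frame_labels = NULL) {
  X <- as.matrix(X)
  structure(list(X = X, mean = colMeans(X), mask = NULL,
                 frame_labels = frame_labels %||% as.character(seq_len(nrow(X)))),
            class = "flat_ensemble")
}

#' @export
print.flat_ensemble <- function(x, ...) {
  cat(sprintf("flat_ensemble: %d frames x %d coordinates\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Rebuild an N x 3 coordinate matrix from a flat 3N vector
#'
#' Inverse of the per-frame layout used by [flatten].
#'
#' @param x 3N numeric vector.
#' @return N x 3 matrix.
#' @export
unflatten <- function(x) {
  if (length(x) %% 3 != 0) stop_input("length must be a multiple of 3")
  matrix(x, ncol = 3, byrow = TRUE)
}

#' Write / read a flat ensemble as delimited text
#'
#' Tab-separated values with a header row; frame labels in the first
#' column.
#'
#' @param flat a `flat_ensemble`.
#' @param path file path.
#' @return `path` (writer) or a `flat_ensemble` (reader).
#' @export
write_flat_ensemble <- function(flat, path) {
  df <- data.frame(frame = flat$frame_labels, flat$X, check.names = FALSE)
  colnames(df) <- c("frame", paste0("c", seq_len(ncol(flat$X))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flat_ensemble
#' @export
read_flat_ensemble <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  flat_ensemble(as.matrix(df[, -1, drop = FALSE]), frame_labels = df[[1]])
}
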