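#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' mapped atom pairs.
#'
#' @param ref_coords n x 3 matrix of template coordinates.
#' @param mov_coords m x 3 matrix of moving-molecule coordinates.
#' @param atom_mapping two-column integer matrix: column 1 indexes rows of
#'   `mov_coords`, column 2 rows of `ref_coords`.  At least 3
#'   non-collinear pairs required.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   such that transformed = mov %*% t(rotation) + translation, and `rmsd`
#'   over mapped pairs.
#' @export
kabsch_superpose <- function(ref_coords, mov_coords, atom_mapping = NULL) {
  ref_coords <- as.matrix(ref_coords); mov_coords <- as.matrix(mov_coords)
  if (is.null(atom_mapping)) {
    stopifnot(nrow(ref_coords) == nrow(mov_coords))
    atom_mapping <- cbind(seq_len(nrow(mov_coords)), seq_len(nrow(ref_coords)))
  }
  atom_mapping <- as.matrix(atom_mapping)
  if (nrow(atom_mapping) < 3) stop("need at least 3 mapped atom pairs")
  P <- mov_coords[atom_mapping[, 1], , drop = FALSE]  # moving
  Q <- ref_coords[atom_mapping[, 2], , drop = FALSE]  # reference
  if (collinear_points(P) || collinear_points(Q))
    stop("mapped atom pairs are collinear; rotation is underdetermined")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)                # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  fitted <- P %*% t(R) + matrix(tvec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

collinear_points <- function(X, tol = 1e-9) {
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

apply_rigid <- function(xyz, rotation, translation) {
  xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

#' Rigidly align a dataset onto a template molecule
#'
#' Each molecule is transformed by the Kabsch fit of its core atoms onto
#' the corresponding template core atoms.  The template itself is left
#' unchanged.
#'
#' @param ds a `qsar_dataset`.
#' @param template_id id of the template molecule (present in `ds`).
#' @param core_mapping named list (by molecule id) of two-column matrices
#'   `cbind(mol_atom, template_atom)` with 1-based indices, e.g. from
#'   [read_core_mapping()].  The template needs no entry.
#' @return The aligned `qsar_dataset`; per-molecule core RMSDs in
#'   attribute "rmsd".
#' @export
align_database <- function(ds, template_id, core_mapping) {
  ids <- dataset_ids(ds)
  ti <- match(template_id, ids)
  if (is.na(ti)) stop("template id not in dataset: ", template_id)
  others <- setdiff(ids, template_id)
  missing <- setdiff(others, names(core_mapping))
  if (length(missing))
    stop("missing core mapping for molecule(s): ",
         paste(missing, collapse = ", "))
  ref <- coords_of(ds$molecules[[ti]])
  rmsds <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_along(ids)) {
    if (k == ti) next
    fit <- kabsch_superpose(ref, coords_of(ds$molecules[[k]]),
                            core_mapping[[ids[k]]])
    ds$molecules[[k]] <- set_coords(
      ds$molecules[[k]],
      apply_rigid(coords_of(ds$molecules[[k]]), fit$rotation, fit$translation))
    rmsds[k] <- fit$rmsd
  }
  attr(ds, "rmsd") <- rmsds
  ds
}
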