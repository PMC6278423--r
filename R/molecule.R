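#' Construct a molecule
#'
#' The basic container of the package: an ordered atom table with 3D
#' coordinates (Angstrom), optional partial charges and per-atom field
#' properties, a bond list, an optional activity (pIC50) and a train/test
#' role.
#'
#' @param id character label, unique within a dataset.
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`; optional
#'   `charge` (elementary charge units).  Field-property columns
#'   (`vdw_radius`, `well_depth`, `hydrophobicity`, `is_donor`,
#'   `is_acceptor`) are filled from [element_parameters()] and simple
#'   donor/acceptor rules when absent.
#' @param bonds data.frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order` (1, 2, 3; aromatic bonds coded 1.5).
#' @param pIC50 numeric activity, `NA` for prediction-only molecules.
#' @param role one of "train", "test", "unassigned".
#' @return An object of class `qsar_mol`.
#' @export
molecule <- function(id, atoms, bonds = NULL, pIC50 = NA_real_,
                     role = "unassigned") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  required <- c("element", "x", "y", "z")
  if (!all(required %in% names(atoms)))
    stop("atoms must have columns element, x, y, z")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("molecule '", id, "': non-finite coordinates")
  if (!is.na(pIC50) && !is.finite(pIC50))
    stop("molecule '", id, "': pIC50 must be finite or NA")
  role <- match.arg(role, c("train", "test", "unassigned"))
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  par <- lookup_element(atoms$element)
  if (is.null(atoms$vdw_radius))     atoms$vdw_radius     <- par$vdw_radius
  if (is.null(atoms$well_depth))     atoms$well_depth     <- par$well_depth
  if (is.null(atoms$hydrophobicity)) atoms$hydrophobicity <- par$hydrophobicity
  if (is.null(atoms$is_donor) || is.null(atoms$is_acceptor)) {
    da <- assign_donor_acceptor(atoms$element, bonds)
    if (is.null(atoms$is_donor))    atoms$is_donor    <- da$donor
    if (is.null(atoms$is_acceptor)) atoms$is_acceptor <- da$acceptor
  }
  stopifnot(all(atoms$vdw_radius > 0), all(atoms$well_depth >= 0))
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         pIC50 = as.numeric(pIC50), role = role),
    class = "qsar_mol"
  )
}

# Donor: N or O bonded to at least one H.  Acceptor: any N or O except
# nitrogen with four explicit connections (quaternary).  Halogens and S are
# deliberately not flagged; the rules are coarse but symmetric across a
# series, which is what similarity fields need.
assign_donor_acceptor <- function(elements, bonds) {
  n <- length(elements)
  h_nbr <- rep(FALSE, n)
  degree <- rep(0L, n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      degree[i] <- degree[i] + 1L
      degree[j] <- degree[j] + 1L
      if (elements[j] == "H") h_nbr[i] <- TRUE
      if (elements[i] == "H") h_nbr[j] <- TRUE
    }
  }
  no <- elements %in% c("N", "O")
  list(donor = no & h_nbr,
       acceptor = no & !(elements == "N" & degree >= 4L))
}

#' @export
print.qsar_mol <- function(x, ...) {
  cat(sprintf("<qsar_mol %s: %d atoms, %d bonds, pIC50=%s, role=%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              ifelse(is.na(x$pIC50), "NA", format(x$pIC50)), x$role))
  invisible(x)
}

coords_of <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Construct a dataset of molecules
#'
#' @param molecules list of [molecule()] objects with unique ids.
#' @return Object of class `qsar_dataset` (a list with element `molecules`).
#' @export
dataset <- function(molecules) {
  stopifnot(length(molecules) >= 1)
  ids <- vapply(molecules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate molecule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(molecules = molecules), class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  roles <- vapply(x$molecules, `[[`, character(1), "role")
  cat(sprintf("<qsar_dataset: %d molecules (%d train, %d test, %d unassigned)>\n",
              length(x$molecules), sum(roles == "train"),
              sum(roles == "test"), sum(roles == "unassigned")))
  invisible(x)
}

#' @export
length.qsar_dataset <- function(x) length(x$molecules)

dataset_ids <- function(ds) vapply(ds$molecules, `[[`, character(1), "id")

dataset_roles <- function(ds) vapply(ds$molecules, `[[`, character(1), "role")

dataset_activities <- function(ds) vapply(ds$molecules, `[[`, numeric(1), "pIC50")
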