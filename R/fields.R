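#' Build the shared field lattice
#'
#' The lattice extends at least `margin` Angstrom beyond every atom of
#' every molecule on all three axes, with points every `spacing` Angstrom.
#' The origin is anchored at `floor((min - margin)/spacing) * spacing` per
#' axis so that lattices are reproducible and translation-covariant.
#'
#' @param molecules `qsar_dataset` or list of aligned `qsar_mol`.
#' @param margin Angstrom beyond the union bounding box (default 4).
#' @param spacing lattice interval in Angstrom (default 2).
#' @return Object of class `qsar_grid`: list(origin, spacing, dims).
#' @export
build_grid <- function(molecules, margin = 4, spacing = 2) {
  if (inherits(molecules, "qsar_dataset")) molecules <- molecules$molecules
  if (inherits(molecules, "qsar_mol")) molecules <- list(molecules)
  if (!length(molecules)) stop("no molecules given")
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(molecules, coords_of))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  origin <- unname(floor(lo / spacing) * spacing)
  dims <- unname(pmax(2L, as.integer(ceiling((hi - origin) / spacing)) + 1L))
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "qsar_grid")
}

#' @export
print.qsar_grid <- function(x, ...) {
  cat(sprintf("<qsar_grid: %dx%dx%d points, spacing %g A, origin (%g, %g, %g)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Lattice point coordinates
#'
#' @param grid a `qsar_grid`.
#' @return n_points x 3 matrix; x varies fastest, then y, then z.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(a)
    grid$origin[a] + grid$spacing * (seq_len(grid$dims[a]) - 1L))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  as.matrix(pts)
}

n_grid_points <- function(grid) prod(grid$dims)

#' Probe specification for field calculations
#'
#' Defaults follow common grid-field practice: the Lennard-Jones probe is
#' an sp3 carbon (radius and well depth from [element_parameters()]) with
#' charge +1; fields are truncated at 30 kcal/mol; the similarity-field
#' probe has radius 1 Angstrom, charge +1, hydrophobicity +1, donor and
#' acceptor +1, with Gaussian attenuation alpha = 0.3 per square Angstrom.
#'
#' @param probe_radius,probe_well_depth Lennard-Jones probe parameters.
#' @param probe_charge probe charge in elementary units.
#' @param energy_cutoff truncation for steric/electrostatic fields
#'   (kcal/mol, positive).
#' @param attenuation_alpha Gaussian attenuation (1/A^2).
#' @param comsia_probe_radius similarity-probe radius (A).
#' @return list of class `qsar_probe`.
#' @export
probe_spec <- function(probe_radius = NULL, probe_well_depth = NULL,
                       probe_charge = 1, energy_cutoff = 30,
                       attenuation_alpha = 0.3, comsia_probe_radius = 1) {
  cpar <- lookup_element("C")
  if (is.null(probe_radius)) probe_radius <- cpar$vdw_radius
  if (is.null(probe_well_depth)) probe_well_depth <- cpar$well_depth
  stopifnot(energy_cutoff > 0, attenuation_alpha > 0)
  structure(list(probe_radius = probe_radius,
                 probe_well_depth = probe_well_depth,
                 probe_charge = probe_charge,
                 energy_cutoff = energy_cutoff,
                 attenuation_alpha = attenuation_alpha,
                 comsia_probe_radius = comsia_probe_radius),
            class = "qsar_probe")
}

as_points <- function(grid) {
  if (inherits(grid, "qsar_grid")) grid_points(grid) else as.matrix(grid)
}

atom_point_distances <- function(mol, pts) {
  xyz <- coords_of(mol)
  # n_atoms x n_points distance matrix
  d2 <- outer(rowSums(xyz^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(xyz)), rowSums(pts^2)) - 2 * xyz %*% t(pts)
  sqrt(pmax(d2, 0))
}

#' CoMFA steric (Lennard-Jones) field of one molecule
#'
#' Value at lattice point q: sum over atoms of
#' `eps_ip * ((R_ip/r)^12 - 2 (R_ip/r)^6)` with `R_ip = r_i + r_probe` and
#' `eps_ip = sqrt(eps_i * eps_probe)`, truncated to `+cutoff` (and floored
#' at `-cutoff`).  A lattice point coincident with an atom gets `+cutoff`.
#'
#' @param mol `qsar_mol` with vdW parameters set.
#' @param grid `qsar_grid`, or an n x 3 matrix of evaluation points.
#' @param probe `qsar_probe`.
#' @return numeric vector over lattice points (kcal/mol).
#' @export
comfa_steric <- function(mol, grid, probe = probe_spec()) {
  pts <- as_points(grid)
  r <- atom_point_distances(mol, pts)
  Rip <- mol$atoms$vdw_radius + probe$probe_radius
  eps <- sqrt(mol$atoms$well_depth * probe$probe_well_depth)
  coincident <- r < 1e-9
  r[coincident] <- 1e-9
  frac6 <- (Rip / r)^6
  e <- eps * (frac6^2 - 2 * frac6)
  v <- colSums(e)
  v[colSums(coincident) > 0] <- probe$energy_cutoff
  pmin(pmax(v, -probe$energy_cutoff), probe$energy_cutoff)
}

#' CoMFA electrostatic (Coulomb) field of one molecule
#'
#' Value at point q: `sum_i 332.0 * q_i * q_probe / r_iq`, clamped to
#' `+/- cutoff`.  Points whose companion steric value sits at `+cutoff`
#' (inside the molecule) are flagged in the attribute "excluded"; block
#' assembly replaces them by the training column mean.
#'
#' @param mol `qsar_mol` with charges assigned.
#' @param grid `qsar_grid`.
#' @param probe `qsar_probe`.
#' @param steric_field companion steric vector (computed when missing).
#' @return numeric vector with logical attribute "excluded".
#' @export
comfa_electrostatic <- function(mol, grid, probe = probe_spec(),
                                steric_field = NULL) {
  if (anyNA(mol$atoms$charge))
    stop("molecule '", mol$id, "': charges not assigned")
  if (is.null(steric_field)) steric_field <- comfa_steric(mol, grid, probe)
  pts <- as_points(grid)
  r <- atom_point_distances(mol, pts)
  r[r < 1e-9] <- 1e-9
  v <- colSums(COULOMB_K * mol$atoms$charge / r) * probe$probe_charge
  v <- pmin(pmax(v, -probe$energy_cutoff), probe$energy_cutoff)
  attr(v, "excluded") <- steric_field >= probe$energy_cutoff - 1e-12
  v
}

#' CoMSIA similarity fields of one molecule
#'
#' Five Gaussian-attenuated similarity indices: steric (atom property
#' r_vdw^3), electrostatic (partial charge), hydrophobic (atom
#' hydrophobicity), H-bond donor and acceptor (indicator).  Value at point
#' q for property k: `-sum_i w_probe * w_ik * exp(-alpha * r_iq^2)`.  No
#' cutoff is needed; the Gaussian decays smoothly.
#'
#' @param mol `qsar_mol` with charges/properties set.
#' @param grid `qsar_grid`.
#' @param probe `qsar_probe`.
#' @param kinds subset of c("S","E","H","D","A").
#' @return named list of numeric vectors over lattice points.
#' @export
comsia_fields <- function(mol, grid, probe = probe_spec(),
                          kinds = c("S", "E", "H", "D", "A")) {
  kinds <- match.arg(kinds, c("S", "E", "H", "D", "A"), several.ok = TRUE)
  if ("E" %in% kinds && anyNA(mol$atoms$charge))
    stop("molecule '", mol$id, "': charges not assigned")
  pts <- as_points(grid)
  r2 <- atom_point_distances(mol, pts)^2
  g <- exp(-probe$attenuation_alpha * r2)   # n_atoms x n_points
  props <- list(
    S = mol$atoms$vdw_radius^3,
    E = mol$atoms$charge,
    H = mol$atoms$hydrophobicity,
    D = as.numeric(mol$atoms$is_donor),
    A = as.numeric(mol$atoms$is_acceptor))
  out <- lapply(kinds, function(k) -colSums(props[[k]] * g))
  names(out) <- kinds
  out
}

#' Compute a set of field blocks for a dataset
#'
#' @param ds aligned `qsar_dataset` (charges assigned where needed).
#' @param grid `qsar_grid` shared by all molecules.
#' @param probe `qsar_probe`.
#' @param kinds field kinds among `comfa_steric`, `comfa_electrostatic`,
#'   `comsia_S`, `comsia_E`, `comsia_H`, `comsia_D`, `comsia_A`.
#' @param reference optional list of trained blocks whose electrostatic
#'   exclusion fill values (training column means) are reused, as needed
#'   when building descriptor rows for prediction.
#' @return named list of `qsar_field_block`: list(kind, values
#'   (molecules x points), grid, col_fill).
#' @export
compute_fields <- function(ds, grid, probe = probe_spec(),
                           kinds = c("comfa_steric", "comfa_electrostatic"),
                           reference = NULL) {
  all_kinds <- c("comfa_steric", "comfa_electrostatic",
                 paste0("comsia_", c("S", "E", "H", "D", "A")))
  kinds <- match.arg(kinds, all_kinds, several.ok = TRUE)
  mols <- ds$molecules
  np <- n_grid_points(grid)
  blocks <- list()
  steric_cache <- NULL
  if ("comfa_steric" %in% kinds || "comfa_electrostatic" %in% kinds) {
    steric_cache <- t(vapply(mols, comfa_steric, numeric(np),
                             grid = grid, probe = probe))
  }
  if ("comfa_steric" %in% kinds) {
    blocks$comfa_steric <- new_field_block("comfa_steric", steric_cache, grid)
  }
  if ("comfa_electrostatic" %in% kinds) {
    vals <- matrix(0, length(mols), np)
    excl <- matrix(FALSE, length(mols), np)
    for (m in seq_along(mols)) {
      v <- comfa_electrostatic(mols[[m]], grid, probe,
                               steric_field = steric_cache[m, ])
      excl[m, ] <- attr(v, "excluded")
      vals[m, ] <- as.numeric(v)
    }
    fill <- if (!is.null(reference$comfa_electrostatic$col_fill)) {
      reference$comfa_electrostatic$col_fill
    } else {
      compute_exclusion_fill(vals, excl)
    }
    for (j in seq_len(np)) {
      if (any(excl[, j])) vals[excl[, j], j] <- fill[j]
    }
    blocks$comfa_electrostatic <-
      new_field_block("comfa_electrostatic", vals, grid,
                      col_fill = fill, excluded = excl)
  }
  comsia_kinds <- intersect(kinds, paste0("comsia_", c("S","E","H","D","A")))
  if (length(comsia_kinds)) {
    letters_ <- sub("comsia_", "", comsia_kinds)
    per_mol <- lapply(mols, comsia_fields, grid = grid, probe = probe,
                      kinds = letters_)
    for (k in seq_along(comsia_kinds)) {
      vals <- t(vapply(per_mol, function(pm) pm[[letters_[k]]], numeric(np)))
      blocks[[comsia_kinds[k]]] <- new_field_block(comsia_kinds[k], vals, grid)
    }
  }
  blocks[kinds]
}

new_field_block <- function(kind, values, grid, col_fill = NULL,
                            excluded = NULL) {
  stopifnot(!anyNA(values))
  structure(list(kind = kind, values = values, grid = grid,
                 col_fill = col_fill, excluded = excluded),
            class = "qsar_field_block")
}

# Column mean over non-excluded molecules; all-excluded columns fall back
# to 0 (they carry no signal either way).
compute_exclusion_fill <- function(vals, excl) {
  vapply(seq_len(ncol(vals)), function(j) {
    keep <- !excl[, j]
    if (any(keep)) mean(vals[keep, j]) else 0
  }, numeric(1))
}

#' Export a field block as delimited text
#'
#' Writes the molecules x points matrix as TSV plus a sidecar `.grid.json`
#' descriptor (origin, spacing, dims, kind).
#'
#' @param block `qsar_field_block`.
#' @param path output TSV path.
#' @export
write_field_block <- function(block, path) {
  utils::write.table(block$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  desc <- list(kind = block$kind, origin = block$grid$origin,
               spacing = block$grid$spacing, dims = block$grid$dims)
  jsonlite::write_json(desc, paste0(path, ".grid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Contour maps (StDev * Coefficient) from a fitted model
#'
#' For each field block the per-point score is the column standard
#' deviation over training molecules times the model coefficient for that
#' column.  The favoured level is the smallest score s such that points
#' with score >= s carry 80 percent of the total positive score mass; the
#' disfavoured level analogously bounds the most negative points carrying
#' 20 percent of the negative mass.
#'
#' @param model a `qsar_pls` fitted on descriptors from
#'   [assemble_descriptors()].
#' @param desc the `qsar_descriptors` the model was fitted on.
#' @param favored_frac,disfavored_frac contribution fractions (defaults
#'   0.8 and 0.2).
#' @return named list per block: list(kind, score (per lattice point, 0
#'   for filtered columns), favored_level, disfavored_level, flagged).
#' @export
contour_maps <- function(model, desc, favored_frac = 0.8,
                         disfavored_frac = 0.2) {
  out <- list()
  for (b in unique(desc$block_labels)) {
    sel <- desc$block_labels == b
    # sd(raw) * beta(raw) == sd(scaled) * beta(scaled): scale cancels
    score_cols <- desc$col_sd[sel] * model$coefficients[sel]
    score <- numeric(length(desc$mask_by_block[[b]]))
    score[desc$mask_by_block[[b]]] <- score_cols
    lv <- contour_levels(score, favored_frac, disfavored_frac)
    out[[b]] <- list(kind = b, score = score,
                     favored_level = lv$favored,
                     disfavored_level = lv$disfavored,
                     favored_n = lv$favored_n,
                     disfavored_n = lv$disfavored_n,
                     flagged = lv$flagged)
  }
  out
}

contour_levels <- function(score, favored_frac, disfavored_frac) {
  pos <- score[score > 0]; neg <- score[score < 0]
  flagged <- FALSE
  if (!length(pos) && !length(neg)) {
    return(list(favored = 0, disfavored = 0, flagged = TRUE))
  }
  favored <- 0; favored_n <- 0L
  if (length(pos)) {
    s <- sort(pos, decreasing = TRUE)
    cum <- cumsum(s)
    favored_n <- which(cum >= favored_frac * sum(s) - 1e-12)[1]
    favored <- s[favored_n]
  } else flagged <- TRUE
  disfavored <- 0; disfavored_n <- 0L
  if (length(neg)) {
    s <- sort(neg)                       # most negative first
    cum <- cumsum(abs(s))
    disfavored_n <- which(cum >= disfavored_frac * sum(abs(s)) - 1e-12)[1]
    disfavored <- s[disfavored_n]
  }
  if (favored < disfavored) flagged <- TRUE
  list(favored = favored, disfavored = disfavored,
       favored_n = as.integer(favored_n),
       disfavored_n = as.integer(disfavored_n), flagged = flagged)
}

#' Write a contour map as a cube-style volumetric text file
#'
#' Plain-text format: a two-line header, then origin/axis records (in
#' Angstrom), then the scores in x-fastest order, six per line.
#'
#' @param map one entry of [contour_maps()] output.
#' @param grid the `qsar_grid` of the model descriptors.
#' @param path output path.
#' @export
write_contour_cube <- function(map, grid, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("qsar3d contour map: %s", map$kind),
               sprintf("favored_level %.6g disfavored_level %.6g",
                       map$favored_level, map$disfavored_level)), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 0,
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (a in 1:3) {
    ax <- c(0, 0, 0); ax[a] <- grid$spacing
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[a],
                       ax[1], ax[2], ax[3]), con)
  }
  vals <- sprintf("%13.5e", map$score)
  idx <- split(vals, ceiling(seq_along(vals) / 6))
  writeLines(vapply(idx, paste, character(1), collapse = " "), con)
  invisible(path)
}
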