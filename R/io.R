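#' Read 3D structures from an SDF (V2000) or MOL2 file
#'
#' Coordinates are taken as Angstrom.  MOL2 per-atom partial charges are
#' preserved when the charge column is present; SDF formal charges (M  CHG)
#' are recorded as the molecule's total formal charge.  Atom order is
#' preserved exactly as in the file.
#'
#' @param path file path.
#' @param format "sdf" or "mol2"; guessed from the extension when missing.
#' @return A list of [molecule()] objects.
#' @export
read_structures <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     stop("cannot guess format of ", path))
  }
  format <- match.arg(tolower(format), c("sdf", "mol2"))
  lines <- readLines(path)
  if (format == "sdf") parse_sdf(lines) else parse_mol2(lines)
}

parse_sdf <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  if (!length(ends)) { starts <- 1L; ends <- length(lines) + 1L }
  mols <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    rec <- lines[starts[m]:(ends[m] - 1L)]
    rec <- rec[cumsum(rec == "") < Inf]  # keep all; blank leading lines ok
    if (length(rec) < 4L)
      stop("SDF record ", m, ": truncated header")
    counts <- rec[4L]
    natom <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nbond <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(natom) || is.na(nbond))
      stop("SDF record ", m, ": unparseable counts line")
    if (length(rec) < 4L + natom + nbond)
      stop("SDF record ", m, ": truncated atom/bond block")
    at <- rec[4L + seq_len(natom)]
    x <- suppressWarnings(as.numeric(substr(at, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(at, 11, 20)))
    z <- suppressWarnings(as.numeric(substr(at, 21, 30)))
    el <- trimws(substr(at, 31, 34))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("SDF record ", m, ": missing 3D coordinates")
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
    if (nbond > 0) {
      bl <- rec[4L + natom + seq_len(nbond)]
      bi <- suppressWarnings(as.integer(substr(bl, 1, 3)))
      bj <- suppressWarnings(as.integer(substr(bl, 4, 6)))
      bo <- suppressWarnings(as.integer(substr(bl, 7, 9)))
      if (anyNA(bi) || anyNA(bj) || anyNA(bo))
        stop("SDF record ", m, ": unparseable bond block")
      bonds <- data.frame(i = bi, j = bj,
                          order = ifelse(bo == 4L, 1.5, as.numeric(bo)))
    }
    id <- trimws(rec[1L])
    if (!nzchar(id)) id <- paste0("mol", m)
    mols[[m]] <- molecule(
      id, data.frame(element = el, x = x, y = y, z = z,
                     stringsAsFactors = FALSE), bonds)
  }
  mols
}

parse_mol2 <- function(lines) {
  mstarts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(mstarts)) stop("no @<TRIPOS>MOLECULE record found")
  mends <- c(mstarts[-1] - 1L, length(lines))
  mols <- vector("list", length(mstarts))
  for (m in seq_along(mstarts)) {
    rec <- lines[mstarts[m]:mends[m]]
    id <- trimws(rec[2L])
    if (!nzchar(id)) id <- paste0("mol", m)
    asec <- section_lines(rec, "ATOM", m)
    atoms <- lapply(asec, function(ln) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 6L) stop("MOL2 record ", m, ": short ATOM line")
      type <- f[6L]
      el <- sub("\\..*$", "", type)
      chg <- if (length(f) >= 9L) suppressWarnings(as.numeric(f[9L]))
        else NA_real_
      suppressWarnings(data.frame(
        element = el, x = as.numeric(f[3L]), y = as.numeric(f[4L]),
        z = as.numeric(f[5L]), charge = chg, type = type,
        stringsAsFactors = FALSE))
    })
    atoms <- do.call(rbind, atoms)
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
      stop("MOL2 record ", m, ": missing 3D coordinates")
    bsec <- section_lines(rec, "BOND", m, required = FALSE)
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
    if (length(bsec)) {
      bonds <- do.call(rbind, lapply(bsec, function(ln) {
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        ord <- switch(f[4L], ar = 1.5, am = 1, as.numeric(f[4L]))
        data.frame(i = as.integer(f[2L]), j = as.integer(f[3L]), order = ord)
      }))
    }
    if (all(is.na(atoms$charge))) atoms$charge <- NULL
    mol2_type <- atoms$type; atoms$type <- NULL
    mol <- molecule(id, atoms, bonds)
    mol$mol2_type <- mol2_type
    mols[[m]] <- mol
  }
  mols
}

section_lines <- function(rec, name, m, required = TRUE) {
  tag <- paste0("@<TRIPOS>", name)
  i <- which(startsWith(rec, tag))
  if (!length(i)) {
    if (required) stop("MOL2 record ", m, ": missing ", tag, " section")
    return(character())
  }
  i <- i[1L] + 1L
  out <- character()
  while (i <= length(rec) && !startsWith(rec[i], "@<TRIPOS>")) {
    if (nzchar(trimws(rec[i]))) out <- c(out, rec[i])
    i <- i + 1L
  }
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' @param molecules a list of `qsar_mol` or a single molecule.
#' @param path output path.
#' @export
write_sdf <- function(molecules, path) {
  if (inherits(molecules, "qsar_mol")) molecules <- list(molecules)
  con <- file(path, "w"); on.exit(close(con))
  for (mol in molecules) {
    a <- mol$atoms; b <- mol$bonds
    writeLines(c(mol$id, "  qsar3d", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b)) {
      ord <- ifelse(b$order == 1.5, 4L, as.integer(b$order))
      writeLines(sprintf("%3d%3d%3d  0", b$i, b$j, ord), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read an activity table
#'
#' Comma- or tab-delimited text with a header.  Columns: `id`, then either
#' `ic50_uM` (micromolar IC50, converted to pIC50 = -log10(IC50 * 1e-6)) or
#' `pic50` (taken verbatim), and an optional `role` column
#' (train/test/unassigned).  When both activity columns are present,
#' explicit `pic50` values win and `ic50_uM` fills the gaps.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `pic50`, `role`.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!"id" %in% names(d)) stop("activity table must have an 'id' column")
  if (anyDuplicated(d$id))
    stop("duplicate id(s) in activity table: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  has_ic <- "ic50_uM" %in% names(d)
  has_p  <- "pic50" %in% names(d)
  if (!has_ic && !has_p)
    stop("activity table needs an 'ic50_uM' or 'pic50' column")
  pic50 <- rep(NA_real_, nrow(d))
  if (has_ic) {
    ic <- as.numeric(d$ic50_uM)
    bad <- !is.na(ic) & ic <= 0
    if (any(bad))
      stop("nonpositive IC50 for id(s): ", paste(d$id[bad], collapse = ", "))
    pic50 <- -log10(ic * 1e-6)
  }
  if (has_p) {
    p <- as.numeric(d$pic50)
    pic50[!is.na(p)] <- p[!is.na(p)]
  }
  role <- if ("role" %in% names(d)) d$role else rep("unassigned", nrow(d))
  role[is.na(role) | role == ""] <- "unassigned"
  if (!all(role %in% c("train", "test", "unassigned")))
    stop("role column must be train/test/unassigned")
  data.frame(id = as.character(d$id), pic50 = pic50, role = role,
             stringsAsFactors = FALSE)
}

#' Attach activities and roles to structures
#'
#' @param molecules list of `qsar_mol`.
#' @param activities data.frame from [read_activity_table()].
#' @return A `qsar_dataset` with pIC50 and role set per molecule.
#' @export
attach_activities <- function(molecules, activities) {
  ids <- vapply(molecules, `[[`, character(1), "id")
  idx <- match(ids, activities$id)
  for (k in seq_along(molecules)) {
    if (!is.na(idx[k])) {
      molecules[[k]]$pIC50 <- activities$pic50[idx[k]]
      molecules[[k]]$role  <- activities$role[idx[k]]
    }
  }
  dataset(molecules)
}

#' Read a core-atom mapping file
#'
#' Tab-delimited, no header: `mol_id  mol_atom_index  template_atom_index`
#' with 0-based atom indices (converted to 1-based on read).
#'
#' @param path file path.
#' @return named list (by molecule id) of two-column integer matrices
#'   `cbind(mol_atom, template_atom)`, 1-based.
#' @export
read_core_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("mol_id", "mol_atom", "tpl_atom"),
                         stringsAsFactors = FALSE)
  split_idx <- split(seq_len(nrow(d)), d$mol_id)
  lapply(split_idx, function(rows)
    cbind(mol_atom = d$mol_atom[rows] + 1L,
          template_atom = d$tpl_atom[rows] + 1L))
}

#' Write molecules to a MOL2 file (with partial charges)
#'
#' @param molecules a list of `qsar_mol` or a single molecule.
#' @param path output path.
#' @export
write_mol2 <- function(molecules, path) {
  if (inherits(molecules, "qsar_mol")) molecules <- list(molecules)
  con <- file(path, "w"); on.exit(close(con))
  for (mol in molecules) {
    a <- mol$atoms; b <- mol$bonds
    chg_type <- if (all(is.na(a$charge))) "NO_CHARGES" else "USER_CHARGES"
    writeLines(c("@<TRIPOS>MOLECULE", mol$id,
                 sprintf("%5d %5d     0     0     0", nrow(a), nrow(b)),
                 "SMALL", chg_type, "", "@<TRIPOS>ATOM"), con)
    chg <- ifelse(is.na(a$charge), 0, a$charge)
    writeLines(sprintf("%7d %-8s %10.4f %10.4f %10.4f %-6s 1 MOL %10.6f",
                       seq_len(nrow(a)), paste0(a$element, seq_len(nrow(a))),
                       a$x, a$y, a$z, a$element, chg), con)
    writeLines("@<TRIPOS>BOND", con)
    if (nrow(b)) {
      ord <- ifelse(b$order == 1.5, "ar", format(as.integer(b$order)))
      writeLines(sprintf("%6d %5d %5d %s", seq_len(nrow(b)), b$i, b$j, ord),
                 con)
    }
  }
  invisible(path)
}
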