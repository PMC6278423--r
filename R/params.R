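#' Element parameter table
#'
#' Per-element Lennard-Jones and atom-property parameters used by the field
#' kernels.  Values follow the Tripos-style force-field conventions commonly
#' used for grid-field QSAR: van der Waals radii in Angstrom, well depths in
#' kcal/mol, and a coarse per-element hydrophobicity contribution
#' (dimensionless, positive = lipophilic).  The table covers H, C, N, O, S,
#' P, F, Cl, Br, I and Si.
#'
#' @return A data.frame with columns `element`, `vdw_radius`, `well_depth`
#'   and `hydrophobicity`.
#' @export
element_parameters <- function() {
  data.frame(
    element        = c("H",   "C",   "N",   "O",   "S",   "P",
                       "F",   "Cl",  "Br",  "I",   "Si"),
    vdw_radius     = c(1.50,  1.70,  1.55,  1.52,  1.80,  1.80,
                       1.47,  1.75,  1.85,  1.98,  2.10),
    well_depth     = c(0.042, 0.107, 0.095, 0.116, 0.314, 0.314,
                       0.109, 0.314, 0.434, 0.623, 0.402),
    hydrophobicity = c(0.10,  0.50, -0.50, -0.40,  0.40,  0.20,
                       0.30,  0.65,  0.85,  1.00,  0.40),
    stringsAsFactors = FALSE
  )
}

# PEOE (partial equalization of orbital electronegativity) parameters.
# Electronegativity of an atom carrying charge Q is chi(Q) = a + b*Q + c*Q^2
# (eV); the cation electronegativity a + b + c normalises the charge
# transferred along a bond, except for hydrogen where the conventional
# value 20.02 is used.  Parameters per element and hybridisation from the
# original PEOE parameterisation.
peoe_parameters <- function() {
  data.frame(
    element = c("H",
                "C",   "C",   "C",
                "N",   "N",   "N",
                "O",   "O",
                "F",   "Cl",  "Br",  "I",
                "S",   "P",   "Si"),
    hyb     = c("any",
                "sp3", "sp2", "sp",
                "sp3", "sp2", "sp",
                "sp3", "sp2",
                "any", "any", "any", "any",
                "any", "any", "any"),
    a = c(7.17,
          7.98,  8.79, 10.39,
          11.54, 12.87, 15.68,
          14.18, 17.07,
          14.66, 11.00, 10.08,  9.90,
          10.14,  8.90,  7.30),
    b = c(6.24,
          9.18,  9.32,  9.45,
          10.82, 11.15, 11.70,
          12.92, 13.79,
          13.85,  9.69,  8.47,  7.96,
          9.13,  8.24,  6.57),
    c = c(-0.56,
          1.88,  1.51,  0.73,
          1.36,  0.85, -0.27,
          1.39,  0.47,
          2.31,  1.35,  1.16,  0.96,
          1.38,  0.96,  0.66),
    stringsAsFactors = FALSE
  )
}

# Coulomb constant, kcal * Angstrom / (mol * e^2)
COULOMB_K <- 332.0

lookup_element <- function(elements) {
  tab <- element_parameters()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    stop("no parameters for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}
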