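#' Assign Gasteiger (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativity over the
#' sigma framework.  At iteration k, each bond transfers charge
#' `(chi_j - chi_i) / chi_plus * (1/2)^k` from the less to the more
#' electronegative atom, where `chi_plus` is the cation electronegativity
#' of the less electronegative partner (20.02 for hydrogen).  Pi (Hueckel)
#' charges are not computed: conjugated systems receive plain PEOE charges.
#'
#' @param mol a `qsar_mol` with bonds.
#' @param formal_charges optional per-atom integer formal charges (default
#'   all zero); the final charges sum to their total.
#' @param n_iter number of damped iterations (default 6, the published
#'   PEOE default; damping halves each transferred increment per
#'   iteration).
#' @return The molecule with `atoms$charge` set.
#' @export
gasteiger_charges <- function(mol, formal_charges = NULL, n_iter = 6L) {
  a <- mol$atoms
  n <- nrow(a)
  if (is.null(formal_charges)) formal_charges <- rep(0, n)
  stopifnot(length(formal_charges) == n)
  hyb <- infer_hybridization(a$element, mol$bonds)
  par <- peoe_parameters()
  key <- ifelse(paste(a$element, hyb) %in% paste(par$element, par$hyb),
                paste(a$element, hyb), paste(a$element, "any"))
  idx <- match(key, paste(par$element, par$hyb))
  if (anyNA(idx)) {
    stop("no PEOE parameters for element(s): ",
         paste(unique(a$element[is.na(idx)]), collapse = ", "))
  }
  pa <- par$a[idx]; pb <- par$b[idx]; pc <- par$c[idx]
  chi_plus <- ifelse(a$element == "H", 20.02, pa + pb + pc)
  q <- as.numeric(formal_charges)
  b <- mol$bonds
  damp <- 1
  for (k in seq_len(n_iter)) {
    damp <- damp * 0.5
    chi <- pa + pb * q + pc * q^2
    dq <- numeric(n)
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      if (chi[j] >= chi[i]) {
        d <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
      } else {
        d <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
      }
    }
    q <- q + dq
  }
  mol$atoms$charge <- q
  mol
}

# sp if any triple bond or two double bonds; sp2 if any double or aromatic
# bond; else sp3.  MOL2 atom types (C.2, N.ar, ...) override when present.
infer_hybridization <- function(elements, bonds, mol2_type = NULL) {
  n <- length(elements)
  hyb <- rep("sp3", n)
  if (nrow(bonds)) {
    ndouble <- numeric(n); ntriple <- numeric(n); narom <- numeric(n)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]; o <- bonds$order[r]
      if (o == 2) { ndouble[i] <- ndouble[i] + 1; ndouble[j] <- ndouble[j] + 1 }
      if (o == 3) { ntriple[i] <- ntriple[i] + 1; ntriple[j] <- ntriple[j] + 1 }
      if (o == 1.5) { narom[i] <- narom[i] + 1; narom[j] <- narom[j] + 1 }
    }
    hyb[ndouble >= 1 | narom >= 1] <- "sp2"
    hyb[ntriple >= 1 | ndouble >= 2] <- "sp"
  }
  hyb
}
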