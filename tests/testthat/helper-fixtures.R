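# shared builders for tiny in-code fixtures

simple_mol <- function(elements, xyz, charges = NULL, bonds = NULL,
                       id = "m1", ...) {
  atoms <- data.frame(element = elements,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(charges)) atoms$charge <- charges
  molecule(id, atoms, bonds = bonds, ...)
}

# methane with idealised tetrahedral geometry; C bonded to 4 H
methane <- function() {
  s <- 1.09 / sqrt(3)
  simple_mol(c("C", "H", "H", "H", "H"),
             rbind(c(0, 0, 0), c(s, s, s), c(s, -s, -s),
                   c(-s, s, -s), c(-s, -s, s)),
             bonds = data.frame(i = 1L, j = 2:5, order = 1))
}

# ethanol heavy-atom skeleton + hydrogens, atom order C C O H H H H H H
ethanol <- function() {
  xyz <- rbind(
    c(-0.89, 0.12, 0.00), c(0.52, -0.40, 0.00), c(1.44, 0.68, 0.00),
    c(-1.00, 0.75, 0.88), c(-1.00, 0.75, -0.88), c(-1.62, -0.69, 0.00),
    c(0.67, -1.03, 0.88), c(0.67, -1.03, -0.88), c(2.33, 0.33, 0.00))
  simple_mol(c("C", "C", "O", rep("H", 6)), xyz,
             bonds = data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3),
                                j = c(2, 3, 4, 5, 6, 7, 8, 9), order = 1))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y)),
        c(2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x)),
        c(2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)))
}

rigid_transform <- function(xyz, R, t) {
  xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
}

# independent PLS oracle: with c components and univariate y, the PLS
# fit equals least squares of centred y on the Krylov subspace
# span{s, Ms, M^2 s, ...} of M = Xc'Xc applied to s = Xc'yc
krylov_pls_predict <- function(X, y, c, newdata = X) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  s <- crossprod(Xc, yc)
  M <- crossprod(Xc)
  V <- matrix(0, ncol(X), c)
  v <- s
  for (a in seq_len(c)) { V[, a] <- v; v <- M %*% v }
  V <- qr.Q(qr(V))                       # orthonormal basis, same span
  T_ <- Xc %*% V
  beta_t <- qr.coef(qr(T_), yc)
  beta <- V %*% beta_t
  sweep(newdata, 2, xm) %*% beta + ym
}

# build training descriptors + activities for a synthetic series
synth_training <- function(seed = 1, n = 30, noise_sd = 0.1,
                           min_sigma = 2) {
  spec <- synthetic_spec(n_molecules = n, noise_sd = noise_sd, seed = seed)
  ds <- generate_activities(generate_toy_series(spec), spec)
  truth <- attr(ds, "truth")
  tr <- which(dataset_roles(ds) == "train")
  blocks <- compute_fields(ds, truth$grid,
                           kinds = c("comfa_steric", "comfa_electrostatic"))
  tb <- lapply(blocks, function(b) {
    b$values <- b$values[tr, , drop = FALSE]
    if (!is.null(b$excluded)) {
      b$excluded <- b$excluded[tr, , drop = FALSE]
      b$col_fill <- compute_exclusion_fill(b$values, b$excluded)
    }
    b
  })
  desc <- assemble_descriptors(tb, min_sigma = min_sigma)
  list(ds = ds, truth = truth, train = tr, desc = desc,
       y = dataset_activities(ds)[tr])
}
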