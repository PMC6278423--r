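test_that("grid construction covers atoms plus margin on every axis", {
  m <- simple_mol("C", matrix(0, 1, 3))
  g <- build_grid(m, margin = 4, spacing = 2)
  expect_equal(unname(g$origin), c(-4, -4, -4))
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_identical(nrow(grid_points(g)), 125L)

  m2 <- simple_mol(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)))
  g2 <- build_grid(m2, margin = 4, spacing = 2)
  expect_equal(g2$dims[1], 7L)         # x extent [-4, 7] -> 7 points
  expect_equal(g2$origin[1], -4)
  expect_gte(max(grid_points(g2)[, 1]), 3 + 4)

  # translation covariance for shifts on the lattice
  m3 <- simple_mol(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)) +
                     matrix(c(6, -2, 4), 2, 3, byrow = TRUE))
  g3 <- build_grid(m3, margin = 4, spacing = 2)
  expect_equal(g3$origin, g2$origin + c(6, -2, 4))
  expect_equal(g3$dims, g2$dims)
  expect_error(build_grid(list()), "no molecules")
})

test_that("steric field: LJ minimum, distant decay, coincidence cutoff", {
  probe <- probe_spec()
  m <- simple_mol("C", matrix(0, 1, 3))
  Rip <- 1.70 + probe$probe_radius
  eps <- sqrt(0.107 * probe$probe_well_depth)
  # point exactly at the LJ minimum distance: value is -eps
  v <- comfa_steric(m, matrix(c(Rip, 0, 0), 1, 3), probe)
  expect_equal(as.numeric(v), -eps, tolerance = 1e-12)
  # all points >= 12 A away: tiny negative tail
  far <- matrix(c(12, 0, 0, 0, 15, 0, 0, 0, 20), 3, 3, byrow = TRUE)
  vf <- comfa_steric(m, far, probe)
  expect_true(all(vf <= 0 & vf > -1e-3))
  # coincident lattice point gets +cutoff
  v0 <- comfa_steric(m, matrix(0, 1, 3), probe)
  expect_equal(as.numeric(v0), 30)
})

test_that("electrostatic field: zero charges, linearity, clamping", {
  probe <- probe_spec()
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  m0 <- simple_mol(c("C", "O"), xyz, charges = c(0, 0))
  pts <- matrix(rnorm(30, sd = 6), 10, 3)
  expect_true(all(comfa_electrostatic(m0, pts, probe) == 0))

  q <- c(0.3, -0.2)
  mq <- simple_mol(c("C", "O"), xyz, charges = q)
  mn <- simple_mol(c("C", "O"), xyz, charges = -q)
  vq <- comfa_electrostatic(mq, pts, probe)
  vn <- comfa_electrostatic(mn, pts, probe)
  expect_equal(as.numeric(vq), -as.numeric(vn), tolerance = 1e-12)

  # single +0.5 charge at 4 A: 332 * 0.5 / 4 = 41.5, clamped to 30
  mhalf <- simple_mol("C", matrix(0, 1, 3), charges = 0.5)
  vc <- comfa_electrostatic(mhalf, matrix(c(4, 0, 0), 1, 3), probe)
  expect_equal(as.numeric(vc), 30)
  expect_error(comfa_electrostatic(simple_mol("C", matrix(0, 1, 3)), pts),
               "charges not assigned")
})

test_that("similarity fields match hand values and a double-loop oracle", {
  probe <- probe_spec()
  m1 <- simple_mol("C", matrix(0, 1, 3), charges = 0.25)
  # property w at distance 0, probe +1 -> value -w (steric prop r^3)
  v <- comsia_fields(m1, matrix(0, 1, 3), probe)
  expect_equal(as.numeric(v$S), -1.70^3, tolerance = 1e-12)
  expect_equal(as.numeric(v$E), -0.25, tolerance = 1e-12)
  # doubling the distance multiplies by exp(-3 alpha r^2)
  r <- 1.3
  v1 <- comsia_fields(m1, matrix(c(r, 0, 0), 1, 3), probe)$S
  v2 <- comsia_fields(m1, matrix(c(2 * r, 0, 0), 1, 3), probe)$S
  expect_equal(as.numeric(v2 / v1), exp(-3 * probe$attenuation_alpha * r^2),
               tolerance = 1e-12)

  set.seed(21)
  m3 <- simple_mol(c("C", "N", "O"), matrix(rnorm(9), 3, 3),
                   charges = rnorm(3, sd = 0.3))
  pts <- matrix(rnorm(45, sd = 3), 15, 3)
  got <- comsia_fields(m3, pts, probe)
  props <- list(S = m3$atoms$vdw_radius^3, E = m3$atoms$charge,
                H = m3$atoms$hydrophobicity,
                D = as.numeric(m3$atoms$is_donor),
                A = as.numeric(m3$atoms$is_acceptor))
  for (k in names(props)) {
    oracle <- numeric(nrow(pts))
    for (p in seq_len(nrow(pts))) {
      acc <- 0
      for (a in 1:3) {
        d2 <- sum((coords_of(m3)[a, ] - pts[p, ])^2)
        acc <- acc - props[[k]][a] * exp(-probe$attenuation_alpha * d2)
      }
      oracle[p] <- acc
    }
    expect_equal(as.numeric(got[[k]]), oracle, tolerance = 1e-12)
  }
})

test_that("steric and electrostatic kernels match a naive double loop", {
  set.seed(22)
  probe <- probe_spec()
  m <- simple_mol(c("C", "N", "O", "S"), matrix(rnorm(12, sd = 2), 4, 3),
                  charges = rnorm(4, sd = 0.3))
  pts <- matrix(rnorm(60, sd = 4), 20, 3)
  sv <- as.numeric(comfa_steric(m, pts, probe))
  ev <- as.numeric(comfa_electrostatic(m, pts, probe))
  par <- m$atoms
  for (p in seq_len(nrow(pts))) {
    s_acc <- 0; e_acc <- 0
    for (a in 1:4) {
      r <- sqrt(sum((coords_of(m)[a, ] - pts[p, ])^2))
      Rip <- par$vdw_radius[a] + probe$probe_radius
      eps <- sqrt(par$well_depth[a] * probe$probe_well_depth)
      s_acc <- s_acc + eps * ((Rip / r)^12 - 2 * (Rip / r)^6)
      e_acc <- e_acc + 332.0 * par$charge[a] / r
    }
    expect_equal(sv[p], min(max(s_acc, -30), 30), tolerance = 1e-12)
    expect_equal(ev[p], min(max(e_acc, -30), 30), tolerance = 1e-12)
  }
})

test_that("fields are invariant under rigid motion of molecule and lattice", {
  set.seed(23)
  probe <- probe_spec()
  m <- simple_mol(c("C", "N", "O"), matrix(rnorm(9, sd = 2), 3, 3),
                  charges = c(0.2, -0.3, 0.1))
  pts <- matrix(rnorm(90, sd = 4), 30, 3)
  R <- random_rotation(); tv <- c(3, -1, 2)
  mR <- set_coords(m, rigid_transform(coords_of(m), R, tv))
  ptsR <- rigid_transform(pts, R, tv)
  expect_equal(as.numeric(comfa_steric(mR, ptsR, probe)),
               as.numeric(comfa_steric(m, pts, probe)), tolerance = 1e-9)
  expect_equal(as.numeric(comfa_electrostatic(mR, ptsR, probe)),
               as.numeric(comfa_electrostatic(m, pts, probe)),
               tolerance = 1e-9)
  fR <- comsia_fields(mR, ptsR, probe)
  f0 <- comsia_fields(m, pts, probe)
  for (k in names(f0))
    expect_equal(as.numeric(fR[[k]]), as.numeric(f0[[k]]), tolerance = 1e-9)
})

test_that("field kernels are additive over fragments", {
  set.seed(24)
  probe <- probe_spec()
  xyz <- matrix(rnorm(18, sd = 3), 6, 3)
  q <- rnorm(6, sd = 0.2)
  el <- c("C", "C", "N", "O", "S", "C")
  whole <- simple_mol(el, xyz, charges = q)
  f1 <- simple_mol(el[1:3], xyz[1:3, ], charges = q[1:3])
  f2 <- simple_mol(el[4:6], xyz[4:6, ], charges = q[4:6])
  pts <- matrix(rnorm(30, sd = 8), 10, 3)
  # keep points away from the cutoff regime so truncation cannot break sums
  s_whole <- comfa_steric(whole, pts, probe)
  keep <- abs(s_whole) < 29
  expect_equal(as.numeric(s_whole)[keep],
               (as.numeric(comfa_steric(f1, pts, probe)) +
                  as.numeric(comfa_steric(f2, pts, probe)))[keep],
               tolerance = 1e-9)
  cw <- comsia_fields(whole, pts, probe)$S
  expect_equal(as.numeric(cw),
               as.numeric(comsia_fields(f1, pts, probe)$S) +
                 as.numeric(comsia_fields(f2, pts, probe)$S),
               tolerance = 1e-12)
})

test_that("truncation bounds and CoMSIA distant decay hold", {
  set.seed(25)
  probe <- probe_spec()
  spec <- synthetic_spec(n_molecules = 8, seed = 3)
  ds <- generate_toy_series(spec)
  g <- build_grid(ds)
  blocks <- compute_fields(ds, g, probe,
                           kinds = c("comfa_steric", "comfa_electrostatic"))
  expect_true(all(blocks$comfa_steric$values <= 30 + 1e-12))
  expect_true(all(abs(blocks$comfa_electrostatic$values) <= 30 + 1e-12))
  expect_false(anyNA(blocks$comfa_steric$values))
  # 20 A away everything Gaussian has decayed below 1e-10
  far <- matrix(c(25, 25, 25), 1, 3)
  m <- ds$molecules[[1]]
  m <- set_coords(m, sweep(coords_of(m), 2, colMeans(coords_of(m))))
  f <- comsia_fields(m, far, probe)
  expect_true(all(vapply(f, function(v) max(abs(v)), numeric(1)) < 1e-10))
})

test_that("excluded electrostatic cells take the training column mean", {
  probe <- probe_spec()
  # one atom sits exactly on a lattice point for molecule 1 only
  m1 <- simple_mol("C", matrix(c(0, 0, 0), 1, 3), charges = 0.4, id = "a")
  m2 <- simple_mol("C", matrix(c(0.9, 0, 0), 1, 3), charges = -0.2, id = "b")
  m3 <- simple_mol("C", matrix(c(-0.7, 0.2, 0), 1, 3), charges = 0.1, id = "c")
  ds <- dataset(list(m1, m2, m3))
  g <- build_grid(ds, margin = 2, spacing = 2)
  blocks <- compute_fields(ds, g, probe,
                           kinds = c("comfa_steric", "comfa_electrostatic"))
  excl <- blocks$comfa_electrostatic$excluded
  expect_true(any(excl))
  j <- which(colSums(excl) > 0 & colSums(excl) < 3)[1]
  vals <- blocks$comfa_electrostatic$values[, j]
  fill <- blocks$comfa_electrostatic$col_fill[j]
  expect_equal(unname(vals[excl[, j]]),
               rep(fill, sum(excl[, j])), tolerance = 1e-12)
})

test_that("contour levels match a brute-force cumulative oracle", {
  brute_levels <- function(score, ffrac = 0.8, dfrac = 0.2) {
    pos <- sort(score[score > 0], decreasing = TRUE)
    fav <- NA_real_
    for (i in seq_along(pos)) {
      if (sum(pos[1:i]) >= ffrac * sum(pos) - 1e-12) { fav <- pos[i]; break }
    }
    neg <- sort(score[score < 0])
    dis <- NA_real_
    for (i in seq_along(neg)) {
      if (sum(abs(neg[1:i])) >= dfrac * sum(abs(neg)) - 1e-12) {
        dis <- neg[i]; break
      }
    }
    list(favored = fav, disfavored = dis)
  }
  set.seed(26)
  for (rep in 1:5) {
    score <- rnorm(100)
    got <- qsar3d:::contour_levels(score, 0.8, 0.2)
    want <- brute_levels(score)
    expect_equal(got$favored, want$favored)
    expect_equal(got$disfavored, want$disfavored)
  }
  # all equal positive scores: favored set has ceil(0.8 n) points
  eq <- rep(2, 10)
  lv <- qsar3d:::contour_levels(eq, 0.8, 0.2)
  expect_equal(lv$favored_n, ceiling(0.8 * 10))
})

test_that("contour maps from a fitted model honour the scoring rule", {
  st <- synth_training(seed = 9)
  model <- fit_qsar(st$desc, st$y, c_max = 5)
  maps <- contour_maps(model, st$desc)
  expect_named(maps, unique(st$desc$block_labels))
  for (b in names(maps)) {
    sel <- st$desc$block_labels == b
    expected <- st$desc$col_sd[sel] * model$coefficients[sel]
    got <- maps[[b]]$score[st$desc$mask_by_block[[b]]]
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
    expect_gte(maps[[b]]$favored_level, maps[[b]]$disfavored_level)
  }
  # single nonzero coefficient: the favored region is exactly that point
  fake <- model
  fake$coefficients <- numeric(length(model$coefficients))
  fake$coefficients[5] <- 1
  m2 <- contour_maps(fake, st$desc)
  b5 <- st$desc$block_labels[5]
  expect_equal(sum(m2[[b5]]$score >= m2[[b5]]$favored_level &
                     m2[[b5]]$score > 0), 1L)
})
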