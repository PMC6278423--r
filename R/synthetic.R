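#' Specification for a synthetic aligned molecule series
#'
#' Describes a toy series: a shared rigid scaffold plus per-molecule
#' pseudo-substituent atoms at designated sites, with activities generated
#' downstream by a sparse linear model over grid-field values.  Defaults
#' emulate the kind of series the package targets: ~30 compounds, three
#' substituent sites, activities spanning roughly pIC50 2.6-8.5 with
#' 0.1-unit Gaussian noise.
#'
#' @param n_molecules number of molecules (>= 8; default 30).
#' @param scaffold_size number of scaffold atoms (default 8).
#' @param n_sites substituent site count (default 3).
#' @param site_positions optional n_sites x 3 matrix of site centres
#'   (Angstrom); default sites are spread around the scaffold.
#' @param n_effect_cols number of informative grid columns (default 3).
#' @param effect_cols optional explicit grid-point indices of the
#'   informative columns (into the steric block).
#' @param effect_coefs true coefficients, applied per unit standard
#'   deviation of each informative column so that all designated columns
#'   contribute comparable signal (default c(1, -0.8, 0.6)).
#' @param micro_jitter per-molecule positional jitter on substituent
#'   atoms, Angstrom (default 0.05; thermal-scale placement noise).
#' @param noise_sd Gaussian noise on the activity, pIC50 units
#'   (default 0.1).
#' @param activity_range target observed span (default c(2.62, 8.52)).
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return list of class `qsar_synth_spec`.
#' @export
synthetic_spec <- function(n_molecules = 30, scaffold_size = 8, n_sites = 3,
                           site_positions = NULL, n_effect_cols = 3,
                           effect_cols = NULL,
                           effect_coefs = c(1, -0.8, 0.6),
                           micro_jitter = 0.05, noise_sd = 0.1,
                           activity_range = c(2.62, 8.52), seed = 1) {
  stopifnot(n_molecules >= 8, noise_sd >= 0, scaffold_size >= 4,
            n_sites >= 0)
  if (is.null(site_positions) && n_sites > 0) {
    base <- rbind(c(3.5, 0, 0), c(-3.5, 1.5, 0), c(0, 3.5, 1.5),
                  c(0, -3.5, -1.5), c(1.5, 1.5, 3.5))
    site_positions <- base[seq_len(min(n_sites, nrow(base))), , drop = FALSE]
    if (n_sites > nrow(base))
      stop("supply site_positions for more than ", nrow(base), " sites")
  }
  if (n_sites > 1) {
    dmin <- min(stats::dist(site_positions))
    if (dmin < 1) stop("impossible geometry: substituent sites overlap")
  }
  structure(list(n_molecules = n_molecules, scaffold_size = scaffold_size,
                 n_sites = n_sites, site_positions = site_positions,
                 n_effect_cols = n_effect_cols, effect_cols = effect_cols,
                 effect_coefs = effect_coefs, micro_jitter = micro_jitter,
                 noise_sd = noise_sd,
                 activity_range = activity_range, seed = seed),
            class = "qsar_synth_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

# deterministic rigid scaffold: atoms on a zig-zag ladder, mixed elements
scaffold_atoms <- function(size) {
  k <- seq_len(size) - 1L
  elements <- rep(c("C", "C", "N", "C", "O", "C"), length.out = size)
  data.frame(
    element = elements,
    x = 1.4 * (k %% 4) - 2.1,
    y = 1.2 * (k %/% 4) - 0.6,
    z = 0.5 * ((k %% 2) * 2 - 1),
    charge = rep(c(0.05, -0.02, -0.3, 0.1, -0.35, 0.02),
                 length.out = size),
    stringsAsFactors = FALSE)
}

#' Generate an aligned synthetic molecule series
#'
#' All molecules share an identical rigid scaffold (hence are pre-aligned)
#' and differ in pseudo-substituent atoms near the designated sites.
#' Mimicking an R-group series built from a small substituent library,
#' each seed first draws a per-site library of two discrete poses (offset
#' N(0, 0.5 A) from the site centre, with a pose-specific element); each
#' molecule then occupies each site with probability 0.8 by one of the
#' library poses, plus a small per-molecule micro-jitter and a random
#' partial charge.  The discrete pose library keeps the field matrix
#' close to low rank, so a sparse linear activity over it is exactly
#' learnable from noiseless data; coordinates still differ across seeds
#' and molecules.  Output is deterministic under the spec seed.
#'
#' @param spec a `qsar_synth_spec`.
#' @return `qsar_dataset` of charged, aligned molecules with roles
#'   assigned 4:1 train:test (every fifth molecule is test).
#' @export
generate_toy_series <- function(spec) {
  stopifnot(inherits(spec, "qsar_synth_spec"))
  with_seed(spec$seed, {
    scaf <- scaffold_atoms(spec$scaffold_size)
    elems <- c("C", "N", "O", "S", "F", "Cl")
    n_pose <- 2L
    poses <- vector("list", spec$n_sites)
    if (spec$n_sites > 0) {
      for (s in seq_len(spec$n_sites)) {
        poses[[s]] <- list(
          offset = matrix(stats::rnorm(3 * n_pose, 0, 0.5), n_pose, 3),
          element = sample(elems, n_pose, replace = TRUE))
      }
    }
    mols <- vector("list", spec$n_molecules)
    for (m in seq_len(spec$n_molecules)) {
      atoms <- scaf
      if (spec$n_sites > 0) {
        for (s in seq_len(spec$n_sites)) {
          if (stats::runif(1) < 0.8) {
            k <- sample.int(n_pose, 1)
            pos <- spec$site_positions[s, ] + poses[[s]]$offset[k, ] +
              stats::rnorm(3, 0, spec$micro_jitter)
            atoms <- rbind(atoms, data.frame(
              element = poses[[s]]$element[k],
              x = pos[1], y = pos[2], z = pos[3],
              charge = stats::rnorm(1, 0, 0.15),
              stringsAsFactors = FALSE))
          }
        }
      }
      role <- if (m %% 5 == 0) "test" else "train"
      mols[[m]] <- molecule(sprintf("syn%02d", m), atoms, role = role)
    }
    dataset(mols)
  })
}

#' Generate activities from a sparse linear model over grid fields
#'
#' Computes CoMFA steric fields on the series' own lattice, forms the
#' linear signal `sum(coef * field[, effect_col])`, rescales it affinely
#' to the target activity span, and adds Gaussian noise.  With zero
#' noise, y is exactly affine in the designated field columns.
#'
#' @param ds dataset from [generate_toy_series()].
#' @param spec the `qsar_synth_spec` used to build it.
#' @param probe `qsar_probe` for the field computation.
#' @return The dataset with pIC50 set; attribute "truth" records the
#'   effect columns, coefficients, grid and noiseless signal.
#' @export
generate_activities <- function(ds, spec, probe = probe_spec()) {
  grid <- build_grid(ds)
  blocks <- compute_fields(ds, grid, probe, kinds = "comfa_steric")
  V <- blocks$comfa_steric$values
  cols <- spec$effect_cols
  if (is.null(cols)) {
    cols <- pick_effect_columns(V, spec$n_effect_cols)
  }
  if (any(cols < 1 | cols > ncol(V)))
    stop("effect column outside the grid (1..", ncol(V), ")")
  coefs <- rep_len(spec$effect_coefs, length(cols))
  # per-unit-sd application: every informative column contributes
  # comparable signal regardless of its raw field variance
  csd <- apply(V[, cols, drop = FALSE], 2, stats::sd)
  if (all(csd > 0)) coefs <- coefs / csd * mean(csd)
  signal <- as.numeric(V[, cols, drop = FALSE] %*% coefs)
  if (diff(range(signal)) < 1e-9)
    stop("degenerate signal: effect columns carry no variance")
  lo <- spec$activity_range[1]; hi <- spec$activity_range[2]
  y0 <- lo + (signal - min(signal)) / diff(range(signal)) * (hi - lo)
  y <- with_seed(spec$seed + 1L,
                 y0 + stats::rnorm(length(y0), 0, spec$noise_sd))
  for (m in seq_along(ds$molecules)) ds$molecules[[m]]$pIC50 <- y[m]
  attr(ds, "truth") <- list(effect_cols = cols, coefs = coefs, grid = grid,
                            signal = y0)
  ds
}

# informative columns: highest-variance grid columns, greedily skipping
# candidates correlated (|r| >= 0.5) with an already-picked one, so that
# coefficient attribution stays well-posed
pick_effect_columns <- function(V, k) {
  s <- apply(V, 2, stats::sd)
  ord <- order(s, decreasing = TRUE)
  picked <- integer()
  for (j in ord) {
    if (s[j] <= 0) break
    ok <- all(vapply(picked, function(p)
      abs(stats::cor(V[, j], V[, p])) < 0.5, logical(1)))
    if (ok) picked <- c(picked, j)
    if (length(picked) == k) break
  }
  if (length(picked) < k)
    stop("could not find ", k, " weakly correlated informative columns")
  picked
}

#' Reference prediction tables packaged as fixtures
#'
#' Returns the packaged 35-compound actual/predicted pIC50 table for one
#' of the three reference models (28 training and 7 test compounds).
#' Residuals are recomputed as observed minus predicted.
#'
#' @param model_name "comfa", "comsia" or "topomer" (case-insensitive;
#'   "TopomerCoMFA" also accepted).
#' @return `qsar_prediction_table` with 35 rows.
#' @export
paper_fixture <- function(model_name) {
  key <- switch(tolower(gsub("[^a-z]", "", tolower(model_name))),
                comfa = "comfa", comsia = "comsia",
                topomer = "topomer", topomercomfa = "topomer",
                stop("unknown model name: ", model_name))
  path <- system.file("extdata", "table3_predictions.csv",
                      package = "qsar3d", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  prediction_table(d$id, d$y_obs, d[[key]], d$role)
}
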