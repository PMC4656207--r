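# Synthetic data: a two-copy toy structure, degraded "EM" maps, and noisy
# "observed" amplitudes with retained ground-truth phases.

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

rot180_about <- function(u) {
  u <- u / sqrt(sum(u^2))
  2 * outer(u, u) - diag(3)
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Toy protein-like structure with exact NCS operators
#'
#' Builds a compact self-avoiding pseudo-Calpha walk (3.8 Angstrom steps,
#' bounded turning) with one side-chain pseudo-atom per residue, and
#' duplicates it by a proper two-fold NCS rotation plus an in-plane
#' translation, returning the exact operators (forward and inverse, each
#' with a spherical mask over its source copy).
#'
#' @param n_residues residues per copy.
#' @param n_copies 1 or 2.
#' @param seed RNG seed (deterministic output per seed).
#' @param copy_separation centre-to-centre distance of the two copies
#'   (Angstrom).
#' @return list(model = [atom_model()], ncs_ops = list of
#'   [ncs_operator()]s).
#' @export
make_toy_structure <- function(n_residues = 60, n_copies = 2, seed = 1,
                               copy_separation = 26) {
  stopifnot(n_copies %in% c(1, 2))
  with_seed(seed, {
    confine <- max(9, (3 * n_residues * 130 / (4 * pi))^(1 / 3))
    pos <- matrix(0, n_residues, 3)
    dir <- random_unit()
    i <- 2
    backtracks <- 0
    while (i <= n_residues) {
      placed <- FALSE
      for (try in 1:80) {
        nd <- dir + 0.5 * rnorm(3)
        if (sqrt(sum(pos[i - 1, ]^2)) > 0.85 * confine) {
          # drift back towards the centre of the confinement sphere
          toc <- -pos[i - 1, ]
          nd <- nd + 1.5 * toc / sqrt(sum(toc^2))
        }
        nd <- nd / sqrt(sum(nd^2))
        cand <- pos[i - 1, ] + 3.8 * nd
        ok <- sqrt(sum(cand^2)) <= confine
        if (ok && i > 2) {
          d2 <- rowSums(sweep(pos[1:(i - 2), , drop = FALSE], 2, cand)^2)
          ok <- min(d2) >= 2.4^2
        }
        if (ok) {
          pos[i, ] <- cand
          dir <- nd
          placed <- TRUE
          break
        }
      }
      if (placed) {
        i <- i + 1
      } else {
        # dead end: drop the previous residue and retry from there
        backtracks <- backtracks + 1
        if (backtracks > 50 * n_residues)
          stop("self-avoiding walk failed; try another seed")
        i <- max(2, i - 1)
        dir <- random_unit()
      }
    }
    # side-chain pseudo-atoms: 2.3 A offset in the clash-minimising
    # direction (candidates: outward bisector plus random directions)
    side <- matrix(0, n_residues, 3)
    for (i in seq_len(n_residues)) {
      nb <- pos[max(1, i - 1), ] + pos[min(n_residues, i + 1), ]
      v <- pos[i, ] - nb / 2
      if (sum(v^2) < 1e-6) v <- rnorm(3)
      cands <- rbind(v / sqrt(sum(v^2)),
                     t(replicate(24, random_unit())))
      best <- NULL; bestd <- -Inf
      placed_sides <- if (i > 1) side[1:(i - 1), , drop = FALSE] else NULL
      others <- rbind(pos[-i, , drop = FALSE], placed_sides)
      for (ci in seq_len(nrow(cands))) {
        p <- pos[i, ] + 2.3 * cands[ci, ]
        dmin <- min(rowSums(sweep(others, 2, p)^2))
        if (dmin > bestd) { bestd <- dmin; best <- p }
      }
      side[i, ] <- best
    }
    ctr <- colMeans(pos)
    pos <- sweep(pos, 2, ctr); side <- sweep(side, 2, ctr)
    # side-chain pseudo-atoms get markedly higher B: side chains are more
    # mobile, and main-chain density should dominate as it does in real
    # maps
    one <- rbind(
      atom_model("C", pos, B = runif(n_residues, 15, 30), chain = "A",
                 resno = seq_len(n_residues), role = "main"),
      atom_model("O", side, B = runif(n_residues, 45, 65), chain = "A",
                 resno = seq_len(n_residues), role = "side"))
    radius <- max(sqrt(rowSums(rbind(pos, side)^2))) + 3
    if (n_copies == 1) {
      ops <- list(ncs_operator(diag(3), c(0, 0, 0), c(0, 0, 0), radius))
      return(list(model = one, ncs_ops = ops))
    }
    axis <- random_unit()
    R <- rot180_about(axis)
    w <- rnorm(3); w <- w - sum(w * axis) * axis     # perpendicular
    w <- w / sqrt(sum(w^2))
    xyz1 <- model_xyz(one)
    sep <- copy_separation
    repeat {
      tvec <- sep * w
      xyz2 <- xyz1 %*% t(R) + matrix(tvec, nrow(xyz1), 3, byrow = TRUE)
      dmin <- min(sqrt(outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") -
                         2 * xyz1 %*% t(xyz2)))
      if (is.nan(dmin) || dmin >= 2.4) break
      sep <- sep + (2.4 - dmin) + 0.3
    }
    two <- one
    two$chain <- "B"
    two[, c("x", "y", "z")] <- xyz2
    model <- rbind(one, two)
    ops <- list(
      ncs_operator(R, tvec, c(0, 0, 0), radius),
      ncs_operator(t(R), -as.vector(t(R) %*% tvec), tvec, radius))
    list(model = model, ncs_ops = ops)
  })
}

#' Translate a model and its NCS operators together
#'
#' @param model an [atom_model()].
#' @param ncs_ops list of [ncs_operator()]s.
#' @param shift Cartesian translation (Angstrom).
#' @return list(model, ncs_ops) with the shift applied; operators are
#'   conjugated so they remain exact (t' = t + shift - R shift).
#' @export
shift_structure <- function(model, ncs_ops, shift) {
  model[, c("x", "y", "z")] <- sweep(model_xyz(model), 2, shift, "+")
  ops <- lapply(ncs_ops, function(op) {
    ncs_operator(op$R, op$t + shift - as.vector(op$R %*% shift),
                 op$center + shift, op$radius)
  })
  list(model = model, ncs_ops = ops)
}

#' Simulate observed amplitudes with ground-truth phases
#'
#' Amplitudes from [structure_factors_from_model()] with multiplicative
#' Gaussian noise; the exact phased set is returned separately.
#'
#' @param truth an [atom_model()] in the crystal frame.
#' @param cell crystal [unit_cell()].
#' @param sym crystal [sym_ops()].
#' @param d_min resolution limit in Angstrom (default 2.3).
#' @param amp_noise_frac fractional amplitude noise (default 0.05).
#' @param seed RNG seed.
#' @return list(obs = unphased [reflection_set()] with `sigF`,
#'   truth = phased [reflection_set()]).
#' @export
simulate_observed <- function(truth, cell, sym = sym_p1(), d_min = 2.3,
                              amp_noise_frac = 0.05, seed = 1) {
  tf <- structure_factors_from_model(truth, cell, sym, d_min)
  with_seed(seed, {
    fobs <- tf$F * (1 + amp_noise_frac * rnorm(nrow(tf)))
    fobs <- pmax(fobs, 0)
    obs <- reflection_set(tf$h, tf$k, tf$l, fobs, cell,
                          sigF = amp_noise_frac * tf$F)
    list(obs = obs, truth = tf)
  })
}

#' Simulate a degraded "cryo-EM" map
#'
#' Model map truncated at the stated resolution, blurred by B_blur, with
#' wrapped-Gaussian phase noise per coefficient and an optional
#' magnification error; generated either directly in a given cell (at the
#' true position) or in a padded cubic P1 box.
#'
#' @param truth an [atom_model()].
#' @param cell target [unit_cell()]; NULL builds a padded P1 box (edge =
#'   `padding_factor` times the model diameter).
#' @param resolution truncation resolution in Angstrom (default 4.87).
#' @param phase_noise_deg wrapped-Gaussian phase noise sigma, degrees.
#' @param B_blur blurring B-factor in Angstrom^2.
#' @param mag_error magnification error factor applied to the map.
#' @param padding_factor box padding when `cell` is NULL.
#' @param grid grid divisions (default d/3 rule at `resolution`).
#' @param seed RNG seed.
#' @return A [map_grid()].
#' @export
simulate_em_map <- function(truth, cell = NULL, resolution = 4.87,
                            phase_noise_deg = 0, B_blur = 0, mag_error = 1,
                            padding_factor = 2, grid = NULL, seed = 1) {
  if (is.null(cell)) {
    xyz <- model_xyz(truth)
    ctr <- colMeans(xyz)
    diam <- 2 * max(sqrt(rowSums(sweep(xyz, 2, ctr)^2))) + 6
    edge <- padding_factor * diam
    cell <- unit_cell(edge, edge, edge)
    truth[, c("x", "y", "z")] <-
      sweep(xyz, 2, c(edge / 2, edge / 2, edge / 2) - ctr, "+")
  }
  sf <- structure_factors_from_model(truth, cell, sym_p1(), resolution)
  with_seed(seed, {
    F <- sf$F * exp(-B_blur / (4 * sf$d^2))
    phi <- sf$phi + rnorm(nrow(sf), 0, phase_noise_deg)
    noisy <- reflection_set(sf$h, sf$k, sf$l, F, cell, phi = phi)
    if (is.null(grid)) grid <- grid_for_resolution(cell, resolution)
    m <- map_from_structure_factors(noisy, grid = grid)
    if (mag_error != 1) m <- correct_magnification(m, mag_error)
    m
  })
}

#' Starting phases from a positioned EM map
#'
#' Extracts map phases at the observed reflections to the EM resolution
#' and attaches sigma-A-derived FOMs (observed vs map amplitudes).
#'
#' @param obs observed [reflection_set()].
#' @param em_map positioned [map_grid()] on the crystal cell.
#' @param em_res EM resolution limit in Angstrom.
#' @return A [reflection_set()] restricted to d >= em_res with `phi` and
#'   `fom`.
#' @export
em_start_phases <- function(obs, em_map, em_res) {
  sub <- obs[obs$d >= em_res - 1e-9, , drop = FALSE]
  sf <- structure_factors_from_map(em_map, em_res,
                                   hkl = as.data.frame(sub)[, c("h", "k", "l")])
  ns <- max(5L, min(12L, nrow(sub) %/% 200L))
  eo <- normalize_amplitudes_values(sub$F, sub$d, ns)
  ec <- normalize_amplitudes_values(sf$F, sub$d, ns)
  sa <- shell_sigma_a(eo$E, ec$E, eo$shell)
  fom <- bessel_ratio(2 * sa[eo$shell] * eo$E * ec$E / (1 - sa[eo$shell]^2))
  reflection_set(sub$h, sub$k, sub$l, sub$F, get_cell(obs), sigF = sub$sigF,
                 phi = sf$phi, fom = pmin(fom, 0.9999))
}

#' The standard synthetic phase-extension scenario
#'
#' One call producing a self-contained analogue of the intended use case:
#' a two-copy NCS dimer in a cubic P1 cell, 2.3 Angstrom "observed"
#' amplitudes with 5% noise, a 4.87 Angstrom blurred and phase-perturbed
#' "EM" map at the true position, exact NCS operators, starting phases
#' with sigma-A FOMs, a four-shell extension schedule, and a generic
#' reference histogram source.
#'
#' @param seed RNG seed; everything is deterministic per seed.
#' @param n_residues residues per copy (default 60).
#' @param cell_edge cubic cell edge in Angstrom (default 60).
#' @param d_min X-ray resolution (default 2.3).
#' @param em_res EM resolution (default 4.87).
#' @param amp_noise_frac amplitude noise fraction (default 0.05).
#' @param em_phase_noise_deg EM phase noise sigma in degrees (default 45).
#' @param B_blur EM blurring B (default 100).
#' @param solvent_fraction DM solvent fraction (default 0.5).
#' @param n_shells extension shells between em_res and d_min (default 4).
#' @return list of class `phasex_scenario`: obs, truth_phases, em_map,
#'   start_phases, ncs_ops, truth_model, cell, sym, config,
#'   reference_hist (a function of resolution).
#' @export
standard_scenario <- function(seed = 1, n_residues = 60, cell_edge = 60,
                              d_min = 2.3, em_res = 4.87,
                              amp_noise_frac = 0.05,
                              em_phase_noise_deg = 45, B_blur = 100,
                              solvent_fraction = 0.5, n_shells = 4) {
  cell <- unit_cell(cell_edge, cell_edge, cell_edge)
  sym <- sym_p1()
  toy <- make_toy_structure(n_residues, 2, seed = seed)
  ctr <- colMeans(model_xyz(toy$model))
  toy <- shift_structure(toy$model, toy$ncs_ops,
                         rep(cell_edge / 2, 3) - ctr)
  sim <- simulate_observed(toy$model, cell, sym, d_min,
                           amp_noise_frac, seed = seed + 101)
  em_map <- simulate_em_map(toy$model, cell = cell, resolution = em_res,
                            phase_noise_deg = em_phase_noise_deg,
                            B_blur = B_blur,
                            grid = grid_for_resolution(cell, d_min),
                            seed = seed + 202)
  start <- em_start_phases(sim$obs, em_map, em_res)
  # generic (non-truth) histogram source: an independent fold with the
  # same composition and copy number, so the density scale matches
  gen <- make_toy_structure(n_residues, 2, seed = seed + 9001)
  gctr <- colMeans(model_xyz(gen$model))
  gmodel <- gen$model
  gmodel[, c("x", "y", "z")] <-
    sweep(model_xyz(gmodel), 2, rep(cell_edge / 2, 3) - gctr, "+")
  hist_cache <- new.env(parent = emptyenv())
  grid <- grid_for_resolution(cell, d_min)
  reference_hist <- function(d_cur) {
    key <- sprintf("%.4f", d_cur)
    if (is.null(hist_cache[[key]]))
      hist_cache[[key]] <- reference_histogram(
        gmodel, cell, grid, d_cur,
        solvent_fraction = solvent_fraction)
    hist_cache[[key]]
  }
  s3 <- seq(1 / em_res^3, 1 / d_min^3, length.out = n_shells + 1)[-1]
  config <- dm_config(solvent_fraction = solvent_fraction,
                      extension_schedule = s3^(-1 / 3),
                      ncs_ops = toy$ncs_ops, grid = grid)
  structure(list(obs = sim$obs, truth_phases = sim$truth, em_map = em_map,
                 start_phases = start, ncs_ops = toy$ncs_ops,
                 truth_model = toy$model, cell = cell, sym = sym,
                 config = config, reference_hist = reference_hist,
                 seed = seed),
            class = "phasex_scenario")
}

#' @export
print.phasex_scenario <- function(x, ...) {
  cat(sprintf(paste0("phasex_scenario (seed %d): %d atoms, %d reflections",
                     " to %.2f A, EM start to %.2f A\n"),
              x$seed, nrow(x$truth_model), nrow(x$obs), min(x$obs$d),
              min(x$start_phases$d)))
  invisible(x)
}
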