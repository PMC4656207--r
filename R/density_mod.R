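# Real-space density-modification operators and the prime-and-switch cycle.

#' NCS operator with a spherical source mask
#'
#' Rotation/translation pair acting on Cartesian coordinates as
#' `y = R x + t`, together with a sphere (centre, radius) delimiting the
#' source copy it applies to.
#'
#' @param R 3x3 orthonormal rotation (Cartesian).
#' @param t translation in Angstrom (Cartesian).
#' @param center sphere centre of the source copy, Cartesian Angstrom.
#' @param radius sphere radius in Angstrom, positive.
#' @return Object of class `ncs_operator`.
#' @export
ncs_operator <- function(R, t, center, radius) {
  R <- matrix(as.numeric(R), 3, 3)
  if (max(abs(t(R) %*% R - diag(3))) > 1e-8)
    stop("NCS rotation must be orthonormal")
  if (radius <= 0) stop("NCS mask radius must be positive")
  structure(list(R = R, t = as.numeric(t), center = as.numeric(center),
                 radius = radius), class = "ncs_operator")
}

is_identity_op <- function(op) {
  max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t)) < 1e-9
}

#' Density histogram
#'
#' Normalized histogram (frequencies sum to 1) over increasing bin edges.
#'
#' @param edges numeric vector of K+1 increasing bin edges.
#' @param freq numeric vector of K non-negative frequencies.
#' @return Object of class `density_histogram`.
#' @export
density_histogram <- function(edges, freq) {
  if (any(diff(edges) <= 0)) stop("histogram edges must increase")
  if (length(freq) != length(edges) - 1) stop("need one frequency per bin")
  if (any(freq < 0)) stop("frequencies must be non-negative")
  s <- sum(freq)
  if (s <= 0) stop("histogram is empty")
  structure(list(edges = edges, freq = freq / s),
            class = "density_histogram")
}

#' @rdname density_histogram
#' @param values numeric sample to histogram.
#' @param n_bins number of bins (default 64).
#' @export
histogram_of <- function(values, n_bins = 64) {
  rng <- range(values)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  density_histogram(edges, cnt)
}

# quantile function of a density_histogram (linear within bins)
histogram_quantile <- function(hist, p) {
  cdf <- c(0, cumsum(hist$freq))
  cdf <- cdf / cdf[length(cdf)]
  # make cdf strictly increasing for interpolation
  eps <- 1e-12 * seq_along(cdf)
  approx(cdf + eps, hist$edges, xout = pmin(pmax(p, 0), 1), rule = 2)$y
}

#' Wang-style solvent mask
#'
#' Smooths |rho| by a spherical local mean of the given radius and flags
#' the lowest `solvent_fraction` quantile of the smoothed density as
#' solvent; the rest is protein.
#'
#' @param map a [map_grid()].
#' @param solvent_fraction fraction of the cell assigned to solvent, (0,1).
#' @param smoothing_radius sphere radius in Angstrom (default 8).
#' @return A [map_grid()] of 0 (solvent) / 1 (protein) values; attribute
#'   `degenerate` is TRUE when the smoothed map is flat.
#' @export
solvent_mask <- function(map, solvent_fraction, smoothing_radius = 8) {
  if (solvent_fraction <= 0 || solvent_fraction >= 1)
    stop("solvent_fraction must be in (0,1)")
  n <- dim(map$rho)
  kf <- sphere_kernel_fft(map$cell, n, smoothing_radius)
  sm <- fft_convolve(abs(map$rho), kf)
  thr <- quantile(sm, probs = solvent_fraction, names = FALSE)
  protein <- array(as.numeric(sm > thr), dim = n)
  out <- map_grid(map$cell, protein)
  if (sd(as.vector(sm)) < 1e-12 * max(abs(sm), 1e-300)) {
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Solvent flattening
#'
#' Sets every solvent voxel to the solvent-region mean; protein voxels are
#' untouched.
#'
#' @param map a [map_grid()].
#' @param mask protein mask from [solvent_mask()] (1 = protein).
#' @return A [map_grid()].
#' @export
solvent_flatten <- function(map, mask) {
  rho <- map$rho
  solv <- mask$rho < 0.5
  if (any(solv)) rho[solv] <- mean(rho[solv])
  map_grid(map$cell, rho)
}

#' Histogram matching of the protein region
#'
#' Monotone (rank-preserving) transform of the protein-region densities so
#' their empirical CDF matches the target histogram's CDF; solvent is
#' untouched.
#'
#' @param map a [map_grid()].
#' @param target a [density_histogram()] with at least 10 bins.
#' @param protein_mask mask from [solvent_mask()] (1 = protein); NULL
#'   applies the transform to the whole cell.
#' @return A [map_grid()].
#' @export
histogram_match <- function(map, target, protein_mask = NULL) {
  if (length(target$freq) < 10) stop("target histogram needs >= 10 bins")
  rho <- map$rho
  sel <- if (is.null(protein_mask)) rep(TRUE, length(rho)) else
    as.vector(protein_mask$rho >= 0.5)
  v <- rho[sel]
  p <- (rank(v, ties.method = "average") - 0.5) / length(v)
  rho[sel] <- histogram_quantile(target, p)
  map_grid(map$cell, rho)
}

#' Reference density histogram from a model
#'
#' Histogram of the protein region of a model-computed map at the working
#' resolution; used as the histogram-matching target.
#'
#' @param model an [atom_model()].
#' @param cell a [unit_cell()].
#' @param grid integer (nx,ny,nz).
#' @param d_min resolution in Angstrom to band-limit the model map.
#' @param n_bins histogram bins (default 64).
#' @param solvent_fraction fraction used to delimit the protein region.
#' @param smoothing_radius mask smoothing radius in Angstrom.
#' @return A [density_histogram()].
#' @export
reference_histogram <- function(model, cell, grid, d_min, n_bins = 64,
                                solvent_fraction = 0.5,
                                smoothing_radius = 8) {
  m <- model_density_map(model, cell, grid)
  m <- lowpass_map(m, d_min)
  mask <- solvent_mask(m, solvent_fraction, smoothing_radius)
  histogram_of(m$rho[mask$rho >= 0.5], n_bins)
}

# zero all Fourier coefficients beyond d_min
lowpass_map <- function(map, d_min) {
  n <- dim(map$rho)
  farr <- sf_array_from_map(map)
  s2 <- s2_grid(map$cell, n)
  farr[s2 > 1 / d_min^2] <- 0
  map_from_sf_array(farr, map$cell)
}

#' NCS averaging with spherical masks
#'
#' Within each operator's source sphere, the density is replaced by the
#' mean of itself and its image under the operator (trilinear resampling,
#' periodic).  Voxels outside every mask are untouched.  All reads use the
#' input map, so operators act on the original density.
#'
#' @param map a [map_grid()].
#' @param ops list of [ncs_operator()]s; at least one non-identity.
#' @return A [map_grid()].
#' @export
ncs_average <- function(map, ops) {
  if (inherits(ops, "ncs_operator")) ops <- list(ops)
  live <- Filter(Negate(is_identity_op), ops)
  if (!length(live)) return(map)
  n <- dim(map$rho)
  cellO <- cell_orth(map$cell)
  xf <- voxel_frac_coords(n)
  rho <- map$rho
  for (op in live) {
    cf <- as.vector(cart_to_frac(op$center, map$cell))
    dfr <- sweep(xf, 2, cf)
    dfr <- dfr - round(dfr)
    r2 <- rowSums((dfr %*% t(cellO))^2)
    sel <- r2 <= op$radius^2
    if (!any(sel)) stop("NCS mask covers no voxels")
    xc <- frac_to_cart(xf[sel, , drop = FALSE], map$cell)
    # unwrap the source sphere about its centre before applying the op
    xc <- sweep(dfr[sel, , drop = FALSE] %*% t(cellO), 2, op$center, "+")
    yc <- xc %*% t(op$R) + matrix(op$t, nrow(xc), 3, byrow = TRUE)
    yf <- cart_to_frac(yc, map$cell)
    u <- cbind(yf[, 1] %% 1 * n[1], yf[, 2] %% 1 * n[2], yf[, 3] %% 1 * n[3])
    img <- tricubic_periodic(map$rho, u)
    rho[sel] <- (map$rho[sel] + img) / 2
  }
  map_grid(map$cell, rho)
}

#' Density-modification configuration
#'
#' @param solvent_fraction solvent fraction of the cell, (0,1).
#' @param n_inner_cycles inner DM iterations per extension shell.
#' @param extension_schedule strictly decreasing d_min values (Angstrom);
#'   the first entry is the starting resolution, the last the target.
#' @param mask_smoothing_radius solvent-mask smoothing radius (Angstrom).
#' @param use_solvent,use_histogram,use_ncs operator switches.
#' @param ncs_ops list of [ncs_operator()]s (required if `use_ncs`).
#' @param grid optional map grid divisions (default: d_min/3 rule at the
#'   schedule's final resolution).
#' @param convergence_deg inner-cycle convergence threshold on the mean
#'   absolute phase change, degrees (default 1).
#' @return list of class `dm_config`.
#' @export
dm_config <- function(solvent_fraction = 0.5, n_inner_cycles = 5,
                      extension_schedule, mask_smoothing_radius = 8,
                      use_solvent = TRUE, use_histogram = TRUE,
                      use_ncs = TRUE, ncs_ops = NULL, grid = NULL,
                      convergence_deg = 1) {
  if (solvent_fraction <= 0 || solvent_fraction >= 1)
    stop("solvent_fraction must be in (0,1)")
  if (any(diff(extension_schedule) >= 0))
    stop("extension_schedule must be strictly decreasing in d_min")
  if (use_ncs && is.null(ncs_ops)) use_ncs <- FALSE
  structure(list(solvent_fraction = solvent_fraction,
                 n_inner_cycles = n_inner_cycles,
                 extension_schedule = extension_schedule,
                 mask_smoothing_radius = mask_smoothing_radius,
                 use_solvent = use_solvent, use_histogram = use_histogram,
                 use_ncs = use_ncs, ncs_ops = ncs_ops, grid = grid,
                 convergence_deg = convergence_deg),
            class = "dm_config")
}

#' Prime-and-switch density modification with phase extension
#'
#' Iterates, per extension shell: synthesize the FOM-weighted map from the
#' current phases and observed amplitudes; apply the enabled real-space
#' operators (NCS averaging, histogram matching, solvent flattening);
#' back-transform; SWITCH every phase to the modified map's phase (the
#' starting phases are never recombined - this is the bias-removal
#' contract); re-derive each reflection's figure of merit from the
#' per-shell sigma-A between observed and modified-map amplitudes.  Newly
#' reached shells enter with the modified-map phase and the shell FOM.
#'
#' @param obs [reflection_set()] with observed amplitudes `F`.
#' @param start_phases [reflection_set()] with `phi` (+ optional `fom`,
#'   default 1) covering at least the first extension shell.
#' @param config a [dm_config()].
#' @param reference_hist [density_histogram()] target, or a function of
#'   the current shell d_min returning one (required when
#'   `config$use_histogram`).
#' @return A [reflection_set()] with `F`, `phi`, `fom` for all reflections
#'   to the schedule's final d_min; attribute `trace` records per-iteration
#'   mean phase change and mean FOM.
#' @export
prime_and_switch <- function(obs, start_phases, config,
                             reference_hist = NULL) {
  cell <- get_cell(obs)
  sched <- config$extension_schedule
  if (min(sched) < min(obs$d) - 0.01)
    stop("extension schedule goes beyond the resolution of obs")
  if (config$use_histogram && is.null(reference_hist))
    stop("reference_hist required when use_histogram is TRUE")
  refl <- as.data.frame(obs)[obs$d >= min(sched) - 1e-9,
                             c("h", "k", "l", "F", "sigF", "d")]
  sp <- as.data.frame(start_phases)
  m <- match(hkl_key(refl), hkl_key(sp))
  refl$phi <- sp$phi[m]
  refl$fom <- sp$fom[m]
  refl$fom[!is.na(refl$phi) & is.na(refl$fom)] <- 1
  if (!any(!is.na(refl$phi) & refl$d >= sched[1] - 1e-9))
    stop("start phases do not cover the first extension shell")
  grid <- if (is.null(config$grid)) grid_for_resolution(cell, min(sched)) else
    config$grid
  kern <- sphere_kernel_fft(cell, grid, config$mask_smoothing_radius)
  trace <- list()
  for (d_cur in sched) {
    active <- refl$d >= d_cur - 1e-9
    rh <- if (is.function(reference_hist)) reference_hist(d_cur) else
      reference_hist
    for (ic in seq_len(config$n_inner_cycles)) {
      have <- active & !is.na(refl$phi)
      cur <- reflection_set(refl$h[have], refl$k[have], refl$l[have],
                            refl$F[have], cell, phi = refl$phi[have],
                            fom = refl$fom[have])
      map <- map_from_structure_factors(cur, grid = grid,
                                        use_fom_weights = TRUE)
      mod <- map
      if (config$use_ncs) mod <- ncs_average(mod, config$ncs_ops)
      mask <- NULL
      if (config$use_histogram || config$use_solvent) {
        n <- dim(mod$rho)
        sm <- fft_convolve(abs(mod$rho), kern)
        thr <- quantile(sm, probs = config$solvent_fraction, names = FALSE)
        mask <- map_grid(cell, array(as.numeric(sm > thr), dim = n))
      }
      if (config$use_histogram)
        mod <- histogram_match(mod, rh, mask)
      if (config$use_solvent) mod <- solvent_flatten(mod, mask)
      if (!config$use_ncs && !config$use_histogram && !config$use_solvent)
        mod <- map
      sf <- structure_factors_from_map(
        mod, d_cur, hkl = refl[active, c("h", "k", "l")])
      newphi <- sf$phi
      # sigma-A between observed and modified-map amplitudes, per shell
      ns <- max(5L, min(15L, sum(active) %/% 300L))
      eo <- normalize_amplitudes_values(refl$F[active], refl$d[active], ns)
      ec <- normalize_amplitudes_values(sf$F, refl$d[active], ns)
      sa <- shell_sigma_a(eo$E, ec$E, eo$shell)
      newfom <- bessel_ratio(2 * sa[eo$shell] * eo$E * ec$E /
                               (1 - sa[eo$shell]^2))
      prev <- refl$phi[active]
      dphi <- mean(abs(wrap_deg(newphi - prev)), na.rm = TRUE)
      refl$phi[active] <- newphi
      refl$fom[active] <- newfom
      trace[[length(trace) + 1]] <-
        data.frame(d_cur = d_cur, inner = ic, mean_dphi = dphi,
                   mean_fom = mean(newfom))
      if (!is.nan(dphi) && dphi < config$convergence_deg) break
    }
  }
  out <- reflection_set(refl$h, refl$k, refl$l, refl$F, cell,
                        sigF = refl$sigF, phi = refl$phi, fom = refl$fom)
  attr(out, "trace") <- do.call(rbind, trace)
  out
}
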