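# Map preparation for molecular replacement: sharpening, FSC-based FOM
# weighting, magnification correction, and placement in a padded P1 box.

#' B-factor sharpening (or blurring) of a map
#'
#' Scales every Fourier coefficient by exp(+B_sharpen * s^2 / 4), s = 1/d.
#' Positive B sharpens, negative B blurs; the (absent) F000 term is
#' untouched so the mean density is unchanged.
#'
#' @param map a [map_grid()].
#' @param B_sharpen B-factor in Angstrom^2 (finite; sign gives direction).
#' @return A [map_grid()].
#' @export
sharpen_map <- function(map, B_sharpen) {
  stopifnot(is.finite(B_sharpen))
  n <- dim(map$rho)
  farr <- sf_array_from_map(map)
  s2 <- s2_grid(map$cell, n)
  f0 <- farr[1]                       # preserve mean (F000)
  farr <- farr * exp(B_sharpen * s2 / 4)
  farr[1] <- f0
  map_from_sf_array(farr, map$cell)
}

#' Resolution-shell curve
#'
#' Contiguous resolution shells `(d_max, d_min]` with one value each,
#' ordered low to high resolution.
#'
#' @param d_max,d_min shell bounds in Angstrom (vectors; d_max > d_min).
#' @param value per-shell value.
#' @return data.frame of class `shell_curve`.
#' @export
shell_curve <- function(d_max, d_min, value) {
  stopifnot(length(d_max) == length(d_min),
            length(value) == length(d_min))
  if (any(d_max <= d_min)) stop("each shell needs d_max > d_min")
  o <- order(-d_max)
  d_max <- d_max[o]; d_min <- d_min[o]; value <- value[o]
  if (length(d_max) > 1 &&
      any(abs(d_min[-length(d_min)] - d_max[-1]) > 1e-9))
    stop("shells must be contiguous and non-overlapping")
  structure(data.frame(d_max = d_max, d_min = d_min, value = value),
            class = c("shell_curve", "data.frame"))
}

# look up shell values for resolutions d; NA outside coverage
shell_lookup <- function(curve, d) {
  idx <- findInterval(1 / d, 1 / curve$d_max, rightmost.closed = FALSE)
  v <- rep(NA_real_, length(d))
  ok <- idx >= 1 & idx <= nrow(curve) & d >= min(curve$d_min) - 1e-9
  v[ok] <- curve$value[idx[ok]]
  v
}

#' FOM-weight a map from an FSC curve
#'
#' Scales each resolution shell's Fourier coefficients by
#' C_ref = sqrt(max(0, 2 FSC / (1 + FSC))), the standard map-versus-truth
#' weight derived from a half-map FSC; shells with FSC <= 0 are zeroed.
#'
#' @param map a [map_grid()].
#' @param fsc a [shell_curve()] of FSC values in [-1, 1]; must cover every
#'   non-empty coefficient of the map.
#' @return A [map_grid()].
#' @export
fom_weight_map <- function(map, fsc) {
  if (any(fsc$value < -1 | fsc$value > 1)) stop("FSC values must be in [-1,1]")
  n <- dim(map$rho)
  farr <- sf_array_from_map(map)
  s2 <- s2_grid(map$cell, n)
  d <- 1 / sqrt(pmax(s2, 1e-30))
  w <- shell_lookup(fsc, as.vector(d))
  amp <- Mod(as.vector(farr))
  live <- amp > max(amp) * 1e-12
  live[1] <- FALSE                    # F000 carries the mean, leave it
  if (any(live & is.na(w))) {
    dd <- as.vector(d)[live & is.na(w)]
    stop(sprintf("FSC shells do not cover the data range: gap at d = %.3g-%.3g A",
                 min(dd), max(dd)))
  }
  w[is.na(w)] <- 0
  cref <- sqrt(pmax(0, 2 * w / (1 + w)))
  f0 <- farr[1]
  farr <- farr * array(cref, dim = n)
  farr[1] <- f0
  map_from_sf_array(farr, map$cell)
}

#' Magnification correction
#'
#' Rescales the map's length scale by `scale` about the cell centre:
#' a feature of width w becomes width scale*w, densities are divided by
#' scale^3 so the integrated density is conserved, and the cell is kept.
#' Resampling is trilinear.
#'
#' @param map a [map_grid()].
#' @param scale dimensionless magnification factor, sanity-bounded.
#' @param bounds allowed scale range (default c(0.9, 1.1)).
#' @return A [map_grid()].
#' @export
correct_magnification <- function(map, scale, bounds = c(0.9, 1.1)) {
  if (scale < bounds[1] || scale > bounds[2])
    stop(sprintf("magnification scale %.4g outside sanity bounds [%g, %g] (unit mistake?)",
                 scale, bounds[1], bounds[2]))
  if (scale == 1) return(map)
  n <- dim(map$rho)
  # maps are band-limited: exact Fourier 2x oversampling as a prefilter
  # keeps the trilinear step accurate for non-integer scales
  fine <- fourier_upsample(map)
  nf <- dim(fine$rho)
  xf <- voxel_frac_coords(n)
  ctr <- c(0.5, 0.5, 0.5)
  src <- sweep(sweep(xf, 2, ctr), 2, rep(1 / scale, 3), "*")
  src <- sweep(src, 2, ctr, "+")
  u <- cbind(src[, 1] %% 1 * nf[1], src[, 2] %% 1 * nf[2],
             src[, 3] %% 1 * nf[3])
  rho <- array(trilinear_periodic(fine$rho, u) / scale^3, dim = n)
  map_grid(map$cell, rho)
}

# zero-padded reciprocal-space upsampling (exact for band-limited maps);
# the target grid gives >= `samples_per_period` samples of the finest
# occupied Fourier mode along each axis
fourier_upsample <- function(map, samples_per_period = 10) {
  n <- dim(map$rho)
  farr <- fft(map$rho, inverse = TRUE)
  src <- outer_grid_index(n)
  hm <- cbind(signed_index(src[, 1], n[1]), signed_index(src[, 2], n[2]),
              signed_index(src[, 3], n[3]))
  amp <- Mod(as.vector(farr))
  live <- amp > max(amp) * 1e-10
  hmax <- pmax(apply(abs(hm[live, , drop = FALSE]), 2, max), 1)
  nf <- vapply(seq_len(3), function(i)
    nice_fft_size(max(n[i], samples_per_period * hmax[i])), integer(1))
  big <- array(0 + 0i, nf)
  big[sf_linear_index(hm, nf)] <- farr
  map_grid(map$cell, Re(fft(big)) / prod(n))
}

# diameter of the smallest sphere (about the thresholded centroid) holding
# all voxels above mean + n_sigma * sd; list(centre_frac, diameter)
estimate_extent <- function(map, n_sigma = 1) {
  rho <- map$rho
  thr <- mean(rho) + n_sigma * sd(as.vector(rho))
  sel <- which(rho > thr)
  if (!length(sel)) return(NULL)
  n <- dim(rho)
  xf <- voxel_frac_coords(n)[sel, , drop = FALSE]
  # circular mean per axis copes with wrap-around blobs
  ctr <- vapply(1:3, function(i) {
    ang <- xf[, i] * 2 * pi
    (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
  }, numeric(1))
  dfr <- sweep(xf, 2, ctr)
  dfr <- dfr - round(dfr)
  r <- sqrt(rowSums((dfr %*% t(cell_orth(map$cell)))^2))
  list(centre_frac = ctr, diameter = 2 * max(r))
}

#' Place a map at the centre of a padded cubic P1 box
#'
#' Estimates the diameter of the density (smallest sphere containing all
#' voxels above mean + 1 sigma), builds a cubic P1 cell with edge
#' `padding_factor` times that diameter, and resamples the density at the
#' box centre; everything outside the source region is zero.
#'
#' @param map a [map_grid()].
#' @param padding_factor box edge as a multiple of the model diameter;
#'   must be >= 2 (smaller boxes alias the molecular transform, which the
#'   translation search interpolates).
#' @param threshold_sigma threshold (in map sigmas above the mean) used for
#'   the diameter estimate.
#' @param spacing target voxel spacing of the box (default: preserve the
#'   input spacing along a).
#' @return list with elements `map` (the boxed [map_grid()]) and `cell`
#'   (its cubic [unit_cell()]).
#' @export
place_in_p1_box <- function(map, padding_factor = 2, threshold_sigma = 1,
                            spacing = NULL) {
  if (padding_factor < 2)
    stop("padding_factor must be >= 2: the box oversamples the molecular transform")
  ext <- estimate_extent(map, threshold_sigma)
  if (is.null(ext) || ext$diameter <= 0) stop("no density to box")
  edge <- padding_factor * ext$diameter
  if (is.null(spacing)) spacing <- map$cell$a / dim(map$rho)[1]
  nb <- rep(nice_fft_size(edge / spacing), 3)
  box_cell <- unit_cell(edge, edge, edge)
  xf_new <- voxel_frac_coords(nb)
  # Cartesian offset from the box centre
  off <- frac_to_cart(sweep(xf_new, 2, c(0.5, 0.5, 0.5)), box_cell)
  src <- sweep(cart_to_frac(off, map$cell), 2, ext$centre_frac, "+")
  inside <- abs(src[, 1] - ext$centre_frac[1]) < 0.5 &
    abs(src[, 2] - ext$centre_frac[2]) < 0.5 &
    abs(src[, 3] - ext$centre_frac[3]) < 0.5
  n <- dim(map$rho)
  u <- cbind(src[, 1] %% 1 * n[1], src[, 2] %% 1 * n[2], src[, 3] %% 1 * n[3])
  v <- trilinear_periodic(map$rho, u)
  v[!inside] <- 0
  list(map = map_grid(box_cell, array(v, dim = nb)), cell = box_cell)
}
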