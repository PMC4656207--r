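# -- reciprocal-space bookkeeping for FFT arrays ------------------------------

# signed Miller index along one axis for 0-based FFT positions 0..n-1
signed_index <- function(idx0, n) ifelse(idx0 > n / 2, idx0 - n, idx0)

# linear index into an FFT array for Miller triples (rows of hm)
sf_linear_index <- function(hm, n) {
  1 + (hm[, 1] %% n[1]) +
    n[1] * ((hm[, 2] %% n[2]) + n[2] * (hm[, 3] %% n[3]))
}

# |s|^2 = 1/d^2 for every element of an FFT array
s2_grid <- function(cell, n) {
  gs <- cell_recip_metric(cell)
  ix <- outer_grid_index(n)
  hm <- cbind(signed_index(ix[, 1], n[1]),
              signed_index(ix[, 2], n[2]),
              signed_index(ix[, 3], n[3]))
  array(rowSums((hm %*% gs) * hm), dim = n)
}

# full complex structure-factor array of a map: entry at (h mod n) holds
# F(h) = (V/N) * sum rho exp(+2 pi i h.x)
sf_array_from_map <- function(map) {
  n <- dim(map$rho)
  fft(map$rho, inverse = TRUE) * (cell_volume(map$cell) / prod(n))
}

# inverse: real map from a full complex SF array
map_from_sf_array <- function(farr, cell) {
  map_grid(cell, Re(fft(farr)) / cell_volume(cell))
}

check_grid_for_dmin <- function(map, d_min) {
  n <- dim(map$rho)
  a <- c(map$cell$a, map$cell$b, map$cell$c)
  need <- ceiling(3 * a / d_min - 1e-6)
  if (any(n < need))
    stop(sprintf(paste0("grid too coarse for d_min = %.3g A: have %s,",
                        " need at least %s divisions"),
                 d_min, paste(n, collapse = "x"),
                 paste(need, collapse = "x")))
  invisible(TRUE)
}

#' Structure factors from a density map (FFT)
#'
#' Discrete Fourier transform of the map under the convention
#' F(h) = V * mean over the cell of rho(x) exp(+2 pi i h.x).  Returns the
#' unique Friedel hemisphere to `d_min`; F(000) is excluded.
#'
#' @param map a [map_grid()]; grid spacing must be <= d_min/3 per axis.
#' @param d_min high-resolution limit in Angstrom.
#' @param hkl optional data.frame h,k,l at which to evaluate (defaults to
#'   the full hemisphere to d_min).
#' @return A [reflection_set()] with amplitudes `F` and phases `phi`.
#' @export
structure_factors_from_map <- function(map, d_min, hkl = NULL) {
  check_grid_for_dmin(map, d_min)
  if (is.null(hkl)) hkl <- hkl_hemisphere(map$cell, d_min)
  farr <- sf_array_from_map(map)
  n <- dim(map$rho)
  fv <- farr[sf_linear_index(as.matrix(hkl[, c("h", "k", "l")]), n)]
  reflection_set(hkl$h, hkl$k, hkl$l, Mod(fv), map$cell,
                 phi = (Arg(fv) * 180 / pi) %% 360)
}

#' Fourier synthesis of a map from phased reflections
#'
#' Inverse of [structure_factors_from_map()]: places m*F*exp(i phi) (or
#' F*exp(i phi) unweighted) plus Friedel mates on the reciprocal grid and
#' back-transforms; the result is real and zero-mean (no F000 term).
#'
#' @param refl a [reflection_set()] with phases (`phi` non-NA everywhere).
#' @param grid integer (nx,ny,nz); default from [grid_for_resolution()] at
#'   the set's d_min.
#' @param use_fom_weights logical; weight coefficients by `fom`.
#' @param cell override the cell carried by `refl`.
#' @return A [map_grid()].
#' @export
map_from_structure_factors <- function(refl, grid = NULL,
                                       use_fom_weights = FALSE,
                                       cell = NULL) {
  if (is.null(cell)) cell <- get_cell(refl)
  if (any(is.na(refl$phi))) stop("all reflections must carry a phase")
  w <- 1
  if (use_fom_weights) {
    if (any(is.na(refl$fom))) stop("fom required for weighted synthesis")
    w <- refl$fom
  }
  if (is.null(grid)) grid <- grid_for_resolution(cell, min(refl$d))
  n <- as.integer(grid)
  # d_min/3 spacing keeps |h_i| < n_i/2, so h and -h never collide
  check_grid_for_dmin(map_grid(cell, array(0, n)), min(refl$d))
  farr <- array(0 + 0i, dim = n)
  hm <- as.matrix(refl[, c("h", "k", "l")])
  coeff <- w * refl$F * exp(1i * refl$phi * pi / 180)
  farr[sf_linear_index(hm, n)] <- coeff
  farr[sf_linear_index(-hm, n)] <- Conj(coeff)
  map_from_sf_array(farr, cell)
}
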