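#' Real-space density map on a unit-cell grid
#'
#' Density values on an `nx x ny x nz` grid spanning the unit cell;
#' voxel (i,j,k) (1-based) sits at fractional coordinates
#' ((i-1)/nx, (j-1)/ny, (k-1)/nz).
#'
#' @param cell a [unit_cell()].
#' @param rho 3-D numeric array of density values.
#' @return Object of class `map_grid`: list with elements `cell` and `rho`.
#' @export
map_grid <- function(cell, rho) {
  stopifnot(inherits(cell, "unit_cell"), is.array(rho),
            length(dim(rho)) == 3)
  if (any(dim(rho) < 2)) stop("grid must have at least 2 divisions per axis")
  structure(list(cell = cell, rho = rho), class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  n <- dim(x$rho)
  cat(sprintf("map_grid %d x %d x %d  (mean %.4g, sd %.4g)\n",
              n[1], n[2], n[3], mean(x$rho), sd(as.vector(x$rho))))
  print(x$cell)
  invisible(x)
}

#' Grid dimensions of a map
#' @param map a [map_grid()].
#' @export
map_dim <- function(map) dim(map$rho)

# smallest integer >= n whose prime factors are all in {2,3,5}
nice_fft_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Grid divisions adequate for structure-factor work at a resolution
#'
#' Applies the d_min/3 spacing rule per axis and rounds up to FFT-friendly
#' sizes (factors 2, 3, 5 only).
#'
#' @param cell a [unit_cell()].
#' @param d_min resolution in Angstrom.
#' @return integer vector (nx, ny, nz).
#' @export
grid_for_resolution <- function(cell, d_min) {
  stopifnot(d_min > 0)
  vapply(c(cell$a, cell$b, cell$c),
         function(a) nice_fft_size(3 * a / d_min - 1e-6), integer(1))
}

# periodic trilinear interpolation.
# arr: 3-D array; u: m x 3 matrix of continuous 0-based grid coordinates
trilinear_periodic <- function(arr, u) {
  n <- dim(arr)
  i0 <- floor(u)
  f <- u - i0
  out <- numeric(nrow(u))
  for (dx in 0:1) {
    wx <- if (dx == 1) f[, 1] else 1 - f[, 1]
    ix <- (i0[, 1] + dx) %% n[1]
    for (dy in 0:1) {
      wy <- if (dy == 1) f[, 2] else 1 - f[, 2]
      iy <- (i0[, 2] + dy) %% n[2]
      for (dz in 0:1) {
        wz <- if (dz == 1) f[, 3] else 1 - f[, 3]
        iz <- (i0[, 3] + dz) %% n[3]
        idx <- 1 + ix + n[1] * (iy + n[2] * iz)
        out <- out + wx * wy * wz * arr[idx]
      }
    }
  }
  out
}

# periodic tricubic (Catmull-Rom) interpolation; same interface as
# trilinear but with O(h^4) accuracy - used where interpolation loss
# would defeat the operation (NCS averaging)
tricubic_periodic <- function(arr, u) {
  n <- dim(arr)
  i0 <- floor(u)
  f <- u - i0
  cr <- function(t, k) {
    # Catmull-Rom basis for offsets -1, 0, 1, 2
    switch(k + 2,
           ((-t + 2 * t^2 - t^3) / 2),
           ((2 - 5 * t^2 + 3 * t^3) / 2),
           ((t + 4 * t^2 - 3 * t^3) / 2),
           ((-t^2 + t^3) / 2))
  }
  out <- numeric(nrow(u))
  for (dx in -1:2) {
    wx <- cr(f[, 1], dx)
    ix <- (i0[, 1] + dx) %% n[1]
    for (dy in -1:2) {
      wy <- cr(f[, 2], dy)
      iy <- (i0[, 2] + dy) %% n[2]
      wxy <- wx * wy
      for (dz in -1:2) {
        wz <- cr(f[, 3], dz)
        iz <- (i0[, 3] + dz) %% n[3]
        idx <- 1 + ix + n[1] * (iy + n[2] * iz)
        out <- out + wxy * wz * arr[idx]
      }
    }
  }
  out
}

# interpolate map density at fractional coordinates (m x 3), periodic
interp_map_frac <- function(map, xf) {
  n <- dim(map$rho)
  u <- cbind(xf[, 1] %% 1 * n[1], xf[, 2] %% 1 * n[2], xf[, 3] %% 1 * n[3])
  trilinear_periodic(map$rho, u)
}

# fractional coordinates of every voxel, as an N x 3 matrix (x fastest)
voxel_frac_coords <- function(n) {
  cbind(rep_len(rep(seq_len(n[1]) - 1, times = n[2] * n[3]), prod(n)) / n[1],
        rep_len(rep(seq_len(n[2]) - 1, each = n[1]), prod(n[1:2]) * n[3]) / n[2],
        rep(seq_len(n[3]) - 1, each = n[1] * n[2]) / n[3])
}

# circular convolution of a real 3-D array with a kernel given in real space
# (kernel indexed like the array, centred on voxel [1,1,1] with wrap)
fft_convolve <- function(arr, kernel_fft) {
  n <- length(arr)
  Re(fft(fft(arr) * kernel_fft, inverse = TRUE)) / n
}

# FFT of a normalized spherical mean kernel of given radius (Angstrom)
sphere_kernel_fft <- function(cell, n, radius) {
  o <- cell_orth(cell)
  ix <- outer_grid_index(n)
  # minimal-image voxel offsets in fractional units
  xf <- cbind(wrap_frac(ix[, 1] / n[1]), wrap_frac(ix[, 2] / n[2]),
              wrap_frac(ix[, 3] / n[3]))
  r <- sqrt(rowSums((xf %*% t(o))^2))
  k <- as.numeric(r <= radius)
  k <- array(k / sum(k), dim = n)
  fft(k)
}

# integer 0-based voxel index triples in array order
outer_grid_index <- function(n) {
  cbind(rep_len(rep(seq_len(n[1]) - 1L, times = n[2] * n[3]), prod(n)),
        rep_len(rep(seq_len(n[2]) - 1L, each = n[1]), prod(n)),
        rep(seq_len(n[3]) - 1L, each = n[1] * n[2]))
}

#' Read and write CCP4/MRC 2014 maps (mode 2, axis order X,Y,Z)
#'
#' Minimal reader/writer for the MRC 2014 format restricted to mode 2
#' (32-bit float) with column/row/section axes = X/Y/Z and no symmetry
#' records; this is what the rest of the toolchain emits.
#'
#' @param path file path.
#' @return `read_mrc` returns a [map_grid()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  n <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (mode != 2) stop("only MRC mode 2 (float32) is supported")
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps <- hdr_int[19]
  if (!identical(c(mapc, mapr, maps), c(1L, 2L, 3L)))
    stop("only axis order X,Y,Z is supported")
  nsymbt <- hdr_int[24]
  cell <- unit_cell(hdr_num[11], hdr_num[12], hdr_num[13],
                    hdr_num[14], hdr_num[15], hdr_num[16])
  seek(con, 1024 + nsymbt)
  dat <- readBin(con, "numeric", n = prod(n), size = 4, endian = "little")
  map_grid(cell, array(dat, dim = n))
}

#' @rdname read_mrc
#' @param map a [map_grid()] to write.
#' @export
write_mrc <- function(map, path) {
  n <- dim(map$rho)
  rho <- as.vector(map$rho)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                                  # NX NY NZ
  wi(2)                                  # MODE
  wi(c(0, 0, 0))                         # NXSTART..
  wi(n)                                  # MX MY MZ
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))                         # MAPC MAPR MAPS
  wf(c(min(rho), max(rho), mean(rho)))   # DMIN DMAX DMEAN
  wi(1)                                  # ISPG
  wi(0)                                  # NSYMBT
  wi(rep(0, 25))                         # EXTRA (words 25-49)
  wf(c(0, 0, 0))                         # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(rho))                            # RMS
  wi(0)                                  # NLABL
  writeBin(raw(800), con)                # labels
  wf(rho)
  invisible(path)
}
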