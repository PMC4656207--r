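#' Atomic (or pseudo-atomic) model
#'
#' A data frame of atoms with columns `element` (C, N, O, S, or "X" for a
#' generic dummy scatterer), Cartesian `x,y,z` (Angstrom), `B` (isotropic
#' B-factor, Angstrom^2, > 0), `occ` (occupancy in (0,1]), `chain`,
#' `resno`, and `role` ("main" or "side" chain).
#'
#' @param element character vector of element symbols.
#' @param xyz n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param B B-factors (recycled).
#' @param occ occupancies (recycled).
#' @param chain chain identifiers (recycled).
#' @param resno residue numbers (default sequential).
#' @param role "main" or "side" per atom (recycled).
#' @return Object of class `atom_model` (also a data.frame).
#' @export
atom_model <- function(element, xyz, B = 20, occ = 1, chain = "A",
                       resno = NULL, role = "main") {
  xyz <- rbind3(xyz)
  nr <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(nr)
  df <- data.frame(element = rep_len(as.character(element), nr),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   B = rep_len(B, nr), occ = rep_len(occ, nr),
                   chain = rep_len(chain, nr),
                   resno = rep_len(resno, nr),
                   role = rep_len(role, nr),
                   stringsAsFactors = FALSE)
  if (any(df$occ <= 0 | df$occ > 1)) stop("occupancy must be in (0,1]")
  if (any(df$B <= 0)) stop("B-factors must be positive")
  if (!all(df$role %in% c("main", "side")))
    stop('role must be "main" or "side"')
  class(df) <- c("atom_model", "data.frame")
  df
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("atom_model: %d atoms (%d main-chain, %d side-chain)\n",
              nrow(x), sum(x$role == "main"), sum(x$role == "side")))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Cartesian coordinates of a model as a matrix
#' @param model an [atom_model()].
#' @return n x 3 numeric matrix.
#' @export
model_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])

# single-Gaussian form factors f(s) = a * exp(-b s^2 / 4), s = 1/d.
# Coarse one-Gaussian fits to the electron counts / widths of the common
# protein elements; "X" is the generic dummy scatterer.
FORM_FACTORS <- list(C = c(a = 6, b = 20), N = c(a = 7, b = 18),
                     O = c(a = 8, b = 16), S = c(a = 16, b = 12),
                     X = c(a = 6, b = 20))

form_factor_params <- function(element) {
  unknown <- setdiff(unique(element), names(FORM_FACTORS))
  if (length(unknown)) {
    warning(sprintf("unknown element(s) %s: using dummy scatterer",
                    paste(unknown, collapse = ", ")))
    element[element %in% unknown] <- "X"
  }
  m <- do.call(rbind, FORM_FACTORS[element])
  list(a = m[, "a"], b = m[, "b"])
}

#' Structure factors from an atomic model by direct summation
#'
#' Deterministic direct sum
#' F(h) = sum_sym sum_atoms occ * f(s) * exp(-B s^2/4) * exp(2 pi i h.x)
#' with single-Gaussian form factors per element.  This is the reciprocal
#' -space oracle the FFT paths are validated against.
#'
#' @param model an [atom_model()] (Cartesian coordinates).
#' @param cell a [unit_cell()].
#' @param sym a [sym_ops()] object (default P1).
#' @param d_min high-resolution limit in Angstrom.
#' @param hkl optional data.frame of h,k,l to evaluate.
#' @return A [reflection_set()] with `F` and `phi`.
#' @export
structure_factors_from_model <- function(model, cell, sym = sym_p1(),
                                         d_min, hkl = NULL) {
  if (nrow(model) == 0) stop("model has no atoms")
  if (is.null(hkl)) hkl <- hkl_hemisphere(cell, d_min)
  ffp <- form_factor_params(model$element)
  xf <- cart_to_frac(model_xyz(model), cell)
  hm <- as.matrix(hkl[, c("h", "k", "l")])
  gs <- cell_recip_metric(cell)
  s2 <- rowSums((hm %*% gs) * hm)
  fv <- complex(length.out = nrow(hm))
  chunk <- 4000L
  for (op in sym) {
    xs <- xf %*% t(op$R) + matrix(op$t, nrow(xf), 3, byrow = TRUE)
    for (i0 in seq(1, nrow(hm), by = chunk)) {
      ii <- i0:min(i0 + chunk - 1, nrow(hm))
      # per-reflection-per-atom scattering weight
      w <- exp(-outer(s2[ii] / 4, ffp$b + model$B, "*")) *
        matrix(model$occ * ffp$a, length(ii), nrow(model), byrow = TRUE)
      ph <- exp(2i * pi * (hm[ii, , drop = FALSE] %*% t(xs)))
      fv[ii] <- fv[ii] + rowSums(w * ph)
    }
  }
  reflection_set(hkl$h, hkl$k, hkl$l, Mod(fv), cell,
                 phi = (Arg(fv) * 180 / pi) %% 360)
}

#' Sample a model's Gaussian density on a map grid
#'
#' Real-space counterpart of [structure_factors_from_model()]: each atom
#' contributes a 3-D Gaussian a (4 pi / p)^{3/2} exp(-4 pi^2 r^2 / p) with
#' p = b_element + B, the exact Fourier pair of its scattering factor.
#' Symmetry mates are included; periodic images are handled by wrapping.
#'
#' @inheritParams structure_factors_from_model
#' @param grid integer (nx,ny,nz).
#' @param rho_cut relative Gaussian tail cutoff (default 1e-5).
#' @return A [map_grid()] (not band-limited; mean subtracted so the map is
#'   zero-mean like every synthesis in this package).
#' @export
model_density_map <- function(model, cell, grid, sym = sym_p1(),
                              rho_cut = 1e-5) {
  if (nrow(model) == 0) stop("model has no atoms")
  n <- as.integer(grid)
  o <- cell_orth(cell)
  rho <- array(0, dim = n)
  ffp <- form_factor_params(model$element)
  xf <- cart_to_frac(model_xyz(model), cell)
  for (op in sym) {
    xs <- xf %*% t(op$R) + matrix(op$t, nrow(xf), 3, byrow = TRUE)
    for (ai in seq_len(nrow(model))) {
      p <- ffp$b[ai] + model$B[ai]
      rcut <- sqrt(p * log(1 / rho_cut)) / (2 * pi)
      amp <- model$occ[ai] * ffp$a[ai] * (4 * pi / p)^1.5
      ctr <- xs[ai, ] %% 1
      # voxel ranges covering the cutoff sphere (orthogonal bound per axis)
      ext <- rcut / c(cell$a, cell$b, cell$c) * 1.2
      i1 <- floor((ctr - ext) * n); i2 <- ceiling((ctr + ext) * n)
      gx <- i1[1]:i2[1]; gy <- i1[2]:i2[2]; gz <- i1[3]:i2[3]
      df <- cbind(rep(gx / n[1] - ctr[1], times = length(gy) * length(gz)),
                  rep(rep(gy / n[2] - ctr[2], each = length(gx)),
                      times = length(gz)),
                  rep(gz / n[3] - ctr[3], each = length(gx) * length(gy)))
      r2 <- rowSums((df %*% t(o))^2)
      v <- amp * exp(-4 * pi^2 * r2 / p)
      idx <- 1 + (rep(gx, times = length(gy) * length(gz)) %% n[1]) +
        n[1] * ((rep(rep(gy, each = length(gx)), times = length(gz)) %% n[2]) +
                  n[2] * (rep(gz, each = length(gx) * length(gy)) %% n[3]))
      keep <- r2 <= rcut^2
      acc <- tapply(v[keep], idx[keep], sum)  # duplicate wraps can collide
      ia <- as.integer(names(acc))
      rho[ia] <- rho[ia] + as.numeric(acc)
    }
  }
  rho <- rho - mean(rho)
  map_grid(cell, rho)
}

#' Read and write models as PDB files
#'
#' Thin wrappers over `bio3d`: ATOM records only.  Main-chain pseudo-atoms
#' are written with atom name CA, side-chain ones with CB; the mapping is
#' inverted on read.
#'
#' @param path file path.
#' @return `read_pdb_model` returns an [atom_model()].
#' @export
read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  elem[is.na(elem) | elem == ""] <- "X"
  atom_model(elem, cbind(at$x, at$y, at$z),
             B = ifelse(is.na(at$b), 20, at$b),
             occ = ifelse(is.na(at$o), 1, at$o),
             chain = ifelse(is.na(at$chain), "A", at$chain),
             resno = at$resno,
             role = ifelse(trimws(at$elety) == "CA", "main", "side"))
}

#' @rdname read_pdb_model
#' @param model an [atom_model()] to write.
#' @export
write_pdb_model <- function(model, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(model_xyz(model))),
                   type = rep("ATOM", nrow(model)),
                   resno = model$resno,
                   resid = rep("ALA", nrow(model)),
                   chain = model$chain,
                   elety = ifelse(model$role == "main", "CA", "CB"),
                   o = model$occ, b = model$B,
                   elesy = model$element)
  invisible(path)
}
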