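# Molecular replacement by exhaustive amplitude-correlation search.
# The boxed EM map's Fourier transform is the molecular transform; rotations
# resample its amplitudes in reciprocal space, translations add the
# symmetry-copy interference via the phase-shift theorem.

#' ZYZ Euler angles (degrees) to a rotation matrix
#' @param alpha,beta,gamma Euler angles in degrees, R = Rz(a) Ry(b) Rz(g).
#' @export
euler_to_matrix <- function(alpha, beta, gamma) {
  rz <- function(t) {
    c <- cos(t * pi / 180); s <- sin(t * pi / 180)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3)
  }
  ry <- function(t) {
    c <- cos(t * pi / 180); s <- sin(t * pi / 180)
    matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Geodesic distance between rotations, in degrees
#' @param R1,R2 3x3 rotation matrices.
#' @export
rotation_distance <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' A molecular-replacement placement
#'
#' @param rotation 3x3 orthonormal matrix (Cartesian rotation applied to
#'   the boxed map's density).
#' @param translation fractional position of the box centre in the crystal
#'   cell, components wrapped to [0,1).
#' @param score amplitude correlation in [-1,1].
#' @param z_score translation-function Z-score.
#' @return Object of class `placement`.
#' @export
placement <- function(rotation, translation, score = NA_real_,
                      z_score = NA_real_) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation) %% 1,
                 score = score, z_score = z_score),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("placement: score %.4f, Z %.2f, t = (%.4f, %.4f, %.4f)\n",
              x$score, x$z_score, x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

# complex trilinear interpolation of an SF array at continuous reciprocal
# grid coordinates q (m x 3, units of box reciprocal-lattice points)
interp_sf_complex <- function(farr, q) {
  n <- dim(farr)
  if (any(abs(q) > matrix(n / 2 - 1, nrow(q), 3, byrow = TRUE)))
    stop("requested resolution beyond the box transform's limit")
  u <- cbind(q[, 1] %% n[1], q[, 2] %% n[2], q[, 3] %% n[3])
  complex(real = trilinear_periodic(Re(farr), u),
          imaginary = trilinear_periodic(Im(farr), u))
}

# sampled molecular transform of a boxed, centred map.  The density is
# zero-padded into a `pad`-times larger box (finer reciprocal sampling)
# and the box-centre phase ramp is removed so the interpolated array is
# the smooth transform of the molecule at the origin.
boxed_transform <- function(em_map, pad = 2L) {
  n <- dim(em_map$rho)
  np <- n * pad
  big <- array(0, np)
  off <- (np - n) %/% 2
  big[off[1] + seq_len(n[1]), off[2] + seq_len(n[2]),
      off[3] + seq_len(n[3])] <- em_map$rho
  cellp <- unit_cell(em_map$cell$a * pad, em_map$cell$b * pad,
                     em_map$cell$c * pad, em_map$cell$alpha,
                     em_map$cell$beta, em_map$cell$gamma)
  # the original voxel [1,1,1] (frac 0) lands at index off+1, so the box
  # centre sits at fractional (off + n/2)/np; remove that phase ramp
  farr <- fft(big, inverse = TRUE) * (cell_volume(cellp) / prod(np))
  ix <- outer_grid_index(np)
  hm <- cbind(signed_index(ix[, 1], np[1]), signed_index(ix[, 2], np[2]),
              signed_index(ix[, 3], np[3]))
  ctr <- (off + n / 2) / np
  ph <- exp(-2i * pi * as.vector(hm %*% ctr))
  structure(list(sf = array(ph * as.vector(farr), np), cell = cellp),
            class = "boxed_transform")
}

# F_m(s_cart) for a molecule at the origin, from a boxed_transform
molecular_transform <- function(bt, s_cart) {
  q <- s_cart %*% cell_orth(bt$cell)   # rows: t(O) %*% s
  interp_sf_complex(bt$sf, q)
}

# ZYZ Euler grid with beta-dependent alpha spacing (avoids pole oversampling)
euler_grid <- function(step, alpha_range = c(0, 360), beta_range = c(0, 180),
                       gamma_range = c(0, 360)) {
  betas <- seq(beta_range[1], beta_range[2], by = step)
  out <- list()
  for (b in betas) {
    astep <- step / max(sin(b * pi / 180), step / 120)
    alphas <- seq(alpha_range[1], alpha_range[2], by = astep)
    alphas <- alphas[alphas < alpha_range[2] | alpha_range[1] == alpha_range[2]]
    if (!length(alphas)) alphas <- alpha_range[1]
    gammas <- seq(gamma_range[1], gamma_range[2], by = step)
    gammas <- gammas[gammas < gamma_range[2] | gamma_range[1] == gamma_range[2]]
    if (!length(gammas)) gammas <- gamma_range[1]
    out[[length(out) + 1]] <- expand.grid(alpha = alphas, beta = b,
                                          gamma = gammas)
  }
  g <- do.call(rbind, out)
  g[order(g$alpha, g$beta, g$gamma), , drop = FALSE]
}

#' Rotation search against observed amplitudes
#'
#' Scores every rotation on a ZYZ Euler grid by the Pearson correlation
#' between observed amplitudes and the rotationally resampled amplitudes
#' of the boxed map's transform, then refines around the best hits at a
#' quarter of the step.
#'
#' @param obs a [reflection_set()] of observed amplitudes (crystal cell).
#' @param em_map the boxed EM map (from [place_in_p1_box()]).
#' @param angular_step Euler grid step in degrees.
#' @param d_range c(d_low, d_high) resolution window in Angstrom; must be
#'   covered by `obs`.
#' @param limits optional list(alpha, beta, gamma) of c(min,max) ranges to
#'   restrict the search.
#' @param refine logical: two-pass coarse-to-fine refinement (step/4).
#' @param top_n number of coarse hits refined.
#' @return data.frame (alpha, beta, gamma, score) sorted by descending
#'   score; ties broken by lexicographic Euler order.
#' @export
rotation_search <- function(obs, em_map, angular_step, d_range,
                            limits = NULL, refine = TRUE, top_n = 3) {
  d_lo <- max(d_range); d_hi <- min(d_range)
  if (d_hi < min(obs$d) - 1e-6 || d_lo > max(obs$d) + 1e-6)
    stop("d_range outside the resolution coverage of obs")
  sel <- obs$d <= d_lo + 1e-9 & obs$d >= d_hi - 1e-9
  if (sum(sel) < 10) stop("too few reflections in d_range")
  cell <- get_cell(obs)
  hm <- as.matrix(obs[sel, c("h", "k", "l")])
  s_cart <- hm %*% solve(cell_orth(cell))
  fobs <- obs$F[sel]
  bt <- boxed_transform(em_map)
  amp_box <- Mod(bt$sf)
  obox <- cell_orth(bt$cell)
  if (is.null(limits)) limits <- list(alpha = c(0, 360), beta = c(0, 180),
                                      gamma = c(0, 360))
  score_one <- function(R) {
    q <- (s_cart %*% R) %*% obox
    n <- dim(amp_box)
    u <- cbind(q[, 1] %% n[1], q[, 2] %% n[2], q[, 3] %% n[3])
    a <- trilinear_periodic(amp_box, u)
    if (sd(a) == 0) return(0)
    cor(fobs, a)
  }
  run_grid <- function(grid) {
    grid$score <- vapply(seq_len(nrow(grid)), function(i) {
      score_one(euler_to_matrix(grid$alpha[i], grid$beta[i], grid$gamma[i]))
    }, numeric(1))
    grid[order(-grid$score, grid$alpha, grid$beta, grid$gamma), ,
         drop = FALSE]
  }
  # guard: highest requested resolution must stay inside the box transform
  qmax <- max(abs((s_cart %*% diag(3)) %*% obox))
  if (qmax > min(dim(amp_box)) / 2 - 1)
    stop("d_range finer than the boxed map's transform supports")
  res <- run_grid(euler_grid(angular_step, limits$alpha, limits$beta,
                             limits$gamma))
  if (refine && angular_step > 1) {
    fine <- angular_step / 4
    tops <- head(res, top_n)
    extra <- do.call(rbind, lapply(seq_len(nrow(tops)), function(i) {
      euler_grid(fine,
                 tops$alpha[i] + c(-1, 1) * angular_step,
                 pmin(pmax(tops$beta[i] + c(-1, 1) * angular_step, 0), 180),
                 tops$gamma[i] + c(-1, 1) * angular_step)
    }))
    extra$alpha <- extra$alpha %% 360; extra$gamma <- extra$gamma %% 360
    res <- rbind(res, run_grid(extra))
    res <- res[order(-res$score, res$alpha, res$beta, res$gamma), ,
               drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Translation search at a fixed rotation
#'
#' Builds symmetry-expanded model amplitudes for every fractional
#' translation on a grid (phase-shift theorem) and scores the amplitude
#' correlation with the observations.
#'
#' @inheritParams rotation_search
#' @param rotation 3x3 rotation matrix from [rotation_search()].
#' @param sym crystal [sym_ops()].
#' @param grid_step translation grid step in Angstrom; must not be coarser
#'   than the finest obs resolution used.
#' @param d_range optional resolution window (default: all of obs).
#' @return data.frame (tx, ty, tz, score) sorted by descending score, with
#'   attributes `rotation` and `z_score`.
#' @export
translation_search <- function(obs, em_map, rotation, sym = sym_p1(),
                               grid_step = 2, d_range = NULL) {
  cell <- get_cell(obs)
  if (max(abs(em_map$rho)) == 0) stop("no model signal (all-zero map)")
  if (is.null(d_range)) d_range <- c(max(obs$d), min(obs$d))
  d_lo <- max(d_range); d_hi <- min(d_range)
  if (grid_step > d_hi)
    stop(sprintf("grid_step (%.3g A) coarser than d_min (%.3g A)",
                 grid_step, d_hi))
  sel <- obs$d <= d_lo + 1e-9 & obs$d >= d_hi - 1e-9
  hm <- as.matrix(obs[sel, c("h", "k", "l")])
  fobs <- obs$F[sel]
  bt <- boxed_transform(em_map)
  oinv <- solve(cell_orth(cell))
  # per-op complex contributions C_s and phase-gradient indices G_s
  Cs <- list(); Gs <- list()
  for (i in seq_along(sym)) {
    op <- sym[[i]]
    g <- hm %*% op$R                       # h R_s (rows)
    s_cart <- g %*% oinv
    Cs[[i]] <- exp(2i * pi * (hm %*% op$t)) *
      molecular_transform(bt, s_cart %*% rotation)
    Gs[[i]] <- g
  }
  nt <- vapply(c(cell$a, cell$b, cell$c),
               function(a) max(2L, as.integer(ceiling(a / grid_step))),
               integer(1))
  tg <- expand.grid(tx = (0:(nt[1] - 1)) / nt[1],
                    ty = (0:(nt[2] - 1)) / nt[2],
                    tz = (0:(nt[3] - 1)) / nt[3])
  tg <- tg[order(tg$tx, tg$ty, tg$tz), , drop = FALSE]
  scores <- vapply(seq_len(nrow(tg)), function(i) {
    u <- as.numeric(tg[i, ])
    ftot <- 0 + 0i
    for (s in seq_along(Cs))
      ftot <- ftot + Cs[[s]] * exp(2i * pi * as.vector(Gs[[s]] %*% u))
    a <- Mod(ftot)
    if (sd(a) == 0) 0 else cor(fobs, a)
  }, numeric(1))
  tg$score <- scores
  tg <- tg[order(-tg$score, tg$tx, tg$ty, tg$tz), , drop = FALSE]
  rownames(tg) <- NULL
  attr(tg, "rotation") <- rotation
  attr(tg, "z_score") <- if (nrow(tg) >= 100) mr_z_score(tg$score) else NA_real_
  tg
}

#' Z-score of a translation-function score list
#'
#' (top score - mean of the rest) / sd of the rest.
#'
#' @param scores numeric vector of at least 100 translation scores.
#' @return Z-score (0, flagged degenerate, when the rest have zero spread).
#' @export
mr_z_score <- function(scores) {
  if (length(scores) < 100)
    stop("need at least 100 translation scores: use a finer grid")
  top <- max(scores)
  rest <- scores[-which.max(scores)]
  s <- sd(rest)
  if (s == 0) {
    z <- 0
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (top - mean(rest)) / s
}

#' Resample a placed EM map onto the crystal cell
#'
#' Applies the placement's rotation and translation to the boxed density,
#' expands it over the crystal symmetry operators (overlaps summed), and
#' resamples onto the requested crystal grid, ready for
#' [structure_factors_from_map()].
#'
#' @param em_map boxed EM [map_grid()].
#' @param place a [placement()].
#' @param crystal_cell the crystal [unit_cell()].
#' @param sym crystal [sym_ops()].
#' @param grid integer (nx,ny,nz) for the output map.
#' @return A [map_grid()] on the crystal cell.
#' @export
apply_placement <- function(em_map, place, crystal_cell, sym = sym_p1(),
                            grid) {
  n <- as.integer(grid)
  ocry <- cell_orth(crystal_cell)
  obox_inv <- solve(cell_orth(em_map$cell))
  nb <- dim(em_map$rho)
  box_edge <- em_map$cell$a
  if (box_edge / 2 > min(crystal_cell$a, crystal_cell$b, crystal_cell$c))
    warning("box larger than twice the crystal cell: wrapped density may overlap ambiguously")
  xf <- voxel_frac_coords(n)
  rho <- numeric(prod(n))
  rinv <- t(place$rotation)               # orthonormal inverse
  for (op in sym) {
    # y = R_s^{-1} (x - t_s); molecule frame r = R^-1 O (y - u)
    y <- sweep(xf, 2, op$t) %*% t(solve(op$R))
    dfr <- sweep(y, 2, place$translation)
    dfr <- dfr - round(dfr)
    r <- (dfr %*% t(ocry)) %*% t(rinv)
    bf <- sweep(r %*% t(obox_inv), 2, c(0.5, 0.5, 0.5), "+")
    inside <- bf[, 1] >= 0 & bf[, 1] < 1 & bf[, 2] >= 0 & bf[, 2] < 1 &
      bf[, 3] >= 0 & bf[, 3] < 1
    if (!any(inside)) next
    u <- cbind(bf[inside, 1] * nb[1], bf[inside, 2] * nb[2],
               bf[inside, 3] * nb[3])
    rho[inside] <- rho[inside] + trilinear_periodic(em_map$rho, u)
  }
  map_grid(crystal_cell, array(rho, dim = n))
}
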