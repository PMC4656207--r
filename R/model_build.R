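# Simplified automatic model building: peak picking, greedy Calpha-trace
# chaining, and conversion of the traced pseudo-model into a phase source.

#' Peak search in a density map
#'
#' Local maxima (26-neighbour) above mean + sigma_cut * sd, refined to
#' sub-voxel positions by per-axis quadratic interpolation.
#'
#' @param map a [map_grid()].
#' @param sigma_cut height threshold in map sigmas above the mean.
#' @return data.frame (x, y, z, height): Cartesian Angstrom positions
#'   sorted by descending height.
#' @export
find_peaks <- function(map, sigma_cut = 1) {
  rho <- map$rho
  n <- dim(rho)
  thr <- mean(rho) + sigma_cut * sd(as.vector(rho))
  shift <- function(a, s) {
    idx <- lapply(1:3, function(i) ((seq_len(n[i]) - 1 + s[i]) %% n[i]) + 1)
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  ismax <- rho > thr
  if (!any(ismax)) return(data.frame(x = numeric(0), y = numeric(0),
                                     z = numeric(0), height = numeric(0)))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ismax <- ismax & (rho >= shift(rho, c(dx, dy, dz)))
    if (!any(ismax)) break
  }
  sel <- which(ismax)
  if (!length(sel)) return(data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0), height = numeric(0)))
  ix <- arrayInd(sel, n)
  # quadratic sub-voxel refinement along each axis
  off <- matrix(0, length(sel), 3)
  for (ax in 1:3) {
    sp <- c(0, 0, 0); sp[ax] <- 1
    fp <- shift(rho, sp)[sel]
    sm <- shift(rho, -sp)[sel]
    f0 <- rho[sel]
    den <- sm - 2 * f0 + fp
    off[, ax] <- ifelse(abs(den) > 1e-12, pmin(pmax((sm - fp) / (2 * den),
                                                    -0.5), 0.5), 0)
  }
  xf <- sweep(ix - 1 + off, 2, n, "/")
  xc <- frac_to_cart(xf, map$cell)
  out <- data.frame(x = xc[, 1], y = xc[, 2], z = xc[, 3], height = rho[sel])
  out <- out[order(-out$height, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy Calpha-trace chaining of peaks
#'
#' Starting from the highest unused peak, repeatedly appends (at either
#' chain end) the highest unused peak at distance `spacing +/- tol`;
#' chains shorter than 4 are discarded.  Deterministic: ties are broken by
#' height, then lexicographic position.
#'
#' @param peaks data.frame from [find_peaks()].
#' @param spacing target Calpha-Calpha distance in Angstrom (default 3.8).
#' @param tol allowed deviation in Angstrom (default 0.7).
#' @return An [atom_model()] of main-chain dummy pseudo-atoms, one chain
#'   per trace, residues numbered along each chain; empty model allowed.
#' @export
trace_ca_chain <- function(peaks, spacing = 3.8, tol = 0.7) {
  empty <- atom_model(character(0), matrix(numeric(0), 0, 3))
  if (nrow(peaks) < 4) return(empty)
  xyz <- as.matrix(peaks[, c("x", "y", "z")])
  np <- nrow(xyz)
  dm <- as.matrix(dist(xyz))
  linkable <- abs(dm - spacing) <= tol
  diag(linkable) <- FALSE
  used <- rep(FALSE, np)
  chains <- list()
  repeat {
    cand <- which(!used)
    if (!length(cand)) break
    start <- cand[1]                      # peaks are height-sorted
    chain <- c(start)
    used[start] <- TRUE
    repeat {
      grew <- FALSE
      for (endi in c(length(chain), 1)) {
        endp <- chain[endi]
        nb <- which(linkable[endp, ] & !used)
        if (length(nb)) {
          nxt <- nb[which.max(peaks$height[nb])]
          used[nxt] <- TRUE
          chain <- if (endi == 1) c(nxt, chain) else c(chain, nxt)
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (length(chain) >= 4) chains[[length(chains) + 1]] <- chain
  }
  if (!length(chains)) return(empty)
  ids <- LETTERS[(seq_along(chains) - 1) %% 26 + 1]
  do.call(rbind, lapply(seq_along(chains), function(i) {
    idx <- chains[[i]]
    atom_model("X", xyz[idx, , drop = FALSE], B = 30, chain = ids[i],
               resno = seq_along(idx), role = "main")
  }))
}

#' Fraction of built atoms near a true main-chain position
#'
#' For every built atom, the distance to the nearest true main-chain atom
#' is evaluated under the crystal symmetry and lattice translations
#' (minimal image); the recovery is the fraction within `cutoff`.
#' Optionally an origin shift maximising the density overlap of the two
#' point sets is searched first (useful when phase conventions moved the
#' origin, which arbitrary P1 origins permit).
#'
#' @param built,truth [atom_model()]s.
#' @param cutoff distance cutoff in Angstrom (default 1.5).
#' @param cell a [unit_cell()]; NULL treats coordinates as non-periodic.
#' @param sym crystal [sym_ops()].
#' @param origin_search search a best origin shift (FFT cross-correlation
#'   of 1 Angstrom-smoothed point densities) before scoring.
#' @return Fraction in [0,1].
#' @export
ca_recovery <- function(built, truth, cutoff = 1.5, cell = NULL,
                        sym = sym_p1(), origin_search = FALSE) {
  if (nrow(built) == 0) return(0)
  tmain <- truth[truth$role == "main", , drop = FALSE]
  if (nrow(tmain) == 0) stop("truth model has no main-chain atoms")
  bx <- model_xyz(built)
  tx <- model_xyz(tmain)
  if (is.null(cell)) {
    d2 <- outer(rowSums(bx^2), rowSums(tx^2), "+") - 2 * bx %*% t(tx)
    mind <- sqrt(pmax(apply(d2, 1, min), 0))
    return(mean(mind <= cutoff + 1e-9))
  }
  o <- cell_orth(cell)
  tf <- cart_to_frac(tx, cell)
  texp <- do.call(rbind, lapply(sym, function(op) {
    tf %*% t(op$R) + matrix(op$t, nrow(tf), 3, byrow = TRUE)
  }))
  bf <- cart_to_frac(bx, cell)
  if (origin_search) bf <- sweep(bf, 2, best_origin_shift(bf, texp, cell))
  mind <- vapply(seq_len(nrow(bf)), function(i) {
    dfr <- sweep(texp, 2, bf[i, ])
    dfr <- dfr - round(dfr)
    sqrt(min(rowSums((dfr %*% t(o))^2)))
  }, numeric(1))
  mean(mind <= cutoff + 1e-9)
}

# best fractional origin shift of b onto t by FFT cross-correlation of
# Gaussian-smoothed point densities on a ~1 A grid
best_origin_shift <- function(bf, tf, cell, spacing = 1) {
  n <- vapply(c(cell$a, cell$b, cell$c),
              function(a) nice_fft_size(a / spacing), integer(1))
  put <- function(xf) {
    a <- array(0, n)
    idx <- 1 + (floor(xf[, 1] %% 1 * n[1]) +
                  n[1] * (floor(xf[, 2] %% 1 * n[2]) +
                            n[2] * floor(xf[, 3] %% 1 * n[3])))
    for (i in idx) a[i] <- a[i] + 1
    a
  }
  fb <- fft(put(bf)); ft <- fft(put(tf))
  cc <- Re(fft(Conj(fb) * ft, inverse = TRUE))
  best <- arrayInd(which.max(cc), n)
  (best - 1) / n
}

#' Phases from a built pseudo-atom model
#'
#' Structure factors of the traced model (dummy scatterers, uniform B),
#' with per-reflection FOM from the shell sigma-A between observed and
#' model E-values.
#'
#' @param built an [atom_model()] (typically from [trace_ca_chain()]).
#' @param obs [reflection_set()] of observed amplitudes defining the
#'   reflection list.
#' @param sym crystal [sym_ops()].
#' @param B uniform B-factor applied to every atom (default 30).
#' @param n_shells sigma-A shells (default: ~1 per 300 reflections,
#'   between 5 and 15).
#' @return A [reflection_set()] with the observed `F`, model `phi`, and
#'   sigma-A-derived `fom`; attribute `sigma_a` holds the shell curve.
#' @export
phases_from_built_model <- function(built, obs, sym = sym_p1(), B = 30,
                                    n_shells = NULL) {
  if (nrow(built) == 0) stop("no atoms to phase")
  cell <- get_cell(obs)
  mdl <- built
  mdl$B <- B
  calc <- structure_factors_from_model(mdl, cell, sym, d_min = min(obs$d),
                                       hkl = as.data.frame(obs)[, c("h", "k", "l")])
  if (is.null(n_shells))
    n_shells <- max(5L, min(15L, nrow(obs) %/% 300L))
  eo <- normalize_amplitudes(obs, n_shells)
  ec <- normalize_amplitudes(calc, n_shells)
  sa <- estimate_sigma_a(eo, ec, n_shells)
  fom <- fom_from_sigma_a(sa, eo$F, ec$F, obs$d)
  out <- reflection_set(obs$h, obs$k, obs$l, obs$F, cell, sigF = obs$sigF,
                        phi = calc$phi, fom = fom)
  attr(out, "sigma_a") <- sa
  out
}
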