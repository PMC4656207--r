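# Phase-quality metrics: FOM-weighted mean phase error, per-shell curves,
# and map correlation against a reference model.

#' FOM-weighted mean phase error (wMPE)
#'
#' wMPE = sum(m_i |dphi_i|) / sum(m_i) over the matched reflections, with
#' |dphi| the minimal-arc absolute phase difference in [0,180] degrees.
#'
#' @param test [reflection_set()] with `phi` and `fom`.
#' @param reference [reflection_set()] with reference `phi`.
#' @param weighted use the FOM weights (FALSE gives the plain mean).
#' @return wMPE in degrees.
#' @export
weighted_mean_phase_error <- function(test, reference, weighted = TRUE) {
  m <- match_reflections(test, reference)
  ok <- !is.na(m$a$phi) & !is.na(m$b$phi)
  if (!any(ok)) stop("no matched phased reflections")
  dphi <- abs(wrap_deg(m$a$phi[ok] - m$b$phi[ok]))
  w <- if (weighted) m$a$fom[ok] else rep(1, sum(ok))
  w[is.na(w)] <- 1
  if (sum(w) == 0) stop("all weights zero")
  sum(w * dphi) / sum(w)
}

#' Per-shell wMPE
#'
#' @inheritParams weighted_mean_phase_error
#' @param n_shells number of resolution shells.
#' @return A [shell_curve()] of wMPE (degrees) per shell, with attribute
#'   `weight` giving each shell's total FOM weight.
#' @export
phase_error_by_shell <- function(test, reference, n_shells) {
  m <- match_reflections(test, reference)
  ok <- !is.na(m$a$phi) & !is.na(m$b$phi)
  a <- m$a[ok, , drop = FALSE]; b <- m$b[ok, , drop = FALSE]
  shell <- shell_assign(a$d, n_shells)
  dphi <- abs(wrap_deg(a$phi - b$phi))
  w <- a$fom
  w[is.na(w)] <- 1
  vals <- vapply(seq_len(n_shells), function(s) {
    sel <- shell == s
    if (!any(sel) || sum(w[sel]) == 0) return(NA_real_)
    sum(w[sel] * dphi[sel]) / sum(w[sel])
  }, numeric(1))
  dmx <- vapply(seq_len(n_shells), function(s)
    if (any(shell == s)) max(a$d[shell == s]) else NA_real_, numeric(1))
  dmn <- vapply(seq_len(n_shells), function(s)
    if (any(shell == s)) min(a$d[shell == s]) else NA_real_, numeric(1))
  ns <- n_shells
  bounds <- c(Inf, (dmn[-ns] + dmx[-1]) / 2, 0)
  out <- shell_curve(bounds[-(ns + 1)], bounds[-1], vals)
  attr(out, "weight") <- vapply(seq_len(ns), function(s) sum(w[shell == s]),
                                numeric(1))
  out
}

#' Map correlation coefficient against a reference model
#'
#' Pearson correlation between the map and the reference model's map
#' (band-limited to d_min), restricted to voxels within `atom_radius` of
#' atoms of the requested role; voxels claimed by both roles go to the
#' nearer atom.
#'
#' @param map a [map_grid()].
#' @param reference_model an [atom_model()].
#' @param d_min resolution (Angstrom) at which the model map is computed.
#' @param region "all", "main", or "side".
#' @param atom_radius mask radius around each atom, Angstrom (default 2).
#' @param sym crystal [sym_ops()].
#' @param model_map optional precomputed model [map_grid()] on the same
#'   grid (skips the density calculation).
#' @return Pearson correlation in [-1,1].
#' @export
map_correlation <- function(map, reference_model, d_min,
                            region = c("all", "main", "side"),
                            atom_radius = 2, sym = sym_p1(),
                            model_map = NULL) {
  region <- match.arg(region)
  n <- dim(map$rho)
  if (is.null(model_map)) {
    model_map <- model_density_map(reference_model, map$cell, n, sym)
    model_map <- lowpass_map(model_map, d_min)
  }
  rd <- role_distance_arrays(reference_model, map$cell, n, sym, atom_radius)
  sel <- switch(region,
                all = rd$main <= atom_radius | rd$side <= atom_radius,
                main = rd$main <= atom_radius & rd$main <= rd$side,
                side = rd$side <= atom_radius & rd$side < rd$main)
  if (!any(sel)) stop("region mask is empty")
  cor(as.vector(map$rho)[sel], as.vector(model_map$rho)[sel])
}

# per-voxel distance to the nearest main-chain / side-chain atom, capped:
# voxels farther than `radius` from every atom of a role hold Inf
role_distance_arrays <- function(model, cell, n, sym, radius) {
  o <- cell_orth(cell)
  xf <- cart_to_frac(model_xyz(model), cell)
  res <- list(main = rep(Inf, prod(n)), side = rep(Inf, prod(n)))
  ext <- radius / c(cell$a, cell$b, cell$c) * 1.2
  for (op in sym) {
    xs <- xf %*% t(op$R) + matrix(op$t, nrow(xf), 3, byrow = TRUE)
    for (ai in seq_len(nrow(model))) {
      ctr <- xs[ai, ] %% 1
      i1 <- floor((ctr - ext) * n); i2 <- ceiling((ctr + ext) * n)
      gx <- i1[1]:i2[1]; gy <- i1[2]:i2[2]; gz <- i1[3]:i2[3]
      df <- cbind(rep(gx / n[1] - ctr[1], times = length(gy) * length(gz)),
                  rep(rep(gy / n[2] - ctr[2], each = length(gx)),
                      times = length(gz)),
                  rep(gz / n[3] - ctr[3], each = length(gx) * length(gy)))
      r <- sqrt(rowSums((df %*% t(o))^2))
      idx <- 1 + (rep(gx, times = length(gy) * length(gz)) %% n[1]) +
        n[1] * ((rep(rep(gy, each = length(gx)), times = length(gz)) %% n[2]) +
                  n[2] * (rep(gz, each = length(gx) * length(gy)) %% n[3]))
      role <- model$role[ai]
      cur <- res[[role]][idx]
      res[[role]][idx] <- pmin(cur, r)
    }
  }
  res
}
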