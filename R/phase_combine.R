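# sigma-A estimation, figures of merit, and weighted phase combination.

# I1(x)/I0(x), numerically safe for large x (scaled Bessel ratio; the
# asymptotic 1 - 1/(2x) - 1/(8x^2) branch avoids besselI overflow)
bessel_ratio <- function(x) {
  out <- numeric(length(x))
  mid <- x > 0 & x <= 2000
  out[mid] <- besselI(x[mid], 1, expon.scaled = TRUE) /
    besselI(x[mid], 0, expon.scaled = TRUE)
  big <- x > 2000
  out[big] <- 1 - 1 / (2 * x[big]) - 1 / (8 * x[big]^2)
  out
}

# derivative of the Bessel ratio m(X): m'(X) = 1 - m^2 - m/X
bessel_ratio_deriv <- function(x, m) ifelse(x > 0, 1 - m^2 - m / x, 0.5)

# internal: E-values and shell indices from amplitudes + resolutions
normalize_amplitudes_values <- function(F, d, n_shells) {
  shell <- shell_assign(d, n_shells)
  ms <- tapply(F^2, shell, mean)
  E <- F / sqrt(ms[as.character(shell)])
  list(E = as.numeric(E), shell = shell)
}

#' Normalized structure-factor amplitudes (E-values)
#'
#' E = F / sqrt(mean F^2 in shell), so every shell has mean E^2 = 1.
#'
#' @param refl a [reflection_set()].
#' @param n_shells number of resolution shells.
#' @return The reflection set with `F` replaced by E-values and a `shell`
#'   attribute of per-reflection shell indices.
#' @export
normalize_amplitudes <- function(refl, n_shells) {
  nv <- normalize_amplitudes_values(refl$F, refl$d, n_shells)
  out <- refl
  out$F <- nv$E
  attr(out, "shell") <- nv$shell
  out
}

# internal sigma-A per shell from the intensity correlation: for
# acentric data corr(E_obs^2, E_calc^2) = sigma_A^4, so
# sigma_A = clip(corr, 0, 1)^(1/4).  (The raw amplitude product
# <E_obs E_calc> is biased: it tends to ~0.785, not 0, for independent
# data, so it cannot serve as an estimator.)  Shells with fewer than 8
# reflections are merged into a neighbour.
shell_sigma_a <- function(E_obs, E_calc, shell) {
  ns <- max(shell)
  cnt <- tabulate(shell, ns)
  small <- which(cnt < 8 & cnt > 0)
  if (length(small)) {
    warning("sigma-A shells with < 8 reflections merged with neighbours")
    for (s in small) {
      tgt <- if (s > 1) s - 1 else s + 1
      shell[shell == s] <- tgt
    }
  }
  sa <- rep(0, ns)
  for (s in unique(shell)) {
    io <- E_obs[shell == s]^2; ic <- E_calc[shell == s]^2
    if (sd(io) == 0 || sd(ic) == 0) next
    m4 <- cor(io, ic)  # corr of normalized intensities = sigma_A^4
    sa[s] <- min(max(m4, 0), 1)^0.25
  }
  # fill merged-away shells from their absorbing neighbour
  for (s in seq_len(ns)) if (!(s %in% unique(shell)) && s > 1) sa[s] <- sa[s - 1]
  pmin(pmax(sa, 0), 0.999)
}

#' Estimate sigma-A per resolution shell
#'
#' Moment estimator: per shell, sigma_A^4 is estimated by the Pearson
#' correlation of normalized intensities over the matched reflections
#' (the acentric identity corr(E_o^2, E_c^2) = sigma_A^4), clipped to
#' [0, 1] before the fourth root and to [0, 0.999] after.  Shells with
#' fewer than 8 reflections are merged with a neighbour (with a warning).
#'
#' @param E_obs,E_calc matched [reflection_set()]s of E-values (from
#'   [normalize_amplitudes()]), identical (h,k,l) order.
#' @param n_shells number of resolution shells.
#' @return A [shell_curve()] of sigma-A values.
#' @export
estimate_sigma_a <- function(E_obs, E_calc, n_shells) {
  stopifnot(nrow(E_obs) == nrow(E_calc))
  shell <- shell_assign(E_obs$d, n_shells)
  sa <- shell_sigma_a(E_obs$F, E_calc$F, shell)
  dmx <- tapply(E_obs$d, shell, max)
  dmn <- tapply(E_obs$d, shell, min)
  # contiguous bounds: midpoints between adjacent shells
  ns <- length(sa)
  hi <- as.numeric(dmx); lo <- as.numeric(dmn)
  bounds <- c(Inf, (lo[-ns] + hi[-1]) / 2, 0)
  shell_curve(bounds[-(ns + 1)], bounds[-1], sa)
}

#' Figure of merit from sigma-A
#'
#' X = 2 sigma_A E_obs E_calc / (1 - sigma_A^2); the acentric FOM is the
#' Bessel ratio m = I1(X)/I0(X), the centric one tanh(X/2).
#'
#' @param sigA a [shell_curve()] from [estimate_sigma_a()].
#' @param E_obs,E_calc per-reflection E-values (matched vectors).
#' @param d per-reflection resolutions (to look up the shell).
#' @param centric optional logical vector (default all acentric).
#' @return FOM per reflection, in [0,1).
#' @export
fom_from_sigma_a <- function(sigA, E_obs, E_calc, d, centric = NULL) {
  sa <- shell_lookup(sigA, d)
  sa[is.na(sa)] <- 0
  X <- 2 * sa * E_obs * E_calc / (1 - sa^2)
  m <- bessel_ratio(X)
  if (!is.null(centric)) m[centric] <- tanh(X[centric] / 2)
  pmin(m, 0.9999)
}

#' Invert the Bessel-ratio figure of merit
#'
#' Numeric inverse of m = I1(X)/I0(X) (von Mises concentration from its
#' mean resultant), accurate to ~1e-8 via monotone-spline initialisation
#' plus Newton steps.
#'
#' @param m figures of merit in [0, 1).
#' @return X >= 0 with `bessel_ratio(X)` equal to `m`.
#' @export
fom_to_concentration <- function(m) {
  m <- pmin(pmax(m, 0), 0.999999)
  # initial guess: small-m series X ~ 2m + m^3, large-m X ~ 1/(2(1-m))
  x <- ifelse(m < 0.6, 2 * m + m^3 + m^5,
              1 / (2 * (1 - m)) - 0.5)
  x <- pmax(x, 1e-12)
  for (i in 1:40) {
    f <- bessel_ratio(x) - m
    xp <- x - f / bessel_ratio_deriv(x, f + m)
    xp <- pmax(xp, x / 10)
    if (max(abs(xp - x)) < 1e-12 * (1 + max(x))) {
      x <- xp
      break
    }
    x <- xp
  }
  x[m <= 0] <- 0
  x
}

#' Combine two unimodal phase sources
#'
#' Von Mises (unimodal) phase combination: each source's (phi, fom) is
#' turned into a concentration vector X (exp(i phi)), the vectors are
#' added, and the combined FOM is the Bessel ratio of the resultant
#' length.  Reflections present in only one source pass through unchanged.
#' Exact cancellation gives fom 0 (phase degenerate, kept at source 1).
#'
#' @param src1,src2 [reflection_set()]s with `phi` and `fom`.
#' @return A [reflection_set()] over the union of indices with combined
#'   `phi` and `fom` (and `F` from whichever source provides it).
#' @export
combine_phases <- function(src1, src2) {
  for (s in list(src1, src2))
    if (anyDuplicated(hkl_key(s))) stop("duplicated (h,k,l) within a source")
  cell <- get_cell(src1)
  k1 <- hkl_key(src1); k2 <- hkl_key(src2)
  keys <- union(k1, k2)
  i1 <- match(keys, k1); i2 <- match(keys, k2)
  phi1 <- src1$phi[i1]; fom1 <- src1$fom[i1]
  phi2 <- src2$phi[i2]; fom2 <- src2$fom[i2]
  Fv <- ifelse(is.na(i1), src2$F[i2], src1$F[i1])
  hkl <- do.call(rbind, strsplit(keys, ","))
  h <- as.integer(hkl[, 1]); k <- as.integer(hkl[, 2])
  l <- as.integer(hkl[, 3])
  only1 <- is.na(i2) | is.na(fom2) | is.na(phi2)
  only2 <- is.na(i1) | is.na(fom1) | is.na(phi1)
  both <- !only1 & !only2
  phi <- ifelse(only2, phi2, phi1)
  fom <- ifelse(only2, fom2, fom1)
  if (any(both)) {
    x1 <- fom_to_concentration(fom1[both])
    x2 <- fom_to_concentration(fom2[both])
    a1 <- phi1[both] * pi / 180; a2 <- phi2[both] * pi / 180
    A <- x1 * cos(a1) + x2 * cos(a2)
    B <- x1 * sin(a1) + x2 * sin(a2)
    r <- sqrt(A^2 + B^2)
    phc <- ifelse(r > 1e-12, (atan2(B, A) * 180 / pi) %% 360, phi1[both])
    phi[both] <- phc
    fom[both] <- pmin(bessel_ratio(r), 0.9999)
  }
  fom <- pmin(pmax(fom, 0), 0.9999)
  out <- reflection_set(h, k, l, Fv, cell, phi = phi, fom = fom)
  out <- out[order(out$h, out$k, out$l), , drop = FALSE]
  rownames(out) <- NULL
  out
}
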