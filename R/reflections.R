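#' Reflection set
#'
#' A data frame of Miller-indexed reflection records: columns `h,k,l`
#' (integer), `F` (amplitude, arbitrary consistent scale), and optionally
#' `sigF`, `phi` (phase in degrees, [0,360)), `fom` (figure of merit in
#' [0,1]), plus the derived `d` (resolution in Angstrom).  The associated
#' [unit_cell()] is carried in the `"cell"` attribute.  Indices must be
#' unique and lie on the Friedel hemisphere (h>0), (h=0,k>0) or
#' (h=k=0,l>0).
#'
#' @param h,k,l integer Miller indices.
#' @param F non-negative amplitudes.
#' @param cell a [unit_cell()].
#' @param sigF,phi,fom optional per-reflection columns (NA allowed).
#' @return Object of class `reflection_set` (also a data.frame).
#' @export
reflection_set <- function(h, k, l, F, cell, sigF = NULL, phi = NULL,
                           fom = NULL) {
  h <- as.integer(round(h)); k <- as.integer(round(k))
  l <- as.integer(round(l))
  if (anyDuplicated(paste(h, k, l))) stop("duplicate (h,k,l) records")
  if (any(h == 0 & k == 0 & l == 0)) stop("F000 is excluded by convention")
  if (any(F < 0, na.rm = TRUE)) stop("amplitudes must be non-negative")
  df <- data.frame(h = h, k = k, l = l, F = as.numeric(F))
  df$sigF <- if (is.null(sigF)) NA_real_ else as.numeric(sigF)
  df$phi <- if (is.null(phi)) NA_real_ else as.numeric(phi) %% 360
  df$fom <- if (is.null(fom)) NA_real_ else as.numeric(fom)
  if (any(df$fom < 0 | df$fom > 1, na.rm = TRUE))
    stop("fom must lie in [0,1]")
  df$d <- resolution_of(df$h, df$k, df$l, cell)
  attr(df, "cell") <- cell
  class(df) <- c("reflection_set", "data.frame")
  df
}

#' @export
print.reflection_set <- function(x, ...) {
  cell <- attr(x, "cell")
  cat(sprintf("reflection_set: %d reflections, d %.2f - %.2f A\n",
              nrow(x), max(x$d), min(x$d)))
  if (!is.null(cell)) print(cell)
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Cell of a reflection set or map
#' @param x a `reflection_set` or `map_grid`.
#' @export
get_cell <- function(x) {
  if (inherits(x, "map_grid")) x$cell else attr(x, "cell")
}

#' Miller indices of the unique Friedel hemisphere to a resolution limit
#'
#' Enumerates all (h,k,l) with d >= d_min on the hemisphere (h>0) or
#' (h=0,k>0) or (h=k=0,l>0); F000 is excluded.
#'
#' @param cell a [unit_cell()].
#' @param d_min high-resolution limit in Angstrom.
#' @param d_max optional low-resolution limit (default Inf).
#' @return data.frame with columns h,k,l,d sorted by descending d.
#' @export
hkl_hemisphere <- function(cell, d_min, d_max = Inf) {
  stopifnot(d_min > 0)
  hmax <- ceiling(cell$a / d_min) + 1
  kmax <- ceiling(cell$b / d_min) + 1
  lmax <- ceiling(cell$c / d_min) + 1
  g <- expand.grid(h = 0:hmax, k = -kmax:kmax, l = -lmax:lmax)
  keep <- (g$h > 0) | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0)
  g <- g[keep, , drop = FALSE]
  gs <- cell_recip_metric(cell)
  hm <- as.matrix(g)
  d <- 1 / sqrt(rowSums((hm %*% gs) * hm))
  ok <- d >= d_min - 1e-9 & d <= d_max
  g <- g[ok, , drop = FALSE]
  g$d <- d[ok]
  g <- g[order(-g$d, g$h, g$k, g$l), ]
  rownames(g) <- NULL
  g
}

# canonical string key for joins
hkl_key <- function(x) paste(x$h, x$k, x$l, sep = ",")

#' Match two reflection sets on (h,k,l)
#'
#' @param a,b reflection sets (or data frames with h,k,l).
#' @return list of two data frames restricted to the common indices, in
#'   identical order.
#' @export
match_reflections <- function(a, b) {
  ka <- hkl_key(a); kb <- hkl_key(b)
  common <- intersect(ka, kb)
  list(a = a[match(common, ka), , drop = FALSE],
       b = b[match(common, kb), , drop = FALSE])
}

#' Read/write columnar reflection text files
#'
#' Whitespace-separated text with header line `h k l F sigF phi fom`
#' (missing trailing columns allowed).  `phi` in degrees, `d` is recomputed
#' from the cell on read.
#'
#' @param path file path.
#' @param cell a [unit_cell()] (needed on read to derive resolutions).
#' @return `read_hkl` returns a [reflection_set()].
#' @export
read_hkl <- function(path, cell) {
  df <- read.table(path, header = TRUE)
  need <- c("h", "k", "l", "F")
  if (!all(need %in% names(df)))
    stop("reflection file must have columns h k l F")
  reflection_set(df$h, df$k, df$l, df$F, cell,
                 sigF = if ("sigF" %in% names(df)) df$sigF,
                 phi = if ("phi" %in% names(df)) df$phi,
                 fom = if ("fom" %in% names(df)) df$fom)
}

#' @rdname read_hkl
#' @param refl a [reflection_set()] to write.
#' @export
write_hkl <- function(refl, path) {
  df <- as.data.frame(refl)[, c("h", "k", "l", "F", "sigF", "phi", "fom")]
  write.table(format(df, digits = 10, trim = TRUE), path,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolution shell assignment with (near-)equal reflection counts
#'
#' Shells are bins of 1/d^3 (equal reciprocal volume per shell would be
#' equal counts for complete data); assignment is by quantiles of 1/d^3 so
#' counts are balanced even for incomplete sets.
#'
#' @param d resolutions in Angstrom.
#' @param n_shells number of shells.
#' @return integer shell index in 1..n_shells (1 = lowest resolution).
#' @export
shell_assign <- function(d, n_shells) {
  if (n_shells < 1) stop("n_shells must be >= 1")
  if (n_shells == 1) return(rep(1L, length(d)))
  s3 <- 1 / d^3
  br <- quantile(s3, probs = seq(0, 1, length.out = n_shells + 1),
                 names = FALSE, type = 7)
  br[1] <- -Inf; br[n_shells + 1] <- Inf
  br <- cummax(br)  # guard against ties
  findInterval(s3, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' @export
`[.reflection_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "cell") <- attr(x, "cell")
    class(out) <- class(x)
  }
  out
}
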