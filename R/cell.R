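#' Unit cell
#'
#' Construct a unit cell from edge lengths (Angstrom) and angles (degrees).
#'
#' @param a,b,c cell edges in Angstrom, positive.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(60, 60, 60)
#' unit_cell(10, 12, 15, 80, 95, 100)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell edges must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  # positive-definiteness of the metric <=> positive squared volume
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("cell angles give a degenerate (non-positive) metric")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Orthogonalization matrix (a along x)
#'
#' Columns are the cell basis vectors in Cartesian Angstrom;
#' `cartesian = O %*% fractional`.
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
cell_orth <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3)
}

#' Cell volume in cubic Angstrom
#' @param cell a [unit_cell()].
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  cell$a * cell$b * cell$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Real-space metric tensor G (G_ij = a_i . a_j)
#' @param cell a [unit_cell()].
#' @export
cell_metric <- function(cell) {
  o <- cell_orth(cell)
  t(o) %*% o
}

#' Reciprocal metric tensor (inverse of the real-space metric)
#' @param cell a [unit_cell()].
#' @export
cell_recip_metric <- function(cell) solve(cell_metric(cell))

#' Fractional to Cartesian coordinates
#' @param xf n x 3 matrix (or length-3 vector) of fractional coordinates.
#' @param cell a [unit_cell()].
#' @return n x 3 matrix of Cartesian coordinates in Angstrom.
#' @export
frac_to_cart <- function(xf, cell) {
  xf <- rbind3(xf)
  xf %*% t(cell_orth(cell))
}

#' Cartesian to fractional coordinates
#' @param xc n x 3 matrix (or length-3 vector) of Cartesian Angstrom.
#' @param cell a [unit_cell()].
#' @export
cart_to_frac <- function(xc, cell) {
  xc <- rbind3(xc)
  xc %*% t(solve(cell_orth(cell)))
}

# coerce vector -> 1x3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Resolution of Miller indices
#'
#' d-spacing of reflections (h,k,l) in a given cell, d = 1/|s| with s the
#' reciprocal-lattice vector.
#'
#' @param h,k,l integer Miller indices (vectors of equal length).
#' @param cell a [unit_cell()].
#' @return d in Angstrom, positive.
#' @examples
#' resolution_of(1, 0, 0, unit_cell(10, 10, 10))  # 10
#' @export
resolution_of <- function(h, k, l, cell) {
  if (any(h == 0 & k == 0 & l == 0)) stop("F000 has no resolution")
  gs <- cell_recip_metric(cell)
  hm <- cbind(h, k, l)
  s2 <- rowSums((hm %*% gs) * hm)
  1 / sqrt(s2)
}

#' Crystallographic symmetry operators
#'
#' A list of (rotation, translation) pairs acting on fractional coordinates
#' as `x -> R %*% x + t`.  The identity must be (and is kept) first.
#'
#' @param rotations list of 3x3 matrices (integer or rational entries).
#' @param translations list of length-3 fractional translation vectors.
#' @return Object of class `sym_ops` (a list of `list(R, t)`).
#' @export
sym_ops <- function(rotations, translations) {
  stopifnot(length(rotations) == length(translations))
  ops <- Map(function(R, t) list(R = matrix(as.numeric(R), 3, 3),
                                 t = as.numeric(t) %% 1),
             rotations, translations)
  idn <- vapply(ops, function(o) {
    max(abs(o$R - diag(3))) < 1e-9 && max(abs(o$t)) < 1e-9
  }, logical(1))
  if (!any(idn)) stop("identity operator missing")
  ops <- c(ops[which(idn)[1]], ops[!seq_along(ops) %in% which(idn)[1]])
  structure(ops, class = "sym_ops")
}

#' @rdname sym_ops
#' @export
sym_p1 <- function() sym_ops(list(diag(3)), list(c(0, 0, 0)))

#' @rdname sym_ops
#' @details `sym_p21()` returns the two operators of P2\eqn{_1} with the
#'   screw axis along b: (x,y,z) and (-x, y+1/2, -z).
#' @export
sym_p21 <- function() {
  sym_ops(list(diag(3), diag(c(-1, 1, -1))),
          list(c(0, 0, 0), c(0, 0.5, 0)))
}

#' @export
print.sym_ops <- function(x, ...) {
  cat(sprintf("sym_ops: %d operator(s)\n", length(x)))
  invisible(x)
}

#' Number of symmetry operators
#' @param sym a [sym_ops()] object.
#' @export
n_sym_ops <- function(sym) length(sym)

# wrap fractional differences to [-0.5, 0.5)
wrap_frac <- function(x) x - round(x)

# wrap phase difference in degrees to [-180, 180)
wrap_deg <- function(x) {
  ((x + 180) %% 360) - 180
}
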