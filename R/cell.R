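#' Unit cell
#'
#' Construct a crystallographic unit cell from its six constants.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a named list with the six
#'   constants. Derived quantities are available through [cell_volume()],
#'   [orthogonalization_matrix()] and [reciprocal_cell()].
#' @examples
#' cell <- unit_cell(9.854, 9.249, 10.144)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(vals))) {
    abort("unit cell constants must be finite numbers")
  }
  if (any(vals[1:3] <= 0)) {
    abort("unit cell lengths must be positive")
  }
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180)) {
    abort("unit cell angles must lie strictly between 0 and 180 degrees")
  }
  cell <- structure(as.list(vals), class = "unit_cell")
  if (cell_volume(cell) <= 0) {
    abort("degenerate unit cell: volume is not positive")
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' @rdname unit_cell
#' @param cell A `unit_cell` object.
#' @return `cell_volume()`: the cell volume in cubic Angstrom (closed form
#'   `abc * sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`).
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos_deg(cell$alpha); cb <- cos_deg(cell$beta); cg <- cos_deg(cell$gamma)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  cell$a * cell$b * cell$c * sqrt(max(arg, 0))
}

cos_deg <- function(x) cospi(x / 180)
sin_deg <- function(x) sinpi(x / 180)

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Matrix `M` mapping fractional coordinates to Cartesian Angstrom
#' coordinates, in the standard convention with the `a` axis along Cartesian
#' `x` and `b` in the `xy` plane. `det(M)` equals the cell volume.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 numeric matrix.
#' @examples
#' orthogonalization_matrix(unit_cell(10, 10, 10))
#' @export
orthogonalization_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos_deg(cell$alpha); cb <- cos_deg(cell$beta)
  cg <- cos_deg(cell$gamma); sg <- sin_deg(cell$gamma)
  v <- cell_volume(cell)
  if (v <= 0) abort("degenerate unit cell: volume is not positive")
  matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           v / (cell$a * cell$b * sg)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname unit_cell
#' @return `reciprocal_cell()`: a named numeric vector with the reciprocal
#'   constants `a_star`, `b_star`, `c_star` (1/Angstrom) and reciprocal
#'   angles in degrees.
#' @export
reciprocal_cell <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  m <- orthogonalization_matrix(cell)
  g <- crossprod(m)            # direct metric tensor
  gi <- solve(g)               # reciprocal metric tensor
  len <- sqrt(diag(gi))
  ang <- function(i, j) acos(gi[i, j] / (len[i] * len[j])) * 180 / pi
  c(a_star = len[1], b_star = len[2], c_star = len[3],
    alpha_star = ang(2, 3), beta_star = ang(1, 3), gamma_star = ang(1, 2))
}
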