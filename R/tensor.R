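#' Displacement tensors
#'
#' A mean-square displacement (ADP) tensor is stored as a symmetric 3x3
#' matrix carrying a `basis` attribute, either `"cif"` (the dimensionless
#' crystallographic U^cif convention, components referred to the reciprocal
#' basis) or `"cartesian"` (Angstrom^2). `displacement_tensor()` builds one
#' from its six unique components in the conventional order
#' U11, U22, U33, U12, U13, U23.
#'
#' @param u11,u22,u33,u12,u13,u23 Tensor components.
#' @param basis `"cif"` or `"cartesian"`.
#' @return A 3x3 symmetric matrix of class `displacement_tensor`.
#' @examples
#' displacement_tensor(0.01, 0.02, 0.03, basis = "cartesian")
#' @export
displacement_tensor <- function(u11, u22, u33, u12 = 0, u13 = 0, u23 = 0,
                                basis = c("cartesian", "cif")) {
  basis <- match.arg(basis)
  u <- matrix(c(u11, u12, u13,
                u12, u22, u23,
                u13, u23, u33), nrow = 3, byrow = TRUE)
  if (any(!is.finite(u))) abort("displacement tensor components must be finite")
  new_u_tensor(u, basis)
}

new_u_tensor <- function(mat, basis) {
  structure(mat, basis = basis, class = c("displacement_tensor", "matrix", "array"))
}

u_basis <- function(u) {
  b <- attr(u, "basis")
  if (is.null(b)) abort("displacement tensor has no basis tag")
  b
}

# six unique components in U11,U22,U33,U12,U13,U23 order
u_components <- function(u) {
  c(u[1, 1], u[2, 2], u[3, 3], u[1, 2], u[1, 3], u[2, 3])
}

#' @export
print.displacement_tensor <- function(x, ...) {
  cat(sprintf("<displacement_tensor basis=%s>\n", u_basis(x)))
  print(unclass(structure(x, basis = NULL)))
  invisible(x)
}

#' Convert displacement tensors between CIF and Cartesian bases
#'
#' The CIF convention stores dimensionless `U^cif` components referred to the
#' reciprocal lattice; the Cartesian mean-square displacement matrix (in
#' Angstrom^2) is `U_cart = M N U_cif N' M'` where `N = diag(a*, b*, c*)` and
#' `M` is the [orthogonalization_matrix()]. `u_cart_to_cif()` is the exact
#' inverse.
#'
#' @param u A `displacement_tensor` (or plain symmetric 3x3 matrix with a
#'   `basis` attribute) in the source basis.
#' @param cell A [unit_cell()].
#' @return A `displacement_tensor` in the target basis.
#' @export
u_cif_to_cart <- function(u, cell) {
  if (!identical(u_basis(u), "cif")) {
    abort("u_cif_to_cart() expects a tensor tagged with basis 'cif'")
  }
  k <- cif_to_cart_operator(cell)
  new_u_tensor(k %*% unclass(u) %*% t(k), "cartesian")
}

#' @rdname u_cif_to_cart
#' @export
u_cart_to_cif <- function(u, cell) {
  if (!identical(u_basis(u), "cartesian")) {
    abort("u_cart_to_cif() expects a tensor tagged with basis 'cartesian'")
  }
  k <- solve(cif_to_cart_operator(cell))
  new_u_tensor(k %*% unclass(u) %*% t(k), "cif")
}

cif_to_cart_operator <- function(cell) {
  m <- orthogonalization_matrix(cell)
  rec <- reciprocal_cell(cell)
  m %*% diag(rec[1:3])
}

#' Equivalent isotropic displacement
#'
#' Collapse a Cartesian anisotropic displacement tensor to a single
#' equivalent isotropic value, either by arithmetic averaging of the diagonal
#' elements (trace/3, rotation invariant) or geometrically as the cube root
#' of the product of the eigenvalues.
#'
#' @param u A Cartesian-basis `displacement_tensor`.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @param label Optional atom label used in error messages.
#' @return Scalar U_eq in Angstrom^2.
#' @examples
#' u <- displacement_tensor(0.01, 0.02, 0.03)
#' u_eq(u)                       # 0.02
#' u_eq(u, "geometric")          # (6e-6)^(1/3)
#' @export
u_eq <- function(u, method = c("arithmetic", "geometric"), label = NULL) {
  method <- match.arg(method)
  if (!identical(u_basis(u), "cartesian")) {
    abort("u_eq() expects a Cartesian-basis tensor; convert with u_cif_to_cart()")
  }
  if (method == "arithmetic") {
    return(sum(diag(u)) / 3)
  }
  ev <- eigen(unclass(u), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    who <- if (is.null(label)) "tensor" else paste0("atom '", label, "'")
    abort(paste0("geometric U_eq undefined: ", who,
                 " has a non-positive eigenvalue (min ",
                 format(min(ev), digits = 3), ")"))
  }
  prod(ev)^(1 / 3)
}

# Cartesian ADPs for every atom of a structure that has either an
# anisotropic tensor or (optionally) an isotropic one; returns a named list
# of Cartesian displacement_tensor objects.
structure_cart_adps <- function(structure, include_iso = TRUE) {
  at <- structure$atoms
  out <- list()
  for (i in seq_len(nrow(at))) {
    if (!is.na(at$u11[i])) {
      u <- displacement_tensor(at$u11[i], at$u22[i], at$u33[i],
                               at$u12[i], at$u13[i], at$u23[i], basis = "cif")
      out[[at$label[i]]] <- u_cif_to_cart(u, structure$cell)
    } else if (include_iso && !is.na(at$u_iso[i])) {
      out[[at$label[i]]] <- displacement_tensor(
        at$u_iso[i], at$u_iso[i], at$u_iso[i], basis = "cartesian")
    }
  }
  out
}

#' Tidy a set of labelled displacement tensors
#'
#' Flatten a named list of 3x3 displacement tensors into a tibble with one
#' row per atom and columns `u11 ... u23` plus the equivalent isotropic
#' value.
#'
#' @param adps Named list of Cartesian `displacement_tensor` objects.
#' @return A tibble with columns `label`, `u11`..`u23`, `u_eq`.
#' @export
adp_tibble <- function(adps) {
  stopifnot(is.list(adps))
  rows <- imap(adps, function(u, lab) {
    comp <- u_components(u)
    tibble(label = lab,
           u11 = comp[1], u22 = comp[2], u33 = comp[3],
           u12 = comp[4], u13 = comp[5], u23 = comp[6],
           u_eq = sum(comp[1:3]) / 3)
  })
  bind_rows(rows)
}
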