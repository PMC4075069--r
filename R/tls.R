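#' Translation-libration-screw (TLS) rigid-body model
#'
#' The Schomaker-Trueblood description of collective rigid-body motion:
#' `T` (Angstrom^2) is the translation tensor, `L` (rad^2) the libration
#' tensor and `S` (Angstrom rad) the screw correlation tensor. `T` and `L`
#' must be symmetric; the trace of `S` is unobservable from displacement
#' parameters and is projected to exactly zero (the conventional constraint).
#' `T` and `S` depend on the origin, so the origin is always part of the
#' model.
#'
#' @param T,L Symmetric 3x3 matrices.
#' @param S General 3x3 matrix; its trace component is removed.
#' @param origin Cartesian reference point (length-3, Angstrom).
#' @return An object of class `tls_model` with fields `T`, `L`, `S`,
#'   `origin`.
#' @export
tls_model <- function(T, L, S = matrix(0, 3, 3), origin = c(0, 0, 0)) {
  T <- as.matrix(T); L <- as.matrix(L); S <- as.matrix(S)
  check_sym <- function(m, name) {
    if (!all(dim(m) == c(3, 3)) || any(!is.finite(m))) {
      abort(paste0(name, " must be a finite 3x3 matrix"))
    }
    if (max(abs(m - t(m))) > 1e-10) {
      abort(paste0(name, " tensor must be symmetric"))
    }
    (m + t(m)) / 2
  }
  T <- check_sym(T, "T")
  L <- check_sym(L, "L")
  if (!all(dim(S) == c(3, 3)) || any(!is.finite(S))) {
    abort("S must be a finite 3x3 matrix")
  }
  S <- S - diag(3) * sum(diag(S)) / 3
  if (length(origin) != 3 || any(!is.finite(origin))) {
    abort("origin must be a finite Cartesian 3-vector")
  }
  structure(list(T = T, L = L, S = S, origin = as.numeric(origin)),
            class = "tls_model")
}

#' @export
print.tls_model <- function(x, digits = 5, ...) {
  cat("<tls_model> origin:", sprintf("%.4f", x$origin), "\n")
  cat("T (A^2):\n"); print(round(x$T, digits))
  cat("L (rad^2) [diagonal in deg^2:",
      sprintf("%.4f", diag(x$L) * (180 / pi)^2), "]:\n")
  print(signif(x$L, digits))
  cat("S (A rad), trace 0:\n"); print(signif(x$S, digits))
  invisible(x)
}

# A d = omega x d for d = r - origin
skew_for_position <- function(d) {
  matrix(c(0, d[3], -d[2],
           -d[3], 0, d[1],
           d[2], -d[1], 0), nrow = 3, byrow = TRUE)
}

#' Predict ADPs from a TLS model
#'
#' Evaluates the rigid-body displacement tensor at each atomic position:
#' `U(r) = T + A L A' + A S + S' A'` with `A` the antisymmetric matrix
#' satisfying `A w = w x (r - origin)`.
#'
#' @param model A [tls_model()].
#' @param positions Either a numeric matrix with one Cartesian row per atom
#'   and row names as labels, or a data frame with columns `label`, `x`,
#'   `y`, `z` (e.g. from [cart_coords()]).
#' @return Named list of Cartesian `displacement_tensor` objects.
#' @export
predict_adps <- function(model, positions) {
  stopifnot(inherits(model, "tls_model"))
  pos <- as_position_matrix(positions)
  out <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    a <- skew_for_position(pos[i, ] - model$origin)
    u <- model$T + a %*% model$L %*% t(a) + a %*% model$S +
      t(model$S) %*% t(a)
    out[[i]] <- new_u_tensor((u + t(u)) / 2, "cartesian")
  }
  setNames(out, rownames(pos))
}

as_position_matrix <- function(positions) {
  if (is.data.frame(positions)) {
    if (!all(c("label", "x", "y", "z") %in% names(positions))) {
      abort("position table needs columns label, x, y, z")
    }
    pos <- as.matrix(positions[, c("x", "y", "z")])
    rownames(pos) <- positions$label
  } else {
    pos <- as.matrix(positions)
    if (ncol(pos) != 3) abort("positions must have three Cartesian columns")
    if (is.null(rownames(pos))) {
      rownames(pos) <- paste0("atom", seq_len(nrow(pos)))
    }
  }
  pos
}

# the 20 basis models of the linear TLS parameterization; trace(S)=0 is
# built into the 8 S basis matrices
tls_basis_models <- function(origin) {
  sym_basis <- list(
    cbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)),
    cbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 0)),
    cbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
    cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
    cbind(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)),
    cbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0))
  )
  e <- function(i, j) { m <- matrix(0, 3, 3); m[i, j] <- 1; m }
  s_basis <- list(e(1, 1) - e(3, 3), e(2, 2) - e(3, 3),
                  e(1, 2), e(1, 3), e(2, 1), e(2, 3), e(3, 1), e(3, 2))
  zero <- matrix(0, 3, 3)
  models <- c(
    map(sym_basis, ~ tls_model(.x, zero, zero, origin)),
    map(sym_basis, ~ tls_model(zero, .x, zero, origin)),
    map(s_basis, ~ tls_model(zero, zero, .x, origin))
  )
  names(models) <- c(paste0("T", c("11", "22", "33", "12", "13", "23")),
                     paste0("L", c("11", "22", "33", "12", "13", "23")),
                     paste0("S", c("11-33", "22-33", "12", "13", "21",
                                   "23", "31", "32")))
  models
}

#' Fit a TLS model to observed ADPs
#'
#' Linear least squares of the 20 free Schomaker-Trueblood parameters (6 T,
#' 6 L, 8 S after the trace-of-S constraint) against the six unique Cartesian
#' components of each atom's displacement tensor. The origin is fixed at the
#' centroid of the fitted atoms and reported with the model.
#'
#' @param adps Named list of Cartesian `displacement_tensor` objects
#'   (observed, typically non-hydrogen atoms).
#' @param positions Cartesian positions of the same atoms (see
#'   [predict_adps()] for accepted forms).
#' @param weights Optional per-atom weights (e.g. `1/sigma^2`); unit weights
#'   by default.
#' @return An object of class `tls_fit`: fields `model` ([tls_model()]),
#'   `r` (the dimensionless residual
#'   `sqrt(sum w (Uobs - Ucalc)^2 / sum w Uobs^2)` over unique components),
#'   `delta` (named list of residual tensors), `fitted`, `n_obs`
#'   (`6 * n_atoms`), `n_par` (20) and `labels`.
#' @seealso [tidy.tls_fit()], [glance.tls_fit()]
#' @export
fit_tls <- function(adps, positions, weights = NULL) {
  pos <- as_position_matrix(positions)
  labs <- names(adps)
  if (is.null(labs) || !setequal(labs, rownames(pos))) {
    abort("ADP labels and position labels must match")
  }
  pos <- pos[labs, , drop = FALSE]
  n <- length(labs)
  if (n < 4) abort("TLS fit needs at least 4 atoms (20 parameters)")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    abort("weights must be positive, one per atom")
  }
  origin <- colMeans(pos)
  basis <- tls_basis_models(origin)
  x <- matrix(0, nrow = 6 * n, ncol = length(basis))
  for (p in seq_along(basis)) {
    pred <- predict_adps(basis[[p]], pos)
    x[, p] <- unlist(map(pred, u_components))
  }
  y <- unlist(map(adps[labs], function(u) {
    if (!identical(u_basis(u), "cartesian")) {
      abort("fit_tls() requires Cartesian-basis tensors")
    }
    u_components(u)
  }))
  # off-diagonal components enter the tensor norm twice: weighting them by 2
  # makes the fit and its residual invariant under global rotations
  wrow <- rep(weights, each = 6) * rep(c(1, 1, 1, 2, 2, 2), n)
  qrx <- qr(x * sqrt(wrow))
  if (qrx$rank < ncol(x)) {
    abort(paste0("rank-deficient TLS design matrix (rank ", qrx$rank,
                 " < 20): atom arrangement is degenerate ",
                 "(e.g. collinear or coplanar atoms)"))
  }
  beta <- qr.coef(qrx, y * sqrt(wrow))
  model <- tls_model(
    T = comp_to_sym(beta[1:6]),
    L = comp_to_sym(beta[7:12]),
    S = beta[13] * (diag(c(1, 0, -1))) + beta[14] * diag(c(0, 1, -1)) +
      s_offdiag(beta[15:20]),
    origin = origin
  )
  fitted <- predict_adps(model, pos)
  delta <- map2(adps[labs], fitted, function(o, f)
    new_u_tensor(unclass(o) - unclass(f), "cartesian"))
  num <- sum(wrow * (y - unlist(map(fitted, u_components)))^2)
  den <- sum(wrow * y^2)
  structure(list(model = model,
                 r = sqrt(num / den),
                 delta = delta, fitted = fitted,
                 n_obs = 6L * n, n_par = 20L, labels = labs,
                 weights = weights),
            class = "tls_fit")
}

comp_to_sym <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), nrow = 3, byrow = TRUE)
}

s_offdiag <- function(v) {
  # order: S12, S13, S21, S23, S31, S32
  matrix(c(0, v[1], v[2],
           v[3], 0, v[4],
           v[5], v[6], 0), nrow = 3, byrow = TRUE)
}

#' @export
print.tls_fit <- function(x, ...) {
  cat(sprintf("<tls_fit> %d atoms, R = %.3g (%d obs, %d parameters)\n",
              length(x$labels), x$r, x$n_obs, x$n_par))
  print(x$model)
  invisible(x)
}

#' Tidy a TLS fit
#'
#' @param x A [fit_tls()] result.
#' @param ... Unused.
#' @return `tidy()`: tibble with one row per tensor element (`tensor`,
#'   `i`, `j`, `estimate`); `glance()`: one-row tibble with `r`, `n_obs`,
#'   `n_parameters`, `n_atoms`.
#' @export
tidy.tls_fit <- function(x, ...) {
  one <- function(m, name) {
    idx <- which(upper.tri(m, diag = TRUE) | name == "S", arr.ind = TRUE)
    tibble(tensor = name, i = idx[, 1], j = idx[, 2],
           estimate = m[idx])
  }
  bind_rows(one(x$model$T, "T"), one(x$model$L, "L"), one(x$model$S, "S"))
}

#' @rdname tidy.tls_fit
#' @export
glance.tls_fit <- function(x, ...) {
  tibble(r = x$r, n_obs = x$n_obs, n_parameters = x$n_par,
         n_atoms = length(x$labels))
}

#' Subtract internal-mode ADPs from observed ADPs
#'
#' Componentwise tensor difference, used to remove the quantum-chemically
#' computed internal motion from experimental ADPs before a TLS fit. Atoms
#' whose difference acquires a negative eigenvalue are flagged with a warning
#' but kept.
#'
#' @param adps_obs,adps_internal Named lists of Cartesian
#'   `displacement_tensor` objects over the same labels.
#' @return Named list of difference tensors, with attribute `nonpsd` listing
#'   flagged labels.
#' @export
subtract_internal <- function(adps_obs, adps_internal) {
  labs <- names(adps_obs)
  missing_lab <- setdiff(labs, names(adps_internal))
  if (length(missing_lab) > 0) {
    abort(paste0("internal ADPs missing for atom(s): ",
                 paste(missing_lab, collapse = ", ")))
  }
  out <- map(setNames(labs, labs), function(lab) {
    new_u_tensor(unclass(adps_obs[[lab]]) - unclass(adps_internal[[lab]]),
                 "cartesian")
  })
  nonpsd <- names(keep(out, function(u) {
    min(eigen(unclass(u), symmetric = TRUE, only.values = TRUE)$values) < 0
  }))
  if (length(nonpsd) > 0) {
    warn(paste0("internal-mode subtraction left non-positive-definite ",
                "tensor(s) for: ", paste(nonpsd, collapse = ", ")))
  }
  attr(out, "nonpsd") <- nonpsd
  out
}

#' TLS+ONIOM hydrogen displacement parameters
#'
#' The full pipeline combining quantum-chemical internal motion with an
#' experimentally fitted rigid-body term at one temperature:
#' internal ADPs are evaluated from the normal modes (frequency cutoff
#' applied), subtracted from the observed non-hydrogen ADPs, a TLS model is
#' fitted to the corrected non-hydrogen tensors (hydrogen observations are
#' never used in the fit), the fitted rigid-body motion is predicted at the
#' hydrogen positions, and the hydrogen internal term is added back:
#' `U(H) = U_TLS(H) + U_int(H, T)`.
#'
#' @param structure A [crystal_structure()] whose non-hydrogen atoms carry
#'   anisotropic ADPs.
#' @param modes A [normal_mode_set()] covering all atoms of the structure.
#' @param cutoff Internal-mode frequency threshold in cm^-1 (default 200).
#' @param temperature Temperature in Kelvin; defaults to the structure's.
#' @return An object of class `tls_oniom`: `h_adps` (named list of hydrogen
#'   Cartesian tensors), `fit` (the [fit_tls()] report), `u_internal` (all
#'   atoms), `nonh_total` (TLS prediction plus internal term for non-H atoms,
#'   diagnostic), `temperature`.
#' @export
tls_plus_oniom <- function(structure, modes, cutoff = 200,
                           temperature = NULL) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(modes, "mode_set"))
  if (is.null(temperature)) temperature <- structure$temperature
  if (is.null(temperature)) {
    abort("temperature must be given (structure carries none)")
  }
  missing_modes <- setdiff(structure$atoms$label, modes$labels)
  if (length(missing_modes) > 0) {
    abort(paste0("normal modes missing for atom(s): ",
                 paste(missing_modes, collapse = ", ")))
  }
  xyz <- cart_coords(structure)
  is_h <- is_hydrogen(xyz$element)
  obs <- structure_cart_adps(structure, include_iso = FALSE)
  nonh_labs <- xyz$label[!is_h]
  fit_labs <- intersect(nonh_labs, names(obs))
  dropped <- setdiff(nonh_labs, fit_labs)
  if (length(dropped) > 0) {
    warn(paste0("non-hydrogen atom(s) without anisotropic ADPs dropped ",
                "from the TLS fit: ", paste(dropped, collapse = ", ")))
  }
  u_int <- internal_adps(modes, temperature, cutoff)
  ext <- subtract_internal(obs[fit_labs], u_int)
  fit <- fit_tls(ext, xyz[match(fit_labs, xyz$label), ])
  h_labs <- xyz$label[is_h]
  h_adps <- list()
  if (length(h_labs) > 0) {
    u_tls_h <- predict_adps(fit$model, xyz[match(h_labs, xyz$label), ])
    h_adps <- map(setNames(h_labs, h_labs), function(lab) {
      new_u_tensor(unclass(u_tls_h[[lab]]) + unclass(u_int[[lab]]),
                   "cartesian")
    })
  }
  nonh_total <- map(setNames(fit_labs, fit_labs), function(lab) {
    new_u_tensor(unclass(fit$fitted[[lab]]) + unclass(u_int[[lab]]),
                 "cartesian")
  })
  base::structure(list(h_adps = h_adps, fit = fit, u_internal = u_int,
                 nonh_total = nonh_total, temperature = temperature,
                 cutoff = cutoff),
            class = "tls_oniom")
}

#' @export
print.tls_oniom <- function(x, ...) {
  cat(sprintf("<tls_oniom> T = %g K, cutoff = %g cm^-1, %d hydrogen ADPs, TLS R = %.3g\n",
              x$temperature, x$cutoff, length(x$h_adps), x$fit$r))
  invisible(x)
}
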