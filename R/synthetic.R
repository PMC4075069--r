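#' Toy test molecule
#'
#' A 14-atom fragment (7 heavy atoms, 7 hydrogens) built from idealized
#' internal coordinates: a methyl group, a methine hydrogen on a carbon
#' bearing a hydroxyl group, an amide-like C(=O)N terminus and a separate
#' water molecule. It covers four hydrogen environments: `H1c[1c1h1h]`
#' (methyl), `H1c[1o1c1c]` (methine), `H1o[1c]` (hydroxyl) and `H1o[1h]`
#' (water).
#'
#' @return A tibble `label`, `element`, Cartesian `x`, `y`, `z` (Angstrom)
#'   and `parent` (bonded heavy atom for hydrogens, `NA` otherwise).
#' @export
toy_molecule <- function() {
  s3 <- 1 / sqrt(3)
  tet <- function(len, sign) len * s3 * sign
  pos <- list(
    C2 = c(0, 0, 0),
    C1 = tet(1.53, c(1, 1, 1)),
    C3 = tet(1.53, c(1, -1, -1)),
    O1 = tet(1.43, c(-1, 1, -1))
  )
  pos$N1 <- pos$C3 + tet(1.45, c(1, 1, -1))
  pos$O2 <- pos$C3 + tet(1.23, c(1, -1, 1))
  pos$O3 <- c(4.0, 2.0, -2.0)
  pos$H1 <- pos$C1 + tet(1.09, c(1, 1, -1))
  pos$H2 <- pos$C1 + tet(1.09, c(1, -1, 1))
  pos$H3 <- pos$C1 + tet(1.09, c(-1, 1, 1))
  pos$H4 <- pos$C2 + tet(1.09, c(-1, -1, 1))
  pos$H5 <- pos$O1 + tet(0.96, c(-1, 1, 1))
  half <- 104.5 / 2
  wat <- 0.96 * c(cos_deg(half), sin_deg(half), 0)
  pos$H6 <- pos$O3 + wat * c(1, 1, 1)
  pos$H7 <- pos$O3 + wat * c(1, -1, 1)
  offset <- c(4.0, 4.0, 5.0)
  xyz <- t(vapply(pos, function(p) p + offset, numeric(3)))
  parent <- c(C2 = NA, C1 = NA, C3 = NA, O1 = NA, N1 = NA, O2 = NA, O3 = NA,
              H1 = "C1", H2 = "C1", H3 = "C1", H4 = "C2", H5 = "O1",
              H6 = "O3", H7 = "O3")
  tibble(label = rownames(xyz),
         element = substr(rownames(xyz), 1, 1),
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
         parent = unname(parent[rownames(xyz)]))
}

# two unit vectors orthogonal to v and to each other
perp_pair <- function(v) {
  v <- v / sqrt(sum(v^2))
  seed <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- seed - sum(seed * v) * v
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(v[2] * p1[3] - v[3] * p1[2],
          v[3] * p1[1] - v[1] * p1[3],
          v[1] * p1[2] - v[2] * p1[1])
  list(p1, p2 / sqrt(sum(p2^2)))
}

# Normal modes emulating a quantum-chemical frequency calculation on the toy
# molecule: one localized X-H stretch per hydrogen, two bends per hydrogen
# with 90% of the squared amplitude on the hydrogen, two skeletal modes per
# heavy atom, and one collective 80 cm^-1 mode below the default cutoff.
build_fixture_modes <- function(molecule = toy_molecule()) {
  n <- nrow(molecule)
  labels <- molecule$label
  masses <- element_mass(molecule$element)
  xyz <- as.matrix(molecule[, c("x", "y", "z")])
  rownames(xyz) <- labels
  freqs <- numeric(0)
  disp <- list()
  add_mode <- function(freq, mat) {
    freqs <<- c(freqs, freq)
    disp[[length(disp) + 1]] <<- mat / sqrt(sum(mat^2))
  }
  h_rows <- which(!is.na(molecule$parent))
  stretch_freq <- c(H1 = 2950, H2 = 2960, H3 = 2970, H4 = 2980,
                    H5 = 3400, H6 = 3420, H7 = 3440)
  for (idx in seq_along(h_rows)) {
    i <- h_rows[idx]
    lab <- labels[i]
    p_row <- match(molecule$parent[i], labels)
    bond <- xyz[i, ] - xyz[p_row, ]
    bond <- bond / sqrt(sum(bond^2))
    m <- matrix(0, n, 3)
    m[i, ] <- bond
    add_mode(stretch_freq[[lab]], m)
    pp <- perp_pair(bond)
    for (b in 1:2) {
      m <- matrix(0, n, 3)
      m[i, ] <- sqrt(0.9) * pp[[b]]
      m[p_row, ] <- -sqrt(0.1) * pp[[b]]
      add_mode(1300 + 20 * (2 * (idx - 1) + b), m)
    }
    # hydrogens on oxygen get a hindered-rotation (libration) mode, as in
    # hydrogen-bonded crystals: low frequency, almost all amplitude on H
    if (molecule$element[p_row] == "O") {
      m <- matrix(0, n, 3)
      m[i, ] <- sqrt(0.9) * (pp[[1]] + pp[[2]]) / sqrt(2)
      m[p_row, ] <- -sqrt(0.1) * (pp[[1]] + pp[[2]]) / sqrt(2)
      add_mode(if (lab == "H5") 500 else 600 + 10 * idx, m)
    }
  }
  heavy_rows <- which(is.na(molecule$parent))
  axes <- diag(3)
  for (idx in seq_along(heavy_rows)) {
    i <- heavy_rows[idx]
    for (b in 1:2) {
      m <- matrix(0, n, 3)
      m[i, ] <- axes[(idx + b - 2) %% 3 + 1, ]
      add_mode(if (b == 1) 900 + 7 * idx else 1100 + 7 * idx, m)
    }
  }
  low <- matrix(0, n, 3)
  low[, 1] <- 1
  add_mode(80, low)
  normal_mode_set(labels, masses, freqs,
                  array(unlist(disp), dim = c(n, 3, length(disp))))
}

default_tls_base <- function() {
  list(
    T = matrix(c(0.013, 0.0010, -0.0005,
                 0.0010, 0.011, 0.0008,
                 -0.0005, 0.0008, 0.012), 3, 3, byrow = TRUE),
    L = matrix(c(0.0012, 0.00010, 0.00005,
                 0.00010, 0.0009, -0.00008,
                 0.00005, -0.00008, 0.0011), 3, 3, byrow = TRUE),
    S = matrix(c(2.0e-4, 1.5e-4, -1.0e-4,
                 -0.5e-4, -1.0e-4, 1.2e-4,
                 0.8e-4, -0.6e-4, -1.0e-4), 3, 3, byrow = TRUE)
  )
}

#' Synthetic-fixture specification
#'
#' Defines the study conditions of the forward-generated test fixture: a toy
#' crystal whose heavy-atom and hydrogen ADPs at each temperature are the sum
#' of a temperature-scaled rigid-body (TLS) term, the internal-mode term of
#' [internal_adps()] and optional Gaussian noise. The lattice term scales as
#' `g(T) = zero_point + slope * T` (a constant zero-point contribution plus
#' linear classical growth); this surrogate only needs to produce
#' realistically shaped inputs, because the analysis pipeline always fits
#' the lattice term rather than predicting it.
#'
#' @param seed Integer RNG seed; the same seed always yields bit-identical
#'   fixtures.
#' @param temps Temperature grid in Kelvin (default 9, 30, 50, 75, 100, 150,
#'   200, 250).
#' @param noise_sd Gaussian noise on every unique Cartesian ADP component,
#'   Angstrom^2 (default 0: exact forward model).
#' @param cell Unit cell of the toy crystal.
#' @param lattice_zero_point,lattice_slope Parameters of `g(T)`
#'   (dimensionless and 1/K).
#' @param tls_base List with base `T`, `L`, `S` matrices, scaled by `g(T)`.
#' @param cutoff Frequency threshold (cm^-1) used in the forward internal
#'   term; modes below it represent lattice-like motion and are part of the
#'   TLS surrogate instead.
#' @param molecule Atom table as from [toy_molecule()].
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         temps = c(9, 30, 50, 75, 100, 150, 200, 250),
                         noise_sd = 0,
                         cell = unit_cell(9.854, 9.249, 10.144),
                         lattice_zero_point = 0.09,
                         lattice_slope = 0.018,
                         tls_base = default_tls_base(),
                         cutoff = 200,
                         molecule = toy_molecule()) {
  if (length(temps) == 0 || any(temps < 0)) {
    abort("temperature grid must be non-negative")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), temps = temps,
                 noise_sd = noise_sd, cell = cell,
                 lattice_zero_point = lattice_zero_point,
                 lattice_slope = lattice_slope,
                 tls_base = tls_base, cutoff = cutoff,
                 molecule = molecule),
            class = "fixture_spec")
}

#' Generate the synthetic fixture
#'
#' Forward-generates one crystal structure per temperature, the matching
#' normal-mode set and a ground-truth record (scaled TLS models, exact total
#' hydrogen tensors and per-environment ratio curves), so that every stage of
#' the analysis pipeline can be checked against known values.
#'
#' @param spec A [fixture_spec()].
#' @return An object of class `tls_fixture`: `structures` (named list, one
#'   [crystal_structure()] per temperature), `modes`
#'   ([normal_mode_set()]) and `truth` (list with per-temperature `tls`
#'   models, `g` scale factors, `h_adps` Cartesian tensors and `ratio_table`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mol <- spec$molecule
  modes <- build_fixture_modes(mol)
  m_orth <- orthogonalization_matrix(spec$cell)
  frac <- t(solve(m_orth) %*% t(as.matrix(mol[, c("x", "y", "z")])))
  heavy <- is.na(mol$parent)
  origin <- colMeans(as.matrix(mol[heavy, c("x", "y", "z")]))
  pos_tab <- mol[, c("label", "x", "y", "z")]

  set.seed(spec$seed)
  structures <- list()
  truth_tls <- list()
  truth_h <- list()
  truth_records <- list()
  g_all <- numeric(0)
  for (tt in spec$temps) {
    g <- spec$lattice_zero_point + spec$lattice_slope * tt
    model <- tls_model(g * spec$tls_base$T, g * spec$tls_base$L,
                       g * spec$tls_base$S, origin)
    u_lat <- predict_adps(model, pos_tab)
    u_int <- internal_adps(modes, tt, cutoff = spec$cutoff)
    total <- map(setNames(mol$label, mol$label), function(lab) {
      u <- unclass(u_lat[[lab]]) + unclass(u_int[[lab]])
      if (spec$noise_sd > 0) {
        eps <- rnorm(6, sd = spec$noise_sd)
        u <- u + comp_to_sym(eps)
      }
      new_u_tensor(u, "cartesian")
    })
    atoms <- mol[, c("label", "element")]
    atoms$x <- frac[, 1]; atoms$y <- frac[, 2]; atoms$z <- frac[, 3]
    atoms$occupancy <- 1
    comp_cif <- t(vapply(mol$label, function(lab)
      u_components(u_cart_to_cif(total[[lab]], spec$cell)), numeric(6)))
    atoms$u_iso <- vapply(mol$label, function(lab)
      u_eq(total[[lab]]), numeric(1))
    atoms$u11 <- comp_cif[, 1]; atoms$u22 <- comp_cif[, 2]
    atoms$u33 <- comp_cif[, 3]; atoms$u12 <- comp_cif[, 4]
    atoms$u13 <- comp_cif[, 5]; atoms$u23 <- comp_cif[, 6]
    st <- crystal_structure(spec$cell, atoms, temperature = tt,
                            provenance = sprintf("synthetic fixture seed %d",
                                                 spec$seed))
    key <- format(tt)
    structures[[key]] <- st
    truth_tls[[key]] <- model
    g_all <- c(g_all, g)
    h_rows <- which(!heavy)
    truth_h[[key]] <- map(setNames(mol$label[h_rows], mol$label[h_rows]),
                          function(lab) total[[lab]])
    env <- fixture_environments(mol)
    truth_records[[key]] <- tibble(
      h_label = mol$label[h_rows],
      parent_label = mol$parent[h_rows],
      environment = env[mol$label[h_rows]],
      temperature = tt,
      ratio = vapply(h_rows, function(i) {
        u_eq(total[[mol$label[i]]]) / u_eq(total[[mol$parent[i]]])
      }, numeric(1)),
      method = "truth")
  }
  truth <- list(spec = spec, origin = origin, g = setNames(g_all, names(structures)),
                tls = truth_tls, h_adps = truth_h,
                records = bind_rows(truth_records),
                ratio_table = average_by_environment(bind_rows(truth_records)))
  structure(list(structures = structures, modes = modes, truth = truth),
            class = "tls_fixture")
}

# ground-truth environment names straight from the known parent map,
# independent of the bond-perception code path
fixture_environments <- function(mol) {
  env <- character(0)
  for (i in which(!is.na(mol$parent))) {
    p <- mol$parent[i]
    sibs <- mol$label[which(mol$parent == p)]
    others <- c(mol$label[!is.na(mol$parent) & mol$parent == p & mol$label != mol$label[i]])
    # heavy neighbours of the parent via the known skeleton
    skeleton <- list(C1 = "C2", C2 = c("C1", "C3", "O1"), C3 = c("C2", "N1", "O2"),
                     O1 = "C2", O3 = character(0))
    heavies <- setdiff(skeleton[[p]], mol$label[i])
    elems <- c(substr(heavies, 1, 1), rep("H", length(others)))
    bracket <- paste0("1", tolower(sort_bracket_elements(elems)), collapse = "")
    env[mol$label[i]] <- paste0("H1", tolower(substr(p, 1, 1)), "[", bracket, "]")
  }
  env
}

#' @export
print.tls_fixture <- function(x, ...) {
  cat(sprintf("<tls_fixture> %d temperatures (%s K), %d atoms, %d modes, noise_sd = %g\n",
              length(x$structures),
              paste(x$truth$spec$temps, collapse = ", "),
              nrow(x$truth$spec$molecule),
              length(x$modes$frequencies), x$truth$spec$noise_sd))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Writes one CIF per temperature (`fixture_<T>K.cif`), the normal-mode file
#' (`modes.txt`) and a JSON ground-truth sidecar (`truth.json`) with the
#' scale factors, scaled TLS tensors and forward ratio table.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "tls_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (key in names(fixture$structures)) {
    st <- fixture$structures[[key]]
    path <- file.path(dir, sprintf("fixture_%sK.cif", key))
    write_structure_cif(st, path)
    files <- c(files, path)
  }
  mode_path <- file.path(dir, "modes.txt")
  write_modes(fixture$modes, mode_path)
  truth_path <- file.path(dir, "truth.json")
  tr <- fixture$truth
  payload <- list(
    seed = tr$spec$seed,
    temps = tr$spec$temps,
    noise_sd = tr$spec$noise_sd,
    cutoff = tr$spec$cutoff,
    origin = tr$origin,
    g = as.list(tr$g),
    tls = map(tr$tls, function(m)
      list(T = m$T, L = m$L, S = m$S, origin = m$origin)),
    ratio_table = as.data.frame(tr$ratio_table)
  )
  jsonlite::write_json(payload, truth_path, digits = NA, auto_unbox = TRUE)
  invisible(c(files, mode_path, truth_path))
}
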