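#' Normal-mode set
#'
#' Container for the harmonic normal modes of a molecule: per-atom masses and
#' one mass-weighted Cartesian eigenvector per mode, normalized so the sum of
#' squared components over all atoms equals one. Frequencies are wavenumbers
#' in cm^-1; a negative value denotes an imaginary mode.
#'
#' @param labels Character vector of atom labels (aligned with the structure
#'   the modes describe).
#' @param masses Atomic masses in unified atomic mass units, one per atom.
#' @param frequencies Numeric vector of mode wavenumbers (cm^-1).
#' @param displacements Numeric array `[n_atoms, 3, n_modes]` of mass-weighted
#'   eigenvector components.
#' @return An object of class `mode_set`.
#' @export
normal_mode_set <- function(labels, masses, frequencies, displacements) {
  labels <- as.character(labels)
  n <- length(labels)
  if (anyDuplicated(labels)) abort("mode-set atom labels must be unique")
  if (length(masses) != n) abort("one mass per atom label is required")
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    abort("atomic masses must be positive")
  }
  m <- length(frequencies)
  displacements <- array(displacements, dim = c(n, 3, m))
  if (any(!is.finite(displacements))) {
    abort("mode eigenvector components must be finite")
  }
  for (k in seq_len(m)) {
    nrm <- sum(displacements[, , k]^2)
    if (abs(nrm - 1) > 1e-3) {
      abort(sprintf("mode %d (%.1f cm^-1) eigenvector norm %.6f is too far from 1",
                    k, frequencies[k], nrm))
    }
    if (abs(nrm - 1) > 1e-6) {
      warn(sprintf("renormalizing mode %d (%.1f cm^-1): norm was %.8f",
                   k, frequencies[k], nrm))
      displacements[, , k] <- displacements[, , k] / sqrt(nrm)
    }
  }
  structure(list(labels = labels, masses = as.numeric(masses),
                 frequencies = as.numeric(frequencies),
                 displacements = displacements),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d atoms, %d modes (%.1f - %.1f cm^-1)\n",
              length(x$labels), length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Read and write the plain-text normal-mode format
#'
#' The package's mode file format is line-oriented plain text with a
#' versioned header:
#' \preformatted{
#' # tlsoniom-modes v1
#' atoms <N>
#' <label> <mass>          (N lines)
#' mode <frequency_cm-1>   (repeated per mode)
#' <ex> <ey> <ez>          (N lines of mass-weighted components)
#' }
#' Blank lines and `#` comments are ignored. `read_modes()` enforces
#' eigenvector normalization (renormalizes with a warning when off by less
#' than 1e-3, errors otherwise).
#'
#' @param path File path.
#' @return `read_modes()`: a [normal_mode_set()].
#' @export
read_modes <- function(path) {
  if (!file.exists(path)) abort(paste0("mode file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  lines <- trimws(raw[keep])
  if (length(lines) == 0) abort("mode file is empty")

  num <- function(tok, ln) {
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v))) {
      abort(sprintf("unparseable number on line %d of mode file", ln))
    }
    v
  }
  i <- 1
  head <- strsplit(lines[i], "\\s+")[[1]]
  if (length(head) != 2 || head[1] != "atoms") {
    abort(sprintf("expected 'atoms <N>' on line %d", lineno[i]))
  }
  n <- as.integer(head[2])
  if (is.na(n) || n < 1) abort("invalid atom count in mode file header")
  if (length(lines) < 1 + n) abort("mode file truncated in atom header")
  labels <- character(n); masses <- numeric(n)
  for (j in seq_len(n)) {
    i <- i + 1
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (length(tok) != 2) {
      abort(sprintf("expected '<label> <mass>' on line %d", lineno[i]))
    }
    labels[j] <- tok[1]
    masses[j] <- num(tok[2], lineno[i])
  }
  freqs <- numeric(0)
  disp <- list()
  i <- i + 1
  while (i <= length(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (tok[1] != "mode" || length(tok) != 2) {
      abort(sprintf("expected 'mode <frequency>' on line %d", lineno[i]))
    }
    freqs <- c(freqs, num(tok[2], lineno[i]))
    if (i + n > length(lines)) {
      abort(sprintf("mode block starting at line %d is truncated: expected %d component lines",
                    lineno[i], n))
    }
    block <- matrix(0, n, 3)
    for (j in seq_len(n)) {
      i <- i + 1
      ctok <- strsplit(lines[i], "\\s+")[[1]]
      if (length(ctok) != 3) {
        abort(sprintf("expected three components on line %d", lineno[i]))
      }
      block[j, ] <- num(ctok, lineno[i])
    }
    disp[[length(disp) + 1]] <- block
    i <- i + 1
  }
  if (length(disp) == 0) abort("mode file contains no modes")
  arr <- array(unlist(disp), dim = c(n, 3, length(disp)))
  normal_mode_set(labels, masses, freqs, arr)
}

#' @rdname read_modes
#' @param modes A [normal_mode_set()].
#' @return `write_modes()`: invisibly, `path`.
#' @export
write_modes <- function(modes, path) {
  stopifnot(inherits(modes, "mode_set"))
  n <- length(modes$labels)
  lines <- c("# tlsoniom-modes v1",
             paste("atoms", n),
             sprintf("%s %.15g", modes$labels, modes$masses))
  for (k in seq_along(modes$frequencies)) {
    lines <- c(lines, sprintf("mode %.15g", modes$frequencies[k]),
               sprintf("%.17e %.17e %.17e",
                       modes$displacements[, 1, k],
                       modes$displacements[, 2, k],
                       modes$displacements[, 3, k]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Harmonic-oscillator temperature factor
#'
#' The dimensionless factor by which the zero-point mean-square displacement
#' of a harmonic oscillator of wavenumber `frequency` grows at temperature
#' `temperature`: `coth(h c nu / (2 kB T))`, exactly 1 at T = 0 and
#' asymptotically `2 kB T / (h c nu)` in the classical limit.
#'
#' @param frequency Wavenumber(s) in cm^-1; must be positive (imaginary
#'   modes must be filtered out upstream).
#' @param temperature Temperature in Kelvin, `>= 0` (scalar).
#' @return Numeric vector of factors, one per frequency.
#' @examples
#' mode_msd_factor(200, 298.15)   # about 2.23
#' mode_msd_factor(1000, 0)       # exactly 1
#' @export
mode_msd_factor <- function(frequency, temperature) {
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    abort("mode_msd_factor() requires positive frequencies; filter imaginary modes first")
  }
  if (!is.finite(temperature) || temperature < 0) {
    abort("temperature must be a finite non-negative number")
  }
  if (temperature == 0) return(rep(1, length(frequency)))
  x <- .hc_over_kb * frequency / (2 * temperature)
  1 / tanh(x)
}

# zero-point axial MSD of an oscillator: h / (8 pi^2 m c nu), in Angstrom^2
zero_point_msd <- function(mass_amu, frequency) {
  .h_planck / (8 * pi^2 * mass_amu * .amu_kg * .c_cm * frequency) * 1e20
}

#' Internal ADPs from normal modes (molecular Einstein approximation)
#'
#' Sums the mean-square displacement contributions of all normal modes at or
#' above a frequency cutoff into one Cartesian displacement tensor per atom:
#' `U_int(i) = sum_k  h / (8 pi^2 m_i c nu_k) * coth(h c nu_k / (2 kB T))
#' * e_ik e_ik'`, with `e_ik` the mass-weighted eigenvector segment of atom
#' `i` in mode `k`. Each molecule's modes are treated as independent
#' oscillators; lattice phonon dispersion is ignored, which is why the
#' low-frequency modes below `cutoff` are dropped and the lattice
#' contribution is instead taken from a TLS fit (see [tls_plus_oniom()]).
#'
#' @param modes A [normal_mode_set()].
#' @param temperature Temperature in Kelvin (`>= 0`).
#' @param cutoff Frequency threshold in cm^-1 (default 200); modes below it
#'   are omitted entirely.
#' @return Named list (by atom label) of Cartesian `displacement_tensor`
#'   objects in Angstrom^2; positive semi-definite by construction.
#' @export
internal_adps <- function(modes, temperature, cutoff = 200) {
  stopifnot(inherits(modes, "mode_set"))
  freqs <- modes$frequencies
  imag <- freqs <= 0
  if (any(imag)) {
    warn(paste0("skipping imaginary/zero mode(s) at ",
                paste(format(freqs[imag], digits = 6), collapse = ", "),
                " cm^-1"))
  }
  use <- which(!imag & freqs >= cutoff)
  n <- length(modes$labels)
  if (length(use) == 0) {
    warn(sprintf("no mode at or above the %g cm^-1 cutoff: internal ADPs are zero",
                 cutoff))
    zero <- displacement_tensor(0, 0, 0, basis = "cartesian")
    return(setNames(rep(list(zero), n), modes$labels))
  }
  factors <- mode_msd_factor(freqs[use], temperature)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    u <- matrix(0, 3, 3)
    pref <- zero_point_msd(modes$masses[i], freqs[use]) * factors
    for (kk in seq_along(use)) {
      e <- modes$displacements[i, , use[kk]]
      u <- u + pref[kk] * tcrossprod(e)
    }
    out[[i]] <- new_u_tensor((u + t(u)) / 2, "cartesian")
  }
  setNames(out, modes$labels)
}
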