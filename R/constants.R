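# Physical constants (CODATA 2018, exact SI where defined)
.h_planck <- 6.62607015e-34    # J s
.k_boltz  <- 1.380649e-23      # J / K
.c_cm     <- 2.99792458e10     # cm / s  (wavenumbers are per cm)
.amu_kg   <- 1.66053906660e-27 # kg

# h*c/kB in cm K: converts a wavenumber to a characteristic temperature
.hc_over_kb <- .h_planck * .c_cm / .k_boltz

# Element data. Covalent radii from Cordero et al. (2008), Dalton Trans. 2832
# (low-spin value for Fe); masses are IUPAC 2021 standard atomic weights.
.element_table <- data.frame(
  symbol = c("H", "D", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P",
             "S", "Cl", "K", "Ca", "Fe", "Cu", "Zn", "Br", "I"),
  mass = c(1.008, 2.014, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990,
           24.305, 26.982, 28.086, 30.974, 32.06, 35.45, 39.098, 40.078,
           55.845, 63.546, 65.38, 79.904, 126.904),
  r_cov = c(0.31, 0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.21,
            1.11, 1.07, 1.05, 1.02, 2.03, 1.76, 1.32, 1.32, 1.22, 1.20,
            1.39),
  stringsAsFactors = FALSE
)

#' Look up tabulated element properties
#'
#' Returns the atomic mass (unified atomic mass units) or single-bond covalent
#' radius (Angstrom) for a chemical symbol. Symbols are matched
#' case-insensitively; deuterium ("D") is recognised and treated as hydrogen
#' for bonding purposes.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector, `NA` for unrecognised symbols.
#' @examples
#' element_mass("C")
#' covalent_radius(c("O", "H"))
#' @export
element_mass <- function(element) {
  idx <- match(normalize_element(element), .element_table$symbol)
  .element_table$mass[idx]
}

#' @rdname element_mass
#' @export
covalent_radius <- function(element) {
  idx <- match(normalize_element(element), .element_table$symbol)
  .element_table$r_cov[idx]
}

# "cl"/"CL" -> "Cl"; leaves unknown strings untouched so match() yields NA
normalize_element <- function(element) {
  el <- as.character(element)
  out <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  out[!nzchar(el)] <- NA_character_
  out
}

is_known_element <- function(element) {
  !is.na(match(normalize_element(element), .element_table$symbol))
}

# TRUE for hydrogen isotopes: these are the "riding" atoms everywhere below
is_hydrogen <- function(element) {
  normalize_element(element) %in% c("H", "D")
}
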