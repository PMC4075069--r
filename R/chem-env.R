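#' Covalent connectivity from interatomic distances
#'
#' Two atoms are bonded when their Cartesian distance does not exceed the sum
#' of their covalent radii (Cordero et al. 2008 single-bond values) plus a
#' tolerance. Hydrogen-hydrogen bonds are never formed. Hydrogens that end up
#' with zero or more than one non-hydrogen neighbour are reported with a
#' warning; downstream ratio analysis excludes them.
#'
#' @param structure A [crystal_structure()].
#' @param tolerance Distance slack in Angstrom added to the radius sum
#'   (default 0.40).
#' @return An object of class `bond_graph`: list with `bonds` (tibble
#'   `atom1`, `atom2`, `length` with `atom1 < atom2` lexicographically),
#'   `adjacency` (named list of neighbour label vectors) and
#'   `suspect_hydrogens` (labels excluded from classification).
#' @export
build_connectivity <- function(structure, tolerance = 0.40) {
  xyz <- cart_coords(structure)
  n <- nrow(xyz)
  rc <- covalent_radius(xyz$element)
  hyd <- is_hydrogen(xyz$element)
  p <- as.matrix(xyz[, c("x", "y", "z")])
  a1 <- character(0); a2 <- character(0); len <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (hyd[i] && hyd[j]) next
        d <- sqrt(sum((p[i, ] - p[j, ])^2))
        if (d <= rc[i] + rc[j] + tolerance && d > 1e-6) {
          a1 <- c(a1, xyz$label[i]); a2 <- c(a2, xyz$label[j])
          len <- c(len, d)
        }
      }
    }
  }
  adjacency <- setNames(vector("list", n), xyz$label)
  for (k in seq_along(a1)) {
    adjacency[[a1[k]]] <- c(adjacency[[a1[k]]], a2[k])
    adjacency[[a2[k]]] <- c(adjacency[[a2[k]]], a1[k])
  }
  elements <- setNames(xyz$element, xyz$label)
  suspect <- character(0)
  for (lab in xyz$label[hyd]) {
    heavy <- adjacency[[lab]][!is_hydrogen(elements[adjacency[[lab]]])]
    if (length(heavy) != 1) suspect <- c(suspect, lab)
  }
  if (length(suspect) > 0) {
    warn(paste0("hydrogen(s) without exactly one heavy neighbour, ",
                "excluded from ratio analysis: ",
                paste(suspect, collapse = ", ")))
  }
  base::structure(list(
    bonds = tibble(atom1 = a1, atom2 = a2, length = len),
    adjacency = adjacency,
    elements = elements,
    suspect_hydrogens = suspect
  ), class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat("<bond_graph>", nrow(x$bonds), "bonds,", length(x$adjacency), "atoms\n")
  invisible(x)
}

# bracket ordering: next-nearest neighbours sorted reverse-alphabetically by
# element symbol with hydrogen always last (matches e.g. "1n1c1c", "1c1h1h")
sort_bracket_elements <- function(elements) {
  el <- normalize_element(elements)
  h <- is_hydrogen(el)
  c(sort(el[!h], decreasing = TRUE), el[h])
}

#' Invariom-style environment name of a hydrogen atom
#'
#' Builds the chemical-environment name used to group hydrogen atoms: `"H1"`
#' followed by the lowercase parent element, then a bracket listing the
#' parent's other neighbours, each prefixed by its (formal single) bond
#' order, sorted reverse-alphabetically with hydrogen last. Examples:
#' a water hydrogen is `H1o[1h]`, a methyl hydrogen `H1c[1c1h1h]`.
#' All bond orders are emitted as 1; the fractional orders of the full
#' invariom nomenclature are outside this package's scope.
#'
#' @param graph A [build_connectivity()] result.
#' @param structure The matching [crystal_structure()].
#' @param h_label Label of the hydrogen atom to name.
#' @return A single string.
#' @export
h_environment_name <- function(graph, structure, h_label) {
  stopifnot(inherits(graph, "bond_graph"))
  el <- graph$elements
  if (!h_label %in% names(el)) {
    abort(paste0("no atom labelled '", h_label, "'"))
  }
  if (!is_hydrogen(el[h_label])) {
    abort(paste0("atom '", h_label, "' is not a hydrogen"))
  }
  nb <- graph$adjacency[[h_label]]
  heavy <- nb[!is_hydrogen(el[nb])]
  if (length(heavy) != 1) {
    abort(paste0("hydrogen '", h_label, "' has ", length(heavy),
                 " heavy neighbours; exactly one parent atom is required"))
  }
  parent <- heavy
  others <- setdiff(graph$adjacency[[parent]], h_label)
  bracket <- paste0("1", tolower(sort_bracket_elements(el[others])),
                    collapse = "")
  paste0("H1", tolower(normalize_element(el[parent])), "[", bracket, "]")
}

#' Group hydrogens by chemical environment
#'
#' Partitions all hydrogens with a unique parent atom into groups sharing the
#' same environment name (see [h_environment_name()]).
#'
#' @param structure A [crystal_structure()].
#' @param graph Optional pre-computed [build_connectivity()] result.
#' @param tolerance Bond-perception tolerance, forwarded to
#'   [build_connectivity()] when `graph` is not supplied.
#' @return A tibble `h_label`, `parent_label`, `environment`, one row per
#'   valid hydrogen; zero rows when the structure has no (valid) hydrogen.
#' @export
group_hydrogens <- function(structure, graph = NULL, tolerance = 0.40) {
  if (is.null(graph)) graph <- build_connectivity(structure, tolerance)
  el <- graph$elements
  h_labels <- names(el)[is_hydrogen(el)]
  h_labels <- setdiff(h_labels, graph$suspect_hydrogens)
  if (length(h_labels) == 0) {
    return(tibble(h_label = character(0), parent_label = character(0),
                  environment = character(0)))
  }
  rows <- map(h_labels, function(lab) {
    nb <- graph$adjacency[[lab]]
    parent <- nb[!is_hydrogen(el[nb])]
    tibble(h_label = lab, parent_label = parent,
           environment = h_environment_name(graph, structure, lab))
  })
  arrange(bind_rows(rows), .data$environment, .data$h_label)
}
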