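#' Crystal structure container
#'
#' Bundles a unit cell with an atom table. Atoms live in a tibble with one
#' row per site: `label`, `element`, fractional coordinates `x`, `y`, `z`,
#' `occupancy`, the isotropic displacement `u_iso` (Angstrom^2, `NA` when
#' absent) and the six anisotropic components `u11`..`u23` in the CIF
#' convention (`NA` when the atom is isotropic).
#'
#' @param cell A [unit_cell()].
#' @param atoms A data frame with at least `label`, `element`, `x`, `y`, `z`;
#'   missing displacement and occupancy columns are filled with defaults.
#' @param temperature Optional temperature in Kelvin.
#' @param provenance Free-text origin of the model.
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, atoms, temperature = NULL,
                              provenance = "") {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(atoms))
  atoms <- as_tibble(atoms)
  required <- c("label", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("occupancy")) {
    if (!col %in% names(atoms)) atoms[[col]] <- 1
  }
  for (col in c("u_iso", "u11", "u22", "u33", "u12", "u13", "u23")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  atoms$label <- as.character(atoms$label)
  atoms$element <- as.character(atoms$element)
  if (anyDuplicated(atoms$label)) {
    abort("atom labels must be unique")
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("fractional coordinates must be finite")
  }
  bad_el <- unique(atoms$element[!is_known_element(atoms$element)])
  if (length(bad_el) > 0) {
    abort(paste0("unrecognised element symbol(s): ",
                 paste(bad_el, collapse = ", ")))
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
    abort("occupancies must lie in [0, 1]")
  }
  structure(list(cell = cell, atoms = atoms,
                 temperature = temperature, provenance = provenance),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("<crystal_structure>", nrow(x$atoms), "atoms")
  if (!is.null(x$temperature)) cat(sprintf(", T = %g K", x$temperature))
  cat("\n")
  print(x$cell)
  n_aniso <- sum(!is.na(x$atoms$u11))
  cat(sprintf("  %d anisotropic, %d isotropic-only atoms\n",
              n_aniso, sum(is.na(x$atoms$u11) & !is.na(x$atoms$u_iso))))
  invisible(x)
}

#' Cartesian coordinates of a structure
#'
#' @param structure A [crystal_structure()].
#' @return A tibble `label`, `element`, `x`, `y`, `z` with Cartesian
#'   coordinates in Angstrom (convention of [orthogonalization_matrix()]).
#' @export
cart_coords <- function(structure) {
  stopifnot(inherits(structure, "crystal_structure"))
  m <- orthogonalization_matrix(structure$cell)
  frac <- t(as.matrix(structure$atoms[, c("x", "y", "z")]))
  xyz <- t(m %*% frac)
  tibble(label = structure$atoms$label, element = structure$atoms$element,
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# ---------------------------------------------------------------------------
# CIF 1.1 subset parser. Handles data_ blocks, key-value items, loop_
# constructs, '...'/"..." quoting, comments, multi-line semicolon text
# fields, and numeric standard uncertainties in parentheses.

cif_tokenize <- function(lines) {
  tokens <- character(0)
  i <- 1
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (startsWith(line, ";")) {         # semicolon text field: one value
      buf <- substring(line, 2)
      i <- i + 1
      while (i <= n && !startsWith(lines[i], ";")) {
        buf <- paste(buf, lines[i], sep = "\n")
        i <- i + 1
      }
      tokens <- c(tokens, buf)
      i <- i + 1
      next
    }
    pos <- 1
    len <- nchar(line)
    while (pos <= len) {
      ch <- substr(line, pos, pos)
      if (ch %in% c(" ", "\t")) { pos <- pos + 1; next }
      if (ch == "#") break
      if (ch %in% c("'", '"')) {
        close <- pos + 1
        while (close <= len &&
               !(substr(line, close, close) == ch &&
                 (close == len || substr(line, close + 1, close + 1) %in% c(" ", "\t")))) {
          close <- close + 1
        }
        if (close > len) abort(sprintf("unterminated quote on line %d", i))
        tokens <- c(tokens, substr(line, pos + 1, close - 1))
        pos <- close + 1
        next
      }
      stop_at <- regexpr("[ \t]", substring(line, pos))
      word <- if (stop_at == -1) substring(line, pos) else
        substr(line, pos, pos + stop_at - 2)
      tokens <- c(tokens, word)
      pos <- pos + nchar(word)
    }
    i <- i + 1
  }
  tokens
}

# Parse one data block from a token stream into key-value items and loops.
cif_parse_tokens <- function(tokens) {
  blocks <- list()
  cur <- NULL
  cur_name <- NULL
  k <- 1
  n <- length(tokens)
  flush <- function() {
    if (!is.null(cur_name)) blocks[[cur_name]] <<- cur
  }
  is_tag <- function(tok) startsWith(tok, "_")
  while (k <= n) {
    tok <- tokens[k]
    if (grepl("^data_", tok, ignore.case = TRUE)) {
      flush()
      cur_name <- substring(tok, 6)
      cur <- list(items = list(), loops = list())
      k <- k + 1
    } else if (is.null(cur)) {
      k <- k + 1                         # content before any data_ block
    } else if (identical(tolower(tok), "loop_")) {
      k <- k + 1
      tags <- character(0)
      while (k <= n && is_tag(tokens[k])) {
        tags <- c(tags, tolower(tokens[k]))
        k <- k + 1
      }
      vals <- character(0)
      while (k <= n && !is_tag(tokens[k]) &&
             !identical(tolower(tokens[k]), "loop_") &&
             !grepl("^data_", tokens[k], ignore.case = TRUE)) {
        vals <- c(vals, tokens[k])
        k <- k + 1
      }
      if (length(tags) == 0 || length(vals) %% length(tags) != 0) {
        abort("malformed CIF loop: row length does not match column count")
      }
      tab <- as.data.frame(matrix(vals, ncol = length(tags), byrow = TRUE),
                           stringsAsFactors = FALSE)
      names(tab) <- tags
      cur$loops[[length(cur$loops) + 1]] <- tab
    } else if (is_tag(tok)) {
      if (k + 1 > n) abort(sprintf("CIF item %s has no value", tok))
      cur$items[[tolower(tok)]] <- tokens[k + 1]
      k <- k + 2
    } else {
      k <- k + 1                         # stray token; ignore
    }
  }
  flush()
  blocks
}

# "9.854(3)" -> value 9.854, su 0.003; "." / "?" -> NA
cif_number <- function(x) {
  x <- as.character(x)
  value <- rep(NA_real_, length(x))
  su <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || s %in% c(".", "?", "")) next
    m <- regmatches(s, regexec("^([-+0-9.eEdD]+)\\(([0-9]+)\\)$", s))[[1]]
    if (length(m) == 3) {
      base <- m[2]
      dec <- if (grepl("\\.", base)) nchar(sub("^[^.]*\\.", "", base)) else 0
      value[i] <- as.numeric(base)
      su[i] <- as.numeric(m[3]) * 10^(-dec)
    } else {
      v <- suppressWarnings(as.numeric(gsub("[dD]", "e", s)))
      if (is.na(v)) abort(sprintf("cannot parse CIF number '%s'", s))
      value[i] <- v
    }
  }
  list(value = value, su = su)
}

cif_find_loop <- function(block, tag) {
  for (tab in block$loops) if (tag %in% names(tab)) return(tab)
  NULL
}

#' Read a small-molecule CIF file
#'
#' Parses a CIF 1.1 file containing cell constants and an `_atom_site` loop,
#' with an optional `_atom_site_aniso` loop. Both `U`- and `B`-convention
#' displacement items are accepted (`U = B / (8 pi^2)`). Standard
#' uncertainties in parentheses are parsed and kept in the `su` attribute of
#' the returned object but are not propagated by any computation.
#'
#' @param path Path to the CIF file.
#' @param block Optional data-block name; by default the first block that
#'   contains cell constants is used.
#' @return A [crystal_structure()]. Atoms listed in the aniso loop carry
#'   `u11`..`u23`; others carry `u_iso` only. Atoms with no displacement item
#'   at all are kept and flagged with a warning.
#' @export
read_cif <- function(path, block = NULL) {
  if (!file.exists(path)) abort(paste0("CIF file not found: ", path))
  blocks <- cif_parse_tokens(cif_tokenize(readLines(path, warn = FALSE)))
  if (length(blocks) == 0) abort("no data_ block found in CIF file")
  if (!is.null(block)) {
    if (!block %in% names(blocks)) {
      abort(paste0("data block '", block, "' not present; available: ",
                   paste(names(blocks), collapse = ", ")))
    }
    blk <- blocks[[block]]
  } else {
    has_cell <- vapply(blocks, function(b)
      !is.null(b$items[["_cell_length_a"]]), logical(1))
    if (!any(has_cell)) abort("no data block with cell constants found")
    blk <- blocks[[which(has_cell)[1]]]
  }

  su_records <- list()
  grab_cell <- function(tag) {
    v <- blk$items[[tag]]
    if (is.null(v)) abort(paste0("missing required cell item ", tag))
    p <- cif_number(v)
    if (!is.na(p$su)) {
      su_records[[length(su_records) + 1]] <<-
        tibble(item = tag, label = NA_character_, su = p$su)
    }
    p$value
  }
  cell <- unit_cell(grab_cell("_cell_length_a"),
                    grab_cell("_cell_length_b"),
                    grab_cell("_cell_length_c"),
                    grab_cell("_cell_angle_alpha"),
                    grab_cell("_cell_angle_beta"),
                    grab_cell("_cell_angle_gamma"))

  temperature <- NULL
  for (tag in c("_diffrn_ambient_temperature", "_cell_measurement_temperature")) {
    if (!is.null(blk$items[[tag]])) {
      temperature <- cif_number(blk$items[[tag]])$value
      break
    }
  }

  sites <- cif_find_loop(blk, "_atom_site_label")
  if (is.null(sites)) abort("CIF file has no _atom_site loop")

  col_num <- function(tab, tag, item_name = tag) {
    if (!tag %in% names(tab)) return(rep(NA_real_, nrow(tab)))
    p <- cif_number(tab[[tag]])
    keep <- which(!is.na(p$su))
    if (length(keep) > 0) {
      su_records[[length(su_records) + 1]] <<-
        tibble(item = item_name, label = tab[["_atom_site_label"]][keep] %||%
                 tab[["_atom_site_aniso_label"]][keep], su = p$su[keep])
    }
    p$value
  }

  label <- sites[["_atom_site_label"]]
  element <- if ("_atom_site_type_symbol" %in% names(sites)) {
    gsub("[^A-Za-z].*$", "", sites[["_atom_site_type_symbol"]])
  } else {
    element_from_label(label)
  }
  u_iso <- col_num(sites, "_atom_site_u_iso_or_equiv")
  if (all(is.na(u_iso)) && "_atom_site_b_iso_or_equiv" %in% names(sites)) {
    u_iso <- col_num(sites, "_atom_site_b_iso_or_equiv") / (8 * pi^2)
  }
  occ <- col_num(sites, "_atom_site_occupancy")
  occ[is.na(occ)] <- 1

  atoms <- tibble(label = label, element = normalize_element(element),
                  x = col_num(sites, "_atom_site_fract_x"),
                  y = col_num(sites, "_atom_site_fract_y"),
                  z = col_num(sites, "_atom_site_fract_z"),
                  occupancy = occ, u_iso = u_iso,
                  u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
                  u12 = NA_real_, u13 = NA_real_, u23 = NA_real_)

  aniso <- cif_find_loop(blk, "_atom_site_aniso_label")
  if (!is.null(aniso)) {
    is_b <- "_atom_site_aniso_b_11" %in% names(aniso)
    comp_tags <- paste0("_atom_site_aniso_", if (is_b) "b" else "u",
                        "_", c("11", "22", "33", "12", "13", "23"))
    conv <- if (is_b) 1 / (8 * pi^2) else 1
    for (r in seq_len(nrow(aniso))) {
      lab <- aniso[["_atom_site_aniso_label"]][r]
      row <- match(lab, atoms$label)     # case-sensitive by construction
      if (is.na(row)) {
        abort(paste0("aniso loop label '", lab,
                     "' has no matching _atom_site entry"))
      }
      vals <- vapply(comp_tags, function(tg) cif_number(aniso[[tg]][r])$value,
                     numeric(1)) * conv
      atoms[row, c("u11", "u22", "u33", "u12", "u13", "u23")] <- as.list(vals)
    }
  }

  no_disp <- is.na(atoms$u_iso) & is.na(atoms$u11)
  if (any(no_disp)) {
    warn(paste0("atom(s) without any displacement item: ",
                paste(atoms$label[no_disp], collapse = ", ")))
  }
  if (any(atoms$occupancy < 1)) {
    warn(paste0("partially occupied (disordered) atom(s): ",
                paste(atoms$label[atoms$occupancy < 1], collapse = ", ")))
  }

  st <- crystal_structure(cell, atoms, temperature = temperature,
                          provenance = paste0("read_cif: ", path))
  st$su <- if (length(su_records) > 0) bind_rows(su_records) else
    tibble(item = character(0), label = character(0), su = numeric(0))
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

element_from_label <- function(label) {
  two <- normalize_element(substr(label, 1, 2))
  one <- normalize_element(substr(label, 1, 1))
  ifelse(grepl("^[A-Za-z]{2}", label) & is_known_element(two) &
           !is_known_element(substr(label, 2, 2)), two, one)
}

#' Write a crystal structure to CIF
#'
#' Emits a CIF 1.1 file re-readable by [read_cif()]: cell constants, an
#' `_atom_site` loop (with `U_iso_or_equiv` where available) and an
#' `_atom_site_aniso_U` loop for anisotropic atoms. Numbers are written with
#' twelve decimal places so that a write/read round trip is exact to well
#' below 1e-9.
#'
#' @param structure A [crystal_structure()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- structure$atoms
  num <- function(x) ifelse(is.na(x), ".", sprintf("%.12f", x))
  lines <- c("data_tlsoniom",
             sprintf("_cell_length_a %s", num(structure$cell$a)),
             sprintf("_cell_length_b %s", num(structure$cell$b)),
             sprintf("_cell_length_c %s", num(structure$cell$c)),
             sprintf("_cell_angle_alpha %s", num(structure$cell$alpha)),
             sprintf("_cell_angle_beta %s", num(structure$cell$beta)),
             sprintf("_cell_angle_gamma %s", num(structure$cell$gamma)))
  if (!is.null(structure$temperature)) {
    lines <- c(lines, sprintf("_diffrn_ambient_temperature %s",
                              num(structure$temperature)))
  }
  lines <- c(lines, "loop_",
             " _atom_site_label", " _atom_site_type_symbol",
             " _atom_site_fract_x", " _atom_site_fract_y",
             " _atom_site_fract_z", " _atom_site_occupancy",
             " _atom_site_U_iso_or_equiv",
             sprintf("%s %s %s %s %s %s %s",
                     at$label, at$element, num(at$x), num(at$y), num(at$z),
                     num(at$occupancy), num(at$u_iso)))
  has_aniso <- !is.na(at$u11)
  if (any(has_aniso)) {
    an <- at[has_aniso, ]
    lines <- c(lines, "loop_",
               " _atom_site_aniso_label",
               paste0(" _atom_site_aniso_U_", c("11", "22", "33", "12", "13", "23")),
               sprintf("%s %s %s %s %s %s %s",
                       an$label, num(an$u11), num(an$u22), num(an$u33),
                       num(an$u12), num(an$u13), num(an$u23)))
  }
  tryCatch(writeLines(lines, path),
           error = function(e) abort(paste0("cannot write CIF to '", path,
                                            "': ", conditionMessage(e))))
  invisible(path)
}
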