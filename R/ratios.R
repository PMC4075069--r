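#' Hydrogen-to-parent displacement ratio
#'
#' The ratio of a hydrogen's (equivalent) isotropic displacement to the
#' equivalent isotropic displacement of its bonded parent atom, the quantity
#' conventionally fixed at 1.2 or 1.5 in riding-hydrogen refinement. The
#' numerator is the hydrogen's `u_iso` when only an isotropic value is
#' present, otherwise the `u_eq` of its anisotropic tensor; the denominator
#' is always the parent's `u_eq`, with the same averaging method.
#'
#' @param structure A [crystal_structure()].
#' @param h_label Label of one hydrogen atom.
#' @param averaging `"arithmetic"` (default) or `"geometric"`, passed to
#'   [u_eq()].
#' @param graph Optional pre-computed [build_connectivity()] result.
#' @return A one-row tibble: `h_label`, `parent_label`, `environment`,
#'   `temperature`, `ratio`, `method`.
#' @export
hydrogen_ratio <- function(structure, h_label,
                           averaging = c("arithmetic", "geometric"),
                           graph = NULL) {
  averaging <- match.arg(averaging)
  res <- hydrogen_ratios(structure, averaging = averaging, graph = graph)
  out <- res[res$h_label == h_label, ]
  if (nrow(out) == 0) {
    abort(paste0("no ratio for '", h_label,
                 "': not a valid hydrogen or displacement data missing"))
  }
  out
}

#' All hydrogen-to-parent ratios of a structure
#'
#' Vectorized form of [hydrogen_ratio()]. Hydrogens without usable
#' displacement data, or whose parent lacks an anisotropic tensor, are
#' skipped with a warning. When `h_adps` is supplied (e.g. the `h_adps`
#' field of a [tls_plus_oniom()] result) the hydrogen numerators are taken
#' from those tensors instead of the structure and the records are tagged
#' `method = "tls_oniom"`.
#'
#' @inheritParams hydrogen_ratio
#' @param h_adps Optional named list of Cartesian hydrogen tensors replacing
#'   the observed hydrogen displacement data.
#' @param temperature Optional override for the record temperature.
#' @return A tibble of ratio records (possibly zero rows).
#' @export
hydrogen_ratios <- function(structure,
                            averaging = c("arithmetic", "geometric"),
                            graph = NULL, h_adps = NULL,
                            temperature = NULL) {
  averaging <- match.arg(averaging)
  groups <- group_hydrogens(structure, graph = graph)
  temp <- temperature %||% structure$temperature %||% NA_real_
  method <- if (is.null(h_adps)) "observed" else "tls_oniom"
  if (nrow(groups) == 0) {
    return(empty_ratio_records())
  }
  cart <- structure_cart_adps(structure, include_iso = FALSE)
  at <- structure$atoms
  skipped <- character(0)
  rows <- list()
  for (k in seq_len(nrow(groups))) {
    h <- groups$h_label[k]
    p <- groups$parent_label[k]
    if (!p %in% names(cart)) {
      skipped <- c(skipped, h)
      next
    }
    num <- NA_real_
    if (!is.null(h_adps)) {
      if (h %in% names(h_adps)) num <- u_eq(h_adps[[h]], averaging, label = h)
    } else if (h %in% names(cart)) {
      num <- u_eq(cart[[h]], averaging, label = h)
    } else {
      uiso <- at$u_iso[match(h, at$label)]
      if (!is.na(uiso)) num <- uiso
    }
    if (is.na(num)) {
      skipped <- c(skipped, h)
      next
    }
    rows[[length(rows) + 1]] <- tibble(
      h_label = h, parent_label = p, environment = groups$environment[k],
      temperature = temp, ratio = num / u_eq(cart[[p]], averaging, label = p),
      method = method)
  }
  if (length(skipped) > 0) {
    warn(paste0("skipping hydrogen(s) with missing displacement data: ",
                paste(skipped, collapse = ", ")))
  }
  if (length(rows) == 0) return(empty_ratio_records())
  bind_rows(rows)
}

empty_ratio_records <- function() {
  tibble(h_label = character(0), parent_label = character(0),
         environment = character(0), temperature = numeric(0),
         ratio = numeric(0), method = character(0))
}

#' Average ratios per chemical environment
#'
#' Collapses per-hydrogen ratio records to one row per (environment,
#' temperature): unweighted mean, sample standard deviation (0 when n = 1)
#' and member count.
#'
#' @param records A tibble of ratio records from [hydrogen_ratios()].
#' @return A `ratio_table`: tibble `environment`, `temperature`,
#'   `mean_ratio`, `sd_ratio`, `n`.
#' @export
average_by_environment <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("average_by_environment() needs at least one ratio record")
  }
  tab <- records |>
    group_by(.data$environment, .data$temperature) |>
    summarise(mean_ratio = mean(.data$ratio),
              sd_ratio = if (n() > 1) sd(.data$ratio) else 0,
              n = n(), .groups = "drop") |>
    arrange(.data$environment, .data$temperature)
  class(tab) <- c("ratio_table", class(tab))
  tab
}

#' Temperature-dependent multiplier curves
#'
#' Builds the per-environment multiplier table across a temperature series,
#' either from observed hydrogen displacement data (one structure per
#' temperature) or from the TLS+ONIOM recombination when normal modes are
#' supplied. Deviations from the conventional constants 1.2 and 1.5 are
#' appended.
#'
#' @param structures List of [crystal_structure()] objects, one per
#'   temperature (each must carry its temperature).
#' @param modes Optional [normal_mode_set()]; when given, hydrogen numerators
#'   come from [tls_plus_oniom()] at each structure's temperature.
#' @param cutoff Frequency threshold forwarded to [tls_plus_oniom()].
#' @param averaging Equivalent-isotropic averaging method.
#' @return A `ratio_table` tibble with additional columns `dev_12` and
#'   `dev_15` (mean ratio minus 1.2 and 1.5).
#' @export
multiplier_curve <- function(structures, modes = NULL, cutoff = 200,
                             averaging = c("arithmetic", "geometric")) {
  averaging <- match.arg(averaging)
  stopifnot(is.list(structures), length(structures) > 0)
  records <- list()
  for (st in structures) {
    if (is.null(st$temperature) || is.na(st$temperature)) {
      warn("structure without a temperature skipped in multiplier_curve()")
      next
    }
    if (is.null(modes)) {
      rec <- hydrogen_ratios(st, averaging = averaging)
    } else {
      to <- tls_plus_oniom(st, modes, cutoff = cutoff)
      rec <- hydrogen_ratios(st, averaging = averaging, h_adps = to$h_adps)
    }
    records[[length(records) + 1]] <- rec
  }
  if (length(records) == 0) {
    abort("no structure with a temperature was supplied")
  }
  tab <- average_by_environment(bind_rows(records))
  tab$dev_12 <- tab$mean_ratio - 1.2
  tab$dev_15 <- tab$mean_ratio - 1.5
  tab
}

#' Write a ratio table to TSV
#'
#' @param table A `ratio_table` from [average_by_environment()] or
#'   [multiplier_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ratio_tsv <- function(table, path) {
  df <- as.data.frame(table)
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot multiplier curves
#'
#' Ratio versus temperature, one curve per hydrogen environment, with the
#' conventional 1.2 and 1.5 levels drawn as dashed reference lines and error
#' bars of one sample standard deviation where a group has more than one
#' member.
#'
#' @param object A `ratio_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratio_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temperature,
                                       y = .data$mean_ratio,
                                       colour = .data$environment)) +
    ggplot2::geom_hline(yintercept = c(1.2, 1.5), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ratio - .data$sd_ratio,
                                        ymax = .data$mean_ratio + .data$sd_ratio),
                           width = 3, alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (K)",
                  y = expression(U[eq](H) / U[eq](parent)),
                  colour = "Environment")
}

#' Largest sp3-methine hydrogen ratio of a structure
#'
#' Convenience summary used to compare against the conventional multipliers:
#' the maximum hydrogen/parent U_eq ratio over hydrogens bonded to an sp3
#' carbon with three non-hydrogen next-nearest neighbours (environment names
#' of the form `H1c[1x1y1z]` with no hydrogen in the bracket).
#'
#' @param structure A [crystal_structure()] with hydrogen displacement data
#'   (e.g. a neutron model).
#' @param averaging Averaging method for [u_eq()].
#' @return A scalar, or `NA` if no such hydrogen exists.
#' @export
max_methine_ratio <- function(structure,
                              averaging = c("arithmetic", "geometric")) {
  averaging <- match.arg(averaging)
  rec <- hydrogen_ratios(structure, averaging = averaging)
  sel <- grepl("^H1c\\[(1[a-gi-z][a-z]?){3}\\]$", rec$environment)
  if (!any(sel)) return(NA_real_)
  max(rec$ratio[sel])
}
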