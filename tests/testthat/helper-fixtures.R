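# Builders for small in-code fixtures used across the suite.

# crystal structure from a Cartesian atom table in a large cubic box
structure_from_cart <- function(atoms, box = 20, temperature = NULL, ...) {
  cell <- unit_cell(box, box, box)
  atoms$x <- atoms$x / box
  atoms$y <- atoms$y / box
  atoms$z <- atoms$z / box
  crystal_structure(cell, atoms, temperature = temperature, ...)
}

tet_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# ideal water molecule (O-H 0.96 A, H-O-H 104.5 deg), Cartesian
water_atoms <- function(origin = c(0, 0, 0)) {
  half <- 104.5 / 2 * pi / 180
  tibble::tibble(
    label = c("O1", "H1", "H2"),
    element = c("O", "H", "H"),
    x = origin[1] + c(0, 0.96 * cos(half), 0.96 * cos(half)),
    y = origin[2] + c(0, 0.96 * sin(half), -0.96 * sin(half)),
    z = origin[3]
  )
}

# idealized model-compound geometries carrying exactly the atoms needed for
# environment naming (tetrahedral sp3 skeletons)
model_compound <- function(name) {
  d <- tet_dirs()
  atom <- function(label, element, xyz) {
    tibble::tibble(label = label, element = element,
                   x = xyz[1], y = xyz[2], z = xyz[3])
  }
  atoms <- switch(
    name,
    water = water_atoms(),
    methanol = dplyr::bind_rows(
      atom("C1", "C", c(0, 0, 0)),
      atom("O1", "O", 1.43 * d[1, ]),
      atom("H1", "H", 1.43 * d[1, ] - 0.96 * d[2, ]),
      atom("H2", "H", 1.09 * d[2, ]),
      atom("H3", "H", 1.09 * d[3, ]),
      atom("H4", "H", 1.09 * d[4, ])
    ),
    ethane = dplyr::bind_rows(
      atom("C1", "C", c(0, 0, 0)),
      atom("C2", "C", 1.53 * d[1, ]),
      atom("H1", "H", 1.09 * d[2, ]),
      atom("H2", "H", 1.09 * d[3, ]),
      atom("H3", "H", 1.09 * d[4, ]),
      atom("H4", "H", 1.53 * d[1, ] - 1.09 * d[2, ]),
      atom("H5", "H", 1.53 * d[1, ] - 1.09 * d[3, ]),
      atom("H6", "H", 1.53 * d[1, ] - 1.09 * d[4, ])
    ),
    propane = dplyr::bind_rows(
      atom("C2", "C", c(0, 0, 0)),
      atom("C1", "C", 1.53 * d[1, ]),
      atom("C3", "C", 1.53 * d[2, ]),
      atom("H1", "H", 1.09 * d[3, ]),
      atom("H2", "H", 1.09 * d[4, ])
    ),
    aminopropane = dplyr::bind_rows(   # 2-aminopropane central CH
      atom("C2", "C", c(0, 0, 0)),
      atom("C1", "C", 1.53 * d[1, ]),
      atom("C3", "C", 1.53 * d[2, ]),
      atom("N1", "N", 1.47 * d[3, ]),
      atom("H1", "H", 1.09 * d[4, ])
    ),
    propanol = dplyr::bind_rows(       # 2-propanol central CH
      atom("C2", "C", c(0, 0, 0)),
      atom("C1", "C", 1.53 * d[1, ]),
      atom("C3", "C", 1.53 * d[2, ]),
      atom("O1", "O", 1.43 * d[3, ]),
      atom("H1", "H", 1.09 * d[4, ])
    ),
    ethylamine = dplyr::bind_rows(     # CH2 of ethylamine
      atom("C2", "C", c(0, 0, 0)),
      atom("C1", "C", 1.53 * d[1, ]),
      atom("N1", "N", 1.47 * d[2, ]),
      atom("H1", "H", 1.09 * d[3, ]),
      atom("H2", "H", 1.09 * d[4, ])
    ),
    stop("unknown model compound ", name)
  )
  atoms$x <- atoms$x + 10
  atoms$y <- atoms$y + 10
  atoms$z <- atoms$z + 10
  structure_from_cart(atoms)
}

# random symmetric positive-definite 3x3 with eigenvalues of order `scale`
rand_psd3 <- function(scale = 0.02) {
  a <- matrix(rnorm(9), 3, 3)
  s <- crossprod(a)
  s / max(eigen(s, symmetric = TRUE, only.values = TRUE)$values) * scale +
    diag(3) * scale * 0.1
}

rand_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random physically plausible TLS model
rand_tls_model <- function(origin = c(0, 0, 0)) {
  tls_model(T = rand_psd3(0.015), L = rand_psd3(0.0015),
            S = matrix(rnorm(9, sd = 3e-4), 3, 3), origin = origin)
}

# random atom cloud, guaranteed non-degenerate
rand_cloud <- function(n = 12, spread = 2.5) {
  pos <- matrix(rnorm(3 * n, sd = spread), n, 3)
  rownames(pos) <- paste0("X", seq_len(n))
  pos
}

max_tensor_diff <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  max(vapply(names(a), function(l)
    max(abs(unclass(a[[l]]) - unclass(b[[l]]))), numeric(1)))
}

max_tls_param_diff <- function(m1, m2) {
  max(abs(m1$T - m2$T), abs(m1$L - m2$L), abs(m1$S - m2$S))
}

write_mini_cif <- function(lines, path = tempfile(fileext = ".cif")) {
  writeLines(lines, path)
  path
}
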