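test_that("a minimal CIF with one isotropic atom reads correctly", {
  path <- write_mini_cif(c(
    "data_mini",
    "_cell_length_a 10.0", "_cell_length_b 10.0", "_cell_length_c 10.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_",
    " _atom_site_label", " _atom_site_type_symbol",
    " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
    " _atom_site_U_iso_or_equiv",
    "C1 C 0.1 0.2 0.3 0.01"
  ))
  st <- read_cif(path)
  expect_s3_class(st, "crystal_structure")
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$u_iso, 0.01)
  expect_true(is.na(st$atoms$u11))
  expect_equal(st$atoms$occupancy, 1)
})

test_that("an isotropic aniso loop gives U_eq equal to its components", {
  path <- write_mini_cif(c(
    "data_iso",
    "_cell_length_a 9.854", "_cell_length_b 9.249", "_cell_length_c 10.144",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_",
    " _atom_site_label", " _atom_site_type_symbol",
    " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
    "O1 O 0.5 0.5 0.5",
    "loop_",
    " _atom_site_aniso_label",
    " _atom_site_aniso_U_11", " _atom_site_aniso_U_22",
    " _atom_site_aniso_U_33", " _atom_site_aniso_U_12",
    " _atom_site_aniso_U_13", " _atom_site_aniso_U_23",
    "O1 0.02 0.02 0.02 0 0 0"
  ))
  st <- read_cif(path)
  adps <- tlsoniom:::structure_cart_adps(st)
  expect_equal(u_eq(adps$O1), 0.02, tolerance = 1e-12)
})

test_that("write/read round trip preserves the structure to 1e-12", {
  fx <- generate_fixture(fixture_spec(temps = c(9, 150)))
  st <- fx$structures[["9"]]
  path <- tempfile(fileext = ".cif")
  write_structure_cif(st, path)
  st2 <- read_cif(path)
  expect_equal(st2$atoms$label, st$atoms$label)
  expect_equal(st2$atoms$element, st$atoms$element)
  for (col in c("x", "y", "z", "u_iso", "u11", "u22", "u33",
                "u12", "u13", "u23")) {
    expect_lt(max(abs(st2$atoms[[col]] - st$atoms[[col]])), 1e-12)
  }
  expect_equal(st2$temperature, 9)
  expect_lt(abs(st2$cell$a - st$cell$a), 1e-12)
})

test_that("structures without ADPs produce a valid CIF without aniso loop", {
  st <- structure_from_cart(water_atoms(c(10, 10, 10)))
  path <- tempfile(fileext = ".cif")
  expect_warning(write_structure_cif(st, path) |> read_cif(),
                 "without any displacement")
  txt <- readLines(path)
  expect_false(any(grepl("aniso", txt)))
  suppressWarnings(st2 <- read_cif(path))
  expect_equal(nrow(st2$atoms), 3)
})

test_that("atom count is preserved for a multi-fragment asymmetric unit", {
  # toy fixture contains a molecule plus a separate water: 14 sites
  fx <- generate_fixture(fixture_spec(temps = 9))
  path <- tempfile(fileext = ".cif")
  write_structure_cif(fx$structures[["9"]], path)
  expect_equal(nrow(read_cif(path)$atoms), 14)
})

test_that("missing cell and orphan aniso labels are fatal", {
  no_cell <- write_mini_cif(c(
    "data_x", "loop_", " _atom_site_label", " _atom_site_fract_x",
    " _atom_site_fract_y", " _atom_site_fract_z", "C1 0 0 0"
  ))
  expect_error(read_cif(no_cell), "cell")

  orphan <- write_mini_cif(c(
    "data_x",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_",
    " _atom_site_label", " _atom_site_type_symbol",
    " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
    "C1 C 0 0 0",
    "loop_",
    " _atom_site_aniso_label",
    " _atom_site_aniso_U_11", " _atom_site_aniso_U_22",
    " _atom_site_aniso_U_33", " _atom_site_aniso_U_12",
    " _atom_site_aniso_U_13", " _atom_site_aniso_U_23",
    "C9 0.02 0.02 0.02 0 0 0"
  ))
  expect_error(read_cif(orphan), "C9")
})

test_that("B-convention displacement items are converted to U", {
  b <- 0.015 * 8 * pi^2
  path <- write_mini_cif(c(
    "data_b",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_",
    " _atom_site_label", " _atom_site_type_symbol",
    " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
    " _atom_site_B_iso_or_equiv",
    sprintf("C1 C 0.1 0.1 0.1 %.10f", b)
  ))
  st <- read_cif(path)
  expect_equal(st$atoms$u_iso, 0.015, tolerance = 1e-8)
})

test_that("standard uncertainties in parentheses are parsed and stored", {
  path <- write_mini_cif(c(
    "data_su",
    "_cell_length_a 9.854(3)", "_cell_length_b 9.249(3)",
    "_cell_length_c 10.144(2)",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "_diffrn_ambient_temperature 9",
    "loop_",
    " _atom_site_label", " _atom_site_type_symbol",
    " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
    " _atom_site_U_iso_or_equiv",
    "C1 C 0.12345(8) 0.2 0.3 0.0123(4)"
  ))
  st <- read_cif(path)
  expect_equal(st$cell$a, 9.854)
  expect_equal(st$atoms$x, 0.12345)
  expect_equal(st$temperature, 9)
  su <- st$su
  expect_equal(su$su[su$item == "_cell_length_a"], 0.003)
  expect_true(4e-4 %in% su$su)   # the U_iso s.u.
  expect_true(8e-5 %in% su$su)   # the fract_x s.u.
})

test_that("data blocks can be selected by name", {
  path <- write_mini_cif(c(
    "data_first",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", " _atom_site_label", " _atom_site_type_symbol",
    " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
    " _atom_site_U_iso_or_equiv",
    "C1 C 0 0 0 0.01",
    "data_second",
    "_cell_length_a 12", "_cell_length_b 12", "_cell_length_c 12",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", " _atom_site_label", " _atom_site_type_symbol",
    " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
    " _atom_site_U_iso_or_equiv",
    "N1 N 0 0 0 0.02"
  ))
  expect_equal(read_cif(path)$cell$a, 10)
  expect_equal(read_cif(path, block = "second")$cell$a, 12)
  expect_error(read_cif(path, block = "third"), "not present")
})
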