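Package: tlsoniom
Title: Temperature-Dependent Riding-Hydrogen Displacement Ratios from
    TLS and Internal-Mode Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving temperature-dependent multipliers of the
    riding-hydrogen model in crystallographic refinement. Reads and writes
    small-molecule CIF files with anisotropic displacement parameters,
    converts displacement tensors between crystallographic and Cartesian
    bases, classifies hydrogen atoms by their covalent bonding environment
    (invariom-style names), converts quantum-chemical normal modes into
    temperature-dependent internal atomic displacement tensors within the
    molecular Einstein approximation, fits Schomaker-Trueblood
    translation-libration-screw (TLS) rigid-body models to non-hydrogen
    displacement parameters after internal-mode subtraction, recombines
    both contributions to predict hydrogen displacement parameters
    (TLS+ONIOM), and tabulates per-environment ratios of hydrogen to
    parent-atom equivalent isotropic displacement versus temperature.
    Includes a synthetic fixture generator with known ground truth and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
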