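---
title: "Temperature-dependent riding-hydrogen multipliers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-dependent riding-hydrogen multipliers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsoniom)
```

## The model

An atom's thermal motion in a crystal is summarized by its anisotropic
displacement parameter (ADP), a symmetric 3×3 mean-square displacement
tensor $U$. For hydrogen, X-ray refinement usually cannot determine $U$
freely, so the riding model ties the hydrogen's isotropic displacement to
its parent atom: $U_\mathrm{iso}(\mathrm{H}) = k \cdot
U_\mathrm{eq}(X)$ with $k$ fixed at 1.2 or 1.5. This package computes how
$k$ actually depends on temperature by splitting atomic motion into two
physically distinct parts.

**Internal (intramolecular) motion.** Within the molecular Einstein
approximation, every normal mode of the molecule is an independent harmonic
oscillator. A mode of wavenumber $\nu$ contributes to atom $i$ (mass $m_i$,
mass-weighted eigenvector segment $\mathbf{e}_{ik}$):

$$U_\mathrm{int}(i) \;=\; \sum_{k:\ \nu_k \ge \nu_\mathrm{cut}}
\frac{h}{8\pi^2 m_i c \nu_k}\,
\coth\!\left(\frac{h c \nu_k}{2 k_B T}\right)\,
\mathbf{e}_{ik}\mathbf{e}_{ik}^\top .$$

The prefactor is the quantum zero-point mean-square amplitude
($h/8\pi^2 m c\nu \approx 0.0169$ Å² at 1000 cm⁻¹ for 1 amu); the
$\coth$ factor is exactly 1 at $T=0$ and crosses over to the classical
equipartition line $2k_BT/hc\nu$ at high temperature. Because the amplitude
scales as $1/m$, hydrogen dominates the internal term — this mass asymmetry
is the entire reason the riding multiplier is temperature dependent.

**External (lattice) motion.** Rigid-body motion of the molecule in the
crystal field is described by the Schomaker–Trueblood TLS model:

$$U(\mathbf r) = \mathbf T + A\,\mathbf L\,A^\top + A\,\mathbf S +
\mathbf S^\top A^\top, \qquad A\,\boldsymbol\omega =
\boldsymbol\omega \times (\mathbf r - \mathbf r_0),$$

with translation tensor $\mathbf T$ (Å²), libration tensor $\mathbf L$
(rad²) and screw tensor $\mathbf S$ (Å·rad). Because molecular Einstein
frequencies below roughly 200 cm⁻¹ are dominated by motion of the molecule
against its crystal environment — which an isolated-cluster calculation
cannot get right — modes below the cutoff are discarded and the lattice
part is *measured* instead, by fitting T, L, S to the observed non-hydrogen
ADPs after subtracting their (small, nearly isotropic) internal part.

**Recombination.** The fitted rigid-body field is evaluated at the hydrogen
positions, which never entered the fit, and the hydrogen internal term is
added back: $U(\mathrm H) = U_\mathrm{TLS}(\mathrm H) +
U_\mathrm{int}(\mathrm H, T)$. Ratios
$U_\mathrm{eq}(\mathrm H)/U_\mathrm{eq}(X)$ are then grouped by chemical
environment and averaged.

## Parameters that matter

* `cutoff` (cm⁻¹, default **200**): the frequency below which internal
  modes are attributed to the lattice and dropped. Too low, and badly
  approximated cluster modes inflate every ADP; too high, and genuine
  internal motion leaks into the TLS term. The default follows the
  established practice for this method; it is exposed on every relevant
  function and CLI subcommand.
* Temperature grid (K, default **9, 30, 50, 75, 100, 150, 200, 250**): the
  multi-temperature series the multiplier tables are evaluated on,
  matching the span over which the multiplier varies most (everything
  interesting happens below ~150 K).
* `averaging` (`"arithmetic"` default, `"geometric"`): how an anisotropic
  tensor collapses to $U_\mathrm{eq}$ — trace/3, or the cube root of the
  eigenvalue product. The arithmetic mean is rotation invariant and defined
  for non-positive tensors, hence the default; both are available because
  the two conventions bracket the value a least-squares isotropic
  refinement would produce. For strongly anisotropic hydrogen tensors at
  low temperature the two can differ by 20–30%; for near-isotropic heavy
  atoms they agree closely.
* Bond-perception `tolerance` (Å, default **0.40**) over Cordero et al.
  (2008) covalent radii, with H–H bonds forbidden. Hydrogens with zero or
  two heavy neighbours are excluded from ratio analysis with a warning.

## Chemical-environment names

Hydrogens are classified by a name of the form `H1x[...]`: parent element
(lowercase) and, in brackets, the parent's other neighbours, each with a
formal bond-order prefix of 1, sorted reverse-alphabetically with hydrogen
last (`H1o[1h]` water, `H1c[1c1h1h]` methyl, `H1c[1o1c1c]` an sp³ CH next
to a hydroxyl group). Two limitations are deliberate: all bond orders are
emitted as 1 (the fractional orders of the full invariom nomenclature never
occur in hydrogen names for ordinary organic molecules), and the in-bracket
ordering is fixed by the published single-bond examples only — ties beyond
those cases follow the same reverse-alphabetical rule by construction.

## Numerical choices

* **TLS fit**: linear least squares over 20 free parameters (6 T, 6 L, 8 S
  with trace(S) = 0). The trace of S is unobservable from ADPs; forcing it
  to zero is a convention, not physics. The origin is fixed at the centroid
  of the fitted atoms and serialized with the model, since T and S are
  origin dependent. Off-diagonal tensor components are weighted twice in
  the objective (the tensor/Frobenius norm): with single counting the fit
  and its residual would change under a rigid rotation of the frame, which
  would be unphysical. The residual
  $R = [\sum w (U_\mathrm{obs}-U_\mathrm{calc})^2 / \sum w
  U_\mathrm{obs}^2]^{1/2}$ uses the same weights. Rank deficiency (collinear
  or coplanar atom sets) is detected from the QR decomposition and reported
  as an error rather than silently regularized.
* **Coth evaluation**: `1/tanh(x)`; for large $x$ (low $T$) `tanh`
  saturates at 1 exactly, giving the zero-point limit without special
  casing; $T = 0$ returns exactly 1.
* **Basis conversions**: $U_\mathrm{cart} = M N U_\mathrm{cif} N^\top
  M^\top$ with $N = \mathrm{diag}(a^*, b^*, c^*)$ and $M$ the
  orthogonalization matrix in the convention $a \parallel x$, $b$ in the
  $xy$ plane (the convention is stated because different programs differ).
  We always transform through the full metric rather than using the
  orthorhombic shortcut formula, so monoclinic and triclinic cells are
  handled identically.
* **Degenerate inputs**: non-positive-semidefinite tensors are kept and
  flagged (only geometric $U_\mathrm{eq}$ refuses them, naming the atom);
  internal-mode subtraction that produces a negative eigenvalue flags the
  atom but proceeds; imaginary frequencies are skipped with a warning
  listing them; a cutoff above every mode yields exact zero internal
  tensors plus a warning.
* **CIF I/O**: a purpose-built reader/writer for the small-molecule CIF 1.1
  subset (cell, `_atom_site`, `_atom_site_aniso` loops, `U` and `B`
  conventions, parenthesised standard uncertainties, multiple data blocks).
  Standard uncertainties are parsed and stored but not propagated; group
  scatter across chemically equivalent hydrogens serves as the uncertainty
  estimate instead. Files are written with 12 decimal places so write/read
  round trips are exact to ~1e-12 — structures are treated as exchange
  format, not display format.

## What the synthetic generator emulates

`generate_fixture()` forward-generates a toy crystal (7 heavy atoms +
methyl, methine, hydroxyl and water hydrogens in a P1 orthorhombic cell)
whose ADPs at each temperature are exactly

$$U(i, T) = g(T)\, U_\mathrm{TLS}(i) + U_\mathrm{int}(i, T)
\;[+\;\mathcal N(0, \sigma^2)],$$

with $g(T) = g_0 + g_1 T$ ($g_0 = 0.09$, $g_1 = 0.018\,\mathrm{K}^{-1}$): a
constant zero-point lattice contribution plus classical linear growth. A
strictly linear law is used rather than one that is flat below some onset
temperature, because with a frozen lattice the ratio would *rise* slightly
with temperature through the internal $\coth$ factor, spoiling the monotone
shape the fixture is meant to exhibit; the analysis pipeline never predicts
the lattice law anyway — it always fits it. The mode list contains
localized X–H stretches (2950–3440 cm⁻¹), bends (1300–1560 cm⁻¹, 90% of
the squared amplitude on H), hindered rotations for O–H hydrogens
(500–670 cm⁻¹) as found in hydrogen-bonded crystals, two skeletal modes
per heavy atom (~900/1100 cm⁻¹) and one collective 80 cm⁻¹ mode that sits
below the default cutoff. Defaults were chosen to reproduce realistic
magnitudes — parent $U_\mathrm{eq}\approx 0.004$ Å² at 9 K growing to
$\approx 0.06$ Å² at 250 K, hydrogen ratios of ~2.8–4.9 at 9 K falling to
1.2–1.4 at 250 K.

What passing on this fixture does **not** show about real data: the
generator's modes are neither orthogonal nor complete (they are independent
oscillators by construction), its noise is uncorrelated Gaussian on tensor
components rather than refinement noise with its correlation structure, the
lattice motion is exactly TLS-shaped (real crystals have non-rigid
contributions the fit absorbs imperfectly), and there is no methyl
rotational disorder — the known failure mode of multiplier analysis for
`H1c[1c1h1h]` environments at higher temperatures, which is out of scope
here. Exact recovery on the fixture validates the algebra and bookkeeping
of the pipeline, not the physics of any particular crystal.

## Problem sizes used in the test-suite and acceptance runs

TLS round trips use 12-atom random clouds; Monte-Carlo covariance oracles
use 4×10⁵ finite-rotation samples (1% comparison) and 10⁶ Gaussian samples
for tensor second moments; noise-scaling studies use 40–100 replicates per
noise level; the full pipeline runs on all 8 default temperatures. These
sizes make every statistical comparison comfortably tighter than its
asserted tolerance while the whole suite stays fast.

## Known limitations

* Asymmetric unit contents only (P1 view): no symmetry expansion, no
  structure-factor or refinement machinery.
* One rigid body for the whole asymmetric unit, including solvent;
  per-fragment TLS is not implemented. Hydrogens are never part of the
  rigid-body fit.
* Standard uncertainties are carried, not propagated.
* Environment names use unit bond orders; aromatic/amide fractional orders
  are outside the naming scope.
* The quantum-chemistry step itself (geometry optimization, frequency
  calculation) is upstream of this package: modes enter through a
  documented text format, and a converter from vendor outputs is a
  deliberate plug-in point rather than a dependency.
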