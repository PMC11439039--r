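---
title: "Distance-spectral descriptors: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-spectral descriptors: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distspectra)
```

## The model

A hydrogen-suppressed molecular skeleton is an undirected, simple, connected
graph: vertices are heavy atoms, edges are bonds, every bond has unit length.
All structure enters through two combinatorial layers computed once per
molecule:

1. **Geodesic distances.** The matrix `D` of shortest-path lengths, the
   per-vertex transmissions `Tr(w)` (row sums), their mean `t` and the total
   transmission `sigma = sum(Tr)/2` (the Wiener index). Disconnection is a
   hard error at this stage: every distance-based matrix is undefined when
   some distance is infinite.
2. **Szeged edge cuts.** For each bond `e = wz`, `q_w` counts vertices
   strictly closer to `w` than to `z`, `q_z` symmetrically, and
   `q_0 = n - q_w - q_z` counts equidistant vertices. Each endpoint counts
   itself, so `q_w, q_z >= 1`. On bipartite graphs the two endpoint distances
   always differ in parity, so `q_0 = 0` and `q_w + q_z = n` — a property the
   test suite asserts on every generated nanostructure.

Eleven symmetric chemical matrices are built from these layers (see
`?build_matrix`). Edge-supported kinds (`SZEGED`, `PI`, `ABC2`, `GA2`) carry
explicit zeros off the bond support; distance-supported kinds (`DIST`,
`HARARY`, `DEGDIST`, `GUTMAN`) are formula-valued on every off-diagonal pair.
Matrices are dense: the intended problem sizes (up to a few thousand atoms)
are comfortably within dense symmetric eigensolver territory, and sparse
storage would buy nothing once the distance matrix — inherently dense — is in
play.

From each spectrum `delta_1 >= ... >= delta_n` three invariants are reported:
the spectral radius `delta_1`, the graph energy `sum(|delta_i|)`, and the
Estrada index `sum(exp(delta_i))`. The Laplacian-type kinds are special in
both sums: their eigenvalues concentrate around the mean transmission rather
than zero, so the energy centers at `t` (`sum(|delta_i - t|)`; the trace is
`n * t`, so the centered values sum to zero exactly), and the Estrada exponents
are shifted.

## Tunable parameters

- **`estrada_shift`** (`"sigma"`, `"t"`, `"none"`; default `"sigma"`). The
  conventional definitions of the distance-Laplacian Estrada index shift the
  exponents by the total transmission `sigma`, while the matching energies
  center at the mean transmission `t`. The two conventions disagree in the
  literature this package follows; both are implemented. `sigma` is the
  default because it is the printed form of the definitions the package
  implements, even though it drives the index to numerical zero for large
  graphs (`sigma` grows like `n^2 * diameter`, far faster than `delta_1`);
  `"t"` is the variant that keeps the index on a comparable scale to the
  energy. The choice only affects `Es_DLAP` and `Es_DSLAP`.
- **`exponent_cap`** (default 700, units of the eigenvalue itself). `exp()`
  overflows double precision near 709.8. Szeged eigenvalues grow roughly
  quadratically with atom count, so `Es_SZEGED` (and for larger systems
  `Es_DIST`, `Es_SCHULTZ`) overflow well before a thousand atoms. Above the
  cap the index is evaluated as `delta_1 + log(sum(exp(delta_i - delta_1)))`
  and reported as the *logarithm* of the Estrada index, flagged via the
  `log_domain` attribute and the pipeline's JSON sidecar. Comparisons across
  molecules must not mix flagged and unflagged values.
- **`precision`** (default 4 decimals) controls written reports only; full
  double precision is kept internally.
- **Zero thresholds.** Negative-eigenvalue counting and the positive
  semidefiniteness checks use an absolute threshold of 1e-9, appropriate for
  integer matrices of modest norm; eigensolver symmetry validation uses a
  relative 1e-8.

## Generators and what they emulate

The generators produce the sp² carbon frameworks used as descriptor
benchmarks. All are deterministic — identical calls give identical vertex
numberings — and there is no randomness anywhere in the package.

- **`make_nanocone(n)`** builds the one-hexagonal nanocone `CNC6[n]`: a
  central hexagon wrapped by `n` hexagon layers (benzene, coronene,
  circumcoronene, ... for n = 0, 1, 2, ...), with `6(n+1)^2` atoms and
  `9n^2 + 15n + 6` bonds.
- **`make_zigzag_nanotube(m, n)`** has two geometries. The default
  `"lattice"` is the *flat* two-dimensional polyhex lattice of the tube —
  `n` columns of hexagons alternating `m` and `m - 1` per column, nestled so
  the strip stays straight. This is the structure whose descriptor series the
  shipped reference tables validate against: the reference values were
  produced from 2D drawings, and the flat lattice reproduces their
  transmission-based columns to all four printed decimals, which a closed
  cylinder provably does not. `"cylinder"` closes the lattice into the
  physical tube (`2m(n+1)` atoms, `m(3n+2)` bonds); use it when the object of
  study is the periodic nanotube itself rather than the reference series.
- **`make_armchair_nanotube(m, n)`** is the armchair-orientation cylinder:
  `n + 1` rings of `2m` atoms, paired in-ring bonds alternating with ring
  parity, full axial bonding — `2m(n+1)` atoms and `m(3n+1)` bonds. An
  armchair cylinder with this vertex count cannot have `m(3n+2)` bonds (the
  count the zigzag cylinder has): each atom carries exactly one in-ring bond,
  fixing the in-ring total at `m(n+1)`.
- **`benzenoid_catalogue(name)`** returns one of 30 curated lower benzenoid
  skeletons. The catalogue is stored as hexagon-cell coordinates and built by
  the same patch machinery as the nanocones, so every entry goes through one
  tested construction path. Membership follows common usage for "the lower
  benzenoids"; users reproducing a specific published test set should verify
  the membership against their source (the package accepts arbitrary
  edge-list TSVs as a substitute).

Boundary atoms of degree 2 are kept everywhere — descriptor values depend on
them — and no hydrogen capping or pruning is applied.

What a green test on these families does and does not establish: the
generators emulate idealized, defect-free lattices. Real nanotube and
nanocone samples have caps, defects and finite-temperature geometry that the
graph model deliberately ignores; agreement with the reference series
validates the combinatorics and the spectral pipeline, not any physical
property of a synthesized sample.

## The screening regression

The QSPR layer regresses a *descriptor* on the two measured properties
jointly, `descriptor ~ Hc + Ent` with intercept — that is the direction used
by the screening protocol this package implements (the printed model forms
put the descriptor on the left), even though predictive QSPR usually inverts
it; `fit_property_model(..., response = "property")` provides the inverse for
actual prediction. The multiple correlation coefficient is `rho = sqrt(r2)`,
95% confidence half-widths use the t-distribution with `n - 3` degrees of
freedom, and `rank_descriptors()` orders by `rho` descending with
alphabetical tie-breaks. No multiple-testing correction is applied — the
protocol screens dozens of descriptors and reports raw correlations — so the
report states the number screened and readers should treat small differences
in `rho` accordingly. Experimental heat capacities and entropies are an
external input; the package ships none.

`fit_series()` fits descriptor series against a size parameter with linear or
quadratic least squares only. Sinusoidal forms were deliberately excluded:
on monotone series of ten points they are non-identifiable (fitted confidence
intervals orders of magnitude wider than the coefficients) and carry no
structural meaning.

## Numerical and design notes

- Distances come from igraph's unweighted BFS; the test suite checks them
  against an independent boolean matrix-power oracle.
- Eigendecomposition uses R's symmetric `eigen()`; the suite cross-checks all
  33 invariants on every graph with up to 8 vertices against an independently
  implemented cyclic Jacobi eigensolver. (A characteristic-polynomial
  root-finding oracle was tried first and abandoned: roots of multiplicity
  three — which occur already for the distance Laplacian of the 8-cycle —
  cannot be resolved to 1e-6 in double precision from polynomial
  coefficients.)
- Ties among eigenvalues are broken by value only; no eigenvectors are
  computed, so tie order is immaterial.
- `ABC2` on the single edge of K2 has `q_w + q_z - 2 = 0` and the entry is 0
  straight from the formula; no special case exists.
- Vertex indices are 0-based in every file format, report and error message.
- Connectivity is enforced at distance computation, not graph construction,
  so generators can assemble graphs incrementally.
- Determinism extends to the byte level: rerunning the pipeline with
  identical inputs and configuration writes byte-identical CSV output.

## Known limitations

- The shipped reference series for the nanostructure families reproduce
  exactly in their transmission-based columns (Harary and degree-distance
  energies) for the systematic family members, and the test suite documents
  the exceptions it found: one tube row matching a defective 13-hexagon
  drawing variant rather than the systematic lattice, slight deviations in
  the two largest nanocone rows, and — most importantly — the three
  edge-cut-based reference columns (`Es_GA2`, `En_GA2`, `Es_ABC2`), which
  cannot be produced by the printed matrix definitions under *any* symmetric
  edge-cut convention: on the single-layer nanocone (coronene), edges whose
  endpoints are exchanged by a graph automorphism must receive a `GA2` entry
  of exactly 1, and no assignment of the remaining edge-orbit entries within
  the formula's range reproduces the reference energy/Estrada pair. The
  package therefore implements the standard printed convention and leaves the
  corresponding acceptance check failing by design, with the evidence encoded
  in `tests/testthat/test-acceptance.R`.
- Weighted or directed graphs, explicit hydrogens, 3D geometry and chiral
  (non-zigzag, non-armchair) nanotubes are out of scope.
- Estrada indices in the log-domain regime are reported on a different scale
  than unflagged values; downstream statistics must handle the flag.
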