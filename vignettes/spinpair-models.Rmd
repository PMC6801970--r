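---
title: "Modelling exchange and dipolar couplings in nitroxide radical pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exchange and dipolar couplings in nitroxide radical pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinpair)
```

## The system and the models

TEMPO ((2,2,6,6-tetramethylpiperidin-1-yl)oxyl) is a chemically stable
nitroxide radical, the workhorse spin probe of EPR spectroscopy in
biochemistry. When two such radicals approach each other, two magnetic
interactions appear: the Heisenberg *exchange coupling* J, an
orbital-overlap effect that decays roughly exponentially with distance,
and the *magnetic dipole–dipole coupling*, which splits the triplet state
at zero field and decays as \(1/r^3\). Both are routinely inverted to
obtain distances between spin labels, so having transparent, tested
phenomenological models of each is useful well beyond any one study.

This package implements three such model families on an idealized
geometry: a pair of nitroxides with *colinear* N–O bonds, oxygen atoms
facing each other at distance \(r_\mathrm{OO}\), and the two singly
occupied \(\pi^*\) lobes twisted by an angle \(\alpha\) about the common
axis. Two archetypes matter: orthogonal lobes (\(\alpha = 90^\circ\),
"configuration 1", zero \(\pi\)-overlap, ferromagnetic J > 0) and
parallel lobes (\(\alpha = 0^\circ\), "configuration 2", maximal
\(\pi\)–\(\pi\) overlap, antiferromagnetic J < 0).

## Exchange coupling

The broken-symmetry estimate of J from a pair of unrestricted
single-determinant calculations is the Yamaguchi formula,

\[
J = -\frac{E_{HS} - E_{BS}}
          {\langle S^2\rangle_{HS} - \langle S^2\rangle_{BS}},
\]

implemented by `yamaguchi_j()` with hartree→cm\(^{-1}\) conversion fixed
in `spin_constants()`. The package does not compute the energies
themselves (no electronic-structure engine is involved); it provides the
arithmetic, its unit handling, and the degenerate-denominator guard.

The magneto-structural laws are single exponentials
\(J(r) = j^0 e^{-a r}\) (`exponential_law()`, `eval_exponential()`), and
the angular law

\[
J(r, \alpha) = J_F(r) + J_{AF}^0(r)\cos^2\alpha,
\]

which follows from the overlap integral between the two lobes varying as
\(\cos\alpha\) and the antiferromagnetic component being proportional to
the squared overlap (`angular_exchange_model()`, `eval_angular()`). The
packaged reference parameters are \(j_F^0 = 7663.86\) cm\(^{-1}\),
\(a_F = 2.812\) Å\(^{-1}\) for the ferromagnetic branch and
\(j_{AF}^0 = -193496\) cm\(^{-1}\), \(a = 3.080\) Å\(^{-1}\) for the
antiferromagnetic component obtained by subtracting the ferromagnetic
curve from the parallel-lobe data (`exchange_reference_laws()`).

```{r exchange}
laws <- exchange_reference_laws()
eval_angular(laws$angular, r = 4, alpha = c(0, 45, 90))
```

### Fitting

`fit_exponential()` uses nonlinear least squares with a deterministic
log-linear initialization: the line through \(\log|J|\) versus r supplies
the starting values, Levenberg–Marquardt refines them. With exactly two
points the closed-form interpolant is returned. A single exponential
cannot change sign, so sign-mixed data are rejected rather than silently
absorbed. Reported uncertainties are asymptotic standard errors, also
expressible as percentages via `format_estimate()` to match the
"value ± abs (pct%)" reporting style.

One calibration subtlety: when the noise is *relative* (a constant
fraction of each J, as our generator produces), J spans three decades
over r ∈ [3, 5] Å and an unweighted fit has badly miscalibrated standard
errors. Passing `weights = 1/j^2` makes the fit a proper generalized
least squares for that noise model; the test suite checks ±3 SE coverage
over 200 seeded replicates that way. With five points and two parameters
the standard errors carry only 3 degrees of freedom, so nominal 3-SE
coverage is \(P(|t_3| \le 3) \approx 0.942\), not the Gaussian 0.997 —
the suite asserts coverage ≥ 0.90 accordingly.

`margins_to_model()` handles the solvent-bridged cases where only the
two angular margins are known: the \(\alpha = 90^\circ\) value is
identified with \(J_F\) (even when slightly negative, as bridged pairs
can produce) and the curve is interpolated with \(\cos^2\alpha\), with no
new fit implied.

## Zero-field splitting from point dipoles

For the S = 1 state of the radical pair the dipolar spin Hamiltonian is
parameterized by the axial D and rhombic E. If each radical is idealized
as a single point spin, the pairwise coupling magnitude in cm\(^{-1}\)
with r in Å is

\[ |D_{AB}| = \frac{1.299\,g^2}{r^3}, \qquad D = -\tfrac12 |D_{AB}|, \]

with E = 0. The *two-point model* (`point_dipole_D()`) places the spins
at the N–O bond midpoints, so \(r = r_\mathrm{OO} + d_\mathrm{NO}\).
The *four-point model* distributes each radical's spin over the four
barycentres of the two \(\pi\)-lobes: sites at N ± \(l_{\pi N}\) and
O ± \(l_{\pi O}\) along the lobe axis, each carrying half the atomic
spin population (N: 0.45, O: 0.51). The packaged offsets are
\(l_{\pi N} = 0.574\) Å and \(l_{\pi O} = 0.461\) Å.

The pairwise scalar law alone cannot produce E, so the package assembles
the full anisotropic tensor

\[
T = C g^2 \sum_i \sum_j \sigma_{Ai}\sigma_{Bj}
    \frac{1}{r_{ij}^3}\bigl(\mathbf 1 - 3\hat r_{ij}\hat r_{ij}^T\bigr),
\]

with the scalar C pinned by an *anchor contract*: for two unit spins on a
common axis, `extract_DE(dipolar_tensor(...))` must reproduce
\(|D| = \tfrac12\,1.299\,g^2/r^3\) exactly, which fixes C = 1.299/6.
`extract_DE()` diagonalizes the tensor, orders the principal values by
magnitude (\(|t_{zz}| \ge |t_{yy}| \ge |t_{xx}|\)), and returns
\(D = \tfrac32 t_{zz}\), \(E = (t_{xx} - t_{yy})/2\), which guarantees
\(|E/D| \le 1/3\). On exact degeneracy of the minor values E is set to
exactly zero and the axial flag recorded, removing numerical sign
flapping.

```{r zfs}
point_dipole_D(9)                            # two-point model, cm^-1
dimer_zfs(9, alpha = 0, point_dipole_model("four_point"))
```

At \(r_\mathrm{OO}\) = 8 and 9 Å the two-point model gives
3.26×10⁻³ and 2.40×10⁻³ cm\(^{-1}\), in few-percent agreement with
reported ab initio values (3.34–3.47×10⁻³ and 2.40–2.42×10⁻³). Below
about 6 Å the detailed shape of the spin density dominates and the point
models are not expected to match — the ab initio D even changes sign
there, which no point-dipole model can reproduce. The package therefore
reports the model's signed D under its ordering convention and compares
magnitudes only at long range.

Two symmetry facts are built into the tests: E vanishes identically when
the lobes are orthogonal (a mirror symmetry of the four-point site set),
and develops only for parallel lobes at finite offsets; and
\(\log|D|\) versus \(\log r\) approaches slope −3 at long range for every
model variant.

`fit_lobe_offsets()` adjusts \((l_{\pi N}, l_{\pi O})\) by
Levenberg–Marquardt on the stacked D and E residuals against a reference
curve, holding the populations fixed (they are treated as transferable
between systems). On model-generated data it recovers the generating
offsets to 10⁻⁴ Å. One caveat documented by the tests: against a
*two-point* reference the problem is nearly degenerate — the l → 0 limit
of the four-point model places sites at the N and O nuclei, not at the
bond midpoint, so several offset pairs reproduce the reference curve
almost equally well; the fit is then judged by curve agreement, not by
the offset values.

## Complexation energetics and basis-cutoff extrapolation

For host–guest complexes (TEMPO in cucurbit[6]uril and in
β-cyclodextrin) the package implements the bookkeeping layer over
quantum-chemical total energies, which themselves enter only as packaged
fixtures:

* `interaction_energy()`: \(\Delta E = E_{AB} - E_A - E_B\), hartree
  converted at 627.5095 kcal/mol — this reproduces every printed ΔE cell
  of the packaged cutoff tables to the last digit.
* `counterpoise_corrected()`: \(\Delta E_\mathrm{corr} = E_{AB} - E_A^* -
  E_B^*\) with the monomers in the full dimer basis, plus the BSSE
  increment \(\Delta E_\mathrm{corr} - \Delta E\).
* `apply_dispersion_shift()`: additive Grimme-increment bookkeeping with
  provenance recorded (e.g. +64.51 kcal/mol removes the D2 term from the
  CB[6] series, +27.85 from the β-CD series).
* `fit_cutoff_extrapolation()`: plane-wave energies converge with the
  kinetic-energy cutoff as \(E = E_0 + a e^{-b\,e_\mathrm{cut}}\); each
  component series is fitted independently and the extrapolated
  interaction energy is \(E_{AB,\infty} - E_{A,\infty} - E_{B,\infty}\).

The extrapolation fit is initialized deterministically from the geometric
structure of the energy increments (ratio of the last two increments
gives b, the projected geometric tail gives \(E_0\)), which is exact for
noise-free exponential data on an equally spaced grid and converges on
all packaged tables. Component-wise fitting is the default mode because
the packaged infinite-cutoff rows are component-consistent: for the
CB[6] series it reproduces the printed 20.269 kcal/mol within
0.001 kcal/mol, while fitting the ΔE series directly lands near 20.3.
The β-CD series has non-geometric early increments, so its printed
infinite-cutoff row is verified arithmetically (−21.900 kcal/mol) but
not asserted as a fit target.

```{r energetics}
s <- as_convergence_series(spinpair_fixture("table2"))
as.numeric(extrapolated_interaction(s))
```

## Synthetic data and what the tests show

`gen_exchange_dataset()`, `gen_convergence_series()` and
`gen_reference_zfs_curves()` generate inputs with the structure the
models assume: exponential-in-r, \(\cos^2\alpha\)-in-angle exchange
surfaces with optional relative Gaussian noise; exponentially converging
cutoff series with optional absolute Gaussian noise; and D/E reference
curves from either point-spin model. All generators are pure functions
of their parameters and an explicit seed (via an RNG-state-preserving
wrapper), so identical seeds give identical tables.

The noise models are package inventions for exercising the fitting
stages — the reference curves themselves are noise-free model laws. The
generators emulate none of the things that make real data hard: no
BS-DFT convergence noise, no conformational averaging, no solvent
configuration sampling, no short-range spin-density detail. Passing
tests therefore demonstrate the *internal* consistency of the models and
fits (round-trips, oracle equivalence, symmetry properties, coverage
calibration), and agreement with the packaged reference values at long
range; they say nothing about how well the point-dipole picture performs
below ~6 Å, where it is known to fail.

## Numerical choices and problem sizes

* Canonical units: cm\(^{-1}\) for couplings, Å for lengths, degrees at
  the interface (radians internally); conversions fixed once in
  `spin_constants()`.
* g defaults to the free-electron 2.0023, overridable (g ~ 2 is adequate
  for nitroxides); \(d_\mathrm{NO}\) defaults to 1.28 Å, a typical
  nitroxide N–O bond length, chosen once so that the two-point model
  reproduces the long-range reference D values.
* Fits are Levenberg–Marquardt with closed-form deterministic starts; no
  random restarts, no global search. Non-convergence raises an error
  naming the offending curve.
* Tie-break: exact minor-eigenvalue degeneracy maps to E = 0 exactly.
* Test problem sizes: ≤ 10-site random tensors against a brute-force
  double-loop oracle; 200 seeded replicates for coverage checks; distance
  grids of 5–13 points. The full suite runs in a few seconds on one CPU.

## Known limitations

* No electronic structure anywhere: J from energies, spin densities,
  hyperfine couplings and absolute complexation energies are out of
  scope; printed values enter as fixtures only.
* The point-dipole D is sign-rigid; short-range sign changes seen in
  ab initio data are outside the model family.
* The \(k_{ab}\) proportionality between \(J_{AF}\) and the squared
  overlap is deliberately not represented — it has no published numeric
  value; the maximal-overlap product is absorbed into \(j_{AF}^0\).
* Solvent placements are labels with a steric constraint
  (\(r_\mathrm{OO} \ge 5\) Å), not atomistic geometries.
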