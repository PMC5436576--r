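---
title: "Helical parameters and twist handedness of regular peptide backbones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical parameters and twist handedness of regular peptide backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptwist)
```

## The model

A *regular* backbone repeats the same internal coordinates — three bond
lengths ($v_{n\alpha}, v_{\alpha c}, v_{cn}$), three bond angles
($\sigma_n, \sigma_\alpha, \sigma_c$) and three dihedral angles
($\phi, \psi, \omega$) — in every residue. Such a chain necessarily traces a
helix: each residue is carried onto the next by one fixed rigid motion, and
any rigid motion is a screw, i.e. a rotation by some angle $\theta$ about an
axis combined with a translation $d$ along it. All backbone atoms of one type
(N, C$\alpha$ or carbonyl C) therefore lie on a common cylinder of radius
$\rho_i$ around that axis.

`peptwist` computes $(d, \theta)$ two independent ways:

* **Analytically.** The closed forms express $\cos(\theta/2)$ and
  $d\sin(\theta/2)$ as four-term sums of half-angle cosines/sines of
  $(\pm\phi \pm \psi \pm \omega)/2$ weighted by half-angle products of the
  bond angles (and, for $d$, signed sums of the bond lengths). $\theta$ is
  recovered as $2\arccos(\cdot) \in [0^\circ, 360^\circ)$ and $d$ by
  division by $\sin(\theta/2)$, so $d$ carries the sign.
  `helical_params_exact()` implements these term by term.
* **Geometrically.** `build_regular()` places the chain in 3-D by
  internal-coordinate extension and `screw_decomposition()` recovers the
  rotation angle, axial translation and per-type axis distances from the
  residue-to-residue superposition (Kabsch on the three-atom frames). This
  is the package's internal oracle: it shares no code or algebra with the
  closed forms, and the two routes agree to $10^{-6}$ across random states
  (the test suite checks 200 of them).

The radius identity $2\rho_i^2(1 - \cos\theta) + d^2 = d_i^2$, where $d_i$
is the distance between adjacent atoms of type $i$ (`same_type_distance()`),
gives the per-type radii; $d_\alpha$ is the familiar 3.8 Å C$\alpha$–C$\alpha$
distance for trans backbones (2.8 Å for cis).

## Handedness

The twist handedness metric is

$$h = \frac{d}{|d|}\,\sin\theta \in [-1, 1],$$

negative for left-handed twists, positive for right-handed, with $|h|$
measuring the extent of twist. The sign of $d$ supplies the frame of
reference in which $\theta$ is read: the two equivalent screw
representations $(d, \theta)$ and $(-d, 360^\circ - \theta)$ give the same
$h$. Two flat families are special:

* $d = 0$: perfectly flat, maximally curved (ring-like) backbones. Here
  $|d|^{-1}$ is undefined and the package reports `NA` with region
  `flat_circular` — deliberately *not* 0, because a flat ring has no
  handedness rather than zero-strength handedness.
* $\theta = 180^\circ$: flat, optimally extended zig-zags; $h = 0$, region
  `flat_extended`.

Away from these boundaries the $(d, \theta)$ plane splits into four
quadrants: $d > 0,\ \theta < 180^\circ$ and $d < 0,\ \theta > 180^\circ$ are
right-handed, the other two left-handed.

```{r}
helical_params(dihedral_state(-57, -47, 180))   # ideal alpha helix
helical_params(dihedral_state(-100, -100, 180)) # left-handed, negative rise
```

The second call answers a question that is hard to eyeball from a
Ramachandran position alone: $\phi = \psi = -100^\circ$ is *left*-handed
($h \approx -0.95$) although it sits on the "right-handed" side of the
naive diagonal picture.

## Simplified trans/cis forms and coefficient re-derivation

With equilibrium geometry ($v_{n\alpha} = 1.459$, $v_{\alpha c} = 1.525$,
$v_{cn} = 1.336$ Å; $\sigma_n = 121.7^\circ$, $\sigma_\alpha = 111.0^\circ$,
$\sigma_c = 117.2^\circ$) and a fixed $\omega$, the four-term forms collapse
to two terms in $s = (\phi+\psi)/2$ and $t = (\phi-\psi)/2$. At
$\omega = 180^\circ$ the half-angle factor $\cos(\omega/2)$ vanishes, which
kills the cosine pair of the $\cos(\theta/2)$ expression and the sine pair
of the $d\sin(\theta/2)$ expression; at $\omega = 0^\circ$ the roles swap.
`helical_params_simplified()` evaluates the published coefficients
verbatim; `derive_simplified_coefficients()` re-derives them from any
geometry by evaluating the exact forms at basis points and solving the
2-term systems — no symbolic algebra, and exact because the forms are
linear in the basis functions:

```{r}
round(derive_simplified_coefficients(180), 4)
round(derive_simplified_coefficients(0), 4)
```

Basis points: the sine pair reads off directly at $(s,t) = (90^\circ, 0)$
and $(0, 90^\circ)$; the cosine pair is obtained from $(0, 0)$ and
$(180^\circ, 0)$, which give the sum and difference of the two
coefficients. (A 2×2 system at $(0,0)$ and $(90^\circ, 90^\circ)$ would be
singular — both cosine basis functions vanish at the latter point.) For any
$\omega$ other than $0/180^\circ$ (mod 360) all four basis terms survive,
so no two-term reduction exists and the function refuses rather than
returning a lossy fit.

The simplified and exact routes agree to within the coefficient rounding:
the maximum deviation over the full 2° grid is below $2\times10^{-3}$ on
both $\cos(\theta/2)$ and $d\sin(\theta/2)$.

## The $\omega$ wrapping convention

Every summand of the exact forms contains half-angles, so $\omega$ and
$\omega + 360^\circ$ give sign-opposite results: a single representative
must be fixed. `wrap_omega()` maps $\omega$ into $[\Delta, \Delta + 360)$
with $\Delta = -90^\circ$ by default, which keeps both the cis
($0 \pm 5^\circ$) and trans ($180 \pm 5^\circ$) populations contiguous and
pins cis to 0 (never 360) and trans to 180 (never $-180$). $\Delta$ is
configurable.

## Validation by coordinate-based chirality indices

Because $h$ is analytic, the package cross-validates it against indices
computed purely from built 3-D coordinates:

* `chi1()` — mean normalised scalar triple product of consecutive
  C$\alpha$ step vectors (range $[-1, 1]$);
* `chi2()` — mean signed C$\alpha$-trace torsion (radians);
* `chi3()` — a G0S-type quadruple-sum shape pseudoscalar.

All three negate exactly under reflection and vanish on achiral traces.
Over the full 2° trans and cis grids, every cell with $|h| > 0.05$ has
$\mathrm{sign}(\chi_1) = \mathrm{sign}(\chi_2) = \mathrm{sign}(h)$ on a
12-residue built chain (the test suite verifies all ~64,000 cells).
$\chi_3$ is different: with forward displacement vectors
$v_{ij} = P_j - P_i$ and distinct-index quadruples, direct summation gives
a *negative* value ($-0.013$) for the right-handed $\alpha$-helix trace and
a positive one for the left-handed $(-100, -100)$ helix. G0S-type indices
are not monotone in twist handedness — their sign depends on the pitch
regime — so `chi3()` is provided for completeness and parity checks, and
$\chi_1/\chi_2$ are the sign validators.

## Surveys, boundaries and region counting

`rama_grid()` evaluates the full map over an inclusive-endpoint grid
($\{-180, -178, \dots, 178, 180\}$ at the default 2° step — 181×181 cells
with a duplicated seam, matching the conventional printed grid).
Choices worth knowing:

* **Boundary extraction** (`boundary_curves()`) traces zero contours of the
  smooth fields $\cos(\theta/2)$ (zero set: $\theta = 180^\circ$) and
  $d\sin(\theta/2)$ (zero set: $d = 0$) via marching squares with linear
  interpolation on grid edges — never of $\theta$ or $d$ themselves, which
  would branch at the $\theta$ wrap.
* **Region counting** (`count_sign_regions()`) labels 4-connected
  components of $\mathrm{sign}(h)$ on the square as plotted (no periodic
  wrap), excluding undefined cells, cells with $|h| \le 10^{-12}$, and the
  duplicated seam row/column. Every $\omega$ in $\{0, 45, \dots, 315\}$
  yields at least four regions, so the naive single-diagonal picture of
  handedness fails for every amide geometry, not just trans.
* **The naive diagonal rule** (right-handed iff $\phi + \psi < 0$) agrees
  with $\mathrm{sign}(h)$ on *less* than 100% of the map overall, but on
  exactly 100% of cells that are both on the $d > 0$ side (where the
  protein-dominated regions live) and at least 20° from both boundary
  curves — a quantitative form of "the naive picture works only where
  structured proteins sample".
* **Frame conversion** (`frame_convert()`) is pure relabelling by
  $\pm 360^\circ$; no value is recomputed, so the multiset of $(d, \theta,
  h)$ is preserved. Because the inclusive seam does not biject between
  frames, the source seam is collapsed and the target seam re-duplicated;
  at seam cells the stored $(d, \theta)$ may be the equivalent screw
  representation, with identical $h$.
* **The cis special point.** For cis backbones the two boundary families
  meet near $\phi = -\psi \approx \pm 35^\circ$: root-finding the exact
  $\cos(\theta/2)$ field along $\psi = -\phi$ gives $34.76^\circ$, where
  $|d\sin(\theta/2)| \approx 0.0016$ Å. (The coarser figure of
  $\pm 36^\circ$ sometimes quoted appears to be grid-resolution rounding;
  the package's checks use the window $[33^\circ, 37^\circ]$.) A backbone
  there is simultaneously flat-curved and flat-extended — realisable only
  as a two-residue cis ring, and provably impossible for trans backbones,
  whose two boundary curves stay more than 20° apart everywhere.

`thetad_envelope()` produces the universal Cartesian $(\theta, d)$ cloud
for a band of $\omega$ values (default half-width 5°, 1° sweep step). It is
"universal" because every backbone — cis, trans or strained — has a place
in it, unlike a single Ramachandran plot, which must fix $\omega$.

## Builder conventions and numerical choices

* First residue in a canonical frame (N at origin, C$\alpha$ on $+x$, C in
  the $xy$-plane); all reported quantities are frame-invariant, the choice
  only makes coordinates reproducible. $\phi$ of residue 1 has no preceding
  carbonyl and is unused.
* $\omega_i$ belongs to the peptide bond *following* residue $i$.
* Carbonyl oxygens are optional on `write_pdb()` (1.229 Å, 120.5° from
  C$\alpha$–C, trans to the next N), cosmetic only, and dropped on reading.
* $\arccos$ inputs are clamped to $[-1, 1]$ only when within $10^{-12}$ of
  the boundary; larger excursions raise an error instead of being masked.
* $\theta = 0$ (mod 360) makes $d$ undefined and is signalled as degenerate
  geometry; for physical backbone geometry the trans grid never exceeds
  $\cos(\theta/2) \approx 0.846$, so the degenerate region is unreachable.
* Undefined/flat tolerances: $\varepsilon_d = 10^{-9}$ Å on $|d|$ and
  $10^{-9}$ on $|\sin\theta|$. Exact-zero tests would be numerically
  meaningless; these keep the classification deterministic.
* The screw oracle requires a regular chain (residue-to-residue transform
  constant to $10^{-6}$) and refuses axes with $|\sin\alpha| < 10^{-3}$,
  where the axis direction is ill-conditioned.

## Problem sizes used by the checks

The test suite evaluates the full 181×181 2° grids for the trans/cis
agreement, boundary and concordance properties (building ~64,000 12-residue
chains for the $\chi_1/\chi_2$ cross-validation), 15° grids across six
$\omega$ values for mirror antisymmetry, 200 random states for the
builder–oracle–analytic triangle, and eight $\omega$ values at 2° for
region counting. These sizes were chosen to match the survey resolution the
maps are defined on while keeping a full run in a few minutes.

## What the generated data do and do not show

All fixtures are built by the package's own builder from ideal equilibrium
geometry. Passing checks therefore demonstrate internal consistency of the
closed forms, the builder and the screw oracle, and correctness of the maps
for *platonic* regular backbones. They do not probe real proteins:
conformation-dependent bond-angle/length variation, non-ideal $\omega$,
side-chain sterics and chain irregularity are outside the model, and for
strained backbones only the exact equations (not the simplified
coefficients) remain faithful. Finite built chains also carry end effects:
$\chi_1/\chi_2$ on a 12-mer are attenuated relative to an infinite helix,
which is why the sign — not the magnitude — is the validated quantity.

## Known limitations

* Glycine-placeholder backbones only; no side chains, hydrogens or
  energetics.
* `chi3()` costs $O(N^4)$ and refuses $N > 30$ by default.
* Secondary-structure assignment and database occupancy statistics are out
  of scope; region labels here describe twist handedness, not
  protein-likeness.
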