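---
title: "From wall shear stress to endothelial permeability: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wall shear stress to endothelial permeability: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoperm)
```

## Scope

`endoperm` post-processes time-resolved wall shear stress (WSS) and pressure
fields on a triangulated vessel surface into maps of endothelial hydraulic
conductivity and macromolecule flux, and scores thresholded permeability maps
against reference masks (for example calcification footprints). It does
**not** solve a flow problem: the WSS and pressure histories are inputs,
produced by a CFD/FSI solver or by the package's own synthetic generator.

## Model chain

### 1. Compound shear indices

For a traction history $\boldsymbol\tau(t)$ over one cycle of period $T$:

* **TAWSS** $= \frac1T \oint \lVert\boldsymbol\tau\rVert\,dt$ — mean shear
  magnitude.
* **OSI** $= \tfrac12\left(1 - \lVert\oint\boldsymbol\tau\,dt\rVert /
  \oint\lVert\boldsymbol\tau\rVert\,dt\right)$ — directional oscillation,
  in $[0, \tfrac12]$.
* **HOLMES** $= \mathrm{TAWSS}\cdot(\tfrac12 - \mathrm{OSI})$ — a compound
  index that is small where shear is either weak or strongly reversing, the
  two atheroprone regimes.
* **RRT** $= \left[(1 - 2\,\mathrm{OSI})\cdot\mathrm{TAWSS}\right]^{-1}$ —
  relative residence time; undefined where the denominator vanishes.

All cycle integrals use periodic trapezoidal quadrature: samples are given at
$0 = t_1 < \dots < t_{n} < T$ and the wrap-around segment from $t_n$ back to
$t_1 + T$ is included, so a pure sinusoid sampled uniformly integrates to
machine-precision zero. At vertices with identically zero shear the OSI is
defined as 0 and flagged; where the RRT denominator vanishes (OSI $= 1/2$ or
TAWSS $= 0$) the RRT value is the sentinel `NaN` with a logical flag, and
flagged vertices are excluded (and tallied) by the thresholding step rather
than silently dropped.

### 2. Wall rheology

Blood viscosity follows the Carreau–Yasuda law
$\mu(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
\left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}$
with defaults $\eta_\infty = 2.2$, $\eta_0 = 22$ mPa·s, $\lambda = 0.11$ s,
$a = 0.644$, $n = 0.392$. The wall shear *rate* is recovered from the wall
shear *stress* by inverting $\tau = \mu(\dot\gamma)\,\dot\gamma$, which is
strictly increasing in $\dot\gamma$; the package inverts it with a vectorized
bisection on $[0, \tau/\eta_\infty]$ (64 halvings, residual-checked), which is
robust for every admissible parameter set, needs no derivative, and is exact
to ~$10^{-19}$ relative. A `plasma` mode with constant $\mu = 1$ mPa·s is
provided as the comparison variant; at low wall shear the Carreau–Yasuda
viscosity is an order of magnitude above plasma, which is exactly the regime
where leaky-junction conductivity matters.

### 3. Endothelial permeability cascade

The shear stimulus index (SSI; HOLMES by default, TAWSS as the magnitude-only
variant) drives an empirical cell-morphology cascade:

$$\mathrm{ECSI} = 0.380\,e^{-0.79\,\mathrm{SSI}} +
  0.225\,e^{-0.043\,\mathrm{SSI}},\qquad
  \mathrm{MC} = 0.003739\,e^{14.75\,\mathrm{ECSI}},\qquad
  \mathrm{LC} = 0.307 + 0.805\,\mathrm{MC}$$

ECSI is the endothelial cell shape index (elongated cells under high shear
score low), MC the mitotic fraction, LC the leaky-cell fraction. The
leaky-junction area fraction is $\phi = \mathrm{LC}\,\pi R_{cell}^2 /
A_{ref}$ ($R_{cell} = 15\,\mu$m, $A_{ref} = 1\,$mm²), clipped to $[0,1]$ with
a warning. A single leaky junction is a slit of half-width $w = 20$ nm and
depth $l_{lj} = 2\,\mu$m with Poiseuille slit conductivity
$L_{p,slj} = w^2/(3\mu\,l_{lj})$, so the tissue-level leaky-junction
conductivity is $L_{p,lj} = \phi\,L_{p,slj}$.

Volume flux follows Kedem–Katchalsky,
$J_{v,lj} = L_{p,lj}(\Delta p_{end} - \sigma_d\,\Delta\Pi)$, with the
transmural pressure either `local_time_avg` (per-vertex time mean minus the
external pressure, default) or `uniform` (area-weighted space–time mean).
Solute flux uses the Patlak equation with modified Péclet number
$Pe = J_{v,lj}(1-\sigma_f)/P_{lj}$; below $|Pe| < 10^{-6}$ the code switches
to the series expansion of $Pe/(1-e^{-Pe})$ to avoid catastrophic
cancellation, and the switch is continuity-tested. A fixed 10% vesicular
pathway is added to the junctional solute flux.

### 4. Atheroprone masks and overlap scores

Vertices with $L_{p,lj}$ strictly above the threshold
$1.2\times10^{-11}$ m²·s/kg form the predicted atheroprone mask. Against a
reference mask, `region_statistics()` reports per-region and whole-surface
area percentages plus two match scores, all area-weighted with one-third
triangle-rule vertex areas:

* `pct_match` — intersection over *reference* area (sensitivity-like;
  saturates at 100 for any over-predicting variant);
* `pct_match_iou` — intersection over *union*, which penalizes
  over-prediction and is therefore the ranking key in `compare_variants()`.

Axial regions use half-open intervals $[z_k, z_{k+1})$ with the final
breakpoint closed, so boundary vertex rings are assigned deterministically.

## Synthetic generator

`make_cylinder_fields()` builds an open cylinder (default radius 10 mm,
length 90 mm, 24 × 30 vertices) with three engineered axial zones and
64 samples over a 1 s cycle:

| zone | regime | waveform (Pa) | character |
|------|--------|----------------|-----------|
| 1 | healthy | $4 + 1\sin$ | high, unidirectional |
| 2 | low-oscillatory | $0.05 + 0.3\sin$ (+ harmonics) | weak, reversing |
| 3 | reversing | $4\sin$ | moderate magnitude, OSI $= 1/2$ |

Each zone's indices have closed forms (the cycle mean of
$\lvert A + B\sin\rvert$ is analytic), so the generator doubles as an oracle:
`closed_form_indices()` and `ground_truth_mask()` return the analytic index
values and the exactly atheroprone zones. Optional multiplicative noise and
seeded label flips let property tests probe robustness. The generator's
defaults are the package's study conditions and are not tuned to any test.

What passing tests show: the discrete pipeline reproduces analytic indices to
$\sim10^{-5}$ relative at 512 samples/cycle, the cascade recovers the normal
baseline conductivity at healthy shear within its empirical uncertainty, and
on the engineered geometry the HOLMES + Carreau–Yasuda variant localizes the
ground truth exactly while magnitude-only or plasma variants do not. What
they do **not** show: validity on patient geometries, of the empirical
cascade coefficients outside their fitted range, or of any flow solution —
none is computed here.

## Numerical choices

* Periodic trapezoid for cycle integrals — spectrally accurate for smooth
  periodic integrands; for integrands with kinks ($\lvert\sin\rvert$) the
  error is $O(h^2)$ with a known $h^2/3$ coefficient at the kinks.
* Bisection (not Newton) for the WSS → shear-rate inversion — unconditional
  convergence; 64 halvings reach double-precision limits.
* Patlak small-$Pe$ series below $10^{-6}$.
* `NaN`-plus-flag sentinel for undefined RRT; flags propagate to masks as
  exclusions with an `n_excluded` tally.
* 32-bit FNV-1a hash of the canonical deparsed configuration embedded in
  every output file's provenance line.
* Default problem sizes (24 × 30 mesh, 64 samples) are the package's own
  choice: large enough that discretization error is far below every decision
  threshold, small enough for second-scale test runs.

## Limitations

The cascade is empirical and steady-state: coefficients come from cultured
endothelium and the junction geometry is idealized (straight slit, fixed
cell radius). Transmural pressure uses the endothelium-referenced mean only;
no poroelastic wall model is included. The oncotic term defaults to zero
($\sigma_d\,\Delta\Pi = 0$) and normal-junction conductivity to zero, both
overridable. The generator produces cylinders, not patient geometry, and the
reference masks it provides are index-derived ground truth, not imaging data.
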