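---
title: "Depth-resolved elasticity mapping: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved elasticity mapping: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afm3d)
```

## The model and its assumptions

`afm3d` analyses AFM force–indentation curves under the *average-modulus*
reading of Hertzian contact mechanics. The sample under the tip is modelled
as a stack of thin homogeneous layers; pressing to depth `h` probes the
depth-averaged Young's modulus

$$\bar E(h) = \frac{1}{h}\int_0^h E(y)\,dy,$$

and this average — not the half-space modulus — is what a truncated-window
fit of a classical force law returns. The assumptions inherited from that
framework are: purely elastic response (no viscoelastic creep or
hysteresis, so only approach curves should be supplied), no adhesion,
a rigid axisymmetric indenter, lateral homogeneity within one pixel, and a
sample thick enough that the rigid support does not contribute (the
bottom/substrate effect is *not* corrected — it is handled by masking, see
below). Incompressibility (`v = 0.5`) is the default Poisson's ratio, the
standard convention for hydrated gels and cells; it is recorded in every
output sidecar so the choice is auditable.

For spheres the package distinguishes the paraboloidal small-depth law from
the exact Sneddon solution, in which the contact radius is defined
implicitly by $\ln\frac{R+r_c}{R-r_c} = \frac{2h}{r_c}$. The left side
increases and the right side decreases in $r_c$, so the root is unique; it
is found by bracketed root-finding on $(\varepsilon, R(1-\varepsilon))$
with $\varepsilon = 10^{-15}R$, polished by a few Newton steps, and the
residual is verified below $10^{-9}$ before the value is accepted. At
$h/R = 10^{-3}$ the two force laws agree within 1%; at $h/R = 0.5$ they
differ by far more, which is why colloidal-probe work at large relative
depth needs the exact form. A series-corrected spherical law
(paraboloid times a correction factor $Z \le 1$) is exposed for callers who
have coefficient values, but is off by default because no coefficient set
ships with the package.

## The two estimators and what a map value means

Because each Hertzian law factors as $F = \bar E\, g(h)$ with a single
linear parameter, the windowed least-squares estimate over $[0, h_j]$ is the
closed form $\hat{\bar E} = \sum F_i g_i / \sum g_i^2$. This is the default
(`windowed_ls`) and is exactly the minimizer a brute-force 1-D search finds
(tested). For sphere geometry the exact Sneddon bracket is also linear in
the modulus, so the same projection applies; no iterative fit is needed.

A map value produced by `windowed_ls` therefore means: *the best constant
modulus explaining the whole curve from contact down to this depth*. On
depth-varying samples this is a $g^2$-weighted average of the pointwise
$\bar E(h)$ over the window — it lies between the window's pointwise
extremes (tested as an invariant) but is not equal to $\bar E(h_j)$ itself.
The alternative estimator (`pointwise`, $\bar E(h) = F(h)/g(h)$ with linear
force interpolation) tracks the profile exactly at sampled depths but uses
a single force sample, so it is noisier. The window form $[0, h_j]$ (rather
than incremental segments $[h_{j-1}, h_j]$) was chosen because the
truncated-fit description of the method is cumulative; the ambiguity is
real and both estimators are first-class and selectable everywhere,
including the CLI.

Negative fitted moduli (possible near contact under noise) are clipped to
zero with a warning, never silently.

## The power-law profile fit

Cell-like depth profiles follow $\bar E(h) = a h^b + c$ with $a, c > 0$,
$b < 0$. The fit is deliberately deterministic: an outer log-spaced grid
over $b \in [-3, -10^{-3}]$ (bounds covering published cell exponents while
keeping the profile integrable at 0), golden-section refinement of the best
bracket, and for each candidate $b$ an inner non-negative linear solve for
$(a, c)$ — a two-parameter active-set step, so no random starts and no
convergence tuning. Fitting is performed with depths in nm and moduli in
kPa, the field's reporting convention, so `a` is returned in kPa·nm^(−b).
A flat profile makes $a$ and $b$ unidentifiable; it is detected and
returned as a degenerate fit with `c` equal to the mean, flagged rather
than guessed.

At 1% multiplicative noise the three parameters are strongly collinear
(`a` and `c` trade off against `b`), so the package's stated recovery
tolerance is: fitted *profile* within 2% RMS, individual parameters within
25% (24 depths, fixed seed). The identifiable quantity is the profile;
asserting tight parameter recovery under noise would be pretending the
problem is better conditioned than it is. On noiseless profiles, recovery
is to $10^{-6}$ relative or better.

## From grid to 3D characterization

`build_depth_maps()` applies the estimator pixel-by-pixel over a shared
depth grid (default: M = 8 depths, equally spaced between 10% of the
common maximum depth and that maximum, so every slice is computable at
every pixel; M = 8 and M = 4 are the typical choices for cell work). The
computation is pixel-independent by construction — results are addressed
by pixel coordinate, never by evaluation order. A requested depth reachable
by fewer than half the pixels is a configuration error listing the
per-pixel depth range, not a silent hole.

Substrate-affected regions — pixels whose apparent stiffness is inflated by
the rigid support under thin sample margins — are removed by
`mask_by_threshold()`. The cut is an explicit user choice (`min`, `max`, or
top-quantile rule); there is deliberately no default threshold, because the
delimitation of the affected region is a judgment call that must be
declared for the analysis to be reproducible. Masked pixels are excluded
from every downstream distribution and counted in the export sidecar;
masking only ever grows the mask.

Per depth, the unmasked values are summarized by a Gaussian. The default
route is moment matching (mean and n−1 standard deviation): exact,
deterministic, and free of binning choices. A histogram least-squares route
(Freedman–Diaconis bins, density-normalized, started from the moments) is
provided for comparability with curve-fitted histograms, falling back to
moments with a warning when fewer than five bins are populated. Published
per-depth values rarely state which of the two was used; providing both
makes the comparison explicit. Each summary maps to the dimensionless
vector $(x, y, z) = (\mu\,[\mathrm{kPa}], \sigma\,[\mathrm{kPa}],
h\,[\mathrm{nm}])$, and the collection over depths is also expressible as
an indicator-weighted mixture (exactly one component active per depth),
which is convenient for plotting the per-depth densities together.

Trend classification compares consecutive $(x, y)$ components with a
relative tolerance of 5%: monotone decrease of $x$ beyond tolerance is
*softening*, increase *stiffening*, everything within tolerance
*depth-independent* (a 154 → 153 kPa agarose-like sequence, Δ < 1%,
classifies depth-independent at this default); the $\sigma$ axis maps to
*homogenizing* / *heterogenizing* / *stable-sigma*, and mixed up-down
sequences are reported as the neutral label with an explicit mixed-trend
note rather than forced into a direction.

## Contact-point detection

Deposited force–indentation data are assumed pre-aligned (h = 0 at
contact), and that is the package default. For raw piezo/deflection data a
ratio-of-variances scan is provided: the signal variance in a window after
each candidate split divided by the variance in the window before it, with
the argmax taken as the contact point. An initially considered variant that
linearly detrends each window was rejected after testing: detrending makes
a window containing the contact kink score *higher* than a window of
smooth post-contact curve, biasing the detected index early by about half a
window on noiseless constructions; the plain variance ratio locates the
construction's true index exactly and is invariant to constant signal
offsets. A best score below 10 (pure-noise ratios hover near 1; genuine
contacts score orders of magnitude higher) sets a low-confidence flag and
returns offset 0 instead of a guess.

## The synthetic generator: what it emulates, what it does not

`simulate_force_volume()` inverts the analysis model: each pixel's force is
$F(h_j) = g(h_j)\,\bar E(h_j)$ for a prescribed modulus structure —
discrete slices, a continuous $E(y)$ averaged by adaptive quadrature
(relative tolerance $10^{-10}$), a constant, or the $a h^b + c$ profile —
with Gaussian force noise applied afterwards as
$F \leftarrow F(1 + \varepsilon_m) + \varepsilon_a$, the additive level
quoted relative to the maximum force. Noise enters force only: depth noise
would make the inversion ill-defined, and force noise dominates in practice
at these spring constants. Default acquisition parameters mirror typical
cell experiments: 64 × 64 pixels over 5 × 5 µm (78.125 nm pitch), depths to
800 nm, ~100–200 samples per curve; field means and spreads used in tests
(e.g. 8.46 ± 2.78 kPa at 300 nm) are taken from published fibroblast-scale
values. Seeding is reproducible under partial regeneration: one master
seed spawns per-pixel substreams through a fixed counter hash, so pixel
(r, c) gets the same noise regardless of which other pixels are generated.

What the generator does *not* emulate — and therefore what a green
recovery test does not establish robustness against — includes: substrate
(bottom) stiffening, adhesion and jump-to-contact, viscoelastic rate
dependence, thermal drift, tilt, and contact-point misalignment (synthetic
curves are perfectly aligned). Spherical-tip synthetic curves with
depth-varying moduli use the paraboloidal law, which is the averaging
theory's stated domain; the exact Sneddon law is available for
constant-modulus validation only.

## Numerical and interface choices

All computation is in strict SI (m, N, Pa); the interface layer converts to
nm/nN/kPa. This removes the $10^9$-scale unit bugs endemic to AFM analysis,
and the round-trip is tested to $10^{-12}$. Curve files are UTF-8 text with
`#` key–value headers and a mandatory `units:` line; readers repair
non-monotone depth ordering by stable sort and average duplicate depths
(dwell points carry force information and are not dropped), reporting the
repair count. Pixels are 0-based (row, col), row-major, top-left origin.
Masked cells export as the literal string `NA`. File readers require 8
samples by default (a curve shorter than that cannot support a 5-point
window fit plus slack), while programmatic constructors accept 2; the
minimum is a parameter, not a hard constant. Configuration files for the
CLI are JSON; every output directory carries a `run_config.json` with the
resolved configuration and seed, and reruns are byte-identical.

## Known limitations

No bottom-effect correction (masking is exclusion, not correction); no
adhesive or viscoelastic models; no multi-peak (e.g. two-population tissue)
decomposition of the per-depth distributions — the Gaussian summary is
unimodal by design; no proprietary binary instrument formats (convert to
the text dialect instead). The published fibroblast force-volume dataset
used for the end-to-end reproduction criterion is openly deposited but
cannot be bundled with the package; the corresponding acceptance test
documents how to supply it and reports its absence honestly instead of
skipping.
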