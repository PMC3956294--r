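---
title: "Models and methods behind nodescale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nodescale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodescale)
```

# The scientific problem

Fission yeast divides at a reproducible size, and the mid-cell node
protein cdr2p acts as the reporter that couples size to the division
decision: the density of cdr2p in cortical nodes rises with the cell's
surface area, not its volume or length. `nodescale` implements the
quantitative machinery around this claim — mechanistic accumulation
models, fluorescence-profile quantification, and division-size
statistics — and pairs every measurement procedure with a seeded
synthetic generator so the whole pipeline can be closed and tested
without microscopy data.

# Cell geometry

Cells are spherocylinders: a cylinder of radius $R$ with hemispherical
caps, total length $L$. Total membrane area is then exactly
$A_{cor} = 2\pi R L$ and volume
$V = \pi R^2 (L - 2R) + \tfrac{4}{3}\pi R^3$; the medial nodal band of
axial width $w_{nod}$ occupies membrane area $A_{nod} = 2\pi R\,
w_{nod}$. Wild-type-like defaults are $R = 1.5$ µm and $L$ growing
from 7 to 14 µm over the cell cycle.

Measured cells enter as traced half-profiles (axial position $x$,
local radius $r$, zero at both tips), assumed radially symmetric.
`measure_contour()` integrates the surface and solid of revolution
with midpoint (trapezoid-type) quadrature per segment — second-order
accurate, so at a 0.01 µm sampling step an ideal spherocylinder is
recovered well within 0.5%. Contours are assumed pre-clipped to
exclude the septum, and no 2D segmentation is attempted: profiles and
traced outlines are the package's ingestion boundary.

# Steady-state accumulation models

Cdr2p exists in cytoplasmic, cortical and nodal forms. Because
binding/unbinding (seconds to minutes) is much faster than growth
(hours), each cell size is treated as a quasi-steady state.

**Model I (uniform cortex).** Cytoplasmic protein at concentration
$\rho_{cyt}$ associates anywhere on the membrane with parameter
$\beta$; cortical protein dissociates at $\nu$ or is taken up into the
nodal region at $\alpha$; nodal protein dissociates at $\eta$. The two
balance equations solve exactly to

$$\rho_{nod} = \rho_{cyt}\,\frac{\beta}{\eta}
  \left(\frac{\nu}{\alpha} + \frac{A_{nod}}{A_{cor}}\right)^{-1},
  \qquad \rho_{cor} = \rho_{nod}\,\frac{\eta}{\alpha}.$$

Size sensing requires $\nu/\alpha \ll 1$ (cortical protein is far more
likely to reach the nodes than fall off) and an $A_{nod}$ that does not
grow proportionally with $A_{cor}$. Defaults: $\eta = 5\times10^{-3}$
s$^{-1}$ (a ~3 min nodal FRAP turnover), $\alpha = 1.0$ s$^{-1}$
(bounded below by the observed nodal/cortical density contrast
$\rho_{nod}/\rho_{cor} = \alpha/\eta$), $\nu = 5\times10^{-3}$
s$^{-1}$. $\beta$ enters all densities only as a prefactor and defaults
to 1 in arbitrary units; reported densities are relative unless a
calibration is supplied. With these values and a fixed 3 µm band the
nodal density roughly doubles from $L = 7$ to $14$ µm.

**Direct-to-node null model.** If cytoplasmic protein binds the nodes
directly, balance gives $\rho_{nod} = (\beta/\eta)\rho_{cyt}$,
independent of size: localization alone senses nothing. Sensing needs
one process scaling with total area and a second confined to a region
that does not.

**Model II (modification intermediate).** Cortical unbinding (at
$\nu$) releases a *modified* cytoplasmic form that binds the nodal
region with constant $\alpha$ (µm s$^{-1}$) or reverts at $\mu$:

$$\rho_{nod} = \frac{\beta}{\eta}\,\frac{A_{cor}}{A_{nod}}
  \left(\frac{\mu V}{\alpha A_{nod}} + 1\right)^{-1} \rho_{cyt},$$

reducing to a pure area read-out when $\mu = 0$ and whenever
$\alpha A_{nod} \gg \mu V$. Defaults: $\nu = 0.5$ s$^{-1}$ (keeps
cortical levels low), $\alpha = 0.5$ µm s$^{-1}$,
$\eta = 5\times10^{-3}$ s$^{-1}$, $\mu = 0.03$ s$^{-1}$.

**Cytoplasmic trend.** The cytoplasm dilutes slightly with growth:
$\rho_{cyt}(L) = \rho_{ref}\,(1 - 0.01\,(L - L_{ref}))$ per µm,
clamped at zero. The reference length is not pinned down by the
normalization "to the average cytoplasmic intensity", so we take
$L_{ref} = 10.5$ µm, the midpoint of the 7–14 µm range; with the
constant-cytoplasm variant the results barely differ.

**Numerics.** The closed forms are the primary implementation. The
`model*_numeric()` solvers re-derive each steady state directly from
the balance equations by damped Newton iteration with analytic
Jacobians, converging to a relative residual of $10^{-12}$ of the
largest flux term. Newton runs on the raw copy numbers rather than
their logarithms: the balances are linear (one exact step) and several
legitimate steady states contain exact zeros (e.g. $\beta = 0$, or
$\alpha = 0$ with $\mu > 0$) that a log parameterization cannot
represent. Degenerate models raise errors naming the singularity
($A_{nod} = 0$ with $\nu = 0$ in Model I; $A_{nod} = 0$, $\nu = 0$, or
$\alpha = \mu = 0$ in Model II).

**Fitting.** `fit_scaling_prefactor()` fits the single free
multiplicative prefactor ($\beta\rho_{ref}$ in fluorescence units) of
a chosen model to (length, density) data by linear least squares,
holding all rates fixed. $A_{nod}$ is held constant at
$2\pi R \cdot 3$ µm² — the medial measurement band — configurable via
`w_nod`.

# The 1D spatial model

With explicit cortical diffusion, the quasi-steady cortical density
obeys
$$0 = D_{cor}\,\rho_{cor}'' - \nu\,\rho_{cor} - \alpha(x)\,\rho_{cor}
    + \beta\,\rho_{cyt}$$
on $x \in [-L/2, L/2]$, with nodal uptake
$\alpha(x) = \alpha_0 e^{-x^2/2\omega^2}$ centered at mid-cell and a
band width that saturates with length,
$\omega(L) = a(1 - e^{-L/s})$, $a = 2.2$ µm, $s = 7$ µm. Nodes are
essentially immobile ($D_{nod} = 0$ by default), so
$\rho_{nod}(x) = \alpha(x)\rho_{cor}(x)/\eta$ pointwise; with
$D_{nod} > 0$ the analogous equation is solved. Defaults
$D_{cor} = 0.2$ µm² s$^{-1}$, $\alpha_0 = 0.5$ s$^{-1}$,
$\nu = \eta = 5\times10^{-3}$ s$^{-1}$. The reach check
$\sqrt{2 D_{cor} \tau}$ with $\tau = 180$ s gives 8.49 µm, above the
~5 µm tip-to-node distance, so cortical protein can carry the area
signal to mid-cell before dissociating.

**Discretization.** Second-order central finite differences on a
uniform grid (default step 0.02 µm), sparse tridiagonal direct solve.
Reflecting (zero-flux) tips are imposed with mirrored ghost points;
halving the grid step changes the central-band mean by under 0.1%.

**Boundary conditions — an instructive subtlety.** "Hard wall" tips
admit two readings. Zero-flux (reflecting) walls conserve protein:
influx $\beta\rho_{cyt}L$ exactly balances $\nu\int\rho_{cor} +
\eta\int\rho_{nod}$, and with $\alpha_0 = 0$ the cortex is uniform at
$\beta\rho_{cyt}/\nu$. This is the package default — the 1D domain
stands for a closed membrane surface. However, at the default
parameters the nodal band is a *strong* absorber (absorption length
$\sqrt{D_{cor}/\alpha_0} \approx 0.63$ µm, much smaller than
$\omega$): it depletes cortical protein at its own center, nodal
uptake concentrates at the band flanks, and the mean nodal density in
the central 3 µm window stays nearly flat (within ~2%) as $L$ grows
from 7 to 14 µm — even though *total* nodal content still rises
monotonically by ~1.9x. With absorbing tips ($\rho_{cor} = 0$ at the
ends, `boundary = "absorbing"`), short cells lose relatively more
protein at the nearby walls and the central-band mean rises
monotonically with length — the published scaling behavior of this
model, suggesting the original implementation lost protein at the
domain ends. Both conditions are exposed; the test suite verifies
conservation, symmetry and the well-mixed limit under reflecting
walls, verifies the absorbing balance including the computed wall
flux, and checks the band-mean scaling claim under the absorbing
interpretation while asserting (not hiding) the reflecting flatness.

In the well-mixed limit ($D_{cor} \to$ large) the solution reproduces
the uniform Model I with $\alpha A_{nod}/A_{cor}$ replaced by the
numerically integrated mean of $\alpha(x)$, within 1%. An independent
shooting-method solution (two superposed initial-value integrations)
agrees with the finite-difference solution to $10^{-6}$ relative on a
0.0025 µm grid; at the default 0.02 µm step the $O(h^2)$ truncation
error (~$10^{-4}$) dominates such a comparison, so the oracle check
runs on the finer grid.

Densities are per membrane area with the circumferential dimension
collapsed; the factor $2\pi R$ enters only when integrating to copy
numbers (`nodal_metrics()`), and the "nodal density" observable is the
mean over the central 3 µm window, matching the fixed medial
measurement ROI.

# Profile quantification

**Polar gradients.** Measured tip profiles are normalized to 1 at the
tip after shifting so the intensity is zero 5 µm from the tip, then
fitted to $e^{-x/\lambda}$ over [0, 5] µm. The model curve is passed
through the *same* pin-to-zero normalization as the data; fitting the
raw exponential to pinned data would be biased by the tail value
$e^{-5/\lambda}$ (about 9% at $\lambda = 1.5$ µm), whereas the
normalized form recovers a clean exponential exactly. Non-decaying
profiles are flagged as failures, not fitted.

**Node bands.** Axial profiles are fitted to
$a\,e^{-(x - x_0)^2/2\sigma^2} + b$ by Levenberg–Marquardt least
squares. A fit is accepted only if $r^2 \ge 0.8$ and
$\sigma > 0.5$ µm; the width filter removes fits distorted by one very
bright node, and the $r^2$ threshold quantifies the otherwise
unspecified "good quality of fit" (both configurable). Start values
come from the profile moments, with exactly-zero starts nudged —
a relative-step numeric Jacobian degenerates at 0.

**Medial band.** Background-subtracted sum and mean over a fixed
window (default 3 µm) centered on the profile; errors if the window
exceeds the profile. Sums are additive over disjoint sub-bands.

**Node detection.** Local maxima above `threshold_factor` (default 2)
times the background; plateaus count once at their leftmost point.
Nodes closer than the profile resolution merge, so the count is a
documented lower bound.

**FRAP.** Recovery traces are fitted to
$I(t) = A(1 - e^{-kt}) + c$ — a single exponential with floating
plateau, the simplest form consistent with "exponential" recovery —
and $t_{1/2} = \ln 2/k$. Flat or decreasing traces are flagged.

**Molecule counting.** A pure intensity ratio against a calibrated
standard: bacterial flagellar-motor GFP spots at 22 molecules per dot
for per-node counts, or a whole-cell standard (~9600 molecules) for
cell totals.

**Cortical loops.** Outline profiles indexed by the angle seen from
the cell center (chosen tip at angle 0) are binned into 100 sectors;
sector centers convert to distance from the tip along the cortex using
the mid-plane stadium outline (two semicircles joined by straight
lines), so angle $\pi$ maps to the half-perimeter $(L - 2R) + \pi R$.
Empty sectors are flagged missing, never interpolated.

# Statistics

**Jensen–Shannon distance.** $\sqrt{H(m) - (H(p) + H(q))/2}$ with
$m = (p+q)/2$ and base-2 entropies, so the range is exactly [0, 1]
(0 = identical, 1 = disjoint), with $0\log 0 \equiv 0$. Inputs must
already be probability vectors on shared edges — no silent
renormalization. For continuous samples, `shared_histogram()` builds
shared edges with Freedman–Diaconis widths on the pooled sample (the
binning convention is not otherwise specified, so a standard rule is
used consistently across compared groups).

**Correlation robustness.** For each of $n_{reps}$ replicates
(default $10^6$), every (growth rate, accumulation rate) pair is
perturbed by Gaussian noise with its own measured errors — both
members of the pair — and an OLS slope is fitted; the reported
probability is the fraction of replicates with slope $\le 0$. The
computation is vectorized in chunks, seeded explicitly with R's own
generator (a fixed seed reproduces the estimate exactly; R has no
counter-based stream in base, and seeded reproducibility is the
invariant that matters).

**Matched subsets.** To compare strains at equal area (or volume),
each strain contributes the cells within `pooled mean` $\times (1 \pm
f)$, with $f$ scanned over 10–20% per strain to bring the cross-strain
subset means within 1%. The selection window is centered on the pooled
mean across strains: centering on each strain's own mean could never
equalize the subset means, so the pooled mean is the only reading
under which the stated procedure can achieve its stated goal. If no
window succeeds, the best achievable selection is returned with a
warning flag.

# Synthetic data: what it emulates and what it does not

Generators are seeded (identical seed and spec give bit-identical
output) and attach their generating parameters to every record, so
recovery tests always compare against recorded truth.

- `gen_population()`: per-cell radii and growth rates are Gaussian;
  division occurs when the rule's quantity (area / volume / length /
  time) crosses `threshold` times a lognormal multiplier of mean 1
  (cv default 5% — division-size scatter of a tight sizer). Birth size
  is half of division size (symmetric division); for the timer rule
  this closes to $L_{div} = 2 g T$. Default three-strain radii
  1.5/1.75/1.3 µm with a shared 150 µm² area threshold span division
  lengths of several µm.
- `gen_cdr2_profile()`: cortical baseline plus nodal band, with
  multiplicative Gaussian noise (cv 5% default — measurement noise is
  not otherwise characterized) and a known additive background. The
  band can be painted as a Gaussian of width $\omega(L)$ (the imaged
  shape) or as a uniform band over the model's $w_{nod}$ window. The
  scaling pipeline driver uses the uniform shape so that the 3 µm
  medial window measures exactly the density the model defines over
  $A_{nod}$; with the Gaussian shape the window captures a
  length-dependent fraction of the band (the fraction inside 1.5 µm
  falls as $\omega$ grows), which distorts a single-prefactor model
  fit — a real effect worth knowing about when quantifying real
  images with fixed ROIs. A discrete variant places a Poisson number
  of ~90-molecule nodes at Gaussian positions for node-counting tests.
- `gen_pom1_profiles()`, `gen_frap()`, `gen_growth_tracks()`:
  exponential tip gradients, single-exponential recovery curves, and
  rate pairs under sizer coupling (accumulation ∝ growth) or timer
  coupling (accumulation constant).

What passing tests show is that the *procedures* are correct and
mutually consistent at realistic noise levels; the generators do not
emulate out-of-focus light, bleaching, segmentation error, nuclear
exclusion, or cell-cycle stage structure, so they say nothing about
those systematics in real images.

# Pipeline drivers and problem sizes

`run_scaling_analysis()`, `run_division_size_analysis()` and
`run_sizer_timer_test()` wire generators, models, fitters and
statistics into figure-level analyses driven by config lists or YAML
files. Configs are validated before any computation (an explicit
integer seed is mandatory; unknown fields are rejected), and every
report embeds the package version and an MD5 hash of the canonical
JSON form of its config. Identical configs give identical reports.

Default problem sizes are chosen to exercise the statistics at the
scale of the emulated experiments while keeping any run interactive:
100 cells per scaling run, 100 cells per strain for division-size
analysis, 21 growth-track pairs, 14 FRAP curves, 267 cytoplasmic
intensities, 200 nodes for molecule counting, and $10^4$–$10^5$
Monte-Carlo replicates in routine runs (the robustness estimator is
exact in distribution at any replicate count; more replicates only
narrow the binomial error).

# Known limitations

- No node formation/growth dynamics and no time-dependent relaxation:
  only quasi-steady states.
- The 1D spatial model collapses the circumference; no 2D membrane or
  particle simulation.
- The band-mean flatness of the reflecting-wall spatial model at
  default parameters (above) means the spatial model's central-band
  scaling depends on the tip boundary interpretation; the uniform
  models are unaffected.
- Real-data ingestion is limited to CSV profiles, contours and
  dimension tables; no image processing.
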