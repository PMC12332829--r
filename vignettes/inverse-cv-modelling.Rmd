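---
title: "Thin-layer CV simulation and inverse learning of interface parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-layer CV simulation and inverse learning of interface parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvinverse)
```

## The model

Cyclic voltammetry of a dissolved one-electron redox probe is modelled
as one-dimensional diffusion of the oxidized species perpendicular to
the electrode,

$$\frac{\partial c(z,t)}{\partial t} = D\,\frac{\partial^2 c(z,t)}{\partial z^2},$$

with three auxiliary conditions. At the electrode surface ($z=0$) the
flux obeys Butler–Volmer kinetics,

$$\left.\frac{\partial c}{\partial z}\right|_{0}
  = \frac{k_0}{D}\left[c|_0\,e^{-\alpha f\,\eta(t)}
  - (c_b - c|_0)\,e^{(1-\alpha) f\,\eta(t)}\right],
  \qquad f = F/RT,\; \eta = E(t) - E_f^0,$$

at the far boundary ($z=L$) the concentration is pinned at the bulk
value $c_b$, and the initial field is uniform at $c_b$. The applied
potential $E(t)$ is a triangular wave with slope $\pm v$ between the
sweep limits. The Faradaic current is
$i(t) = F\,A\,D\,\partial c/\partial z|_0$ with $A$ the
electrochemically active surface area (ECSA), reported with the IUPAC
sign convention (anodic positive).

Three modelling assumptions are worth making explicit:

* **Single-field formulation.** Only the oxidized species is tracked;
  the reduced species' surface concentration is $c_b - c|_0$, exactly as
  the boundary condition is written. This presumes equal diffusivities
  of the two oxidation states and a closed surface mass balance, which
  is a good approximation for an outer-sphere couple such as
  hexaammineruthenium.
* **Faradaic-only current.** Double-layer (capacitive) charging, ohmic
  drop and convection/migration are not modelled. Experimental
  peak-to-background ratios are therefore data-side quantities, never
  simulated ones.
* **Area semantics.** The area in the current expression is the ECSA —
  it is one of the learnable parameters and must influence the
  simulated current to be identifiable. The geometric area $A_g$
  (default 12.56 mm²) is used only to convert currents to current
  densities for reporting.

The domain length follows the rule
$L = 6\sqrt{2 D\,|E_R - E_L| / v}$ — six diffusion lengths for the time
scale of a full sweep — so the far-field boundary does not perturb the
surface flux for any realistic candidate parameter set.

## Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| window $E_L \ldots E_R$ | $-0.6 \ldots +0.1$ V | the probe's reduction peak sits near $-0.3$ V vs an Ag pseudo-reference; the window brackets both peaks |
| start / direction | $E_R$, negative sweep | the bulk species is the oxidized probe, so the informative first sweep is cathodic |
| $E_f^0$ | $-0.25$ V | midway between the probe's oxidation and reduction peaks vs the pseudo-reference; a config input, never fitted |
| scan rate $v$ | 0.1 V/s | routine characterization speed; configurable 25–200 mV/s |
| $E_\mathrm{step}$ | 10 mV | typical potentiostat recording step |
| $c_b$ | $10^{-5}$ mol/cm³ | 10 mM probe |
| grid | 500 nodes | converged to <1% in peak current (see below) |
| sub-steps per $E_\mathrm{step}$ | 10 | implicit Euler error well below the spatial error at this setting |
| $T$ | 298 K | room temperature |

Internal units are ampere, volt, second, centimetre and mol/cm³;
conversions (µA/mm², nmol/cm², pg/mL) happen only at I/O boundaries.

## Numerical scheme

Space is discretized by a finite-volume/central-difference stencil on
uniform nodes, time by backward Euler. The Butler–Volmer condition is
applied *semi-implicitly*: the exponentials are evaluated at the
new-step potential while the surface concentration enters implicitly,
so the first matrix row stays linear and the system stays tridiagonal;
each step is solved by the Thomas algorithm in $O(n)$ (compiled C++).
Consequences and guards:

* The one-sided surface gradient $(c_1 - c_0)/\Delta z$ *equals* the
  Butler–Volmer flux by construction of the boundary row, so the
  current is consistent with the kinetics at every step.
* The dimensionless overpotential argument $f\,\eta$ is clamped to
  $\pm 50$ before exponentiation; beyond that the boundary condition is
  numerically indistinguishable from a Nernstian/diffusion-limited one
  and the clamp only prevents overflow.
* The scheme is monotone, so the field stays in $[0, c_b]$; a
  non-finite field raises an error naming the failing time step.
* Peak positions and heights are refined by a three-point parabola
  around the discrete extremum. With 10 mV recording steps this keeps
  the peak separation a smooth function of the kinetics, which the
  third GA objective needs; without it $E_{pp}$ would be quantized to
  the recording step.

Accuracy at the defaults, as exercised by the test suite: the
reversible-limit cathodic peak is within 3% of the Randles–Ševčík
closed form and the separation within 5 mV of the ~59 mV one-electron
value; refining 500 → 1000 nodes moves peak currents by <1%; the
species balance (column content vs time-integrated boundary fluxes)
closes to ≤0.5%; peak current is linear in $\sqrt{v}$ over 25–200 mV/s
with $R^2 > 0.999$.

## The inverse problem

The learner minimizes the three percent relative errors
$(\Delta I_{ox}, \Delta I_{red}, \Delta E_{pp})$, each
$100\,(x^{exp} - x^{sim})/x^{exp}$, over bounded
$(D, k_0, \alpha, \mathrm{ECSA})$. All three errors are carried on the
percent scale so the objectives are commensurate; they are stored
signed but minimized in magnitude. The GA is an elitist non-dominated
sorting algorithm (simulated binary crossover, polynomial mutation,
binary tournament on rank then crowding). $D$, $k_0$ and ECSA are
searched on a log₁₀ scale because they span decades; $\alpha$ is
linear. After convergence the Pareto-front member with the smallest
Euclidean norm of the error magnitudes is the *elitist* (ties: smaller
$|\Delta E_{pp}|$, then smaller $D$); the procedure is repeated three
times with seeds `seed + r` and the per-parameter median is the
headline estimate, with the maximum relative deviation from the median
reported as dispersion. Defaults — population 48, 60 generations —
complete one repeat of a two- or three-parameter inversion in tens of
seconds on one CPU; errors are unweighted before the norm-to-origin
selection. A candidate whose forward simulation fails is penalized with
an infinite error vector rather than aborting the run, and bounds
collapsed to a point (`lower == upper`) fix a parameter exactly.

### Identifiability

A single-scan-rate voltammogram constrains fewer combinations than the
four parameters. In the semi-infinite regime the trace depends on
$(D, k_0, \mathrm{ECSA}, \alpha)$ only through
$\mathrm{ECSA}\sqrt{D}$ (peak magnitudes), $k_0/\sqrt{D}$ (degree of
reversibility) and $\alpha$ (peak asymmetry): the transformation
$D \to \lambda D$, $k_0 \to \sqrt{\lambda}\,k_0$,
$\mathrm{ECSA} \to \mathrm{ECSA}/\sqrt{\lambda}$ leaves the features
essentially unchanged. Practical consequences:

* **Two-parameter inversions** (e.g. $D$ and $k_0$ with $\alpha$ and
  ECSA fixed) are well posed; noise-free round trips recover the truth
  to well under 1%.
* **Three-parameter inversions** ($D$, $k_0$, ECSA with $\alpha$
  fixed) retain one degenerate direction. Repeats converge to error
  norms of a few tenths of a percent yet scatter along the $\lambda$
  manifold, so individual parameters are *not* reliably recovered from
  one scan rate even though $\mathrm{ECSA}\sqrt{D}$ and $k_0/\sqrt{D}$
  are. The acceptance test that asks for per-parameter recovery in this
  configuration documents exactly this failure mode.
* Fixing ECSA from an independent measurement, or fitting several scan
  rates jointly, removes the degeneracy; joint multi-trace fitting is
  outside this package's scope.

## Assay statistics

The 4PL calibration $y = d + (a-d)/(1 + (x/c)^b)$ is fitted by
Levenberg–Marquardt least squares on group means, with the dose axis
log-transformed internally for conditioning and parameters reported on
the natural scale; starting values are derived from the response
extremes and the mid-response concentration, with jittered restarts.
The limit of detection follows the IUPAC 3.3σ reading: the lowest
concentration group that differs from the reference (lowest) group by a
two-sided Welch t-test at $p<0.05$ contributes its response SD, which
is converted to concentration units through the local 4PL slope,
$\mathrm{LOD} = 3.3\,\sigma/|y'(x)|$ — an LOD left in current units
would not be comparable across platforms. The SNR is the
background-corrected ratio
$(I^{target}-I^{background})/(I^{interferent}-I^{background})$,
invariant under a common additive shift of all three signals.

The Brown–Anson surface-concentration estimate is implemented exactly
as the printed form
$\gamma = \dfrac{4RT\,I_{ox}}{A_g F^2 v}\cdot\dfrac{1}{\mathrm{ECSA}}$
under the stated unit reading ($I_{ox}$ supplied as µA/mm² and
converted to total current via $A_g$; areas in cm²):

```{r brown-anson}
g <- brown_anson_gamma(I_ox = 12.6, v = 0.1, ECSA = 0.1125,
                       A_g_mm2 = 12.56, T_K = 298)
as.numeric(g)       # nmol/cm^2 under this reading
attr(g, "interpretation")
```

The published figure for these inputs is 25.1 nmol/cm²; direct
substitution under this reading (or under single-area variants of the
classical Brown–Anson relation) does not reproduce that figure, so the
package reports the computed value together with the unit
interpretation rather than forcing agreement.

## What the synthetic generator does and does not emulate

`generate_synthetic_cv()` adds i.i.d. zero-mean Gaussian current noise
to a simulated trace under a fixed seed. It emulates quasi-reversible
single-electron voltammetry of a 10 mM probe at 25–200 mV/s with
instrument-like recording (10 mV steps) — sufficient for testing
feature extraction, round-trip identifiability and the I/O layer. It
does **not** emulate capacitive background, ohmic distortion,
reference-electrode drift, or correlated (1/f) noise, so green
round-trip tests demonstrate correctness of the estimator under the
model's own assumptions, not robustness to every artefact of real
potentiostat data.

## Problem sizes used by the tests

Full-accuracy checks (analytic oracles, grid convergence, mass balance,
acceptance round trips) run at the standard conditions: 500–1000 nodes,
10 sub-steps, one cycle, and GA budgets of 48×60 with 3 repeats.
Unit tests that exercise logic rather than accuracy use coarser grids
(150–300 nodes) and smaller GA budgets; the grid-search oracle
comparison uses a 40×40 log grid over $(D, k_0)$.

## Known limitations

* Faradaic-only model: no capacitive current, no iR compensation, no
  migration or convection, one spatial dimension, no adaptive meshing.
* One cycle is simulated by default (configurable); experimental
  multi-cycle averages are supported on the feature side.
* The reduction-peak error is computed on signed currents; since both
  experimental and simulated reduction peaks are negative under the
  sign convention, the signs cancel in the ratio.
* The GA has no gradient-based refinement stage; the last fraction of a
  percent of convergence is bought with generations, not polish.
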