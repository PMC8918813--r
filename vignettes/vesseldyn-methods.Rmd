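---
title: "Methods: quantifying endothelial morphodynamics and trunk haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying endothelial morphodynamics and trunk haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseldyn)
```

# The biological problem

Between roughly 26 and 44 hours post-fertilization (hpf) the zebrafish
trunk remodels its intersegmental vessels (ISVs): arterial sprouts from
the dorsal aorta (DA) anastomose dorsally into the DLAV, venous sprouts
from the posterior cardinal vein (PCV) reconnect about half of the ISVs,
and the network settles into alternating arterial (aISV) and venous
(vISV) identities. The cellular currency of this remodelling is the
behaviour of individual endothelial cells: directed dorsoventral
migration, divisions, and immigration/emigration of cells between each
ISV and its neighbours (DLAV dorsally, PCV ventrally). `vesseldyn`
quantifies all of these from 3D+t nuclei tracks, and couples them to an
idealized haemodynamic model of the same network.

Because the deposited tracking data are an external download, the
package carries a first-class synthetic generator that reproduces the
statistical structure the analysis assumes, together with a ground-truth
event ledger. Every stage of the pipeline is therefore testable offline,
with known right answers.

# Canonical alignment

All downstream quantities read the dorsoventral position off the y
coordinate, so tracks are first moved into a canonical frame: DA
centroid at the origin, DA axis along +x, DLAV in the positive-y half
plane with its centroid rolled into the z = 0 plane.

The DA axis is fitted to the pooled positions of all aorta nuclei over
the whole recording. We deliberately use an orthogonal (total least
squares) line — the principal axis of the centred cloud — rather than a
regression of y on x: an ordinary regression is not rotation invariant,
and the quantity wanted here is a geometric axis of a point cloud whose
orientation in the microscope frame is arbitrary. The OLS variant is
kept behind `fitAortaAxis(..., method = "ols")` for parity checks
against pipelines that regressed coordinates.

Two conventions close the remaining gauge freedom, both of which cancel
in every reported quantity:

* the x origin is the DA point-cloud centroid (any x shift cancels in
  velocities and region assignments);
* the roll about the axis maps the DLAV centroid to y > 0, z = 0. If
  the DLAV initially maps to negative y, the half-turn about x
  (y -> -y, z -> -z) that fixes it is recorded as `dorsalFlip`.

The transform is rigid by construction; the test suite checks isometry
(pairwise distances to 1e-9 relative), idempotence, and equivariance —
aligning a rigidly perturbed copy of a dataset reproduces the alignment
of the original to numerical precision. Note that equivariance, not
pointwise equality with the generator's internal coordinates, is the
exact property: re-fitting an axis to a noisy cloud recovers the true
frame only up to a small tilt (sub-degree at realistic noise), which is
why recovered coordinates agree with generator truth to ~0.1 um rather
than machine precision.

# Windowed dorsoventral velocity

Per cell and per 2-h window, stepped every 10 min across 26-44 hpf, the
velocity is the signed y displacement between the cell's first and last
sample inside the window, divided by the time between those two
samples. Positive is dorsal (away from the DA). Using the first/last
displacement rather than a regression slope matches the defining notion
of "signed displacement over the window"; dividing by the actually
spanned time (rather than the nominal 2 h) keeps the estimator unbiased
for cells that cover a window only partially — daughters born
mid-window, tracks ending — which a fixed divisor would shrink toward
zero. For full-coverage cells the two divisors are identical.

A cell contributes to the class (aISV/vISV) of the ISV it occupies for
the majority of the window; cells mostly in the DLAV or ventral band
contribute nothing. Windows pool cells; the 95% interval on the class
mean is a seeded nonparametric bootstrap over cells (2000 resamples by
default) — the bootstrap was chosen because the per-window cell sample
is small, skewed by lineage structure, and no parametric form is
defensible.

# Fate, regions, and event detection

**Fate.** An ISV's identity is its final-frame ventral connection: PCV
means venous, DA means arterial, applied retroactively to all earlier
frames. The connectivity table is an explicit input (the synthetic
generator emits it; for real data it is what an annotator reads off the
final frame). A geometric fallback marks an ISV venous when its member
cells traverse the ventral band late in the recording; it is a
heuristic and the explicit table takes precedence. ISVs absent at the
final frame are flagged unresolved and excluded from class statistics.

**Region map.** Canonical y is partitioned into a ventral PCV/DA band
(y < y_DA + delta), a DLAV band (y > y_DLAV - delta) and the ISV band
between, with delta = 5 um; within the ISV band a point belongs to the
nearest ISV axis in x. The bands make the partition total: every point
is assigned exactly once, so cell counts never double-count.

**Hysteresis.** An exchange event is recorded only when a cell's region
assignment changes *and* the new assignment persists for at least K = 6
consecutive frames (1 h at 10-min frames). Boundary flicker shorter
than K produces no events, and the output is invariant to adding such
flicker — the original counts were made by expert visual inspection,
and the persistence rule is the reproducible surrogate: a cell has
"exchanged" when it has demonstrably taken up residence elsewhere.
delta and K are tunable (`regionMap()`, `detectExchanges()`); defaults
were chosen once against the geometry (5 um is ~10 noise SDs from any
injected cell's resting position) and are not data-fitted.

**Mitoses** are lineage branchings: a division is encoded as the parent
track ending and two daughter tracks starting with `parent_id` set, so
counting is a pure lineage query, attributed to the vessel containing
the parent at its last frame. More than two daughters is a data error.
F-actin-based visual cues for mitosis are out of scope.

**Accounting identity.** With no cell death (true of the synthetic
data; losses in real data are censoring), per ISV:
`cellNumber(t1) - cellNumber(t0) = net_immigration + mitoses`, where
`net_immigration = immigration - emigration`. The suite asserts this
exactly at zero noise.

# The idealized flow network

The haemodynamic model is Poiseuille flow on a graph. The default build
is 30 ISVs alternating aISV/vISV along a DA chain: the DA runs from an
inlet through the aISV base nodes to an outlet, the DLAV chain crosses
all 30 apices, aISVs connect DA to DLAV, and each vISV hangs from the
DLAV down to a terminal sink node (the PCV itself is not part of the
graph; it is the pressure sink). Boundary nodes are exactly the DA
inlet, DA outlet, and the 15 vISV terminals.

Each edge j carries conductance

$$G_j = \frac{\pi D_j^4}{128 \mu L_j},$$

with per-class diameter series D_j(t) (linearly interpolated between
measurements; exact grid hits return the stored value). Flow balance at
every interior node gives a linear system [G]{p} = {b} for nodal
pressures, re-assembled and re-solved at every time point; edges with
no diameter measurement (D = 0) are held at a conductance floor of
1e-30 so the system stays invertible, and report zero shear. Per edge,

$$Q_j = G_j\,\Delta p_j, \qquad
  \tau_j = \frac{32 \mu |Q_j|}{\pi D_j^3} = \frac{D_j \Delta p_j}{4 L_j},$$

and the identity between the two shear forms is asserted at 1e-12
relative on every edge — it is an exact algebraic consequence of the
Poiseuille relations and a sharp regression guard against unit slips
(everything is strict SI internally; micrometres are converted once at
the interface, because a D^4 law turns any unit slip catastrophic).

Boundary conditions: inlet pressure 201.3 Pa (adult DA estimate), sinks
at 0 Pa, viscosity 0.0035 kg/(m s). The aorta outlet applies the inlet
pressure dissipated over the length of the fish (2 mm) to the fraction
of the aorta inside the model, P_out = P_in (1 - L_DA,model / L_fish);
this gradient rule is a replaceable hook in `flowParameters()` since
other boundary treatments are defensible.

Two model properties worth stating plainly:

* **Viscosity invariance.** Under fixed pressure boundary conditions a
  uniform viscosity rescale leaves the shear series unchanged exactly
  (G scales as 1/mu, Q as 1/mu, tau as mu.Q). So the model *cannot*
  represent a viscosity-mediated shear reduction (e.g. loss of
  circulating erythrocytes) by changing mu alone; that would require
  changing the pressure boundary conditions. The package asserts the
  invariance rather than pretending otherwise, and no flow prediction
  for reduced-haematocrit conditions is claimed.
* **Network coupling.** Same-class ISVs are *not* interchangeable at
  finite conduit conductance — edge ISVs see different DA/DLAV
  resistance than interior ones (differences of tens of percent at
  realistic diameters). Exact same-class equality emerges only in the
  equipotential-conduit limit, which the tests approach with very wide
  DA/DLAV. Conversely the coupling is real physics: enlarging only the
  vISVs raises the shear in aISVs whose own diameter never changes,
  and increasing any vISV diameter can only increase total inlet flow
  (conductance monotonicity). Both are asserted.

The solver is a sparse symmetric solve over the interior nodes with a
dense fallback; correctness is checked against an independently
assembled dense full-system oracle on randomized networks of up to 50
nodes (agreement to 1e-10 relative; Kirchhoff balance to 1e-12
relative of the largest flow). One caveat discovered in testing: a
subnetwork tied to the boundaries *only* through floor edges has
numerically indeterminate pressure (the floor conductance, ~14 orders
below a measured vessel, vanishes in double precision). The floor is
designed for missing measurements inside an otherwise-connected
network, which is the regime the randomized tests draw from.

# Statistics

**Discrete Kolmogorov-Smirnov.** Per-vessel event counts are small
integers with massive ties, where the classical two-sample KS p-value
is invalid. `discreteKs()` computes D as the largest ECDF difference
over the pooled discrete support and calibrates it conditionally on the
pooled data: full enumeration of all label assignments when
choose(n, n_a) is small (method "exact"), otherwise seeded Monte-Carlo
permutation (default 10^4 resamples, p = (1 + hits)/(B + 1)). The
implementation is from the statistic's definition; with all values
distinct D reduces to the classical two-sample D (cross-checked against
`stats::ks.test`). A one-sample form against a discrete reference pmf
is provided with a simulated p. Calibration is part of the acceptance
suite: the type-I rate at alpha = 0.05 over 1000 null replicates
(Poisson counts, n = 30 per arm) must sit in 5% +/- 2%. Permutation
p-values on heavily tied counts are mildly conservative by
discreteness, which is the correct direction of error for this use.

**Circular statistics.** Migration directionality angles are compared
with Watson's two-sample U-squared, computed from the variance of the
ECDF difference over the pooled order statistics — a rotation-invariant
statistic, asserted invariant to 1e-12 under common rotation. The
p-value uses the asymptotic series 2*sum((-1)^(j-1) exp(-2 j^2 pi^2 U2))
when both arms have >= 8 observations, else (or on request) a seeded
permutation; permutation p-values are checked for null uniformity.
First-moment descriptors (`circularMeanSd()`) flag the mean direction
as undefined when the resultant length is numerically zero. Welch's
t-test for effective speeds is `stats::t.test` with Satterthwaite df.

**Correlations** of per-ISV drivers (mitoses, net immigration) with
final diameter are Pearson by default, Spearman on request; the choice
is exposed because counts are short-range integers and neither is
canonical.

# The synthetic generator

`generateEmbryo()` emits nuclei tracks on the canonical scaffold (DA at
y = 0, DLAV at y = isv_length, ISVs at multiples of isv_spacing), with:

* phase-dependent dorsoventral drift per class — defaults: sprouting
  (26-30 hpf) 5 um/h in future vISVs vs 3.9 in future aISVs;
  anastomosis (30-33) 2 vs 1; remodelling (33-40) +3 vs -0.6; near zero
  after 40 hpf. The phase cut points are narrative, not measured, so
  they are configurable; 30/33/40 are the package defaults.
* iid Gaussian positional noise of 0.5 um per frame, applied as
  measurement noise (not a random walk — tracking error does not
  accumulate). 0.5 um is small against the 2-h displacements at the
  stated drifts and ~10 sigma from any region boundary.
* mitosis as a per-cell exponential hazard that branches tracks
  (defaults 0.013 /cell/h in aISVs, 0.033 in vISVs — chosen once to
  land the per-vessel division counts near one per aISV and nearly two
  per vISV over the recording).
* inter-vessel exchange as continuous translocations spanning >= 3
  frames (6 by default), never teleports, so detection must work on
  realistic paths; per-vessel probabilities of at least one event
  default to 0.60 (DLAV -> aISV immigration), 0.76 (vISV -> DLAV
  emigration) and 0.92 (PCV -> vISV immigration). The PCV is a source
  band below the aorta (y < 0), entering at the ISV's ventral end.
* linear per-class diameter growth (4 um at 26 hpf to ~7 um aISV /
  ~8 um vISV at 44 hpf), 55 um ISV spacing and 80 um ISV length —
  realistic trunk geometry chosen once.
* optionally, emission in a random rigid frame to exercise alignment,
  with canonical coordinates retained in the ground truth.

Each embryo draws from its own RNG stream keyed by (seed, embryo id),
so any embryo regenerates identically in isolation and datasets are
byte-reproducible. All injected events land in a ledger that downstream
detection is scored against (precision = recall = 1 required at zero
noise).

What the generator does **not** emulate — and hence what green tests do
not show about real data: segmentation/tracking errors (identity
switches, dropouts), cell death, curved or drifting vessel axes,
embryo-to-embryo geometry variation, flow-coupled migration feedback,
and any correlation structure between events beyond the per-vessel
probabilities. Parameter-recovery results certify the estimators, not
the biology.

One deliberate scoring choice: drift recovery is measured on cells the
ledger does not mark as translocating. An exchanging cell's traversal
is a large directed displacement that is not a sample of the resident
drift parameter; including such cells tests a different (and
ill-posed) quantity. The full `windowedVelocity()` output over all
cells remains what the pipeline reports.

`generateMonolayer()` emulates the scratch-wound assay: a 500-um
cell-free gap with the wound edge along y and free space at x > 0;
control-like cells advance persistently at 15 um/h into the gap,
knockdown-like cells keep the same step scale but take random per-cell
persistent directions, collapsing net advance while preserving
chord-based effective speed. Wound area shrinks with the mean front
advance, giving closure percentages consistent with the tracks.

# Problem sizes and numerical choices

The default test and acceptance runs use 20 synthetic embryos (10 ISVs,
~90 cells each, 109 frames) for parameter recovery, 10 at zero noise
for event recovery, 20-25 randomized networks (<= 50 nodes) for solver
equivalence, 1000 null replicates at 10^4 permutations for KS
calibration and 500 replicates at 999 permutations for U-squared
uniformity — sizes at which the Monte-Carlo error of every check is
comfortably below its tolerance. Permutation loops run in C++ under R's
RNG so all p-values are seed-stable. Bootstrap intervals are percentile
type with 2000 resamples. Tie-breaking in region assignment is by
nearest ISV axis; equality at a band boundary resolves ventral/dlav by
strict inequality of the band conditions. Degenerate inputs error
loudly and early: coincident axis clouds, DLAV centroids on the axis,
empty samples, fewer than two distinct angles, negative diameters.

# Known limitations

* The windowed velocity pools cells (not displacement samples), and
  exchange fractions pool ISVs over all embryos rather than averaging
  per-embryo fractions; both choices are flagged in the output rather
  than configurable.
* The flow model is steady, Newtonian, and rigid-walled: no pulsatility,
  no haematocrit-dependent viscosity, no coupling of shear back onto
  migration.
* The geometric fate fallback needs late ventral traffic to call a
  vein; quiet vISVs would be miscalled arterial, which is why the
  explicit connectivity table is the primary input.
* `runPipeline()` orchestrates the synthetic end-to-end run; applying
  the pipeline to a downloaded tracking deposition requires mapping its
  column schema onto the flat track dialect first (extra columns are
  tolerated on read).
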