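---
title: "The strokesim model: synthetic vasculature, embolus transport and lesion formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The strokesim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`strokesim` simulates embolic stroke as a stochastic transport problem on a
synthetic cerebral arterial tree. This vignette is the package's own account
of the model: what is simulated, which parameters matter, which design
choices were open and how they were resolved, and what the synthetic setting
does and does not say about real brains.

## The model in one paragraph

An embolus of diameter $d$ is released at the circle of Willis and moves
instantaneously through a binary arterial tree. At each bifurcation it
passes into branch A with probability
$$p_A = \tfrac{1}{2}\left[\tanh\!\big(\sigma\,\mathrm{atanh}(2f_A/(f_A+f_B)-1)\big)+1\right],$$
where $f_A, f_B$ are the steady flows in the daughters; at $\sigma = 1$ this
is exactly the flow fraction, and large $\sigma$ forces the higher-flow
branch. Two size rules override the draw: if the embolus is wider than
exactly one daughter it takes the larger one; if wider than both, the parent
vessel is obstructed. A lodged embolus shrinks linearly at the dissolution
rate $\Delta$ and re-enters the larger daughter once it fits. Every terminal
vessel is monitored for lack of flow; a continuous zero-flow interval of at
least $\tau$ produces an ischaemic lesion in the tissue that terminal
perfuses. Lesion volume, expressed as % of brain volume, follows an offset
power law in embolus diameter,
$$\%\,\text{infarct} = a\big((d-d')/d_0\big)^b, \qquad d' \approx \tau\Delta,$$
because the demand (and hence tissue) distal to a vessel of diameter $\delta$
in a Murray tree is proportional to $\delta^\gamma$, and the occluding vessel
at the moment the lesion forms has diameter just above $d - \tau\Delta$.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\gamma$ | 3.2 | — | bifurcation exponent: $d_p^\gamma = d_a^\gamma + d_b^\gamma$ at every bifurcation |
| $d_{MCA}, d_{PCA}, d_{ACA}, d_{CA}$ | 3.1, 2.7, 2.6, 1.5 | mm | territory artery diameters; their Murray combination fixes $d_0 \approx 4.03$ mm |
| $\sigma$ | 1 | — | routing sharpness; overlap maps conventionally use 1.25 |
| $\Delta$ | 0.533 | mm / 24 h | linear dissolution rate (0.267 as the slow alternative; a 2.67 mm embolus fully dissolves in 5 or 10 days respectively) |
| $\tau$ | 4 | h | continuous no-flow duration after which a terminal's territory is lesioned |
| `max_time` | 24 | h | simulation horizon; open zero-flow intervals at the horizon count toward the criterion once they reach $\tau$ |
| `leaves_per_hemisphere` | 4096 | — | main-tree leaf budget; 2·4096 = 8192 main segments per hemisphere, 16,384 after mirroring |
| `generations` | 5 | — | appended symmetric subtrees: 32 terminals and 62 segments per main leaf |
| grey:white demand | 3:1 | — | relative metabolic demand used for site sampling (typical cerebral blood-flow ratio) |
| voxel spacing | 2 | mm | phantom resolution (4 mm in the test suite) |

## The phantom and what it stands for

No imaging data ships with the package, so a parametric phantom substitutes
for a real grey/white segmentation: an ellipsoidal cerebrum (semi-axes
70 × 85 × 60 mm) whose outer radial shell (50% of the volume) is grey
matter, plus a posterior–inferior cerebellar ellipsoid. Perfusion
territories are angular sectors — MCA lateral, ACA anterior–medial, PCA
posterior–inferior, with the cerebellum fused into the PCA label — whose
sector thresholds are data-driven quantiles, so the realised per-territory
volume fractions match the configured ones (by default the Murray-law demand
shares $d_i^\gamma/\sum d^\gamma \approx 0.43 : 0.28 : 0.25 : 0.04$, which
makes the emergent territory trunk diameters land near the printed artery
diameters). The voxel grid is arranged so that no voxel centre lies on the
mid-sagittal plane and all sector scores depend only on $|x|$ and $(y,z)$:
mirror symmetry of tissue and (L/R-swapped) territory labels is exact by
construction, and so is the left/right symmetry of the vascular tree grown
on it. The cerebellar ellipsoid's size was chosen once so its exclusive
volume approximates the cerebellar-artery demand share; this is geometry
calibration, not a fitted quantity.

## Growing the surrogate vasculature

The tree is grown per territory over perfusion sites sampled with
probability proportional to voxel demand. Each territory receives a leaf
budget proportional to its demand share (largest-remainder apportionment,
at least one leaf each; requesting more leaves than sites is an error naming
the territory). Growth is sequential and constructive: anchor sites are
inserted in a seeded random order, and each new site becomes a leaf attached
by a new bifurcation at the nearest point of the existing territory tree
(the nearest segment is split there, clamped to the inner 90% of its length
so no zero-length pieces arise). Remaining sites attach to their nearest
leaf and add to its demand. Diameters are then assigned bottom-up: leaf
diameter $\propto$ (leaf demand)$^{1/\gamma}$ and exact Murray combination
at every junction, so the demand distal to any main-tree vessel equals
$(d/d_\text{root})^\gamma$ exactly — the mechanism behind the power law's
exponent.

An earlier design used balanced recursive bisection of the site set
(splitting each set into equal-demand halves). It was abandoned for a
structural reason worth recording: in a balanced tree the demand distal to
the occluding vessel is quantised in factor-of-two steps, so lesion volumes
overshoot the smooth $d^\gamma$ law by $\mathbb{E}[2^U] \approx 1.44$ on
average and the fitted prefactor lands far above 50%. Real arterial trees —
and trees grown by annealing or constrained constructive optimisation — are
strongly side-branching: a dominant trunk sheds small branches, so distal
demand varies almost continuously with diameter. The sequential
nearest-insertion rule reproduces exactly that morphology with no tunable
parameter.

Two discrete levels remain by construction and should be kept in mind:

* the circle-of-Willis cascade. The four territory trunks join as
  ((MCA, PCA), (ACA, CA)) through junction segments whose diameters follow
  Murray's law; a hemisphere is fed by a single trunk (a pass-through
  segment, the terminal carotid), which also makes the per-hemisphere
  segment count exactly $2L$ — 8192 at the default budget, 16,384 after
  mirroring, excluding the joining input whose diameter $2^{1/\gamma} d_0$
  conserves flow at the join. Emboli wider than $d_{MCA}$ block whole
  territory pairs in one step; the region $d > 3.1$ mm is therefore outside
  the smooth power-law regime of this model class.
* the appended subtrees. Every main leaf carries a symmetric 5-generation
  subtree (diameter factor $2^{-1/\gamma}$ per generation, lengths shrinking
  by $2^{-1/3}$ — lengths only enter resistances, and routing uses flow
  ratios, so this choice is immaterial). Below the main-leaf scale
  (≈ 0.2–0.45 mm at the default budget) the factor-two demand steps of these
  symmetric subtrees re-introduce the quantisation overshoot for the
  smallest emboli.

## Flows, occlusions and the ischaemia clock

Flows are steady Poiseuille: resistance `length/diameter^4` in model units
(only ratios matter), one inlet with fixed total inflow, equal pressures at
all terminals. `solve_flows()` reduces the tree in two linear-time passes
(equivalent subtree resistances bottom-up, flow splitting by inverse
equivalent resistance top-down) and is verified against a dense Kirchhoff
nodal solve on random trees. An occluded segment has infinite resistance:
exactly its distal terminals lose flow, and with a fixed input flow no other
terminal's flow decreases. (The converse — that removing an occlusion
decreases no terminal's flow — is false under this boundary condition:
un-occluding a subtree takes flow back from its siblings.)

That structural fact licenses the event loop's main shortcut: during a
stroke the only occlusion is the embolus itself, so the zero-flow terminal
set is the contiguous Euler-tour range distal to the lodge site, and the
per-terminal ischaemia clocks can be updated per event in time proportional
to the terminals shed, using the baseline flow solution throughout (routing
only ever happens while no occlusion is present). The general path —
`record_flow_interval()` over all terminal flows per event — is implemented
too, and a test asserts both give identical outcomes. Clock semantics: a
positive-flow interval closes any open zero-flow run at its start; the
lesion criterion `longest continuous run ≥ τ` treats a run still open at the
horizon as closed there.

Lesion volume is tissue-based: each brain voxel belongs to its nearest
perfusion site (Euclidean, ties to the lowest site index — which makes voxel
ownership exactly mirror-symmetric), each site to the terminal that owns it,
and the infarct is the volume of voxels owned by lesioned terminals as a
percentage of brain volume. The alternative reading — % of the vascular
tree occluded, i.e. the lesioned demand fraction — differs only through the
grey/white volume-vs-demand weighting and can be computed from the same
objects; the tissue-volume definition is the default because lesion volumes
on imaging are tissue volumes.

## Trials, the power-law fit and its conditioning

`run_cohort()` runs independent strokes (per-run seeds derived from a master
seed; rows in deterministic order) over a diameter grid or a size
distribution ("flat" = continuous uniform, by default up to 2.67 mm with a
0.1 mm lower bound, since a shower's true lower cutoff is unknown).
`fit_power_law()` fits $a((d-d')/d_0)^b$ directly to the individual stroke
rows with Levenberg–Marquardt (`minpack.lm::nlsLM`), start values $a = 50$,
$b = \gamma$, $d' = \tau\Delta$, and $d'$ constrained to the model domain
$d' < \min(d)$.

The three-parameter fit deserves a warning that the package states openly:
$d'$ shifts predictions by only a few percent over the fitted range, which
is smaller than the structural wiggle of any *single* tree realisation
(each realisation's top-level branches are a handful of discrete demand
chunks), so unweighted least squares leaves $d'$ essentially unidentified —
its estimate can sit at either constraint boundary and varies strongly with
the tree seed, and $a$ absorbs the supra-$d_{MCA}$ plateau when the grid
extends beyond 3.1 mm. Two regularities remain robust and are what the test
suite asserts: the exponent $b$ stays near $\gamma$, and with $d'$ held at
its analytic value $\tau\Delta$ (the `d_prime` argument) the prefactor lands
near 50% with $b \approx 3.1$ on grids inside the smooth regime. Fits at the
two dissolution rates agree on $(a, b)$; the $d'$-vs-$\Delta$ scaling, by
contrast, is not recoverable from the free fit on a single surrogate tree,
and the package does not pretend otherwise.

`overlap_map()` accumulates per-voxel lesion frequencies over a cohort
(conventionally at $\sigma = 1.25$); integrated territory probabilities put
MCA well above ACA for a flat shower, and left/right integrated
probabilities agree within Monte Carlo error on the symmetric tree.
`embolus_diameter_from_volume()` applies the inverted law
$d = d_0(\%/a)^{1/b} + \tau\Delta$; composed with the forward law it is the
identity to machine precision.

## Numerical choices

* Murray conservation is exact to construction and asserted at 1e-9
  relative; appended-subtree diameter ratios are exact.
* The growth split point is clamped to $t \in [0.05, 0.95]$ along the
  nearest segment; segment lengths have a 1e-6 mm floor.
* `branch_probability()` handles the `atanh` limits explicitly: a zero-flow
  branch gets probability 0; both branches zero is an error (the caller
  never routes into a dead subtree because flows are solved first).
* Dissolution timing is exact arithmetic, `(d - threshold)/Δ`, converted to
  hours; Δ = 0 means permanent occlusion.
* Serialization writes coordinates with 17 significant digits (SWC) and
  full-precision JSON, so `read_tree(write_tree(x))` round-trips to 1e-12.
* Degenerate inputs are rejected with configuration errors: zero-volume
  ellipsoids, non-positive diameters/lengths, out-of-order clock intervals,
  distributions wider than the input vessel.

## Problem sizes

The defaults used by the shipped analyses: phantom at 2 mm spacing
(~196,000 brain voxels), 4096 leaves per hemisphere (524,289 segments,
262,144 terminals, ~32,800 perfusion sites), cohorts of 40 diameters × 25
runs. The test suite uses a 4 mm phantom and a 256-leaf tree for property
checks and the full-scale objects only where the checked claim requires
them. These sizes were chosen so that a full cohort pair plus fits completes
in about a minute on a single core.

## Limitations

* The vasculature is a surrogate: no anastomoses, no circle-of-Willis
  variants (the complete-CoW case only), no venous side, no pulsatility, no
  autoregulation, and territory shapes are angular-sector approximations —
  results that depend on true territory geometry (e.g. radiological
  comparisons) are out of scope.
* One embolus per simulation; showers interact only through cohort
  statistics, not haemodynamically.
* Above $d_{MCA}$ and below the main-leaf scale, lesion volumes are
  quantised by the discrete top cascade and the symmetric appended subtrees
  respectively; fitted coefficients using data in those regimes inherit that
  distortion.
* Passing the symmetry, scaling and territory-ordering tests on the phantom
  demonstrates internal consistency of the model, not anatomical accuracy of
  any individual prediction.
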