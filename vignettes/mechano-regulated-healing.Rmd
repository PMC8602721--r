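---
title: "Mechano-regulated peri-implant bone healing: the simulator, the neural surrogate, and its explanation"
author: "MechanoHeal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-regulated peri-implant bone healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

After a dental implant is inserted, the granulation tissue that fills the
peri-implant gap (the *callus*) differentiates day by day into resorption,
mature bone, immature bone, cartilage or fibrous tissue, depending on the
local mechanical environment. The mechano-regulation hypothesis makes this
quantitative: two biophysical stimuli — the octahedral shear strain
$\gamma$ of the solid phase and the interstitial fluid speed $\nu$ — are
combined into a single cell stimulus factor

$$ S = \frac{\gamma}{a} + \frac{\nu}{b}, \qquad a = 0.0375,\;
   b = 3\ \mu\mathrm{m/s}, $$

and the value of $S$ selects the tissue phenotype a callus pixel
differentiates into on the next day. Iterating solve → stimulus →
phenotype → material update for 35 days produces a full healing history
and, from its final map, the clinically used performance indexes of an
implant design (tissue fractions, bone area, bone–implant contact,
marginal bone loss).

`MechanoHeal` implements this workflow three times over:

1. a **ground-truth simulator** on a structured pixel grid
   (`runHealing()`),
2. a **multi-network neural surrogate** that replaces the per-day physics
   with learned predictions and rolls the whole history out from the day-0
   state alone (`trainSurrogate()`, `rollout()`),
3. a **Deep Taylor decomposition** layer that explains the surrogate's
   predictions pixel by pixel (`dtdRelevanceMLP()`, `dtdRelevanceUnet()`,
   `swapExperiment()`).

# The simulator

## Grid and geometry

The domain is a structured pixel grid: rows run axially from the occlusal
crest downward, columns radially from the implant axis outward; the
axisymmetric half-model is represented as the right half-plane. The
full-scale frame is 210 × 52 pixels; the default pixel size (0.055 mm)
makes a default implant span roughly 180 of the 210 rows, which keeps
peri-implant strain magnitudes in the regime the stimulus thresholds
expect. Implants are parametric (`ImplantParams()`): core radius, thread
pitch/depth/profile (triangular, trapezoidal or buttress), apex shape and
collar height, rasterized without interpolation so that elements and
pixels coincide. A callus band of configurable width (default 3 px) wraps
the embedded implant; a cortical layer (default ≈ 6% of the rows) tops the
cancellous bone. The stem-cell source (`cellOriginMask`) is the callus
boundary facing host bone; the load surface is the implant's top row.

`generateImplantLibrary()` draws valid random designs from documented
ranges (body length 0.62–0.85 of the rows, radius 0.12–0.24 of the
columns, pitch 6–14 rows, depth up to half the radius with occasional
two-zone depth profiles). These ranges are the package's own choice: the
original 65-design library is not described parametrically anywhere, so a
family wide enough to produce qualitatively different healing outcomes
(threaded/smooth, deep/shallow threads, different apexes) was fixed once.

## Per-day physics

The original workflow solved axisymmetric Biot poroelasticity in a
commercial FE package. Here the same two stimuli are produced by a
simplified, decoupled chain, each step a sparse direct solve:

* **Elasticity** (`solveElasticity()`): quasi-static plane-**stress**
  equilibrium on bilinear quadrilateral pixel elements with per-pixel
  heterogeneous $E$, $\nu_p$, under an 8 µm downward displacement of the
  implant top; symmetry on the axis, fixed outer bone boundary. Plane
  stress (not plane strain) was chosen so that the uniaxial patch test has
  the textbook solution $\varepsilon_{xx} = +\nu_p\,\delta/h$, and the
  out-of-plane principal-strain channel is the plane-stress value
  $\varepsilon_z = -\nu_p/(1-\nu_p)(\varepsilon_x+\varepsilon_y)$, giving
  the three principal-strain channels the workflow expects.
* **Fluid** (`solveFluid()`): one-step consolidation
  $\nabla\!\cdot\!(k\nabla p) = \dot\varepsilon_{vol}$ on the porous
  pixels with harmonic-mean face permeabilities, drained outer boundaries,
  no-flux axis and impermeable implant, then Darcy velocity
  $v = -k\nabla p$. The volumetric strain rate is the day's strain state
  applied over one masticatory loading period (1 s), not over the 1-day
  iteration step: the stimulus-relevant flow is the one induced by a
  biting cycle, and this convention lands callus velocities in the µm/s
  range of the fluid constant $b$.
* **Diffusion** (`diffuseStemCells()`): implicit Euler for the stem-cell
  concentration $n \in [0,1]$ on the callus, clamped at saturation on the
  cell origin, no-flux elsewhere. The maximum principle holds by
  construction. The default $D = 0.001\ \mathrm{mm^2/day}$ was calibrated
  once so that the mean callus concentration of the default full-scale
  geometry reaches 0.90 of saturation on day 35, and is config-overridable.

The half-model boundary conditions are tied to the axis-on-the-left
convention, so literal mirror symmetry is only testable for the diffusion
step (whose boundaries are mask-defined); the elastic and fluid solves are
instead checked against dense, independently assembled oracles on tiny
grids.

## The update loop

Each day, in this order: solve elasticity and fluid; compute
$\gamma = \tfrac{2}{3}\sqrt{\sum(\Delta\varepsilon)^2}$ (the standard
octahedral shear strain; the source text cites but does not print the
formula) and $\nu = \sqrt{v_x^2+v_y^2}$; classify each callus pixel by the
left-closed $S$-interval; diffuse the stem cells; blend the material as

$$ X = (1-n)\,X_g + n\,X_d $$

between granulation properties $X_g$ and the differentiated phenotype's
properties $X_d$ (the saturation concentration is normalized to 1); and
smooth $E$, $\nu_p$, $k$ by averaging with up to the nine previous days'
blended values to damp day-to-day oscillation. The order of smoothing
after blending is this package's reading of the method description; the
original order is only shown in an unavailable supplement.

Two tables close the model, both config-overridable because the original
supplementary tables are unavailable; the defaults follow the established
mechano-regulation literature:

* $S$-intervals: resorption $S<0.01$, mature bone $0.01\le S<0.267$,
  immature bone $0.267\le S<1$, cartilage $1\le S<3$, fibrous $S\ge 3$.
  Boundary values belong to the interval they open (left-closed), so
  $S = 0.267$ is immature bone; `classifyPhenotype()` and the phase
  diagram share this rule.
* per-phenotype properties (`defaultMaterialTable()`): granulation
  0.2 MPa, fibrous 2 MPa, cartilage 10 MPa, immature bone 1 GPa, mature
  bone 6 GPa, with literature permeabilities; cortical/cancellous host
  bone 14.8/1.85 GPa; Ti-6Al-4V implant 110 GPa, $\nu_p = 0.3$,
  impermeable (the alloy is named in the source but its values are not
  printed — these are the literature standards). Resorption pixels get
  granulation-like low stiffness so they stay in the loop and can
  re-differentiate; whether the original implementation allows that
  reversal is unstated.

# The surrogate

Four learned components replace the per-day physics; all of them are
authored in base R (no deep-learning framework exists in the target
environment), with exact analytic gradients verified against finite
differences in the test suite.

* **Field net** (Network 1, `trainFieldNet()`): an encoder–decoder with
  inception-style 1/3/5-kernel blocks and skip connections maps the 4
  material channels ($\log_{10}E$, $\nu_p$, $\log_{10}k$, $n$ — the two
  decade-spanning channels are log-scaled before z-scoring) to the 6
  physical channels (three sorted principal strains, $v_x$, $v_y$, and the
  *next* day's $n$). Targets are z-scored per channel with training-split
  statistics; a zero-variance channel gets loss weight 0 (guard
  $10^{-8}$). Adam, early stopping with patience 20 epochs.
* **Pixel classifier** (Network 2, `trainPixelClassifier()`): an MLP
  (default 3 × 64) maps the 5 mechanical/fluid values at one callus pixel
  to the 5 phenotypes, trained with focal loss
  $-\alpha_c(1-p_t)^{\gamma_f}\log p_t$ against the strong class imbalance
  (mature bone dominates late days); default $\alpha_c$ = inverse class
  frequency, $\gamma_f = 2$.
* **Denoiser** (Network 3, `trainDenoiser()`): a U-Net consumes the
  one-hot phenotype map assembled from Network 2 plus a callus-mask
  channel and reproduces the simulator's map, removing singular pixels.
  It trains on two input families: Network 2's own predictions, and
  truth maps with a fraction of callus pixels randomly flipped — the
  canonical singular-pixel-removal task, which also teaches clean-map
  preservation.
* **Resorption forest** (`trainResorptionForest()`): resorption and
  mature bone sit in adjacent $S$-intervals and are the classic confusion
  of this workflow, so a bagged CART forest retrained on exactly that
  two-class subproblem corrects those pixels. Features are the 5 field
  values plus their 4-neighborhood means (the original feature set is not
  stated); only resorption/mature pixels may change, and only into each
  other.

**Day pairs.** A $(T{+}1)$-day history is recomposed into all
$\binom{T+1}{2}$ ordered day pairs (630 for days 0–35,
`makeDayPairs()`). The single-state interfaces of the networks consume
gap-1 pairs directly; how the original workflow feeds gap > 1 pairs into
single-step networks is not explained, so this package uses them as
curriculum augmentation — down-weighted ($1/\mathrm{gap}$) extra labels
for the classifier and noisier inputs for the denoiser — up to a
configurable `curriculumGap`. This interpretation is a design choice, not
the original mechanism.

**Split and seeds.** The 80/20 train/test split is by implant *case* (the
unit is unstated in the source; case-level prevents day-pair leakage
across the split, and the suite audits this). One master seed fans out
deterministically to the split and every component.

**Rollout** (`rollout()`): from the day-0 material alone, each day runs
field net → classifier → denoiser → forest → analytic blend with the
predicted $n$ → 9-step smoothing → next day's input. The analytic steps
are shared with the simulator, so surrogate error enters only through the
learned components.

# Explanation

Deep Taylor decomposition redistributes a predicted score backward layer
by layer. Hidden layers use the $z^+$ rule (relevance follows
positive-weight contributions of the non-negative post-ReLU activations);
the input layer uses the box-constrained $z^B$ rule with per-channel
bounds from the actual input. Biases take no relevance, so the propagated
total is conserved — the suite checks conservation to $10^{-3}$ relative
on random networks and against a hand-computed 3-neuron example. In the
U-Net, padding entries carry bounds $l = h = 0$ so no relevance leaks
into the padded frame.

Two analyses are built on top:

* **Dominant property / phase diagram** (`dominantProperty()`,
  `phaseDiagram()`): per callus pixel-day, the $(\gamma, \nu)$ point on
  log axes, its phenotype region, and the classifier-input channel with
  the largest relevance (ties broken by channel order; zero relevance is
  "undetermined"; pixels with $\gamma = 0$ or $\nu = 0$ are dropped and
  counted). Which network the original six-way attribution (including
  $n$) used is not stated; this package attributes over the classifier's
  five inputs by default and leaves the target network a config switch.
* **Geometry importance / segment swap** (`geometryImportance()`,
  `swapExperiment()`): per day, DTD on the field net with the summed
  positive callus-region output evidence as target, keeping the top 5%
  (configurable — no threshold is printed in the source) of pixels by
  total relevance. The swap experiment exchanges an axial segment between
  two designs, rolls out the originals and hybrids, and reports the
  final-day phenotype agreement outside the swapped rows — the
  operational test that the surrogate's attributions are local.

# What the synthetic world does and does not establish

The generator plus simulator *are* the data source: no external dataset
exists. The synthetic world reproduces the structural features the method
needs — heterogeneous stiffness spanning five decades, stimulus values
covering all five phenotype intervals on day 0, callus saturation
dynamics, thread-scale strain concentration — but it is a plane-stress
stand-in for an axisymmetric poroelastic model, with literature tables in
place of unavailable supplementary ones. A green test therefore
establishes that the pipeline reproduces *its own* simulator at reduced
scale, not that it reproduces the original commercial-solver numbers;
`replicationStudy()` reports the four headline metrics (held-out field
correlations, cross-case index correlations, final-day accuracy, per-
phenotype AUC) against the published bounds with pass/warn status rather
than asserting them.

# Numerical choices

* Sparse direct solves (Matrix package); dense-oracle agreement to
  $10^{-8}$ relative on ≤ 16 × 16 grids.
* "Outside" pixels get $E = 10^{-3}$ MPa so the stiffness matrix stays
  definite; the implant is impermeable exactly ($k = 0$, $v \equiv 0$).
* Standardization guards: $\sigma \ge 10^{-8}$; focal-loss probability
  clamp $10^{-8}$; DTD denominators $+10^{-12}$.
* Phenotype interval ties: left-closed, documented above.
* Geometry importance uses an exact top-$k$ threshold (sort-based), so
  tie behavior is reproducible.
* RNG: every stochastic entry point takes a seed and restores the
  caller's RNG state (`.withSeed`); histories and rollouts are bit-
  reproducible.

# Limitations

* Plane-stress, decoupled consolidation is not Biot poroelasticity; only
  the two stimuli the phenotype rule consumes are preserved.
* No contact/friction at the bone–implant interface, no viscoelasticity,
  no angiogenesis or cell proliferation beyond diffusion.
* The commercial implant geometries and the experimental comparison of
  the original study are out of scope; hybrids are parametric stand-ins.
* Desk-scale defaults (small grids, modest epochs) are sized for a single
  CPU; the full-scale replication protocol is hours, not minutes, and its
  bounds are reported, not asserted.
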