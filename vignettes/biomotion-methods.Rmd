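---
title: "Methods: two-pathway biological movement recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-pathway biological movement recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomotion)
```

## Overview

`biomotion` implements a biologically inspired human action recognition model
organized as two parallel streams, mirroring the ventral ("form") and dorsal
("motion") pathways of primate visual cortex:

* the **form pathway** learns, per action class, a sparse deformable template
  of Gabor wavelet elements (an *active basis model*, ABM) trained by the
  *shared sketch algorithm* (SSA);
* the **motion pathway** estimates dense bidirectional optical flow between
  consecutive frames and summarizes *where* motion energy concentrates via a
  time-dependent fuzzy division of the flow field into four quadrant cells.

The fuzzy division gates the candidate action classes to the dominant limb
group (upper-limb actions such as boxing/clapping/waving versus lower-limb
actions such as walking/jogging/running); a *synergetic neural network* (SNN)
then scores the gated classes by order parameters against melted action
prototypes, and a sequence label is taken by per-frame majority vote.

## Form pathway

### Gabor dictionary

The dictionary contains `n` orientations × `m` scales of even/odd Gabor pairs
(defaults n = 8, m = 2, 17 px kernels at the finest scale). Orientations are
the bar angles {kπ/n}; scale frequencies follow ω_i = ω₀/s^(i−1) with
ω₀ = π/2 rad/px and s = √2 by default, so successive scales differ by a
factor 2 in area. The literal scale rule printed in the source material
("ω = 2/i") is typographically ambiguous, so the progression is exposed as
two config parameters (`omega0`, `scale_step`) rather than hard-coded.
Kernels are DC-removed and ℓ2-normalized; the even/odd pair is orthogonal by
symmetry. Responses are quadrature magnitudes of zero-padded, center-anchored
correlation, computed by FFT over a linear-convolution pad (the test suite
pins this against a nested-loop oracle at 1e−10).

### Response transform

Raw magnitudes are squared, **whitened by one frame-level mean-square
statistic shared across all element maps**, and passed through a sigmoid
bounded by ζ (default 6). Two deliberate choices here:

* whitening is *not* per orientation map — normalizing each map by its own
  energy would equalize orientations and destroy the selectivity that the SSA
  selection step depends on;
* the whitening statistic is computed over the frame interior (excluding a
  half-kernel margin), because zero-padded border responses depend on the
  frame's DC level. With this choice template scores are invariant to
  additive intensity shifts to ~1e−6.

### Shared sketch algorithm

SSA greedily selects dictionary placements maximizing the *sum over training
frames* of locally max-pooled saturated responses, then suppresses all
placements within an inhibition radius (default: half the kernel size at the
selected scale) whose orientation lies within one dictionary step. Pooling
during *selection* is over location only; orientation perturbation applies at
match time. The reason is exactness rather than taste: pooled maps of
adjacent nominal orientations contain the same response maximum, so
selection with orientation pooling ties exactly and the chosen nominal
orientation would be arbitrary.

Element weights δ_i are the mean pooled response at selection; the score is a
log-likelihood ratio M = Σ δ_i·h_i − Σ log Φ(δ_i), where log Φ(δ) is
estimated as log of the empirical mean of exp(δ·h) over a pool of background
responses sampled outside the selected elements (capped at 20 000 samples,
deterministically strided). This follows the exponential-family template
matching construction; the natural parameter is folded into δ.

Matching scans all template translations over the frame lattice; ties break
at the smallest row then column shift. Localization of a template is reliable
perpendicular to its dominant structure; a bar much longer than the template
support is ambiguous along its own axis (aperture effect), which the tests
respect by using short bars.

## Motion pathway

### Variational bidirectional flow

`estimate_flow` minimizes, per direction,

E = Σ E_data + ρ·E_symmetric + ξ·E_smooth,

with Charbonnier (robust ℓ1-like) penalties: brightness constancy under
Gaussian pre-smoothing (σ = 0.8), a symmetric coupling term
‖w_fwd(x) + w_bwd(x + w_fwd(x))‖ tying the two directions together, and
total-variation-like smoothness. Optimization is coarse-to-fine (factor 0.5
pyramid, ≥ 12 px coarsest) with outer warping iterations and inner
reweighting, the per-pixel 2×2 linearized system solved in closed form inside
weighted Jacobi sweeps. Numerical choices that mattered:

* **IRLS weight epsilons** for the smoothness and coupling terms are softer
  (0.05) than the energy's Charbonnier ε (1e−3): weight stiffness ~1/ε at
  zero residual stalls the Jacobi sweeps and, for the coupling term, pins
  both fields at the zero initialization;
* the coupling is **deferred for the first outer iteration of each level** —
  at zero initialization it is a consistency penalty about the wrong point;
* ρ is small (0.05) so the coupling regularizes consistency without
  overpowering the data term on smooth textures;
* per-warp increments are clipped to ±1 px, the validity radius of the
  brightness linearization;
* the Jacobi sweep count is scaled down at finer pyramid levels (halved per
  level, floor 15): the slow-to-converge uniform flow modes are resolved at
  the cheap coarse levels, and the finest level only needs local correction;
* total energy is evaluated after every outer iteration and an increasing
  step is rejected, so the reported fields never have higher energy than the
  zero-flow initialization.

Layer visibility masks are an input contract (default all-ones); no
segmentation is inferred. The "compressed" flow is SAD block matching with
integer displacements, ties broken by smallest displacement norm then
row-major order, and — deliberately — no smoothing.

### Fuzzy flow division

The frame is split into quadrants C1..C4 at H/2 and W/2. Per frame, the
location of maximal flow speed is fuzzified through triangular memberships
peaking at the cell centers (H/4, 3H/4, W/4, 3W/4) and vanishing at cell
edges; per cell the x- and y-components aggregate by max. The boundary
constants printed in the source are corrupted; this canonical cell-center
geometry is the implemented reading. An all-zero flow returns uniform
memberships (0.25) and no winner, so static frames cannot flip the winner.

Accumulation over time uses the memory coefficient
η = ±1/(k+β), where k counts frames since the winner cell changed (capped at
N). Defaults τ = 0.1 s, β = β′ = 2, N = 3 follow the stated operating point
of the source system. Two readings were genuinely open:

* **branch direction**: the literal condition ("accumulate when the
  instantaneous membership has *not* increased") keeps every accumulated
  membership at zero forever — at cold start the instantaneous winner
  membership always exceeds the stored 0, so the negative branch would fire
  indefinitely and the gate would be inert. We implement the functional
  reading: accumulate (+1/(k+β)) while the winner's instantaneous membership
  confirms the stored value, adjust down (−1/(k+β′)) when it drops below it.
* **non-winner cells**: the source defines η only for the winner. Without
  decay, stale cells would hold the gate open forever; non-winners therefore
  decay toward 0 at rate 1/(k+β′).

Upper/lower limb scores are maxima over the corresponding cell pairs
(left/right aggregation exists but is off by default). The gate keeps only
the dominant group's classes when |μ_upper − μ_lower| exceeds the margin
(default 0.05) and keeps *all* classes under ambiguity — it can never return
an empty set.

## Synergetic classifier

Samples are flattened, centered and ℓ2-normalized. The adjoint of the
prototype matrix V is either the Moore-Penrose pseudoinverse (V'V)⁻¹V' —
the only reading consistent with the required biorthogonality
v_k⁺v_j = δ_kj, the printed formula being corrupted — or the MPOD-penalized
class adjoint E(V'V + P₁O + P₂I)⁻¹V', with O read as the all-ones matrix and
E the block row-selector (one row of ones per class). Classification takes
the argmax order parameter ε = V⁺q, the fixed point of the winner-take-all
competition dynamics; the iterative dynamics themselves are out of scope.

"Melting" synthesizes several samples of one class into one template: the
single-class MPOD row, renormalized. It is exact on duplicates and singleton
inputs, and on noisy variants of a base pattern it correlates with the base
more strongly than any single variant. Action prototypes are built in two
stages: melt across subjects within each of the five snippets, then melt the
five snippet prototypes into the final prototype. Both the five snippet
prototypes and the final one are retained; classification scores against the
retained set by default (`snn$prototype_mode = "retained"`), with a
`"final"` mode available — the source does not state which set enters the
final decision.

## Pipeline

Frames are processed in temporal order only (shuffling frames destroys the
biological percept being modeled); `select_frames` takes an evenly strided
subset of at least three frames. Motion guidance of SSA is realized as an
ROI: the bounding box of pixels whose flow speed exceeds the 0.9 quantile,
dilated by 4 px; training restricts element centers to the union ROI of all
training frames, and matching restricts candidate shifts to the per-frame
ROI. The per-frame decision is gate-then-SNN: order parameters restricted to
the gated classes; the ABM match contributes localization only (a config
flag can include it, off by default — another point the source leaves open).
Sequence labels are majority votes, ties broken by summed order parameters.
Training supports vertical-axis mirror augmentation of the training map.

## Synthetic fixtures and what green tests establish

No external benchmark footage is used. Three seeded generators stand in:

* **oriented bars** (anti-aliased, plus i.i.d. Gaussian noise, σ = 0.1 in
  the training tests) exercise dictionary selectivity and SSA;
* **translation pairs**: heavily blurred white noise translated *toroidally*,
  so ground-truth flow is exactly (dx, dy) at every pixel — border ambiguity
  is removed from the acceptance checks by construction;
* **action sequences**: a static trunk blob plus one appendage blob
  oscillating sinusoidally (amplitude 8 px, period 8 frames by default),
  hard-confined to the upper or lower half-frame, with optional static
  clutter and per-frame noise.

Defaults (64×64 frames, 8 frames/sequence, 5 training subjects per class for
the end-to-end benchmark) were chosen once as a desk-scale stand-in for
downsampled surveillance-style footage. The generators emulate limb-localized
motion energy and style variation across seeds; they do **not** emulate
camera shake, scale variation, articulated kinematics, background motion, or
inter-class confusion between actions *within* the same limb group. A green
end-to-end test therefore establishes that the machinery is wired correctly
and that gating plus prototype matching recovers constructed class structure
— not that any benchmark accuracy transfers.

## Known limitations

* No rotation or viewpoint invariance; single actor per frame.
* Flow defaults are tuned for small displacements (≤ ~4 px/frame at 64 px
  frames); larger motion needs deeper pyramids.
* The fuzzy division is 2×2; finer divisions would be needed for actions
  distinguished within a limb group by location.
* Pure-R implementation: practical for desk-scale frames (≤ ~200 px), not
  for real-time use.
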