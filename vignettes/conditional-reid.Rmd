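---
title: "Behaviour- and orientation-conditioned re-identification of pied cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour- and orientation-conditioned re-identification of pied cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowreid)
```

## The problem and the model

Holstein-Friesian cattle carry pied coats whose patch patterns are highly
individual but **not bilaterally symmetric**: the left and right flank of one
animal are, for identification purposes, two unrelated patterns. A camera
watching a free-moving group therefore sees, for each animal, a family of
appearances indexed by its *behaviour* $\kappa \in \{ll, lr, s\}$
(lying-left, lying-right, standing) and its *orientation* $\theta \in
[0^\circ, 360^\circ)$, the spine angle in the image plane (tail implant
towards withers; in this package $0^\circ$ points along $+x$ and positive
angles turn towards $+y$). Lying-left exposes mostly the right flank,
lying-right the left flank, and a standing animal exposes the flank
determined by its viewing side. Any re-identification scheme that ignores
this will, sooner or later, compare a left flank against right-flank
references and fail for reasons no descriptor can fix.

The pipeline implemented here has three parts.

**Embedding network.** `build_network()` constructs a small
encoder: a two-stage separable-convolution stem, nine inception modules
(four parallel branches — $1{\times}1$, separable $3{\times}3$, separable
$5{\times}5$, and $3{\times}3$ max-pool followed by $1{\times}1$ — each
producing $c$ channels, concatenated to $4c$), max pooling after the stem
and after modules 2 and 4, instance normalisation at three points (stem,
module 3, module 6), an adaptive average pool after module 6 (so inputs of
any size reach a fixed grid), global average pooling, a linear map to 32
dimensions and L2 normalisation. All convolutions except the $1{\times}1$
reducers are separable and all use replicate padding. The channel schedule
of the default configuration is $(64, 128, 128, 256, 256, 512, 512, 512,
512)$ with stem widths $32$ and $100$; this transcription is pinned by the
budget of $1160\,$k trainable parameters that `count_parameters()`
reproduces. In this package's accounting a separable convolution carries a
bias on both its depthwise and its pointwise part (so a $3{\times}3$
separable block $c_1 \to c_2$ has $9c_1 + c_1 + c_1 c_2 + c_2$ parameters),
and the three instance-normalisation layers have trainable affine
parameters. Scaling the final depth $d$ scales the whole schedule
proportionally ($c = d/4$ per branch, $d$ divisible by 4), which is how the
reduced `final_depth = 64` test configuration is derived.

**Histogram loss.** For a batch of embeddings with identity labels, the
loss is a differentiable estimate of
$P(s_{\text{neg}} \ge s_{\text{pos}})$: cosine similarities of all positive
(same identity) and negative pairs are soft-assigned by linear interpolation
to 201 nodes spanning $[-1, 1]$ (step 0.01), and the loss is
$\sum_r h^-_r \, H^+_r$ with $H^+$ the cumulative positive histogram. The
201-node grid is the conventional choice for this loss; the estimate agrees
with the brute-force pair-rank probability to within one bin width, which
the test suite asserts.

**Conditional gallery search.** A reference database stores
$(\mathbf{b}, \text{identity}, \kappa, \theta)$ entries. A query with
behaviour $i$ and orientation $j$ is compared only against entries with
$\kappa = i$ and circular distance $d(\theta, j) \le 45^\circ$. Because all
embeddings are unit vectors, all $m$ similarities are one matrix product
$B^\top \mathbf{a}$. If $m < m_{\min} = \lceil N / (16B) \rceil$ — a quarter
of the subset size expected under a homogeneous gallery of $N$ entries and
$B$ behaviours — the window widens symmetrically by $2.5^\circ$ per side
until the quota is met or the circle is covered. A KNN vote over the
$k$ most similar entries ranks identities by vote count, ties broken by the
mean similarity of the voting neighbours; identities outside the top-$k$
follow, ordered by their best similarity.

## Training procedure

Batches contain 25 unique instances: five identities with five instances
each, all with one behaviour and orientations inside
$[j - 22.5^\circ, j + 22.5^\circ]$ around a uniformly drawn centre $j$; the
window grows in $5^\circ$ steps of total width only when some identity
cannot fill its quota. The *unconditioned* baseline redraws behaviour and
orientation independently per slot, keeping the marginal distribution but
destroying within-batch homogeneity. Before training, left-right mirroring
doubles the identity count: the mirrored instance is a **new** identity with
behaviour ll $\leftrightarrow$ lr and orientation $\theta \mapsto
(180^\circ - \theta) \bmod 360^\circ$. Images are augmented with colour
jitter, shear, rotations within $\pm 10^\circ$, scale jitter, and a
horizontal or vertical black band occluding up to 40 % of the area.
Optimisation is Adam (learning rate $10^{-3}$) on the histogram loss;
gradients flow through a hand-derived backward pass for every layer,
verified against central finite differences in the test suite.

From a configurable epoch onward (default 51, i.e. inactive in the short
desk-scale runs used here) behaviour sampling probabilities track validation
rank-1 accuracy: $p_i \propto 1 - \mathrm{acc1}_i$, clipped from below at
$1/(2|B|) = 1/6$ and renormalised over the unclipped behaviours. The clipped
set only grows during renormalisation, so the update terminates; with all
behaviours solved ($\mathrm{acc1} = 1$) it falls back to uniform.

This conditioning means the network never has to merge a cow's two flanks
into one cluster; each (identity × behaviour × orientation-bin) cell acts as
a *fictive individual*. With $45^\circ$ bins, mirroring, and the strongly
bimodal orientations of lying animals (8 effective bins standing, 2 for each
lying behaviour), one actual animal contributes $2 \times (8 + 2 + 2) = 24$
fictive individuals — `fictive_individual_count()` implements exactly this
accounting.

## The multi-task pose/behaviour loss

The orientation and behaviour metadata come, upstream, from a pose estimator
whose output stack holds 6 keypoint-probability channels, 24 association
channels and 3 behaviour channels (softmax over ll/lr/s per pixel). The
package implements the loss and its decoding against any backbone producing
such a stack:

$$L = \beta_1 \tfrac{1}{wh|P|}\textstyle\sum_{i \in P} \lVert \hat Y_i - Y_i \rVert^2
  + \beta_2 \tfrac{1}{1 + \sum_{i \in A} \lVert 1_{Y_i \ne 0} \rVert}
    \textstyle\sum_{i \in A} \lvert 1_{Y_i \ne 0} \odot (\hat Y_i - Y_i) \rvert^{\gamma}
  - \beta_3 \tfrac{1}{1 + \sum_{i \in B} \lVert 1_{Y_i \ne 0} \rVert}
    \textstyle\sum_{i \in B} Y_i \log(\hat Y_i + 10^{-10}).$$

Ground-truth behaviour channels are 1 exactly where the central-keypoint
(withers) heatmap exceeds 0.2 and the animal displays that behaviour; with
several animals, per-animal contributions accumulate and clip to $\{0,1\}$.
`adapt_betas()` rescales the three terms so each averages $1/3$ (mean total
1). The exponent of the association term is configurable with default
$\gamma = 2$, i.e. a masked squared error consistent with the location term.
Orientation estimation takes the spine vector from tail implant to withers,
falling back to the hip midpoint and then to a single hip; segments
associate to a skeleton only when exactly one detected withers lies inside
the mask. Behaviour decoding averages the softmaxed channels over the
central-heat $> 0.2$ region (falling back to the withers pixel), with ties
broken by the fixed channel order (ll first).

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces instance segments with the statistical
structure the method exploits:

- **Coat classes** follow the six-way scheme (r/b under 20 % white, rw/bw
  between 20 % and 80 %, wr/wb above 80 %) with the default herd mix
  `r 7, b 6, rw 12, bw 11, wr 10, wb 2` over 48 animals; per-identity white
  fractions are drawn uniformly inside the class range.
- **Flank textures** are thresholded smoothed-noise fields ("blobs") at a
  patch length scale (default canvas/6), thresholded at the empirical
  quantile matching the white fraction; the two flanks use independent
  seeds, so opposite-flank views of one animal are as unrelated as two
  different animals of the same class.
- **Flank visibility**: lying-left renders the right flank, lying-right the
  left; a standing animal shows its left flank for $\sin\theta > 0$ and its
  right for $\sin\theta < 0$, with a linear blend within $15^\circ$ of the
  head-on/tail-on views and body-length foreshortening
  $0.45 + 0.55\,\lvert \sin\theta \rvert$.
- **Orientations** are uniform for standing animals and bimodal for lying
  ones (wrapped-normal modes $180^\circ$ apart, default $45^\circ/225^\circ$
  with $20^\circ$ spread) — lying cattle align with pen structures, which is
  exactly why lying behaviours occupy only two effective orientation bins.
- **Occlusion** cuts an axis-aligned band (up to 40 % of the canvas, the
  same cap as the training augmentation; dataset default draws from
  $[0, 0.2]$).
- **Mirroring** is exact: a mirrored identity's render equals the flipped
  parent render to floating-point rounding, because the affine resampler
  uses centred coordinates and therefore commutes with index-reversal flips.

The generator does **not** emulate photorealistic shading, night-vision
imagery, perspective distortion, multi-animal occlusion geometry, or the
within-animal correlation of patch *style* across the body (patch size and
edge character are similar across a real animal's flanks even though the
patterns differ; the generator exposes independent seeds only). Passing
tests therefore demonstrate that the pipeline exploits flank structure as
designed — not that any particular accuracy transfers to camera data.

## Numerical and design choices

- **Orientation convention** ($0^\circ = +x$, positive towards $+y$, range
  $[0, 360)$ half-open) is fixed package-wide; the mirror map is
  $\theta \mapsto (180 - \theta) \bmod 360$. Circular distance is
  $d(a,b) = \min(|a-b|, 360-|a-b|)$; window membership is inclusive.
- **$k$ rule.** A subset-majority vote ($k = m$) ignores similarity
  entirely and degenerates to "largest subset identity wins"; the default is
  $k = \lceil \sqrt{m} \rceil$, the common KNN heuristic, with the literal
  $k = m$ available via `k_rule = "all"`.
- **$m_{\min}$ rounding**: ceiling, floored at 1 (the rule yields
  non-integers).
- **Inference window expansion** reuses the training sampler's step
  ($2.5^\circ$ per side).
- **Joint assignment probabilities** are KNN vote shares with additive
  $1/m$ smoothing (so unvoted identities keep nonzero probability and the
  log-product objective stays finite); the optimal one-to-one assignment is
  found by an $O(n^3)$ Hungarian algorithm, validated against exhaustive
  permutation search.
- **Splitting protocol**: test identities are 6 random animals from each of
  the two most abundant classes (rw, bw), so evaluation cannot reduce to
  classifying the amount of white; instances split per-instance Bernoulli
  75/25 into reference/evaluation and 90/10 into training/validation. Seen
  identities (the remaining rw/bw training animals) carry an additional
  seen-reference/seen-evaluation role — they belong to both the training
  partition and the seen-evaluation protocol, so the package records the
  primary partition in `split` and the role in `seen_role`. The
  overall-evaluation protocol (`overall_split()`) instead takes an exact
  25 % of each (identity, behaviour) stratum.
- **Confidence intervals** are exact Clopper-Pearson (beta quantiles),
  chosen for small per-behaviour counts.
- **Degenerate inputs** fail loudly: empty masks, unknown behaviours or
  coat labels, orientations outside $[0,360)$, occlusion beyond the 40 %
  cap, galleries without the query behaviour, $k > m$, more simultaneous
  queries than identities.

## Desk-scale problem sizes

The package's experiments are sized for a workstation CPU: synthetic canvases
of 64 px, the `final_depth = 64` network (~30 k parameters), training runs of
5 epochs × 50 batches, and herds of 12–20 identities with 24–50 instances
each. The conditioning experiment in the acceptance suite uses 20 identities
with 40 reference and 10 query instances each over ten seeded replicates.
These sizes are the package's reference conditions for its own tests; the
default 512-px, 1160 k-parameter configuration is the production network.

## Known limitations

- Training the pose/behaviour backbone itself is out of scope; the package
  implements the loss, ground truth, decoding and geometry against a
  configurable stack, and the synthetic pipeline supplies orientation and
  behaviour as metadata.
- The embedding trainer is a plain Adam loop without learning-rate
  schedules, checkpoint averaging or early stopping; runs of hundreds of
  epochs on real imagery would want those.
- The generator's identities are exchangeable; real herds have near-duplicate
  animals and family structure that make the task harder in ways the
  synthetic tests do not measure.
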