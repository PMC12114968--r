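# cowreid

Re-identification of Holstein-Friesian cattle from camera images, without
requiring a standardised pose.

Most visual re-identification systems for cattle assume a fixed viewpoint
(top-down, or a race-way side view). In group housing the animals lie, stand
and turn freely, and the pied Holstein coat makes the problem harder than it
looks: the left and right flank of one animal carry *independent* patch
patterns, so a left-flank query matched against right-flank reference images
fails no matter how good the descriptor is. `cowreid` implements an
embedding-based re-identification pipeline that treats the animal's
**behaviour** (lying-left `ll`, lying-right `lr`, standing `s`) and
**orientation** (spine angle θ in the image plane, degrees in [0, 360)) as
first-class metadata:

- a lightweight inception-style CNN (nine modules, separable convolutions,
  ~1.16 M parameters) maps a masked instance segment to a 32-dimensional
  L2-normalised embedding **a**; similarity between unit embeddings is the
  cosine, s(**a**, **b**) = **a**·**b**;
- the network is trained with the **histogram loss** — a differentiable
  estimate of P(s_neg ≥ s_pos) over a batch — on batches of 5 identities ×
  5 instances that all share one behaviour and a narrow orientation window
  [j − 22.5°, j + 22.5°], widened in 5° steps only when an identity cannot
  fill its quota; left-right mirroring doubles the identity count
  (ll ↔ lr, θ → 180° − θ) and behaviours whose validation rank-1 accuracy
  lags are sampled proportionally to 1 − acc1, floored at 1/6;
- at inference, a query with behaviour κ = i and orientation θ = j is ranked
  only against reference embeddings with the same behaviour and θ ∈
  [j − 45°, j + 45°] (circular); if fewer than
  m_min = ⌈N/(16·B)⌉ references qualify — 25 % of the expected subset
  under a homogeneous gallery — the window expands symmetrically; a KNN
  vote over the k = ⌈√m⌉ nearest references ranks candidate identities;
- when several animals share a frame, `joint_reidentify()` assigns each a
  *distinct* identity by maximising the joint probability (Hungarian
  assignment over smoothed vote shares);
- evaluation is the CMC curve: rank-n accuracy per behaviour with exact
  Clopper-Pearson 95 % intervals, averaged over behaviours.

Because the method's claims are about the *statistical structure* of the
problem rather than any one image collection, the package ships a procedural
generator of pied-coat instance segments (`generate_dataset()`): each
identity draws a coat class (r/b/rw/bw/wr/wb by white fraction) and two
independent thresholded-noise flank textures; behaviour and orientation
decide which flank is rendered, exactly the confound the conditional gallery
search is designed to remove. All tests and experiments run on this
generator — no camera data required.

## Worked example

```r
library(cowreid)

# a small synthetic herd: 8 animals, 30 segments each
herd <- generate_dataset(n_ids = 8, per_id = 30, seed = 42, canvas_px = 64)

# train the reduced-depth embedding network briefly
emb <- train_embedder(herd,
                      network_cfg = network_config(input_px = 64,
                                                   final_depth = 64),
                      epochs = 3, batches_per_epoch = 30, seed = 1,
                      verbose = TRUE)
#> epoch 1/3  mean histogram loss 0.4449
#> epoch 2/3  mean histogram loss 0.4195
#> epoch 3/3  mean histogram loss 0.4075

# reference gallery: first 25 instances per animal; queries: the last 5
by_id <- split(seq_len(nrow(herd$metadata)), herd$metadata$identity)
ref <- unlist(lapply(by_id, head, 25)); qry <- unlist(lapply(by_id, tail, 5))
E <- predict(emb, herd$segments)
db <- reference_database(E[ref, ], herd$metadata$identity[ref],
                         herd$metadata$behaviour[ref],
                         herd$metadata$orientation_deg[ref])
print(db)
#> cow reference database: 200 embeddings (32-d), 8 identities
#> ll lr  s
#> 59 51 90

# re-identify the queries with metadata conditioning
preds <- lapply(qry, function(i) {
  reidentify(db, list(embedding = E[i, ],
                      behaviour = herd$metadata$behaviour[i],
                      orientation_deg = herd$metadata$orientation_deg[i]))
})
ev <- rank_n_accuracy(preds, herd$metadata$identity[qry],
                      herd$metadata$behaviour[qry], n_max = 3)
print(ev$averaged)
#>   n  accuracy
#> 1 1 0.4111111
#> 2 2 0.5622222
#> 3 3 0.6762963
```

The histogram loss falls as training proceeds, and after only 90 batches the
behaviour-averaged rank-1 accuracy over 40 held-out queries is 0.41 against
a chance level of 1/8 = 0.125 — the herd mix deliberately includes
nearly-monochrome `r` and `b` animals, which at 64 px are genuinely hard.
Longer training (the defaults are 5 epochs × 50 batches) and the
conditioning of the gallery search raise this substantially; the
acceptance experiment in `tests/testthat/test-acceptance.R` quantifies the
conditioned-vs-unconditioned gap over ten seeded replicates.

A thin command-line wrapper (`inst/cli/cowreid.R`) exposes the same pipeline
as subcommands `simulate`, `train-embed`, `build-ref`, `reid` (with
`--no-metadata` for the unconditioned protocol and `--joint` for the unique
assignment), `evaluate` and `split`.

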