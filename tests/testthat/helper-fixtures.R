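# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Small synthetic dataset shared across tests (12 identities, herd coat mix).
small_dataset <- function() {
  memo("small_dataset",
       generate_dataset(n_ids = 12, per_id = 24, seed = 101, canvas_px = 64))
}

# A briefly trained reduced-depth embedder on the small dataset.
trained_embedder <- function() {
  memo("trained_embedder", {
    train_embedder(small_dataset(),
                   network_cfg = network_config(input_px = 64, final_depth = 64),
                   epochs = 5, batches_per_epoch = 20, seed = 202)
  })
}

# Reduced-depth untrained network for shape/determinism checks.
tiny_network <- function() {
  memo("tiny_network",
       build_network(network_config(input_px = 64, final_depth = 64), seed = 7))
}

# Metadata table shaped like the herd composition (counts 7,6,12,11,10,2 over
# 48 identities), instances only as rows, no rendered images.
herd_metadata <- function(per_id = 10, seed = 5) {
  memo(sprintf("herd_meta_%d_%d", per_id, seed), {
    counts <- c(r = 7, b = 6, rw = 12, bw = 11, wr = 10, wb = 2)
    ids <- sprintf("id%02d", seq_len(sum(counts)))
    coat <- rep(names(counts), times = counts)
    withr::with_seed(seed, {
      data.frame(
        file = sprintf("f%04d.png", seq_len(length(ids) * per_id)),
        identity = rep(ids, each = per_id),
        coat_class = rep(coat, each = per_id),
        behaviour = sample(c("ll", "lr", "s"), length(ids) * per_id,
                           replace = TRUE),
        orientation_deg = runif(length(ids) * per_id, 0, 360),
        stringsAsFactors = FALSE
      )
    })
  })
}

# Random unit-norm embeddings.
runit <- function(n, d = 32) {
  e <- matrix(rnorm(n * d), n, d)
  e / sqrt(rowSums(e^2))
}
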