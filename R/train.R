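# Embedding-network training: Adam on the histogram loss over conditional
# (or unconditional) 5-identities x 5-instances batches.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the embedding network on a segment dataset
#'
#' Batches of 25 instances (five identities, five instances each) are drawn
#' either conditionally -- all instances of a batch share one behaviour and a
#' narrow orientation window -- or unconditionally, and the network is
#' optimised with Adam on the histogram loss.  Mirroring (which doubles the
#' identity count), photometric/geometric augmentation and adaptive behaviour
#' sampling follow the training recipe of the re-identification method.
#'
#' @param dataset a `cow_dataset`.
#' @param network_cfg a [network_config()].
#' @param epochs,batches_per_epoch training schedule.
#' @param lr Adam learning rate.
#' @param conditioned use behaviour/orientation-conditional batches.
#' @param mirror double the identities by left-right mirroring.
#' @param augment apply photometric/geometric augmentation.
#' @param input_px network input size (defaults to the config's).
#' @param seed master seed; every random draw derives from it.
#' @param adapt_from epoch from which behaviour-sampling probabilities track
#'   validation rank-1 accuracy (default 51, i.e. off for short runs).
#' @param adapt_every cadence (epochs) of the behaviour-probability update.
#' @param val_fraction fraction of instances held out per identity for the
#'   adaptive-sampling evaluation.
#' @param verbose print per-epoch mean loss.
#' @return object of class `cow_embedder`: list with `network`, `history`
#'   (per-batch losses), `state` (behaviour sampling state), `config`.
#' @export
train_embedder <- function(dataset, network_cfg = network_config(input_px = 64,
                                                                 final_depth = 64),
                           epochs = 5L, batches_per_epoch = 50L, lr = 1e-3,
                           conditioned = TRUE, mirror = TRUE, augment = TRUE,
                           input_px = NULL, seed = 1L, adapt_from = 51L,
                           adapt_every = 10L, val_fraction = 0.1,
                           verbose = FALSE) {
  input_px <- input_px %||% network_cfg$input_px
  train_ds <- if (mirror) mirror_augment(dataset) else dataset
  net <- build_network(network_cfg, seed = seed)
  opt <- adam_init(net$params)
  state <- sampling_state()
  history <- numeric(0)
  val_idx <- NULL
  if (adapt_from <= epochs) {
    val_idx <- withr::with_seed(derive_seed(seed, 900L), {
      unlist(lapply(split(seq_len(nrow(train_ds$metadata)),
                          train_ds$metadata$identity), function(ix) {
        sample(ix, max(1L, round(length(ix) * val_fraction)))
      }), use.names = FALSE)
    })
  }
  for (ep in seq_len(epochs)) {
    ep_losses <- numeric(batches_per_epoch)
    for (bt in seq_len(batches_per_epoch)) {
      bseed <- derive_seed(seed, ep * 10000L + bt)
      batch <- if (conditioned) {
        sample_conditioned_batch(train_ds, state, seed = bseed)
      } else {
        sample_unconditioned_batch(train_ds, seed = bseed, state = state)
      }
      segs <- train_ds$segments[batch$indices]
      if (augment) {
        segs <- lapply(seq_along(segs), function(k) {
          augment_image(segs[[k]], seed = derive_seed(bseed, k))
        })
      }
      imgs <- lapply(segs, preprocess_segment, n = input_px)
      b <- stack_batch(imgs)
      fwd <- network_forward(net, b$x, b$h, b$w, b$n, keep_cache = TRUE)
      labels <- train_ds$metadata$identity[batch$indices]
      hl <- histogram_loss(fwd$emb, labels, gradient = TRUE)
      grads <- network_backward(net, fwd, hl$grad)
      upd <- adam_step(net$params, grads, opt, lr = lr)
      net$params <- upd$params; opt <- upd$state
      ep_losses[bt] <- hl$loss
    }
    history <- c(history, ep_losses)
    if (verbose) {
      message(sprintf("epoch %d/%d  mean histogram loss %.4f",
                      ep, epochs, mean(ep_losses)))
    }
    if (!is.null(val_idx) && ep >= adapt_from && (ep - adapt_from) %% adapt_every == 0) {
      acc1 <- validation_rank1(net, train_ds, val_idx, input_px, seed)
      state <- update_behaviour_probs(acc1, state = state)
    }
  }
  structure(list(network = net, history = history, state = state,
                 config = list(epochs = epochs,
                               batches_per_epoch = batches_per_epoch,
                               lr = lr, conditioned = conditioned,
                               mirror = mirror, augment = augment,
                               input_px = input_px, seed = seed)),
            class = "cow_embedder")
}

# Rank-1 accuracy per behaviour on a validation subset, using the remaining
# training instances as the reference gallery.
validation_rank1 <- function(net, ds, val_idx, input_px, seed) {
  ref_idx <- setdiff(seq_len(nrow(ds$metadata)), val_idx)
  ref_emb <- embed_instances(net, ds$segments[ref_idx], input_px)
  db <- reference_database(ref_emb, ds$metadata$identity[ref_idx],
                           ds$metadata$behaviour[ref_idx],
                           ds$metadata$orientation_deg[ref_idx])
  val_emb <- embed_instances(net, ds$segments[val_idx], input_px)
  hits <- list(ll = logical(0), lr = logical(0), s = logical(0))
  for (k in seq_along(val_idx)) {
    i <- val_idx[k]
    q <- list(embedding = val_emb[k, ],
              behaviour = ds$metadata$behaviour[i],
              orientation_deg = ds$metadata$orientation_deg[i])
    r <- reidentify(db, q)
    hit <- r$ranking$identity[1] == ds$metadata$identity[i]
    hits[[q$behaviour]] <- c(hits[[q$behaviour]], hit)
  }
  vapply(BEHAVIOURS, function(b) {
    if (length(hits[[b]]) == 0) 1 else mean(hits[[b]])
  }, numeric(1))
}

#' @export
print.cow_embedder <- function(x, ...) {
  cat("cow embedder\n")
  print(x$network)
  cat(sprintf("  trained           : %d batches, final-epoch mean loss %.4f\n",
              length(x$history),
              mean(utils::tail(x$history, x$config$batches_per_epoch))))
  cat("  batch sampling    :",
      if (x$config$conditioned) "behaviour/orientation conditioned"
      else "unconditioned", "\n")
  invisible(x)
}

#' Embeddings for new segments from a trained embedder
#'
#' @param object a `cow_embedder`.
#' @param segments list of `cow_segment`s.
#' @param ... unused.
#' @return matrix of unit-norm embeddings, one row per segment.
#' @export
predict.cow_embedder <- function(object, segments, ...) {
  embed_instances(object$network, segments, object$config$input_px)
}

#' Save / load a trained embedder
#'
#' Weights go to a flat binary array (`weights.bin` + JSON sidecar); the
#' network configuration and training metadata to `embedder.json`.
#'
#' @param embedder a `cow_embedder`.
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
save_embedder <- function(embedder, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  P <- embedder$network$params
  write_array_bin(unlist(P, use.names = FALSE), file.path(dir, "weights.bin"))
  shapes <- lapply(P, function(p) if (is.matrix(p)) dim(p) else length(p))
  meta <- list(config = unclass(embedder$network$cfg),
               train = embedder$config,
               history = embedder$history,
               behaviour_probs = as.list(embedder$state$behaviour_probs),
               shapes = shapes)
  jsonlite::write_json(meta, file.path(dir, "embedder.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_embedder
#' @export
load_embedder <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "embedder.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(network_config, meta$config[c("input_px", "embed_dim",
                                               "pool_to")] |>
                   c(list(channel_schedule = meta$config$channel_schedule,
                          stem_channels = meta$config$stem_channels)))
  flat <- read_array_bin(file.path(dir, "weights.bin"))
  P <- list()
  off <- 0L
  for (nm in names(meta$shapes)) {
    sh <- meta$shapes[[nm]]
    len <- prod(sh)
    v <- flat[(off + 1):(off + len)]
    P[[nm]] <- if (length(sh) == 2) matrix(v, sh[1], sh[2]) else v
    off <- off + len
  }
  net <- structure(list(cfg = cfg, params = P), class = "cow_network")
  state <- sampling_state(unlist(meta$behaviour_probs))
  structure(list(network = net, history = meta$history, state = state,
                 config = meta$train),
            class = "cow_embedder")
}
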