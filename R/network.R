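# Lightweight inception-style embedding network.
#
# Topology: a two-stage separable-convolution stem, nine inception modules
# (four parallel branches of c channels each -- 1x1, separable 3x3, separable
# 5x5, and 3x3-maxpool + 1x1 -- concatenated to 4c), max pooling after the
# stem and after modules 2 and 4, three instance-normalisation layers (stem,
# module 3, module 6), an adaptive average pool after module 6 so inputs of
# any size reach a fixed spatial grid, then global average pooling, a linear
# map to the embedding dimension and L2 normalisation.  All convolutions are
# separable except the 1x1 layers inside the inception modules; all use
# replicate padding.
#
# Tensors are (n*h*w) x channels matrices (see src/kernels.cpp for the
# layout); 1x1 convolutions are therefore single BLAS products.

# Channel schedule transcribed for the default (512 px, final depth 512)
# configuration; scaled proportionally for other final depths.
BASE_SCHEDULE <- c(64, 128, 128, 256, 256, 512, 512, 512, 512)
BASE_STEM <- c(32, 100)
BASE_FINAL <- 512

#' Embedding network configuration
#'
#' @param input_px preferred square input size in pixels (any size is
#'   accepted at inference thanks to the adaptive pooling layer).
#' @param final_depth output depth of the last inception module; the whole
#'   channel schedule scales proportionally with it (must be divisible by 4).
#' @param embed_dim embedding dimensionality (default 32).
#' @param pool_to spatial size the adaptive average pool maps to after module
#'   six; defaults to `input_px / 16`, the size a default input reaches there.
#' @param channel_schedule optional explicit 9-vector of module output depths
#'   (each divisible by 4); overrides `final_depth` scaling.
#' @param stem_channels optional explicit 2-vector of stem widths.
#' @return object of class `cow_network_config`.
#' @export
network_config <- function(input_px = 512, final_depth = 512, embed_dim = 32,
                           pool_to = NULL, channel_schedule = NULL,
                           stem_channels = NULL) {
  if (is.null(channel_schedule)) {
    f <- final_depth / BASE_FINAL
    channel_schedule <- pmax(4L, as.integer(round(BASE_SCHEDULE * f / 4) * 4))
  }
  if (length(channel_schedule) != 9) {
    stop("channel_schedule must have exactly 9 entries (nine inception modules)")
  }
  if (any(channel_schedule %% 4 != 0)) {
    stop("module depths must be divisible by 4 (four branches of c channels)")
  }
  if (is.null(stem_channels)) {
    f <- channel_schedule[9] / BASE_FINAL
    stem_channels <- pmax(4L, as.integer(round(BASE_STEM * f)))
  }
  pool_to <- as.integer(pool_to %||% max(1L, input_px %/% 16L))
  structure(list(
    input_px = as.integer(input_px), embed_dim = as.integer(embed_dim),
    n_inception = 9L, channel_schedule = as.integer(channel_schedule),
    stem_channels = as.integer(stem_channels), pool_to = pool_to,
    padding_mode = "replicate", norm_positions = c("stem", "m3", "m6")
  ), class = "cow_network_config")
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build (initialise) an embedding network
#'
#' @param cfg a [network_config()].
#' @param seed seed for the weight initialisation.
#' @return object of class `cow_network` holding the configuration and the
#'   named parameter list.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "cow_network_config"))
  P <- list()
  withr::with_seed(derive_seed(seed, 77L), {
    s1 <- cfg$stem_channels[1]; s2 <- cfg$stem_channels[2]
    P[["stem1.dw.K"]] <- he_init(9, 3, 9)
    P[["stem1.dw.b"]] <- numeric(3)
    P[["stem1.pw.W"]] <- he_init(3, s1, 3)
    P[["stem1.pw.b"]] <- numeric(s1)
    P[["stem1.in.g"]] <- rep(1, s1)
    P[["stem1.in.b"]] <- numeric(s1)
    P[["stem2.dw.K"]] <- he_init(9, s1, 9)
    P[["stem2.dw.b"]] <- numeric(s1)
    P[["stem2.pw.W"]] <- he_init(s1, s2, s1)
    P[["stem2.pw.b"]] <- numeric(s2)
    din <- s2
    for (i in 1:9) {
      c <- cfg$channel_schedule[i] %/% 4L
      pre <- sprintf("m%d", i)
      P[[paste0(pre, ".b1.W")]] <- he_init(din, c, din)
      P[[paste0(pre, ".b1.b")]] <- numeric(c)
      P[[paste0(pre, ".b2.K")]] <- he_init(9, din, 9)
      P[[paste0(pre, ".b2.kb")]] <- numeric(din)
      P[[paste0(pre, ".b2.W")]] <- he_init(din, c, din)
      P[[paste0(pre, ".b2.b")]] <- numeric(c)
      P[[paste0(pre, ".b3.K")]] <- he_init(25, din, 25)
      P[[paste0(pre, ".b3.kb")]] <- numeric(din)
      P[[paste0(pre, ".b3.W")]] <- he_init(din, c, din)
      P[[paste0(pre, ".b3.b")]] <- numeric(c)
      P[[paste0(pre, ".b4.W")]] <- he_init(din, c, din)
      P[[paste0(pre, ".b4.b")]] <- numeric(c)
      if (i %in% c(3L, 6L)) {
        P[[sprintf("norm%d.g", i)]] <- rep(1, 4L * c)
        P[[sprintf("norm%d.b", i)]] <- numeric(4L * c)
      }
      din <- 4L * c
    }
    P[["head.W"]] <- he_init(din, cfg$embed_dim, din)
    P[["head.b"]] <- numeric(cfg$embed_dim)
  })
  structure(list(cfg = cfg, params = P), class = "cow_network")
}

#' @export
print.cow_network <- function(x, ...) {
  cfg <- x$cfg
  cat("cow embedding network\n")
  cat("  inception modules :", cfg$n_inception, "\n")
  cat("  channel schedule  :", paste(cfg$channel_schedule, collapse = " "), "\n")
  cat("  stem channels     :", paste(cfg$stem_channels, collapse = " "), "\n")
  cat("  embedding dim     :", cfg$embed_dim, "(L2 normalised)\n")
  cat("  parameters        :", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Count trainable parameters of a network
#'
#' @param network a `cow_network`.
#' @return integer number of trainable scalars.
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "cow_network"))
  sum(vapply(network$params, length, integer(1)))
}

## ---- primitive ops (forward + backward pairs) ------------------------------

addb <- function(y, b) y + rep(b, each = nrow(y))

pw_fwd <- function(x, W, b) addb(x %*% W, b)
pw_bwd <- function(x, W, g) {
  list(dx = g %*% t(W), dW = crossprod(x, g), db = colSums(g))
}

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(y, g) cpp_relu_bwd(y, g)   # uses the post-activation output
pw_relu <- function(x, W, b) cpp_bias_relu(x %*% W, b)

instnorm_fwd <- function(x, h, w, n, gamma, beta, eps = 1e-5) {
  out <- cpp_instnorm_fwd(x, h, w, n, gamma, beta, eps)
  out$h <- h; out$w <- w; out$n <- n
  out
}

instnorm_bwd <- function(cache, gamma, g) {
  cpp_instnorm_bwd(cache$xhat, cache$isd, gamma, g, cache$h, cache$w, cache$n)
}

l2norm_fwd <- function(x) {
  r <- sqrt(pmax(rowSums(x * x), 1e-24))
  list(y = x / r, r = r)
}
l2norm_bwd <- function(cache, g) {
  y <- cache$y
  (g - y * rowSums(g * y)) / cache$r
}

## ---- network forward / backward --------------------------------------------

inception_fwd <- function(x, h, w, n, P, pre, keep) {
  sp <- cpp_incspatial_fwd(x, h, w, n,
                           P[[paste0(pre, ".b2.K")]], P[[paste0(pre, ".b2.kb")]],
                           P[[paste0(pre, ".b3.K")]], P[[paste0(pre, ".b3.kb")]])
  b1 <- pw_relu(x, P[[paste0(pre, ".b1.W")]], P[[paste0(pre, ".b1.b")]])
  b2 <- pw_relu(sp$d3, P[[paste0(pre, ".b2.W")]], P[[paste0(pre, ".b2.b")]])
  b3 <- pw_relu(sp$d5, P[[paste0(pre, ".b3.W")]], P[[paste0(pre, ".b3.b")]])
  b4 <- pw_relu(sp$mp, P[[paste0(pre, ".b4.W")]], P[[paste0(pre, ".b4.b")]])
  y <- cbind(b1, b2, b3, b4)
  cache <- if (keep) list(x = x, d2 = sp$d3, d3 = sp$d5, mpy = sp$mp,
                          mpi = sp$mpi, b1 = b1, b2 = b2, b3 = b3, b4 = b4,
                          h = h, w = w, n = n)
  list(y = y, cache = cache)
}

inception_bwd <- function(cache, P, pre, g, grads) {
  c <- ncol(cache$b1)
  h <- cache$h; w <- cache$w; n <- cache$n
  g1 <- relu_bwd(cache$b1, g[, 1:c, drop = FALSE])
  g2 <- relu_bwd(cache$b2, g[, (c + 1):(2 * c), drop = FALSE])
  g3 <- relu_bwd(cache$b3, g[, (2 * c + 1):(3 * c), drop = FALSE])
  g4 <- relu_bwd(cache$b4, g[, (3 * c + 1):(4 * c), drop = FALSE])
  r1 <- pw_bwd(cache$x, P[[paste0(pre, ".b1.W")]], g1)
  r2 <- pw_bwd(cache$d2, P[[paste0(pre, ".b2.W")]], g2)
  r3 <- pw_bwd(cache$d3, P[[paste0(pre, ".b3.W")]], g3)
  r4 <- pw_bwd(cache$mpy, P[[paste0(pre, ".b4.W")]], g4)
  sp <- cpp_incspatial_bwd(cache$x, r2$dx, r3$dx, r4$dx, cache$mpi,
                           P[[paste0(pre, ".b2.K")]], P[[paste0(pre, ".b3.K")]],
                           h, w, n)
  dx <- r1$dx + sp$dx
  grads[[paste0(pre, ".b1.W")]] <- r1$dW; grads[[paste0(pre, ".b1.b")]] <- r1$db
  grads[[paste0(pre, ".b2.K")]] <- sp$dk3; grads[[paste0(pre, ".b2.kb")]] <- sp$db3
  grads[[paste0(pre, ".b2.W")]] <- r2$dW; grads[[paste0(pre, ".b2.b")]] <- r2$db
  grads[[paste0(pre, ".b3.K")]] <- sp$dk5; grads[[paste0(pre, ".b3.kb")]] <- sp$db5
  grads[[paste0(pre, ".b3.W")]] <- r3$dW; grads[[paste0(pre, ".b3.b")]] <- r3$db
  grads[[paste0(pre, ".b4.W")]] <- r4$dW; grads[[paste0(pre, ".b4.b")]] <- r4$db
  list(dx = dx, grads = grads)
}

#' Forward pass of the embedding network
#'
#' @param network a `cow_network`.
#' @param x input batch as an `(n*h*w) x 3` matrix (image-major rows,
#'   column-major pixels) or a single `h x w x 3` array.
#' @param h,w,n spatial size and batch size (inferred for an array input).
#' @param keep_cache keep intermediate activations for [network_backward()].
#' @return list with `emb` (n x embed_dim matrix of unit-norm embeddings) and,
#'   if requested, the backward cache.
#' @export
network_forward <- function(network, x, h = NULL, w = NULL, n = 1L,
                            keep_cache = FALSE) {
  stopifnot(inherits(network, "cow_network"))
  P <- network$params; cfg <- network$cfg
  if (is.array(x) && length(dim(x)) == 3) {
    h <- dim(x)[1]; w <- dim(x)[2]; n <- 1L
    x <- img_to_mat(x)
  }
  stopifnot(!is.null(h), !is.null(w))
  cc <- list()
  keep <- keep_cache
  # stem 1: sep conv -> instance norm -> relu -> maxpool2
  d1 <- cpp_dw_conv_fwd(x, h, w, n, P[["stem1.dw.K"]], P[["stem1.dw.b"]])
  p1 <- pw_fwd(d1, P[["stem1.pw.W"]], P[["stem1.pw.b"]])
  in1 <- instnorm_fwd(p1, h, w, n, P[["stem1.in.g"]], P[["stem1.in.b"]])
  r1 <- relu_fwd(in1$y)
  mp1 <- cpp_maxpool_fwd(r1, h, w, n, 2L, 2L, 0L)
  if (keep) cc$stem1 <- list(x = x, d1 = d1, in1 = in1, r1 = r1, mpi = mp1$idx,
                             h = h, w = w, n = n)
  h <- mp1$oh; w <- mp1$ow; cur <- mp1$y
  # stem 2: sep conv -> relu
  d2 <- cpp_dw_conv_fwd(cur, h, w, n, P[["stem2.dw.K"]], P[["stem2.dw.b"]])
  r2 <- pw_relu(d2, P[["stem2.pw.W"]], P[["stem2.pw.b"]])
  if (keep) cc$stem2 <- list(x = cur, d2 = d2, r2 = r2, h = h, w = w, n = n)
  cur <- r2
  for (i in 1:9) {
    pre <- sprintf("m%d", i)
    ic <- inception_fwd(cur, h, w, n, P, pre, keep)
    cur <- ic$y
    if (keep) cc[[pre]] <- ic$cache
    if (i %in% c(3L, 6L)) {
      nm <- sprintf("norm%d", i)
      nf <- instnorm_fwd(cur, h, w, n, P[[paste0(nm, ".g")]], P[[paste0(nm, ".b")]])
      if (keep) cc[[nm]] <- nf
      cur <- nf$y
    }
    if (i %in% c(2L, 4L)) {
      mp <- cpp_maxpool_fwd(cur, h, w, n, 2L, 2L, 0L)
      if (keep) cc[[sprintf("pool%d", i)]] <- list(idx = mp$idx, nrow_in = nrow(cur))
      cur <- mp$y; h <- mp$oh; w <- mp$ow
    }
    if (i == 6L && (h != cfg$pool_to || w != cfg$pool_to)) {
      if (keep) cc$apool <- list(h = h, w = w)
      cur <- cpp_adapt_avgpool_fwd(cur, h, w, n, cfg$pool_to, cfg$pool_to)
      h <- cfg$pool_to; w <- cfg$pool_to
    }
  }
  # global average pool -> linear -> L2 normalise
  grp <- rep(seq_len(n), each = h * w)
  gap <- rowsum(cur, grp) / (h * w)
  if (keep) cc$gap <- list(x_hw = h * w, h = h, w = w, grp = grp)
  lin <- pw_fwd(gap, P[["head.W"]], P[["head.b"]])
  l2 <- l2norm_fwd(lin)
  if (keep) cc$head <- list(gap = gap, l2 = l2)
  list(emb = l2$y, cache = if (keep) cc, h = h, w = w, n = n)
}

# Backpropagate a gradient w.r.t. the embeddings through the network.
# Returns a named list of parameter gradients.
network_backward <- function(network, fwd, dEmb) {
  P <- network$params; cfg <- network$cfg
  cc <- fwd$cache
  stopifnot(!is.null(cc))
  grads <- list()
  g <- l2norm_bwd(cc$head$l2, dEmb)
  hb <- pw_bwd(cc$head$gap, P[["head.W"]], g)
  grads[["head.W"]] <- hb$dW; grads[["head.b"]] <- hb$db
  g <- hb$dx[cc$gap$grp, , drop = FALSE] / cc$gap$x_hw
  h <- cc$gap$h; w <- cc$gap$w; n <- fwd$n
  for (i in 9:1) {
    pre <- sprintf("m%d", i)
    if (i == 6L && !is.null(cc$apool)) {
      g <- cpp_adapt_avgpool_bwd(g, cc$apool$h, cc$apool$w, n,
                                 cfg$pool_to, cfg$pool_to)
      h <- cc$apool$h; w <- cc$apool$w
    }
    if (i %in% c(2L, 4L)) {
      pc <- cc[[sprintf("pool%d", i)]]
      g <- cpp_maxpool_bwd(g, pc$idx, pc$nrow_in)
      h <- cc[[pre]]$h; w <- cc[[pre]]$w
    }
    if (i %in% c(3L, 6L)) {
      nm <- sprintf("norm%d", i)
      nb <- instnorm_bwd(cc[[nm]], P[[paste0(nm, ".g")]], g)
      grads[[paste0(nm, ".g")]] <- nb$dg; grads[[paste0(nm, ".b")]] <- nb$db
      g <- nb$dx
    }
    ib <- inception_bwd(cc[[pre]], P, pre, g, grads)
    g <- ib$dx; grads <- ib$grads
  }
  # stem 2
  g <- relu_bwd(cc$stem2$r2, g)
  s2 <- pw_bwd(cc$stem2$d2, P[["stem2.pw.W"]], g)
  grads[["stem2.pw.W"]] <- s2$dW; grads[["stem2.pw.b"]] <- s2$db
  k2 <- cpp_dw_conv_bwd(cc$stem2$x, s2$dx, cc$stem2$h, cc$stem2$w, n,
                        P[["stem2.dw.K"]])
  grads[["stem2.dw.K"]] <- k2$dk; grads[["stem2.dw.b"]] <- k2$db
  g <- k2$dx
  # stem 1
  g <- cpp_maxpool_bwd(g, cc$stem1$mpi, nrow(cc$stem1$r1))
  g <- relu_bwd(cc$stem1$r1, g)
  nb <- instnorm_bwd(cc$stem1$in1, P[["stem1.in.g"]], g)
  grads[["stem1.in.g"]] <- nb$dg; grads[["stem1.in.b"]] <- nb$db
  s1 <- pw_bwd(cc$stem1$d1, P[["stem1.pw.W"]], nb$dx)
  grads[["stem1.pw.W"]] <- s1$dW; grads[["stem1.pw.b"]] <- s1$db
  k1 <- cpp_dw_conv_bwd(cc$stem1$x, s1$dx, cc$stem1$h, cc$stem1$w, n,
                        P[["stem1.dw.K"]])
  grads[["stem1.dw.K"]] <- k1$dk; grads[["stem1.dw.b"]] <- k1$db
  grads
}

## ---- preprocessing ----------------------------------------------------------

#' Preprocess an instance segment for embedding
#'
#' Crops to the mask bounding box, zeroes background pixels, rescales equally
#' along both axes so the larger dimension equals `n`, and zero-pads the
#' smaller dimension symmetrically to an `n x n` RGB raster.
#'
#' @param seg a `cow_segment` (or list with `image` and `mask`).
#' @param n target size in pixels.
#' @return `n x n x 3` array.
#' @export
preprocess_segment <- function(seg, n = 512) {
  if (n <= 0) stop("n must be positive")
  mask <- seg$mask
  if (sum(mask) == 0) stop("empty mask: nothing to preprocess")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  img <- seg$image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  m <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  img <- img * as.vector(m)
  h <- nrow(m); w <- ncol(m)
  s <- n / max(h, w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  img <- img_resize(img, nh, nw)
  out <- array(0, dim = c(n, n, 3))
  r0 <- (n - nh) %/% 2L; c0 <- (n - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw), ] <- img
  out
}

# Stack a list of n x n x 3 arrays into the batch matrix layout.
stack_batch <- function(imgs) {
  n <- length(imgs)
  d <- dim(imgs[[1]])
  x <- matrix(0, n * d[1] * d[2], 3)
  for (b in seq_len(n)) {
    x[((b - 1) * d[1] * d[2] + 1):(b * d[1] * d[2]), ] <- img_to_mat(imgs[[b]])
  }
  list(x = x, h = d[1], w = d[2], n = n)
}

#' Embed a list of instance segments
#'
#' @param network a `cow_network`.
#' @param segments list of `cow_segment`s.
#' @param input_px input size (defaults to the network's configured size).
#' @param batch_size forward-pass batch size.
#' @return matrix with one unit-norm embedding row per segment.
#' @export
embed_instances <- function(network, segments, input_px = NULL, batch_size = 25L) {
  input_px <- input_px %||% network$cfg$input_px
  out <- matrix(0, length(segments), network$cfg$embed_dim)
  i <- 1L
  while (i <= length(segments)) {
    j <- min(i + batch_size - 1L, length(segments))
    imgs <- lapply(segments[i:j], preprocess_segment, n = input_px)
    b <- stack_batch(imgs)
    out[i:j, ] <- network_forward(network, b$x, b$h, b$w, b$n)$emb
    i <- j + 1L
  }
  out
}
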