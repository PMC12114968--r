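# Histogram loss for deep metric learning: estimate, from a batch, the
# probability that a randomly drawn negative pair (different identities) has a
# cosine similarity at least as large as a randomly drawn positive pair (same
# identity).  Pair similarities are soft-assigned to a regular grid over
# [-1, 1] by linear interpolation, which makes the estimate differentiable in
# the embeddings.

#' Histogram loss over a batch of embeddings
#'
#' @param embeddings n x d matrix of (unit-norm) embeddings.
#' @param labels length-n identity labels; at least two distinct labels, each
#'   with at least two members, are required.
#' @param n_bins number of histogram nodes over `[-1, 1]` (default 201, i.e.
#'   a 0.01 step).
#' @param gradient also return the gradient w.r.t. the embeddings.
#' @return the loss in `[0, 1]`; with `gradient = TRUE`, a list with `loss`
#'   and `grad` (n x d matrix).
#' @export
histogram_loss <- function(embeddings, labels, n_bins = 201L, gradient = FALSE) {
  n <- nrow(embeddings)
  stopifnot(length(labels) == n, n_bins >= 2)
  if (length(unique(labels)) < 2) {
    stop("histogram loss needs at least two identities in the batch")
  }
  S <- tcrossprod(embeddings)
  iu <- which(upper.tri(S))
  same <- outer(labels, labels, "==")[iu]
  s <- pmin(1, pmax(-1, S[iu]))
  pos <- s[same]; neg <- s[!same]
  if (length(pos) == 0) stop("no positive pairs: need >=2 members per identity")
  delta <- 2 / (n_bins - 1)
  soft_hist <- function(v) {
    # linear interpolation onto nodes 1..n_bins; returns hist and the
    # per-sample lower node index and fraction (for the gradient)
    pos01 <- (v + 1) / delta
    i0 <- pmin(floor(pos01), n_bins - 2)   # 0-based lower node
    f <- pos01 - i0
    h <- numeric(n_bins)
    tab0 <- rowsum((1 - f), i0)
    tab1 <- rowsum(f, i0)
    h[as.integer(rownames(tab0)) + 1L] <- h[as.integer(rownames(tab0)) + 1L] + tab0
    h[as.integer(rownames(tab1)) + 2L] <- h[as.integer(rownames(tab1)) + 2L] + tab1
    list(h = h / length(v), i0 = i0, f = f)
  }
  hp <- soft_hist(pos)
  hn <- soft_hist(neg)
  Hp <- cumsum(hp$h)                 # P(pos <= node r)
  loss <- sum(hn$h * Hp)
  if (!gradient) return(loss)
  # dL/ds for a negative sample: (Hp[i0+2] - Hp[i0+1]) / delta / n_neg
  # dL/ds for a positive sample: (Rn[i0+2] - Rn[i0+1]) / delta / n_pos,
  # where Rn[r] = sum_{q >= r} hn[q].
  Rn <- rev(cumsum(rev(hn$h)))
  gneg <- (Hp[hn$i0 + 2L] - Hp[hn$i0 + 1L]) / delta / length(neg)
  gpos <- (Rn[hp$i0 + 2L] - Rn[hp$i0 + 1L]) / delta / length(pos)
  dS <- matrix(0, n, n)
  gs <- numeric(length(iu))
  gs[same] <- gpos
  gs[!same] <- gneg
  dS[iu] <- gs
  grad <- (dS + t(dS)) %*% embeddings
  list(loss = loss, grad = grad)
}
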