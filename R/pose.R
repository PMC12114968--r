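# Multi-task pose-estimation / behaviour-classification utilities: the
# behaviour-extended loss, its ground-truth construction, adaptive term
# balancing, skeleton-segment association and spine-based orientation
# estimation.
#
# A heatmap stack bundles, per pixel, 6 keypoint-probability channels (P),
# 24 keypoint-association channels (A) and 3 behaviour channels (B, in the
# fixed order ll, lr, s; softmax-normalised when predicted, {0,1}-valued as
# ground truth).

DEFAULT_KEYPOINTS <- c("withers", "tail_implant", "hip_left", "hip_right",
                       "head", "shoulder")

#' Construct a skeleton of named 2-D keypoints
#'
#' Keypoints are named numeric vectors `c(x, y, confidence)`; missing
#' keypoints are simply absent (never encoded as zero coordinates).
#' Coordinates follow the package convention: angles are measured from the +x
#' axis towards +y, counter-clockwise positive.
#'
#' @param ... named keypoints, e.g. `withers = c(10, 4, 0.9)` (confidence
#'   defaults to 1 when omitted).
#' @return object of class `cow_skeleton`.
#' @export
skeleton <- function(...) {
  kp <- list(...)
  stopifnot(length(kp) == 0 || !is.null(names(kp)))
  kp <- lapply(kp, function(p) {
    stopifnot(is.numeric(p), length(p) %in% c(2, 3), all(is.finite(p)))
    if (length(p) == 2) p <- c(p, 1)
    if (p[3] < 0 || p[3] > 1) stop("confidence must be in [0, 1]")
    setNames(p, c("x", "y", "confidence"))
  })
  structure(list(keypoints = kp), class = "cow_skeleton")
}

#' Heatmap stack container
#'
#' @param P `h x w x 6` keypoint-probability channels (values in `[0,1]`).
#' @param A `h x w x 24` association channels.
#' @param B `h x w x 3` behaviour channels in the order `ll`, `lr`, `s`.
#' @param keypoint_names names of the P channels.
#' @param predicted if `TRUE`, B channels must be softmax-normalised
#'   (sum to 1 per pixel); ground-truth stacks are `{0,1}`-valued.
#' @return object of class `cow_heatmap_stack`.
#' @export
heatmap_stack <- function(P, A, B, keypoint_names = DEFAULT_KEYPOINTS,
                          predicted = FALSE) {
  stopifnot(length(dim(P)) == 3, length(dim(A)) == 3, length(dim(B)) == 3)
  h <- dim(P)[1]; w <- dim(P)[2]
  stopifnot(dim(A)[1] == h, dim(A)[2] == w, dim(B)[1] == h, dim(B)[2] == w,
            dim(B)[3] == 3)
  if (any(P < -1e-9) || any(P > 1 + 1e-9)) stop("P channels must lie in [0,1]")
  if (predicted) {
    if (any(B < 0)) stop("predicted behaviour probabilities must be nonnegative")
    sums <- B[, , 1] + B[, , 2] + B[, , 3]
    if (any(abs(sums - 1) > 1e-6)) {
      stop("predicted behaviour channels must be softmax-normalised per pixel")
    }
  }
  structure(list(P = P, A = A, B = B, w = w, h = h,
                 keypoint_names = keypoint_names, predicted = predicted),
            class = "cow_heatmap_stack")
}

#' Ground-truth behaviour channels from the central-keypoint heatmap
#'
#' A pixel of the channel for the displayed behaviour is 1 exactly where the
#' central-keypoint (withers) heatmap exceeds 0.2; everything else is 0.  For
#' several animals, pass lists: per-animal contributions are accumulated and
#' clipped to `{0,1}`.
#'
#' @param central_heatmap `h x w` matrix in `[0,1]`, or a list of such
#'   matrices (one per animal).
#' @param behaviour behaviour label(s) (`ll`, `lr`, `s`), one per animal.
#' @param threshold heat threshold (0.2).
#' @return `h x w x 3` array of `{0,1}` channels in the order `ll`, `lr`, `s`.
#' @export
build_behaviour_ground_truth <- function(central_heatmap, behaviour,
                                         threshold = 0.2) {
  if (!is.list(central_heatmap)) central_heatmap <- list(central_heatmap)
  stopifnot_behaviour(behaviour)
  stopifnot(length(behaviour) == length(central_heatmap))
  h <- nrow(central_heatmap[[1]]); w <- ncol(central_heatmap[[1]])
  out <- array(0, dim = c(h, w, 3))
  for (k in seq_along(central_heatmap)) {
    hm <- central_heatmap[[k]]
    stopifnot(all(hm >= 0), all(hm <= 1))
    ch <- match(behaviour[k], BEHAVIOURS)
    out[, , ch] <- out[, , ch] + (hm > threshold)
  }
  pmin(out, 1)
}

#' Loss-term weights of the multi-task loss
#'
#' @param beta1,beta2,beta3 weights of the location, association and
#'   behaviour terms (positive during training).
#' @param gamma exponent of the masked association error (default 2).
#' @return object of class `cow_loss_weights`; `epsilon` is fixed at `1e-10`.
#' @export
loss_weights <- function(beta1 = 1, beta2 = 1, beta3 = 1, gamma = 2) {
  stopifnot(beta1 >= 0, beta2 >= 0, beta3 >= 0, gamma > 0)
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3, gamma = gamma,
                 epsilon = 1e-10), class = "cow_loss_weights")
}

#' Multi-task loss: keypoint location + association + behaviour
#'
#' The location term is the mean squared error over the keypoint channels,
#' `beta1 / (w*h*|P|) * sum (Yhat - Y)^2`; the association term the masked
#' gamma-power error over the association channels, normalised by one plus
#' the number of nonzero ground-truth pixels; the behaviour term the
#' cross-entropy `-beta3 * sum Y * log(Yhat + 1e-10)` over the behaviour
#' channels with the same style of normaliser.
#'
#' @param pred,truth `cow_heatmap_stack`s of matching shape (`pred` with
#'   softmax-normalised behaviour channels).
#' @param weights a [loss_weights()].
#' @return list with `total`, `location`, `association`, `behaviour`.
#' @export
multitask_loss <- function(pred, truth, weights = loss_weights()) {
  stopifnot(inherits(pred, "cow_heatmap_stack"),
            inherits(truth, "cow_heatmap_stack"),
            inherits(weights, "cow_loss_weights"))
  if (pred$w != truth$w || pred$h != truth$h ||
      !all(dim(pred$A) == dim(truth$A))) {
    stop("prediction and ground truth shapes do not match")
  }
  if (any(pred$B < 0)) stop("negative predicted behaviour probability")
  w <- pred$w; h <- pred$h
  nP <- dim(pred$P)[3]
  location <- weights$beta1 * sum((pred$P - truth$P)^2) / (w * h * nP)
  maskA <- truth$A != 0
  nA <- sum(maskA)
  association <- weights$beta2 *
    sum((abs(pred$A - truth$A)[maskA])^weights$gamma) / (1 + nA)
  maskB <- truth$B != 0
  nB <- sum(maskB)
  behaviour <- -weights$beta3 *
    sum(truth$B * log(pred$B + weights$epsilon)) / (1 + nB)
  list(total = location + association + behaviour,
       location = location, association = association, behaviour = behaviour)
}

#' Adapt loss-term weights so each term contributes equally
#'
#' Given average unscaled term values over a training window, sets
#' `beta_i = target_share / mean_i`, so every rescaled term averages
#' `target_share` (1/3) and the mean total loss is 1.  The update is
#' idempotent for a fixed history.
#'
#' @param term_means length-3 numeric: mean unscaled location, association
#'   and behaviour terms (must be positive).
#' @param target_share target contribution per term (1/3).
#' @param gamma association exponent carried into the returned weights.
#' @return a [loss_weights()].
#' @export
adapt_betas <- function(term_means, target_share = 1 / 3, gamma = 2) {
  stopifnot(length(term_means) == 3)
  if (any(term_means <= 0)) {
    stop("term averages must be positive (degenerate training signal)")
  }
  b <- target_share / term_means
  loss_weights(beta1 = b[1], beta2 = b[2], beta3 = b[3], gamma = gamma)
}

#' Associate instance segments with detected skeletons
#'
#' A skeleton is a candidate for a segment iff its withers keypoint lies
#' inside the segment mask; only segments with exactly one candidate are
#' associated, the others are discarded with a reason.
#'
#' @param masks list of binary `h x w` masks (same pixel frame as the
#'   skeleton coordinates; a keypoint `(x, y)` addresses `mask[y + 1, x + 1]`,
#'   i.e. 0-based pixel coordinates).
#' @param skeletons list of `cow_skeleton`s.
#' @return list with `pairs` (data.frame `segment`, `skeleton`) and
#'   `discarded` (data.frame `segment`, `reason`).
#' @export
associate_segments_skeletons <- function(masks, skeletons) {
  withers_inside <- function(sk, mask) {
    p <- sk$keypoints[["withers"]]
    if (is.null(p)) return(FALSE)
    r <- floor(p["y"]) + 1L; c <- floor(p["x"]) + 1L
    r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c] > 0
  }
  pairs <- list(); disc <- list()
  for (m in seq_along(masks)) {
    cand <- which(vapply(skeletons, withers_inside, logical(1),
                         mask = masks[[m]]))
    if (length(cand) == 1) {
      pairs[[length(pairs) + 1]] <- data.frame(segment = m, skeleton = cand)
    } else {
      reason <- if (length(cand) == 0) "no skeleton inside segment"
                else sprintf("%d skeletons inside segment", length(cand))
      disc[[length(disc) + 1]] <- data.frame(segment = m, reason = reason)
    }
  }
  list(
    pairs = if (length(pairs)) do.call(rbind, pairs)
            else data.frame(segment = integer(0), skeleton = integer(0)),
    discarded = if (length(disc)) do.call(rbind, disc)
                else data.frame(segment = integer(0), reason = character(0))
  )
}

#' Estimate the animal orientation from a skeleton
#'
#' The spine is the vector from the tail implant to the withers; if the tail
#' implant is missing, the midpoint of the two hips substitutes for it, and
#' if only one hip was detected, that hip alone.  The angle is measured from
#' the +x axis towards +y, counter-clockwise positive, in `[0, 360)`.
#'
#' @param skel a `cow_skeleton` with at least the withers and one of
#'   tail implant / hip keypoints.
#' @return orientation in degrees.
#' @export
estimate_orientation <- function(skel) {
  kp <- skel$keypoints
  withers <- kp[["withers"]]
  if (is.null(withers)) stop("orientation unavailable: withers not detected")
  tail_pt <- kp[["tail_implant"]]
  if (is.null(tail_pt)) {
    hl <- kp[["hip_left"]]; hr <- kp[["hip_right"]]
    if (!is.null(hl) && !is.null(hr)) {
      tail_pt <- (hl[1:2] + hr[1:2]) / 2
    } else if (!is.null(hl)) {
      tail_pt <- hl
    } else if (!is.null(hr)) {
      tail_pt <- hr
    } else {
      stop("orientation unavailable: no tail implant or hip keypoint")
    }
  }
  v <- unname(withers[1:2] - tail_pt[1:2])
  norm_angle(atan2(v[2], v[1]) * 180 / pi)
}

#' Decode the behaviour from a predicted heatmap stack
#'
#' Averages the softmax-normalised behaviour channels over the region where
#' the predicted central-keypoint (withers) channel exceeds the threshold,
#' and returns the argmax label with its averaged probability.  Ties break by
#' the fixed channel order (`ll` first).  If the region is empty, the single
#' pixel at the withers detection is used.
#'
#' @param stack predicted `cow_heatmap_stack` (withers = first P channel).
#' @param withers_xy withers position `c(x, y)` in 0-based pixel coordinates.
#' @param threshold central-heat threshold (0.2).
#' @return list with `value` (label) and `probability`.
#' @export
decode_behaviour <- function(stack, withers_xy, threshold = 0.2) {
  stopifnot(inherits(stack, "cow_heatmap_stack"))
  central <- stack$P[, , match("withers", stack$keypoint_names)]
  region <- central > threshold
  if (!any(region)) {
    r <- floor(withers_xy[2]) + 1L; c <- floor(withers_xy[1]) + 1L
    stopifnot(r >= 1, r <= stack$h, c >= 1, c <= stack$w)
    region <- matrix(FALSE, stack$h, stack$w)
    region[r, c] <- TRUE
  }
  probs <- vapply(1:3, function(ch) mean(stack$B[, , ch][region]), numeric(1))
  names(probs) <- BEHAVIOURS
  best <- which.max(probs)   # which.max takes the first maximum: ll-first tie rule
  list(value = BEHAVIOURS[best], probability = unname(probs[best]))
}
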