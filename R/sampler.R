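# Conditional batch construction and augmentation.  A training batch holds 25
# unique instances: five identities with five instances each, all sharing one
# behaviour and orientations inside a window [j - 22.5, j + 22.5] degrees
# (circular) around a sampled centre j; the window widens in 5-degree steps of
# total width (2.5 per side) only when an identity cannot fill its quota.

#' Behaviour sampling state
#'
#' Sampling probabilities per behaviour with their floor: no behaviour may be
#' sampled with probability below half the homogeneous probability, i.e.
#' `1/(2*3) = 1/6` for three behaviours.
#'
#' @param behaviour_probs named probabilities for `ll`, `lr`, `s` (default
#'   uniform).
#' @return object of class `cow_sampling_state`.
#' @export
sampling_state <- function(behaviour_probs = c(ll = 1, lr = 1, s = 1) / 3) {
  behaviour_probs <- behaviour_probs[BEHAVIOURS]
  stopifnot(abs(sum(behaviour_probs) - 1) < 1e-8)
  structure(list(behaviour_probs = behaviour_probs,
                 acc1_per_behaviour = c(ll = NA_real_, lr = NA_real_, s = NA_real_),
                 floor = 1 / (2 * length(BEHAVIOURS))),
            class = "cow_sampling_state")
}

#' Update behaviour sampling probabilities from rank-1 accuracies
#'
#' Probabilities are set proportional to `1 - acc1` per behaviour, then
#' clipped to the floor `1/(2*|B|)` and renormalised (iteratively) so that
#' hard behaviours are sampled more often without starving the easy ones.
#'
#' @param acc1 named rank-1 accuracies per behaviour, in `[0, 1]`.
#' @param state optional current `cow_sampling_state` to update.
#' @return updated `cow_sampling_state`.
#' @export
update_behaviour_probs <- function(acc1, state = sampling_state()) {
  acc1 <- acc1[BEHAVIOURS]
  stopifnot(all(acc1 >= 0 & acc1 <= 1))
  w <- 1 - acc1
  flo <- state$floor
  if (sum(w) <= 0) {
    p <- rep(1 / length(w), length(w))   # all behaviours solved: uniform
    names(p) <- BEHAVIOURS
  } else {
    p <- w / sum(w)
    # iterative clip-and-renormalise against the floor; the clipped set only
    # grows, so the loop terminates after at most |B| rounds
    clipped <- rep(FALSE, length(p))
    repeat {
      low <- !clipped & p < flo - 1e-12
      if (!any(low)) break
      clipped <- clipped | low
      free <- !clipped
      p[clipped] <- flo
      rest <- 1 - sum(clipped) * flo
      p[free] <- if (sum(w[free]) > 0) rest * w[free] / sum(w[free])
                 else rest / sum(free)
    }
  }
  state$behaviour_probs <- p
  state$acc1_per_behaviour <- acc1
  state
}

# Instances of one identity with a behaviour, inside a circular window.
window_candidates <- function(meta, id, behaviour, centre, half_width) {
  which(meta$identity == id & meta$behaviour == behaviour &
          circular_distance(meta$orientation_deg, centre) <= half_width)
}

#' Sample a behaviour/orientation-conditioned batch
#'
#' @param dataset a `cow_dataset`.
#' @param state a `cow_sampling_state` (behaviour probabilities).
#' @param seed integer seed for this batch.
#' @param n_identities,per_identity batch composition (5 x 5 = 25).
#' @param half_width initial orientation half-window in degrees (22.5).
#' @param widen_step widening step per side in degrees (2.5, i.e. 5 degrees
#'   of total width).
#' @return list with `indices` (into `dataset$segments`), and `spec`
#'   (behaviour, centre orientation, final half-width).
#' @export
sample_conditioned_batch <- function(dataset, state = sampling_state(),
                                     seed = 1L, n_identities = 5L,
                                     per_identity = 5L, half_width = 22.5,
                                     widen_step = 2.5) {
  meta <- dataset$metadata
  withr::with_seed(derive_seed(seed, 31L), {
    behaviour <- sample(BEHAVIOURS, 1, prob = state$behaviour_probs[BEHAVIOURS])
    centre <- runif(1, 0, 360)
    counts <- table(meta$identity[meta$behaviour == behaviour])
    eligible <- names(counts)[counts >= per_identity]
    if (length(eligible) < n_identities) {
      stop(sprintf("only %d identities have >= %d instances with behaviour '%s'",
                   length(eligible), per_identity, behaviour))
    }
    ids <- sample(eligible, n_identities)
    hw <- half_width
    repeat {
      cand <- lapply(ids, window_candidates, meta = meta, behaviour = behaviour,
                     centre = centre, half_width = hw)
      short <- lengths(cand) < per_identity
      if (!any(short)) break
      if (hw >= 180) {
        stop(sprintf("identity %s has fewer than %d unique instances of behaviour '%s'",
                     ids[which(short)[1]], per_identity, behaviour))
      }
      hw <- min(180, hw + widen_step)
    }
    indices <- unlist(lapply(cand, sample, size = per_identity), use.names = FALSE)
  })
  list(indices = indices,
       spec = list(behaviour = behaviour, centre_orientation = centre,
                   half_width = hw))
}

#' Sample an unconditioned batch
#'
#' Same marginal behaviour/orientation distribution as the conditioned
#' sampler, but behaviour and orientation are redrawn independently for every
#' slot, so a batch carries no within-batch homogeneity guarantee.
#'
#' @param dataset a `cow_dataset`.
#' @param seed integer seed.
#' @param state a `cow_sampling_state`.
#' @param n_identities,per_identity batch composition.
#' @return list with `indices` and `spec = NULL`.
#' @export
sample_unconditioned_batch <- function(dataset, seed = 1L,
                                       state = sampling_state(),
                                       n_identities = 5L, per_identity = 5L) {
  meta <- dataset$metadata
  withr::with_seed(derive_seed(seed, 37L), {
    counts <- table(meta$identity)
    eligible <- names(counts)[counts >= per_identity]
    if (length(eligible) < n_identities) {
      stop(sprintf("need >= %d identities with >= %d instances",
                   n_identities, per_identity))
    }
    ids <- sample(eligible, n_identities)
    indices <- integer(0)
    for (id in ids) {
      picked <- integer(0)
      for (slot in seq_len(per_identity)) {
        behaviour <- sample(BEHAVIOURS, 1, prob = state$behaviour_probs[BEHAVIOURS])
        centre <- runif(1, 0, 360)
        hw <- 22.5
        repeat {
          cand <- setdiff(window_candidates(meta, id, behaviour, centre, hw),
                          picked)
          if (length(cand) > 0 || hw >= 180) break
          hw <- hw + 2.5
        }
        if (length(cand) == 0) {   # no instance of that behaviour: any left
          cand <- setdiff(which(meta$identity == id), picked)
        }
        if (length(cand) == 0) stop("identity ", id, " exhausted")
        picked <- c(picked, if (length(cand) == 1) cand else sample(cand, 1))
      }
      indices <- c(indices, picked)
    }
  })
  list(indices = indices, spec = NULL)
}

#' Mirror-augment a dataset
#'
#' Doubles the identity count: every identity gains a mirrored counterpart
#' (suffix `_m`, a new identity) whose instances are the left-right flipped
#' images, with behaviours swapped (`ll` <-> `lr`) and orientations mapped to
#' `(180 - theta) mod 360`.
#'
#' @param dataset a `cow_dataset`.
#' @return a `cow_dataset` with twice the segments and identities.
#' @export
mirror_augment <- function(dataset) {
  swap <- c(ll = "lr", lr = "ll", s = "s")
  mirrored <- lapply(dataset$segments, function(seg) {
    structure(list(
      image = img_flip_h(seg$image), mask = img_flip_h(seg$mask),
      identity_id = paste0(seg$identity_id, "_m"),
      behaviour = swap[[seg$behaviour]],
      orientation_deg = mirror_orientation(seg$orientation_deg),
      occluded_fraction = seg$occluded_fraction,
      coat_class = seg$coat_class, mirrored = TRUE
    ), class = "cow_segment")
  })
  m2 <- dataset$metadata
  m2$identity <- paste0(m2$identity, "_m")
  m2$behaviour <- unname(swap[m2$behaviour])
  m2$orientation_deg <- mirror_orientation(m2$orientation_deg)
  if ("file" %in% names(m2)) m2$file <- sub("\\.png$", "_m.png", m2$file)
  meta <- rbind(dataset$metadata, m2)
  rownames(meta) <- NULL
  structure(list(segments = c(dataset$segments, mirrored), metadata = meta,
                 identities = dataset$identities, canvas_px = dataset$canvas_px),
            class = "cow_dataset")
}

#' Photometric and geometric augmentation of a segment
#'
#' Applies, in order: colour jitter (per-channel gain and brightness), one
#' combined affine warp (rotation within +/-10 degrees, shear, isotropic scale
#' jitter) to image and mask, and a horizontal or vertical black band
#' occluding up to 40 percent of the image area.  Orientation metadata is left
#' unchanged (rotations are small).
#'
#' @param seg a `cow_segment`.
#' @param seed integer seed.
#' @param jitter colour gain half-range (default 0.15).
#' @param rotation max |rotation| in degrees (default 10).
#' @param shear max |shear| coefficient (default 0.1).
#' @param scale max relative scale jitter (default 0.1).
#' @param occlude_max occlusion-fraction cap (default 0.4).
#' @return augmented `cow_segment`.
#' @export
augment_image <- function(seg, seed = 1L, jitter = 0.15, rotation = 10,
                          shear = 0.1, scale = 0.1, occlude_max = 0.4) {
  if (jitter == 0 && rotation == 0 && shear == 0 && scale == 0 &&
      occlude_max == 0) {
    return(seg)
  }
  img <- seg$image; mask <- seg$mask
  h <- nrow(mask); w <- ncol(mask)
  withr::with_seed(derive_seed(seed, 53L), {
    gains <- runif(3, 1 - jitter, 1 + jitter)
    bright <- runif(1, -jitter / 2, jitter / 2)
    rot <- runif(1, -rotation, rotation)
    shx <- runif(1, -shear, shear)
    sc <- runif(1, 1 - scale, 1 + scale)
    occ <- runif(1, 0, occlude_max)
    horiz <- runif(1) < 0.5
    posu <- runif(1)
  })
  for (ch in 1:3) {
    img[, , ch] <- pmin(1, pmax(0, img[, , ch] * gains[ch] + bright))
  }
  if (rotation > 0 || shear > 0 || scale > 0) {
    th <- deg2rad(rot)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Sh <- matrix(c(1, 0, shx, 1), 2, 2)
    M <- (R %*% Sh) / sc    # inverse map: output -> source
    img <- img_warp(img, M)
    mask <- (img_warp(mask, M) > 0.5) * 1
    img <- img * as.vector(mask)
  }
  if (occ > 0) {
    wband <- max(1L, round(occ * (if (horiz) h else w)))
    pos <- 1L + floor(posu * ((if (horiz) h else w) - wband + 1))
    sel <- pos:(pos + wband - 1L)
    if (horiz) img[sel, , ] <- 0 else img[, sel, ] <- 0
  }
  out <- structure(modifyList(unclass(seg), list(image = img, mask = mask)),
                   class = "cow_segment")
  attr(out, "augment_params") <- list(gains = gains, brightness = bright,
                                      rotation = rot, shear = shx, scale = sc,
                                      occlusion = occ)
  out
}

#' Fictive individuals perceived during conditional training
#'
#' Conditional batch sampling makes the network perceive each
#' (identity x behaviour x orientation-bin) combination -- doubled again by
#' mirroring -- as a distinct class.
#'
#' @param n_actual number of actual individuals.
#' @param bins named map from behaviour to effective orientation-bin count
#'   (e.g. 8 bins of 45 degrees for standing but only 2 for each lying
#'   behaviour when lying orientations are bimodal).
#' @param mirrored whether mirror augmentation doubles the count.
#' @return integer number of fictive individuals.
#' @export
fictive_individual_count <- function(n_actual, bins, mirrored = TRUE) {
  stopifnot(all(bins >= 1))
  (if (mirrored) 2L else 1L) * sum(bins) * n_actual
}
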