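# Procedural generator of pied-coat instance segments.  The generator's only
# purpose is to reproduce the statistical structure the re-identification
# method exploits: each identity carries two *independent* flank textures, and
# the behaviour/orientation of an instance determines which flank (or which
# blend of the two) is visible.  Nothing here aims at photorealism.

#' Coat pattern classes of pied Holstein-Friesian cattle
#'
#' Six classes by base colour (red or black Holstein) and white fraction of
#' the coat: under 20\% white the animal counts as red/black (`r`, `b`),
#' between 20\% and 80\% as red-and-white / black-and-white (`rw`, `bw`), and
#' over 80\% as white-and-red / white-and-black (`wr`, `wb`).
#'
#' @return data.frame with columns `label`, `base_colour`, `white_min`,
#'   `white_max`.
#' @export
coat_classes <- function() {
  data.frame(
    label       = c("r", "b", "rw", "bw", "wr", "wb"),
    base_colour = c("red", "black", "red", "black", "red", "black"),
    white_min   = c(0.00, 0.00, 0.20, 0.20, 0.80, 0.80),
    white_max   = c(0.20, 0.20, 0.80, 0.80, 1.00, 1.00),
    stringsAsFactors = FALSE
  )
}

# Observed class frequencies among the 48 animals of the source herd.
default_coat_mix <- function() {
  c(r = 7, b = 6, rw = 12, bw = 11, wr = 10, wb = 2)
}

#' Generate the appearance of one identity
#'
#' Samples a white fraction within the coat-class range and draws independent
#' RNG seeds for the left and right flank textures, so the two flanks of one
#' identity are distinguishable with probability ~1.
#'
#' @param seed integer seed; the appearance is deterministic given it.
#' @param coat_label one of `r`, `b`, `rw`, `bw`, `wr`, `wb`.
#' @param patch_scale patch length scale in pixels (at rendering canvas scale).
#' @return object of class `cow_identity`.
#' @export
generate_identity <- function(seed, coat_label, patch_scale = 42) {
  cc <- coat_classes()
  row <- cc[cc$label == coat_label, ]
  if (nrow(row) != 1) stop("unknown coat label: ", coat_label)
  withr::with_seed(derive_seed(seed, 1L), {
    lo <- max(row$white_min, 0.02)
    hi <- min(row$white_max, 0.97)
    wf <- runif(1, lo, hi)
    ls <- sample.int(2^30, 1)
    rs <- sample.int(2^30, 1)
  })
  structure(list(
    identity_id = sprintf("id%06d", seed %% 1000000L),
    coat = row$label, base_colour = row$base_colour,
    white_fraction = wf, left_flank_seed = ls, right_flank_seed = rs,
    patch_scale = patch_scale, mirrored = FALSE, parent = NULL
  ), class = "cow_identity")
}

#' Mirrored counterpart of an identity
#'
#' The mirrored identity is the fictive animal whose renders are exactly the
#' left-right flipped renders of the parent: behaviours swap (ll <-> lr) and
#' the orientation maps to `(180 - theta) mod 360`.
#'
#' @param app a `cow_identity`.
#' @return a `cow_identity` flagged as mirrored.
#' @export
mirror_identity <- function(app) {
  stopifnot(inherits(app, "cow_identity"))
  if (app$mirrored) return(app$parent)
  structure(modifyList(app, list(
    identity_id = paste0(app$identity_id, "_m"),
    mirrored = TRUE, parent = app
  )), class = "cow_identity")
}

# Thresholded smoothed-noise "blob" field: coarse Gaussian grid, bilinear
# upsampling, threshold at the empirical quantile that yields the requested
# white fraction.  Returns an h x w matrix in {0,1} (1 = white patch).
flank_texture <- function(seed, size_px, patch_scale, white_fraction) {
  g <- max(3L, as.integer(ceiling(size_px / patch_scale)) + 1L)
  field <- withr::with_seed(seed, matrix(rnorm(g * g), g, g))
  field <- img_resize(field, size_px, size_px, fill = 0)
  thr <- quantile(field, probs = 1 - white_fraction, names = FALSE)
  (field > thr) * 1
}

swap_behaviour <- function(b) c(ll = "lr", lr = "ll", s = "s")[[b]]

#' Mirror an orientation angle
#'
#' Under the package convention (0 degrees = +x image axis, counter-clockwise
#' positive) a left-right flip maps an orientation `theta` to
#' `(180 - theta) mod 360`.
#'
#' @param theta orientation(s) in degrees.
#' @return mirrored orientation(s) in `[0, 360)`.
#' @export
mirror_orientation <- function(theta) norm_angle(180 - theta)

# Body silhouette in the canonical animal frame (spine along +x, canvas
# centred), as a {0,1} matrix.  `len_scale` applies foreshortening.
silhouette_mask <- function(behaviour, canvas_px, len_scale = 1) {
  n <- canvas_px
  ax <- seq(-1, 1, length.out = n)
  x <- matrix(ax, n, n, byrow = TRUE)    # +x right
  y <- matrix(rev(ax), n, n)             # +y up (row 1 = top)
  inside <- function(cx, cy, a, b, p = 2) {
    (abs((x - cx) / a)^p + abs((y - cy) / b)^p) <= 1
  }
  if (behaviour == "s") {
    a <- 0.52 * len_scale
    m <- inside(0, 0.08, a, 0.24, 3)                     # trunk
    m <- m | inside(a * 1.02, 0.14, 0.16, 0.11, 2)       # head
    for (lx in c(-0.72, -0.48, 0.42, 0.66) * a) {        # leg stubs
      m <- m | (abs(x - lx) < 0.045 & y < -0.05 & y > -0.46)
    }
  } else {
    # lying: rounded blob, folded-leg bulge towards -y for lying-left and +y
    # for lying-right (the two silhouettes are mirror images about the spine)
    m <- inside(0, 0, 0.50, 0.34, 2.5)
    m <- m | inside(0.58, 0.10, 0.14, 0.11, 2)           # head
    side <- if (behaviour == "ll") -1 else 1
    m <- m | inside(0.05, side * 0.36, 0.32, 0.10, 2)
  }
  m * 1
}

base_colour_rgb <- function(base_colour) {
  if (base_colour == "red") c(0.55, 0.25, 0.15) else c(0.10, 0.10, 0.10)
}

# Visible-flank weight for the left flank.  Standing animals oriented with
# sin(theta) > 0 show the left flank, sin(theta) < 0 the right flank, with a
# linear blend within 15 degrees of the head-on/tail-on views; lying-left
# animals always show the right flank and lying-right the left flank.
left_flank_weight <- function(behaviour, theta) {
  if (behaviour == "ll") return(0)
  if (behaviour == "lr") return(1)
  t <- sin(deg2rad(15))
  min(1, max(0, (sin(deg2rad(theta)) + t) / (2 * t)))
}

# Canonical-frame canvas (image + mask) before rotation to the instance
# orientation.  Deterministic in (appearance, behaviour, theta).
base_canvas <- function(app, behaviour, theta, canvas_px) {
  len_scale <- if (behaviour == "s") 0.45 + 0.55 * abs(sin(deg2rad(theta))) else 1
  mask <- silhouette_mask(behaviour, canvas_px, len_scale)
  texL <- flank_texture(app$left_flank_seed, canvas_px, app$patch_scale,
                        app$white_fraction)
  texR <- flank_texture(app$right_flank_seed, canvas_px, app$patch_scale,
                        app$white_fraction)
  alpha <- left_flank_weight(behaviour, theta)
  white <- alpha * texL + (1 - alpha) * texR
  base <- base_colour_rgb(app$base_colour)
  img <- array(0, dim = c(canvas_px, canvas_px, 3))
  noise_seed <- derive_seed(app$left_flank_seed,
                            round(theta * 16) + 7L * match(behaviour, BEHAVIOURS))
  noise <- withr::with_seed(noise_seed,
                            matrix(rnorm(canvas_px^2, sd = 0.02),
                                   canvas_px, canvas_px))
  for (ch in 1:3) {
    plane <- base[ch] + (0.92 - base[ch]) * white + noise
    img[, , ch] <- pmin(1, pmax(0, plane)) * mask
  }
  list(image = img, mask = mask)
}

#' Render an instance segment of one identity
#'
#' Composes the behaviour-dependent silhouette with the flank texture dictated
#' by (behaviour, orientation), rotates the canvas to the instance
#' orientation, and optionally cuts an occlusion band.  For a mirrored
#' identity the render equals the left-right flip of the parent's render at
#' the mirrored behaviour and orientation (when `occlusion = 0`), up to
#' floating-point rounding of the bilinear weights.
#'
#' @param app a `cow_identity`.
#' @param behaviour one of `ll`, `lr`, `s`.
#' @param orientation_deg orientation in `[0, 360)` (spine angle, 0 = +x,
#'   counter-clockwise positive).
#' @param canvas_px square canvas size in pixels.
#' @param occlusion fraction of the canvas occluded by a black band, in
#'   `[0, 0.4]`.
#' @param seed seed for the occlusion band placement.
#' @return object of class `cow_segment`: list with `image` (h x w x 3),
#'   `mask` (h x w in \{0,1\}), and the metadata fields.
#' @export
render_instance <- function(app, behaviour, orientation_deg, canvas_px = 256,
                            occlusion = 0, seed = 0L) {
  stopifnot(inherits(app, "cow_identity"))
  stopifnot_behaviour(behaviour)
  if (orientation_deg < 0 || orientation_deg >= 360) {
    stop("orientation_deg must lie in [0, 360)")
  }
  if (occlusion < 0 || occlusion > 0.4) {
    stop("occlusion must lie in [0, 0.4] (the augmentation cap)")
  }
  if (app$mirrored) {
    cv <- base_canvas(app$parent, swap_behaviour(behaviour),
                      mirror_orientation(orientation_deg), canvas_px)
    cv$image <- img_flip_v(cv$image)
    cv$mask <- img_flip_v(cv$mask)
  } else {
    cv <- base_canvas(app, behaviour, orientation_deg, canvas_px)
  }
  img <- img_rotate(cv$image, orientation_deg)
  mask <- (img_rotate(cv$mask, orientation_deg) > 0.5) * 1
  img <- img * as.vector(mask)
  if (occlusion > 0) {
    wband <- max(1L, round(occlusion * canvas_px))
    withr::with_seed(derive_seed(seed, 11L), {
      horiz <- runif(1) < 0.5
      pos <- sample.int(canvas_px - wband + 1L, 1)
    })
    sel <- pos:(pos + wband - 1L)
    if (horiz) { img[sel, , ] <- 0; mask[sel, ] <- 0 }
    else { img[, sel, ] <- 0; mask[, sel] <- 0 }
  }
  structure(list(
    image = img, mask = mask, identity_id = app$identity_id,
    behaviour = behaviour, orientation_deg = orientation_deg,
    occluded_fraction = occlusion, coat_class = app$coat,
    mirrored = app$mirrored
  ), class = "cow_segment")
}

# Largest-remainder allocation of n identities over the coat mix.
allocate_coats <- function(n_ids, coat_mix) {
  if (length(coat_mix) == 0 || sum(coat_mix) <= 0) stop("empty coat_mix")
  share <- n_ids * coat_mix / sum(coat_mix)
  cnt <- floor(share)
  rem <- n_ids - sum(cnt)
  if (rem > 0) {
    ord <- order(share - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  rep(names(coat_mix), times = cnt)
}

# Bimodal lying-orientation sampler: wrapped-normal modes 180 degrees apart.
sample_orientation <- function(n, behaviour, modes = c(45, 225), sd = 20) {
  if (behaviour == "s") return(runif(n, 0, 360))
  mu <- modes[sample.int(2, n, replace = TRUE)]
  norm_angle(rnorm(n, mean = mu, sd = sd))
}

#' Generate a synthetic instance-segment dataset
#'
#' @param n_ids number of identities.
#' @param per_id instances per identity.
#' @param coat_mix named frequency table over coat classes (default: the herd
#'   composition `r 7, b 6, rw 12, bw 11, wr 10, wb 2`).
#' @param seed integer seed; generation is bit-reproducible given it.
#' @param canvas_px canvas size (default 256).
#' @param behaviour_probs sampling probabilities for `ll`, `lr`, `s`.
#' @param lying_modes centres of the two lying-orientation modes (degrees,
#'   180 apart by default).
#' @param occlusion_range range from which per-instance occlusion fractions
#'   are drawn uniformly.
#' @param patch_scale patch length scale in pixels; defaults to canvas/6.
#' @return object of class `cow_dataset`: list with `segments` (list of
#'   `cow_segment`), `metadata` (data.frame), `identities`.
#' @export
generate_dataset <- function(n_ids, per_id, coat_mix = default_coat_mix(),
                             seed = 1L, canvas_px = 256,
                             behaviour_probs = c(ll = 0.25, lr = 0.25, s = 0.5),
                             lying_modes = c(45, 225),
                             occlusion_range = c(0, 0.2),
                             patch_scale = NULL) {
  stopifnot(n_ids >= 1, per_id >= 1)
  patch_scale <- patch_scale %||% (canvas_px / 6)
  coats <- allocate_coats(n_ids, coat_mix)
  ids <- lapply(seq_len(n_ids), function(i) {
    app <- generate_identity(derive_seed(seed, 1000L + i), coats[i], patch_scale)
    app$identity_id <- sprintf("id%03d", i)
    app
  })
  segments <- vector("list", n_ids * per_id)
  meta <- vector("list", n_ids * per_id)
  k <- 0L
  for (i in seq_len(n_ids)) {
    draws <- withr::with_seed(derive_seed(seed, 2000L + i), {
      beh <- sample(BEHAVIOURS, per_id, replace = TRUE,
                    prob = behaviour_probs[BEHAVIOURS])
      ori <- vapply(beh, function(b) {
        sample_orientation(1, b, modes = lying_modes)
      }, numeric(1))
      occ <- runif(per_id, occlusion_range[1], occlusion_range[2])
      oseed <- sample.int(2^30, per_id)
      list(beh = beh, ori = ori, occ = occ, oseed = oseed)
    })
    for (j in seq_len(per_id)) {
      k <- k + 1L
      segments[[k]] <- render_instance(ids[[i]], draws$beh[j], draws$ori[j],
                                       canvas_px, draws$occ[j], draws$oseed[j])
      meta[[k]] <- data.frame(
        file = sprintf("seg%05d.png", k),
        identity = ids[[i]]$identity_id,
        behaviour = draws$beh[j],
        orientation_deg = draws$ori[j],
        coat_class = ids[[i]]$coat,
        occluded_fraction = draws$occ[j],
        split = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  structure(list(segments = segments, metadata = metadata, identities = ids,
                 canvas_px = canvas_px),
            class = "cow_dataset")
}

#' Write a dataset as RGBA PNGs plus a metadata CSV
#'
#' The alpha channel of each PNG carries the instance mask.
#'
#' @param dataset a `cow_dataset`.
#' @param dir output directory (created if missing).
#' @return the metadata path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(dataset$segments)) {
    seg <- dataset$segments[[k]]
    h <- nrow(seg$mask); w <- ncol(seg$mask)
    rgba <- array(0, dim = c(h, w, 4))
    rgba[, , 1:3] <- seg$image
    rgba[, , 4] <- seg$mask
    png::writePNG(rgba, file.path(dir, dataset$metadata$file[k]))
  }
  path <- file.path(dir, "metadata.csv")
  write_metadata(dataset$metadata, path)
  invisible(path)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir directory containing the PNGs and `metadata.csv`.
#' @return a `cow_dataset` (without identity appearances).
#' @export
load_dataset <- function(dir) {
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  segments <- lapply(seq_len(nrow(meta)), function(k) {
    rgba <- png::readPNG(file.path(dir, meta$file[k]))
    structure(list(
      image = rgba[, , 1:3, drop = FALSE], mask = (rgba[, , 4] > 0.5) * 1,
      identity_id = meta$identity[k], behaviour = meta$behaviour[k],
      orientation_deg = meta$orientation_deg[k],
      occluded_fraction = meta$occluded_fraction[k] %||% NA_real_,
      coat_class = meta$coat_class[k] %||% NA_character_, mirrored = FALSE
    ), class = "cow_segment")
  })
  structure(list(segments = segments, metadata = meta, identities = NULL,
                 canvas_px = nrow(segments[[1]]$mask)),
            class = "cow_dataset")
}
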