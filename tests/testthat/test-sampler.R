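# Conditional batch sampling, behaviour-probability adaptation, mirroring and
# augmentation.

meta_only_dataset <- function(meta) list(metadata = meta, segments = NULL)

test_that("conditioned batches are behaviour-pure inside the orientation window", {
  ds <- small_dataset()
  for (s in 1:10) {
    b <- sample_conditioned_batch(ds, sampling_state(), seed = s)
    expect_length(b$indices, 25)
    expect_length(unique(b$indices), 25)
    meta <- ds$metadata[b$indices, ]
    expect_equal(length(unique(meta$identity)), 5)
    expect_true(all(table(meta$identity) == 5))
    expect_equal(length(unique(meta$behaviour)), 1)
    expect_equal(meta$behaviour[1], b$spec$behaviour)
    d <- circular_distance(meta$orientation_deg, b$spec$centre_orientation)
    expect_true(all(d <= b$spec$half_width + 1e-9))
    expect_gte(b$spec$half_width, 22.5)
  }
})

test_that("the window widens in 2.5-degree-per-side steps only when needed", {
  # five identities whose standing instances cluster tightly at 0 degrees:
  # most sampled centres force widening well beyond the initial 22.5 degrees
  set.seed(2)
  meta <- data.frame(
    identity = rep(sprintf("c%d", 1:5), each = 6),
    behaviour = "s",
    orientation_deg = runif(30, 0, 10),
    stringsAsFactors = FALSE
  )
  widened <- FALSE
  standing_only <- sampling_state(c(ll = 0, lr = 0, s = 1))
  for (s in 1:20) {
    b <- sample_conditioned_batch(meta_only_dataset(meta), standing_only,
                                  seed = s)
    hw <- b$spec$half_width
    expect_equal((hw - 22.5) %% 2.5, 0)
    if (hw > 45) widened <- TRUE
    d <- circular_distance(
      meta$orientation_deg[b$indices], b$spec$centre_orientation)
    expect_true(all(d <= hw + 1e-9))
  }
  expect_true(widened)
  # an identity with too few instances of the behaviour is reported
  meta_bad <- meta[-(1:2), ]
  errs <- vapply(1:30, function(s) {
    tryCatch({
      sample_conditioned_batch(meta_only_dataset(meta_bad), standing_only,
                               seed = s)
      NA_character_
    }, error = function(e) conditionMessage(e))
  }, character(1))
  expect_true(any(grepl("fewer than 5|only 4 identities", errs)))
})

test_that("orientation windows are circular", {
  expect_equal(circular_distance(10, 350), 20)
  expect_lte(circular_distance(10, 350), 22.5)  # inside the initial window
  expect_equal(circular_distance(0, 180), 180)
  expect_equal(circular_distance(359, 1), 2)
})

test_that("unconditioned batches share shape but not homogeneity", {
  ds <- small_dataset()
  b <- sample_unconditioned_batch(ds, seed = 3)
  expect_length(b$indices, 25)
  expect_equal(length(unique(ds$metadata$identity[b$indices])), 5)
  expect_identical(b$indices, sample_unconditioned_batch(ds, seed = 3)$indices)
  mixed <- any(vapply(1:10, function(s) {
    bi <- sample_unconditioned_batch(ds, seed = s)$indices
    length(unique(ds$metadata$behaviour[bi])) > 1
  }, logical(1)))
  expect_true(mixed)
})

test_that("behaviour probabilities track 1 - acc1 with a 1/6 floor", {
  st <- sampling_state()
  expect_equal(st$floor, 1 / 6)
  even <- update_behaviour_probs(c(ll = 0.9, lr = 0.9, s = 0.9))
  expect_equal(unname(even$behaviour_probs), rep(1 / 3, 3))
  hard <- update_behaviour_probs(c(ll = 1, lr = 1, s = 0.4))
  expect_equal(unname(hard$behaviour_probs[c("ll", "lr", "s")]),
               c(1 / 6, 1 / 6, 2 / 3))
  solved <- update_behaviour_probs(c(ll = 1, lr = 1, s = 1))
  expect_equal(unname(solved$behaviour_probs), rep(1 / 3, 3))
  # property: sums to one and respects the floor for random accuracies
  set.seed(8)
  for (k in 1:200) {
    st2 <- update_behaviour_probs(setNames(runif(3), c("ll", "lr", "s")))
    expect_equal(sum(st2$behaviour_probs), 1, tolerance = 1e-12)
    expect_true(all(st2$behaviour_probs >= 1 / 6 - 1e-9))
  }
})

test_that("mirroring doubles identities, swaps lying sides, maps angles", {
  ds <- generate_dataset(n_ids = 3, per_id = 6, seed = 12, canvas_px = 32)
  m <- mirror_augment(ds)
  expect_equal(length(m$segments), 2 * length(ds$segments))
  expect_equal(length(unique(m$metadata$identity)),
               2 * length(unique(ds$metadata$identity)))
  n <- nrow(ds$metadata)
  swapped <- m$metadata$behaviour[(n + 1):(2 * n)]
  expect_equal(swapped[ds$metadata$behaviour == "ll"],
               rep("lr", sum(ds$metadata$behaviour == "ll")))
  expect_equal(swapped[ds$metadata$behaviour == "s"],
               rep("s", sum(ds$metadata$behaviour == "s")))
  expect_equal(m$metadata$orientation_deg[(n + 1):(2 * n)],
               (180 - ds$metadata$orientation_deg) %% 360)
  expect_equal(mirror_orientation(30), 150)
  # per-identity instance counts and coat classes survive
  expect_equal(unname(table(m$metadata$identity)[paste0(ds$metadata$identity[1], "_m")]),
               unname(table(ds$metadata$identity)[ds$metadata$identity[1]]))
  expect_equal(m$metadata$coat_class[n + 1], ds$metadata$coat_class[1])
  # involution up to renaming: flipping twice restores the images
  m2 <- mirror_augment(m)
  expect_identical(m2$segments[[3 * n + 1]]$image, ds$segments[[1]]$image)
})

test_that("augmentation respects its magnitude caps", {
  ds <- small_dataset()
  seg <- ds$segments[[1]]
  for (s in 1:1000) {
    a <- augment_image(seg, seed = s)
    p <- attr(a, "augment_params")
    expect_lte(p$occlusion, 0.4)
    expect_lte(abs(p$rotation), 10)
    expect_lte(abs(p$shear), 0.1)
  }
  # zero magnitudes: exact identity
  same <- augment_image(seg, seed = 1, jitter = 0, rotation = 0, shear = 0,
                        scale = 0, occlude_max = 0)
  expect_identical(same$image, seg$image)
  # the occlusion band blacks out at most ~40 percent of the raster
  ones <- structure(list(image = array(1, dim = c(64, 64, 3)),
                         mask = matrix(1, 64, 64)), class = "cow_segment")
  for (s in 1:200) {
    a <- augment_image(ones, seed = s, jitter = 0, rotation = 0, shear = 0,
                       scale = 0, occlude_max = 0.4)
    expect_lte(mean(a$image == 0), 0.41)
  }
})

test_that("fictive-individual accounting multiplies bins, mirror and herd size", {
  bins_bimodal <- c(s = 8, ll = 2, lr = 2)
  expect_equal(fictive_individual_count(1, bins_bimodal, mirrored = TRUE), 24)
  expect_equal(fictive_individual_count(1, c(s = 8, ll = 8, lr = 8),
                                        mirrored = FALSE), 24)
  expect_equal(fictive_individual_count(36, bins_bimodal, mirrored = TRUE), 864)
  expect_error(fictive_individual_count(1, c(s = 0, ll = 2, lr = 2)), "bins")
})
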