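# Behaviour-extended multi-task loss, ground truth, beta adaptation,
# skeleton association and orientation estimation.

make_stack <- function(h, w, seed = 1, predicted = TRUE) {
  withr::with_seed(seed, {
    P <- array(runif(h * w * 6), dim = c(h, w, 6))
    A <- array(rnorm(h * w * 24), dim = c(h, w, 24))
    B <- array(runif(h * w * 3), dim = c(h, w, 3))
  })
  if (predicted) {
    sums <- B[, , 1] + B[, , 2] + B[, , 3]
    for (ch in 1:3) B[, , ch] <- B[, , ch] / sums
  } else {
    B <- (B > 0.6) * 1
  }
  heatmap_stack(P, A, B, predicted = predicted)
}

test_that("behaviour ground truth marks the displayed behaviour above 0.2", {
  hm <- matrix(c(0.3, 0.1, 0.25, 0.05), 2, 2)
  gt <- build_behaviour_ground_truth(hm, "s")
  expect_equal(gt[, , 3], (hm > 0.2) * 1)
  expect_equal(gt[, , 1], matrix(0, 2, 2))
  expect_equal(gt[, , 2], matrix(0, 2, 2))
  expect_equal(build_behaviour_ground_truth(matrix(0, 3, 3), "ll"),
               array(0, dim = c(3, 3, 3)))
  # several animals: accumulate per animal, clip to {0,1}
  gt2 <- build_behaviour_ground_truth(list(hm, hm * 0.9), c("s", "s"))
  expect_true(all(gt2 %in% c(0, 1)))
  expect_equal(gt2[1, 1, 3], 1)
  expect_error(build_behaviour_ground_truth(hm, "sideways"), "behaviour")
})

# Independent scalar-loop computation of the three loss terms.
loop_loss <- function(pred, truth, wts) {
  loc <- 0
  for (ch in 1:dim(pred$P)[3]) for (i in 1:pred$h) for (j in 1:pred$w) {
    loc <- loc + (pred$P[i, j, ch] - truth$P[i, j, ch])^2
  }
  loc <- wts$beta1 * loc / (pred$w * pred$h * dim(pred$P)[3])
  ass <- 0; nA <- 0
  for (ch in 1:24) for (i in 1:pred$h) for (j in 1:pred$w) {
    if (truth$A[i, j, ch] != 0) {
      nA <- nA + 1
      ass <- ass + abs(pred$A[i, j, ch] - truth$A[i, j, ch])^wts$gamma
    }
  }
  ass <- wts$beta2 * ass / (1 + nA)
  beh <- 0; nB <- 0
  for (ch in 1:3) for (i in 1:pred$h) for (j in 1:pred$w) {
    if (truth$B[i, j, ch] != 0) nB <- nB + 1
    beh <- beh + truth$B[i, j, ch] * log(pred$B[i, j, ch] + 1e-10)
  }
  beh <- -wts$beta3 * beh / (1 + nB)
  list(total = loc + ass + beh, location = loc, association = ass,
       behaviour = beh)
}

test_that("multi-task loss matches a scalar-loop oracle on random stacks", {
  for (trial in 1:100) {
    pred <- make_stack(3, 4, seed = trial, predicted = TRUE)
    truth <- make_stack(3, 4, seed = trial + 1000, predicted = FALSE)
    truth$B <- build_behaviour_ground_truth(truth$P[, , 1],
                                            sample(c("ll", "lr", "s"), 1))
    wts <- loss_weights(beta1 = runif(1, 0.5, 2), beta2 = runif(1, 0.5, 2),
                        beta3 = runif(1, 0.5, 2))
    got <- multitask_loss(pred, truth, wts)
    want <- loop_loss(pred, truth, wts)
    expect_equal(got$location, want$location, tolerance = 1e-8)
    expect_equal(got$association, want$association, tolerance = 1e-8)
    expect_equal(got$behaviour, want$behaviour, tolerance = 1e-8)
    expect_equal(got$total,
                 got$location + got$association + got$behaviour,
                 tolerance = 1e-12)
    expect_gte(got$location, 0)
    expect_gte(got$association, 0)
    expect_gte(got$behaviour, -1e-9)
  }
})

test_that("perfect predictions give (near-)zero loss terms", {
  truth <- make_stack(4, 4, seed = 3, predicted = FALSE)
  truth$B <- build_behaviour_ground_truth(truth$P[, , 1], "s")
  pred <- truth
  # behaviour channels must be probabilities; set the displayed channel to ~1
  eps <- 1e-12
  pred$B <- array(eps, dim = dim(truth$B))
  pred$B[, , 3] <- 1 - 2 * eps
  pred$predicted <- TRUE
  got <- multitask_loss(pred, truth)
  expect_equal(got$location, 0)
  expect_equal(got$association, 0)
  expect_lt(abs(got$behaviour), 1e-6)
  expect_error(multitask_loss(make_stack(5, 5), truth), "shapes")
})

test_that("beta adaptation balances the three terms to 1/3 each", {
  w <- adapt_betas(c(0.5, 2.0, 0.1))
  expect_equal(c(w$beta1, w$beta2, w$beta3), c(2 / 3, 1 / 6, 10 / 3))
  # rescaled means are 1/3 each, total mean loss 1
  expect_equal(w$beta1 * 0.5, 1 / 3)
  expect_equal(w$beta2 * 2.0, 1 / 3)
  expect_equal(w$beta3 * 0.1, 1 / 3)
  expect_equal(w$beta1 * 0.5 + w$beta2 * 2 + w$beta3 * 0.1, 1)
  balanced <- adapt_betas(c(1, 1, 1) / 3)
  expect_equal(c(balanced$beta1, balanced$beta2, balanced$beta3), c(1, 1, 1))
  # idempotence: same history, same weights
  expect_identical(adapt_betas(c(0.5, 2.0, 0.1)), adapt_betas(c(0.5, 2.0, 0.1)))
  expect_error(adapt_betas(c(0, 1, 1)), "positive")
})

test_that("segments associate with the unique skeleton whose withers is inside", {
  m1 <- matrix(0, 10, 10); m1[2:5, 2:5] <- 1
  m2 <- matrix(0, 10, 10); m2[7:9, 7:9] <- 1
  sk_in <- skeleton(withers = c(3, 3), tail_implant = c(4, 4))
  sk_out <- skeleton(withers = c(0, 0))
  sk_in2 <- skeleton(withers = c(4, 2))
  res <- associate_segments_skeletons(list(m1, m2), list(sk_in, sk_out))
  expect_equal(res$pairs$segment, 1)
  expect_equal(res$pairs$skeleton, 1)
  expect_equal(res$discarded$segment, 2)
  # two candidate skeletons: discard
  res2 <- associate_segments_skeletons(list(m1), list(sk_in, sk_in2))
  expect_equal(nrow(res2$pairs), 0)
  expect_match(res2$discarded$reason, "2 skeletons")
  # skeleton without withers is never a candidate
  res3 <- associate_segments_skeletons(list(m1),
                                       list(skeleton(tail_implant = c(3, 3))))
  expect_equal(nrow(res3$pairs), 0)
})

test_that("orientation follows the tail-to-withers vector with fallbacks", {
  expect_equal(estimate_orientation(skeleton(withers = c(1, 0),
                                             tail_implant = c(0, 0))), 0)
  expect_equal(estimate_orientation(skeleton(withers = c(0, 1),
                                             tail_implant = c(0, 0))), 90)
  # hip-midpoint fallback
  expect_equal(estimate_orientation(skeleton(withers = c(1, 0),
                                             hip_left = c(0, 1),
                                             hip_right = c(0, -1))), 0)
  # single-hip fallback
  expect_equal(estimate_orientation(skeleton(withers = c(1, 1),
                                             hip_left = c(0, 1))), 0)
  expect_error(estimate_orientation(skeleton(tail_implant = c(0, 0))),
               "withers")
  expect_error(estimate_orientation(skeleton(withers = c(1, 0))),
               "no tail implant or hip")
})

test_that("orientation commutes with the left-right mirror convention", {
  mirror_skel <- function(sk) {
    kp <- lapply(sk$keypoints, function(p) { p["x"] <- -p["x"]; p })
    # left/right keypoints swap under mirroring
    nm <- names(kp)
    nm[nm == "hip_left"] <- "tmp"; nm[nm == "hip_right"] <- "hip_left"
    nm[nm == "tmp"] <- "hip_right"
    names(kp) <- nm
    structure(list(keypoints = kp), class = "cow_skeleton")
  }
  set.seed(31)
  for (k in 1:50) {
    sk <- skeleton(withers = c(rnorm(2), 1), tail_implant = c(rnorm(2), 1),
                   hip_left = c(rnorm(2), 1), hip_right = c(rnorm(2), 1))
    th <- estimate_orientation(sk)
    thm <- estimate_orientation(mirror_skel(sk))
    expect_equal(thm, mirror_orientation(th), tolerance = 1e-10)
  }
})

test_that("behaviour decoding averages over the central-heat region", {
  # constant field: label s with probability 0.7
  P <- array(0, dim = c(5, 5, 6)); P[, , 1] <- 0.5
  A <- array(0, dim = c(5, 5, 24))
  B <- array(0, dim = c(5, 5, 3))
  B[, , 1] <- 0.1; B[, , 2] <- 0.2; B[, , 3] <- 0.7
  st <- heatmap_stack(P, A, B, predicted = TRUE)
  got <- decode_behaviour(st, c(2, 2))
  expect_equal(got$value, "s")
  expect_equal(got$probability, 0.7)
  # loop oracle on a random 5x5 stack
  st2 <- make_stack(5, 5, seed = 77)
  st2$P[, , 1] <- matrix(runif(25), 5, 5)
  got2 <- decode_behaviour(st2, c(2, 2))
  region <- st2$P[, , 1] > 0.2
  avg <- c(0, 0, 0)
  for (ch in 1:3) avg[ch] <- mean(st2$B[, , ch][region])
  expect_equal(got2$value, c("ll", "lr", "s")[which.max(avg)])
  # tie: ll wins by fixed channel order
  B3 <- array(0, dim = c(5, 5, 3)); B3[, , 1] <- 0.5; B3[, , 2] <- 0.5
  st3 <- heatmap_stack(P, A, B3, predicted = TRUE)
  expect_equal(decode_behaviour(st3, c(2, 2))$value, "ll")
  # empty region falls back to the withers pixel
  P0 <- array(0, dim = c(5, 5, 6))
  st4 <- heatmap_stack(P0, A, B, predicted = TRUE)
  expect_equal(decode_behaviour(st4, c(1, 3))$value, "s")
})
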