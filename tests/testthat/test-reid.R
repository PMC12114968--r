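# Reference gallery, conditional subset selection, KNN ranking and the joint
# unique-assignment extension.

make_db <- function(m = 60, seed = 1, ids = letters[1:6]) {
  withr::with_seed(seed, {
    emb <- runit(m)
    reference_database(emb,
                       identity = sample(ids, m, replace = TRUE),
                       behaviour = sample(c("ll", "lr", "s"), m, replace = TRUE),
                       orientation_deg = runif(m, 0, 360))
  })
}

test_that("the minimum subset size is ceil(N / (16 B)), floored at one", {
  expect_equal(min_subset_size(480, 3), 10)
  expect_equal(min_subset_size(48, 3), 1)
  expect_equal(min_subset_size(49, 3), 2)   # ceiling of 49/48
  expect_equal(min_subset_size(1, 3), 1)
  expect_error(min_subset_size(480, 0), "positive")
  db <- make_db(96)
  expect_equal(min_subset_size(db), 2)
})

test_that("m_min is a quarter of the homogeneous 90-degree-window population", {
  for (N in c(480, 1536, 9600)) for (B in c(2, 3, 4)) {
    raw <- N / (16 * B)                  # before rounding
    expected_window <- (90 / 360) * N / B
    expect_equal(raw / expected_window, 0.25)
  }
})

test_that("subset selection honours behaviour, circular window and expansion", {
  withr::with_seed(3, {
    emb <- runit(40)
    db <- reference_database(
      emb, identity = rep(letters[1:4], 10),
      behaviour = rep(c("s", "ll"), each = 20),
      orientation_deg = c(350, seq(0, 324, by = 18), rep(c(100, 300), 10)))
  })
  sub <- select_subset(db, "s", theta = 10, half_width = 45, m_min = 1)
  expect_true(all(db$index$behaviour[sub$idx] == "s"))
  expect_true(all(circular_distance(db$index$orientation_deg[sub$idx], 10) <= 45))
  # an entry at 350 degrees is within 20 degrees of a 10-degree query
  expect_true(any(abs(db$index$orientation_deg[sub$idx] - 350) < 1e-9))
  # expansion: demand more entries than the initial window holds
  sub2 <- select_subset(db, "s", theta = 10, half_width = 45, m_min = 15)
  expect_gte(sub2$m, 15)
  expect_gt(sub2$half_width, 45)
  # exhaustion: behaviour with 2 entries expands to the full circle
  db2 <- reference_database(runit(4), rep("a", 4), c("s", "s", "ll", "ll"),
                            c(10, 200, 0, 0))
  sub3 <- select_subset(db2, "s", theta = 100, half_width = 45, m_min = 2)
  expect_equal(sub3$m, 2)
  expect_error(select_subset(db2, "lr", 0), "no entries")
})

test_that("selection is independent of entry order and meets m_min when possible", {
  db <- make_db(120, seed = 9)
  sub <- select_subset(db, "s", 77)
  perm <- withr::with_seed(1, sample(120))
  dbp <- reference_database(db$embeddings[perm, ], db$index$identity[perm],
                            db$index$behaviour[perm],
                            db$index$orientation_deg[perm])
  subp <- select_subset(dbp, "s", 77)
  expect_setequal(perm[subp$idx], sub$idx)
  expect_gte(sub$m, min_subset_size(db))
})

test_that("matrix-form similarities equal the pairwise loop", {
  withr::with_seed(7, {
    a <- runit(1)[1, ]
    B <- runit(7)
  })
  sims <- cosine_similarities(a, B)
  loop <- vapply(1:7, function(i) sum(a * B[i, ]), numeric(1))
  expect_lt(max(abs(sims - loop)), 1e-10)
  expect_equal(cosine_similarities(a, matrix(a, 1)), 1, tolerance = 1e-12)
  b_orth <- c(-a[2], a[1], rep(0, 30)) / sqrt(a[1]^2 + a[2]^2)
  expect_equal(cosine_similarities(b_orth, matrix(a, 1)), 0, tolerance = 1e-12)
  expect_error(cosine_similarities(a[1:5], B), "dimension mismatch")
})

# brute-force KNN vote ranking used as oracle
brute_rank <- function(sims, ids, k) {
  top <- order(sims, decreasing = TRUE)[1:k]
  vt <- vapply(unique(ids[top]), function(id) sum(ids[top] == id), integer(1))
  ms <- vapply(unique(ids[top]), function(id) mean(sims[top][ids[top] == id]),
               numeric(1))
  o <- order(-vt, -ms, unique(ids[top]))
  ranked <- unique(ids[top])[o]
  rest <- setdiff(unique(ids), ranked)
  bs <- vapply(rest, function(id) max(sims[ids == id]), numeric(1))
  c(ranked, rest[order(-bs, rest)])
}

test_that("KNN ranking matches exhaustive vote enumeration", {
  expect_equal(rank_identities(c(0.9, 0.8, 0.2), c("A", "A", "B"), 3)$identity,
               c("A", "B"))
  # vote tie broken by mean similarity of the voting neighbours
  tie <- rank_identities(c(0.9, 0.8), c("A", "B"), 2)
  expect_equal(tie$identity, c("A", "B"))
  expect_equal(tie$votes, c(1L, 1L))
  for (trial in 1:50) {
    withr::with_seed(trial, {
      m <- sample(5:30, 1)
      sims <- round(runif(m, -1, 1), 3)
      ids <- sample(LETTERS[1:5], m, replace = TRUE)
      k <- sample(m, 1)
    })
    if (anyDuplicated(sims)) next   # keep the top-k cut unambiguous
    expect_equal(rank_identities(sims, ids, k)$identity,
                 brute_rank(sims, ids, k))
  }
  expect_error(rank_identities(c(1, 0), c("A", "B"), 3), "k must lie")
})

test_that("re-identification recovers the query's own identity", {
  ds <- generate_dataset(n_ids = 5, per_id = 20, seed = 33, canvas_px = 64)
  emb <- predict(trained_embedder(), ds$segments)
  q_i <- which(ds$metadata$behaviour == "s")[1]
  q <- list(embedding = emb[q_i, ], behaviour = ds$metadata$behaviour[q_i],
            orientation_deg = ds$metadata$orientation_deg[q_i])
  # a gallery holding only the query identity's references: rank 1 trivially
  own <- which(ds$metadata$identity == ds$metadata$identity[q_i])
  db_own <- reference_database(emb[own, ], ds$metadata$identity[own],
                               ds$metadata$behaviour[own],
                               ds$metadata$orientation_deg[own])
  expect_equal(reidentify(db_own, q)$ranking$identity[1],
               ds$metadata$identity[q_i])
  # the full five-identity gallery, embedded with a trained network: across
  # many self-queries (each query is one of its own references) the identity
  # is recovered far above the 1-in-5 chance level
  db <- reference_database(emb, ds$metadata$identity, ds$metadata$behaviour,
                           ds$metadata$orientation_deg)
  hits <- vapply(seq_len(100), function(i) {
    qi <- list(embedding = emb[i, ], behaviour = ds$metadata$behaviour[i],
               orientation_deg = ds$metadata$orientation_deg[i])
    reidentify(db, qi)$ranking$identity[1] == ds$metadata$identity[i]
  }, logical(1))
  expect_gt(mean(hits), 0.6)
  r <- reidentify(db, q)
  expect_equal(r$diagnostics$k, ceiling(sqrt(r$diagnostics$m)))
  # the literal k = m rule is available behind a flag
  r2 <- reidentify(db, q, k_rule = "all")
  expect_equal(r2$diagnostics$k, r2$diagnostics$m)
  # ranking is invariant to gallery permutation
  perm <- withr::with_seed(4, sample(nrow(emb)))
  dbp <- reference_database(emb[perm, ], ds$metadata$identity[perm],
                            ds$metadata$behaviour[perm],
                            ds$metadata$orientation_deg[perm])
  expect_equal(reidentify(dbp, q)$ranking, r$ranking)
})

test_that("the Hungarian assignment matches brute force over permutations", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(1:n, function(i) {
      cbind(i, matrix(setdiff(1:n, i)[p], nrow(p))) }))
  }
  for (trial in 1:50) {
    withr::with_seed(trial, {
      n <- sample(2:5, 1)
      cost <- matrix(runif(n * n), n)
    })
    got <- cowreid:::hungarian(cost)
    pp <- perms(n)
    vals <- apply(pp, 1, function(pr) sum(cost[cbind(1:n, pr)]))
    expect_equal(sum(cost[cbind(1:n, got)]), min(vals), tolerance = 1e-12)
  }
})

test_that("joint re-identification maximises the product of identity probabilities", {
  # single query: degenerate case equals the independent rank-1
  db <- make_db(80, seed = 21, ids = c("x", "y", "z"))
  q <- list(embedding = db$embeddings[5, ], behaviour = db$index$behaviour[5],
            orientation_deg = db$index$orientation_deg[5])
  expect_equal(joint_reidentify(list(q), db)[1],
               reidentify(db, q)$ranking$identity[1])
  # oracle: recompute the probability matrix from exported outputs and
  # enumerate all one-to-one assignments
  joint_oracle <- function(queries, db) {
    ids <- sort(unique(db$index$identity))
    P <- t(vapply(queries, function(qq) {
      r <- reidentify(db, qq, conditioned = FALSE)
      v <- setNames(rep(0, length(ids)), ids)
      v[r$ranking$identity] <- r$ranking$votes
      w <- v + 1 / r$diagnostics$m
      w / sum(w)
    }, numeric(length(ids))))
    perms <- expand.grid(rep(list(seq_along(ids)), length(queries)))
    perms <- perms[apply(perms, 1, anyDuplicated) == 0, , drop = FALSE]
    best <- which.max(apply(perms, 1, function(pr) {
      sum(log(P[cbind(seq_along(queries), as.integer(pr))]))
    }))
    ids[as.integer(perms[best, ])]
  }
  for (trial in 1:10) {
    withr::with_seed(100 + trial, {
      qs <- lapply(1:3, function(i) {
        e <- runit(1)[1, ]
        list(embedding = e, behaviour = sample(c("ll", "lr", "s"), 1),
             orientation_deg = runif(1, 0, 360))
      })
    })
    expect_equal(joint_reidentify(qs, db, conditioned = FALSE),
                 joint_oracle(qs, db))
  }
  expect_error(joint_reidentify(rep(list(q), 4), db), "more simultaneous")
})

test_that("two queries colliding on one identity resolve to distinct ones", {
  # search seeded cases until the independent argmaxes collide, then check the
  # joint assignment gives distinct identities and beats (or ties) the greedy
  # product probability
  db <- make_db(40, seed = 55, ids = c("a", "b", "c"))
  found <- FALSE
  for (s in 1:50) {
    qs <- withr::with_seed(s, lapply(1:2, function(i) {
      list(embedding = runit(1)[1, ],
           behaviour = sample(c("ll", "lr", "s"), 1),
           orientation_deg = runif(1, 0, 360))
    }))
    top1 <- vapply(qs, function(q) {
      reidentify(db, q, conditioned = FALSE)$ranking$identity[1]
    }, character(1))
    if (top1[1] != top1[2]) next
    found <- TRUE
    got <- joint_reidentify(qs, db, conditioned = FALSE)
    expect_equal(anyDuplicated(got), 0)
    # the collided identity stays with exactly one of the two queries
    expect_true(top1[1] %in% got)
    break
  }
  expect_true(found)
})
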