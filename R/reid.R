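# Metadata-aware re-identification: behaviour/orientation subset selection
# over a reference gallery with a minimum-size guarantee, cosine-similarity
# ranking, KNN identity voting, and joint unique-assignment over several
# simultaneous queries.

#' Build a reference database (gallery)
#'
#' @param embeddings m x d matrix of unit-norm reference embeddings.
#' @param identity,behaviour,orientation_deg per-entry metadata.
#' @return object of class `cow_refdb`.
#' @export
reference_database <- function(embeddings, identity, behaviour,
                               orientation_deg) {
  embeddings <- as.matrix(embeddings)
  m <- nrow(embeddings)
  stopifnot(length(identity) == m, length(behaviour) == m,
            length(orientation_deg) == m)
  stopifnot_behaviour(behaviour)
  if (any(orientation_deg < 0 | orientation_deg >= 360)) {
    stop("orientations must lie in [0, 360)")
  }
  norms <- sqrt(rowSums(embeddings^2))
  if (any(abs(norms - 1) > 1e-4)) {
    stop("reference embeddings must be L2-normalised")
  }
  structure(list(
    embeddings = embeddings,
    index = data.frame(identity = as.character(identity),
                       behaviour = as.character(behaviour),
                       orientation_deg = as.numeric(orientation_deg),
                       stringsAsFactors = FALSE)
  ), class = "cow_refdb")
}

#' @export
print.cow_refdb <- function(x, ...) {
  cat(sprintf("cow reference database: %d embeddings (%d-d), %d identities\n",
              nrow(x$embeddings), ncol(x$embeddings),
              length(unique(x$index$identity))))
  print(table(x$index$behaviour))
  invisible(x)
}

#' Minimum admissible gallery-subset size
#'
#' `ceil(N / (16 * B))` for `N` reference embeddings and `B` behaviours
#' (floored at 1): 25 percent of the expected number of embeddings inside a
#' 90-degree orientation window if references were spread homogeneously over
#' behaviours and orientations.
#'
#' @param db a `cow_refdb`, or the number of reference embeddings.
#' @param n_behaviours number of behaviours (3).
#' @return integer minimum subset size.
#' @export
min_subset_size <- function(db, n_behaviours = 3L) {
  if (n_behaviours <= 0) stop("n_behaviours must be positive")
  n <- if (inherits(db, "cow_refdb")) nrow(db$embeddings) else db
  if (n < 1) stop("empty reference database")
  max(1L, as.integer(ceiling(n / (16 * n_behaviours))))
}

#' Select the behaviour/orientation-conditioned gallery subset
#'
#' All entries with the query behaviour and an orientation within
#' `[theta - half_width, theta + half_width]` (circular, inclusive).  If
#' fewer than `m_min` entries qualify, the window expands symmetrically
#' (default 2.5 degrees per side per step) until `m >= m_min` or the window
#' covers the full circle.
#'
#' @param db a `cow_refdb`.
#' @param behaviour query behaviour.
#' @param theta query orientation in degrees.
#' @param half_width initial half-window (45 degrees).
#' @param m_min minimum subset size; defaults to [min_subset_size()].
#' @param widen_step expansion step per side in degrees.
#' @return list with `idx` (entry indices), `half_width` (final), `m`.
#' @export
select_subset <- function(db, behaviour, theta, half_width = 45,
                          m_min = NULL, widen_step = 2.5) {
  stopifnot(inherits(db, "cow_refdb"))
  stopifnot_behaviour(behaviour)
  m_min <- m_min %||% min_subset_size(db)
  beh_idx <- which(db$index$behaviour == behaviour)
  if (length(beh_idx) == 0) {
    stop("reference database holds no entries of behaviour '", behaviour, "'")
  }
  d <- circular_distance(db$index$orientation_deg[beh_idx], theta)
  hw <- half_width
  repeat {
    idx <- beh_idx[d <= hw]
    if (length(idx) >= m_min || hw >= 180) break
    hw <- min(180, hw + widen_step)
  }
  list(idx = idx, half_width = hw, m = length(idx))
}

#' Cosine similarities of a query embedding against gallery embeddings
#'
#' For unit-norm vectors the cosine similarity reduces to the dot product, so
#' all `m` similarities are one matrix product `B^T a`.
#'
#' @param a query embedding (unit norm).
#' @param B m x d matrix of gallery embeddings (rows) -- the column-stacked
#'   gallery matrix transposed.
#' @return numeric vector of `m` similarities in `[-1, 1]`.
#' @export
cosine_similarities <- function(a, B) {
  B <- as.matrix(B)
  if (length(a) != ncol(B)) stop("embedding dimension mismatch")
  as.numeric(B %*% a)
}

#' Rank candidate identities by KNN voting
#'
#' Takes the `k` most similar gallery entries; identities are ranked by vote
#' count, ties broken by the mean similarity of their voting neighbours.
#' Identities absent from the top-k follow, ranked by their best similarity.
#'
#' @param sims similarities of the query to the `m` subset entries.
#' @param identities corresponding identity labels.
#' @param k number of neighbours (`1 <= k <= m`).
#' @return data.frame (class `cow_ranking`) with columns `identity`, `votes`,
#'   `score` (mean voting similarity, or best similarity for unvoted
#'   identities), ordered best first.
#' @export
rank_identities <- function(sims, identities, k) {
  m <- length(sims)
  stopifnot(length(identities) == m)
  if (k < 1 || k > m) stop("k must lie in [1, m]")
  ord <- order(sims, decreasing = TRUE)
  top <- ord[seq_len(k)]
  vt <- table(identities[top])
  voted <- data.frame(
    identity = names(vt),
    votes = as.integer(vt),
    score = vapply(names(vt), function(id) {
      mean(sims[top][identities[top] == id])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  voted <- voted[order(-voted$votes, -voted$score, voted$identity), ]
  rest_ids <- setdiff(unique(identities), voted$identity)
  if (length(rest_ids)) {
    rest <- data.frame(
      identity = rest_ids,
      votes = 0L,
      score = vapply(rest_ids, function(id) max(sims[identities == id]),
                     numeric(1)),
      stringsAsFactors = FALSE
    )
    rest <- rest[order(-rest$score, rest$identity), ]
    voted <- rbind(voted, rest)
  }
  rownames(voted) <- NULL
  class(voted) <- c("cow_ranking", "data.frame")
  voted
}

#' Re-identify one query against the reference database
#'
#' Composition of subset selection, cosine similarities and KNN ranking.
#' By default `k = ceiling(sqrt(m))`; `k_rule = "all"` uses the full subset
#' (`k = m`, a subset-majority vote).
#'
#' @param db a `cow_refdb`.
#' @param query list with `embedding`, `behaviour`, `orientation_deg`.
#' @param half_width initial orientation half-window (45 degrees).
#' @param k_rule `"sqrt"` (default) or `"all"`.
#' @param conditioned if `FALSE`, skip metadata conditioning and rank against
#'   the whole gallery (the "without correction" protocol).
#' @return list with `ranking` (a `cow_ranking`) and `diagnostics`
#'   (final half-width, subset size `m`, `k`).
#' @export
reidentify <- function(db, query, half_width = 45, k_rule = c("sqrt", "all"),
                       conditioned = TRUE) {
  k_rule <- match.arg(k_rule)
  if (conditioned) {
    sub <- select_subset(db, query$behaviour, query$orientation_deg,
                         half_width = half_width)
  } else {
    sub <- list(idx = seq_len(nrow(db$embeddings)), half_width = NA_real_,
                m = nrow(db$embeddings))
  }
  sims <- cosine_similarities(query$embedding,
                              db$embeddings[sub$idx, , drop = FALSE])
  k <- if (k_rule == "sqrt") as.integer(ceiling(sqrt(sub$m))) else sub$m
  ranking <- rank_identities(sims, db$index$identity[sub$idx], k)
  list(ranking = ranking,
       diagnostics = list(half_width = sub$half_width, m = sub$m, k = k))
}

# Per-query identity probabilities: vote shares additively smoothed by 1/m.
identity_probabilities <- function(db, query, ...) {
  r <- reidentify(db, query, ...)
  ids <- sort(unique(db$index$identity))
  votes <- setNames(rep(0, length(ids)), ids)
  votes[r$ranking$identity] <- r$ranking$votes
  w <- votes + 1 / r$diagnostics$m
  w / sum(w)
}

# Hungarian algorithm (ascending-potential O(n^2 m) formulation) for the
# rectangular min-cost assignment of rows to distinct columns; n <= m.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)      # p[j]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Jointly re-identify several simultaneous queries with unique identities
#'
#' Each query's ranking is converted to identity probabilities (KNN vote
#' shares with additive `1/m` smoothing); the one-to-one assignment of
#' identities to queries maximising the joint probability (the sum of log
#' probabilities) is found with the Hungarian algorithm.  An animal cannot
#' appear twice in one frame, so all assigned identities are distinct.
#'
#' @param queries list of queries (as for [reidentify()]).
#' @param db a `cow_refdb`.
#' @param ... passed to [reidentify()].
#' @return character vector of assigned identities, one per query.
#' @export
joint_reidentify <- function(queries, db, ...) {
  ids <- sort(unique(db$index$identity))
  if (length(queries) > length(ids)) {
    stop("more simultaneous queries than identities in the reference database")
  }
  P <- t(vapply(queries, function(q) identity_probabilities(db, q, ...),
                numeric(length(ids))))
  cost <- -log(P)
  sel <- hungarian(cost)
  ids[sel]
}
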