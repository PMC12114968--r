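# Rank-n (CMC) evaluation per behaviour, exact binomial confidence
# intervals, error-reduction statistics and the dataset-splitting protocol.

ranked_ids <- function(pred) {
  if (inherits(pred, "cow_ranking")) pred$identity
  else if (is.list(pred) && !is.null(pred$ranking)) pred$ranking$identity
  else as.character(pred)
}

#' Rank-n accuracy per behaviour
#'
#' Fraction of instances whose true identity appears among the top-n ranked
#' candidates, computed for each behaviour separately and then averaged
#' (unweighted) over behaviours, for n = 1..`n_max`.  Instances without a
#' ranking count as failures at every n.
#'
#' @param predictions list of rankings (a `cow_ranking`, a [reidentify()]
#'   result, or a character vector of ranked identities); `NULL` elements are
#'   unranked instances.
#' @param truths true identity per instance.
#' @param behaviours behaviour label per instance.
#' @param n_max deepest rank evaluated (default 5).
#' @return object of class `cow_eval`: list with `rank_n` (data.frame:
#'   behaviour, n, successes, total, accuracy, ci_low, ci_high) and
#'   `averaged` (data.frame: n, accuracy).
#' @export
rank_n_accuracy <- function(predictions, truths, behaviours, n_max = 5L) {
  stopifnot(length(predictions) == length(truths),
            length(truths) == length(behaviours))
  stopifnot_behaviour(behaviours)
  unranked <- vapply(predictions, is.null, logical(1))
  if (any(unranked)) {
    warning(sum(unranked), " instance(s) without ranking counted as failures")
  }
  hit_rank <- vapply(seq_along(predictions), function(i) {
    if (unranked[i]) return(Inf)
    r <- match(truths[i], ranked_ids(predictions[[i]]))
    if (is.na(r)) Inf else r
  }, numeric(1))
  rows <- list()
  for (b in BEHAVIOURS) {
    sel <- behaviours == b
    if (!any(sel)) next
    for (n in seq_len(n_max)) {
      s <- sum(hit_rank[sel] <= n)
      tot <- sum(sel)
      ci <- binomial_ci95(s, tot)
      rows[[length(rows) + 1]] <- data.frame(
        behaviour = b, n = n, successes = s, total = tot, accuracy = s / tot,
        ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }
  }
  rank_n <- do.call(rbind, rows)
  averaged <- aggregate(accuracy ~ n, data = rank_n, FUN = mean)
  structure(list(rank_n = rank_n, averaged = averaged), class = "cow_eval")
}

#' Exact (Clopper-Pearson) two-sided 95 percent binomial interval
#'
#' @param successes,total counts with `0 <= successes <= total`, `total >= 1`.
#' @return numeric `c(low, high)`.
#' @export
binomial_ci95 <- function(successes, total) {
  if (total < 1) stop("total must be at least 1")
  stopifnot(successes >= 0, successes <= total)
  low <- if (successes == 0) 0 else qbeta(0.025, successes, total - successes + 1)
  high <- if (successes == total) 1 else qbeta(0.975, successes + 1,
                                               total - successes)
  c(low, high)
}

#' Relative reduction in error rate
#'
#' `((1 - acc_without) - (1 - acc_with)) / (1 - acc_without)`: the fraction of
#' previously mis-identified instances that the improved protocol resolves.
#'
#' @param acc_without,acc_with accuracies in `[0, 1]`, `acc_without < 1`.
#' @return relative error reduction (can be negative if accuracy drops).
#' @export
error_reduction <- function(acc_without, acc_with) {
  stopifnot(acc_without >= 0, acc_without <= 1, acc_with >= 0, acc_with <= 1)
  if (acc_without >= 1) stop("error reduction undefined: baseline error is zero")
  ((1 - acc_without) - (1 - acc_with)) / (1 - acc_without)
}

#' Split a dataset into reference/evaluation/training/validation parts
#'
#' Test identities are `n_test_per_class` random animals from each of the two
#' most abundant coat classes (`rw`, `bw`); their instances go to a
#' new-reference or new-evaluation database with 75/25 percent probability.
#' All remaining identities are training identities; their instances split
#' into training/validation with 90/10 percent probability.  The remaining
#' `rw`/`bw` training identities form the seen identities, whose instances
#' additionally receive a seen-reference/seen-evaluation role (75/25).
#'
#' @param metadata metadata table with columns `identity`, `coat_class`.
#' @param seed integer seed; the split is reproducible given it.
#' @param n_test_per_class test identities drawn per test class (default 6).
#' @param test_classes the two most abundant coat classes.
#' @param ref_prob reference probability for test/seen instances (0.75).
#' @param train_prob training probability for training identities (0.9).
#' @return object of class `cow_split`: list with `test_ids`, `train_ids`,
#'   `seen_ids`, and `assignment` (data.frame: identity, split, seen_role).
#' @export
split_datasets <- function(metadata, seed = 1L, n_test_per_class = 6L,
                           test_classes = c("rw", "bw"), ref_prob = 0.75,
                           train_prob = 0.9) {
  stopifnot(all(c("identity", "coat_class") %in% names(metadata)))
  id_coat <- unique(metadata[, c("identity", "coat_class")])
  withr::with_seed(derive_seed(seed, 71L), {
    test_ids <- unlist(lapply(test_classes, function(cl) {
      pool <- id_coat$identity[id_coat$coat_class == cl]
      if (length(pool) < n_test_per_class) {
        stop(sprintf("only %d identities of class %s (need %d)",
                     length(pool), cl, n_test_per_class))
      }
      sample(pool, n_test_per_class)
    }))
    train_ids <- setdiff(id_coat$identity, test_ids)
    seen_ids <- intersect(train_ids,
                          id_coat$identity[id_coat$coat_class %in% test_classes])
    n <- nrow(metadata)
    is_test <- metadata$identity %in% test_ids
    is_seen <- metadata$identity %in% seen_ids
    u_ref <- runif(n)
    u_train <- runif(n)
    u_seen <- runif(n)
    split <- ifelse(is_test,
                    ifelse(u_ref < ref_prob, "new-reference", "new-evaluation"),
                    ifelse(u_train < train_prob, "training", "validation"))
    seen_role <- ifelse(is_seen,
                        ifelse(u_seen < ref_prob, "seen-reference",
                               "seen-evaluation"),
                        NA_character_)
  })
  structure(list(
    test_ids = sort(test_ids), train_ids = sort(train_ids),
    seen_ids = sort(seen_ids),
    assignment = data.frame(identity = metadata$identity, split = split,
                            seen_role = seen_role, stringsAsFactors = FALSE)
  ), class = "cow_split")
}

#' Export embeddings for external 2-D visualisation
#'
#' Writes a binary array container (`embeddings.bin` + JSON sidecar) and a
#' CSV index with one row per instance (identity, behaviour, orientation,
#' coat class).
#'
#' @param segments list of `cow_segment`s (or a `cow_dataset`).
#' @param embedder a `cow_embedder` (or `cow_network`).
#' @param dir output directory.
#' @return invisibly, the embedding matrix.
#' @export
export_embeddings <- function(segments, embedder, dir) {
  if (inherits(segments, "cow_dataset")) segments <- segments$segments
  emb <- if (inherits(embedder, "cow_embedder")) predict(embedder, segments)
         else embed_instances(embedder, segments)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_array_bin(emb, file.path(dir, "embeddings.bin"))
  idx <- data.frame(
    identity = vapply(segments, `[[`, "", "identity_id"),
    behaviour = vapply(segments, `[[`, "", "behaviour"),
    orientation_deg = vapply(segments, `[[`, 0, "orientation_deg"),
    coat_class = vapply(segments, function(s) s$coat_class %||% NA_character_,
                        ""),
    stringsAsFactors = FALSE)
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(emb)
}

#' Stratified overall-evaluation split
#'
#' Selects an exact fraction (default 25 percent, rounded) of the instances
#' of every identity within every behaviour for evaluation; of the remainder,
#' an exact 10 percent becomes validation and the rest training.
#'
#' @param metadata metadata table with `identity` and `behaviour` columns.
#' @param seed integer seed.
#' @param eval_frac evaluation fraction per (identity, behaviour) stratum.
#' @param val_frac validation fraction of the non-evaluation instances.
#' @return character vector (one of `overall-evaluation`,
#'   `overall-validation`, `overall-training`) per metadata row.
#' @export
overall_split <- function(metadata, seed = 1L, eval_frac = 0.25,
                          val_frac = 0.1) {
  out <- rep("overall-training", nrow(metadata))
  withr::with_seed(derive_seed(seed, 73L), {
    strata <- split(seq_len(nrow(metadata)),
                    list(metadata$identity, metadata$behaviour), drop = TRUE)
    for (ix in strata) {
      n_eval <- round(length(ix) * eval_frac)
      ev <- if (n_eval > 0) sample(ix, n_eval) else integer(0)
      out[ev] <- "overall-evaluation"
      rest <- setdiff(ix, ev)
      n_val <- round(length(rest) * val_frac)
      if (n_val > 0) out[sample(rest, n_val)] <- "overall-validation"
    }
  })
  out
}
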