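# File formats: validated metadata CSV, a binary array container with a JSON
# sidecar (embeddings, weights, heatmap stacks), reference-database
# persistence and the run configuration.

#' Read and validate a segment metadata table
#'
#' Requires columns `file`, `identity`, `behaviour`, `orientation_deg`;
#' behaviours must be in the closed vocabulary `ll`/`lr`/`s` and orientations
#' in the half-open range `[0, 360)`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("file", "identity", "behaviour", "orientation_deg")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata lacks required column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!meta$behaviour %in% BEHAVIOURS)
  if (length(bad)) {
    stop(sprintf("row %d: unknown behaviour '%s' (must be ll, lr or s)",
                 bad[1], meta$behaviour[bad[1]]))
  }
  bad <- which(!is.finite(meta$orientation_deg) | meta$orientation_deg < 0 |
                 meta$orientation_deg >= 360)
  if (length(bad)) {
    stop(sprintf("row %d: orientation %s outside [0, 360)",
                 bad[1], format(meta$orientation_deg[bad[1]])))
  }
  meta
}

#' @rdname read_metadata
#' @param metadata the table to write.
#' @export
write_metadata <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' Binary array container with a JSON sidecar
#'
#' Stores a numeric vector/matrix/array as little-endian doubles in
#' column-major order; the sidecar (`<path>.json`) records dtype, dims and
#' ordering, so the file is readable without this package.
#'
#' @param x numeric vector, matrix or array.
#' @param path target path (conventionally `*.bin`).
#' @return `path`, invisibly.
#' @export
write_array_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  header <- list(dtype = "float64", order = "column-major",
                 dim = if (is.null(dim(x))) length(x) else dim(x))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_array_bin
#' @export
read_array_bin <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(header$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(header$dim) == 2) x <- matrix(x, header$dim[1], header$dim[2])
  else if (length(header$dim) > 2) x <- array(x, dim = header$dim)
  x
}

#' Save / load a reference database
#'
#' Layout: `embeddings.bin` (+ JSON sidecar), `index.csv` (identity,
#' behaviour, orientation), `meta.json` -- inspectable without the package.
#'
#' @param db a `cow_refdb`.
#' @param dir target directory.
#' @return `dir` (save) or a `cow_refdb` (load).
#' @export
save_reference_db <- function(db, dir) {
  stopifnot(inherits(db, "cow_refdb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_array_bin(db$embeddings, file.path(dir, "embeddings.bin"))
  write.csv(db$index, file.path(dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(list(entries = nrow(db$embeddings),
                            dim = ncol(db$embeddings),
                            behaviours = as.list(table(db$index$behaviour))),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_reference_db
#' @export
load_reference_db <- function(dir) {
  emb <- read_array_bin(file.path(dir, "embeddings.bin"))
  idx <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  reference_database(emb, idx$identity, idx$behaviour, idx$orientation_deg)
}

#' Run configuration with package defaults
#'
#' A plain named list gathering every tunable of the pipeline, derived from a
#' single master seed; round-trips losslessly through YAML.
#'
#' @param seed master seed.
#' @param ... overrides of the defaults (nested lists are merged).
#' @return configuration list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    image = list(canvas_px = 256L, input_px = 64L),
    network = list(final_depth = 64L, embed_dim = 32L),
    sampler = list(half_width = 22.5, widen_step = 2.5,
                   rotation = 10, occlude_max = 0.4),
    reid = list(half_width = 45, widen_step = 2.5, k_rule = "sqrt"),
    train = list(epochs = 5L, batches_per_epoch = 50L, lr = 1e-3,
                 conditioned = TRUE, mirror = TRUE, augment = TRUE)
  )
  modifyList(cfg, list(...))
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @param path YAML path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(run_config(seed = cfg$seed %||% 1L), cfg)
}

#' Read / write skeleton detections as CSV records
#'
#' Columns: `frame`, `skeleton`, `name`, `x`, `y`, `confidence`; one row per
#' detected keypoint.  Reading returns a list of [skeleton()]s per
#' (frame, skeleton) pair, missing keypoints simply absent.
#'
#' @param path CSV path.
#' @return list of `cow_skeleton`s with `frame` attributes.
#' @export
read_skeletons <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "skeleton", "name", "x", "y", "confidence")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("skeleton CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(d, list(d$frame, d$skeleton), drop = TRUE), function(g) {
    kp <- setNames(lapply(seq_len(nrow(g)), function(i) {
      c(g$x[i], g$y[i], g$confidence[i])
    }), g$name)
    sk <- do.call(skeleton, kp)
    attr(sk, "frame") <- g$frame[1]
    sk
  })
  unname(out)
}

#' @rdname read_skeletons
#' @param skeletons list of `cow_skeleton`s (optionally with `frame`
#'   attributes).
#' @export
write_skeletons <- function(skeletons, path) {
  rows <- lapply(seq_along(skeletons), function(i) {
    sk <- skeletons[[i]]
    do.call(rbind, lapply(names(sk$keypoints), function(nm) {
      p <- sk$keypoints[[nm]]
      data.frame(frame = attr(sk, "frame") %||% 1L, skeleton = i, name = nm,
                 x = p[["x"]], y = p[["y"]], confidence = p[["confidence"]])
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Persist a heatmap stack as a binary array with a JSON channel header
#'
#' The sidecar names the channel order (keypoint names, association channels,
#' behaviours `ll`, `lr`, `s`), so stored stacks are self-describing.
#'
#' @param stack a [heatmap_stack()].
#' @param path target path (`*.bin`).
#' @return `path` (save) or a `cow_heatmap_stack` (load), invisibly.
#' @export
save_heatmap_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cow_heatmap_stack"))
  arr <- array(c(stack$P, stack$A, stack$B),
               dim = c(stack$h, stack$w, dim(stack$P)[3] + dim(stack$A)[3] + 3))
  write_array_bin(arr, path)
  header <- jsonlite::read_json(paste0(path, ".json"))
  header$channels <- list(P = as.list(stack$keypoint_names),
                          A = dim(stack$A)[3],
                          B = list("ll", "lr", "s"))
  header$predicted <- stack$predicted
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_heatmap_stack
#' @export
load_heatmap_stack <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- read_array_bin(path)
  nP <- length(header$channels$P)
  nA <- header$channels$A
  heatmap_stack(arr[, , seq_len(nP), drop = FALSE],
                arr[, , nP + seq_len(nA), drop = FALSE],
                arr[, , nP + nA + 1:3, drop = FALSE],
                keypoint_names = header$channels$P,
                predicted = isTRUE(header$predicted))
}
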