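#' cowreid: conditional re-identification of Holstein-Friesian cattle
#'
#' Tools for embedding-based cattle re-identification under variable pose:
#' a procedural pied-coat segment generator, a lightweight inception-style
#' embedding network trained with histogram loss, behaviour/orientation
#' conditional batch sampling, metadata-aware gallery search with KNN voting,
#' and rank-n evaluation.
#'
#' @name cowreid-package
#' @keywords internal
"_PACKAGE"

BEHAVIOURS <- c("ll", "lr", "s")

#' Circular distance between two angles in degrees
#'
#' @param a,b angles in degrees (any real; reduced mod 360).
#' @return elementwise circular distance in `[0, 180]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

norm_angle <- function(a) a %% 360

deg2rad <- function(d) d * pi / 180

# Derive a child RNG seed from a parent seed and a salt, staying within the
# 32-bit integer range R requires.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 2654435761 + salt * 97 + 13) %% 2147483647)
}

stopifnot_behaviour <- function(behaviour) {
  if (!all(behaviour %in% BEHAVIOURS)) {
    stop("behaviour must be one of ", paste(BEHAVIOURS, collapse = ", "),
         " (got ", paste(setdiff(behaviour, BEHAVIOURS), collapse = ", "), ")")
  }
  invisible(behaviour)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
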