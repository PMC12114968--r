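# Bilinear affine resampling helpers over the C++ kernel.  Images are h x w x c
# arrays (values in [0,1]); masks are h x w matrices.  All sampling uses centred
# coordinates, so horizontal/vertical flips (exact index reversals) commute
# exactly with the warps -- a property the synthetic renderer's mirror
# convention relies on.

img_to_mat <- function(img) {
  d <- dim(img)
  if (length(d) == 2) d <- c(d, 1L)
  matrix(img, nrow = d[1] * d[2], ncol = d[3])
}

mat_to_img <- function(m, h, w) {
  c <- ncol(m)
  if (c == 1L) matrix(m, h, w) else array(m, dim = c(h, w, c))
}

# Generic warp: M maps centred output (x=col, y=row-down) coords to centred
# source coords; inverse mapping convention.
img_warp <- function(img, M, t = c(0, 0), oh = NULL, ow = NULL, fill = 0) {
  d <- dim(img); h <- d[1]; w <- d[2]
  oh <- oh %||% h; ow <- ow %||% w
  out <- cpp_affine_sample(img_to_mat(img), h, w, as.integer(oh), as.integer(ow),
                           M, as.numeric(t), fill)
  mat_to_img(out, oh, ow)
}

# Rotate image content by `deg` counter-clockwise in the mathematical
# convention (y axis up).  In raster coordinates (y down) the inverse map is
# [[cos, -sin], [sin, cos]].
img_rotate <- function(img, deg, fill = 0) {
  th <- deg2rad(deg)
  M <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  img_warp(img, M, fill = fill)
}

img_resize <- function(img, oh, ow, fill = 0) {
  d <- dim(img)
  M <- matrix(c(d[2] / ow, 0, 0, d[1] / oh), 2, 2)
  img_warp(img, M, oh = oh, ow = ow, fill = fill)
}

img_flip_h <- function(img) {
  if (length(dim(img)) == 2) img[, ncol(img):1, drop = FALSE]
  else img[, dim(img)[2]:1, , drop = FALSE]
}

img_flip_v <- function(img) {
  if (length(dim(img)) == 2) img[nrow(img):1, , drop = FALSE]
  else img[dim(img)[1]:1, , , drop = FALSE]
}
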