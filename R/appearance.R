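#' Crop a detection to the re-identification input convention
#'
#' Appearance features for re-identification are extracted from square
#' patches: field seedlings have bounding boxes concentrated near a 1:1
#' aspect ratio, so — unlike the 1:2 pedestrian convention — crops are
#' brought to a square by padding the shorter axis symmetrically with
#' white (intensity 255) rather than by anisotropic stretching, then
#' resampled to a fixed 128 x 128 input resolution. Content aspect is
#' preserved; boxes partially outside the image are clipped to the image
#' extent first.
#'
#' @param image Numeric array `height x width x 3`, intensities 0-255.
#' @param box Box `c(x1, y1, x2, y2)` in continuous pixel coordinates;
#'   pixel `i` covers the interval `(i-1, i]`, so an integer box
#'   `(0, 0, w, h)` selects exactly `w x h` pixels and sub-pixel corners
#'   expand to the enclosing pixel range.
#' @param size Output side length in pixels (default 128).
#' @return Integer array `size x size x 3` with values in 0-255.
#' @export
square_pad_crop <- function(image, box, size = 128L) {
  d <- dim(image)
  if (length(d) != 3L || d[[3]] != 3L)
    stop("image must be a height x width x 3 array", call. = FALSE)
  h_img <- d[[1]]; w_img <- d[[2]]
  # clip the box to the image extent; a box fully outside is an error
  x1 <- max(1L, floor(box[[1]]) + 1L); y1 <- max(1L, floor(box[[2]]) + 1L)
  x2 <- min(w_img, ceiling(box[[3]])); y2 <- min(h_img, ceiling(box[[4]]))
  if (x1 > x2 || y1 > y2)
    stop("bounding box lies fully outside the image", call. = FALSE)
  crop <- image[y1:y2, x1:x2, , drop = FALSE]
  ch <- dim(crop)[[1]]; cw <- dim(crop)[[2]]
  side <- max(ch, cw)
  sq <- array(255, dim = c(side, side, 3L))
  top  <- floor((side - ch) / 2)
  left <- floor((side - cw) / 2)
  sq[(top + 1):(top + ch), (left + 1):(left + cw), ] <- crop
  out <- resize_bilinear(sq, size, size)
  storage.mode(out) <- "integer"
  out
}

# Bilinear resampling with pixel-center alignment: output pixel i samples
# the source at (i - 0.5) * in/out + 0.5, so resizing to the same size is
# the identity (which makes the crop convention idempotent on conforming
# patches). Values are clamped to [0, 255] and rounded.
resize_bilinear <- function(img, out_h, out_w) {
  in_h <- dim(img)[[1]]; in_w <- dim(img)[[2]]
  sy <- (seq_len(out_h) - 0.5) * in_h / out_h + 0.5
  sx <- (seq_len(out_w) - 0.5) * in_w / out_w + 0.5
  y0 <- pmin(pmax(floor(sy), 1L), in_h); y1 <- pmin(y0 + 1L, in_h)
  x0 <- pmin(pmax(floor(sx), 1L), in_w); x1 <- pmin(x0 + 1L, in_w)
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, dim(img)[[3]]))
  for (ch in seq_len(dim(img)[[3]])) {
    p <- img[, , ch]
    # interpolate rows then columns, vectorized over the output grid
    a <- p[y0, x0, drop = FALSE]; b <- p[y0, x1, drop = FALSE]
    c_ <- p[y1, x0, drop = FALSE]; d_ <- p[y1, x1, drop = FALSE]
    WX <- matrix(wx, out_h, out_w, byrow = TRUE)
    WY <- matrix(wy, out_h, out_w)
    out[, , ch] <- (a * (1 - WX) + b * WX) * (1 - WY) + (c_ * (1 - WX) + d_ * WX) * WY
  }
  round(pmin(pmax(out, 0), 255))
}

#' Deterministic synthetic appearance embeddings
#'
#' Stand-in for a trained re-identification network: each identity is
#' assigned a fixed random direction on the unit sphere (a "base"
#' embedding), and each draw adds isotropic Gaussian noise of standard
#' deviation `noise_sd` before renormalizing. Same-identity draws are
#' therefore closer in cosine distance than cross-identity draws, in
#' expectation, with `noise_sd` controlling how discriminative the
#' embedding is. The output is fully determined by `(identity, seed)`.
#'
#' Any embedding provider with this signature — returning a unit-norm
#' numeric vector per detection — can replace this function in the
#' tracking pipeline; the tracker only consumes vectors.
#'
#' @param identity Non-negative integer identity.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (>= 0; 0 gives the identity's base vector exactly).
#' @param seed Integer seed for the draw; pass different seeds to obtain
#'   independent draws for the same identity.
#' @param dim Embedding dimension (default 128).
#' @return Unit-norm numeric vector of length `dim`.
#' @export
synthetic_embedder <- function(identity, noise_sd = 0.1, seed = 0L, dim = 128L) {
  stopifnot(noise_sd >= 0, dim >= 2L)
  base <- with_local_seed(mix_seed(2654435761, identity), stats::rnorm(dim))
  base <- base / sqrt(sum(base^2))
  if (noise_sd > 0) {
    noise <- with_local_seed(mix_seed(mix_seed(97, identity), seed),
                             stats::rnorm(dim, sd = noise_sd))
    base <- base + noise
  }
  base / sqrt(sum(base^2))
}

#' Cosine distance between embeddings
#'
#' `1 - <a, b> / (|a||b|)`: 0 for identical direction, 1 for orthogonal,
#' 2 for opposite. This is the appearance metric used by the association
#' stage of the tracker.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Distance in \[0, 2\].
#' @export
cosine_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Cosine distances between one embedding matrix (rows) and one vector;
# rows are assumed unit-norm (gallery invariant).
cosine_distance_many <- function(G, v) {
  1 - as.numeric(G %*% v) / sqrt(sum(v^2))
}

# --- seeded-draw plumbing -------------------------------------------------

# Deterministic 31-bit seed mixer; keeps derived seeds valid R integers.
mix_seed <- function(a, b) {
  as.integer((as.double(a) * 69069 + as.double(b) + 1) %% 2147483647)
}

# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so library calls do not perturb user simulations.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
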