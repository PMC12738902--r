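#' Classification-loss parameters
#'
#' Parameters of the combined quality-focal / binary-cross-entropy
#' classification loss used to counter class imbalance between abundant
#' normal transplants and the rare buried-seedling and bare-root states:
#' `gamma` is the focusing exponent on the quality gap `|y - sigma|`,
#' `alpha` the positive-class balance weight, and `j`, `k` the mixing
#' weights of the focal and cross-entropy terms. Defaults are the
#' selected operating point `gamma = 1.5`, `alpha = 0.3`, `j = k = 0.5`.
#'
#' @param gamma Focusing exponent, >= 0.
#' @param alpha Class-balance weight in (0, 1).
#' @param j,k Non-negative combination weights.
#' @return Named list of class `loss_params`.
#' @export
loss_params <- function(gamma = 1.5, alpha = 0.3, j = 0.5, k = 0.5) {
  if (gamma < 0 || j < 0 || k < 0)
    stop("gamma, j, k must be non-negative", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(gamma = gamma, alpha = alpha, j = j, k = k),
            class = "loss_params")
}

#' Class-balance weight
#'
#' `alpha_t = y * alpha + (1 - y) * (1 - alpha)`: positive labels are
#' weighted by `alpha`, negatives by `1 - alpha`.
#'
#' @param y Binary label(s) in \{0, 1\} (vectorized).
#' @param alpha Balance weight in (0, 1).
#' @return Numeric vector of weights.
#' @export
alpha_t <- function(y, alpha) {
  y * alpha + (1 - y) * (1 - alpha)
}

.sigma_eps <- 1e-7

clip_sigma <- function(sigma) {
  pmin(pmax(sigma, .sigma_eps), 1 - .sigma_eps)
}

#' Binary cross-entropy loss
#'
#' `-(y log sigma + (1 - y) log(1 - sigma))`, elementwise. Predictions
#' are clipped to `[1e-7, 1 - 1e-7]` for numerical stability, except that
#' an exactly correct prediction (`sigma == y`) yields exactly zero loss.
#'
#' @param y Binary label(s) in \{0, 1\}.
#' @param sigma Predicted probability/probabilities in \[0, 1\].
#' @return Non-negative numeric vector.
#' @export
bce <- function(y, sigma) {
  check_probs(sigma)
  exact <- sigma == y
  s <- clip_sigma(sigma)
  out <- -(y * log(s) + (1 - y) * log(1 - s))
  out[exact] <- 0
  out
}

#' Quality focal loss
#'
#' `-alpha_t * |y - sigma|^gamma * ((1 - y) log(1 - sigma) + y log sigma)`:
#' binary cross-entropy modulated by the quality gap `|y - sigma|^gamma`
#' (down-weighting easy examples) and by the class-balance weight
#' `alpha_t`. With `gamma = 0` it reduces to `alpha_t * bce`.
#'
#' @param y Binary label(s) in \{0, 1\}.
#' @param sigma Predicted probability/probabilities in \[0, 1\].
#' @param params A [loss_params()].
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' qfocal_loss(1, 0.5) # 0.3 * 0.5^1.5 * log(2)
qfocal_loss <- function(y, sigma, params = loss_params()) {
  check_probs(sigma)
  alpha_t(y, params$alpha) * abs(y - sigma)^params$gamma * bce(y, sigma)
}

#' Combined classification loss
#'
#' Weighted sum `j * qfocal + k * bce`, evaluated elementwise over a
#' batch of `(y, sigma)` pairs and averaged. This couples the adaptive
#' reweighting of the focal term with the noise robustness of plain
#' cross-entropy; it is zero exactly when every prediction is perfect.
#'
#' @inheritParams qfocal_loss
#' @return Non-negative scalar: the mean combined loss over the batch.
#' @export
combined_cls_loss <- function(y, sigma, params = loss_params()) {
  stopifnot(length(y) == length(sigma))
  mean(params$j * qfocal_loss(y, sigma, params) + params$k * bce(y, sigma))
}

check_probs <- function(sigma) {
  if (any(sigma < 0 | sigma > 1))
    stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  invisible(sigma)
}

# --- triplet attention forward pass ---------------------------------------

#' Z-pool channel compression
#'
#' Compresses a `C x H x W` feature tensor to two channels by
#' concatenating the per-position maximum and mean over the channel
#' dimension — the pooling operator feeding each attention branch.
#'
#' @param x Numeric array `C x H x W`.
#' @return Numeric array `2 x H x W`; channel 1 is the max, channel 2 the
#'   mean.
#' @export
z_pool <- function(x) {
  d <- dim(x)
  if (length(d) != 3L) stop("feature tensor must be C x H x W", call. = FALSE)
  out <- array(0, dim = c(2L, d[[2]], d[[3]]))
  out[1L, , ] <- apply(x, c(2L, 3L), max)
  out[2L, , ] <- apply(x, c(2L, 3L), mean)
  out
}

#' Attention branch kernels
#'
#' The three attention branches each convolve the 2-channel Z-pooled map
#' with one `2 x k x k` kernel (plus scalar bias) to produce a single
#' attention map. Batch normalization is modeled as the identity so the
#' forward computation is self-contained.
#'
#' @param k Odd spatial kernel size (default 7, zero padding `(k-1)/2`).
#' @param init `"zero"` for all-zero kernels (useful for algebraic
#'   checks: attention becomes uniformly 0.5) or `"random"` for small
#'   Gaussian weights.
#' @param seed Seed for random initialization.
#' @return List of class `attention_kernels` with elements `hw`, `cw`,
#'   `ch` (one per branch), each a list `(weight = 2 x k x k array,
#'   bias = scalar)`.
#' @export
attention_kernels <- function(k = 7L, init = c("zero", "random"), seed = 1L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("attention kernel size must be odd", call. = FALSE)
  init <- match.arg(init)
  make <- function(s) {
    w <- if (init == "zero") array(0, dim = c(2L, k, k))
         else with_local_seed(mix_seed(seed, s),
                              array(stats::rnorm(2 * k * k, sd = 0.1),
                                    dim = c(2L, k, k)))
    list(weight = w, bias = 0)
  }
  structure(list(hw = make(1L), cw = make(2L), ch = make(3L), k = k),
            class = "attention_kernels")
}

# 2D convolution of a 2-channel map with one 2 x k x k kernel, zero
# padding (k-1)/2, stride 1. Plain loops; tensors in this module are
# small reference inputs, not training batches.
conv2_2ch <- function(zmap, kernel) {
  k <- dim(kernel$weight)[[2]]
  pad <- (k - 1L) %/% 2L
  H <- dim(zmap)[[2]]; W <- dim(zmap)[[3]]
  padded <- array(0, dim = c(2L, H + 2L * pad, W + 2L * pad))
  padded[, pad + seq_len(H), pad + seq_len(W)] <- zmap
  out <- matrix(kernel$bias, H, W)
  for (ch in 1:2) {
    for (di in seq_len(k)) {
      for (dj in seq_len(k)) {
        w <- kernel$weight[ch, di, dj]
        if (w != 0)
          out <- out + w * padded[ch, (di - 1L) + seq_len(H),
                                  (dj - 1L) + seq_len(W)]
      }
    }
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Triplet-attention forward pass
#'
#' Parameter-light attention over a `C x H x W` feature tensor using
#' three parallel branches. Two branches rotate the tensor so that the
#' channel dimension interacts with one spatial dimension (C-H and C-W
#' respectively); the third operates on the tensor as-is (pure spatial
#' attention). Each branch Z-pools its (rotated) tensor to 2 channels,
#' convolves to a single map, applies a sigmoid, multiplies the rotated
#' tensor by the resulting attention weights, and rotates back; the
#' output is the average of the three branches and has the shape of the
#' input. With all-zero kernels every sigmoid is 0.5 and the output is
#' exactly half the input.
#'
#' @param x Numeric array `C x H x W`.
#' @param kernels An [attention_kernels()] object.
#' @return Numeric array with `dim(x)`.
#' @export
triplet_attention <- function(x, kernels = attention_kernels()) {
  d <- dim(x)
  if (length(d) != 3L) stop("feature tensor must be C x H x W", call. = FALSE)
  if (!all(is.finite(x))) stop("feature tensor must be finite", call. = FALSE)

  branch <- function(xr, kernel) {
    att <- sigmoid(conv2_2ch(z_pool(xr), kernel))
    sweep(xr, c(2L, 3L), att, `*`)
  }

  # branch 1: rotate about W so channels swap with height (C-H interaction)
  x_hw <- aperm(x, c(2L, 1L, 3L))
  b1 <- aperm(branch(x_hw, kernels$hw), c(2L, 1L, 3L))
  # branch 2: rotate about H so channels swap with width (C-W interaction)
  x_cw <- aperm(x, c(3L, 2L, 1L))
  b2 <- aperm(branch(x_cw, kernels$cw), c(3L, 2L, 1L))
  # branch 3: identity orientation (spatial attention)
  b3 <- branch(x, kernels$ch)

  (b1 + b2 + b3) / 3
}
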