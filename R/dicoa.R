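# Dilated contextual attention (DiCoA) ----------------------------------------
#
# Self-attention restricted to a delta-dilated k x k neighborhood of every
# pixel of a C x H x W feature map. The operator returns a weighted feature
# map y (same shape as the input, residual form) and the post-softmax score
# field DPS with D = k^2 scores per pixel. Near borders the whole dilated
# window is shifted inward so that every pixel keeps exactly D valid
# neighbors (the shifted-window rule used by neighborhood-attention
# implementations); when an axis is shorter than the dilated window span the
# per-position clamp is applied instead.

# Axis positions: for every coordinate i in 0..(n-1) return the k neighbor
# coordinates along that axis (0-based), as a k x n integer matrix.
axis_positions <- function(n, k, delta) {
  r <- (k - 1L) %/% 2L
  offsets <- delta * seq.int(-r, r)
  i <- seq.int(0L, n - 1L)
  lo <- r * delta
  hi <- n - 1L - r * delta
  if (lo <= hi) {
    centers <- clamp(i, lo, hi)            # shifted-window rule
    outer(offsets, centers, `+`)
  } else {
    # window span exceeds the axis: clamp each position individually
    pos <- outer(offsets, i, `+`)
    matrix(clamp(pos, 0L, n - 1L), nrow = k)
  }
}

check_k_delta <- function(k, delta) {
  if (!is_count(k) || k <= 0 || k %% 2 == 0)
    param_error("k must be a positive odd integer")
  if (!is_count(delta) || delta < 1)
    param_error("delta must be an integer >= 1")
}

#' Neighbor positions of one pixel in a dilated neighborhood
#'
#' Returns the `D = k^2` (row, col) coordinates attended to by pixel
#' `(i, j)` of an `H x W` feature map, in row-major order over the
#' `(row offset, col offset)` pairs. For interior pixels these are
#' `(i + delta * a, j + delta * b)` for `a, b in -(k-1)/2 .. (k-1)/2`; near a
#' border the whole window is shifted inward so all positions stay in bounds.
#'
#' @param i,j 0-based pixel row and column.
#' @param k Odd neighborhood size (default 3, giving D = 9).
#' @param delta Dilation (spacing between attended neighbors), >= 1.
#' @param H,W Feature-map extents.
#' @return Integer matrix `D x 2` of 0-based (row, col) positions.
#' @export
neighbor_positions <- function(i, j, k = 3L, delta = 1L, H, W) {
  check_k_delta(k, delta)
  if (!is_count(i) || i < 0 || i >= H || !is_count(j) || j < 0 || j >= W)
    param_error("pixel (i, j) must lie in [0, H) x [0, W)")
  rows <- axis_positions(H, k, delta)[, i + 1L]
  cols <- axis_positions(W, k, delta)[, j + 1L]
  cbind(row = rep(rows, each = k), col = rep(cols, times = k))
}

#' Precomputed neighbor index for a whole feature map
#'
#' Builds the per-axis neighbor coordinate tables used by the vectorized
#' attention operators, so gathers reduce to array subsetting.
#'
#' @inheritParams neighbor_positions
#' @return An object of class `neighbor_index` with elements `row_pos`
#'   (`k x H`), `col_pos` (`k x W`), `k`, `delta`, `D`, `H`, `W`.
#' @export
neighbor_index <- function(k = 3L, delta = 1L, H, W) {
  check_k_delta(k, delta)
  if (!is_count(H) || H < 1 || !is_count(W) || W < 1)
    param_error("H and W must be positive integers")
  structure(
    list(row_pos = axis_positions(H, k, delta),
         col_pos = axis_positions(W, k, delta),
         k = as.integer(k), delta = as.integer(delta),
         D = as.integer(k^2), H = as.integer(H), W = as.integer(W)),
    class = "neighbor_index"
  )
}

# Decompose neighbor number n (1..D) into (row offset slot a, col slot b).
neighbor_slots <- function(n, k) {
  a <- (n - 1L) %/% k + 1L
  b <- (n - 1L) %% k + 1L
  c(a, b)
}

#' Initialise 1x1 query/key/value projection weights
#'
#' Random Gaussian initialisation (scaled by `1/sqrt(C_in)`) of the three
#' pointwise convolutions that project a feature map to queries, keys and
#' values. Queries and keys are projected to `channels` outputs (256 in the
#' detection-stage configuration); the value projection keeps the input
#' channel count so the attention-weighted aggregate is shape-compatible
#' with the residual update.
#'
#' @param c_in Input channel count.
#' @param channels Query/key output channel count (default 256).
#' @param seed RNG seed.
#' @return List with elements `q`, `k`, `v`, each a list `(W, b)`; `q`/`k`
#'   weights are `channels x c_in`, `v` is `c_in x c_in`, biases zero.
#' @export
init_qkv_weights <- function(c_in, channels = 256L, seed = 1L) {
  if (!is_count(c_in) || c_in < 1 || !is_count(channels) || channels < 1)
    param_error("c_in and channels must be positive integers")
  with_seed(seed, {
    mk <- function(n_out) list(
      W = matrix(stats::rnorm(n_out * c_in, sd = 1 / sqrt(c_in)),
                 nrow = n_out),
      b = numeric(n_out)
    )
    list(q = mk(channels), k = mk(channels), v = mk(c_in))
  })
}

apply_1x1 <- function(x, w) {
  d <- dim(x)
  out <- w$W %*% matrix(x, nrow = d[1]) + w$b
  array(out, dim = c(nrow(w$W), d[2], d[3]))
}

#' Project a feature map to queries, keys and values
#'
#' Applies three 1x1 convolutions (kernel 1, stride 1): every output pixel is
#' a linear map of the same input pixel only.
#'
#' @param x Feature map `C x H x W`.
#' @param weights Weight list as produced by [init_qkv_weights()].
#' @return List of feature maps `Q`, `K` (`channels x H x W`) and `V`
#'   (`C x H x W`).
#' @export
project_qkv <- function(x, weights) {
  assert_feature_map(x)
  for (nm in c("q", "k", "v")) {
    w <- weights[[nm]]
    if (is.null(w$W) || ncol(w$W) != dim(x)[1])
      shape_error(sprintf(
        "weights$%s expects %s input channels, feature map has %d",
        nm, if (is.null(w$W)) "?" else ncol(w$W), dim(x)[1]))
  }
  list(Q = apply_1x1(x, weights$q),
       K = apply_1x1(x, weights$k),
       V = apply_1x1(x, weights$v))
}

# Gather the n-th neighbor plane of a C x H x W map as a C x H x W array.
gather_plane <- function(map, index, n) {
  s <- neighbor_slots(n, index$k)
  map[, index$row_pos[s[1], ] + 1L, index$col_pos[s[2], ] + 1L, drop = FALSE]
}

#' Dilated-neighborhood attention scores
#'
#' For every pixel, the dot product over channels between its query and the
#' keys of its D dilated neighbors, softmax-normalised per pixel. The raw
#' logits are used as-is (no `1/sqrt(d)` factor) unless `scale_qk = TRUE`.
#'
#' @param Q,K Query and key feature maps of identical shape.
#' @param index A [neighbor_index()] built for the maps' spatial extents.
#' @param scale_qk If `TRUE`, divide logits by `sqrt(C)` before the softmax.
#' @return `D x H x W` score array of class `dicoa_scores`; for every pixel
#'   the D scores are non-negative and sum to 1.
#' @export
attention_scores <- function(Q, K, index, scale_qk = FALSE) {
  assert_feature_map(Q, "Q"); assert_feature_map(K, "K")
  if (!identical(dim(Q), dim(K))) shape_error("Q and K differ in shape")
  d <- dim(Q)
  if (index$H != d[2] || index$W != d[3])
    shape_error("neighbor index was built for a different spatial shape")
  D <- index$D
  logits <- array(0, dim = c(D, d[2], d[3]))
  for (n in seq_len(D)) {
    Kn <- gather_plane(K, index, n)
    logits[n, , ] <- colSums(Q * Kn, dims = 1L)
  }
  if (isTRUE(scale_qk)) logits <- logits / sqrt(d[1])
  if (any(!is.finite(logits))) {
    bad <- which(!is.finite(logits), arr.ind = TRUE)[1, ]
    mito_error("mito_numeric_error", sprintf(
      "non-finite attention logit at pixel (i=%d, j=%d)",
      bad[2] - 1L, bad[3] - 1L))
  }
  # per-pixel softmax over the neighbor axis
  m <- logits[1, , ]
  if (D > 1L) for (n in 2:D) m <- pmax(m, logits[n, , ])
  e <- array(0, dim = dim(logits))
  for (n in seq_len(D)) e[n, , ] <- exp(logits[n, , ] - m)
  s <- e[1, , , drop = FALSE][1, , ]
  if (D > 1L) for (n in 2:D) s <- s + e[n, , ]
  for (n in seq_len(D)) e[n, , ] <- e[n, , ] / s
  structure(e, class = "dicoa_scores")
}

#' Gather neighborhood values
#'
#' Pure gather of the value projection over the dilated neighborhood:
#' `stack[n, c, i, j] = V[c, rho_n(i, j)]`. No arithmetic is performed.
#'
#' @param V Value feature map `C x H x W`.
#' @param index A [neighbor_index()] built for `V`'s spatial extents.
#' @return Array `D x C x H x W`.
#' @export
gather_values <- function(V, index) {
  assert_feature_map(V, "V")
  d <- dim(V)
  if (index$H != d[2] || index$W != d[3])
    shape_error("neighbor index was built for a different spatial shape")
  out <- array(0, dim = c(index$D, d))
  for (n in seq_len(index$D)) out[n, , , ] <- gather_plane(V, index, n)
  out
}

# Per-position normalization over channels of a C x H x W array.
normalize_channels <- function(a, method, eps = 1e-6) {
  switch(method,
    identity = a,
    channel = {
      C <- dim(a)[1]
      mu <- colSums(a, dims = 1L) / C
      v  <- colSums(a^2, dims = 1L) / C - mu^2
      rep_sp <- function(m) aperm(array(m, dim = c(dim(a)[2:3], C)), c(3, 1, 2))
      (a - rep_sp(mu)) / rep_sp(sqrt(pmax(v, 0) + eps))
    },
    l2 = {
      nrm <- sqrt(colSums(a^2, dims = 1L) + eps)
      C <- dim(a)[1]
      a / aperm(array(nrm, dim = c(dim(a)[2:3], C)), c(3, 1, 2))
    },
    param_error(sprintf("unknown norm '%s'", method))
  )
}

#' Attention-weighted residual feature update
#'
#' Computes `y[c,i,j] = norm(sum_n DPS[n,i,j] * V[c, rho_n(i,j)]) + x[c,i,j]`:
#' the neighborhood values weighted by the attention scores, normalised, and
#' added back onto the input (residual form). `norm` is a per-position
#' channel normalisation (zero mean, unit variance over channels), a
#' per-position L2 normalisation, or the identity; all map the zero vector to
#' zero, so a zero value projection leaves the input unchanged.
#'
#' @param dps `D x H x W` score array; per-pixel sums must be within `1e-4`
#'   of 1 or a contract violation is raised.
#' @param V Value feature map `C x H x W`.
#' @param x Input feature map `C x H x W` (the residual branch).
#' @param index A [neighbor_index()] for the spatial extents.
#' @param norm One of `"channel"`, `"l2"`, `"identity"`.
#' @return Feature map `y` with the same shape as `x`.
#' @export
update_features <- function(dps, V, x, index, norm = "channel") {
  assert_feature_map(V, "V"); assert_feature_map(x, "x")
  if (!identical(dim(V), dim(x))) shape_error("V and x differ in shape")
  d <- dim(x)
  if (length(dim(dps)) != 3L || !all(dim(dps) == c(index$D, d[2], d[3])))
    shape_error("DPS shape does not match (D, H, W)")
  sums <- colSums(unclass(dps), dims = 1L)
  if (any(abs(sums - 1) > 1e-4))
    contract_error("DPS is not normalized: per-pixel sums deviate from 1 by > 1e-4")
  C <- d[1]
  acc <- array(0, dim = d)
  for (n in seq_len(index$D)) {
    Vn <- gather_plane(V, index, n)
    w  <- array(rep(dps[n, , ], each = C), dim = d)
    acc <- acc + Vn * w
  }
  normalize_channels(acc, norm) + x
}

#' Default DiCoA parameter block
#'
#' @param k Neighborhood size (odd; default 3).
#' @param delta Dilation (default 1).
#' @param channels Projection channels (default 256).
#' @param norm Normalisation used in the feature update.
#' @param scale_qk Whether to scale logits by `1/sqrt(C)`.
#' @param weights Optional precomputed [init_qkv_weights()]; if `NULL`,
#'   weights are initialised from `seed` at first use.
#' @param seed Seed for weight initialisation.
#' @return Parameter list of class `dicoa_params`.
#' @export
dicoa_params <- function(k = 3L, delta = 1L, channels = 256L,
                         norm = c("channel", "l2", "identity"),
                         scale_qk = FALSE, weights = NULL, seed = 1L) {
  check_k_delta(k, delta)
  structure(list(k = as.integer(k), delta = as.integer(delta),
                 channels = as.integer(channels), norm = match.arg(norm),
                 scale_qk = isTRUE(scale_qk), weights = weights,
                 seed = as.integer(seed)),
            class = "dicoa_params")
}

#' DiCoA forward pass
#'
#' Full operator: project the input to Q/K/V with 1x1 convolutions, compute
#' dilated-neighborhood attention scores, gather and weight the neighborhood
#' values, normalise, and add the residual. Returns both the weighted feature
#' map (fed onward in a detection backbone) and the score field (summarised
#' into a per-box attention confidence by [dps_to_pdicoa()]).
#'
#' @param x Input feature map `C x H x W`.
#' @param params A [dicoa_params()] block.
#' @return List with `y` (feature map, same shape as `x`) and `dps`
#'   (`D x H x W` scores).
#' @export
dicoa_forward <- function(x, params = dicoa_params()) {
  assert_feature_map(x)
  d <- dim(x)
  w <- params$weights %||%
    init_qkv_weights(d[1], params$channels, params$seed)
  qkv <- project_qkv(x, w)
  idx <- neighbor_index(params$k, params$delta, d[2], d[3])
  dps <- attention_scores(qkv$Q, qkv$K, idx, scale_qk = params$scale_qk)
  y <- update_features(dps, qkv$V, x, idx, norm = params$norm)
  list(y = y, dps = dps)
}

#' Literal loop reference for the DiCoA forward pass
#'
#' A deliberately slow, pixel-by-pixel implementation of the same operator
#' (per-pixel softmax over explicitly enumerated neighbor positions, explicit
#' weighted sums). It shares no array-manipulation code with
#' [dicoa_forward()] and serves as the independent reference the vectorized
#' path is checked against.
#'
#' @inheritParams dicoa_forward
#' @return Same structure as [dicoa_forward()].
#' @export
dicoa_forward_reference <- function(x, params = dicoa_params()) {
  assert_feature_map(x)
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  w <- params$weights %||%
    init_qkv_weights(C, params$channels, params$seed)
  proj <- function(px, ww) as.numeric(ww$W %*% px + ww$b)
  D <- params$k^2
  dps <- array(NA_real_, dim = c(D, H, W))
  y <- array(NA_real_, dim = d)
  for (i in seq_len(H) - 1L) {
    for (j in seq_len(W) - 1L) {
      px <- x[, i + 1L, j + 1L]
      q <- proj(px, w$q)
      pos <- neighbor_positions(i, j, params$k, params$delta, H, W)
      logit <- numeric(D)
      vals <- matrix(0, nrow = C, ncol = D)
      for (n in seq_len(D)) {
        nb <- x[, pos[n, 1] + 1L, pos[n, 2] + 1L]
        logit[n] <- sum(q * proj(nb, w$k))
        vals[, n] <- proj(nb, w$v)
      }
      if (params$scale_qk) logit <- logit / sqrt(length(q))
      e <- exp(logit - max(logit))
      sc <- e / sum(e)
      dps[, i + 1L, j + 1L] <- sc
      agg <- as.numeric(vals %*% sc)
      agg <- switch(params$norm,
        identity = agg,
        channel = (agg - mean(agg)) /
          sqrt(max(mean(agg^2) - mean(agg)^2, 0) + 1e-6),
        l2 = agg / sqrt(sum(agg^2) + 1e-6))
      y[, i + 1L, j + 1L] <- agg + px
    }
  }
  list(y = y, dps = structure(dps, class = "dicoa_scores"))
}

#' Summarise the attention score field into a per-box confidence
#'
#' Projects a detection box onto the feature map (dividing by the stride and
#' rounding outward to at least one pixel), averages the per-pixel maximum
#' neighbor score over that footprint, and rescales so that a uniform score
#' field (`1/D` everywhere, no attention contrast) maps to 0 and a one-hot
#' field maps to 1. With `D = 1` the field is uniform by construction and the
#' result is defined as 0.
#'
#' @param dps `D x H x W` score array.
#' @param box A list or one-row data frame with `x`, `y` (center, image
#'   pixels, 0-based) and `w`, `h` (box extent in image pixels).
#' @param stride Image-to-feature-map downscaling factor.
#' @return Scalar attention confidence in `[0, 1]`.
#' @export
dps_to_pdicoa <- function(dps, box, stride = 8) {
  d <- dim(dps); D <- d[1]; H <- d[2]; W <- d[3]
  if (stride <= 0) param_error("stride must be positive")
  fr0 <- floor((box$y - box$h / 2) / stride)
  fr1 <- ceiling((box$y + box$h / 2) / stride) - 1
  fc0 <- floor((box$x - box$w / 2) / stride)
  fc1 <- ceiling((box$x + box$w / 2) / stride) - 1
  if (fr1 < fr0) fr1 <- fr0
  if (fc1 < fc0) fc1 <- fc0
  if (fr1 < 0 || fr0 > H - 1 || fc1 < 0 || fc0 > W - 1)
    mito_error("mito_footprint_error",
               "box footprint lies entirely outside the feature map")
  rows <- clamp(fr0, 0, H - 1):clamp(fr1, 0, H - 1) + 1L
  cols <- clamp(fc0, 0, W - 1):clamp(fc1, 0, W - 1) + 1L
  if (D == 1L) return(0)
  sub <- unclass(dps)[, rows, cols, drop = FALSE]
  mx <- apply(sub, c(2, 3), max)
  v <- mean(mx)
  clamp((v - 1 / D) / (1 - 1 / D), 0, 1)
}
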