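# Dilated contextual attention operator

test_that("neighbor positions: interior, dilation, and border shift", {
  # interior 8-neighborhood plus self
  pos <- neighbor_positions(5, 5, k = 3, delta = 1, H = 12, W = 12)
  expect_equal(pos, cbind(row = rep(4:6, each = 3), col = rep(4:6, 3)))
  # dilation-2 offsets
  pos2 <- neighbor_positions(5, 5, k = 3, delta = 2, H = 12, W = 12)
  expect_equal(pos2, cbind(row = rep(c(3, 5, 7), each = 3),
                           col = rep(c(3, 5, 7), 3)))
  # corner pixel: the whole window shifts inward
  pos0 <- neighbor_positions(0, 0, k = 3, delta = 1, H = 12, W = 12)
  expect_equal(pos0, cbind(row = rep(0:2, each = 3), col = rep(0:2, 3)))
})

test_that("neighbor positions agree with the brute-force shift oracle", {
  for (k in c(1, 3, 5)) for (delta in 1:3) {
    H <- 9; W <- 11
    for (i in c(0, 1, 4, H - 1)) for (j in c(0, 2, 5, W - 1)) {
      got <- neighbor_positions(i, j, k, delta, H, W)
      want <- oracle_neighbor_positions(i, j, k, delta, H, W)
      expect_equal(unname(got), unname(want),
                   info = sprintf("k=%d delta=%d i=%d j=%d", k, delta, i, j))
      expect_equal(nrow(got), k^2)
      expect_true(all(got[, 1] >= 0 & got[, 1] < H &
                      got[, 2] >= 0 & got[, 2] < W))
    }
  }
})

test_that("invalid neighborhood parameters are rejected", {
  expect_error(neighbor_positions(0, 0, k = 2, delta = 1, H = 8, W = 8),
               class = "mito_param_error")
  expect_error(neighbor_positions(0, 0, k = -3, delta = 1, H = 8, W = 8),
               class = "mito_param_error")
  expect_error(neighbor_positions(0, 0, k = 3, delta = 0, H = 8, W = 8),
               class = "mito_param_error")
})

test_that("qkv projection is a per-pixel linear map", {
  x <- generate_feature_fixture(5, 6, 7, seed = 11)
  w <- init_qkv_weights(5, channels = 8, seed = 2)
  out <- project_qkv(x, w)
  expect_equal(dim(out$Q), c(8, 6, 7))
  expect_equal(dim(out$V), c(5, 6, 7))
  # zero input stays zero under zero bias
  z <- project_qkv(array(0, dim = c(5, 6, 7)), w)
  expect_equal(max(abs(z$Q)), 0)
  expect_equal(max(abs(z$V)), 0)
  # identity weights reproduce the input
  wi <- w
  wi$q$W <- diag(5)
  wi$q$b <- numeric(5)
  expect_equal(project_qkv(x, wi)$Q, x)
  # explicit per-pixel matrix-vector oracle
  for (pix in list(c(1, 1), c(3, 5), c(6, 7))) {
    expect_equal(out$K[, pix[1], pix[2]],
                 as.numeric(w$k$W %*% x[, pix[1], pix[2]]))
  }
  expect_error(project_qkv(generate_feature_fixture(3, 4, 4), w),
               class = "mito_shape_error")
})

test_that("attention scores: degenerate and random cases match Eq. semantics", {
  idx <- neighbor_index(3, 1, 6, 6)
  # constant K over space -> equal logits -> uniform scores
  Q <- generate_feature_fixture(4, 6, 6, seed = 1)
  K <- array(rep(stats::rnorm(4), 36), dim = c(4, 6, 6))
  sc <- attention_scores(Q, K, idx)
  expect_equal(max(abs(sc - 1 / 9)), 0, tolerance = 1e-12)
  # zero queries -> uniform
  sc0 <- attention_scores(array(0, dim = c(4, 6, 6)),
                          generate_feature_fixture(4, 6, 6, seed = 2), idx)
  expect_equal(max(abs(sc0 - 1 / 9)), 0, tolerance = 1e-12)
  # random Q, K vs explicit triple loop
  for (delta in 1:3) {
    H <- 12; W <- 12; C <- 8
    Q <- generate_feature_fixture(C, H, W, seed = 30 + delta)
    K <- generate_feature_fixture(C, H, W, seed = 60 + delta)
    idx2 <- neighbor_index(3, delta, H, W)
    got <- attention_scores(Q, K, idx2)
    for (i in c(0, 3, 11)) for (j in c(0, 7, 11)) {
      pos <- oracle_neighbor_positions(i, j, 3, delta, H, W)
      logit <- vapply(seq_len(9), function(n)
        sum(Q[, i + 1, j + 1] * K[, pos[n, 1] + 1, pos[n, 2] + 1]),
        numeric(1))
      want <- exp(logit - max(logit)); want <- want / sum(want)
      expect_equal(got[, i + 1, j + 1], want, tolerance = 1e-5)
    }
  }
})

test_that("score field is a per-pixel probability distribution", {
  for (delta in 1:3) {
    x <- generate_feature_fixture(6, 10, 13, seed = delta)
    out <- dicoa_forward(x, dicoa_params(channels = 8, delta = delta,
                                         seed = delta))
    sums <- colSums(unclass(out$dps), dims = 1)
    expect_lt(max(abs(sums - 1)), 1e-6)
    expect_true(all(out$dps >= 0 & out$dps <= 1))
  }
})

test_that("value gathering is a pure gather", {
  idx <- neighbor_index(3, 1, 8, 8)
  # constant value map -> constant stack
  V <- array(2.5, dim = c(3, 8, 8))
  expect_equal(max(abs(gather_values(V, idx) - 2.5)), 0)
  # interior pixel equals the row-major 3x3 patch
  V <- generate_feature_fixture(3, 8, 8, seed = 5)
  st <- gather_values(V, idx)
  i <- 4; j <- 4  # 0-based interior
  patch <- sapply(1:9, function(n) {
    a <- (n - 1) %/% 3 - 1; b <- (n - 1) %% 3 - 1
    V[, i + a + 1, j + b + 1]
  })
  expect_equal(st[, , i + 1, j + 1], t(patch))
  # random gather equals loop oracle
  for (i in c(0, 2, 7)) for (j in c(0, 3, 7)) {
    pos <- oracle_neighbor_positions(i, j, 3, 1, 8, 8)
    for (n in c(1, 5, 9))
      expect_equal(st[n, , i + 1, j + 1], V[, pos[n, 1] + 1, pos[n, 2] + 1])
  }
})

test_that("feature update obeys the residual contract", {
  x <- generate_feature_fixture(4, 7, 7, seed = 3)
  idx <- neighbor_index(3, 1, 7, 7)
  dps <- array(1 / 9, dim = c(9, 7, 7))
  # V = 0 and norm(0) = 0 -> y = x exactly
  expect_equal(update_features(dps, array(0, dim = dim(x)), x, idx,
                               norm = "channel"), x)
  # uniform scores, constant V, identity norm -> y = v + x
  V <- array(3.25, dim = dim(x))
  expect_equal(update_features(dps, V, x, idx, norm = "identity"), x + 3.25)
  # unnormalized DPS is rejected
  bad <- dps; bad[1, 2, 2] <- bad[1, 2, 2] + 1e-2
  expect_error(update_features(bad, V, x, idx), class = "mito_contract_error")
})

test_that("vectorized forward pass equals the literal loop reference", {
  for (C in c(4, 8)) for (delta in 1:2) for (nrm in c("channel", "identity")) {
    x <- generate_feature_fixture(C, 9, 9, seed = C * 10 + delta)
    p <- dicoa_params(channels = 8, delta = delta, norm = nrm,
                      seed = C + delta)
    a <- dicoa_forward(x, p)
    b <- dicoa_forward_reference(x, p)
    expect_lt(max(abs(a$y - b$y)), 1e-5)
    expect_lt(max(abs(a$dps - b$dps)), 1e-5)
    expect_equal(dim(a$y), dim(x))
  }
})

test_that("forward pass is translation-equivariant on interior pixels", {
  C <- 4; H <- 14; W <- 14; s <- 2
  base <- generate_feature_fixture(C, H, W, seed = 9)
  shifted <- array(0, dim = c(C, H, W))
  shifted[, (1 + s):H, (1 + s):W] <- base[, 1:(H - s), 1:(W - s)]
  p <- dicoa_params(channels = 8, norm = "identity", seed = 4)
  ya <- dicoa_forward(base, p)$y
  yb <- dicoa_forward(shifted, p)$y
  # compare interior crops whose dilated neighborhoods are interior in both
  core_a <- ya[, 3:(H - s - 2), 3:(W - s - 2)]
  core_b <- yb[, (3 + s):(H - 2), (3 + s):(W - 2)]
  expect_equal(core_a, core_b, tolerance = 1e-10)
})

test_that("k = 1 reduces to the trivially local operator", {
  x <- generate_feature_fixture(3, 6, 6, seed = 2)
  out <- dicoa_forward(x, dicoa_params(k = 1, channels = 4,
                                       norm = "identity", seed = 3))
  expect_equal(max(abs(out$dps - 1)), 0)
  w <- init_qkv_weights(3, 4, seed = 3)
  expect_equal(out$y, apply_v <- {
    v <- array(w$v$W %*% matrix(x, 3), dim = dim(x))
    v + x
  }, tolerance = 1e-12)
})

test_that("score field summarises to a bounded per-box confidence", {
  # uniform field -> 0 for any box
  dps <- array(1 / 9, dim = c(9, 16, 16))
  box <- list(x = 40, y = 40, w = 24, h = 24)
  expect_equal(dps_to_pdicoa(dps, box, stride = 8), 0)
  # one-hot field -> 1
  hot <- array(0, dim = c(9, 16, 16)); hot[4, , ] <- 1
  expect_equal(dps_to_pdicoa(hot, box, stride = 8), 1)
  # random field equals the brute-force footprint mean
  dps <- withr::with_seed(8, {
    a <- array(stats::rexp(9 * 16 * 16), dim = c(9, 16, 16))
    sw <- colSums(a, dims = 1)
    a / aperm(array(sw, dim = c(16, 16, 9)), c(3, 1, 2))
  })
  b2 <- list(x = 52, y = 36, w = 30, h = 20)
  rows <- (floor((36 - 10) / 8):(ceiling((36 + 10) / 8) - 1)) + 1
  cols <- (floor((52 - 15) / 8):(ceiling((52 + 15) / 8) - 1)) + 1
  v <- mean(apply(dps[, rows, cols], c(2, 3), max))
  expect_equal(dps_to_pdicoa(dps, b2, stride = 8),
               (v - 1 / 9) / (1 - 1 / 9))
  # box entirely outside the map errors
  expect_error(dps_to_pdicoa(dps, list(x = 500, y = 500, w = 10, h = 10), 8),
               class = "mito_footprint_error")
})

test_that("feature fixtures are seeded and well-scaled", {
  a <- generate_feature_fixture(4, 5, 6, seed = 42)
  b <- generate_feature_fixture(4, 5, 6, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_feature_fixture(4, 5, 6, seed = 43)))
  big <- generate_feature_fixture(64, 64, 64, seed = 1)
  expect_lt(abs(mean(big)), 0.05)
})
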