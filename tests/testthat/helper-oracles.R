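# Independent slow oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles rather
# than reusing package internals.

# Neighbor positions by brute force: try every inward shift of the dilated
# window, smallest |shift| first, and take the first that is fully in
# bounds; fall back to per-position clamping when no shift fits.
oracle_neighbor_positions <- function(i, j, k, delta, H, W) {
  r <- (k - 1) / 2
  offs <- delta * (-r:r)
  fit_shift <- function(coord, n) {
    shifts <- seq(-(n - 1), n - 1)
    shifts <- shifts[order(abs(shifts), shifts)]
    for (shift in shifts) {
      pos <- coord + shift + offs
      if (all(pos >= 0 & pos <= n - 1)) return(pos)
    }
    pmin(pmax(coord + offs, 0), n - 1)
  }
  rows <- fit_shift(i, H)
  cols <- fit_shift(j, W)
  cbind(row = rep(rows, each = k), col = rep(cols, times = k))
}

# O(n^2) greedy NMS written as repeated max-extraction over a live set.
oracle_nms <- function(boxes, iou_thr) {
  score <- ifelse(is.na(boxes$p_det), boxes$p_obj, boxes$p_det)
  alive <- rep(TRUE, nrow(boxes))
  kept <- integer(0)
  iou1 <- function(i, j) {
    inter_w <- max(0, min(boxes$x[i] + boxes$w[i] / 2, boxes$x[j] + boxes$w[j] / 2) -
                      max(boxes$x[i] - boxes$w[i] / 2, boxes$x[j] - boxes$w[j] / 2))
    inter_h <- max(0, min(boxes$y[i] + boxes$h[i] / 2, boxes$y[j] + boxes$h[j] / 2) -
                      max(boxes$y[i] - boxes$h[i] / 2, boxes$y[j] - boxes$h[j] / 2))
    inter <- inter_w * inter_h
    inter / (boxes$w[i] * boxes$h[i] + boxes$w[j] * boxes$h[j] - inter)
  }
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(-score[cand], boxes$y[cand], boxes$x[cand])][1]
    kept <- c(kept, best)
    alive[best] <- FALSE
    for (j in which(alive)) if (iou1(best, j) > iou_thr) alive[j] <- FALSE
  }
  sort(kept)
}

# Greedy center-distance matcher implemented over a globally sorted pair
# list (different route than the package's matrix scan).
oracle_match <- function(preds, truths, radius) {
  cand <- expand.grid(p = seq_len(nrow(preds)), t = seq_len(nrow(truths)))
  if (nrow(cand) == 0) return(list(tp = 0L, fp = nrow(preds), fn = nrow(truths)))
  cand$d <- sqrt((preds$x[cand$p] - truths$x[cand$t])^2 +
                 (preds$y[cand$p] - truths$y[cand$t])^2)
  cand <- cand[cand$d <= radius, , drop = FALSE]
  cand <- cand[order(cand$d, cand$p, cand$t), , drop = FALSE]
  up <- logical(nrow(preds)); ut <- logical(nrow(truths)); tp <- 0L
  for (r in seq_len(nrow(cand))) {
    p <- cand$p[r]; t <- cand$t[r]
    if (!up[p] && !ut[t]) { up[p] <- TRUE; ut[t] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(preds) - tp, fn = nrow(truths) - tp)
}

# Exhaustive stride-1 HPF search over all integer origins.
oracle_select_hpf <- function(points, slide_dim, window) {
  h <- window[1]; w <- window[2]
  best_count <- -1L; best <- c(0L, 0L)
  for (or in 0:(slide_dim[1] - h)) {
    iny <- points$y >= or & points$y < or + h
    if (sum(iny) <= best_count) next
    px <- points$x[iny]
    for (oc in 0:(slide_dim[2] - w)) {
      cnt <- sum(px >= oc & px < oc + w)
      if (cnt > best_count) { best_count <- cnt; best <- c(or, oc) }
    }
  }
  list(origin = best, count = best_count)
}

# Random detection-box tables for property tests.
random_boxes <- function(n, dim = c(600, 600), seed = 1) {
  withr::with_seed(seed, data.frame(
    x = runif(n, 10, dim[2] - 10), y = runif(n, 10, dim[1] - 10),
    w = runif(n, 8, 40), h = runif(n, 8, 40),
    p_obj = runif(n), p_dicoa = NA_real_, p_det = runif(n),
    p_cls = NA_real_, p = NA_real_))
}

# Small shared synthetic config for backend tests (kept modest so the suite
# stays fast).
test_synth_cfg <- function(seed = 7) {
  synth_config(slide_dim = c(1200, 1200), mitotic_density = 60,
               distractor_density = 3000, seed = seed)
}

# Control: train the same head on label-shuffled crops (test-side copy of the
# training recipe, used for the permutation control).
train_reference_classifier_shuffled <- function(cfg, n_pos, n_neg, seed) {
  cs <- generate_crop_set(cfg, n_pos, n_neg, seed = seed)
  labels <- withr::with_seed(seed + 1, sample(cs$labels))
  base <- train_reference_classifier(cfg, n_pos, n_neg, seed = seed)
  X <- t(vapply(cs$crops, function(cr)
    fuse_features(base$backbone_a(cr), base$backbone_b(cr)),
    numeric(length(base$head$w))))
  df <- as.data.frame(X)
  df$y <- as.integer(labels == "mitosis")
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  co <- coef(fit); co[is.na(co)] <- 0
  list(backbone_a = base$backbone_a, backbone_b = base$backbone_b,
       head = list(w = co[-1], b = co[1]))
}

# A scriptable mock detector: reports a fixed set of slide-coordinate boxes,
# translated into whatever tile it is shown (it cannot see the origin, so the
# test wires tiles of known content via closures over pixel markers).
marker_detector <- function(truth, p_obj = 0.9, blind_recenter = FALSE) {
  force(truth)
  function(tile_img) {
    # markers: single bright-red pixels encode object centers
    idx <- which(tile_img[, , 1] > 0.99 & tile_img[, , 2] < 0.01,
                 arr.ind = TRUE)
    if (blind_recenter && nrow(idx) > 0 &&
        any(abs(idx[, 1] - nrow(tile_img) / 2) < 5)) {
      idx <- idx[0, , drop = FALSE]
    }
    boxes <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                        w = rep(16, nrow(idx)), h = rep(16, nrow(idx)),
                        p_obj = rep(p_obj, nrow(idx)))
    list(boxes = boxes)
  }
}

marker_slide <- function(dim, centers) {
  img <- array(0.5, dim = c(dim, 3))
  for (i in seq_len(nrow(centers))) {
    img[centers[i, 1] + 1, centers[i, 2] + 1, ] <- c(1, 0, 0)
  }
  img
}

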