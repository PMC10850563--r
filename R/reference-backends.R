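# Reference backends ------------------------------------------------------------
#
# Classical image-analysis implementations of the pluggable detector and
# classifier contracts, so the whole cascade can be exercised and trained on
# synthetic tiles in minutes on one CPU. The detector segments dark blobs
# (smoothing + Otsu threshold + connected components), summarises each blob
# with moment/shape features, and scores it with a binomial GLM; a DiCoA pass
# over a downsampled tile feature map supplies the attention score field, in
# line with the placement contract (attention applied to the deepest feature
# map, its score field summarised per box). The classifier implements the
# dual-backbone channel-concat + global-average-pool + linear head exactly;
# the two backbones are distinct hand-crafted convolutional feature stems.

# --- blob extraction ----------------------------------------------------------

# Segment dark blobs in an H x W x 3 tile. Returns a data frame of candidate
# boxes with moment features (centers 0-based).
extract_blobs <- function(img, min_area = 25, sigma = 1.5) {
  dark <- 1 - (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  sm <- EBImage::gblur(dark, sigma = sigma)
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  # guard: an object-free tile puts Otsu inside the background noise band;
  # requiring contrast over the tile median suppresses that case
  thr <- max(thr, stats::median(sm) + 0.08)
  mask <- sm > thr
  if (!any(mask)) return(empty_blobs())
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  labm <- EBImage::imageData(lab)
  idx <- which(labm > 0)
  if (!length(idx)) return(empty_blobs())
  ids <- labm[idx]
  pos <- arrayInd(idx, dim(labm))
  r <- pos[, 1] - 1; cc <- pos[, 2] - 1
  area <- as.numeric(rowsum(rep(1, length(ids)), ids))
  uid <- sort(unique(ids))
  cy <- as.numeric(rowsum(r, ids)) / area
  cx <- as.numeric(rowsum(cc, ids)) / area
  # central second moments -> ellipse axes and eccentricity
  myy <- as.numeric(rowsum(r^2, ids)) / area - cy^2
  mxx <- as.numeric(rowsum(cc^2, ids)) / area - cx^2
  mxy <- as.numeric(rowsum(r * cc, ids)) / area - cy * cx
  tr <- mxx + myy
  det2 <- sqrt(pmax((mxx - myy)^2 / 4 + mxy^2, 0))
  l1 <- pmax(tr / 2 + det2, 1e-9)
  l2 <- pmax(tr / 2 - det2, 1e-9)
  ecc <- sqrt(pmax(1 - l2 / l1, 0))
  darkness <- as.numeric(rowsum(dark[idx], ids)) / area
  h <- as.numeric(tapply(r, ids, max) - tapply(r, ids, min)) + 1
  w <- as.numeric(tapply(cc, ids, max) - tapply(cc, ids, min)) + 1
  out <- data.frame(x = cx, y = cy, w = w, h = h, area = area,
                    eccentricity = ecc, major = 4 * sqrt(l1),
                    darkness = darkness)
  out[out$area >= min_area, , drop = FALSE]
}

empty_blobs <- function() {
  data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
             area = numeric(0), eccentricity = numeric(0),
             major = numeric(0), darkness = numeric(0))
}

blob_feature_matrix <- function(blobs) {
  cbind(log_area = log(blobs$area),
        eccentricity = blobs$eccentricity,
        major = blobs$major / 10,
        darkness = blobs$darkness,
        aspect = pmax(blobs$w, blobs$h) / pmax(pmin(blobs$w, blobs$h), 1))
}

# --- tile feature map for the attention pass ----------------------------------

# Block-mean pooling of a matrix by an integer stride.
block_pool <- function(m, stride) {
  H <- (nrow(m) %/% stride) * stride
  W <- (ncol(m) %/% stride) * stride
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  hb <- H %/% stride; wb <- W %/% stride
  a <- array(m, dim = c(stride, hb, stride, wb))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# 4-channel hand-crafted feature map of a tile at the given stride:
# darkness, row/col gradient magnitudes, local contrast.
tile_feature_map <- function(img, stride = 8L) {
  dark <- 1 - (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  gr <- abs(rbind(diff(dark), 0))
  gc <- abs(cbind(t(diff(t(dark))), 0))
  mu <- block_pool(dark, stride)
  mu2 <- block_pool(dark^2, stride)
  ctr <- sqrt(pmax(mu2 - mu^2, 0))
  fm <- array(0, dim = c(4L, dim(mu)))
  fm[1, , ] <- mu
  fm[2, , ] <- block_pool(gr, stride)
  fm[3, , ] <- block_pool(gc, stride)
  fm[4, , ] <- ctr
  fm
}

# --- reference detector -------------------------------------------------------

#' Train the reference detector on synthetic tiles
#'
#' Samples training tiles from seeded synthetic slides, extracts candidate
#' blobs, labels each candidate by proximity to a mitosis annotation, and
#' fits a binomial GLM on the blob features to produce `Pobj`. The DiCoA
#' projection weights for the tile feature map are initialised from the same
#' seed. Deterministic given `(cfg, seed)`.
#'
#' @param cfg A [synth_config()] for the training slides.
#' @param n_tiles Number of 512 x 512 training tiles to sample (default 24).
#' @param seed RNG seed.
#' @param label_radius Candidate-to-annotation distance that defines a
#'   positive training label (default 15 px).
#' @param dicoa DiCoA parameters for the tile feature map; defaults to
#'   `dicoa_params(channels = 16)` at stride 8.
#' @param stride Feature-map stride (default 8).
#' @return Object of class `c("reference_detector", "mito_detector")`.
#' @export
train_reference_detector <- function(cfg, n_tiles = 24L, seed = 1L,
                                     label_radius = 15,
                                     dicoa = NULL, stride = 8L) {
  slide <- generate_slide(cfg)
  tiles <- sample_training_tiles(dim(slide$image)[1:2], slide$annotations,
                                 n_tiles, seed = derive_seed(seed, 1L))
  feats <- NULL; labels <- integer(0)
  for (tl in tiles) {
    img <- slide$image[tl$origin["row"] + 1:512,
                       tl$origin["col"] + 1:512, , drop = FALSE]
    blobs <- extract_blobs(img)
    if (!nrow(blobs)) next
    lab <- vapply(seq_len(nrow(blobs)), function(i) {
      ann <- tl$annotations
      nrow(ann) > 0 && any((ann$x - blobs$x[i])^2 +
                           (ann$y - blobs$y[i])^2 <= label_radius^2)
    }, logical(1))
    feats <- rbind(feats, blob_feature_matrix(blobs))
    labels <- c(labels, as.integer(lab))
  }
  if (is.null(feats) || length(unique(labels)) < 2)
    size_error("training tiles produced no label contrast; raise densities")
  df <- as.data.frame(feats)
  df$y <- labels
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  params <- dicoa %||% dicoa_params(channels = 16L, seed = derive_seed(seed, 2L))
  if (is.null(params$weights))
    params$weights <- init_qkv_weights(4L, params$channels,
                                       seed = derive_seed(seed, 2L))
  structure(list(coef = stats::coef(fit), dicoa = params,
                 stride = as.integer(stride), label_radius = label_radius),
            class = c("reference_detector", "mito_detector"))
}

#' @export
predict_tile.reference_detector <- function(detector, tile_image) {
  blobs <- extract_blobs(tile_image)
  if (!nrow(blobs))
    return(list(boxes = as_detection_boxes(NULL), dps = NULL))
  fm <- tile_feature_map(tile_image, detector$stride)
  att <- dicoa_forward(fm, detector$dicoa)
  X <- cbind(1, blob_feature_matrix(blobs))
  p_obj <- as.numeric(stats::plogis(X %*% detector$coef))
  p_dicoa <- vapply(seq_len(nrow(blobs)), function(i)
    dps_to_pdicoa(att$dps, blobs[i, ], stride = detector$stride),
    numeric(1))
  boxes <- data.frame(x = blobs$x, y = blobs$y,
                      w = pmax(blobs$w, 8), h = pmax(blobs$h, 8),
                      p_obj = p_obj, p_dicoa = p_dicoa)
  list(boxes = as_detection_boxes(boxes), dps = att$dps)
}

# --- reference classifier -----------------------------------------------------

# Backbone A: a segmentation stem focused on the crop center. Extracts dark
# blobs and emits the shape features of the blob nearest the crop center
# (zeros when the center is empty) as a 1 x 1 spatial map with 5 channels.
# Nonlinear stems are what real classification backbones are; this one is
# just shallow.
reference_backbone_a <- function(crop_img) {
  blobs <- extract_blobs(crop_img, min_area = 20)
  d <- dim(crop_img)
  ctr <- c(y = (d[1] - 1) / 2, x = (d[2] - 1) / 2)
  out <- array(0, dim = c(1L, 1L, 5L))
  if (nrow(blobs)) {
    dist <- sqrt((blobs$x - ctr["x"])^2 + (blobs$y - ctr["y"])^2)
    i <- which.min(dist)
    if (dist[i] <= 24)
      out[1, 1, ] <- blob_feature_matrix(blobs[i, , drop = FALSE])[1, ]
  }
  out
}

# Backbone B: a global context stem: 1 x 1 spatial map with 4 channels
# (mean darkness, darkness contrast, gradient energy, dark-pixel fraction).
reference_backbone_b <- function(crop_img) {
  dark <- 1 - (crop_img[, , 1] + crop_img[, , 2] + crop_img[, , 3]) / 3
  gr <- abs(diff(dark))
  out <- array(0, dim = c(1L, 1L, 4L))
  out[1, 1, ] <- c(mean(dark), stats::sd(dark), mean(gr), mean(dark > 0.4))
  out
}

#' Train the reference dual-backbone classifier
#'
#' Generates a seeded labelled crop set, pools the two backbone feature maps
#' through the channel-concat + global-average-pool contract, and fits the
#' linear head as a binomial GLM. Deterministic given `(cfg, seed)`.
#'
#' @param cfg A [synth_config()] for the crop-source slides.
#' @param n_pos,n_neg Training crop counts (defaults 60/60).
#' @param seed RNG seed.
#' @return Classifier backend list usable with [classify_crop()] /
#'   [run_classification()]; class `reference_classifier`.
#' @export
train_reference_classifier <- function(cfg, n_pos = 60L, n_neg = 60L,
                                       seed = 1L) {
  cs <- generate_crop_set(cfg, n_pos, n_neg, seed = derive_seed(seed, 11L))
  X <- t(vapply(cs$crops, function(cr)
    fuse_features(reference_backbone_a(cr), reference_backbone_b(cr)),
    numeric(ncol_pooled())))
  df <- as.data.frame(X)
  df$y <- as.integer(cs$labels == "mitosis")
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  structure(list(backbone_a = reference_backbone_a,
                 backbone_b = reference_backbone_b,
                 head = list(w = co[-1], b = co[1])),
            class = c("reference_classifier", "list"))
}

ncol_pooled <- function() 5L + 4L
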