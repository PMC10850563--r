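# Classification stage ---------------------------------------------------------
#
# Re-scores detected boxes: each box is re-cropped so its center coincides
# with the center of a fixed-size classification window (center adjustment),
# two backbone feature extractors run on the crop, their feature maps are
# concatenated along channels and global-average-pooled, a fully connected
# head produces Pcls, and the final confidence is
#     P = omega * Pdet + (1 - omega) * Pcls .
#
# Crops here are H x W x 3 arrays (channel-last, like decoded images); the
# backbone feature maps are H' x W' x C arrays (channel-last).

#' Center-adjusted crop window for a detection
#'
#' Computes the `crop x crop` window whose center pixel (index
#' `crop/2`, 0-based) coincides with the box center. At slide edges the
#' window is shifted inward (never padded) and the applied shift is recorded
#' in `center_offset`.
#'
#' @param box One-row detection box (needs `x`, `y`).
#' @param slide_dim `(H, W)` slide extents.
#' @param crop Crop side length (default 128).
#' @return Object of class `crop_region`: `origin` (0-based row, col),
#'   `size`, `center_offset` (`(dy, dx)` shift applied, zero for interior
#'   boxes), and the source `box`.
#' @export
center_adjust <- function(box, slide_dim, crop = 128L) {
  cy <- round(box$y); cx <- round(box$x)
  if (cy < 0 || cy >= slide_dim[1] || cx < 0 || cx >= slide_dim[2])
    mito_error("mito_bounds_error", "box center lies outside the slide")
  half <- crop %/% 2L
  want_r <- cy - half
  want_c <- cx - half
  or <- clamp(want_r, 0, slide_dim[1] - crop)
  oc <- clamp(want_c, 0, slide_dim[2] - crop)
  structure(
    list(origin = c(row = or, col = oc), size = as.integer(crop),
         center_offset = c(dy = or - want_r, dx = oc - want_c),
         box = box),
    class = "crop_region"
  )
}

#' Extract the pixels of a crop region
#'
#' @param slide Slide image `H x W x 3`.
#' @param region A [center_adjust()] crop region.
#' @return `crop x crop x 3` array.
#' @export
crop_pixels <- function(slide, region) {
  s <- region$size
  slide[region$origin["row"] + seq_len(s),
        region$origin["col"] + seq_len(s), , drop = FALSE]
}

#' Concatenate two backbone feature maps and global-average-pool
#'
#' The two feature maps (same spatial extents, `C1` and `C2` channels) are
#' concatenated along the channel axis and compressed by 2-d global average
#' pooling to a single vector of length `C1 + C2`.
#'
#' @param fA,fB Channel-last feature arrays `H x W x C1` and `H x W x C2`.
#' @return Numeric vector of length `C1 + C2` (spatial mean per channel).
#' @export
fuse_features <- function(fA, fB) {
  if (length(dim(fA)) != 3 || length(dim(fB)) != 3)
    shape_error("backbone outputs must be H x W x C arrays")
  if (!identical(dim(fA)[1:2], dim(fB)[1:2]))
    shape_error("backbone outputs differ in spatial extent")
  c(apply(fA, 3, mean), apply(fB, 3, mean))
}

#' Classify one crop with a dual-backbone backend
#'
#' Runs both backbones, fuses their features via [fuse_features()], and
#' applies the backend's linear head with a sigmoid squashing to produce the
#' mitosis confidence.
#'
#' @param crop_img `crop x crop x 3` pixel array.
#' @param backend Classifier backend: `list(backbone_a, backbone_b,
#'   head = list(w, b))` where the backbones map a crop to a channel-last
#'   feature array.
#' @return `Pcls` in `[0, 1]`.
#' @export
classify_crop <- function(crop_img, backend) {
  v <- fuse_features(backend$backbone_a(crop_img),
                     backend$backbone_b(crop_img))
  if (length(backend$head$w) != length(v))
    shape_error("head weight length does not match pooled feature length")
  stats::plogis(sum(backend$head$w * v) + backend$head$b)
}

#' Fuse detection and classification confidences
#'
#' `P = omega * Pdet + (1 - omega) * Pcls`: the final confidence is a convex
#' combination, so it always lies between the two stage confidences.
#'
#' @param p_det,p_cls Stage confidences in `[0, 1]` (vectorised).
#' @param omega Detection-stage weight in `[0, 1]` (default 0.5).
#' @return Final confidence(s) `P`.
#' @export
fuse_final_confidence <- function(p_det, p_cls, omega = 0.5) {
  if (any(p_det < 0 | p_det > 1, na.rm = TRUE) ||
      any(p_cls < 0 | p_cls > 1, na.rm = TRUE))
    range_error("confidences must lie in [0, 1]")
  if (length(omega) != 1 || omega < 0 || omega > 1)
    range_error("omega must be a scalar in [0, 1]")
  omega * p_det + (1 - omega) * p_cls
}

#' Classification-stage re-scoring of detected boxes
#'
#' For every detection: center-adjust a crop, classify it, and fuse `Pdet`
#' with `Pcls` into the final confidence `P`. Box geometry and ordering are
#' never modified.
#'
#' @param boxes Detection boxes with `p_det` set.
#' @param slide Slide image `H x W x 3`.
#' @param backend Classifier backend (see [classify_crop()]).
#' @param omega Fusion weight (default 0.5).
#' @param crop Crop side length (default 128).
#' @return The boxes with `p_cls` and `p` filled in.
#' @export
run_classification <- function(boxes, slide, backend, omega = 0.5,
                               crop = 128L) {
  boxes <- as_detection_boxes(boxes)
  if (nrow(boxes) == 0) return(boxes)
  if (any(is.na(boxes$p_det)))
    contract_error("run_classification requires p_det on every box")
  d <- dim(slide)
  boxes$p_cls <- vapply(seq_len(nrow(boxes)), function(i) {
    region <- center_adjust(boxes[i, ], d[1:2], crop)
    classify_crop(crop_pixels(slide, region), backend)
  }, numeric(1))
  boxes$p <- fuse_final_confidence(boxes$p_det, boxes$p_cls, omega)
  boxes
}
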