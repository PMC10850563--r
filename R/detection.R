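# Detection stage --------------------------------------------------------------
#
# Sliding-window tiling over a slide, a pluggable per-tile detector backend,
# relocation of border detections onto re-centered windows, greedy NMS, and
# the detection-stage confidence fusion
#     Pdet = (1 - alpha) * Pobj + alpha * Pdicoa .
#
# Detection boxes travel as data frames with columns
#   x, y   : center coordinates, slide pixels, 0-based (x = col, y = row)
#   w, h   : box extents in pixels
#   p_obj  : detector confidence
#   p_dicoa, p_det, p_cls, p : optional downstream confidences (NA if unset)

DETECTION_COLS <- c("x", "y", "w", "h", "p_obj", "p_dicoa", "p_det", "p_cls", "p")

#' Construct or validate a detection-box table
#'
#' @param df Data frame with at least `x`, `y`, `w`, `h`, `p_obj`; missing
#'   confidence columns are added as `NA`.
#' @return Validated data frame with the full detection-box column set.
#' @export
as_detection_boxes <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(DETECTION_COLS)), DETECTION_COLS))
    return(out)
  }
  need <- c("x", "y", "w", "h", "p_obj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    schema_error(paste("detection boxes missing columns:",
                       paste(miss, collapse = ", ")))
  for (col in setdiff(DETECTION_COLS, names(df))) df[[col]] <- NA_real_
  if (any(df$w <= 0 | df$h <= 0))
    schema_error("detection boxes must have positive w and h")
  for (col in c("p_obj", "p_dicoa", "p_det", "p_cls", "p")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      range_error(sprintf("%s outside [0, 1]", col))
  }
  df[, union(DETECTION_COLS, names(df))]
}

#' Fuse detector and attention confidences
#'
#' `Pdet = (1 - alpha) * Pobj + alpha * Pdicoa`, the detection-stage update
#' that blends the backbone's objectness score with the attention-derived
#' score. Affine and monotone in both inputs; `alpha = 0` returns `Pobj`,
#' `alpha = 1` returns `Pdicoa`.
#'
#' @param p_obj,p_dicoa Confidences in `[0, 1]` (vectorised).
#' @param alpha Attention weight in `[0, 1]` (default 0.5).
#' @return Fused confidence(s) in `[0, 1]`.
#' @export
fuse_detection_confidence <- function(p_obj, p_dicoa, alpha = 0.5) {
  if (any(p_obj < 0 | p_obj > 1, na.rm = TRUE) ||
      any(p_dicoa < 0 | p_dicoa > 1, na.rm = TRUE))
    range_error("confidences must lie in [0, 1]")
  if (length(alpha) != 1 || alpha < 0 || alpha > 1)
    range_error("alpha must be a scalar in [0, 1]")
  (1 - alpha) * p_obj + alpha * p_dicoa
}

axis_origins <- function(n, tile, overlap) {
  if (n <= tile) return(0L)
  step <- tile - overlap
  if (step <= 0) param_error("overlap must be smaller than the tile size")
  o <- seq.int(0L, n - tile, by = step)
  if (o[length(o)] != n - tile) o <- c(o, n - tile)
  as.integer(o)
}

#' Tile a slide with an overlapping sliding window
#'
#' Produces tile origins covering the slide completely; the last row/column
#' of tiles is aligned to the slide edge so no tile leaves the slide. A slide
#' smaller than the tile yields a single origin-(0,0) tile flagged `padded`.
#'
#' @param slide_dim Integer vector `(H, W)` in pixels.
#' @param tile Tile side length (default 512).
#' @param overlap Overlap between adjacent tiles in pixels (default 64).
#' @return Data frame with 0-based `row`, `col` origins and a `padded` flag;
#'   tile size attached as attribute `tile`.
#' @export
tile_slide <- function(slide_dim, tile = 512L, overlap = 64L) {
  if (length(slide_dim) != 2 || any(slide_dim < 1))
    size_error("slide_dim must be two positive extents (H, W)")
  rows <- axis_origins(slide_dim[1], tile, overlap)
  cols <- axis_origins(slide_dim[2], tile, overlap)
  g <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  g$padded <- slide_dim[1] < tile | slide_dim[2] < tile
  attr(g, "tile") <- as.integer(tile)
  g
}

#' Intersection-over-union of center-size boxes
#'
#' @param a One-row box (list/data frame with `x`, `y`, `w`, `h`).
#' @param b Box table to compare against (vectorised).
#' @return Numeric IoU vector.
#' @export
box_iou <- function(a, b) {
  ax0 <- a$x - a$w / 2; ax1 <- a$x + a$w / 2
  ay0 <- a$y - a$h / 2; ay1 <- a$y + a$h / 2
  bx0 <- b$x - b$w / 2; bx1 <- b$x + b$w / 2
  by0 <- b$y - b$h / 2; by1 <- b$y + b$h / 2
  iw <- pmax(0, pmin(ax1, bx1) - pmax(ax0, bx0))
  ih <- pmax(0, pmin(ay1, by1) - pmax(ay0, by0))
  inter <- iw * ih
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Greedy non-maximum suppression
#'
#' Keeps boxes in descending confidence order (`p_det` if set, else
#' `p_obj`), suppressing any remaining box whose IoU with a kept box exceeds
#' the threshold. Confidence ties are broken deterministically by lower
#' `(y, x)`.
#'
#' @param boxes Detection-box data frame.
#' @param iou_threshold Suppression threshold (default 0.3).
#' @return The surviving boxes, in the original row order.
#' @export
nms <- function(boxes, iou_threshold = 0.3) {
  boxes <- as_detection_boxes(boxes)
  n <- nrow(boxes)
  if (n <= 1) return(boxes)
  score <- ifelse(is.na(boxes$p_det), boxes$p_obj, boxes$p_det)
  ord <- order(-score, boxes$y, boxes$x)
  alive <- rep(TRUE, n)
  for (ii in seq_len(n - 1)) {
    i <- ord[ii]
    if (!alive[i]) next
    rest <- ord[(ii + 1):n]
    rest <- rest[alive[rest]]
    if (!length(rest)) break
    iou <- box_iou(boxes[i, ], boxes[rest, ])
    alive[rest[iou > iou_threshold]] <- FALSE
  }
  boxes[sort(which(alive)), , drop = FALSE]
}

#' Sample random training tiles with re-based annotations
#'
#' Draws `n` uniformly random in-bounds tile origins (reproducible under
#' `seed`) and pairs each with the annotations whose centers fall inside the
#' tile, coordinates re-based to the tile frame.
#'
#' @param slide_dim `(H, W)` slide extents.
#' @param annotations Annotation data frame (`x`, `y`, `w`, `h`, `label`).
#' @param n Number of tiles.
#' @param seed RNG seed.
#' @param tile Tile side length (default 512).
#' @return List of `n` elements, each `list(origin = c(row, col),
#'   annotations = <re-based data frame>)`.
#' @export
sample_training_tiles <- function(slide_dim, annotations, n, seed = 1L,
                                  tile = 512L) {
  if (!is_count(n) || n < 1) param_error("n must be a positive integer")
  if (any(slide_dim < tile))
    size_error("slide must be at least the tile size in each dimension")
  with_seed(seed, {
    rows <- sample.int(slide_dim[1] - tile + 1L, n, replace = TRUE) - 1L
    cols <- sample.int(slide_dim[2] - tile + 1L, n, replace = TRUE) - 1L
    lapply(seq_len(n), function(i) {
      keep <- annotations$y >= rows[i] & annotations$y < rows[i] + tile &
              annotations$x >= cols[i] & annotations$x < cols[i] + tile
      ann <- annotations[keep, , drop = FALSE]
      ann$x <- ann$x - cols[i]
      ann$y <- ann$y - rows[i]
      list(origin = c(row = rows[i], col = cols[i]), annotations = ann)
    })
  })
}

# Extract a tile-sized crop centered on (y, x), shifted inward at slide edges
# (padded with the background median only if the slide itself is smaller than
# the tile). Returns list(image, origin, padded).
centered_tile <- function(slide, y, x, tile) {
  d <- dim(slide)
  or <- clamp(round(y) - tile %/% 2, 0, max(d[1] - tile, 0))
  oc <- clamp(round(x) - tile %/% 2, 0, max(d[2] - tile, 0))
  h <- min(tile, d[1]); w <- min(tile, d[2])
  img <- slide[or + seq_len(h), oc + seq_len(w), , drop = FALSE]
  padded <- h < tile || w < tile
  if (padded) {
    full <- array(stats::median(img), dim = c(tile, tile, dim(slide)[3]))
    full[seq_len(h), seq_len(w), ] <- img
    img <- full
  }
  list(image = img, origin = c(row = or, col = oc), padded = padded)
}

#' Re-evaluate detections near tile borders on re-centered windows
#'
#' Detections whose center lies within `margin` pixels of a border of their
#' source tile were produced with truncated context and are re-evaluated: a
#' fresh tile is centered on the box, the detector re-run, and the nearest
#' re-detected box within `match_radius` supplies the replacement `p_obj`
#' (and `p_dicoa` when available). Border boxes with no match are dropped;
#' interior boxes pass through untouched.
#'
#' @param boxes Detection boxes in slide coordinates, carrying `tile_row`,
#'   `tile_col` source-tile origin columns.
#' @param detector A detector backend (see [predict_tile()]).
#' @param slide Slide image array `H x W x 3`.
#' @param margin Border margin in pixels (default 32).
#' @param tile Tile side length (default 512).
#' @param match_radius Center-distance matching radius in pixels (default 25).
#' @return Filtered/updated detection boxes (source-tile columns preserved).
#' @export
window_relocation <- function(boxes, detector, slide, margin = 32L,
                              tile = 512L, match_radius = 25) {
  if (margin >= tile / 2) param_error("margin must be smaller than tile/2")
  if (nrow(boxes) == 0) return(boxes)
  if (!all(c("tile_row", "tile_col") %in% names(boxes)))
    schema_error("window_relocation needs tile_row/tile_col source origins")
  bdist <- pmin(boxes$x - boxes$tile_col,
                boxes$tile_col + tile - 1 - boxes$x,
                boxes$y - boxes$tile_row,
                boxes$tile_row + tile - 1 - boxes$y)
  border <- which(bdist < margin)
  if (!length(border)) return(boxes)
  drop <- logical(nrow(boxes))
  for (i in border) {
    ct <- centered_tile(slide, boxes$y[i], boxes$x[i], tile)
    redet <- predict_tile(detector, ct$image)$boxes
    if (nrow(redet) == 0) { drop[i] <- TRUE; next }
    rx <- redet$x + ct$origin["col"]
    ry <- redet$y + ct$origin["row"]
    dist <- sqrt((rx - boxes$x[i])^2 + (ry - boxes$y[i])^2)
    j <- which.min(dist)
    if (dist[j] > match_radius) { drop[i] <- TRUE; next }
    boxes$p_obj[i] <- redet$p_obj[j]
    if (!is.null(redet$p_dicoa) && !is.na(redet$p_dicoa[j]))
      boxes$p_dicoa[i] <- redet$p_dicoa[j]
  }
  boxes[!drop, , drop = FALSE]
}

#' Run a detector backend on one tile
#'
#' Generic the detection scaffold calls once per tile. Backends return
#' `list(boxes = <data frame with x, y, w, h, p_obj[, p_dicoa]>)` in tile
#' coordinates; function backends are called directly.
#'
#' @param detector Backend object or function.
#' @param tile_image `tile x tile x 3` image array in `[0, 1]`.
#' @return `list(boxes = ...)`.
#' @export
predict_tile <- function(detector, tile_image) UseMethod("predict_tile")

#' @export
predict_tile.function <- function(detector, tile_image) detector(tile_image)

#' @export
predict_tile.default <- function(detector, tile_image) {
  param_error("detector does not implement the backend contract")
}

#' Detection-stage inference over a whole slide
#'
#' Tiles the slide, runs the detector on each tile, maps detections to slide
#' coordinates, relocates border detections onto re-centered windows, fuses
#' `Pobj` with `Pdicoa` into `Pdet` (boxes without an attention score keep
#' `Pdet = Pobj`), drops boxes below the score floor, and applies greedy NMS
#' ranked by the fused confidence.
#'
#' @param slide Slide image array `H x W x 3` in `[0, 1]`.
#' @param detector Detector backend.
#' @param config Detection config block; see [default_config()]`$detect`.
#' @return Detection boxes in slide coordinates with `p_det` set.
#' @export
run_detection <- function(slide, detector, config = default_config()$detect) {
  d <- dim(slide)
  tiles <- tile_slide(d[1:2], config$tile, config$overlap)
  tile <- attr(tiles, "tile")
  parts <- lapply(seq_len(nrow(tiles)), function(i) {
    or <- tiles$row[i]; oc <- tiles$col[i]
    h <- min(tile, d[1]); w <- min(tile, d[2])
    img <- slide[or + seq_len(h), oc + seq_len(w), , drop = FALSE]
    if (tiles$padded[i]) {
      full <- array(stats::median(img), dim = c(tile, tile, d[3]))
      full[seq_len(h), seq_len(w), ] <- img
      img <- full
    }
    bx <- as_detection_boxes(predict_tile(detector, img)$boxes)
    if (nrow(bx) == 0) return(NULL)
    bx$x <- bx$x + oc
    bx$y <- bx$y + or
    bx$tile_row <- or
    bx$tile_col <- oc
    bx
  })
  boxes <- do.call(rbind, parts)
  if (is.null(boxes) || nrow(boxes) == 0) return(as_detection_boxes(NULL))
  if (config$margin > 0)
    boxes <- window_relocation(boxes, detector, slide,
                               margin = config$margin, tile = tile,
                               match_radius = config$match_radius %||% 25)
  boxes$p_det <- ifelse(is.na(boxes$p_dicoa), boxes$p_obj,
                        fuse_detection_confidence(boxes$p_obj, boxes$p_dicoa,
                                                  config$alpha))
  boxes <- boxes[boxes$p_det >= (config$score_floor %||% 0), , drop = FALSE]
  boxes <- nms(boxes, config$nms_iou)
  boxes$tile_row <- NULL
  boxes$tile_col <- NULL
  rownames(boxes) <- NULL
  boxes
}
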