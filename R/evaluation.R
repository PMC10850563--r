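# Evaluation -------------------------------------------------------------------
#
# Center-distance matching of predictions against annotated mitotic figures,
# the standard confusion-count metrics
#     recall      = TP / (TP + FN)
#     precision   = TP / (TP + FP)
#     F1          = 2 * recall * precision / (recall + precision)
#     accuracy    = (TP + TN) / (TP + TN + FP + FN)
#     specificity = TN / (TN + FP)
# high-power-field (HPF) selection (the 7110 x 5333-px rectangle covering the
# standard 10-HPF, 2.37-mm^2 counting region at 0.25 um/px), GA/GB mitotic
# counting, and the MAPE/MAE threshold sweep.

#' Standard HPF window extents
#'
#' The mitotic-count region: one `7110 x 7110`-wide by `5333`-high pixel
#' rectangle at 0.25 um/px, equal in area to the conventional 10 high-power
#' fields (2.37 mm^2). `scale` shrinks it proportionally for scaled-down
#' slides; any `scale != 1` is flagged non-standard in reports.
#'
#' @param scale Proportional scaling factor (default 1).
#' @return `c(height, width)` in pixels.
#' @export
hpf_window_dim <- function(scale = 1) {
  if (scale <= 0) param_error("scale must be positive")
  round(c(height = 5333, width = 7110) * scale)
}

final_confidence <- function(boxes) {
  p <- boxes$p
  if (is.null(p)) p <- rep(NA_real_, nrow(boxes))
  p <- ifelse(is.na(p), boxes$p_det %||% NA_real_, p)
  ifelse(is.na(p), boxes$p_obj, p)
}

#' Match predictions to ground-truth centers
#'
#' Predictions with final confidence below `threshold` are discarded, then
#' prediction-truth pairs are matched greedily by ascending center distance;
#' a pair is valid only if the distance is at most `radius`. Each prediction
#' and each truth participates in at most one pair. Ties are broken by lower
#' prediction index, then lower truth index. In this detection setting there
#' are no true negatives, so `tn = 0`.
#'
#' @param preds Detection boxes (need `x`, `y` and a confidence).
#' @param truths Annotation data frame with `x`, `y`.
#' @param radius Matching radius in pixels (default 25, about one mitotic
#'   figure diameter at 0.25 um/px).
#' @param threshold Confidence cutoff (default 0: keep all).
#' @return `match_result` list: `tp`, `fp`, `fn`, `tn`, and `pairs`
#'   (data frame `pred`, `truth`, `distance`; indices refer to the retained
#'   prediction rows / truth rows).
#' @export
match_detections <- function(preds, truths, radius = 25, threshold = 0) {
  if (radius <= 0) param_error("radius must be positive")
  keep <- if (nrow(preds)) final_confidence(preds) >= threshold else logical(0)
  preds <- preds[keep, , drop = FALSE]
  np <- nrow(preds); nt <- nrow(truths)
  pairs <- data.frame(pred = integer(0), truth = integer(0),
                      distance = numeric(0))
  if (np > 0 && nt > 0) {
    dmat <- sqrt(outer(preds$x, truths$x, `-`)^2 +
                 outer(preds$y, truths$y, `-`)^2)
    cand <- which(dmat <= radius, arr.ind = TRUE)
    if (nrow(cand)) {
      dd <- dmat[cand]
      ord <- order(dd, cand[, 1], cand[, 2])
      used_p <- logical(np); used_t <- logical(nt)
      for (r in ord) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_p[i] || used_t[j]) next
        used_p[i] <- TRUE; used_t[j] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = i, truth = j,
                                         distance = dmat[i, j]))
      }
    }
  }
  structure(list(tp = nrow(pairs), fp = np - nrow(pairs),
                 fn = nt - nrow(pairs), tn = 0L, pairs = pairs),
            class = "match_result")
}

#' Confusion-count metrics
#'
#' Computes recall (sensitivity), precision, F1, accuracy and specificity
#' from TP/FP/FN/TN counts. Any metric whose denominator is zero is returned
#' as 0 and named in the `degenerate` flag vector.
#'
#' @param m A `match_result` or list with `tp`, `fp`, `fn`, `tn`.
#' @return List with the five metrics and `degenerate`, a character vector of
#'   flagged zero-denominator metrics.
#' @export
detection_metrics <- function(m) {
  counts <- c(m$tp, m$fp, m$fn, m$tn %||% 0)
  if (any(counts < 0) || any(counts != round(counts)))
    contract_error("TP/FP/FN/TN must be non-negative integers")
  tp <- m$tp; fp <- m$fp; fn <- m$fn; tn <- m$tn %||% 0
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); 0 } else num / den
  }
  recall <- safe(tp, tp + fn, "recall")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- safe(2 * recall * precision, recall + precision, "f1")
  accuracy <- safe(tp + tn, tp + tn + fp + fn, "accuracy")
  specificity <- safe(tn, tn + fp, "specificity")
  list(recall = recall, precision = precision, f1 = f1,
       accuracy = accuracy, specificity = specificity,
       degenerate = flagged)
}

#' Count points inside an HPF window
#'
#' Membership is half-open on both axes: a point at the window origin counts,
#' a point at `origin + size` does not.
#'
#' @param points Data frame with `x`, `y` (0-based pixel coordinates).
#' @param window List with `origin = c(row, col)`, `height`, `width`.
#' @return Integer count.
#' @export
count_in_window <- function(points, window) {
  if (nrow(points) == 0) return(0L)
  o <- window$origin
  sum(points$y >= o[1] & points$y < o[1] + window$height &
      points$x >= o[2] & points$x < o[2] + window$width)
}

# Candidate origins along one axis: the coarse stride grid, the edge-aligned
# extremes, and the point-aligned event origins floor(p - size) + 1 (the
# lowest integer origin whose half-open window still covers point p). The
# maximum of the coverage count over integer origins, and its smallest
# argmax, are always attained on this candidate set.
axis_candidates <- function(points, size, extent, stride) {
  last <- extent - size
  cand <- unique(c(seq.int(0L, last, by = max(1L, stride)), last,
                   clamp(floor(points - size) + 1, 0, last)))
  sort(cand)
}

#' Select the high-power field with the highest predicted count
#'
#' Searches integer window origins for the `height x width` rectangle
#' containing the most detections at or above the confidence threshold.
#' Candidates combine a coarse stride grid, the edge-aligned extremes, and
#' detection-aligned origins, which makes the search exact: the returned
#' window attains the true maximum over all integer origins, and ties are
#' broken by the smallest `(row, col)` origin.
#'
#' @param detections Detection boxes.
#' @param slide_dim `(H, W)` slide extents.
#' @param threshold Confidence cutoff (default 0).
#' @param stride Coarse grid stride in pixels (default 256).
#' @param window `c(height, width)` of the HPF rectangle; defaults to the
#'   standard [hpf_window_dim()]. Pass a scaled window for scaled-down
#'   slides.
#' @return `hpf_window` list: `origin` (0-based row, col), `height`,
#'   `width`, `count`, `threshold`.
#' @export
select_hpf <- function(detections, slide_dim, threshold = 0, stride = 256L,
                       window = hpf_window_dim()) {
  h <- window[1]; w <- window[2]
  if (slide_dim[1] < h || slide_dim[2] < w)
    size_error("slide is smaller than the HPF window; pass a scaled window")
  keep <- if (nrow(detections))
    final_confidence(detections) >= threshold else logical(0)
  pts <- detections[keep, c("x", "y"), drop = FALSE]
  rows <- axis_candidates(pts$y, h, slide_dim[1], stride)
  cols <- axis_candidates(pts$x, w, slide_dim[2], stride)
  best <- list(count = -1L, origin = c(row = 0L, col = 0L))
  for (or in rows) {
    iny <- pts$y >= or & pts$y < or + h
    if (sum(iny) <= best$count) next
    px <- pts$x[iny]
    for (oc in cols) {
      cnt <- sum(px >= oc & px < oc + w)
      if (cnt > best$count) {
        best$count <- cnt
        best$origin <- c(row = or, col = oc)
      }
    }
  }
  structure(list(origin = best$origin, height = h, width = w,
                 count = as.integer(best$count), threshold = threshold),
            class = "hpf_window")
}

#' Mitotic count in the selected HPF
#'
#' The HPF window is always selected from the predictions (the model proposes
#' the field). In fully automated mode (`GA`) the predicted count inside the
#' window is the mitotic count; in human-machine interactive mode (`GB`) the
#' count of ground-truth annotations inside the same window is used instead.
#'
#' @param detections Detection boxes.
#' @param truths Annotation data frame with `x`, `y`.
#' @param slide_dim `(H, W)` slide extents.
#' @param mode `"GA"` (automated) or `"GB"` (interactive).
#' @param threshold Confidence cutoff for predictions.
#' @param window,stride Passed to [select_hpf()].
#' @return List: `mode`, `count`, and the selected `window`.
#' @export
mitotic_count <- function(detections, truths, slide_dim,
                          mode = c("GA", "GB"), threshold = 0,
                          window = hpf_window_dim(), stride = 256L) {
  mode <- match.arg(mode)
  win <- select_hpf(detections, slide_dim, threshold, stride, window)
  count <- if (mode == "GA") win$count
           else count_in_window(truths, win)
  list(mode = mode, count = as.integer(count), window = win)
}

#' MAPE/MAE threshold sweep over per-slide mitotic counts
#'
#' Each slide's reference mitotic count is the annotation count inside the
#' HPF selected from the annotations themselves (the region a pathologist
#' would count). For every candidate threshold the per-slide GA or GB count
#' is computed from the predictions, then
#'   MAPE = mean(|pred - true| / true) * 100 and MAE = mean(|pred - true|).
#' Returns the report at the MAPE-minimising threshold (ties go to the lower
#' threshold). A zero reference count makes MAPE undefined and raises an
#' error naming the slide.
#'
#' @param slides List of per-slide fixtures, each
#'   `list(detections, truths, slide_dim[, window, stride])`.
#' @param thresholds Numeric vector of candidate confidence cutoffs.
#' @param mode `"GA"` or `"GB"`.
#' @param window,stride Defaults applied to slides that do not carry their
#'   own.
#' @return `count_report` list: `threshold`, `mape`, `mae`, `per_slide`
#'   (data frame with predicted and true counts at the chosen threshold) and
#'   `sweep` (MAPE/MAE per threshold).
#' @export
count_error_sweep <- function(slides, thresholds, mode = c("GA", "GB"),
                              window = hpf_window_dim(), stride = 256L) {
  mode <- match.arg(mode)
  if (!length(slides)) param_error("need at least one slide")
  thresholds <- sort(unique(thresholds))
  true_counts <- vapply(seq_along(slides), function(si) {
    s <- slides[[si]]
    truth_boxes <- data.frame(x = s$truths$x, y = s$truths$y,
                              p_obj = rep(1, nrow(s$truths)))
    win <- select_hpf(truth_boxes, s$slide_dim, threshold = 0,
                      stride = s$stride %||% stride,
                      window = s$window %||% window)
    tc <- count_in_window(s$truths, win)
    if (tc == 0)
      mito_error("mito_undefined_mape", sprintf(
        "slide %d has a zero true count in its reference HPF; MAPE undefined",
        si))
    tc
  }, numeric(1))
  eval_thr <- function(thr) {
    counts <- lapply(seq_along(slides), function(si) {
      s <- slides[[si]]
      mc <- mitotic_count(s$detections, s$truths, s$slide_dim, mode,
                          threshold = thr, window = s$window %||% window,
                          stride = s$stride %||% stride)
      data.frame(slide = si, predicted = mc$count, true = true_counts[si])
    })
    do.call(rbind, counts)
  }
  sweep <- lapply(thresholds, function(thr) {
    per <- eval_thr(thr)
    data.frame(threshold = thr,
               mape = mean(abs(per$predicted - per$true) / per$true) * 100,
               mae = mean(abs(per$predicted - per$true)))
  })
  sweep <- do.call(rbind, sweep)
  best <- which.min(sweep$mape)   # which.min takes the first (lowest) tie
  structure(list(threshold = sweep$threshold[best],
                 mape = sweep$mape[best], mae = sweep$mae[best],
                 per_slide = eval_thr(sweep$threshold[best]),
                 sweep = sweep, mode = mode),
            class = "count_report")
}
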