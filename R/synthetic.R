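# Synthetic histology-like data ------------------------------------------------
#
# Seeded generators producing eosin-textured tiles populated with dense round
# "nuclei" distractors and sparse elongated, irregular "mitotic figures",
# with exact annotations by construction. The scale convention is the
# package-wide nominal 0.25 um/px, so densities are stated per mm^2 and the
# 7110 x 5333-px HPF window is coherent with them. These fixtures provide the
# minimal morphology contrast (eccentric dark blobs vs round blobs) that a
# classical detector can learn in minutes; they do not attempt realistic
# stain or scanner statistics.

#' Synthetic slide configuration
#'
#' @param slide_dim `(H, W)` slide extents in pixels.
#' @param mpp Microns per pixel (default 0.25, the nominal scan resolution).
#' @param mitotic_density Expected mitotic figures per mm^2 (default 10,
#'   a high-grade-tumor-like rate).
#' @param distractor_density Expected non-mitotic nuclei per mm^2
#'   (default 4000, a dense-tumor nuclear density).
#' @param mitotic_size Range (px) of the mitotic figure major-axis length.
#' @param elongation Range of the major/minor axis ratio of mitotic figures.
#' @param distractor_radius Range (px) of nucleus radii.
#' @param hotspot Optional `list(center = c(row, col), radius, multiplier)`:
#'   within `radius` of `center` the mitotic density is multiplied.
#' @param min_separation Minimum center distance between mitotic figures
#'   (px); keeps annotations unambiguous for center-distance matching.
#' @param seed RNG seed; identical config + seed reproduce the slide
#'   bit-for-bit.
#' @return `synth_config` list.
#' @export
synth_config <- function(slide_dim = c(2000L, 2000L), mpp = 0.25,
                         mitotic_density = 10, distractor_density = 4000,
                         mitotic_size = c(20, 36), elongation = c(2.2, 3.5),
                         distractor_radius = c(6, 10), hotspot = NULL,
                         min_separation = 50, seed = 1L) {
  if (any(slide_dim < 32)) size_error("slide_dim extents must be >= 32")
  if (mitotic_density < 0 || distractor_density < 0)
    param_error("densities must be non-negative")
  structure(list(slide_dim = as.integer(slide_dim), mpp = mpp,
                 mitotic_density = mitotic_density,
                 distractor_density = distractor_density,
                 mitotic_size = mitotic_size, elongation = elongation,
                 distractor_radius = distractor_radius, hotspot = hotspot,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "synth_config")
}

# Soft-edged blob footprint on a local patch: 1-based row/col index vectors
# and a blend-weight matrix (edge softness ~1.2 px). The caller blends the
# patch into its channel matrices, which keeps subassignment in place.
blob_patch <- function(dims, row, col, a, b, theta, wobble = NULL) {
  R <- ceiling(a * 1.45) + 2
  r0 <- max(0, floor(row - R)); r1 <- min(dims[1] - 1, ceiling(row + R))
  c0 <- max(0, floor(col - R)); c1 <- min(dims[2] - 1, ceiling(col + R))
  if (r1 < r0 || c1 < c0) return(NULL)
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - row, nrow = length(rr), ncol = length(cc))
  dx <- matrix(cc - col, nrow = length(rr), ncol = length(cc), byrow = TRUE)
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  u <- sqrt((xr / a)^2 + (yr / b)^2)
  lim <- 1
  if (!is.null(wobble)) {
    phi <- atan2(yr, xr)
    lim <- 1 + wobble$a1 * sin(3 * phi + wobble$p1) +
               wobble$a2 * sin(5 * phi + wobble$p2)
  }
  list(rows = rr + 1L, cols = cc + 1L,
       wgt = clamp((lim - u) * a / 1.2, 0, 1))
}

blob_bbox <- function(a, b, theta, wobble_amp = 0) {
  s <- 1 + wobble_amp
  w <- 2 * sqrt((a * cos(theta))^2 + (b * sin(theta))^2) * s
  h <- 2 * sqrt((a * sin(theta))^2 + (b * cos(theta))^2) * s
  c(w = w, h = h)
}

# Draw n points uniformly on the slide (with an edge margin), enforcing a
# minimum pairwise separation from `existing` and among themselves.
place_separated <- function(n, slide_dim, min_sep, margin = 16,
                            existing = NULL, max_tries = 400L) {
  pts <- existing
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      p <- c(stats::runif(1, margin, slide_dim[1] - margin),
             stats::runif(1, margin, slide_dim[2] - margin))
      ok <- is.null(pts) || nrow(pts) == 0 ||
        all((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 >= min_sep^2)
      if (ok) { pts <- rbind(pts, p); out <- rbind(out, p); break }
      if (t == max_tries)
        size_error("could not place objects at the requested density/separation")
    }
  }
  out
}

in_disc <- function(n, center, radius) {
  t <- stats::runif(n, 0, 2 * pi)
  r <- radius * sqrt(stats::runif(n))
  cbind(center[1] + r * sin(t), center[2] + r * cos(t))
}

#' Generate a synthetic slide with exact annotations
#'
#' Renders a textured background, Poisson-distributed round nuclei
#' distractors, and sparse elongated mitotic figures (optionally concentrated
#' in a hotspot). Every mitotic figure yields exactly one annotation record;
#' distractor centers are returned separately for crop sampling.
#'
#' @param cfg A [synth_config()].
#' @return List: `image` (`H x W x 3` in `[0, 1]`), `annotations` (data frame
#'   `slide_id`, `x`, `y`, `w`, `h`, `label`), `distractors` (data frame
#'   `x`, `y`), `config`.
#' @export
generate_slide <- function(cfg) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  d <- cfg$slide_dim
  area_mm2 <- prod(d) * (cfg$mpp / 1000)^2
  with_seed(cfg$seed, {
    # background: eosin-pink base + smooth texture field + fine grain
    base <- c(0.91, 0.80, 0.87)
    tex <- EBImage::gblur(matrix(stats::rnorm(prod(d)), d[1], d[2]),
                          sigma = max(4, min(d) / 60))
    tex <- tex / max(abs(range(tex)), 1e-8) * 0.035
    grain <- matrix(stats::rnorm(prod(d), sd = 0.008), d[1], d[2])
    ch1 <- base[1] + tex + grain
    ch2 <- base[2] + tex + grain
    ch3 <- base[3] + tex + grain
    # nuclei distractors
    n_dis <- stats::rpois(1, cfg$distractor_density * area_mm2)
    dis <- if (n_dis > 0)
      cbind(stats::runif(n_dis, 4, d[1] - 4), stats::runif(n_dis, 4, d[2] - 4))
    else matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_dis)) {
      r <- stats::runif(1, cfg$distractor_radius[1], cfg$distractor_radius[2])
      shade <- stats::runif(1, -0.05, 0.05)
      col3 <- clamp(c(0.46, 0.32, 0.62) + shade, 0, 1)
      p <- blob_patch(d, dis[i, 1], dis[i, 2],
                      a = r * stats::runif(1, 0.9, 1.1), b = r,
                      theta = stats::runif(1, 0, pi))
      if (!is.null(p)) {
        w <- p$wgt
        ch1[p$rows, p$cols] <- ch1[p$rows, p$cols] * (1 - w) + col3[1] * w
        ch2[p$rows, p$cols] <- ch2[p$rows, p$cols] * (1 - w) + col3[2] * w
        ch3[p$rows, p$cols] <- ch3[p$rows, p$cols] * (1 - w) + col3[3] * w
      }
    }

    # mitotic figures: baseline field + optional hotspot surplus
    n_base <- stats::rpois(1, cfg$mitotic_density * area_mm2)
    mito <- place_separated(n_base, d, cfg$min_separation)
    if (!is.null(cfg$hotspot)) {
      hs <- cfg$hotspot
      hs_area <- pi * hs$radius^2 * (cfg$mpp / 1000)^2
      n_hot <- stats::rpois(1, cfg$mitotic_density * (hs$multiplier - 1) * hs_area)
      for (i in seq_len(n_hot)) {
        for (t in 1:400) {
          p <- in_disc(1, hs$center, hs$radius)
          inb <- p[1] > 16 && p[1] < d[1] - 16 && p[2] > 16 && p[2] < d[2] - 16
          ok <- inb && (nrow(mito) == 0 ||
            all((mito[, 1] - p[1])^2 + (mito[, 2] - p[2])^2 >=
                  cfg$min_separation^2))
          if (ok) { mito <- rbind(mito, p); break }
        }
      }
    }
    ann <- data.frame(slide_id = character(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), label = character(0))
    for (i in seq_len(nrow(mito))) {
      len <- stats::runif(1, cfg$mitotic_size[1], cfg$mitotic_size[2])
      rho <- stats::runif(1, cfg$elongation[1], cfg$elongation[2])
      a <- len / 2; b <- a / rho
      theta <- stats::runif(1, 0, pi)
      wob <- list(a1 = stats::runif(1, 0.06, 0.14),
                  p1 = stats::runif(1, 0, 2 * pi),
                  a2 = stats::runif(1, 0.04, 0.10),
                  p2 = stats::runif(1, 0, 2 * pi))
      shade <- stats::runif(1, -0.04, 0.04)
      col3 <- clamp(c(0.17, 0.09, 0.26) + shade, 0, 1)
      p <- blob_patch(d, mito[i, 1], mito[i, 2], a, b, theta, wob)
      if (!is.null(p)) {
        w <- p$wgt
        ch1[p$rows, p$cols] <- ch1[p$rows, p$cols] * (1 - w) + col3[1] * w
        ch2[p$rows, p$cols] <- ch2[p$rows, p$cols] * (1 - w) + col3[2] * w
        ch3[p$rows, p$cols] <- ch3[p$rows, p$cols] * (1 - w) + col3[3] * w
      }
      bb <- blob_bbox(a, b, theta, wob$a1 + wob$a2)
      ann <- rbind(ann, data.frame(
        slide_id = "synthetic", x = mito[i, 2], y = mito[i, 1],
        w = bb["w"], h = bb["h"], label = "mitosis"))
    }
    rownames(ann) <- NULL
    img <- array(0, dim = c(d, 3L))
    img[, , 1] <- ch1; img[, , 2] <- ch2; img[, , 3] <- ch3
    img <- clamp(img, 0, 1)
    list(image = img,
         annotations = ann,
         distractors = data.frame(x = dis[, 2], y = dis[, 1]),
         config = cfg)
  })
}

#' Generate labelled classification crops
#'
#' Produces `n_pos` crops centered on mitotic figures and `n_neg` negative
#' crops (half centered on nuclei distractors, half on clear background),
#' sampled from as many seeded synthetic slides as needed.
#'
#' @param cfg A [synth_config()] describing the source slides.
#' @param n_pos,n_neg Crop counts.
#' @param seed RNG seed (independent of `cfg$seed`).
#' @param crop Crop side length (default 128).
#' @return List with `crops` (list of `crop x crop x 3` arrays), `labels`
#'   (character, `"mitosis"`/`"negative"`), and `meta` (source data frame).
#' @export
generate_crop_set <- function(cfg, n_pos, n_neg, seed = 1L, crop = 128L) {
  if (n_pos < 0 || n_neg < 0) param_error("crop counts must be >= 0")
  crops <- list(); labels <- character(0)
  meta <- data.frame(slide_seed = integer(0), x = numeric(0), y = numeric(0),
                     source = character(0))
  want_dis <- ceiling(n_neg / 2); want_bg <- n_neg - want_dis
  got_pos <- 0; got_dis <- 0; got_bg <- 0
  round_i <- 0L
  while ((got_pos < n_pos || got_dis < want_dis || got_bg < want_bg) &&
         round_i < 50L) {
    round_i <- round_i + 1L
    scfg <- cfg
    scfg$seed <- derive_seed(seed, round_i)
    sl <- generate_slide(scfg)
    d <- dim(sl$image)
    take_crop <- function(y, x) {
      region <- center_adjust(list(x = x, y = y), d[1:2], crop)
      crop_pixels(sl$image, region)
    }
    ann <- sl$annotations
    for (i in seq_len(nrow(ann))) {
      if (got_pos >= n_pos) break
      crops[[length(crops) + 1L]] <- take_crop(ann$y[i], ann$x[i])
      labels <- c(labels, "mitosis")
      meta <- rbind(meta, data.frame(slide_seed = scfg$seed, x = ann$x[i],
                                     y = ann$y[i], source = "mitosis"))
      got_pos <- got_pos + 1
    }
    dis <- sl$distractors
    dis_pick <- with_seed(derive_seed(seed, 1000L + round_i),
                          sample(seq_len(nrow(dis))))
    for (i in dis_pick) {
      if (got_dis >= want_dis) break
      near_mito <- nrow(ann) > 0 &&
        any((ann$x - dis$x[i])^2 + (ann$y - dis$y[i])^2 < 32^2)
      if (near_mito) next
      crops[[length(crops) + 1L]] <- take_crop(dis$y[i], dis$x[i])
      labels <- c(labels, "negative")
      meta <- rbind(meta, data.frame(slide_seed = scfg$seed, x = dis$x[i],
                                     y = dis$y[i], source = "distractor"))
      got_dis <- got_dis + 1
    }
    bg <- with_seed(derive_seed(seed, 2000L + round_i), {
      n <- max(0, want_bg - got_bg)
      cbind(stats::runif(n, 8, d[1] - 8), stats::runif(n, 8, d[2] - 8))
    })
    for (i in seq_len(nrow(bg))) {
      if (got_bg >= want_bg) break
      near_mito <- nrow(ann) > 0 &&
        any((ann$x - bg[i, 2])^2 + (ann$y - bg[i, 1])^2 < 48^2)
      if (near_mito) next
      crops[[length(crops) + 1L]] <- take_crop(bg[i, 1], bg[i, 2])
      labels <- c(labels, "negative")
      meta <- rbind(meta, data.frame(slide_seed = scfg$seed, x = bg[i, 2],
                                     y = bg[i, 1], source = "background"))
      got_bg <- got_bg + 1
    }
  }
  if (got_pos < n_pos || got_dis < want_dis || got_bg < want_bg)
    size_error("could not collect the requested crop counts; raise densities or slide size")
  list(crops = crops, labels = labels, meta = meta)
}

#' Generate an evaluation fixture with known matching outcome
#'
#' Places `n_true` ground-truth centers uniformly with pairwise separation
#' greater than twice the matching radius, then derives detections by
#' dropping each truth independently with probability `miss_rate`, jittering
#' surviving centers with isotropic Gaussian noise, and adding a
#' Poisson-distributed number of false positives placed far from every truth.
#' Because separations exceed `2 * radius` and false positives stay out of
#' matching range, the expected match result is exact whenever the jitter
#' stays below the radius.
#'
#' @param slide_dim `(H, W)` extents.
#' @param n_true Number of ground-truth objects.
#' @param miss_rate Per-truth Bernoulli miss probability.
#' @param false_rate Poisson mean of the false-positive count.
#' @param jitter_sd Gaussian center jitter (px, per axis).
#' @param radius Matching radius the fixture is designed for (default 25).
#' @param seed RNG seed.
#' @return List: `truths`, `detections` (detection-box data frame with
#'   `p_det` set), and `expected = list(tp, fp, fn)`.
#' @export
generate_detection_fixture <- function(slide_dim, n_true, miss_rate = 0,
                                       false_rate = 0, jitter_sd = 0,
                                       radius = 25, seed = 1L) {
  if (miss_rate < 0 || miss_rate > 1) param_error("miss_rate must be in [0, 1]")
  if (false_rate < 0) param_error("false_rate must be >= 0")
  with_seed(seed, {
    pts <- place_separated(n_true, slide_dim, min_sep = 2 * radius + 10,
                           margin = radius + 5)
    truths <- data.frame(slide_id = "fixture",
                         x = pts[, 2], y = pts[, 1],
                         w = 20, h = 20, label = "mitosis")
    kept <- stats::runif(n_true) >= miss_rate
    det <- truths[kept, c("x", "y", "w", "h"), drop = FALSE]
    if (nrow(det)) {
      det$x <- det$x + stats::rnorm(nrow(det), sd = jitter_sd)
      det$y <- det$y + stats::rnorm(nrow(det), sd = jitter_sd)
      det$p_obj <- stats::runif(nrow(det), 0.55, 1)
    } else det$p_obj <- numeric(0)
    n_fp <- stats::rpois(1, false_rate)
    if (n_fp > 0) {
      fp_pts <- place_separated(n_fp, slide_dim,
                                min_sep = 2 * radius + 10,
                                margin = radius + 5, existing = pts)
      fp <- data.frame(x = fp_pts[, 2], y = fp_pts[, 1], w = 20, h = 20,
                       p_obj = stats::runif(n_fp, 0.05, 0.9))
      det <- rbind(det, fp)
    }
    det <- as_detection_boxes(det)
    det$p_det <- det$p_obj
    rownames(det) <- NULL
    list(truths = truths, detections = det,
         expected = list(tp = sum(kept), fp = n_fp, fn = sum(!kept)))
  })
}
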