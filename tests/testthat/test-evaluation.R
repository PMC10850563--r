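# Evaluation: matching, metrics, HPF selection, counting, MAPE/MAE sweep

test_that("center-distance matching follows the greedy-by-distance rule", {
  t1 <- data.frame(x = 100, y = 100)
  p1 <- data.frame(x = 100, y = 100, p_obj = 0.9)
  m <- match_detections(p1, t1, radius = 25)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  # two predictions near one truth: the closer wins, the other is a FP
  p2 <- data.frame(x = c(103, 101), y = c(100, 100), p_obj = c(0.9, 0.2))
  m2 <- match_detections(p2, t1, radius = 25)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  expect_equal(m2$pairs$pred, 2)
  # threshold discards low-confidence predictions before matching
  m3 <- match_detections(p2, t1, radius = 25, threshold = 0.5)
  expect_equal(c(m3$tp, m3$fp), c(1, 0))
})

test_that("matching equals the sorted-pair oracle and conserves counts", {
  for (seed in 1:12) {
    n_p <- sample.int(12, 1)
    n_t <- sample.int(12, 1)
    preds <- withr::with_seed(seed, data.frame(
      x = runif(n_p, 0, 200), y = runif(n_p, 0, 200), p_obj = runif(n_p)))
    truths <- withr::with_seed(seed + 100, data.frame(
      x = runif(n_t, 0, 200), y = runif(n_t, 0, 200)))
    m <- match_detections(preds, truths, radius = 40)
    o <- oracle_match(preds, truths, radius = 40)
    expect_equal(c(m$tp, m$fp, m$fn), c(o$tp, o$fp, o$fn),
                 info = paste("seed", seed))
    expect_equal(m$tp + m$fp, nrow(preds))
    expect_equal(m$tp + m$fn, nrow(truths))
    # raising the threshold never increases TP or FP
    prev <- match_detections(preds, truths, 40, 0)
    for (thr in c(0.25, 0.5, 0.75, 1)) {
      cur <- match_detections(preds, truths, 40, thr)
      expect_lte(cur$tp, prev$tp)
      expect_lte(cur$fp, prev$fp)
      prev <- cur
    }
  }
})

test_that("metric formulas match their definitions", {
  m <- detection_metrics(list(tp = 5, fp = 5, fn = 5, tn = 0))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  # an operating point in the realistic working range
  m2 <- detection_metrics(list(tp = 832, fp = 174, fn = 168, tn = 0))
  expect_equal(m2$recall, 0.832, tolerance = 1e-12)
  expect_equal(m2$precision, 832 / 1006, tolerance = 1e-12)
  expect_equal(m2$f1, 2 * m2$recall * m2$precision / (m2$recall + m2$precision),
               tolerance = 1e-12)
  # degenerate zero counts come back flagged
  z <- detection_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_equal(unlist(z[c("recall", "precision", "f1", "accuracy",
                          "specificity")], use.names = FALSE),
               rep(0, 5))
  expect_setequal(z$degenerate,
                  c("recall", "precision", "f1", "accuracy", "specificity"))
  expect_error(detection_metrics(list(tp = -1, fp = 0, fn = 0, tn = 0)),
               class = "mito_contract_error")
  # formulas on random non-degenerate tuples
  for (seed in 1:50) {
    cnt <- withr::with_seed(seed, as.list(sample.int(500, 4)))
    names(cnt) <- c("tp", "fp", "fn", "tn")
    mm <- detection_metrics(cnt)
    expect_equal(mm$recall, cnt$tp / (cnt$tp + cnt$fn), tolerance = 1e-12)
    expect_equal(mm$precision, cnt$tp / (cnt$tp + cnt$fp), tolerance = 1e-12)
    expect_equal(mm$f1, 2 * mm$recall * mm$precision /
                   (mm$recall + mm$precision), tolerance = 1e-12)
    expect_equal(mm$accuracy, (cnt$tp + cnt$tn) /
                   (cnt$tp + cnt$tn + cnt$fp + cnt$fn), tolerance = 1e-12)
    expect_equal(mm$specificity, cnt$tn / (cnt$tn + cnt$fp), tolerance = 1e-12)
  }
})

test_that("window membership is half-open at both edges", {
  win <- list(origin = c(100, 200), height = 50, width = 80)
  expect_equal(count_in_window(data.frame(x = 200, y = 100), win), 1)
  expect_equal(count_in_window(data.frame(x = 280, y = 100), win), 0)
  expect_equal(count_in_window(data.frame(x = 279.99, y = 149.99), win), 1)
  pts <- withr::with_seed(3, data.frame(x = runif(300, 0, 400),
                                        y = runif(300, 0, 300)))
  loop <- sum(vapply(seq_len(300), function(i)
    pts$y[i] >= 100 && pts$y[i] < 150 && pts$x[i] >= 200 && pts$x[i] < 280,
    logical(1)))
  expect_equal(count_in_window(pts, win), loop)
})

test_that("HPF selection is exact against exhaustive stride-1 search", {
  window <- c(150, 200)
  for (seed in 1:12) {
    dims <- c(400, 500)
    n <- withr::with_seed(seed, rpois(1, 25))
    det <- withr::with_seed(seed + 7, data.frame(
      x = runif(n, 0, dims[2] - 1), y = runif(n, 0, dims[1] - 1),
      p_obj = runif(n)))
    got <- select_hpf(det, dims, threshold = 0.3, stride = 256,
                      window = window)
    want <- oracle_select_hpf(det[det$p_obj >= 0.3, ], dims, window)
    expect_equal(got$count, want$count, info = paste("seed", seed))
    expect_equal(unname(got$origin), want$origin, info = paste("seed", seed))
  }
  # degenerate cases: clustered corner and empty input
  corner <- data.frame(x = c(450, 470, 480), y = c(350, 380, 390),
                       p_obj = 1)
  sel <- select_hpf(corner, c(400, 500), window = window)
  expect_equal(sel$count, 3)
  none <- select_hpf(as_detection_boxes(NULL), c(400, 500), window = window)
  expect_equal(unname(none$origin), c(0, 0))
  expect_equal(none$count, 0)
  expect_error(select_hpf(corner, c(400, 500)), class = "mito_size_error")
})

test_that("GA and GB counting follow their definitions", {
  dims <- c(600, 800)
  window <- c(150, 200)
  truths <- data.frame(x = c(100, 120, 140, 700), y = c(100, 110, 120, 500))
  perfect <- data.frame(x = truths$x, y = truths$y, p_obj = 0.9)
  ga <- mitotic_count(perfect, truths, dims, "GA", window = window)
  gb <- mitotic_count(perfect, truths, dims, "GB", window = window)
  expect_equal(ga$count, gb$count)
  # empty predictions: GA 0, GB counts truths in the (0, 0) tie-break window
  ga0 <- mitotic_count(as_detection_boxes(NULL), truths, dims, "GA",
                       window = window)
  gb0 <- mitotic_count(as_detection_boxes(NULL), truths, dims, "GB",
                       window = window)
  expect_equal(ga0$count, 0)
  expect_equal(unname(gb0$window$origin), c(0, 0))
  expect_equal(gb0$count, 3)
  # diverging predictions: GB reads the truth in the predicted window
  off <- data.frame(x = c(700, 710), y = c(480, 500), p_obj = 0.9)
  gb2 <- mitotic_count(off, truths, dims, "GB", window = window)
  expect_equal(gb2$count, 1)
})

test_that("MAPE/MAE sweep picks the lowest-MAPE threshold", {
  dims <- c(600, 800); window <- c(150, 200)
  mk_slide <- function(seed, extra_fp_conf = NULL) {
    truths <- withr::with_seed(seed, data.frame(
      x = runif(12, 50, 250), y = runif(12, 40, 140)))
    det <- data.frame(x = truths$x, y = truths$y, p_obj = 0.9)
    if (!is.null(extra_fp_conf))
      det <- rbind(det, data.frame(x = 60 + seq_along(extra_fp_conf) * 10,
                                   y = 60, p_obj = extra_fp_conf))
    list(detections = as_detection_boxes(cbind(det, w = 10, h = 10)),
         truths = truths, slide_dim = dims, window = window)
  }
  # perfect detections at every threshold: zero errors, lowest threshold
  r <- count_error_sweep(list(mk_slide(1), mk_slide(2)),
                         thresholds = c(0.2, 0.5, 0.8), mode = "GA")
  expect_equal(r$mape, 0)
  expect_equal(r$mae, 0)
  expect_equal(r$threshold, 0.2)
  # single slide, one spurious low-confidence detection: pred 13 vs true 12
  # below 0.5, exact above
  r2 <- count_error_sweep(list(mk_slide(3, extra_fp_conf = 0.4)),
                          thresholds = c(0.2, 0.6), mode = "GA")
  expect_equal(r2$threshold, 0.6)
  expect_equal(r2$mape, 0)
  sw <- r2$sweep
  expect_equal(sw$mape[sw$threshold == 0.2], 100 / 12, tolerance = 1e-12)
  expect_equal(sw$mae[sw$threshold == 0.2], 1)
  # GB mode reads truth counts in the predicted window
  r3 <- count_error_sweep(list(mk_slide(4, extra_fp_conf = 0.4)),
                          thresholds = c(0.2), mode = "GB")
  expect_equal(r3$mape, 0)
  # zero true count in the reference HPF raises
  empty <- list(detections = mk_slide(5)$detections,
                truths = data.frame(x = numeric(0), y = numeric(0)),
                slide_dim = dims, window = window)
  expect_error(count_error_sweep(list(empty), thresholds = 0.5),
               class = "mito_undefined_mape")
})

test_that("sweep equals an independent per-threshold recomputation", {
  dims <- c(600, 800); window <- c(150, 200)
  slides <- lapply(1:3, function(seed) {
    fx <- generate_detection_fixture(dims, n_true = 10, miss_rate = 0.2,
                                     false_rate = 4, jitter_sd = 2,
                                     radius = 25, seed = seed)
    list(detections = fx$detections, truths = fx$truths, slide_dim = dims,
         window = window)
  })
  thrs <- c(0.1, 0.4, 0.7)
  r <- count_error_sweep(slides, thrs, mode = "GA")
  for (ti in seq_along(thrs)) {
    errs <- vapply(slides, function(s) {
      pw <- select_hpf(s$detections, dims, thrs[ti], 256, window)
      tw <- select_hpf(data.frame(x = s$truths$x, y = s$truths$y, p_obj = 1),
                       dims, 0, 256, window)
      abs(pw$count - count_in_window(s$truths, tw))
    }, numeric(1))
    tru <- vapply(slides, function(s) {
      tw <- select_hpf(data.frame(x = s$truths$x, y = s$truths$y, p_obj = 1),
                       dims, 0, 256, window)
      count_in_window(s$truths, tw)
    }, numeric(1))
    expect_equal(r$sweep$mape[ti], mean(errs / tru) * 100, tolerance = 1e-12)
    expect_equal(r$sweep$mae[ti], mean(errs), tolerance = 1e-12)
  }
  expect_equal(r$threshold, r$sweep$threshold[which.min(r$sweep$mape)])
})
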