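# End-to-end pipeline -----------------------------------------------------------
#
# detect -> classify -> evaluate on one slide, with deterministic outputs,
# per-stage timings and a config hash so runs are auditable.

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        null = "null")
  # small rolling hash; stable across sessions, no extra dependency
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full detection / classification / evaluation pipeline
#'
#' If no slide is supplied, a synthetic slide is generated from the
#' `simulate` config block under the given seed. If no backends are
#' supplied, the reference detector and classifier are trained on separate
#' seeded synthetic data. Detection JSON and the report are written to
#' `out_dir` when given; writers are deterministic, so identical
#' config + seed produce byte-identical files.
#'
#' @param config Partial configuration (merged over [default_config()]).
#' @param seed Global seed for simulation and backend training.
#' @param out_dir Optional output directory.
#' @param slide Optional `H x W x 3` slide image (else simulated).
#' @param truths Optional annotation data frame (else from simulation).
#' @param detector,classifier Optional backends (else reference backends).
#' @param threshold Confidence cutoff used for the detection metrics
#'   (default 0.5).
#' @return Report list: `detections` (scored boxes), `match`, `metrics`,
#'   `hpf`, `count_ga`, `count_gb`, `timings` (seconds per stage),
#'   `config_hash`, `flags`.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL,
                         slide = NULL, truths = NULL,
                         detector = NULL, classifier = NULL,
                         threshold = 0.5) {
  config <- validate_config(config)
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) mito_error(
      class(e)[1], sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e))))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  if (is.null(slide)) {
    sim <- tick("simulate", {
      sc <- config$simulate
      generate_slide(synth_config(
        slide_dim = sc$slide_dim, mpp = sc$mpp,
        mitotic_density = sc$mitotic_density,
        distractor_density = sc$distractor_density,
        hotspot = sc$hotspot, seed = derive_seed(seed, 0L)))
    })
    slide <- sim$image
    if (is.null(truths)) truths <- sim$annotations
  }
  if (is.null(truths)) param_error("truths are required when a slide is supplied")

  train_cfg <- synth_config(
    slide_dim = config$simulate$slide_dim, mpp = config$simulate$mpp,
    mitotic_density = max(config$simulate$mitotic_density, 60),
    distractor_density = config$simulate$distractor_density,
    seed = derive_seed(seed, 100L))
  if (is.null(detector))
    detector <- tick("train_detector",
                     train_reference_detector(train_cfg,
                                              seed = derive_seed(seed, 101L)))
  if (is.null(classifier))
    classifier <- tick("train_classifier",
                       train_reference_classifier(train_cfg,
                                                  seed = derive_seed(seed, 102L)))

  boxes <- tick("detect", run_detection(slide, detector, config$detect))
  boxes <- tick("classify",
                run_classification(boxes, slide, classifier,
                                   omega = config$classify$omega,
                                   crop = config$classify$crop))

  d <- dim(slide)
  ev <- config$evaluate
  window <- hpf_window_dim(ev$hpf_scale)
  flags <- character(0)
  if (ev$hpf_scale != 1)
    flags <- c(flags, sprintf("non-standard HPF window (scale %g)",
                              ev$hpf_scale))
  report <- tick("evaluate", {
    m <- match_detections(boxes, truths, radius = ev$radius,
                          threshold = threshold)
    met <- detection_metrics(m)
    hpf <- if (d[1] >= window[1] && d[2] >= window[2])
      select_hpf(boxes, d[1:2], threshold, ev$stride, window) else NULL
    counts <- if (!is.null(hpf)) list(
      ga = mitotic_count(boxes, truths, d[1:2], "GA", threshold,
                         window, ev$stride)$count,
      gb = mitotic_count(boxes, truths, d[1:2], "GB", threshold,
                         window, ev$stride)$count
    ) else {
      flags <- c(flags, "slide smaller than HPF window; counts skipped")
      list(ga = NA_integer_, gb = NA_integer_)
    }
    list(match = m, metrics = met, hpf = hpf, counts = counts)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_detections(boxes, file.path(out_dir, "detections.json"))
    summary <- list(
      schema_version = SCHEMA_VERSION,
      config_hash = config_hash(config),
      threshold = threshold,
      metrics = report$metrics[c("recall", "precision", "f1")],
      count_ga = report$counts$ga, count_gb = report$counts$gb,
      n_detections = nrow(boxes), n_truths = nrow(truths),
      flags = flags, timings = as.list(timings))
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }

  list(detections = boxes, truths = truths, match = report$match,
       metrics = report$metrics, hpf = report$hpf,
       count_ga = report$counts$ga, count_gb = report$counts$gb,
       threshold = threshold, timings = timings,
       config_hash = config_hash(config), flags = flags)
}
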