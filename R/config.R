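# Run configuration ------------------------------------------------------------

#' Default run configuration
#'
#' The fully-defaulted configuration is valid as-is. Blocks:
#' * `dicoa`: attention operator (`k = 3`, `delta = 1`, 256 projection
#'   channels, channel normalisation, no logit scaling, fusion weight
#'   `alpha = 0.5`).
#' * `detect`: 512-px tiles with 64-px overlap, 32-px relocation margin,
#'   25-px relocation match radius, NMS IoU 0.3, score floor 0.05.
#' * `classify`: 128-px crops, fusion weight `omega = 0.5`, reference
#'   backend.
#' * `evaluate`: 25-px matching radius, standard HPF window at scale 1,
#'   256-px HPF search stride, threshold sweep grid.
#' * `simulate`: synthetic-slide defaults (see [synth_config()]).
#'
#' @return Nested configuration list, schema-versioned.
#' @export
default_config <- function() {
  list(
    schema_version = SCHEMA_VERSION,
    dicoa = list(k = 3L, delta = 1L, channels = 256L, norm = "channel",
                 scale_qk = FALSE, alpha = 0.5),
    detect = list(tile = 512L, overlap = 64L, margin = 32L,
                  match_radius = 25, alpha = 0.5, nms_iou = 0.3,
                  score_floor = 0.05),
    classify = list(crop = 128L, omega = 0.5, backend = "reference"),
    evaluate = list(radius = 25, hpf_scale = 1, stride = 256L,
                    thresholds = seq(0.05, 0.95, by = 0.05)),
    simulate = list(slide_dim = c(2000L, 2000L), mpp = 0.25,
                    mitotic_density = 10, distractor_density = 4000,
                    hotspot = NULL, seed = 1L)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      schema_error(sprintf("unknown config key: %s", here))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        schema_error(sprintf("config key %s must be a block", here))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a configuration against the schema
#'
#' Unknown keys are rejected with a schema error naming the offending key;
#' values present in `config` override the defaults.
#'
#' @param config Nested list (possibly partial).
#' @return The fully-merged configuration.
#' @export
validate_config <- function(config = list()) {
  if (!is.list(config)) schema_error("config must be a list")
  merge_config(default_config(), config)
}

#' Load a YAML configuration file
#'
#' @param path YAML file; missing blocks fall back to [default_config()].
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("no such file: %s", path))
  validate_config(yaml::read_yaml(path) %||% list())
}
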