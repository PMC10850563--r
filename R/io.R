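# File formats -----------------------------------------------------------------
#
# JSON is the canonical interchange (schema-versioned, sorted keys, fixed
# float formatting so writers are byte-deterministic); CSV is offered for
# spreadsheet use. Coordinates in files follow the internal convention:
# 0-based pixel centers, x = column, y = row.

ANNOTATION_COLS <- c("slide_id", "x", "y", "w", "h", "label")
SCHEMA_VERSION <- "1.0"

validate_annotations <- function(df, where = "annotations") {
  need <- c("slide_id", "x", "y", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    schema_error(sprintf("%s missing columns: %s", where,
                         paste(miss, collapse = ", ")))
  if (is.null(df$w)) df$w <- NA_real_
  if (is.null(df$h)) df$h <- NA_real_
  for (col in c("x", "y", "w", "h"))
    df[[col]] <- as.numeric(df[[col]])
  bad <- which(!is.na(df$w) & df$w <= 0 | !is.na(df$h) & df$h <= 0)
  if (length(bad))
    schema_error(sprintf("%s record %d has non-positive box extent",
                         where, bad[1]))
  bad <- which(is.na(df$x) | is.na(df$y))
  if (length(bad))
    schema_error(sprintf("%s record %d has missing coordinates", where, bad[1]))
  df[, ANNOTATION_COLS]
}

#' Read an annotation set
#'
#' Accepts CSV (columns `slide_id`, `x`, `y`, optional `w`, `h`, `label`) or
#' the package's JSON annotation schema. Coordinates are validated and
#' normalised to the internal 0-based center convention.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return Annotation data frame.
#' @export
read_annotations <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) schema_error(sprintf("no such file: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    obj <- tryCatch(jsonlite::fromJSON(path),
                    error = function(e) schema_error(
                      sprintf("malformed JSON in %s: %s", path,
                              conditionMessage(e))))
    recs <- if (!is.null(obj$annotations)) obj$annotations else obj
    df <- as.data.frame(recs, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0)
    return(stats::setNames(as.data.frame(
      c(list(character(0)), rep(list(numeric(0)), 4), list(character(0)))),
      ANNOTATION_COLS))
  validate_annotations(df, where = path)
}

#' Write an annotation set
#'
#' @param annotations Annotation data frame.
#' @param path Destination; `.json` writes the schema-versioned JSON dialect,
#'   anything else CSV.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(schema_version = SCHEMA_VERSION,
                annotations = annotations)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(annotations, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an RGB image
#'
#' PNG and TIFF are supported; grayscale images are expanded to RGB and an
#' alpha channel is discarded. Values are returned in `[0, 1]`.
#'
#' @param path File path.
#' @return `H x W x 3` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("no such file: %s", path))
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    mito_error("mito_format_error",
               sprintf("unsupported image format: %s", path))
  }
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3)
    mito_error("mito_format_error", "image must have 1, 3 or 4 channels")
  img
}

#' Write an RGB image
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Destination `.png` or `.tif(f)`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- clamp(image, 0, 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(image, path)
  } else {
    mito_error("mito_format_error",
               sprintf("unsupported image format: %s", path))
  }
  invisible(path)
}

#' Read a rectangular region of an image
#'
#' Region semantics: the request `(origin, size)` returns exactly that
#' window. The current implementation decodes the full image and crops
#' (desk-scale slides); the interface is the stable part.
#'
#' @param path Image path.
#' @param origin 0-based `(row, col)` of the region's top-left pixel.
#' @param size `(height, width)` of the region.
#' @return `height x width x 3` array.
#' @export
read_image_region <- function(path, origin, size) {
  img <- read_image(path)
  d <- dim(img)
  if (any(origin < 0) || origin[1] + size[1] > d[1] ||
      origin[2] + size[2] > d[2])
    size_error("requested region exceeds image bounds")
  img[origin[1] + seq_len(size[1]), origin[2] + seq_len(size[2]), ,
      drop = FALSE]
}

format_num <- function(x) {
  # fixed 6-decimal formatting keeps writers byte-deterministic
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- as.numeric(sprintf("%.6f", x[ok]))
  out
}

#' Write detections to the canonical JSON schema
#'
#' Records are sorted by `(y, x)` and floats fixed to 6 decimals, so the
#' writer is byte-deterministic for identical inputs.
#'
#' @param boxes Detection-box data frame.
#' @param path Destination `.json` (or `.csv` for the spreadsheet dialect).
#' @param slide_id Identifier stored in the file.
#' @return `path`, invisibly.
#' @export
write_detections <- function(boxes, path, slide_id = "slide") {
  boxes <- as_detection_boxes(boxes)
  boxes <- boxes[order(boxes$y, boxes$x), DETECTION_COLS, drop = FALSE]
  for (col in DETECTION_COLS) boxes[[col]] <- format_num(boxes[[col]])
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(cbind(slide_id = slide_id, boxes), path,
                     row.names = FALSE)
  } else {
    obj <- list(schema_version = SCHEMA_VERSION, slide_id = slide_id,
                detections = boxes)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read detections written by [write_detections()]
#'
#' @param path Source `.json` or `.csv`.
#' @return Detection-box data frame (attribute `slide_id` attached for the
#'   JSON dialect).
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("no such file: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$slide_id <- NULL
    return(as_detection_boxes(df))
  }
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) schema_error(
                    sprintf("malformed JSON in %s: %s", path,
                            conditionMessage(e))))
  if (is.null(obj$detections))
    schema_error(sprintf("%s has no 'detections' field", path))
  det <- as.data.frame(obj$detections, stringsAsFactors = FALSE)
  if (nrow(det)) det[] <- lapply(det, function(v) {
    v[vapply(v, is.null, logical(1))] <- NA
    as.numeric(unlist(v))
  })
  out <- as_detection_boxes(det)
  attr(out, "slide_id") <- obj$slide_id
  out
}
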