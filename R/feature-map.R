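# Feature-map semantics --------------------------------------------------------
#
# A feature map is a plain numeric array with dim = c(C, H, W): channel-first,
# matching the tensor layout detection backbones use. All spatial coordinates
# in this package are 0-based (row, col); conversion to R's 1-based array
# indices happens at the point of subsetting.

#' Validate a channel-first feature map
#'
#' Checks that `x` is a finite numeric array of dimension `C x H x W` with all
#' extents at least 1.
#'
#' @param x Object to validate.
#' @param what Name used in error messages.
#' @return `x`, invisibly.
#' @export
assert_feature_map <- function(x, what = "x") {
  if (!is.array(x) || length(dim(x)) != 3L)
    shape_error(sprintf("%s must be a 3-d array with dim (C, H, W)", what))
  if (any(dim(x) < 1L))
    shape_error(sprintf("%s has a zero extent: (%s)", what,
                        paste(dim(x), collapse = ", ")))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    mito_error("mito_numeric_error",
               sprintf("%s contains non-finite values", what))
  invisible(x)
}

#' Generate a seeded standard-normal feature-map fixture
#'
#' Draws a `C x H x W` array of independent standard-normal values under a
#' fixed seed. Used throughout the test-suite as the canonical random tensor
#' fixture for the attention oracles.
#'
#' @param C,H,W Positive integer extents (channels, height, width).
#' @param seed Integer RNG seed; identical seeds give identical tensors.
#' @return Numeric array with `dim = c(C, H, W)`.
#' @export
generate_feature_fixture <- function(C, H, W, seed = 1L) {
  if (!is_count(C) || C < 1 || !is_count(H) || H < 1 || !is_count(W) || W < 1)
    param_error("C, H, W must be positive integers")
  with_seed(seed, array(stats::rnorm(C * H * W), dim = c(C, H, W)))
}
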