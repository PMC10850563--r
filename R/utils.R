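#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------
#
# All package errors carry a condition class so callers (and the CLI, which
# maps classes to exit codes) can distinguish schema problems from contract
# violations from plain invalid parameters.

mito_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mito_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

schema_error   <- function(msg) mito_error("mito_schema_error", msg)
contract_error <- function(msg) mito_error("mito_contract_error", msg)
param_error    <- function(msg) mito_error("mito_param_error", msg)
range_error    <- function(msg) mito_error("mito_range_error", msg)
shape_error    <- function(msg) mito_error("mito_shape_error", msg)
size_error     <- function(msg) mito_error("mito_size_error", msg)

# RNG helpers ------------------------------------------------------------------

# Derive a reproducible child seed from a base seed and a stream index,
# kept within 32-bit integer range.
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.double(seed) * 48271 + stream * 10007) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Misc -------------------------------------------------------------------------

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
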