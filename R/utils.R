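#' @keywords internal
"_PACKAGE"

# Collect validation failures and report them all at once.
collect_errors <- function() {
  errs <- character()
  list(
    check = function(ok, msg) if (!isTRUE(ok)) errs[[length(errs) + 1L]] <<- msg,
    fail_if_any = function(context) {
      if (length(errs))
        stop(context, ":\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
      invisible(TRUE)
    },
    messages = function() errs
  )
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic child-seed derivation so stages can be re-run alone.
# Exact in double precision, result < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is_count(seed))
  as.integer((seed * 48271 + 7919 * stream) %% 2147483629)
}

# Pixel-centre coordinate grids for a patch of size dim = c(nrow, ncol),
# centred on (cy, cx) (row, col).
coord_grid <- function(dim, cy, cx) {
  dy <- matrix(seq_len(dim[1]) - cy, dim[1], dim[2])
  dx <- matrix(rep(seq_len(dim[2]) - cx, each = dim[1]), dim[1], dim[2])
  list(dy = dy, dx = dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
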