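# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under an optional seed
#'
#' When `seed` is `NULL` the expression runs against the current RNG stream;
#' otherwise it runs under `withr::with_seed()` so the global RNG state is
#' left untouched.
#' @noRd
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Derive a stream of child seeds from one master seed
#'
#' Keeps every derived seed strictly below 2^31 so it is a valid R integer.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed_if(seed, sample.int(.Machine$integer.max, n))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, min, max, x),
         call. = FALSE)
  }
  invisible(x)
}

# Reverse complement of single DNA bases (vectorised, character in/out).
revcomp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Write `lines` (or a data.frame via `writer`) atomically: the target file
# either keeps its old content or receives the complete new content.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
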