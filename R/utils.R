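#' @keywords internal
"_PACKAGE"

# Internal assertion helpers. All user-facing errors go through these so the
# error classes named in the function contracts are machine-testable.

msr_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "musuppr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(cond, class, msg) {
  if (!isTRUE(cond)) msr_error(class, msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Derive a stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed integer
#' hash, so that each stage is individually reproducible while stages remain
#' statistically independent. The rule is a 32-bit linear congruential step on
#' `seed` combined with a stage index; results always lie in `[1, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (or a stage name, hashed by character
#'   codes).
#' @return an integer seed.
#' @export
split_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  a <- 1103515245; m <- 2147483647
  s <- (as.double(seed) %% m)
  s <- (s * a + 12345 + as.double(stage) * 2654435761) %% m
  # a couple of extra mixing rounds so nearby (seed, stage) pairs decorrelate
  for (i in 1:2) s <- (s * a + 12345) %% m
  as.integer(s %% (m - 2) + 1)
}

# sliding-window column extraction: rows = window, cols = window index
window_starts <- function(n, len, step) {
  if (n < len) return(integer(0))
  seq.int(1L, n - len + 1L, by = step)
}
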