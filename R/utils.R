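# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic stages of the pipeline draw their random numbers from
#' sub-seeds derived deterministically from one master seed and a label
#' (e.g. a participant id), so results do not depend on the order in which
#' participants are processed and no hidden global RNG state is shared
#' between stages.
#'
#' @param seed Integer master seed.
#' @param stream Integer or character label of the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1L, 7L)
#' substream_seed(1L, "participant-7")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (is.character(stream)) {
    stopifnot(length(stream) == 1L)
    codes <- utf8ToInt(stream)
  } else {
    stopifnot(is.numeric(stream), all(is.finite(stream)))
    codes <- as.numeric(stream)
  }
  m <- 2147483647 # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- abs(seed) %% m
  # multiplicative-congruential mixing (Lehmer constants); exact below 2^53
  for (k in codes) {
    h <- (h * 48271 + (abs(k) %% m) + 12345) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seed without disturbing the caller's
# RNG state.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# stop() with a condition class so callers/tests can distinguish error kinds.
abort_smst <- function(message, class) {
  stop(structure(
    class = c(class, "smst_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
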