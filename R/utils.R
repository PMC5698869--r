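# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed
#'
#' All stochastic generators in the package take a single integer seed.  When
#' a dataset is built from many independently reproducible pieces (one per
#' subject and block, say), child seeds are derived arithmetically from the
#' root so that any subset can be regenerated without generating the rest.
#'
#' @param root integer root seed.
#' @param ... one or more non-negative integer offsets (e.g. subject index,
#'   block index); combined positionally.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, 3, 2)
child_seed <- function(root, ...) {
  idx <- c(...)
  stopifnot(length(root) == 1, is.finite(root))
  s <- as.double(root) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 69069 + 104729 * as.double(idx[k]) + 7919 * k) %% 2147483647
  }
  as.integer(s)
}

# set.seed only when a seed is supplied; NULL leaves the RNG stream alone
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

# scalar numeric check
is_num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
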