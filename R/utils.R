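# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stable 31-bit string hash
#'
#' Deterministic polynomial rolling hash used to derive per-task random seeds
#' from subgrouping descriptors. Stable across R sessions and platforms
#' (depends only on UTF-8 code points), unlike `set.seed(sum(utf8ToInt(x)))`
#' style schemes it is order-sensitive.
#'
#' @param x Character scalar.
#' @return Integer in `[0, 2^31 - 2]`.
#' @keywords internal
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  mod <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h)
}

# Mix an experiment seed with string/int components into a reproducible
# sub-seed below 2^31. Adding components never perturbs seeds derived from
# other component combinations.
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) as.character(p), character(1))
  key <- paste(c(format(seed), parts), collapse = "\r")
  stable_hash(key)
}

# Canonical key for a set of sample ids: order-insensitive, used for
# deduplicating subgroupings with identical mutated-sample sets.
sample_set_key <- function(samples) {
  stable_hash(paste(sort(unique(samples)), collapse = "|"))
}

abort_input <- function(msg) abort(msg, class = "mutsubsig_input_error")
abort_config <- function(msg) abort(msg, class = "mutsubsig_config_error")
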