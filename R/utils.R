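`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

#' Derive a reproducible child seed from a base seed and a label
#'
#' Fans a single pipeline seed out to per-stage seeds by stable hashing of
#' the stage label, so inserting or reordering stages does not perturb the
#' random streams of other stages. The result is always a valid 32-bit
#' integer seed.
#'
#' @param seed Integer base seed.
#' @param label Character stage label.
#' @return An integer seed.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) %% 1000003
  as.integer((abs(seed) %% 65521 * 7919 + h * 104729 + 17) %%
               (.Machine$integer.max - 1L)) + 1L
}
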