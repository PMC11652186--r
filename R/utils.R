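# Internal helpers shared across modules.

sigmoid <- function(x) stats::plogis(x)

# Population (divide-by-n) standard deviation; fixed for reproducibility.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- rlang::`%||%`

abort_if <- function(cond, msg, class = "ocrchart_error") {
  if (isTRUE(cond)) rlang::abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  abort_if(!ok, sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                        name,
                        if (closed_lower) "[" else "(", format(lower),
                        format(upper), if (closed_upper) "]" else ")"))
  invisible(x)
}

# Derive a stage seed from a root seed, staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset * 7919) %% 2147483587L) + 1L
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; `seed = NULL` runs in the ambient stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

as_feature_matrix_input <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  abort_if(!is.matrix(x) || !is.numeric(x), "expected a numeric matrix or data frame")
  x
}
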