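#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with the offending field named.
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_config(field, sprintf("must lie in %s%s, %s%s",
                               if (strict_lower) "(" else "[", lower, upper,
                               if (strict_upper) ")" else "]"))
  invisible(x)
}

# Population z-score of a numeric vector (denominator n, not n-1).
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("zero-variance column", call. = FALSE)
  (x - m) / s
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to compare recovered metabolite modules against a known ground
#' truth partition; 1 means identical partitions, 0 is the expected value
#' for independent labelings.
#'
#' @param a,b vectors of cluster labels (any type coercible to factor),
#'   same length.
#' @return numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Derive a sub-stream seed from a base seed with a fixed offset, kept
# within the 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}
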