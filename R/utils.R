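`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort_input("'%s' must be a single number in %s%s, %s%s (got %s)",
                name, if (strict_lower) "(" else "[", format(lower),
                format(upper), if (strict_upper) ")" else "]",
                paste(format(x), collapse = ","))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_scalar(x, name, lower = 0, strict_lower = TRUE)
}

check_flag_vector <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || !all(x %in% c(0, 1)))
    abort_input("'%s' must be a binary (0/1) vector without NAs", name)
  invisible(x)
}

#' Derive reproducible child seeds from a master seed
#'
#' Every source of randomness in the package draws its own seed from a parent
#' seed through this one function, which makes nested simulations (replicates,
#' arms, subjects) reproducible independently of execution order or worker
#' count. Child seeds are sampled without replacement from `1:(2^31 - 2)` under
#' the parent seed, so they remain valid 32-bit integer seeds.
#'
#' @param seed Integer parent seed.
#' @param n Number of child seeds required.
#' @return Integer vector of `n` seeds.
#' @export
#' @examples
#' derive_seeds(1L, 3L)
derive_seeds <- function(seed, n) {
  seed <- as.integer(seed)
  if (is.na(seed)) abort_input("'seed' must be coercible to integer")
  check_scalar(n, "n", lower = 1)
  withr::with_seed(seed, sample.int(2147483646L, as.integer(n)))
}

# Evaluate `code` under `seed` when given, otherwise use the ambient RNG state.
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

iso_time <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
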