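# Internal helpers: argument checking and rounding.

abort_input <- function(msg, ..., class = "plasfit_invalid_input") {
  rlang::abort(message = sprintf(msg, ...), class = class)
}

check_number <- function(x, arg, positive = FALSE, non_negative = FALSE,
                         finite = TRUE, allow_vec = TRUE) {
  if (!is.numeric(x) || (!allow_vec && length(x) != 1L)) {
    abort_input("`%s` must be numeric%s.", arg, if (allow_vec) "" else " of length 1")
  }
  if (anyNA(x)) abort_input("`%s` contains missing values.", arg)
  if (finite && any(!is.finite(x))) abort_input("`%s` must be finite.", arg)
  if (positive && any(x <= 0)) abort_input("`%s` must be strictly positive.", arg)
  if (non_negative && any(x < 0)) abort_input("`%s` must be non-negative.", arg)
  invisible(x)
}

check_count <- function(x, arg, positive = FALSE) {
  check_number(x, arg, non_negative = !positive, positive = positive)
  if (any(x != trunc(x))) abort_input("`%s` must be a whole number.", arg)
  invisible(x)
}

check_columns <- function(data, cols, arg = "data") {
  if (!is.data.frame(data)) abort_input("`%s` must be a data frame.", arg)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort_input("`%s` is missing required column(s): %s.", arg,
                paste0("`", missing, "`", collapse = ", "))
  }
  invisible(data)
}

# Round half away from zero at `digits` decimals (base round() is
# round-half-even, which does not match the copy-number table convention).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `code` under a fixed RNG seed when `seed` is given, without
# disturbing the caller's RNG state; otherwise use the ambient stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
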