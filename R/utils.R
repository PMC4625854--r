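# Internal helpers shared across modules.

# Validate a scalar count (positive integer-valued number).
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "pdblood_validation_error")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_min) x > min else x >= min) && x <= max
  if (!ok) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                  format(min), format(max)),
          class = "pdblood_validation_error")
  }
  as.numeric(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name),
          class = "pdblood_validation_error")
  }
  x
}

# Run `expr` under a local RNG state seeded with `seed` (no global pollution).
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Geometric mean, guarding against non-positive input.
geom_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Two-class label vector -> factor with levels control, case.
as_class_factor <- function(labels) {
  lv <- c("control", "case")
  if (!all(labels %in% lv)) {
    abort("class labels must be 'case' or 'control'.",
          class = "pdblood_validation_error")
  }
  factor(labels, levels = lv)
}
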