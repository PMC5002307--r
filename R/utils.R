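# Internal helpers shared across modules.

#' Wrap an angular difference into [-180, 180) degrees
#'
#' Angular differences entering the Gaussian similarity measure are wrapped
#' so that physically close bearings on either side of north compare as
#' close (350 deg vs 10 deg is a 20 deg difference, not 340 deg).
#'
#' @param a numeric vector of angle differences in degrees.
#' @return numeric vector in \[-180, 180).
#' @examples
#' wrap_angle(350 - 10)   # -20
#' wrap_angle(c(0, 180, -190, 720))
#' @export
wrap_angle <- function(a) {
  ((a + 180) %% 360) - 180
}

# Normalize a heading to [0, 360).
norm_heading <- function(a) a %% 360

# Run `expr` under `seed` if non-NULL, otherwise with the ambient RNG state.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Scalar checks used by constructors; `what` names the argument in errors.
check_number <- function(x, what, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` must be in %s%g, %g%s (got %g)", what,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x
    ), call. = FALSE)
  }
  as.numeric(x)
}

check_count <- function(x, what, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower) {
    stop(sprintf("`%s` must be an integer >= %d", what, lower), call. = FALSE)
  }
  as.integer(x)
}
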