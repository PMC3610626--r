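#' @keywords internal
"_PACKAGE"

# Parameter validation helpers ------------------------------------------------

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("`%s` must be a finite numeric scalar", name)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_param("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
               if (strict_lower) "(" else "[", lower, upper,
               if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_param("`%s` must be a finite numeric matrix", name)
  }
  invisible(x)
}

# All stochastic code paths run under a locally scoped seed so that generators
# are deterministic and never disturb the caller's RNG state.
with_local_seed <- function(seed, code) {
  force(seed)
  withr::with_seed(as.integer(seed), code)
}

# Derive per-segment/per-restart sub-seeds from a master seed, kept < 2^31.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
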