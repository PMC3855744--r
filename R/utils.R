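# small internal helpers

# round half away from zero (matches how the published ratio table rounds,
# e.g. 1.84 -> 1.8, 22.5% -> 23%); base round() is banker's rounding
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

check_scalar <- function(x, name, min = -Inf, max = Inf,
                         allow_null = FALSE, strict_min = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < min || x > max || (strict_min && x == min))
    stop(sprintf("'%s' out of range [%s, %s]: %s", name,
                 if (strict_min) paste0(min, ")") else min, max, x),
         call. = FALSE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
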