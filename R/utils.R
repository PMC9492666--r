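# internal helpers: classed conditions and argument checks

ss_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "synergyscreen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ss_stop("invalid_argument", "`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    ss_stop("invalid_argument", "`%s` = %g is outside its allowed range", name, x)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lower = min)
  if (x != round(x)) ss_stop("invalid_argument", "`%s` must be an integer", name)
  invisible(as.integer(x))
}
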