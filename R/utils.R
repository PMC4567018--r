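# Round half away from zero (base round() rounds half to even, which
# disagrees with the scoring rule's arithmetic on .5 boundaries).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lungscore <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "lungscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
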