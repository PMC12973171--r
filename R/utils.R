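# Internal helpers: classed error conditions and small validators.

fw_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fragwave_error"),
                      call = call))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    fw_stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                    name, format(lower), format(upper)),
            "fragwave_parameter_error")
  }
  invisible(x)
}

assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] >= x[2]) {
    fw_stop(sprintf("`%s` must be a length-2 numeric interval with low < high",
                    name), "fragwave_parameter_error")
  }
  invisible(x)
}

is_odd <- function(n) n %% 2L == 1L

`%||%` <- function(a, b) if (is.null(a)) b else a
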