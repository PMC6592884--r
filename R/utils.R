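# Internal helpers shared across modules.

# All stochastic entry points funnel through here so that a given seed
# produces the same stream regardless of the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ..., class = "bloomregime_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    stopf("`%s` must be a single finite number %s %s, got %s.",
          name, if (strict) ">" else ">=", format(min),
          paste(format(x), collapse = ", "),
          class = "bloomregime_config_error")
  }
  invisible(x)
}

# Matrix of the model inputs in canonical column order.
input_matrix <- function(data, inputs = chla_inputs) {
  missing <- setdiff(inputs, names(data))
  if (length(missing) > 0) {
    stopf("Input variable(s) %s absent from the data.",
          paste0("`", missing, "`", collapse = ", "),
          class = "bloomregime_contract_error")
  }
  as.matrix(data[inputs])
}
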