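# internal helpers shared across modules

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# render an age as it appears in node labels: no scientific notation,
# no padding, trailing ".0" never produced for whole numbers
format_age <- function(age) {
  format(age, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}
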