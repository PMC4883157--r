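# numerically stable log(sum(exp(x))); -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

assert_count <- function(x, name, min = 0) {
  if (length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.numeric(x))
}
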