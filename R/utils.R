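# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ps <- function(..., class = "pupsyntax_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "pupsyntax_error")))
}

warn_ps <- function(...) warning(paste0(...), call. = FALSE)

assert_that <- function(cond, ..., class = "pupsyntax_error") {
  if (!isTRUE(cond)) stop_ps(..., class = class)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Periodic Hann window of length n.
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# Truncated-normal sampler via inverse CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)
}

# Log-normal sampler truncated to [lo, hi) by inverse CDF.
rtrunclnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  u <- stats::runif(n, plo, phi)
  q <- stats::qlnorm(u, meanlog, sdlog)
  pmin(pmax(q, lo), hi * (1 - 1e-12))
}
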