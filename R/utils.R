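# internal helpers shared across modules

clip01 <- function(x) pmin(1, pmax(0, x))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed for ensemble member k. Keeps everything
# below 2^31 - 1 so it stays a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + as.numeric(k) * 16807) %%
               2147483647)
}

# Fractional-year time stamp with months at their mid-points.
year_frac <- function(year, month) year + (month - 0.5) / 12

stopf <- function(fmt, ..., class = "coralproj_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "coralproj_error")))
}
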