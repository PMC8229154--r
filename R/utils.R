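# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' @keywords internal
ic_number <- function(ic_id) {
  as.integer(sub("^IC", "", ic_id))
}

# Derive independent sub-seeds from one user seed; kept below 2^31.
spawn_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Population (1/n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

skewness <- function(x) {
  s <- sd_pop(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
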