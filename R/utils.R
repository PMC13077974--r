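#' Round half away from zero
#'
#' Commercial rounding used for all reported metrics: exact halves move away
#' from zero (`round_half_away(0.8085, 3)` is `0.809`), unlike base [round()],
#' which rounds halves to even. Computation is always carried at full double
#' precision; rounding is applied only when a value is *reported*.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(0.8085, 3) # 0.809
#' round_half_away(47.7, 0)   # 48
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 nudge compensates for decimal fractions that have no exact
  # binary representation (0.8085 * 1000 == 808.4999...)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic seed for a named stratum: seed + a stable hash of the name,
# kept well below .Machine$integer.max. Adding a new stratum never changes
# the stream of an existing one.
derive_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 100000L
  (as.integer(seed) %% 20000000L) * 100L + h %% 100L + h
}

n_chars <- function(x) nchar(x, type = "chars")

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

compact_chr <- function(x) x[!is.na(x) & nzchar(x)]
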