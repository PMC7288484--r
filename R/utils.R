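# Internal helpers: argument checks and deterministic substream seeding.

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`", name, "` must be a single finite number")
  if (x < lower || (strict_lower && x <= lower))
    stop_invalid("`", name, "` must be ", if (strict_lower) "> " else ">= ",
                 lower, " (got ", x, ")")
  if (x > upper || (strict_upper && x >= upper))
    stop_invalid("`", name, "` must be ", if (strict_upper) "< " else "<= ",
                 upper, " (got ", x, ")")
  x
}

check_count <- function(x, name, lower = 0L) {
  x <- check_number(x, name, lower = lower)
  if (x != round(x)) stop_invalid("`", name, "` must be a whole number")
  as.integer(x)
}

# Deterministic substream seed derived from a master seed and integer ids.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() accepts it on all
# platforms. A multiplicative mix is enough here: ids are small structured
# integers (stream number, look position), not adversarial.
mix_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (id in ids) {
    s <- (s * 48271 + as.double(id) * 8191 + 1) %% 2147483647
  }
  as.integer(s %% 2147483645) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
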