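# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals; base round() is banker's
# rounding, while the lab's printed percentages use conventional half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of num/den at `digits` decimals, NA-safe for empty denominators.
pct_of <- function(num, den, digits = 2) {
  if (is.na(den) || den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

is_finite_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Timestamps are timezone-naive wall-clock times in one configured lab
# timezone; internally everything is POSIXct pinned to UTC so arithmetic
# and serialisation are deterministic across machines.
av_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x)) {
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    return(out)
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  abort("cannot interpret value as a timestamp", class = "av_bad_input")
}

format_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Derive a stream-specific RNG seed from the master seed so that one
# module's draw count changing does not shift every other module's stream.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Parse a numeric result value; categorical values yield NA without warning.
numeric_value <- function(x) suppressWarnings(as.numeric(x))

# Split a ";"-separated sample-flag field into a character vector.
parse_flags <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}
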