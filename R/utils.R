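#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when reporting correct-to-incorrect ratios (base R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(9 / 1.9, 2) # 4.74
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Quantize to the 3-decimal resolution of the command protocol.  Values
# supplied to the network travel through DDD.DDD command strings, so the
# engine works at this resolution; quantizing here makes direct training and
# command-script replay bit-identical.
quantize_value <- function(x) as.numeric(sprintf("%.3f", x))

#' Format a fact value for the command protocol
#'
#' Fact values are exchanged as fixed-point strings with three integer and
#' three decimal digits, e.g. `000.393`.
#'
#' @param x Numeric vector in `[0, 999.999]`.
#' @return Character vector of `DDD.DDD` strings.
#' @examples
#' format_gdes_value(53 / 135) # "000.393"
#' @export
format_gdes_value <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0 & x <= 999.999))
  sprintf("%07.3f", x)
}

# Random version-4-style GUID: 32 hex characters in 8-4-4-4-12 grouping.
# Drawn from the session RNG so networks built under set.seed() are
# reproducible.
new_guid <- function(n = 1) {
  hex <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i) {
    h <- sample(hex, 32, replace = TRUE)
    h[13] <- "4"
    h[17] <- sample(c("8", "9", "a", "b"), 1)
    paste0(
      paste(h[1:8], collapse = ""), "-",
      paste(h[9:12], collapse = ""), "-",
      paste(h[13:16], collapse = ""), "-",
      paste(h[17:20], collapse = ""), "-",
      paste(h[21:32], collapse = "")
    )
  }, character(1))
}

is_guid <- function(x) {
  grepl("^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$", x)
}

# Elapsed-time helpers.  Offsets are stored as integer centiseconds (100 Hz
# sampling) and rendered as MM:SS.CC, or H:MM:SS.CC past the first hour,
# e.g. "30:00.00" and "1:00:00.00".
format_time_cs <- function(cs) {
  cs <- as.integer(round(cs))
  h <- cs %/% 360000L
  rem <- cs %% 360000L
  m <- rem %/% 6000L
  s <- (rem %% 6000L) / 100
  ifelse(h > 0L,
    sprintf("%d:%02d:%05.2f", h, m, s),
    sprintf("%02d:%05.2f", m, s)
  )
}

parse_time_cs <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || !length(p) %in% 2:3) {
      return(NA_integer_)
    }
    if (length(p) == 2) p <- c(0, p)
    as.integer(round(p[1] * 360000 + p[2] * 6000 + p[3] * 100))
  }, integer(1))
}

# Derive a child RNG seed below 2^31 from a parent seed and stream indices.
child_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483587
  s <- as.numeric(seed) %% m
  for (i in idx) {
    s <- (s * 48271 + as.numeric(i) * 9973 + 1) %% m
  }
  as.integer(s) + 1L
}
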