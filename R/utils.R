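## Internal helpers: hierarchical seeding, hashing, misc.

#' Derive a child seed from a parent seed and an index path
#'
#' Deterministic mixing of a parent seed with one or more integer indices,
#' used to give every session / unit / electrode its own reproducible RNG
#' stream so that subsets of an experiment regenerate identically.
#'
#' @param seed parent seed (non-negative integer below 2^31).
#' @param ... integer indices identifying the child stream.
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
childSeed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 69069 + (as.numeric(k) + 1) * 40503 + 12345) %% m
  }
  as.integer(s)
}

## Evaluate expr with a local RNG state seeded by `seed`; restores the
## caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## FNV-1a 32-bit hash over a character scalar; returned as 8-digit hex.
## Multiplication is split into 16-bit halves so all arithmetic stays exact.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  p <- 16777619
  m32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * p) %% m32 + ((hi * p) %% 65536) * 65536) %% m32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## bitwXor for values up to 2^32 stored in doubles.
bitwXor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

## Canonical hash of an R list (configs) via its JSON serialization.
configHashOf <- function(x) {
  fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                           force = TRUE, null = "null"))
}

## Half-open interval spike count: number of t with start <= t < end.
countInWindow <- function(times, start, end) {
  sum(times >= start & times < end)
}

## stopifnot with a formatted message
failIf <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

phaseLevels <- function() c("pre", "I", "II", "III", "IV")

## Screen locations: 0..8 row-major on the 3x3 grid, 4 = centre (foveal).
peripheralLocations <- function() setdiff(0:8, 4L)

## Angle of each peripheral location around the centre, radians.
locationAngle <- function(loc) {
  row <- loc %/% 3L
  col <- loc %% 3L
  atan2(1 - row, col - 1)
}

## Diametric (point-reflected) location; centre maps to an adjacent cell
## (the task pairs the centre cue with a neighbouring nonmatch).
diametricLocation <- function(loc) {
  ifelse(loc == 4L, 5L, 8L - loc)
}
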