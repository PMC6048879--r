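#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves going up, the
#' convention used throughout the participation and coverage reports
#' (integer percentages in participation tables, one decimal in coverage
#' tables). Base [round()] uses banker's rounding and is unsuitable for
#' reproducing printed report percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(95.44)      # 95
#' roundHalfUp(95.629, 1)  # 95.6
#' roundHalfUp(0.5)        # 1
#' @export
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  u <- x * scale
  # absorb representation error so values that are exact halves (or exact
  # integers) in decimal behave as such
  near <- abs(u - round(u)) < 1e-8
  u[near] <- round(u[near])
  floor(u + 0.5) / scale
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws from its own seed derived
#' deterministically from the master seed and a stage label, so stages can
#' be re-run in isolation and adding a stage never perturbs the draws of
#' another. The derivation is a 31-bit polynomial hash of the label folded
#' into the master seed.
#'
#' @param seed master seed (integer).
#' @param stage character scalar naming the stage, e.g. `"survey"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derivedSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  s <- (as.numeric(seed) %% m * 48271 + h) %% m
  as.integer(max(1, s %% (m - 1)))
}

# evaluate `expr` with a temporary RNG state seeded by `seed`; the caller's
# RNG state is untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop() with a row-addressed message for table readers/validators
rowStop <- function(row, fmt, ...) {
  stop(sprintf("row %d: %s", row, sprintf(fmt, ...)), call. = FALSE)
}

# first offending index or 0
firstBad <- function(bad) if (any(bad)) which(bad)[1L] else 0L

# require columns, in any order, naming the file kind in errors
requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# parse a numeric column, error citing the first malformed row
parseNumericColumn <- function(x, col, what) {
  x <- trimws(as.character(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    rowStop(firstBad(bad), "malformed numeric value '%s' in %s column '%s'",
            x[firstBad(bad)], what, col)
  }
  v
}

# parse ISO-8601 dates, blanks -> NA, malformed -> row-addressed error
parseDateColumn <- function(x, col, what) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  filled <- !is.na(x) & nzchar(x)
  v <- as.Date(x[filled], format = "%Y-%m-%d", optional = TRUE)
  bad <- is.na(v)
  if (any(bad)) {
    idx <- which(filled)[firstBad(bad)]
    rowStop(idx, "malformed date '%s' in %s column '%s'",
            x[idx], what, col)
  }
  out[filled] <- v
  out
}

fmtDate <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))

# thousands-separated integer formatting for rendered tables
fmtCount <- function(n) formatC(n, format = "d", big.mark = ",")
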