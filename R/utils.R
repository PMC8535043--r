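# Internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties moved away from zero (0.905 -> 0.91 at two
#' decimals), matching how clinical tables are conventionally rounded.
#' Base [round()] uses round-half-to-even and is unsuitable for reproducing
#' reported two-decimal metrics.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.905, 2) # 0.91
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by an epsilon proportional to x to absorb binary representation
  # error (0.905 is stored just below its decimal value)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Format "mean ± sd" at two decimals
#' @noRd
fmt_mean_sd <- function(mean, sd, digits = 2) {
  sprintf("%.*f ± %.*f", digits, round_half_away(mean, digits),
          digits, round_half_away(sd, digits))
}

#' Pearson correlation that treats zero-variance vectors as uncorrelated
#' @noRd
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
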