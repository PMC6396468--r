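#' Sigmoid (inverse logit)
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`. Vectorised; the inverse of [logit()] on
#' the open unit interval.
#'
#' @param x Numeric vector.
#' @return Numeric vector in (0, 1).
#' @examples
#' sigmoid(0)           # 0.5
#' logit(sigmoid(1.7))  # 1.7
#' @export
sigmoid <- function(x) {
  stopifnot(is.numeric(x))
  1 / (1 + exp(-x))
}

#' Logit (log-odds)
#'
#' `logit(p) = log(p / (1 - p))`. Inputs must lie strictly inside (0, 1);
#' callers holding possibly-degenerate PSI values must clip first with
#' [clip_psi()].
#'
#' @param p Numeric vector strictly inside (0, 1).
#' @return Numeric vector.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires values strictly inside (0, 1); clip first with clip_psi()")
  }
  log(p / (1 - p))
}

#' Clip PSI values away from 0 and 1
#'
#' Percent-spliced-in values are clipped to `[eps, 1 - eps]` (default
#' `eps = 1e-5`) so that the logit transform stays finite. This is the single
#' place where clipping happens; all logit entry points route through it.
#'
#' @param p Numeric vector in \[0, 1\].
#' @param eps Clipping constant, default `1e-5`.
#' @return Clipped numeric vector.
#' @export
clip_psi <- function(p, eps = 1e-5) {
  stopifnot(is.numeric(p), eps > 0, eps < 0.5)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("PSI values must lie in [0, 1]")
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Logit with clipping
#'
#' Convenience composition `logit(clip_psi(p))`, the transform applied to
#' reference PSI values before adding a predicted delta-logit.
#'
#' @inheritParams clip_psi
#' @return Numeric vector.
#' @export
logit_clipped <- function(p, eps = 1e-5) logit(clip_psi(p, eps))

# Reverse complement of a plain character string (A/C/G/T/N, case folded to
# upper). Biostrings handles the heavy lifting.
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
}

# Pad a string with N on the left/right to reach `width`.
pad_n <- function(s, width, side = c("left", "right")) {
  side <- match.arg(side)
  k <- width - nchar(s)
  if (k <= 0L) return(s)
  pad <- strrep("N", k)
  if (side == "left") paste0(pad, s) else paste0(s, pad)
}

# Deterministic child seeds below 2^31, derived from one user-facing seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
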