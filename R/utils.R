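# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Draw reproducible child seeds from the current RNG stream
#'
#' Top-level simulators seed the global RNG once and hand deterministic
#' child seeds to their sub-generators, so that per-family or per-block
#' streams stay reproducible independent of evaluation order.
#'
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
.child_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

# Percent with one-decimal rounding, the convention used for reported
# karyotype frequencies.
.pct1 <- function(x) round(100 * x, 1)

# Harmonic number sum_{i=1}^{k} 1/i
.harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))
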