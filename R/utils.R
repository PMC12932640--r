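# Internal numeric and RNG helpers shared across modules.

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' log(exp(a) - exp(b)) for a >= b, clamped at -Inf when b >= a
#' @noRd
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Named sub-streams derived from one master seed so cohorts can be
# regenerated independently.  Offsets are arbitrary fixed primes; the
# result is kept inside the 32-bit signed range set.seed() accepts.
.stream_offsets <- c(
  maf      = 104729L,
  exposure = 224737L,
  outcome  = 350377L,
  reference = 479909L,
  pheno_exposure = 611953L,
  pheno_outcome  = 746773L,
  proteome = 882377L
)

#' Derive a deterministic child seed from a master seed and a stream name
#' @noRd
derive_seed <- function(seed, stream, index = 0L) {
  off <- .stream_offsets[[stream]]
  if (is.null(off)) stop("unknown RNG stream: ", stream)
  as.integer((as.double(seed) * 69069 + off + 1009 * index) %% 2147483647)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
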