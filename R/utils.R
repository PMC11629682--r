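# Internal helpers shared across modules: classed error conditions, seed
# substreams, and plain-character sequence utilities.

#' Signal a classed pipeline error
#'
#' All contract violations raise conditions whose class carries a stable,
#' hyphenated identifier (e.g. "infeasible-config", "dangling-reference") so
#' callers and tests can match on the failure mode rather than on message
#' text.
#'
#' @param class condition class string, e.g. "empty-sample"
#' @param msg human-readable message
#' @keywords internal
mp_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "mecphage_error")))
}

#' Derive a named RNG substream seed from a master seed
#'
#' Every stochastic phase draws from its own substream so that adding a phase
#' never perturbs the draws of another. Exact in double arithmetic; result is
#' a valid 32-bit seed.
#'
#' @keywords internal
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 100000L
  as.integer((abs(as.numeric(seed)) * 1000003 + h) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random i.i.d. uniform DNA string
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Apply point substitutions at a per-base rate
#'
#' Each position mutates independently with probability `rate`; a mutated
#' base is replaced by one of the three other bases uniformly. Returns the
#' mutated string; the logical mutation mask is attached as attribute "mask"
#' so callers can know the realized identity exactly.
#'
#' @keywords internal
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) {
    attr(seq, "mask") <- logical(n)
    return(seq)
  }
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(n) < rate
  if (any(hit)) {
    idx <- which(hit)
    offs <- sample.int(3L, length(idx), replace = TRUE)
    cur <- match(x[idx], DNA_BASES)
    x[idx] <- DNA_BASES[((cur - 1L + offs) %% 4L) + 1L]
  }
  out <- paste(x, collapse = "")
  attr(out, "mask") <- hit
  out
}

#' Reverse complement of a plain character sequence
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Lookup table mapping ASCII codes to 2-bit base codes (A=0 C=1 G=2 T=3),
# NA for anything else (notably N).
.base_code <- local({
  tab <- rep(NA_real_, 128)
  tab[utf8ToInt("A")] <- 0
  tab[utf8ToInt("C")] <- 1
  tab[utf8ToInt("G")] <- 2
  tab[utf8ToInt("T")] <- 3
  tab[utf8ToInt("a")] <- 0
  tab[utf8ToInt("c")] <- 1
  tab[utf8ToInt("g")] <- 2
  tab[utf8ToInt("t")] <- 3
  tab
})

#' Encode a sequence as 2-bit base codes (NA at ambiguous bases)
#' @keywords internal
encode_dna <- function(seq) {
  .base_code[utf8ToInt(seq)]
}

#' Percentage helper used by run summaries
#'
#' Plain 100 * n / d, the arithmetic behind all "x of y bins (~z%)" summary
#' statistics.
#'
#' @param n numerator count
#' @param d denominator count
#' @return percentage (0-100 scale)
#' @export
fraction_pct <- function(n, d) {
  if (d <= 0) mp_stop("invalid-input", "denominator must be positive")
  100 * n / d
}
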