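# MinHash-style k-mer sketching and sketch ANI. Stands in for the
# alignment-based ANI used by genome dereplication tools: canonical k-mers
# are hashed, a bottom-s sketch retained, Jaccard estimated from the merged
# sketch, and ANI derived with the Mash distance formula
# ANI = 100 * (1 + ln(2J/(1+J)) / k).

# Affine hash modulo the largest prime below 2^53. k <= 17 keeps the 2-bit
# k-mer encoding below 2^34, so a * code + c stays below 2^53 and the whole
# computation is exact in doubles.
.HASH_M <- 9007199254740881
.HASH_A <- 387421
.HASH_C <- 271828182

#' Hash 2-bit k-mer codes
#' @keywords internal
hash_codes <- function(codes) {
  (codes * .HASH_A + .HASH_C) %% .HASH_M
}

#' Canonical k-mer codes of a sequence
#'
#' Returns one numeric code per k-mer start position: the minimum of the
#' forward and reverse-complement 2-bit encodings (so a sequence and its
#' reverse complement yield the same code multiset). Positions whose window
#' contains an ambiguous base are NA.
#'
#' @param seq character scalar (A/C/G/T/N)
#' @param k k-mer size (>= 11, <= 17 so codes stay exact in doubles)
#' @keywords internal
kmer_codes <- function(seq, k = 17L) {
  stopifnot(k >= 11L, k <= 17L)
  v <- encode_dna(seq)
  n <- length(v)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  fwd <- numeric(m)
  rc <- numeric(m)
  for (j in 0:(k - 1L)) {
    x <- v[(1L + j):(m + j)]
    fwd <- fwd + x * 4^(k - 1L - j)
    rc <- rc + (3 - x) * 4^j
  }
  pmin(fwd, rc)
}

#' Build a bottom-s MinHash sketch
#'
#' @param seq character scalar, length >= k (else signals "too-short")
#' @param k k-mer size, default 17
#' @param sketch_size number of minimum hash values retained, default 1000
#' @param source_id optional identifier carried along
#' @return an object of class `kmer_sketch`: list(source_id, k, sketch_size,
#'   hashes sorted ascending, n_kmers = number of distinct canonical k-mers)
#' @export
sketch <- function(seq, k = 17L, sketch_size = 1000L, source_id = NA_character_) {
  if (nchar(seq) < k) mp_stop("too-short", "sequence shorter than k")
  codes <- unique(kmer_codes(seq, k))
  codes <- codes[!is.na(codes)]
  h <- sort(hash_codes(codes))
  structure(
    list(source_id = source_id, k = as.integer(k),
         sketch_size = as.integer(sketch_size),
         hashes = utils::head(h, sketch_size), n_kmers = length(codes)),
    class = "kmer_sketch"
  )
}

#' Estimate ANI from two sketches
#'
#' Jaccard is estimated on the merged bottom-s sketch (Mash's estimator),
#' then converted to ANI = 100 * (1 + ln(2J/(1+J))/k), clipped to [0, 100];
#' J = 0 maps to ANI 0 by convention.
#'
#' @param a,b `kmer_sketch` objects with identical k and sketch_size
#' @return list of class `ani_estimate`: id_a, id_b, ani (percent), jaccard,
#'   shared_hashes
#' @export
estimate_ani <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k || a$sketch_size != b$sketch_size) {
    mp_stop("incompatible-sketches", "sketches have different k or sketch_size")
  }
  s <- a$sketch_size
  merged <- utils::head(sort(unique(c(a$hashes, b$hashes))), s)
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- if (length(merged) == 0L) 0 else shared / length(merged)
  ani <- if (j <= 0) 0 else 100 * (1 + log(2 * j / (1 + j)) / a$k)
  structure(
    list(id_a = a$source_id, id_b = b$source_id,
         ani = min(100, max(0, ani)), jaccard = j, shared_hashes = shared),
    class = "ani_estimate"
  )
}

#' Pairwise sketch-ANI table for a set of sequences
#'
#' @param seqs named character vector
#' @param k,sketch_size sketch parameters
#' @return data.frame(id_a, id_b, ani) over all unordered pairs
#' @export
ani_table <- function(seqs, k = 17L, sketch_size = 1000L) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  sk <- lapply(ids, function(i) sketch(seqs[[i]], k, sketch_size, i))
  names(sk) <- ids
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      ani = numeric(0)))
  }
  pairs <- utils::combn(n, 2L)
  ani <- vapply(seq_len(ncol(pairs)), function(p) {
    estimate_ani(sk[[pairs[1L, p]]], sk[[pairs[2L, p]]])$ani
  }, numeric(1))
  data.frame(id_a = ids[pairs[1L, ]], id_b = ids[pairs[2L, ]], ani = ani,
             stringsAsFactors = FALSE)
}

#' Exact k-mer containment of sequence a in sequence b
#'
#' Fraction of a's distinct canonical k-mers present in b (full sets, not
#' sketches).
#'
#' @keywords internal
kmer_containment <- function(seq_a, seq_b, k = 17L) {
  ca <- unique(kmer_codes(seq_a, k))
  ca <- ca[!is.na(ca)]
  cb <- unique(kmer_codes(seq_b, k))
  cb <- cb[!is.na(cb)]
  if (length(ca) == 0L) return(0)
  mean(ca %in% cb)
}

#' Matched-region coverage of sequence a by sequence b
#'
#' Fraction of a's length covered by clusters (gap <= max_gap) of positions
#' whose canonical k-mer occurs in b. Unlike raw k-mer containment this is
#' robust to uniform point substitutions: at a few percent divergence the
#' matching k-mers still blanket the homologous span.
#'
#' @keywords internal
kmer_coverage <- function(seq_a, seq_b, k = 17L, max_gap = 500L) {
  ca <- kmer_codes(seq_a, k)
  cb <- unique(kmer_codes(seq_b, k))
  cb <- cb[!is.na(cb)]
  hit <- which(!is.na(ca) & ca %in% cb)
  if (length(hit) == 0L) return(0)
  brk <- which(diff(hit) > max_gap)
  starts <- hit[c(1L, brk + 1L)]
  ends <- hit[c(brk, length(hit))] + k - 1L
  sum(ends - starts + 1L) / nchar(seq_a)
}
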