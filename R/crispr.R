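# CRT-style CRISPR array detection: scan for an exact 8-bp seed recurring at
# spacings compatible with one repeat plus one spacer, chain recurrences into
# candidate arrays, extend repeat boundaries while instances agree, then
# validate repeat count, length bounds, repeat similarity and spacer
# dissimilarity. Detection is strand-naive (an array on the reverse strand
# is reported as its reverse-complemented repeats at mirrored coordinates).

#' CRISPR detection parameters (CRT/MinCED defaults)
#'
#' @param min_repeats minimum repeat instances per array (3)
#' @param repeat_len allowed repeat length range, default c(23, 47)
#' @param spacer_len allowed spacer length range, default c(26, 50)
#' @param seed_len exact seed window length (8)
#' @param repeat_identity_min minimum mean pairwise repeat identity (0.9)
#' @param spacer_identity_max maximum mean pairwise spacer identity (0.62)
#' @param extension_agreement minimum column agreement for tolerating a
#'   single dissenting instance while extending repeat boundaries (0.75);
#'   see [detect_arrays()] for the exact rule
#' @export
crispr_params <- function(min_repeats = 3L, repeat_len = c(23L, 47L),
                          spacer_len = c(26L, 50L), seed_len = 8L,
                          repeat_identity_min = 0.9,
                          spacer_identity_max = 0.62,
                          extension_agreement = 0.75) {
  list(min_repeats = min_repeats, repeat_len = repeat_len,
       spacer_len = spacer_len, seed_len = seed_len,
       repeat_identity_min = repeat_identity_min,
       spacer_identity_max = spacer_identity_max,
       extension_agreement = extension_agreement)
}

# identity between two strings: matching positions over the longer length
# (prefix-aligned; adequate for near-equal-length repeats/spacers)
str_identity <- function(a, b) {
  na <- nchar(a)
  nb <- nchar(b)
  m <- min(na, nb)
  if (m == 0L) return(0)
  xa <- strsplit(substr(a, 1, m), "")[[1]]
  xb <- strsplit(substr(b, 1, m), "")[[1]]
  sum(xa == xb) / max(na, nb)
}

mean_pairwise_identity <- function(strings) {
  n <- length(strings)
  if (n < 2L) return(1)
  pairs <- utils::combn(n, 2L)
  mean(vapply(seq_len(ncol(pairs)), function(p) {
    str_identity(strings[pairs[1L, p]], strings[pairs[2L, p]])
  }, numeric(1)))
}

# forward (strand-specific) seed codes, NA at ambiguous bases
seed_codes <- function(v, k) {
  n <- length(v)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  out <- numeric(m)
  for (j in 0:(k - 1L)) out <- out + v[(1L + j):(m + j)] * 4^(k - 1L - j)
  out
}

#' Detect CRISPR arrays in a contig
#'
#' @param contig character scalar sequence
#' @param params a [crispr_params()] list
#' @param bin_id,contig_id identifiers carried into the result
#' @return list of arrays; each is a list with bin_id, contig_id, start, end
#'   (0-based half-open), repeat_consensus, repeats (data.frame start,
#'   sequence) and spacers (data.frame start, sequence), in coordinate order
#' @export
detect_arrays <- function(contig, params = crispr_params(),
                          bin_id = NA_character_, contig_id = NA_character_) {
  p <- params
  L <- nchar(contig)
  if (L < p$repeat_len[1] * p$min_repeats +
      p$spacer_len[1] * (p$min_repeats - 1L)) {
    return(list())
  }
  v <- encode_dna(contig)
  codes <- seed_codes(v, p$seed_len)
  m <- length(codes)
  dmin <- p$repeat_len[1] + p$spacer_len[1]
  dmax <- p$repeat_len[2] + p$spacer_len[2]

  # candidate seed pairs (i, i+d) with identical seed_len-mers
  nexts <- vector("list", m)
  for (d in dmin:dmax) {
    if (d >= m) break
    hit <- which(!is.na(codes[1:(m - d)]) &
                   codes[1:(m - d)] == codes[(1 + d):m])
    for (i in hit) nexts[[i]] <- c(nexts[[i]], i + d)
  }
  starts_with_next <- which(vapply(nexts, length, integer(1)) > 0L)
  if (length(starts_with_next) == 0L) return(list())

  chains <- list()
  chain_member <- logical(m)
  for (i in starts_with_next) {
    if (chain_member[i]) next
    chain <- i
    cur <- i
    repeat {
      nx <- nexts[[cur]]
      if (is.null(nx)) break
      nx <- nx[!chain_member[nx]]
      if (length(nx) == 0L) break
      cur <- min(nx)
      chain <- c(chain, cur)
    }
    if (length(chain) >= p$min_repeats) {
      chain_member[chain] <- TRUE
      chains[[length(chains) + 1L]] <- chain
    }
  }
  if (length(chains) == 0L) return(list())

  x <- strsplit(contig, "", fixed = TRUE)[[1]]
  candidates <- list()
  for (S in chains) {
    n_inst <- length(S)
    gaps <- diff(S)
    # maximum repeat length that keeps every spacer >= spacer_len[1]
    max_rep <- min(p$repeat_len[2], min(gaps) - p$spacer_len[1])
    if (max_rep < p$seed_len) next
    agree_n <- function(off) {
      pos <- S + off
      if (any(pos < 1L | pos > L)) return(0L)
      max(table(x[pos]))
    }
    # a column joins the repeat when all instances agree, or when exactly
    # one dissents (an isolated point mutation) and the next column out
    # agrees fully — so chance agreement in spacers does not extend the
    # boundary but single substitutions do not truncate it
    can_extend <- function(off, dir) {
      a <- agree_n(off)
      if (a == n_inst) return(TRUE)
      n_inst >= 4L && a >= n_inst - 1L &&
        a / n_inst >= p$extension_agreement &&
        agree_n(off + dir) == n_inst
    }
    lo <- 0L
    while (lo > -(max_rep - p$seed_len) && can_extend(lo - 1L, -1L)) {
      lo <- lo - 1L
    }
    hi <- p$seed_len - 1L
    while ((hi - lo + 1L) < max_rep && can_extend(hi + 1L, 1L)) hi <- hi + 1L
    rep_len <- hi - lo + 1L
    if (rep_len < p$repeat_len[1] || rep_len > p$repeat_len[2]) next
    rep_starts <- S + lo
    rep_seqs <- substring(contig, rep_starts, rep_starts + rep_len - 1L)
    spc_starts <- rep_starts[-n_inst] + rep_len
    spc_ends <- rep_starts[-1L] - 1L
    spc_len <- spc_ends - spc_starts + 1L
    if (any(spc_len < p$spacer_len[1] | spc_len > p$spacer_len[2])) next
    spc_seqs <- substring(contig, spc_starts, spc_ends)
    if (mean_pairwise_identity(rep_seqs) < p$repeat_identity_min) next
    if (mean_pairwise_identity(spc_seqs) > p$spacer_identity_max) next
    cons <- apply(matrix(unlist(strsplit(rep_seqs, "")), nrow = rep_len),
                  1L, function(col) names(which.max(table(col))))
    candidates[[length(candidates) + 1L]] <- list(
      bin_id = bin_id, contig_id = contig_id,
      start = rep_starts[1L] - 1L,
      end = rep_starts[n_inst] + rep_len - 1L,
      repeat_consensus = paste(cons, collapse = ""),
      repeats = data.frame(start = rep_starts - 1L, sequence = rep_seqs,
                           stringsAsFactors = FALSE),
      spacers = data.frame(start = spc_starts - 1L, sequence = spc_seqs,
                           stringsAsFactors = FALSE))
  }
  if (length(candidates) == 0L) return(list())

  # resolve overlaps: more repeats, then longer span, then smaller start
  ord <- order(-vapply(candidates, function(a) nrow(a$repeats), integer(1)),
               -vapply(candidates, function(a) a$end - a$start, numeric(1)),
               vapply(candidates, function(a) a$start, numeric(1)))
  kept <- list()
  for (i in ord) {
    a <- candidates[[i]]
    clash <- any(vapply(kept, function(b) {
      a$start < b$end && b$start < a$end
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept[order(vapply(kept, function(a) a$start, numeric(1)))]
}

#' Detect arrays across a set of contigs
#'
#' @param contigs named character vector of contig sequences
#' @param bin_of_contig named character vector contig id -> bin id
#' @param params a [crispr_params()]
#' @return flat list of arrays (see [detect_arrays()])
#' @export
detect_crispr <- function(contigs, bin_of_contig = NULL,
                          params = crispr_params()) {
  out <- list()
  for (id in names(contigs)) {
    bid <- if (is.null(bin_of_contig)) NA_character_ else bin_of_contig[[id]]
    out <- c(out, detect_arrays(contigs[[id]], params, bin_id = bid,
                                contig_id = id))
  }
  out
}

#' Spacer table from detected arrays
#'
#' One row per spacer; duplicate spacer sequences are retained because
#' provenance (which bin and array a spacer came from) matters downstream.
#'
#' @param arrays list of arrays from [detect_arrays()]
#' @return data.frame(bin_id, contig_id, array_index, spacer_index, sequence)
#' @export
extract_spacers <- function(arrays) {
  empty <- data.frame(bin_id = character(0), contig_id = character(0),
                      array_index = integer(0), spacer_index = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (length(arrays) == 0L) return(empty)
  rows <- lapply(seq_along(arrays), function(ai) {
    a <- arrays[[ai]]
    if (nrow(a$spacers) == 0L) return(NULL)
    data.frame(bin_id = a$bin_id, contig_id = a$contig_id, array_index = ai,
               spacer_index = seq_len(nrow(a$spacers)),
               sequence = a$spacers$sequence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Export arrays as GFF3
#'
#' One `repeat_region` feature per array with child `direct_repeat` features;
#' coordinates are converted to GFF3's 1-based inclusive convention.
#'
#' @param arrays list of arrays from [detect_arrays()]
#' @param file output path
#' @export
crispr_gff3 <- function(arrays, file) {
  lines <- "##gff-version 3"
  for (ai in seq_along(arrays)) {
    a <- arrays[[ai]]
    rid <- paste0("crispr", ai)
    lines <- c(lines, paste(
      a$contig_id, "mecphage", "repeat_region", a$start + 1L, a$end, ".",
      ".", ".", paste0("ID=", rid, ";rpt_family=CRISPR"), sep = "\t"))
    for (ri in seq_len(nrow(a$repeats))) {
      s <- a$repeats$start[ri]
      lines <- c(lines, paste(
        a$contig_id, "mecphage", "direct_repeat", s + 1L,
        s + nchar(a$repeats$sequence[ri]), ".", ".", ".",
        paste0("ID=", rid, "_r", ri, ";Parent=", rid), sep = "\t"))
    }
  }
  writeLines(lines, file)
  invisible(file)
}
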