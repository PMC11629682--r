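# Homology operations built on canonical k-mers and mismatch-tolerant string
# matching: prophage-region calling by k-mer containment of known phages in
# bin contigs, prophage-vs-VLP induction matching (sketch ANI + containment),
# and spacer-to-protospacer matching on both strands.

#' Prophage-calling parameters
#'
#' @param k k-mer size for containment (17)
#' @param window window length (bp) for the containment scan (500)
#' @param window_containment fraction of window k-mers that must match to
#'   seed a candidate region (0.5)
#' @param max_gap matches separated by more than this many bp are split into
#'   separate regions (500)
#' @param min_len minimum reported region length, mirrors the >= 5 kb phage
#'   filter (5000)
#' @export
prophage_params <- function(k = 17L, window = 500L, window_containment = 0.5,
                            max_gap = 500L, min_len = 5000L) {
  list(k = k, window = window, window_containment = window_containment,
       max_gap = max_gap, min_len = min_len)
}

#' Detect prophage regions in bin contigs by homology to known phages
#'
#' For each phage, positions of bin-contig k-mers present in the phage's
#' k-mer set are clustered (gap <= max_gap); clusters are kept when their
#' windowed containment reaches the threshold and their span is >= min_len.
#' Overlapping calls for the same phage are merged by the gap rule.
#'
#' @param contigs named character vector of bin contig sequences
#' @param phage_seqs named character vector of phage contig sequences
#' @param params a [prophage_params()]
#' @param bin_of_contig optional named map contig id -> bin id
#' @return data.frame(bin_id, contig_id, start, end, phage_id, containment,
#'   mean_identity); coordinates 0-based half-open
#' @export
detect_prophage_regions <- function(contigs, phage_seqs,
                                    params = prophage_params(),
                                    bin_of_contig = NULL) {
  if (length(phage_seqs) == 0L) {
    mp_stop("invalid-input", "phage_set must be non-empty")
  }
  p <- params
  contig_codes <- lapply(contigs, kmer_codes, k = p$k)
  rows <- list()
  for (ph in names(phage_seqs)) {
    pc <- unique(kmer_codes(phage_seqs[[ph]], p$k))
    pc <- pc[!is.na(pc)]
    if (length(pc) == 0L) next
    for (ci in names(contigs)) {
      cc <- contig_codes[[ci]]
      if (length(cc) == 0L) next
      hit <- which(!is.na(cc) & cc %in% pc)
      if (length(hit) < p$min_len / 2L) next
      # cluster hit positions by gap
      brk <- which(diff(hit) > p$max_gap)
      cl_start <- c(1L, brk + 1L)
      cl_end <- c(brk, length(hit))
      for (g in seq_along(cl_start)) {
        h <- hit[cl_start[g]:cl_end[g]]
        s <- h[1L] - 1L              # 0-based
        e <- h[length(h)] - 1L + p$k # 0-based half-open, end of last k-mer
        if (e - s < p$min_len) next
        n_pos <- e - s - p$k + 1L
        dens <- length(h) / n_pos
        if (dens < p$window_containment) next
        containment <- mean(pc %in% cc[h])
        rows[[length(rows) + 1L]] <- data.frame(
          bin_id = if (is.null(bin_of_contig)) NA_character_ else
            bin_of_contig[[ci]],
          contig_id = ci, start = s, end = e, phage_id = ph,
          containment = containment,
          mean_identity = min(100, 100 * dens^(1 / p$k)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(bin_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      phage_id = character(0), containment = numeric(0),
                      mean_identity = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig_id, out$start, out$phage_id), , drop = FALSE]
}

#' Match a prophage-region sequence against VLP contigs (induction)
#'
#' A VLP contig matches when sketch ANI >= `ani_min` and the matched-region
#' coverage of the shorter sequence in the longer (see
#' [kmer_coverage()]) is >= `containment_min`.
#' The paper-level criterion "also detected among the VLP" has no stated
#' operational threshold; these defaults are this package's documented
#' choice.
#'
#' @param prophage_seq character scalar (the region sequence)
#' @param vlp_seqs named character vector of VLP contig sequences
#' @param k,sketch_size sketch parameters
#' @param ani_min,containment_min match thresholds
#' @return data.frame(vlp_contig_id, ani, containment) of matches only
#' @export
match_induction <- function(prophage_seq, vlp_seqs, k = 17L,
                            sketch_size = 1000L, ani_min = 95,
                            containment_min = 0.8) {
  out <- data.frame(vlp_contig_id = character(0), ani = numeric(0),
                    containment = numeric(0), stringsAsFactors = FALSE)
  if (length(vlp_seqs) == 0L || nchar(prophage_seq) < k) return(out)
  sp <- sketch(prophage_seq, k, sketch_size, "prophage")
  for (v in names(vlp_seqs)) {
    if (nchar(vlp_seqs[[v]]) < k) next
    ani <- estimate_ani(sp, sketch(vlp_seqs[[v]], k, sketch_size, v))$ani
    if (ani < ani_min) next
    shorter_first <- nchar(prophage_seq) <= nchar(vlp_seqs[[v]])
    cont <- if (shorter_first) {
      kmer_coverage(prophage_seq, vlp_seqs[[v]], k)
    } else {
      kmer_coverage(vlp_seqs[[v]], prophage_seq, k)
    }
    if (cont >= containment_min) {
      out <- rbind(out, data.frame(vlp_contig_id = v, ani = ani,
                                   containment = cont,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

count_mismatches <- function(a, b) {
  xa <- strsplit(a, "", fixed = TRUE)[[1]]
  xb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(xa != xb)
}

#' Match CRISPR spacers to phage contigs (protospacer search)
#'
#' Full-length, ungapped scan of both strands of every phage contig; every
#' placement with at most `max_mismatches` substitutions is reported (no
#' best-hit collapsing). Ambiguous bases never match.
#'
#' @param spacers data.frame from [extract_spacers()] (columns bin_id,
#'   array_index, spacer_index, sequence; spacer lengths 26-50)
#' @param phage_seqs named character vector of phage contig sequences
#' @param max_mismatches default 1
#' @return data.frame(bin_id, array_index, spacer_index, sequence,
#'   phage_contig_id, position, strand, mismatches); position is the 0-based
#'   start of the match on the forward strand of the phage contig
#' @export
match_spacers <- function(spacers, phage_seqs, max_mismatches = 1L) {
  empty <- data.frame(bin_id = character(0), array_index = integer(0),
                      spacer_index = integer(0), sequence = character(0),
                      phage_contig_id = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(spacers) == 0L || length(phage_seqs) == 0L) return(empty)
  if (any(nchar(spacers$sequence) < 26L | nchar(spacers$sequence) > 50L)) {
    mp_stop("invalid-input", "spacer lengths must lie in [26, 50]")
  }
  subjects <- lapply(phage_seqs, Biostrings::DNAString)
  rows <- list()
  for (si in seq_len(nrow(spacers))) {
    pat <- Biostrings::DNAString(spacers$sequence[si])
    pats <- list(`+` = pat, `-` = Biostrings::reverseComplement(pat))
    for (pid in names(subjects)) {
      for (strand in c("+", "-")) {
        mt <- Biostrings::matchPattern(pats[[strand]], subjects[[pid]],
                                       max.mismatch = max_mismatches,
                                       with.indels = FALSE)
        if (length(mt) == 0L) next
        starts <- Biostrings::start(mt)
        matched <- as.character(mt)
        mm <- vapply(matched, count_mismatches,
                     b = as.character(pats[[strand]]), integer(1),
                     USE.NAMES = FALSE)
        keep <- mm <= max_mismatches
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          bin_id = spacers$bin_id[si], array_index = spacers$array_index[si],
          spacer_index = spacers$spacer_index[si],
          sequence = spacers$sequence[si], phage_contig_id = pid,
          position = starts[keep] - 1L, strand = strand,
          mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
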