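# Quality filtering and ANI-based species clustering with representative
# selection: average-linkage hierarchical clustering on d = 1 - ANI/100 cut
# at 0.05 (the 95% species boundary), dRep-style representative scoring for
# prokaryotes and highest-CheckV-completeness for phages, and the
# ">70% completeness and <10% contamination" species retention rule.

#' Filter phage contigs by length and viral gene content
#'
#' Keeps contigs with length >= 5000 and at least one viral gene ("at least"
#' is inclusive on both boundaries). Order is preserved.
#'
#' @param phage_meta data.frame with columns contig_id, viral_gene_count and
#'   either a `length` column or sequences supplied via `seqs`
#' @param seqs optional named character vector to derive lengths from
#' @param min_len minimum length, default 5000
#' @return the retained rows of `phage_meta`
#' @export
filter_phage_contigs <- function(phage_meta, seqs = NULL, min_len = 5000L) {
  len <- if (!is.null(phage_meta$length)) phage_meta$length
  else nchar(seqs[phage_meta$contig_id])
  keep <- len >= min_len & phage_meta$viral_gene_count >= 1L
  phage_meta[keep, , drop = FALSE]
}

#' Cluster genomes/contigs into species at an ANI threshold
#'
#' Average-linkage hierarchical clustering on distance 1 - ANI/100, cut at
#' 1 - threshold/100 (default 0.05). Pairs absent from `ani` are treated as
#' ANI 0. Deterministic given the input ids: cluster ids are assigned in
#' order of each cluster's lexicographically smallest member.
#'
#' @param ids character vector of item ids
#' @param ani data.frame(id_a, id_b, ani) (symmetric pairs, each once)
#' @param threshold ANI percent threshold, default 95
#' @param prefix species id prefix, e.g. "sp" or "ph"
#' @return data.frame(member_id, species_id)
#' @export
cluster_species <- function(ids, ani, threshold = 95, prefix = "sp") {
  n <- length(ids)
  stopifnot(n >= 1L, !anyDuplicated(ids))
  if (n == 1L) {
    return(data.frame(member_id = ids, species_id = paste0(prefix, "001"),
                      stringsAsFactors = FALSE))
  }
  D <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  if (nrow(ani)) {
    ia <- match(ani$id_a, ids)
    ib <- match(ani$id_b, ids)
    ok <- !is.na(ia) & !is.na(ib)
    d <- 1 - ani$ani[ok] / 100
    D[cbind(ia[ok], ib[ok])] <- d
    D[cbind(ib[ok], ia[ok])] <- d
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  grp <- stats::cutree(hc, h = 1 - threshold / 100)
  # deterministic ids ordered by smallest member id
  first <- vapply(split(ids, grp), min, character(1))
  newid <- rank(first)
  sp <- sprintf("%s%03d", prefix, newid[as.character(grp)])
  data.frame(member_id = ids, species_id = sp, stringsAsFactors = FALSE)
}

n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Select a species representative
#'
#' Prokaryotes maximize completeness - 5 x contamination +
#' 0.5 x log10(N50); phages maximize CheckV completeness. Ties are broken by
#' total length, then lexicographic id.
#'
#' @param member_ids cluster member ids
#' @param metadata for prokaryotes: data.frame(bin_id, completeness,
#'   contamination); for phages: data.frame(contig_id, completeness)
#' @param lengths named list (id -> vector of contig lengths) for
#'   prokaryotes, or named numeric (id -> length) for phages
#' @param kind "prokaryote" or "phage"
#' @return the representative id
#' @export
select_representative <- function(member_ids, metadata, lengths,
                                  kind = c("prokaryote", "phage")) {
  kind <- match.arg(kind)
  stopifnot(length(member_ids) >= 1L)
  if (kind == "prokaryote") {
    i <- match(member_ids, metadata$bin_id)
    score <- metadata$completeness[i] - 5 * metadata$contamination[i] +
      0.5 * log10(vapply(lengths[member_ids], n50, numeric(1)))
    total <- vapply(lengths[member_ids], sum, numeric(1))
  } else {
    i <- match(member_ids, metadata$contig_id)
    score <- metadata$completeness[i]
    total <- unlist(lengths[member_ids])
  }
  ord <- order(-score, -total, member_ids)
  member_ids[ord[1L]]
}

#' Retain prokaryote species clusters by bin quality
#'
#' A cluster is kept iff at least one member has completeness > 70 and
#' contamination < 10 (strict inequalities, as printed).
#'
#' @param clusters data.frame(member_id, species_id)
#' @param metadata data.frame(bin_id, completeness, contamination)
#' @return the retained rows of `clusters`
#' @export
retain_prokaryote_species <- function(clusters, metadata) {
  i <- match(clusters$member_id, metadata$bin_id)
  good <- metadata$completeness[i] > 70 & metadata$contamination[i] < 10
  keep_sp <- unique(clusters$species_id[good])
  clusters[clusters$species_id %in% keep_sp, , drop = FALSE]
}
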