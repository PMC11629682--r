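# Host-phage association network. Evidence classes: "prophage" (temperate
# phage detected inside a member bin), "induced_prophage" (that prophage also
# found among the VLP contigs) and "crispr_match" (spacer-protospacer match,
# evidence of a past infection). Edges live at species level; multiple
# supporting records collapse onto one (host, phage, evidence) row.

.empty_edges <- function() {
  data.frame(host_species = character(0), phage_species = character(0),
             evidence = character(0), n_support = integer(0),
             support = character(0), stringsAsFactors = FALSE)
}

collapse_edges <- function(host, phage, evidence, support) {
  if (length(host) == 0L) return(.empty_edges())
  key <- paste(host, phage, evidence, sep = "\r")
  ord <- order(key)
  agg <- tapply(support[ord], key[ord], function(x)
    paste(sort(unique(x)), collapse = ";"))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(host_species = vapply(parts, `[`, "", 1L),
             phage_species = vapply(parts, `[`, "", 2L),
             evidence = vapply(parts, `[`, "", 3L),
             n_support = vapply(strsplit(unname(agg), ";"), length, 1L),
             support = unname(agg), stringsAsFactors = FALSE)
}

#' Species-level lifestyle call under the OR rule
#'
#' A phage species counts as temperate when ANY member contig is labelled
#' temperate by ANY of the supplied predictor columns (mirroring "identified
#' as temperate by PhaTYP, VIBRANT, or PhageBoost").
#'
#' @param phage_meta data.frame with contig_id and any subset of
#'   lifestyle_phatyp / lifestyle_vibrant / lifestyle_phageboost columns
#' @param phage_membership named character vector contig id -> phage species
#' @return named logical vector per phage species
#' @export
species_is_temperate <- function(phage_meta, phage_membership) {
  cols <- intersect(c("lifestyle_phatyp", "lifestyle_vibrant",
                      "lifestyle_phageboost"), names(phage_meta))
  temp_contig <- rep(FALSE, nrow(phage_meta))
  for (cl in cols) temp_contig <- temp_contig | (phage_meta[[cl]] %in% "temperate")
  sp <- phage_membership[phage_meta$contig_id]
  vapply(split(temp_contig, sp), any, logical(1))
}

#' Call prophage associations from detected regions
#'
#' One (host species, phage species, "prophage") edge per pair with at least
#' one supporting region whose phage species is temperate under the OR rule;
#' regions of virulent-by-all phages are excluded and returned in the
#' `excluded` attribute.
#'
#' @param regions data.frame from [detect_prophage_regions()]
#' @param phage_meta phage metadata with lifestyle columns
#' @param bin_membership named character vector bin id -> host species
#' @param phage_membership named character vector phage contig id -> species
#' @return edge data.frame (host_species, phage_species, evidence,
#'   n_support, support) with attribute `excluded`
#' @export
call_prophage_associations <- function(regions, phage_meta, bin_membership,
                                       phage_membership) {
  if (nrow(regions) == 0L) return(.empty_edges())
  host <- unname(bin_membership[regions$bin_id])
  phage <- unname(phage_membership[regions$phage_id])
  if (anyNA(host) || anyNA(phage)) {
    bad <- unique(c(regions$bin_id[is.na(host)],
                    regions$phage_id[is.na(phage)]))
    mp_stop("dangling-reference",
            paste("regions reference unknown species:",
                  paste(bad, collapse = ", ")))
  }
  temperate <- species_is_temperate(phage_meta, phage_membership)
  is_temp <- temperate[phage]
  support <- paste0(regions$contig_id, ":", regions$start, "-", regions$end,
                    "/", regions$phage_id)
  edges <- collapse_edges(host[is_temp], phage[is_temp], "prophage",
                          support[is_temp])
  attr(edges, "excluded") <- data.frame(
    host_species = host[!is_temp], phage_species = phage[!is_temp],
    support = support[!is_temp],
    reason = rep("virulent-by-all-predictors", sum(!is_temp)),
    stringsAsFactors = FALSE)
  edges
}

#' Promote prophage edges with VLP evidence to induced_prophage
#'
#' Adds an "induced_prophage" row for every prophage edge whose (host,
#' phage) pair appears among the induction matches; the prophage evidence is
#' retained. Induction matches without a prophage edge create no edge and
#' are returned in the `orphans` attribute.
#'
#' @param associations edge data.frame
#' @param induction_matches data.frame(host_species, phage_species, support)
#' @return updated edge data.frame with attribute `orphans`
#' @export
promote_induced <- function(associations, induction_matches) {
  pro <- associations[associations$evidence == "prophage", , drop = FALSE]
  if (nrow(induction_matches) == 0L) {
    attr(associations, "orphans") <- induction_matches
    return(associations)
  }
  key_pro <- paste(pro$host_species, pro$phage_species)
  key_ind <- paste(induction_matches$host_species,
                   induction_matches$phage_species)
  hit <- key_ind %in% key_pro
  ind <- induction_matches[hit, , drop = FALSE]
  support <- if ("support" %in% names(ind)) ind$support else
    paste0(ind$host_species, "~", ind$phage_species)
  out <- rbind(associations,
               collapse_edges(ind$host_species, ind$phage_species,
                              "induced_prophage", support))
  attr(out, "orphans") <- induction_matches[!hit, , drop = FALSE]
  out
}

#' Call CRISPR-match associations from spacer hits
#'
#' @param spacer_hits data.frame from [match_spacers()]
#' @param bin_membership named character vector bin id -> host species
#' @param phage_membership named character vector phage contig id -> species
#' @param phage_dataset optional named character vector contig id -> dataset;
#'   with `vlp_only = TRUE` (the default, matching the network figure logic)
#'   only hits against VLP-dataset contigs produce edges
#' @param vlp_only restrict to VLP-dataset phages
#' @return edge data.frame, one row per (host, phage) pair with all
#'   supporting spacer hits collapsed
#' @export
call_crispr_associations <- function(spacer_hits, bin_membership,
                                     phage_membership, phage_dataset = NULL,
                                     vlp_only = TRUE) {
  if (nrow(spacer_hits) == 0L) return(.empty_edges())
  hits <- spacer_hits
  if (vlp_only && !is.null(phage_dataset)) {
    hits <- hits[phage_dataset[hits$phage_contig_id] %in% "VLP", ,
                 drop = FALSE]
  }
  if (nrow(hits) == 0L) return(.empty_edges())
  host <- unname(bin_membership[hits$bin_id])
  phage <- unname(phage_membership[hits$phage_contig_id])
  if (anyNA(host) || anyNA(phage)) {
    mp_stop("dangling-reference", "spacer hits reference unknown ids")
  }
  support <- paste0(hits$bin_id, ".a", hits$array_index, ".s",
                    hits$spacer_index, "@", hits$phage_contig_id, ":",
                    hits$position, hits$strand)
  collapse_edges(host, phage, "crispr_match", support)
}

#' Summarize associated-phage abundance among the VLP
#'
#' Per VLP sample, sums the relative abundance of phage species associated
#' with (a) anode-affiliated hosts, (b) cathode-affiliated hosts, (c)
#' non-electrode hosts and (d) no host. A phage associated with hosts in
#' several categories counts in each (categories may overlap by design).
#'
#' @param edges edge data.frame
#' @param phage_abundance phage species x VLP sample percent matrix
#' @param affiliation data.frame(species_id, call) for host species
#' @return list with `per_sample` (category x sample matrix) and `range`
#'   (data.frame category, min, max across samples)
#' @export
summarize_network_abundance <- function(edges, phage_abundance, affiliation) {
  call_of <- stats::setNames(affiliation$call, affiliation$species_id)
  phages <- rownames(phage_abundance)
  cat_sets <- list(
    anode_associated = unique(edges$phage_species[
      call_of[edges$host_species] %in% "anode"]),
    cathode_associated = unique(edges$phage_species[
      call_of[edges$host_species] %in% "cathode"]),
    nonelectrode_associated = unique(edges$phage_species[
      call_of[edges$host_species] %in% "none"]))
  cat_sets$unassociated <- setdiff(phages, unique(edges$phage_species))
  per_sample <- t(vapply(cat_sets, function(set) {
    colSums(phage_abundance[intersect(set, phages), , drop = FALSE])
  }, numeric(ncol(phage_abundance))))
  rng <- data.frame(category = rownames(per_sample),
                    min = apply(per_sample, 1L, min),
                    max = apply(per_sample, 1L, max),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(per_sample = per_sample, range = rng)
}

#' Write / read an association edge list (TSV round-trip)
#' @param edges edge data.frame
#' @param file path
#' @export
write_edges <- function(edges, file) {
  utils::write.table(edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_edges
#' @export
read_edges <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE,
                    colClasses = c(host_species = "character",
                                   phage_species = "character",
                                   evidence = "character",
                                   n_support = "integer",
                                   support = "character"))
}

#' Export the association network as GraphML
#'
#' Nodes are host and phage species (attribute `kind`); edges carry the
#' evidence class and support count.
#'
#' @param edges edge data.frame
#' @param file output path
#' @export
write_graphml <- function(edges, file) {
  nodes <- data.frame(
    name = c(unique(edges$host_species), unique(edges$phage_species)),
    kind = c(rep("host", length(unique(edges$host_species))),
             rep("phage", length(unique(edges$phage_species)))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("host_species", "phage_species", "evidence", "n_support")],
    directed = FALSE, vertices = nodes)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
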