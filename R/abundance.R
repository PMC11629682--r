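# Relative abundance aggregation and electrode-affiliation classification.
# A species is putatively electrode-affiliated when its mean relative
# abundance on an electrode exceeds 0.1% and both its mean and maximum
# abundance there exceed those in the tubing, suspension and inoculum
# samples (strict inequalities throughout).

#' Aggregate read counts into species relative abundances (percent)
#'
#' abundance(species, sample) = 100 x sum of counts over member contigs /
#' total counts in the sample. Counts on contigs not mapped to any species
#' form the reported "unassigned" remainder, so column sums can be < 100.
#'
#' @param counts contig x sample count matrix
#' @param contig_species named character vector contig id -> species id
#'   (contigs absent from the map count as unassigned)
#' @return matrix species x sample of percentages, with attribute
#'   `unassigned` (named numeric, percent per sample)
#' @export
species_abundance <- function(counts, contig_species) {
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    mp_stop("empty-sample",
            paste("samples with zero total counts:",
                  paste(colnames(counts)[totals <= 0], collapse = ", ")))
  }
  sp <- contig_species[rownames(counts)]
  assigned <- !is.na(sp)
  agg <- rowsum(counts[assigned, , drop = FALSE], group = sp[assigned])
  pct <- sweep(agg, 2L, totals, "/") * 100
  attr(pct, "unassigned") <- 100 - colSums(pct)
  pct
}

#' Classify electrode-affiliated species
#'
#' For each electrode E in {anode, cathode}: a species passes for E iff
#' mean_E > `min_mean` AND mean_E > mean_NE AND max_E > max_NE, where NE is
#' the union of tubing, suspension and inoculum samples. A species passing
#' for both electrodes is assigned the electrode with the larger mean
#' (tie -> anode).
#'
#' @param abundance species x sample percent matrix (see
#'   [species_abundance()])
#' @param manifest data.frame(sample_id, mec_id, location, dataset); only
#'   samples present as columns are used
#' @param min_mean electrode mean threshold in percent, default 0.1
#' @return data.frame(species_id, call, mean_anode, max_anode, mean_cathode,
#'   max_cathode, mean_ne, max_ne)
#' @export
classify_affiliation <- function(abundance, manifest, min_mean = 0.1) {
  loc <- manifest$location[match(colnames(abundance), manifest$sample_id)]
  an <- which(loc == "anode")
  ca <- which(loc == "cathode")
  ne <- which(loc %in% c("tubing", "suspension", "inoculum"))
  if (length(an) < 1L || length(ca) < 1L || length(ne) < 1L) {
    mp_stop("invalid-input",
            "need at least one anode, one cathode and one non-electrode sample")
  }
  stat <- function(idx, f) apply(abundance[, idx, drop = FALSE], 1L, f)
  mean_an <- stat(an, mean); max_an <- stat(an, max)
  mean_ca <- stat(ca, mean); max_ca <- stat(ca, max)
  mean_ne <- stat(ne, mean); max_ne <- stat(ne, max)
  pass_an <- mean_an > min_mean & mean_an > mean_ne & max_an > max_ne
  pass_ca <- mean_ca > min_mean & mean_ca > mean_ne & max_ca > max_ne
  call <- ifelse(pass_an & pass_ca,
                 ifelse(mean_ca > mean_an, "cathode", "anode"),
                 ifelse(pass_an, "anode",
                        ifelse(pass_ca, "cathode", "none")))
  data.frame(species_id = rownames(abundance), call = call,
             mean_anode = mean_an, max_anode = max_an,
             mean_cathode = mean_ca, max_cathode = max_ca,
             mean_ne = mean_ne, max_ne = max_ne,
             row.names = NULL, stringsAsFactors = FALSE)
}
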