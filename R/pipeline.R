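# Dataset I/O with validation, pipeline configuration, and end-to-end
# orchestration: filter -> cluster -> CRISPR -> matching -> abundances ->
# affiliation -> network -> diversity -> prevalence, with every stage's
# tables written to a results directory plus a machine-readable summary.

#' Pipeline configuration
#'
#' All module parameters in one serializable list. Defaults follow the
#' analysis conventions: 95% ANI species threshold, >= 5 kb phage filter,
#' 0.1% electrode-affiliation mean threshold, completeness groups of 36,
#' diversity orders {0, 1, 2}, at most 1 spacer mismatch.
#'
#' @param ani_threshold species ANI threshold (percent)
#' @param phage_min_len minimum phage contig length (bp)
#' @param affiliation_min_mean electrode mean abundance threshold (percent)
#' @param group_size completeness group size for prevalence curves
#' @param q_orders diversity orders
#' @param max_mismatches spacer matching mismatch budget
#' @param n_perm Mantel permutations
#' @param k,sketch_size k-mer sketch parameters
#' @param crispr_vlp_only restrict CRISPR edges to VLP-dataset phages
#' @param seed master seed
#' @export
pipeline_config <- function(ani_threshold = 95, phage_min_len = 5000L,
                            affiliation_min_mean = 0.1, group_size = 36L,
                            q_orders = c(0, 1, 2), max_mismatches = 1L,
                            n_perm = 999L, k = 17L, sketch_size = 1000L,
                            crispr_vlp_only = TRUE, seed = 1L) {
  if (ani_threshold <= 50 || ani_threshold > 100 || phage_min_len < 0 ||
      affiliation_min_mean < 0 || group_size < 1 || any(q_orders < 0)) {
    mp_stop("invalid-config", "pipeline parameter out of range")
  }
  list(ani_threshold = ani_threshold, phage_min_len = phage_min_len,
       affiliation_min_mean = affiliation_min_mean, group_size = group_size,
       q_orders = q_orders, max_mismatches = max_mismatches, n_perm = n_perm,
       k = k, sketch_size = sketch_size, crispr_vlp_only = crispr_vlp_only,
       seed = seed)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    mp_stop("invalid-config",
            paste("unknown config keys:", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    mp_stop("missing-column",
            paste0(what, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
}

#' Read and cross-validate a dataset directory
#'
#' Expects the layout written by [write_dataset()]: bins.fasta (headers
#' `binID|contigID`), phages.fasta, bin_metadata.tsv, phage_metadata.tsv,
#' counts.tsv (wide, contig_id first), manifest.tsv. Duplicate ids and
#' dangling references raise named validation errors listing the offenders.
#'
#' @param dir dataset directory
#' @return a `mec_dataset` list (ground-truth tables attached when present)
#' @export
read_inputs <- function(dir) {
  fa <- function(f) {
    x <- Biostrings::readDNAStringSet(file.path(dir, f))
    if (anyDuplicated(names(x))) {
      mp_stop("duplicate-id",
              paste0(f, " has duplicate headers: ",
                     paste(unique(names(x)[duplicated(names(x))]),
                           collapse = ", ")))
    }
    stats::setNames(as.character(x), names(x))
  }
  bins_raw <- fa("bins.fasta")
  parts <- strsplit(names(bins_raw), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    mp_stop("invalid-input", "bin FASTA headers must be 'binID|contigID'")
  }
  bin_of_contig <- stats::setNames(vapply(parts, `[`, "", 1L),
                                   vapply(parts, `[`, "", 2L))
  bin_seqs <- stats::setNames(unname(bins_raw), names(bin_of_contig))
  phage_seqs <- fa("phages.fasta")

  tsv <- function(f) utils::read.delim(file.path(dir, f),
                                       stringsAsFactors = FALSE,
                                       check.names = FALSE)
  bin_meta <- tsv("bin_metadata.tsv")
  require_columns(bin_meta, c("bin_id", "sample_id", "completeness",
                              "contamination"), "bin_metadata.tsv")
  phage_meta <- tsv("phage_metadata.tsv")
  require_columns(phage_meta, c("contig_id", "dataset", "viral_gene_count",
                                "completeness"), "phage_metadata.tsv")
  manifest <- tsv("manifest.tsv")
  require_columns(manifest, c("sample_id", "mec_id", "location", "dataset"),
                  "manifest.tsv")
  cnt <- tsv("counts.tsv")
  require_columns(cnt, "contig_id", "counts.tsv")
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$contig_id

  dup <- function(x, what) {
    if (anyDuplicated(x)) {
      mp_stop("duplicate-id", paste0("duplicate ", what, ": ",
                                     paste(unique(x[duplicated(x)]),
                                           collapse = ", ")))
    }
  }
  dup(bin_meta$bin_id, "bin ids")
  dup(phage_meta$contig_id, "phage contig ids")
  dup(manifest$sample_id, "sample ids")
  dup(rownames(counts), "count contig ids")
  key <- paste(manifest$mec_id, manifest$location, manifest$dataset)
  dup(key, "(mec, location, dataset) sample records")

  dangle <- function(bad, what) {
    if (length(bad)) {
      mp_stop("dangling-reference",
              paste0(what, ": ", paste(bad, collapse = ", ")))
    }
  }
  dangle(setdiff(bin_meta$bin_id, unique(bin_of_contig)),
         "bin metadata references absent bins")
  dangle(setdiff(unique(bin_of_contig), bin_meta$bin_id),
         "bins lacking metadata")
  dangle(setdiff(phage_meta$contig_id, names(phage_seqs)),
         "phage metadata references absent contigs")
  dangle(setdiff(names(phage_seqs), phage_meta$contig_id),
         "phage contigs lacking metadata")
  dangle(setdiff(rownames(counts),
                 c(names(bin_seqs), names(phage_seqs))),
         "count rows reference unknown contigs")
  dangle(setdiff(colnames(counts), manifest$sample_id),
         "count columns reference unknown samples")
  bad_loc <- setdiff(unique(manifest$location),
                     c("anode", "cathode", "tubing", "suspension",
                       "inoculum", "foam"))
  if (length(bad_loc)) {
    mp_stop("invalid-input",
            paste("unknown sample locations:", paste(bad_loc, collapse = ", ")))
  }

  gt <- list()
  for (f in list.files(dir, pattern = "^gt_.*\\.tsv$")) {
    gt[[sub("^gt_(.*)\\.tsv$", "\\1", f)]] <- tsv(f)
  }
  structure(list(bin_seqs = bin_seqs, bin_of_contig = bin_of_contig,
                 bin_meta = bin_meta, phage_seqs = phage_seqs,
                 phage_meta = phage_meta, counts = counts,
                 manifest = manifest,
                 ground_truth = if (length(gt)) gt else NULL),
            class = "mec_dataset")
}

# concatenate a bin's contigs with N runs so no chimeric k-mers form
bin_super_seq <- function(contigs, k) {
  paste(contigs, collapse = strrep("N", k))
}

stage_wrap <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0("stage '", name, "' failed: ",
                               conditionMessage(e)),
                        class = c(class(e)[1], "pipeline-stage-error")))
  })
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order and writes every table, the
#' network exports, a machine-readable JSON summary and a run log to
#' `out_dir`.
#'
#' @param dataset a `mec_dataset` (from [generate_dataset()] or
#'   [read_inputs()]) or a dataset directory path
#' @param out_dir results directory
#' @param config a [pipeline_config()]
#' @return the summary list, invisibly; all outputs on disk
#' @export
run_pipeline <- function(dataset, out_dir, config = pipeline_config()) {
  if (is.character(dataset)) dataset <- read_inputs(dataset)
  stopifnot(inherits(dataset, "mec_dataset"))
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv_out <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  log_lines <- c(paste0("mecphage ",
                        as.character(utils::packageVersion("mecphage"))),
                 paste0("seed: ", cfg$seed),
                 paste0("parameters: ",
                        jsonlite::toJSON(cfg, auto_unbox = TRUE)))

  ## 1. filter phage contigs
  phage_keep <- stage_wrap("filter", filter_phage_contigs(
    dataset$phage_meta, seqs = dataset$phage_seqs,
    min_len = cfg$phage_min_len))
  phage_seqs <- dataset$phage_seqs[phage_keep$contig_id]
  log_lines <- c(log_lines, sprintf("phage contigs kept: %d of %d",
                                    nrow(phage_keep),
                                    nrow(dataset$phage_meta)))

  ## 2. cluster phages and bins at the ANI threshold
  clusters <- stage_wrap("cluster", {
    ph_ani <- ani_table(phage_seqs, cfg$k, cfg$sketch_size)
    ph_cl <- cluster_species(names(phage_seqs), ph_ani, cfg$ani_threshold,
                             prefix = "ph")
    bin_ids <- unique(dataset$bin_of_contig)
    bin_seq <- vapply(bin_ids, function(b) {
      bin_super_seq(dataset$bin_seqs[names(dataset$bin_of_contig)[
        dataset$bin_of_contig == b]], cfg$k)
    }, character(1))
    bin_ani <- ani_table(bin_seq, cfg$k, cfg$sketch_size)
    pro_cl <- cluster_species(bin_ids, bin_ani, cfg$ani_threshold,
                              prefix = "sp")
    list(phage = ph_cl, prok = pro_cl)
  })
  prok_cl <- stage_wrap("retain", retain_prokaryote_species(
    clusters$prok, dataset$bin_meta))
  bin_lengths <- lapply(
    stats::setNames(unique(dataset$bin_of_contig),
                    unique(dataset$bin_of_contig)),
    function(b) nchar(dataset$bin_seqs[names(dataset$bin_of_contig)[
      dataset$bin_of_contig == b]]))
  phage_lengths <- nchar(phage_seqs)
  rep_of <- function(cl, kind, meta, lens) {
    vapply(split(cl$member_id, cl$species_id), select_representative,
           character(1), metadata = meta, lengths = lens, kind = kind)
  }
  prok_reps <- rep_of(prok_cl, "prokaryote", dataset$bin_meta, bin_lengths)
  phage_reps <- rep_of(clusters$phage, "phage", phage_keep,
                       as.list(phage_lengths))
  bin_membership <- stats::setNames(prok_cl$species_id, prok_cl$member_id)
  phage_membership <- stats::setNames(clusters$phage$species_id,
                                      clusters$phage$member_id)
  tsv_out(transform(prok_cl,
                    is_representative = member_id %in% prok_reps),
          "clusters_prokaryote.tsv")
  tsv_out(transform(clusters$phage,
                    is_representative = member_id %in% phage_reps),
          "clusters_phage.tsv")

  ## 3. CRISPR arrays and spacers (retained bins only)
  retained_contigs <- names(dataset$bin_of_contig)[
    dataset$bin_of_contig %in% prok_cl$member_id]
  arrays <- stage_wrap("crispr", detect_crispr(
    dataset$bin_seqs[retained_contigs],
    dataset$bin_of_contig[retained_contigs]))
  spacers <- extract_spacers(arrays)
  crispr_gff3(arrays, file.path(out_dir, "crispr.gff3"))
  tsv_out(spacers, "spacers.tsv")

  ## 4. spacer-protospacer matching
  hits <- stage_wrap("match", match_spacers(spacers, phage_seqs,
                                            cfg$max_mismatches))
  tsv_out(hits, "spacer_hits.tsv")

  ## 5. prophage regions and induction
  regions <- stage_wrap("prophage", detect_prophage_regions(
    dataset$bin_seqs[retained_contigs], phage_seqs,
    prophage_params(k = cfg$k, min_len = cfg$phage_min_len),
    dataset$bin_of_contig[retained_contigs]))
  tsv_out(data.frame(contig = regions$contig_id, start = regions$start,
                     end = regions$end,
                     name = sprintf("%s/%s", regions$bin_id,
                                    regions$phage_id),
                     score = round(regions$containment, 4),
                     strand = rep(".", nrow(regions))),
          "prophage_regions.bed")
  vlp_ids <- phage_keep$contig_id[phage_keep$dataset == "VLP"]
  induction <- stage_wrap("induction", {
    if (nrow(regions) == 0L || length(vlp_ids) == 0L) {
      data.frame(host_species = character(0), phage_species = character(0),
                 support = character(0), stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_len(nrow(regions)), function(i) {
        r <- regions[i, ]
        seq <- substr(dataset$bin_seqs[[r$contig_id]], r$start + 1L, r$end)
        m <- match_induction(seq, phage_seqs[vlp_ids], cfg$k,
                             cfg$sketch_size)
        if (nrow(m) == 0L) return(NULL)
        data.frame(host_species = bin_membership[[r$bin_id]],
                   phage_species = phage_membership[[r$phage_id]],
                   support = paste0(r$contig_id, ":", r$start, "-", r$end,
                                    "~", m$vlp_contig_id),
                   stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) do.call(rbind, rows) else
        data.frame(host_species = character(0),
                   phage_species = character(0), support = character(0),
                   stringsAsFactors = FALSE)
    }
  })

  ## 6. abundances and affiliation
  prok_samples <- dataset$manifest$sample_id[
    dataset$manifest$dataset == "prokaryotic"]
  vlp_samples <- dataset$manifest$sample_id[dataset$manifest$dataset == "VLP"]
  contig_sp <- stats::setNames(
    bin_membership[dataset$bin_of_contig[names(dataset$bin_of_contig)]],
    names(dataset$bin_of_contig))
  prok_abund <- stage_wrap("abundance", species_abundance(
    dataset$counts[names(dataset$bin_seqs),
                   intersect(prok_samples, colnames(dataset$counts)),
                   drop = FALSE],
    contig_sp))
  tsv_out(data.frame(species_id = rownames(prok_abund), prok_abund,
                     check.names = FALSE), "abundance_prokaryote.tsv")
  affiliation <- stage_wrap("affiliate", classify_affiliation(
    prok_abund, dataset$manifest, cfg$affiliation_min_mean))
  tsv_out(affiliation, "affiliation.tsv")
  phage_abund <- NULL
  if (length(vlp_samples) && length(phage_seqs)) {
    vs <- intersect(vlp_samples, colnames(dataset$counts))
    vtot <- colSums(dataset$counts[names(phage_seqs), vs, drop = FALSE])
    vs <- vs[vtot > 0]
    if (length(vs)) {
      phage_abund <- stage_wrap("abundance", species_abundance(
        dataset$counts[names(phage_seqs), vs, drop = FALSE],
        phage_membership))
      tsv_out(data.frame(species_id = rownames(phage_abund), phage_abund,
                         check.names = FALSE), "abundance_phage.tsv")
    }
  }

  ## 7. association network
  edges <- stage_wrap("associate", {
    e <- call_prophage_associations(regions, phage_keep, bin_membership,
                                    phage_membership)
    e <- promote_induced(e, induction)
    ce <- call_crispr_associations(
      hits, bin_membership, phage_membership,
      stats::setNames(phage_keep$dataset, phage_keep$contig_id),
      vlp_only = cfg$crispr_vlp_only)
    rbind(e, ce)
  })
  write_edges(edges, file.path(out_dir, "edges.tsv"))
  if (nrow(edges)) write_graphml(edges, file.path(out_dir, "network.graphml"))
  net_abund <- if (!is.null(phage_abund) && nrow(edges)) {
    summarize_network_abundance(edges, phage_abund,
                                affiliation[, c("species_id", "call")])
  } else NULL
  if (!is.null(net_abund)) tsv_out(net_abund$range, "network_abundance.tsv")

  ## 8. diversity
  mecs <- unique(dataset$manifest$mec_id[dataset$manifest$dataset == "VLP"])
  div <- stage_wrap("diversity", {
    out <- list()
    for (q in cfg$q_orders) {
      qn <- paste0("q", q)
      if (!is.null(phage_abund) && ncol(phage_abund) >= 2L) {
        D <- dissimilarity_matrix(phage_abund, q)
        tsv_out(data.frame(sample = rownames(D), D, check.names = FALSE),
                paste0("dissimilarity_phage_", qn, ".tsv"))
        out[[paste0("phage_", qn)]] <- D
      }
      for (loc in c("anode", "cathode")) {
        smp <- dataset$manifest$sample_id[
          dataset$manifest$dataset == "prokaryotic" &
            dataset$manifest$location == loc]
        smp <- intersect(smp, colnames(prok_abund))
        if (length(smp) >= 2L) {
          D <- dissimilarity_matrix(prok_abund, q, smp)
          tsv_out(data.frame(sample = rownames(D), D, check.names = FALSE),
                  paste0("dissimilarity_", loc, "_", qn, ".tsv"))
          out[[paste0(loc, "_", qn)]] <- D
        }
      }
    }
    out
  })
  correlations <- list()
  for (q in cfg$q_orders) {
    qn <- paste0("q", q)
    for (loc in c("anode", "cathode")) {
      dp <- div[[paste0("phage_", qn)]]
      dl <- div[[paste0(loc, "_", qn)]]
      if (is.null(dp) || is.null(dl) || nrow(dp) < 4L) next
      # match by MEC
      mec_of <- stats::setNames(dataset$manifest$mec_id,
                                dataset$manifest$sample_id)
      common <- intersect(mec_of[rownames(dl)], mec_of[rownames(dp)])
      if (length(common) < 4L) next
      il <- rownames(dl)[match(common, mec_of[rownames(dl)])]
      ip <- rownames(dp)[match(common, mec_of[rownames(dp)])]
      da <- dl[il, il]
      db <- dp[ip, ip]
      dimnames(da) <- dimnames(db) <- list(common, common)
      ct <- correlate_dissimilarities(
        da, db, n_perm = cfg$n_perm,
        seed = substream_seed(cfg$seed, paste0("mantel_", loc, "_", qn)))
      correlations[[paste0(loc, "_", qn)]] <- list(r = ct$r, p = ct$p)
    }
  }
  pcoa_out <- NULL
  if (!is.null(div$phage_q1) && nrow(div$phage_q1) >= 3L) {
    pcoa_out <- pcoa(div$phage_q1)
    tsv_out(data.frame(sample = rownames(pcoa_out$coordinates),
                       pcoa_out$coordinates, check.names = FALSE),
            "pcoa_phage_q1.tsv")
  }

  ## 9. prevalence by completeness
  retained_bins <- unique(prok_cl$member_id)
  bins_flagged <- data.frame(
    bin_id = retained_bins,
    completeness = dataset$bin_meta$completeness[
      match(retained_bins, dataset$bin_meta$bin_id)],
    has_prophage = retained_bins %in% regions$bin_id,
    has_crispr = retained_bins %in%
      vapply(arrays, function(a) a$bin_id, character(1)),
    stringsAsFactors = FALSE)
  prev_pro <- prevalence_by_completeness(bins_flagged, "has_prophage",
                                         cfg$group_size)
  prev_cri <- prevalence_by_completeness(bins_flagged, "has_crispr",
                                         cfg$group_size)
  tsv_out(prev_pro, "prevalence_prophage.tsv")
  tsv_out(prev_cri, "prevalence_crispr.tsv")

  ## 10. summary
  ev_counts <- table(edges$evidence)
  med <- function(D) if (is.null(D)) NA_real_ else
    stats::median(D[upper.tri(D)])
  summary <- list(
    n_bins = length(unique(dataset$bin_of_contig)),
    n_species = length(unique(prok_cl$species_id)),
    n_phage_contigs = nrow(phage_keep),
    n_phage_species = length(unique(clusters$phage$species_id)),
    pct_bins_with_prophage = fraction_pct(
      sum(bins_flagged$has_prophage), nrow(bins_flagged)),
    pct_bins_with_crispr = fraction_pct(
      sum(bins_flagged$has_crispr), nrow(bins_flagged)),
    associations = list(
      prophage = as.integer(ev_counts["prophage"] %||% 0L),
      induced_prophage = as.integer(ev_counts["induced_prophage"] %||% 0L),
      crispr_match = as.integer(ev_counts["crispr_match"] %||% 0L),
      hosts = length(unique(edges$host_species)),
      phages = length(unique(edges$phage_species)),
      pairs = nrow(unique(edges[, c("host_species", "phage_species")]))),
    affiliation = list(anode = sum(affiliation$call == "anode"),
                       cathode = sum(affiliation$call == "cathode")),
    dissimilarity_median = lapply(
      stats::setNames(nm = names(div)), function(nm) med(div[[nm]])),
    shared_pct_phage_q1 = if (!is.null(div$phage_q1))
      shared_fraction(med(div$phage_q1)) else NA_integer_,
    correlations = correlations,
    network_abundance = if (!is.null(net_abund)) net_abund$range else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  writeLines(c(log_lines, "status: complete"),
             file.path(out_dir, "run_log.txt"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
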