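# Ground-truthed synthetic MEC community generator. Emits everything the
# downstream pipeline consumes — bin and phage FASTA, metadata tables
# standing in for external-tool outputs (CheckM/CheckV quality, lifestyle
# predictions), a per-contig read-count table, a sample manifest — plus a
# ground-truth manifest of planted prophages, CRISPR arrays/links, induced
# prophages, species memberships and electrode affiliations.
#
# The stated world: nine MECs sampled at anode, cathode, tubing and
# suspension; host genomes are multi-contig drafts whose bins are random
# truncations plus point substitutions (so true ANI is analytically known);
# prophages are mutation-perturbed phage insertions; CRISPR arrays alternate
# a fixed repeat with spacers, some copied verbatim from emitted VLP contigs;
# abundances are log-normal with electrode enrichment for designated
# affiliated species and a modest suspension/tubing enrichment for everything
# else (bulk sludge organisms).

#' Synthetic community configuration
#'
#' Builds and validates the configuration for [generate_dataset()]. Defaults
#' are the package's fixed "stated world" (see the methods vignette); they
#' are deliberately desk-scale.
#'
#' @param n_mecs number of MECs (>= 2), default 9
#' @param n_host_species,n_phage_species planted species counts
#' @param prophage_prob probability a host species carries a prophage
#' @param induction_prob probability a planted prophage is also emitted as a
#'   VLP contig (induction)
#' @param crispr_prob probability a host species carries a CRISPR array
#' @param spacers_per_array integer range (min, max) of spacers per array
#' @param protospacer_match_prob probability a spacer is copied from an
#'   emitted VLP contig (creating a true spacer-protospacer link)
#' @param mutation_rate per-base substitution probability within a species
#'   cluster
#' @param completeness_range percent interval for per-bin retained fraction
#' @param abundance_lognormal named list of c(mu, sigma) per sample type
#'   (anode, cathode, tubing, suspension, inoculum, vlp) for the per-sample
#'   log-normal noise
#' @param affiliation_effect multiplicative electrode enrichment of
#'   affiliated species
#' @param n_affiliated named vector c(anode=, cathode=) of planted affiliated
#'   species
#' @param genome_size_range,n_contigs_range,phage_size_range,bins_per_species
#'   structural ranges of the planted genomes and bins
#' @param vlp_prob probability a phage species is free-living (emitted among
#'   the VLP independently of induction)
#' @param ne_enrichment enrichment of non-affiliated species in
#'   tubing/suspension/inoculum samples
#' @param temperate_frac fraction of phage species that are truly temperate
#' @param predictor_accuracy per-predictor probability of reporting the true
#'   lifestyle
#' @param depth count scale (expected counts per kb at unit abundance)
#' @param include_inoculum,include_foam optional extra samples (off by
#'   default; no downstream statistic in scope uses them)
#' @param seed master seed; all phases derive named substreams from it
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_mecs = 9L,
                         n_host_species = 12L,
                         n_phage_species = 20L,
                         prophage_prob = 0.5,
                         induction_prob = 0.3,
                         crispr_prob = 0.5,
                         spacers_per_array = c(3L, 8L),
                         protospacer_match_prob = 0.7,
                         mutation_rate = 0.005,
                         completeness_range = c(55, 100),
                         abundance_lognormal = NULL,
                         affiliation_effect = 50,
                         n_affiliated = c(anode = 2L, cathode = 2L),
                         genome_size_range = c(40000L, 120000L),
                         n_contigs_range = c(2L, 6L),
                         phage_size_range = c(8000L, 40000L),
                         bins_per_species = c(1L, 4L),
                         vlp_prob = 0.8,
                         ne_enrichment = 3,
                         temperate_frac = 0.6,
                         predictor_accuracy = 0.95,
                         depth = 50,
                         include_inoculum = FALSE,
                         include_foam = FALSE,
                         seed = 1L) {
  if (is.null(abundance_lognormal)) {
    abundance_lognormal <- list(
      anode = c(0, 0.4), cathode = c(0, 0.4), tubing = c(0, 0.4),
      suspension = c(0, 0.4), inoculum = c(0, 0.4), vlp = c(0, 0.6))
  }
  cfg <- list(
    n_mecs = as.integer(n_mecs), n_host_species = as.integer(n_host_species),
    n_phage_species = as.integer(n_phage_species),
    prophage_prob = prophage_prob, induction_prob = induction_prob,
    crispr_prob = crispr_prob,
    spacers_per_array = as.integer(spacers_per_array),
    protospacer_match_prob = protospacer_match_prob,
    mutation_rate = mutation_rate,
    completeness_range = completeness_range,
    abundance_lognormal = abundance_lognormal,
    affiliation_effect = affiliation_effect,
    n_affiliated = n_affiliated,
    genome_size_range = as.integer(genome_size_range),
    n_contigs_range = as.integer(n_contigs_range),
    phage_size_range = as.integer(phage_size_range),
    bins_per_species = as.integer(bins_per_species),
    vlp_prob = vlp_prob, ne_enrichment = ne_enrichment,
    temperate_frac = temperate_frac,
    predictor_accuracy = predictor_accuracy,
    depth = depth,
    include_inoculum = include_inoculum, include_foam = include_foam,
    seed = as.integer(seed))

  probs <- c(cfg$prophage_prob, cfg$induction_prob, cfg$crispr_prob,
             cfg$protospacer_match_prob, cfg$mutation_rate, cfg$vlp_prob)
  if (any(probs < 0 | probs > 1)) {
    mp_stop("invalid-config", "all probabilities must lie in [0,1]")
  }
  if (cfg$n_mecs < 2L) {
    mp_stop("invalid-config", "n_mecs must be >= 2 (pairwise statistics)")
  }
  if (cfg$completeness_range[1] <= 0 || cfg$completeness_range[2] > 100 ||
      diff(cfg$completeness_range) < 0) {
    mp_stop("invalid-config", "completeness_range must lie within (0,100]")
  }
  if (cfg$phage_size_range[1] < 5000L || cfg$phage_size_range[2] > 161000L) {
    mp_stop("invalid-config", "phage sizes must lie within [5, 161] kb")
  }
  structure(cfg, class = "synth_config")
}

prok_locations <- function(cfg) {
  locs <- c("anode", "cathode", "tubing", "suspension")
  if (cfg$include_inoculum) locs <- c(locs, "inoculum")
  if (cfg$include_foam) locs <- c(locs, "foam")
  locs
}

#' Sample manifest for a configuration
#' @keywords internal
build_manifest <- function(cfg) {
  mecs <- paste0("M", seq_len(cfg$n_mecs))
  locs <- prok_locations(cfg)
  prok <- expand.grid(mec_id = mecs, location = locs,
                      stringsAsFactors = FALSE)
  prok <- prok[order(prok$mec_id, prok$location), ]
  prok$dataset <- "prokaryotic"
  prok$sample_id <- paste0(prok$mec_id, "_", prok$location)
  vlp <- data.frame(mec_id = mecs, location = "suspension",
                    dataset = "VLP", sample_id = paste0(mecs, "_vlp"),
                    stringsAsFactors = FALSE)
  out <- rbind(prok[, c("sample_id", "mec_id", "location", "dataset")],
               vlp[, c("sample_id", "mec_id", "location", "dataset")])
  rownames(out) <- NULL
  out
}

#' Truncate a genome to a target completeness
#'
#' Removes contiguous blocks (0.5-3 kb, uniform position, length-weighted
#' contig choice) until the retained fraction matches the target; each
#' internal deletion splits a contig into two pieces, as binning of a
#' fragmented assembly would. Prophage and CRISPR regions are removable like
#' any other region.
#'
#' @param genome named character vector of contig sequences
#' @param completeness_target percent in (0, 100]
#' @param seed RNG seed for this truncation
#' @return list with `contigs` (named character vector, names
#'   `<orig>_p<i>`), `map` (data.frame new_contig, orig_contig, orig_start,
#'   orig_end; 0-based half-open original coordinates), and
#'   `retained_fraction`
#' @export
truncate_bin <- function(genome, completeness_target, seed = 1L) {
  if (completeness_target <= 0 || completeness_target > 100) {
    mp_stop("invalid-input", "completeness_target must be in (0,100]")
  }
  set.seed(seed)
  total <- sum(nchar(genome))
  pieces <- data.frame(orig = names(genome), start = 0,
                       end = nchar(genome), stringsAsFactors = FALSE)
  need <- total - round(total * completeness_target / 100)
  need <- min(need, total - 1L)
  while (need > 0 && nrow(pieces) > 0) {
    lens <- pieces$end - pieces$start
    block <- min(need, round(runif(1, 500, 3000)))
    i <- if (nrow(pieces) == 1L) 1L else sample.int(nrow(pieces), 1L, prob = lens)
    len <- lens[i]
    if (len <= block) {
      need <- need - len
      pieces <- pieces[-i, , drop = FALSE]
    } else {
      at <- pieces$start[i] + sample.int(len - block + 1L, 1L) - 1L
      left <- pieces[i, ]
      right <- pieces[i, ]
      left$end <- at
      right$start <- at + block
      keep <- rbind(left, right)
      keep <- keep[keep$end > keep$start, , drop = FALSE]
      pieces <- rbind(pieces[-i, , drop = FALSE], keep)
      need <- need - block
    }
  }
  pieces <- pieces[order(match(pieces$orig, names(genome)), pieces$start), ,
                   drop = FALSE]
  idx <- stats::ave(seq_len(nrow(pieces)), pieces$orig, FUN = seq_along)
  pieces$new_contig <- paste0(pieces$orig, "_p", idx)
  contigs <- vapply(seq_len(nrow(pieces)), function(i) {
    substr(genome[[pieces$orig[i]]], pieces$start[i] + 1L, pieces$end[i])
  }, character(1))
  names(contigs) <- pieces$new_contig
  list(contigs = contigs,
       map = data.frame(new_contig = pieces$new_contig,
                        orig_contig = pieces$orig,
                        orig_start = pieces$start, orig_end = pieces$end,
                        stringsAsFactors = FALSE),
       retained_fraction = sum(nchar(contigs)) / total)
}

# Map an interval [s, e) on an original contig through a truncation map.
# Returns zero or more rows (new_contig, new_start, new_end, intact).
map_interval <- function(map, orig_contig, s, e) {
  hits <- map[map$orig_contig == orig_contig &
                map$orig_end > s & map$orig_start < e, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  data.frame(new_contig = hits$new_contig,
             new_start = pmax(s, hits$orig_start) - hits$orig_start,
             new_end = pmin(e, hits$orig_end) - hits$orig_start,
             intact = hits$orig_start <= s & hits$orig_end >= e,
             stringsAsFactors = FALSE)
}

draw_lifestyle_labels <- function(true_lifestyle, acc) {
  vapply(true_lifestyle, function(tl) {
    if (runif(1) < acc) tl else setdiff(c("temperate", "virulent"), tl)[1]
  }, character(1))
}

#' Generate a ground-truthed synthetic MEC dataset
#'
#' Deterministic for a fixed config seed (named substreams per phase). If
#' `out_dir` is given, all sequence files, metadata tables, the read-count
#' table, the manifest, the ground truth and the config are written there as
#' FASTA/TSV/YAML (byte-identical across runs).
#'
#' @param config a [synth_config()]
#' @param out_dir optional output directory
#' @return list with elements `bin_seqs` (named character; contig id ->
#'   sequence), `bin_of_contig` (named character), `bin_meta`, `phage_seqs`,
#'   `phage_meta`, `counts` (contig x sample matrix), `manifest`,
#'   `ground_truth` (list of data.frames), `config`
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  if (cfg$prophage_prob > 0 &&
      cfg$phage_size_range[1] > cfg$genome_size_range[2]) {
    mp_stop("infeasible-config",
            "smallest phage cannot fit in the largest possible host contig")
  }

  ## --- phage genomes -------------------------------------------------
  set.seed(substream_seed(cfg$seed, "phages"))
  pn <- cfg$n_phage_species
  phage_ids <- sprintf("P%03d", seq_len(pn))
  phage_len <- round(runif(pn, cfg$phage_size_range[1], cfg$phage_size_range[2]))
  phage_genomes <- lapply(phage_len, random_dna)
  names(phage_genomes) <- phage_ids
  temperate <- runif(pn) < cfg$temperate_frac
  if (cfg$prophage_prob > 0 && !any(temperate)) temperate[1] <- TRUE
  true_lifestyle <- ifelse(temperate, "temperate", "virulent")
  names(true_lifestyle) <- phage_ids

  ## --- host genomes --------------------------------------------------
  set.seed(substream_seed(cfg$seed, "hosts"))
  hn <- cfg$n_host_species
  host_ids <- sprintf("H%02d", seq_len(hn))
  hosts <- lapply(seq_len(hn), function(i) {
    total <- round(runif(1, cfg$genome_size_range[1], cfg$genome_size_range[2]))
    nc <- sample(seq(cfg$n_contigs_range[1], cfg$n_contigs_range[2]), 1L)
    # the first contig carries 40-60% of the genome (assemblies have a
    # dominant contig; also guarantees prophage insertions can fit)
    p1 <- runif(1, 0.4, 0.6)
    rest <- runif(nc - 1L) + 0.25
    sizes <- round(c(p1, (1 - p1) * rest / sum(rest)) * total)
    sizes[sizes < 1000L] <- 1000L
    ctg <- vapply(sizes, random_dna, character(1))
    names(ctg) <- paste0(host_ids[i], "_c", seq_len(nc))
    ctg
  })
  names(hosts) <- host_ids

  ## --- VLP presence --------------------------------------------------
  set.seed(substream_seed(cfg$seed, "vlp_presence"))
  free_vlp <- runif(pn) < cfg$vlp_prob
  free_vlp[1] <- TRUE   # core phage, keeps every VLP sample non-empty
  names(free_vlp) <- phage_ids

  ## --- plant prophages ------------------------------------------------
  set.seed(substream_seed(cfg$seed, "plant"))
  prophage_plan <- list()
  for (h in host_ids) {
    if (runif(1) >= cfg$prophage_prob) next
    lens <- nchar(hosts[[h]])
    target_ctg <- names(lens)[which.max(lens)]
    eligible <- phage_ids[temperate & phage_len <= lens[target_ctg] ]
    if (length(eligible) == 0L) {
      mp_stop("infeasible-config",
              paste0("no temperate phage fits the largest contig of ", h))
    }
    ph <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    insert <- mutate_seq(phage_genomes[[ph]], cfg$mutation_rate)
    clen <- lens[target_ctg]
    at <- sample.int(clen - 1000L, 1L) + 500L   # 0-based insertion point
    s <- hosts[[h]][[target_ctg]]
    hosts[[h]][[target_ctg]] <- paste0(substr(s, 1, at),
                                       insert, substr(s, at + 1L, clen))
    prophage_plan[[length(prophage_plan) + 1L]] <- list(
      host = h, phage = ph, contig = target_ctg,
      start = at, end = at + nchar(insert), seq = as.character(insert))
  }

  ## --- VLP + PRO phage contigs ---------------------------------------
  set.seed(substream_seed(cfg$seed, "vlp"))
  phage_seqs <- character(0)
  phage_rows <- list()
  contig_species <- character(0)
  add_phage <- function(id, seq, dataset, species, completeness) {
    phage_seqs[[id]] <<- seq
    contig_species[[id]] <<- species
    phage_rows[[length(phage_rows) + 1L]] <<- data.frame(
      contig_id = id, dataset = dataset,
      viral_gene_count = stats::rpois(1, nchar(seq) / 5000) + 1L,
      lifestyle_phatyp = NA_character_, lifestyle_vibrant = NA_character_,
      lifestyle_phageboost = NA_character_,
      completeness = round(completeness, 1), stringsAsFactors = FALSE)
  }
  for (p in phage_ids[free_vlp]) {
    add_phage(paste0("V_", p), mutate_seq(phage_genomes[[p]], cfg$mutation_rate),
              "VLP", p, runif(1, 70, 100))
  }
  induced_rows <- list()
  for (pp in prophage_plan) {
    pro_id <- paste0("PRO_", pp$phage, "_", pp$host)
    add_phage(pro_id, pp$seq, "PRO", pp$phage, runif(1, 80, 100))
    if (runif(1) < cfg$induction_prob) {
      ind_id <- paste0("V_", pp$phage, "_ind_", pp$host)
      add_phage(ind_id, pp$seq, "VLP", pp$phage, runif(1, 80, 100))
      induced_rows[[length(induced_rows) + 1L]] <- data.frame(
        host_species = pp$host, phage_species = pp$phage,
        vlp_contig_id = ind_id, pro_contig_id = pro_id,
        stringsAsFactors = FALSE)
    }
  }
  phage_meta <- do.call(rbind, phage_rows)
  # lifestyle predictor labels, each correct with predictor_accuracy
  tl <- true_lifestyle[contig_species[phage_meta$contig_id]]
  phage_meta$lifestyle_phatyp <- draw_lifestyle_labels(tl, cfg$predictor_accuracy)
  phage_meta$lifestyle_vibrant <- draw_lifestyle_labels(tl, cfg$predictor_accuracy)
  phage_meta$lifestyle_phageboost <- draw_lifestyle_labels(tl, cfg$predictor_accuracy)

  ## --- CRISPR arrays ---------------------------------------------------
  set.seed(substream_seed(cfg$seed, "crispr"))
  crispr_plan <- list()
  crispr_links <- list()
  vlp_contig_ids <- phage_meta$contig_id[phage_meta$dataset == "VLP"]
  for (h in host_ids) {
    if (runif(1) >= cfg$crispr_prob) next
    rep_len <- sample(25:40, 1L)
    rep_seq <- random_dna(rep_len)
    n_sp <- sample(seq(cfg$spacers_per_array[1], cfg$spacers_per_array[2]), 1L)
    spacers <- character(n_sp)
    for (si in seq_len(n_sp)) {
      slen <- sample(28:40, 1L)
      if (length(vlp_contig_ids) > 0 && runif(1) < cfg$protospacer_match_prob) {
        src <- if (length(vlp_contig_ids) == 1L) vlp_contig_ids else
          sample(vlp_contig_ids, 1L)
        at <- sample.int(nchar(phage_seqs[[src]]) - slen + 1L, 1L)
        spacers[si] <- substr(phage_seqs[[src]], at, at + slen - 1L)
        crispr_links[[length(crispr_links) + 1L]] <- data.frame(
          host_species = h, phage_species = contig_species[[src]],
          spacer = spacers[si], mismatches = 0L, stringsAsFactors = FALSE)
      } else {
        spacers[si] <- random_dna(slen)
      }
    }
    array_seq <- paste0(rep_seq,
                        paste0(spacers, rep_seq, collapse = ""))
    # insert into a length-weighted random contig, avoiding the prophage
    pp <- Filter(function(x) x$host == h, prophage_plan)
    lens <- nchar(hosts[[h]])
    ctg <- names(lens)[sample.int(length(lens), 1L, prob = lens)]
    avoid <- if (length(pp) && pp[[1]]$contig == ctg) {
      c(pp[[1]]$start - 200L, pp[[1]]$end + 200L)
    } else NULL
    at <- NULL
    for (try in 1:100) {
      cand <- sample.int(lens[ctg] - 400L, 1L) + 200L
      if (is.null(avoid) || cand < avoid[1] || cand > avoid[2]) {
        at <- cand
        break
      }
    }
    if (is.null(at)) next   # pathologically full contig; skip this array
    s <- hosts[[h]][[ctg]]
    hosts[[h]][[ctg]] <- paste0(substr(s, 1, at), array_seq,
                                substr(s, at + 1L, lens[ctg]))
    if (length(pp) && pp[[1]]$contig == ctg && at <= pp[[1]]$start) {
      shift <- nchar(array_seq)
      i <- which(vapply(prophage_plan, function(x)
        identical(x$host, h), logical(1)))[1]
      prophage_plan[[i]]$start <- prophage_plan[[i]]$start + shift
      prophage_plan[[i]]$end <- prophage_plan[[i]]$end + shift
    }
    crispr_plan[[length(crispr_plan) + 1L]] <- list(
      host = h, contig = ctg, start = at, end = at + nchar(array_seq),
      repeat_seq = rep_seq, spacers = spacers)
  }

  ## --- bins ------------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "bins"))
  manifest <- build_manifest(cfg)
  prok_samples <- manifest$sample_id[manifest$dataset == "prokaryotic"]
  bin_seqs <- character(0)
  bin_of_contig <- character(0)
  bin_species <- character(0)
  bin_rows <- list()
  gt_prophages <- list()
  gt_arrays <- list()
  gt_members <- list()
  bin_counter <- 0L
  for (h in host_ids) {
    nb <- sample(seq(cfg$bins_per_species[1], cfg$bins_per_species[2]), 1L)
    origins <- sample(prok_samples, nb)
    for (bi in seq_len(nb)) {
      bin_counter <- bin_counter + 1L
      bin_id <- sprintf("B%03d", bin_counter)
      target <- if (bi == 1L) runif(1, 75, 100) else
        runif(1, cfg$completeness_range[1], cfg$completeness_range[2])
      tr <- truncate_bin(hosts[[h]], target,
                         seed = substream_seed(cfg$seed,
                                               paste0("trunc_", bin_id)))
      set.seed(substream_seed(cfg$seed, paste0("mut_", bin_id)))
      ctgs <- vapply(tr$contigs, function(s)
        as.character(mutate_seq(s, cfg$mutation_rate)), character(1))
      names(ctgs) <- paste0(bin_id, "_", names(tr$contigs))
      tr$map$new_contig <- paste0(bin_id, "_", tr$map$new_contig)
      bin_seqs <- c(bin_seqs, ctgs)
      bin_of_contig <- c(bin_of_contig,
                         stats::setNames(rep(bin_id, length(ctgs)), names(ctgs)))
      bin_species[[bin_id]] <- h
      bin_rows[[bin_counter]] <- data.frame(
        bin_id = bin_id, sample_id = origins[bi],
        completeness = round(100 * tr$retained_fraction, 2),
        contamination = round(runif(1, 0, 8), 2),
        taxonomy = paste0("d__Bacteria;g__Genus", sub("H", "", h)),
        stringsAsFactors = FALSE)
      gt_members[[length(gt_members) + 1L]] <- data.frame(
        member_id = bin_id, species_id = h, kind = "prokaryote",
        stringsAsFactors = FALSE)
      for (pp in Filter(function(x) x$host == h, prophage_plan)) {
        mi <- map_interval(tr$map, pp$contig, pp$start, pp$end)
        if (!is.null(mi)) {
          gt_prophages[[length(gt_prophages) + 1L]] <- data.frame(
            host_species = h, phage_species = pp$phage, bin_id = bin_id,
            contig_id = mi$new_contig, start = mi$new_start,
            end = mi$new_end, intact = mi$intact, stringsAsFactors = FALSE)
        }
      }
      for (cp in Filter(function(x) x$host == h, crispr_plan)) {
        mi <- map_interval(tr$map, cp$contig, cp$start, cp$end)
        mi <- mi[!is.null(mi) && mi$intact, , drop = FALSE]
        if (!is.null(mi) && nrow(mi)) {
          gt_arrays[[length(gt_arrays) + 1L]] <- data.frame(
            bin_id = bin_id, contig_id = mi$new_contig[1],
            start = mi$new_start[1], end = mi$new_end[1],
            repeat_seq = cp$repeat_seq,
            spacers = paste(cp$spacers, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  bin_meta <- do.call(rbind, bin_rows)
  for (id in phage_meta$contig_id) {
    gt_members[[length(gt_members) + 1L]] <- data.frame(
      member_id = id, species_id = contig_species[[id]], kind = "phage",
      stringsAsFactors = FALSE)
  }

  ## --- affiliations ----------------------------------------------------
  set.seed(substream_seed(cfg$seed, "affiliation"))
  n_aff <- cfg$n_affiliated
  aff_ids <- sample(host_ids, sum(n_aff))
  affiliated <- stats::setNames(rep("none", hn), host_ids)
  affiliated[aff_ids[seq_len(n_aff[["anode"]])]] <- "anode"
  affiliated[aff_ids[n_aff[["anode"]] + seq_len(n_aff[["cathode"]])]] <- "cathode"

  ## --- read counts -----------------------------------------------------
  set.seed(substream_seed(cfg$seed, "abundance"))
  samples <- manifest$sample_id
  counts <- matrix(0, nrow = length(bin_seqs) + length(phage_seqs),
                   ncol = length(samples),
                   dimnames = list(c(names(bin_seqs), names(phage_seqs)),
                                   samples))
  host_scale <- stats::setNames(stats::rlnorm(hn, 0, 1.5), host_ids)
  phage_scale <- stats::setNames(stats::rlnorm(pn, 0, 1.5), phage_ids)
  mecs <- unique(manifest$mec_id)
  phage_present <- matrix(runif(pn * length(mecs)) < 0.7, nrow = pn,
                          dimnames = list(phage_ids, mecs))
  phage_present[1, ] <- TRUE
  profile <- function(sp, loc) {
    if (affiliated[[sp]] != "none") {
      if (loc == affiliated[[sp]]) cfg$affiliation_effect else 1
    } else if (loc %in% c("tubing", "suspension", "inoculum")) {
      cfg$ne_enrichment
    } else 1
  }
  for (s in seq_along(samples)) {
    rec <- manifest[s, ]
    if (rec$dataset == "prokaryotic") {
      ln <- cfg$abundance_lognormal[[rec$location]]
      for (h in host_ids) {
        a <- host_scale[[h]] * profile(h, rec$location) *
          stats::rlnorm(1, ln[1], ln[2])
        ctgs <- names(bin_of_contig)[bin_species[bin_of_contig] == h]
        counts[ctgs, s] <- round(a * nchar(bin_seqs[ctgs]) / 1000 * cfg$depth)
      }
    } else {
      ln <- cfg$abundance_lognormal[["vlp"]]
      for (p in phage_ids) {
        if (!phage_present[p, rec$mec_id]) next
        a <- phage_scale[[p]] * stats::rlnorm(1, ln[1], ln[2])
        ctgs <- names(contig_species)[contig_species == p]
        counts[ctgs, s] <- round(a * nchar(phage_seqs[ctgs]) / 1000 * cfg$depth)
      }
    }
  }

  gt <- list(
    cluster_membership = do.call(rbind, gt_members),
    planted_prophages = if (length(gt_prophages)) do.call(rbind, gt_prophages)
      else data.frame(host_species = character(0), phage_species = character(0),
                      bin_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0), intact = logical(0)),
    induced = if (length(induced_rows)) do.call(rbind, induced_rows)
      else data.frame(host_species = character(0), phage_species = character(0),
                      vlp_contig_id = character(0), pro_contig_id = character(0)),
    crispr_links = if (length(crispr_links)) do.call(rbind, crispr_links)
      else data.frame(host_species = character(0), phage_species = character(0),
                      spacer = character(0), mismatches = integer(0)),
    planted_arrays = if (length(gt_arrays)) do.call(rbind, gt_arrays)
      else data.frame(bin_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      repeat_seq = character(0), spacers = character(0)),
    affiliated_species = data.frame(species_id = host_ids,
                                    call = unname(affiliated),
                                    stringsAsFactors = FALSE),
    true_lifestyle = data.frame(phage_species = phage_ids,
                                lifestyle = unname(true_lifestyle),
                                stringsAsFactors = FALSE))

  ds <- list(bin_seqs = bin_seqs, bin_of_contig = bin_of_contig,
             bin_meta = bin_meta, phage_seqs = phage_seqs,
             phage_meta = phage_meta, counts = counts, manifest = manifest,
             ground_truth = gt, config = cfg)
  class(ds) <- "mec_dataset"
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' Write a synthetic dataset to disk
#'
#' FASTA for bin contigs (headers `binID|contigID`) and phage contigs
#' (headers `phageID`), TSV metadata/counts/manifest/ground-truth, YAML
#' config. Byte-identical across runs for a fixed config.
#'
#' @param ds a `mec_dataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  bins <- Biostrings::DNAStringSet(ds$bin_seqs)
  names(bins) <- paste0(ds$bin_of_contig[names(ds$bin_seqs)], "|",
                        names(ds$bin_seqs))
  Biostrings::writeXStringSet(bins, file.path(dir, "bins.fasta"), width = 80L)
  phages <- Biostrings::DNAStringSet(ds$phage_seqs)
  Biostrings::writeXStringSet(phages, file.path(dir, "phages.fasta"),
                              width = 80L)
  tsv(ds$bin_meta, "bin_metadata.tsv")
  tsv(ds$phage_meta, "phage_metadata.tsv")
  cnt <- data.frame(contig_id = rownames(ds$counts), ds$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tsv(cnt, "counts.tsv")
  tsv(ds$manifest, "manifest.tsv")
  for (nm in names(ds$ground_truth)) {
    tsv(ds$ground_truth[[nm]], paste0("gt_", nm, ".tsv"))
  }
  yaml::write_yaml(unclass(ds$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
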