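# Shared fixtures and independent oracles. The default synthetic dataset and
# its pipeline run are generated once per test session and cached.

.cache <- new.env(parent = emptyenv())

# The package's stated default world with the fixed test seed.
default_dataset <- function() {
  if (is.null(.cache$ds)) {
    .cache$ds <- generate_dataset(synth_config(seed = 42))
  }
  .cache$ds
}

default_run <- function() {
  if (is.null(.cache$run_dir)) {
    dir <- file.path(tempdir(), "mecphage-default-run")
    .cache$summary <- run_pipeline(default_dataset(), dir,
                                   pipeline_config(n_perm = 199))
    .cache$run_dir <- dir
  }
  list(dir = .cache$run_dir, summary = .cache$summary)
}

# quick small world for pipeline plumbing tests
small_config <- function(...) {
  synth_config(n_mecs = 4L, n_host_species = 5L, n_phage_species = 6L,
               genome_size_range = c(30000L, 50000L),
               phage_size_range = c(6000L, 15000L), seed = 11L, ...)
}

rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# independent O(n*m) sliding-window spacer scan (both strands, ungapped)
naive_spacer_scan <- function(spacer, subject, max_mm = 1L) {
  L <- nchar(subject)
  m <- nchar(spacer)
  ss <- strsplit(subject, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else rc(spacer)
    pp <- strsplit(pat, "")[[1]]
    mm <- integer(L - m + 1L)
    for (j in seq_len(m)) {
      mm <- mm + (ss[j:(L - m + j)] != pp[j])
    }
    hit <- which(mm <= max_mm)
    if (length(hit)) {
      out[[strand]] <- data.frame(position = hit - 1L, strand = strand,
                                  mismatches = mm[hit],
                                  stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(position = integer(0), strand = character(0),
               mismatches = integer(0))
  }
}

# independent interval-only Monte Carlo of the block-removal model used by
# truncate_bin: returns the estimated probability that [iv1, iv2) survives
# truncation to `target` percent of a single contig of length L
sim_block_retention <- function(L, iv, target, reps) {
  keep <- logical(reps)
  for (r in seq_len(reps)) {
    pieces <- matrix(c(0, L), ncol = 2)
    need <- min(L - round(L * target / 100), L - 1)
    while (need > 0 && nrow(pieces) > 0) {
      lens <- pieces[, 2] - pieces[, 1]
      block <- min(need, round(runif(1, 500, 3000)))
      i <- if (nrow(pieces) == 1L) 1L else sample.int(nrow(pieces), 1L, prob = lens)
      if (lens[i] <= block) {
        need <- need - lens[i]
        pieces <- pieces[-i, , drop = FALSE]
      } else {
        at <- pieces[i, 1] + sample.int(lens[i] - block + 1L, 1L) - 1L
        new <- rbind(c(pieces[i, 1], at), c(at + block, pieces[i, 2]))
        new <- new[new[, 2] > new[, 1], , drop = FALSE]
        pieces <- rbind(pieces[-i, , drop = FALSE], new)
        need <- need - block
      }
    }
    keep[r] <- any(pieces[, 1] <= iv[1] & pieces[, 2] >= iv[2])
  }
  mean(keep)
}

# all permutations of 1..n (n small), for exact Mantel enumeration
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# partition equality up to label renaming
same_partition <- function(a, b) {
  stopifnot(identical(sort(names(a)), sort(names(b))))
  b <- b[names(a)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

precision_recall <- function(found, truth) {
  c(precision = if (length(found)) mean(found %in% truth) else 1,
    recall = if (length(truth)) mean(truth %in% found) else 1)
}
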