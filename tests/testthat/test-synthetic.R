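test_that("probability-zero and probability-one configurations behave", {
  ds0 <- generate_dataset(small_config(prophage_prob = 0, crispr_prob = 0))
  expect_equal(nrow(ds0$ground_truth$planted_prophages), 0)
  expect_equal(nrow(ds0$ground_truth$crispr_links), 0)

  ds1 <- generate_dataset(small_config(prophage_prob = 1, induction_prob = 1))
  gt <- ds1$ground_truth
  planted <- unique(gt$planted_prophages[, c("host_species", "phage_species")])
  expect_gt(nrow(planted), 0)
  induced <- unique(gt$induced[, c("host_species", "phage_species")])
  expect_setequal(paste(planted$host_species, planted$phage_species),
                  paste(induced$host_species, induced$phage_species))
  expect_true(all(gt$induced$vlp_contig_id %in% names(ds1$phage_seqs)))
})

test_that("generation is byte-identical for a fixed seed", {
  d1 <- file.path(tempdir(), "gen1")
  d2 <- file.path(tempdir(), "gen2")
  generate_dataset(small_config(), out_dir = d1)
  generate_dataset(small_config(), out_dir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6), label = f)
  }
})

test_that("infeasible configurations are rejected", {
  cfg <- synth_config(prophage_prob = 1,
                      genome_size_range = c(30000L, 40000L),
                      phage_size_range = c(60000L, 80000L))
  expect_error(generate_dataset(cfg), class = "infeasible-config")
  expect_error(synth_config(prophage_prob = 1.2), class = "invalid-config")
  expect_error(synth_config(n_mecs = 1), class = "invalid-config")
  expect_error(synth_config(completeness_range = c(0, 100)),
               class = "invalid-config")
})

test_that("truncate_bin hits its target and preserves coordinates", {
  genome <- c(c1 = rdna(60000, seed = 20), c2 = rdna(40000))
  full <- truncate_bin(genome, 100, seed = 1)
  expect_identical(unname(full$contigs), unname(genome))
  expect_equal(full$retained_fraction, 1)

  half <- truncate_bin(genome, 50, seed = 2)
  expect_gte(half$retained_fraction, 0.49)
  expect_lte(half$retained_fraction, 0.51)
  # pieces re-slice the original genome exactly
  for (i in seq_len(nrow(half$map))) {
    m <- half$map[i, ]
    expect_identical(half$contigs[[m$new_contig]],
                     substr(genome[[m$orig_contig]], m$orig_start + 1,
                            m$orig_end))
  }
  expect_error(truncate_bin(genome, 0), class = "invalid-input")
})

test_that("prophage retention under truncation matches a Monte-Carlo oracle", {
  genome <- c(c1 = rdna(100000, seed = 21))
  iv <- c(45000, 55000)   # a 10% prophage
  kept <- vapply(1:200, function(i) {
    tr <- truncate_bin(genome, 50, seed = 1000 + i)
    any(tr$map$orig_start <= iv[1] & tr$map$orig_end >= iv[2])
  }, logical(1))
  set.seed(99)
  oracle <- sim_block_retention(100000, iv, 50, 400)
  expect_lt(abs(mean(kept) - oracle), 0.12)
})

test_that("planted-prophage retention is non-decreasing in completeness", {
  genome <- c(c1 = rdna(100000, seed = 22))
  iv <- c(45000, 55000)
  grid <- c(30, 50, 70, 90)
  means <- vapply(grid, function(tg) {
    mean(vapply(1:100, function(i) {
      tr <- truncate_bin(genome, tg, seed = tg * 1000 + i)
      any(tr$map$orig_start <= iv[1] & tr$map$orig_end >= iv[2])
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(means) > -0.05))
})

test_that("default dataset has positive totals in every sample", {
  ds <- default_dataset()
  expect_true(all(colSums(ds$counts) > 0))
  expect_setequal(unique(ds$manifest$dataset), c("prokaryotic", "VLP"))
  # per-bin completeness metadata equals the retained genome fraction
  expect_true(all(ds$bin_meta$completeness > 0 &
                    ds$bin_meta$completeness <= 100))
  # spacer lengths within the CRISPR contract
  sp <- unlist(strsplit(ds$ground_truth$planted_arrays$spacers, ","))
  expect_true(all(nchar(sp) >= 26 & nchar(sp) <= 50))
})
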