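test_that("phage filter applies both thresholds inclusively", {
  meta <- data.frame(contig_id = c("a", "b", "c"),
                     viral_gene_count = c(1L, 3L, 0L),
                     length = c(5000L, 4999L, 80000L),
                     stringsAsFactors = FALSE)
  kept <- filter_phage_contigs(meta)
  expect_identical(kept$contig_id, "a")
})

test_that("clustering obeys the 95% threshold on simple cases", {
  ani3 <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                     ani = c(100, 100, 100))
  cl <- cluster_species(c("a", "b", "c"), ani3)
  expect_equal(length(unique(cl$species_id)), 1)

  ani2 <- data.frame(id_a = "a", id_b = "b", ani = 90)
  cl2 <- cluster_species(c("a", "b"), ani2)
  expect_equal(length(unique(cl2$species_id)), 2)
  expect_equal(sort(cl2$member_id), c("a", "b"))
})

test_that("planted clusters with wide ANI margins are recovered exactly", {
  set.seed(50)
  bases <- lapply(1:3, function(i) rdna(20000))
  seqs <- character(0)
  truth <- character(0)
  for (i in 1:3) {
    for (j in 1:3) {
      id <- paste0("g", i, "_", j)
      seqs[[id]] <- as.character(mutate_seq(bases[[i]], 0.01))
      truth[[id]] <- paste0("sp", i)
    }
  }
  cl <- cluster_species(names(seqs), ani_table(seqs))
  got <- setNames(cl$species_id, cl$member_id)
  expect_true(same_partition(got, truth))
})

test_that("clustering is a partition and invariant to input order", {
  set.seed(51)
  for (rep in 1:100) {
    n <- 8
    ids <- paste0("x", sample(100, n))
    pairs <- t(combn(n, 2))
    ani <- data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
                      ani = runif(nrow(pairs), 80, 100))
    cl1 <- cluster_species(ids, ani)
    expect_setequal(cl1$member_id, ids)
    expect_equal(nrow(cl1), n)
    perm <- sample(n)
    cl2 <- cluster_species(ids[perm], ani)
    p1 <- setNames(cl1$species_id, cl1$member_id)
    p2 <- setNames(cl2$species_id, cl2$member_id)
    expect_true(same_partition(p1, p2))
  }
})

test_that("representative selection follows the scoring rules", {
  phage_meta <- data.frame(contig_id = c("p1", "p2"),
                           completeness = c(90, 60))
  expect_identical(
    select_representative(c("p1", "p2"), phage_meta,
                          c(p1 = 30000, p2 = 30000), "phage"), "p1")
  prok_meta <- data.frame(bin_id = c("b1", "b2"),
                          completeness = c(95, 99),
                          contamination = c(2, 8))
  lens <- list(b1 = c(50000, 50000), b2 = c(50000, 50000))
  # scores 85 + 0.5 log10(N50) vs 59 + 0.5 log10(N50) -> b1
  expect_identical(
    select_representative(c("b1", "b2"), prok_meta, lens, "prokaryote"),
    "b1")
  expect_identical(
    select_representative("b2", prok_meta, lens, "prokaryote"), "b2")
})

test_that("species retention uses strict quality inequalities", {
  meta <- data.frame(bin_id = c("b1", "b2", "b3", "b4", "b5"),
                     completeness = c(70.0, 71, 50, 96, 80),
                     contamination = c(5, 9.9, 2, 12, 3))
  cl <- data.frame(member_id = c("b1", "b2", "b3", "b4", "b5"),
                   species_id = c("s1", "s2", "s3", "s3", "s4"))
  kept <- retain_prokaryote_species(cl, meta)
  # s1: (70.0, 5) fails strict >70; s2: (71, 9.9) passes;
  # s3: (50,2) and (96,12) both fail jointly; s4 passes
  expect_setequal(unique(kept$species_id), c("s2", "s4"))
})

test_that("default-world clustering recovers the planted species exactly", {
  ds <- default_dataset()
  gt <- ds$ground_truth$cluster_membership
  bin_ids <- unique(ds$bin_of_contig)
  bin_seq <- vapply(bin_ids, function(b) {
    paste(ds$bin_seqs[names(ds$bin_of_contig)[ds$bin_of_contig == b]],
          collapse = strrep("N", 17))
  }, character(1))
  cl <- cluster_species(bin_ids, ani_table(bin_seq))
  got <- setNames(cl$species_id, cl$member_id)
  truth <- setNames(gt$species_id[match(bin_ids, gt$member_id)], bin_ids)
  expect_true(same_partition(got, truth))
  expect_equal(length(unique(got)), length(unique(truth)))
})
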