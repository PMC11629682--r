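mk_counts <- function(vals, samples = paste0("s", seq_len(ncol(vals)))) {
  matrix(vals, nrow = nrow(vals), dimnames = list(rownames(vals), samples))
}

test_that("species abundances are percentages with an unassigned remainder", {
  counts <- matrix(c(30, 70, 0,
                     25, 25, 50), ncol = 2,
                   dimnames = list(c("c1", "c2", "c3"), c("s1", "s2")))
  map <- c(c1 = "spA", c2 = "spB")   # c3 unassigned
  ab <- species_abundance(counts, map)
  expect_equal(ab["spA", "s1"], 30)
  expect_equal(ab["spB", "s1"], 70)
  expect_equal(unname(attr(ab, "unassigned")["s1"]), 0)
  expect_equal(ab["spA", "s2"], 25)
  expect_equal(sum(ab[, "s2"]), 50)
  expect_equal(unname(attr(ab, "unassigned")["s2"]), 50)

  one <- species_abundance(matrix(c(7), dimnames = list("c1", "s1")),
                           c(c1 = "spA"))
  expect_equal(one["spA", "s1"], 100)
  bad <- matrix(c(1, 0), ncol = 2, dimnames = list("c1", c("s1", "s2")))
  expect_error(species_abundance(bad, c(c1 = "spA")), class = "empty-sample")
})

test_that("abundances are invariant to per-sample count scaling", {
  set.seed(60)
  counts <- matrix(rpois(30, 50) + 1, nrow = 6,
                   dimnames = list(paste0("c", 1:6), paste0("s", 1:5)))
  map <- setNames(rep(c("spA", "spB"), 3), paste0("c", 1:6))
  a1 <- species_abundance(counts, map)
  a2 <- species_abundance(sweep(counts, 2, c(2, 10, 1, 7, 100), "*"), map)
  expect_equal(a1, a2)
})

aff_fixture <- function(anode, cathode, ne) {
  # 3 anode, 2 cathode, 3 non-electrode samples; one species of interest
  # plus a filler species so columns are meaningful percentages
  vals <- c(anode, cathode, ne)
  ab <- rbind(sp = vals, filler = 100 - vals)
  colnames(ab) <- paste0("s", seq_along(vals))
  manifest <- data.frame(
    sample_id = colnames(ab),
    mec_id = "M1",
    location = c(rep("anode", length(anode)), rep("cathode", length(cathode)),
                 rep("tubing", length(ne))),
    dataset = "prokaryotic", stringsAsFactors = FALSE)
  classify_affiliation(ab, manifest)
}

test_that("the affiliation rule follows the printed criteria strictly", {
  r1 <- aff_fixture(c(3.0, 2.0, 4.0), c(0.0, 0.0), c(0.01, 0.02, 0.0))
  expect_equal(r1$call[r1$species_id == "sp"], "anode")
  # mean exactly 0.1 is not > 0.1
  r2 <- aff_fixture(c(0.09, 0.10, 0.11), c(0, 0), c(0, 0, 0))
  expect_equal(r2$call[r2$species_id == "sp"], "none")
  # max_NE = 0.6 >= max_E = 0.5 blocks the cathode call
  r3 <- aff_fixture(c(0, 0, 0), c(0.5, 0.5), c(0.6, 0.1, 0))
  expect_equal(r3$call[r3$species_id == "sp"], "none")
})

test_that("affiliation calls match a naive re-evaluation on the default world", {
  ds <- default_dataset()
  prok <- ds$manifest$sample_id[ds$manifest$dataset == "prokaryotic"]
  gt_map <- ds$ground_truth$cluster_membership
  contig_sp <- setNames(
    gt_map$species_id[match(ds$bin_of_contig, gt_map$member_id)],
    names(ds$bin_of_contig))
  ab <- species_abundance(ds$counts[names(ds$bin_seqs), prok], contig_sp)
  calls <- classify_affiliation(ab, ds$manifest)

  loc <- ds$manifest$location[match(colnames(ab), ds$manifest$sample_id)]
  for (i in seq_len(nrow(calls))) {
    x <- ab[calls$species_id[i], ]
    verdict <- "none"
    best <- -Inf
    for (e in c("anode", "cathode")) {
      xe <- x[loc == e]
      xne <- x[loc %in% c("tubing", "suspension", "inoculum")]
      if (mean(xe) > 0.1 && mean(xe) > mean(xne) && max(xe) > max(xne) &&
          mean(xe) > best) {
        verdict <- e
        best <- mean(xe)
      }
    }
    expect_identical(calls$call[i], verdict)
  }

  # planted affiliations are recovered
  truth <- ds$ground_truth$affiliated_species
  for (e in c("anode", "cathode")) {
    pr <- precision_recall(calls$species_id[calls$call == e],
                           truth$species_id[truth$call == e])
    expect_gte(pr["precision"], 0.95)
    expect_gte(pr["recall"], 0.95)
  }
})
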