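region_row <- function(bin, phage, contig = "c1", start = 0, end = 30000) {
  data.frame(bin_id = bin, contig_id = contig, start = start, end = end,
             phage_id = phage, containment = 1, mean_identity = 100,
             stringsAsFactors = FALSE)
}
meta2 <- data.frame(contig_id = c("pT", "pV"),
                    dataset = c("VLP", "VLP"),
                    viral_gene_count = c(2L, 2L),
                    lifestyle_phatyp = c("virulent", "virulent"),
                    lifestyle_vibrant = c("temperate", "virulent"),
                    lifestyle_phageboost = c("virulent", "virulent"),
                    completeness = c(90, 90), stringsAsFactors = FALSE)
bm <- c(b1 = "sp1", b2 = "sp1", b3 = "sp2")
pm <- c(pT = "ph1", pV = "ph2")

test_that("prophage edges follow the temperate-by-any-predictor OR rule", {
  regions <- rbind(region_row("b1", "pT"), region_row("b3", "pV"))
  e <- call_prophage_associations(regions, meta2, bm, pm)
  expect_equal(nrow(e), 1)
  expect_equal(e$host_species, "sp1")
  expect_equal(e$evidence, "prophage")
  excl <- attr(e, "excluded")
  expect_equal(nrow(excl), 1)
  expect_equal(excl$phage_species, "ph2")

  # two bins of one host species with the same phage collapse to one edge
  e2 <- call_prophage_associations(
    rbind(region_row("b1", "pT"), region_row("b2", "pT", contig = "c9")),
    meta2, bm, pm)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$n_support, 2)

  expect_error(
    call_prophage_associations(region_row("zz", "pT"), meta2, bm, pm),
    class = "dangling-reference")
})

test_that("induction promotes existing prophage edges only", {
  e <- call_prophage_associations(region_row("b1", "pT"), meta2, bm, pm)
  ind <- data.frame(host_species = "sp1", phage_species = "ph1",
                    support = "c1:0-30000~v9", stringsAsFactors = FALSE)
  up <- promote_induced(e, ind)
  expect_setequal(up$evidence, c("prophage", "induced_prophage"))
  # every induced edge coexists with a prophage edge for the same pair
  ind_rows <- up[up$evidence == "induced_prophage", ]
  pro_keys <- paste(up$host_species, up$phage_species)[up$evidence == "prophage"]
  expect_true(all(paste(ind_rows$host_species, ind_rows$phage_species) %in%
                    pro_keys))

  # no VLP match leaves edges unchanged; orphans create no edge
  none <- promote_induced(e, ind[0, ])
  expect_equal(none$evidence, "prophage")
  orphan <- data.frame(host_species = "sp2", phage_species = "ph2",
                       support = "x", stringsAsFactors = FALSE)
  up2 <- promote_induced(e, orphan)
  expect_equal(nrow(up2), 1)
  expect_equal(nrow(attr(up2, "orphans")), 1)
})

test_that("CRISPR edges collapse spacer hits per species pair", {
  hits <- data.frame(bin_id = "b1", array_index = 1L, spacer_index = 1:3,
                     sequence = "x", phage_contig_id = "pT",
                     position = c(10L, 20L, 30L), strand = "+",
                     mismatches = 0L, stringsAsFactors = FALSE)
  e <- call_crispr_associations(hits, bm, pm)
  expect_equal(nrow(e), 1)
  expect_equal(e$evidence, "crispr_match")
  expect_equal(e$n_support, 3)
  expect_equal(nrow(call_crispr_associations(hits[0, ], bm, pm)), 0)
  # vlp_only drops hits on PRO-dataset contigs
  e2 <- call_crispr_associations(hits, bm, pm,
                                 phage_dataset = c(pT = "PRO"),
                                 vlp_only = TRUE)
  expect_equal(nrow(e2), 0)
})

test_that("network abundance summary respects category overlap", {
  edges <- data.frame(host_species = c("sp1", "sp2"),
                      phage_species = c("ph1", "ph1"),
                      evidence = "prophage", n_support = 1L, support = "x",
                      stringsAsFactors = FALSE)
  ab <- matrix(c(5, 2, 7, 1), nrow = 2,
               dimnames = list(c("ph1", "ph2"), c("v1", "v2")))
  aff <- data.frame(species_id = c("sp1", "sp2"),
                    call = c("anode", "cathode"), stringsAsFactors = FALSE)
  s <- summarize_network_abundance(edges, ab, aff)
  # ph1 is associated with both an anode- and a cathode-affiliated host
  expect_equal(s$per_sample["anode_associated", "v1"], 5)
  expect_equal(s$per_sample["cathode_associated", "v1"], 5)
  expect_equal(s$per_sample["unassociated", "v1"], 2)
  expect_equal(s$range$min[s$range$category == "anode_associated"], 5)
  expect_equal(s$range$max[s$range$category == "anode_associated"], 7)

  none <- summarize_network_abundance(edges[0, ], ab, aff)
  expect_equal(unname(none$per_sample["unassociated", ]), c(7, 8))
})

test_that("edge list and GraphML exports round-trip", {
  edges <- data.frame(host_species = c("sp1", "sp1"),
                      phage_species = c("ph1", "ph2"),
                      evidence = c("prophage", "crispr_match"),
                      n_support = c(2L, 1L),
                      support = c("a;b", "c"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_edges(edges, f)
  expect_identical(read_edges(f), edges)
  g <- tempfile(fileext = ".graphml")
  write_graphml(edges, g)
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gorder(gr), 3)
  expect_equal(igraph::gsize(gr), 2)
  expect_setequal(igraph::edge_attr(gr, "evidence"),
                  c("prophage", "crispr_match"))
})
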