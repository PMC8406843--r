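test_that("taxonomy validation rejects malformed trees", {
  base <- toy_taxonomy()$df
  two_roots <- base; two_roots$parent_id[2] <- NA
  expect_error(taxonomy_table(two_roots), "exactly one root")
  dangling <- base; dangling$parent_id[4] <- "nope"
  expect_error(taxonomy_table(dangling), "missing")
  dup <- rbind(base, base[5, ])
  expect_error(taxonomy_table(dup), "duplicate")
})

test_that("retain_significant keeps hits within 10x of the top e-value", {
  hits <- data.frame(gene_id = "g", taxon_id = c("a", "b", "c"),
                     e_value = c(1e-10, 5e-10, 2e-9), bit_score = 0)
  kept <- retain_significant(hits)
  expect_equal(kept$taxon_id, c("a", "b"))       # 2e-9 > 10 * 1e-10
  # boundary value is inclusive
  hits$e_value[3] <- 1e-9
  expect_equal(nrow(retain_significant(hits)), 3)
  # idempotence
  expect_identical(retain_significant(kept), kept)
  # single hit and all-equal cases retain everything
  expect_equal(nrow(retain_significant(hits[1, , drop = FALSE])), 1)
  hits$e_value <- 1e-8
  expect_equal(nrow(retain_significant(hits)), 3)
})

test_that("lca resolves hand-built cases on the toy tree", {
  tax <- toy_taxonomy()
  expect_equal(lca("sA", tax), "sA")
  expect_equal(lca(c("sA", "sB"), tax), "g1")     # same genus
  expect_equal(lca(c("sA", "sC"), tax), "p1")     # genera g1, g2 share phylum
  expect_equal(lca(c("sA", "g2"), tax), "p1")
  expect_equal(lca(c("root", "sA"), tax), "root")
  expect_error(lca("nope", tax), "nope")
})

test_that("lca equals the path-intersection oracle on random trees (property)", {
  set.seed(99)
  cases <- 0
  for (t in 1:20) {
    tax <- generate_taxonomy(n_species = 40, n_genera = 8, n_phyla = 3, seed = t)
    ids <- tax$df$taxon_id
    for (r in 1:10) {
      taxa <- sample(ids, sample(1:6, 1))
      expect_equal(lca(taxa, tax), lca_oracle(taxa, tax))
      cases <- cases + 1
    }
  }
  expect_gte(cases, 200)
})

test_that("assign_gene_taxa composes retention and LCA", {
  tax <- toy_taxonomy()
  hits <- rbind(
    data.frame(gene_id = "g1", taxon_id = c("sA", "sB", "sC"),
               e_value = c(1e-20, 5e-20, 1e-10), bit_score = 100),
    data.frame(gene_id = "g2", taxon_id = "sC",
               e_value = 1e-8, bit_score = 50))
  out <- assign_gene_taxa(hits, tax)
  expect_equal(out[["g1"]], "g1")   # sC dropped by 10x rule, LCA(sA, sB) = g1
  expect_equal(out[["g2"]], "sC")
  bad <- hits; bad$taxon_id[1] <- "zz"
  expect_error(assign_gene_taxa(bad, tax), "zz")
})

test_that("harboring_species counts, sums and excludes above-species genes", {
  tax <- toy_taxonomy()
  g2e <- data.frame(gene_id = c("g1", "g2", "g3"),
                    feature_id = c("tesB", "tesB", "yciA"))
  g2t <- c(g1 = "sA", g2 = "g1", g3 = "sA")   # g2 resolved at genus rank
  abund <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
  out <- harboring_species(g2e, g2t, abund, tax)
  expect_equal(out$species_enzyme["sA", "tesB"], 0.5)
  expect_equal(out$species_enzyme["sA", "yciA"], 0.2)
  expect_equal(out$species_counts$n_species[out$species_counts$enzyme == "tesB"], 1L)
  expect_equal(out$excluded$gene_id, "g2")
  expect_equal(out$excluded$rank, "genus")
})

test_that("harboring_species equals a brute-force double group-by (property)", {
  set.seed(5)
  tax <- generate_taxonomy(n_species = 12, seed = 5)
  genes <- sprintf("gene_%05d", 1:20)
  species <- tax$df$taxon_id[tax$df$rank == "species"]
  g2t <- setNames(sample(species, 20, replace = TRUE), genes)
  enz <- c("tesA", "tesB", "yciA")
  g2e <- data.frame(gene_id = genes,
                    feature_id = sample(enz, 20, replace = TRUE))
  abund <- setNames(runif(20), genes)
  out <- harboring_species(g2e, g2t, abund, tax)
  for (e in enz) {
    gs <- g2e$gene_id[g2e$feature_id == e]
    expect_equal(out$species_counts$n_species[out$species_counts$enzyme == e],
                 length(unique(g2t[gs])))
    for (s in unique(g2t[gs])) {
      brute <- sum(abund[gs[g2t[gs] == s]])
      expect_equal(out$species_enzyme[s, e], brute, tolerance = 1e-12)
    }
  }
})
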