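test_that("cohort_config rejects invalid fields by name", {
  expect_error(cohort_config(n_ctr = 0), "n_ctr")
  expect_error(cohort_config(n_diff = 300, n_ko = 200), "n_diff")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(harboring_matrix_density = 1.5),
               "harboring_matrix_density")
  expect_error(cohort_config(mediation_paths = list(a = 1)), "mediation_paths")
  expect_error(cohort_config(seed = 1.5), "seed")
})

test_that("generate_cohort is byte-identical under the same seed", {
  cfg <- cohort_config(n_ctr = 10, n_af = 10, n_ko = 30, n_diff = 3, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_ctr = 10, n_af = 10, n_ko = 30, n_diff = 3, seed = 12)
  expect_false(identical(generate_cohort(cfg)$ko$values,
                         generate_cohort(cfg2)$ko$values))
})

test_that("compositional closure holds for every abundance row", {
  for (s in 1:3) {
    co <- generate_cohort(cohort_config(n_ctr = 15, n_af = 15, n_ko = 50,
                                        n_diff = 5, seed = s))
    expect_true(all(abs(rowSums(co$ko$values) - 1) < 1e-9))
    expect_true(all(abs(rowSums(co$species$values) - 1) < 1e-9))
    expect_true(all(co$ko$values >= 0))
  }
})

test_that("planted KOs carry the requested fold change; null config plants nothing", {
  co <- generate_cohort(cohort_config(seed = 3, log2fc_planted = 1))
  expect_length(co$truth$diff_ko_ids, 10)
  ratio <- colMeans(co$ko$values[co$ko$group == "AF", co$truth$diff_ko_ids]) /
           colMeans(co$ko$values[co$ko$group == "CTR", co$truth$diff_ko_ids])
  # closure shrinks the planted 2x ratio a little; it must stay near 2
  expect_true(all(abs(log2(ratio) - 1) < 0.25))

  co0 <- generate_cohort(cohort_config(n_diff = 0, noise_sd = 0, seed = 4))
  expect_length(co0$truth$diff_ko_ids, 0)
  d <- differential_table(co0$ko)
  expect_lt(mean(d$q < 0.05), 0.05)
})

test_that("enzyme abundances equal species-abundance-weighted copy sums", {
  co <- generate_cohort(cohort_config(n_ctr = 8, n_af = 8, seed = 9))
  expected <- co$species$values %*% co$truth$harboring_matrix
  expect_equal(co$enzymes$values, expected, tolerance = 1e-12)
  expect_true(all(co$truth$harboring_matrix >= 0))
})

test_that("truth record VAF follows the closed form and clinicals recover it", {
  cfg <- cohort_config(n_ctr = 1000, n_af = 1000, n_ko = 10, n_diff = 0,
                       noise_sd = 0.3, seed = 21)
  co <- generate_cohort(cfg)
  p <- cfg$mediation_paths
  expect_equal(co$truth$true_vaf, p$a * p$b / (p$a * p$b + p$c_direct))
  fit <- fit_mediation(co$clinical$diversity, co$clinical$hsCRP,
                       co$clinical$LA_diameter)
  expect_lt(abs(fit$vaf - co$truth$true_vaf), 0.05)
})

test_that("gene read tables exercise the minimum-read filter deterministically", {
  expect_equal(nrow(generate_gene_read_table(1, seed = 2)), 1)
  tab <- generate_gene_read_table(60, seed = 5)
  expect_true(any(tab$read_count < 2))
  expect_true(all(tab$gene_length_bp > 0))
  expect_identical(tab, generate_gene_read_table(60, seed = 5))
})

test_that("hit tables span the retention boundary and respect the taxonomy", {
  tax <- generate_taxonomy(n_species = 15, seed = 8)
  hits <- generate_hit_table(tax, 40, seed = 8)
  expect_identical(hits, generate_hit_table(tax, 40, seed = 8))
  per_gene <- table(hits$gene_id)
  expect_true(all(per_gene >= 1 & per_gene <= 10))
  expect_equal(length(per_gene), 40)
  expect_true(all(hits$taxon_id %in% tax$df$taxon_id[tax$df$rank == "species"]))
  # secondary e-values spread over [1, 100] x top: some inside, some outside 10x
  ratios <- unlist(lapply(split(hits, hits$gene_id), function(h) {
    if (nrow(h) > 1) h$e_value[-1] / min(h$e_value) else numeric(0)
  }))
  expect_true(any(ratios <= 10) && any(ratios > 10))
  expect_error(generate_hit_table(data.frame(), 5), "taxonomy")
  expect_error(generate_hit_table(tax, 1, seed = 1), NA)
})

test_that("write_cohort emits readable TSVs and a truth record", {
  co <- generate_cohort(cohort_config(n_ctr = 5, n_af = 5, n_ko = 12,
                                      n_diff = 2, seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_abundance_tsv(paths[["ko"]])
  expect_equal(rt$values, co$ko$values, tolerance = 1e-12)
  expect_equal(as.character(rt$group), as.character(co$ko$group))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(unlist(truth$diff_ko_ids), co$truth$diff_ko_ids)
})
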