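test_that("wilcoxon null and degenerate cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_warning(w <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(w$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact small-sample p equals exhaustive enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p,
               wilcoxon_enum_oracle(c(1, 2, 3), c(4, 5, 6)))
  set.seed(31)
  for (rep in 1:10) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- sample(1:100, nx); y <- sample(setdiff(1:100, x), ny)
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large samples match the tie-corrected normal closed form", {
  set.seed(8)
  for (rep in 1:5) {
    x <- round(rnorm(60, 0, 2), 1)   # rounding induces ties
    y <- round(rnorm(55, 0.4, 2), 1)
    ours <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("bh_adjust matches hand evaluation and is monotone/order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(2)
  for (rep in 1:10) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), q[perm])   # order invariance
    expect_equal(q, stats::p.adjust(p, "BH"))   # independent implementation
  }
})

test_that("log2_fold_change handles pseudo-counts and degenerate input", {
  expect_equal(log2_fold_change(c(2, 2), c(1, 1)), 1)
  expect_equal(log2_fold_change(c(3, 3), c(3, 3)), 0)
  expect_warning(fc <- log2_fold_change(c(0, 0), c(0, 0)), "zero")
  expect_equal(fc, 0)
  expect_error(log2_fold_change(c(0, 0), c(1, 1), pseudo = 0), "pseudo")
  expect_equal(log2_fold_change(c(1, 3), c(2, 2), center = "median"),
               log2(2 / 2))
})

test_that("planted log2FC is recovered within 0.2 on average across seeds", {
  est <- numeric(5)
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(seed = s))
    d <- differential_table(co$ko)
    est[s] <- mean(d$log2fc[d$feature_id %in% co$truth$diff_ko_ids])
  }
  expect_lt(abs(mean(est) - 1), 0.2)
})

test_that("differential_table classifies planted features and honors alpha", {
  co <- generate_cohort(cohort_config(seed = 1))
  d <- differential_table(co$ko)
  expect_setequal(names(d), c("feature_id", "statistic", "p", "q",
                              "log2fc", "direction"))
  expect_true(all(d$q >= d$p))
  sig <- d$feature_id[d$direction != "NS"]
  expect_gte(length(intersect(sig, co$truth$diff_ko_ids)), 9)
  expect_lte(length(setdiff(sig, co$truth$diff_ko_ids)), 3)
  # planted KOs are up in AF, so they must be labelled AF-enriched
  expect_true(all(d$direction[d$feature_id %in% sig &
                              d$feature_id %in% co$truth$diff_ko_ids]
                  == "AF-enriched"))
  expect_true(all(differential_table(co$ko, alpha = 0)$direction == "NS"))
  one_group <- abundance_matrix(co$ko$values[co$ko$group == "AF", ],
                                rep("AF", sum(co$ko$group == "AF")))
  expect_error(differential_table(one_group), "both groups")
})

test_that("label permutation yields roughly uniform raw p-values", {
  co <- generate_cohort(cohort_config(n_ko = 100, n_diff = 10, seed = 6))
  set.seed(6)
  fracs <- replicate(20, {
    perm <- abundance_matrix(co$ko$values, sample(as.character(co$ko$group)))
    d <- differential_table(perm)
    mean(d$p < 0.05)
  })
  expect_lt(mean(fracs), 0.08)   # ~alpha before correction
})
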