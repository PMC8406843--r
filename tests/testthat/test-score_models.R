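test_that("packaged published models evaluate exactly at zero abundance", {
  ko <- published_score_model("KO")
  enzyme <- published_score_model("enzyme")
  species <- published_score_model("species")
  expect_length(ko$coefficients, 8)
  expect_length(enzyme$coefficients, 4)
  expect_length(species$coefficients, 2)
  zeros <- function(m) setNames(rep(0, length(m$coefficients)),
                                names(m$coefficients))
  expect_identical(evaluate_score(ko, zeros(ko)), -1.993)
  expect_identical(evaluate_score(enzyme, zeros(enzyme)), -2.562)
  expect_identical(evaluate_score(species, zeros(species)), 0.2773)
  v <- zeros(ko); v["K00175"] <- 0.001
  expect_equal(evaluate_score(ko, v), -1.993 + 6023.7645 * 0.001,
               tolerance = 1e-12)
})

test_that("evaluate_score handles matrices, missing features and empty models", {
  m <- score_model("toy", 1, c(a = 2, b = -1))
  expect_equal(evaluate_score(m, c(a = 1, b = 1)), 2)
  expect_warning(s <- evaluate_score(m, c(a = 1)), "treated as 0")
  expect_equal(s, 3)
  mat <- matrix(c(1, 0, 1, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(evaluate_score(m, mat), c(1 + 2 - 1, 1 + 0 - 2))
  empty <- score_model("empty", -0.5, setNames(numeric(0), character(0)))
  expect_equal(evaluate_score(empty, mat), c(-0.5, -0.5))
})

test_that("score models round-trip through JSON", {
  m <- score_model("KO", -1.25, c(K00001 = 830.5, K00002 = -12.125),
                   meta = list(lambda = 0.01))
  path <- withr::local_tempfile(fileext = ".json")
  write_score_model(m, path)
  m2 <- read_score_model(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
})

test_that("lasso_select recovers planted features and is seed-deterministic", {
  set.seed(12)
  n <- 120
  x <- matrix(rnorm(n * 52), n, 52, dimnames = list(NULL, paste0("f", 1:52)))
  y <- rbinom(n, 1, plogis(2.5 * x[, 1] - 2.5 * x[, 2]))
  m <- lasso_select(x, y, seed = 4, standardize = TRUE)
  expect_true(all(c("f1", "f2") %in% names(m$coefficients)))
  expect_lte(length(setdiff(names(m$coefficients), c("f1", "f2"))), 5)
  m2 <- lasso_select(x, y, seed = 4, standardize = TRUE)
  expect_identical(m$coefficients, m2$coefficients)
  # effectively infinite penalty shrinks everything away
  m3 <- lasso_select(x, y, lambda = 1e6)
  expect_length(m3$coefficients, 0)
  expect_error(lasso_select(x, rep(1, n)), "both classes")
  expect_error(lasso_select(x[, 1, drop = FALSE], y), "2 candidate")
})

test_that("roc_auc equals the brute-force pairwise oracle on fixtures", {
  expect_equal(suppressWarnings(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    scores <- round(rnorm(n, y), 1)   # rounding creates ties
    expect_equal(suppressWarnings(roc_auc(scores, y))$auc,
                 auc_oracle(scores, y), tolerance = 1e-12)
  }
  expect_warning(const <- roc_auc(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_equal(const$auc, 0.5)
})

test_that("roc_auc CI is ordered and null AUC concentrates near 0.5", {
  set.seed(24)
  y <- rep(c(0, 1), each = 1000)
  r <- roc_auc(rnorm(2000), y)
  expect_lt(abs(r$auc - 0.5), 0.03)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_gt(r$p, 0.001)
})

test_that("nagelkerke_r2 matches the likelihood-ratio formula", {
  y <- c(0, 0, 0, 1, 1, 1, 0, 1)
  expect_equal(nagelkerke_r2(y, rep(mean(y), 8)), 0)
  expect_warning(r_cap <- nagelkerke_r2(y, ifelse(y == 1, 1, 0)), "separation")
  expect_equal(r_cap, 1)
  expect_gt(nagelkerke_r2(y, ifelse(y == 1, 1 - 1e-15, 1e-15)), 0.999)
  # direct likelihood evaluation on a logistic fit of a small fixed table
  x <- c(1, 2, 3, 4, 5, 6, 2, 5)
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  p <- fitted(fit)
  n <- length(y)
  ll1 <- sum(dbinom(y, 1, p, log = TRUE))
  ll0 <- sum(dbinom(y, 1, mean(y), log = TRUE))
  expected <- (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
  expect_equal(nagelkerke_r2(y, p), expected, tolerance = 1e-12)
})

test_that("bootstrap_optimism is deterministic and reports coherent fields", {
  set.seed(3)
  n <- 60
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rbinom(n, 1, 0.5)
  r1 <- suppressWarnings(bootstrap_optimism(x, y, B = 2, seed = 7, cv_folds = 5))
  r2 <- suppressWarnings(bootstrap_optimism(x, y, B = 2, seed = 7, cv_folds = 5))
  expect_identical(r1, r2)
  expect_equal(r1$corrected_auc, r1$apparent_auc - r1$mean_optimism_auc)
  expect_equal(r1$B, 2)
})
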