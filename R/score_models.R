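#' Construct a sparse linear score model
#'
#' A score model is an intercept plus a sparse coefficient vector over
#' selected features; a sample's score is the plain linear combination
#' intercept + sum(coef * abundance).
#'
#' @param name model name, one of \code{"KO"}, \code{"enzyme"},
#'   \code{"species"} (free-form names allowed).
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector of nonzero coefficients.
#' @param meta optional list of selection metadata (lambda, cv_folds, seed).
#' @return object of class \code{score_model}.
#' @export
score_model <- function(name, intercept, coefficients, meta = list()) {
  if (length(coefficients) > 0 && is.null(names(coefficients)))
    stop("coefficients must be named by feature id")
  coefficients <- coefficients[coefficients != 0]
  structure(list(name = name, intercept = as.numeric(intercept),
                 coefficients = coefficients, meta = meta),
            class = "score_model")
}

#' @method print score_model
#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model '%s': intercept %.4g, %d nonzero coefficients\n",
              x$name, x$intercept, length(x$coefficients)))
  invisible(x)
}

#' LASSO feature selection for a two-group score model
#'
#' Fits an L1-penalized logistic regression of group on feature abundances
#' with the penalty chosen by stratified cross-validation, and keeps only
#' features with nonzero coefficients. By default features enter on their
#' raw relative-abundance scale (no standardization), which yields
#' coefficients on the order of 1/abundance; a flag enables internal
#' standardization.
#'
#' @param features an \code{abundance_matrix}, or a plain numeric matrix
#'   (samples x features) when \code{labels} is supplied.
#' @param labels optional 0/1 or CTR/AF labels (taken from the matrix group
#'   when absent); AF is coded 1.
#' @param cv_folds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param lambda \code{"1se"} (default, sparser), \code{"min"}, or a fixed
#'   numeric penalty value.
#' @param standardize standardize features internally (default FALSE).
#' @param name model name.
#' @return a \code{score_model}.
#' @export
lasso_select <- function(features, labels = NULL, cv_folds = 10, seed = 1,
                         lambda = "1se", standardize = FALSE, name = "KO") {
  if (inherits(features, "abundance_matrix")) {
    x <- features$values
    if (is.null(labels)) labels <- features$group
  } else x <- as.matrix(features)
  y <- encode_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present in labels")
  if (ncol(x) < 2) stop("need at least 2 candidate features")
  if (is.numeric(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = standardize, lambda = lambda)
    cf <- as.matrix(stats::coef(fit, s = lambda))
    lam <- lambda
  } else {
    lambda <- match.arg(lambda, c("1se", "min"))
    set.seed(seed)
    foldid <- stratified_folds(y, cv_folds)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            standardize = standardize, foldid = foldid)
    lam <- if (lambda == "1se") cv$lambda.1se else cv$lambda.min
    cf <- as.matrix(stats::coef(cv, s = lam))
  }
  coefs <- cf[-1, 1]
  coefs <- coefs[coefs != 0]
  score_model(name, intercept = cf[1, 1], coefficients = coefs,
              meta = list(lambda = lam, cv_folds = cv_folds, seed = seed,
                          standardize = standardize))
}

encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("CTR", "AF"))
    if (length(bad) > 0) stop("labels must be CTR/AF or 0/1")
    as.integer(labels == "AF")
  } else as.integer(labels)
}

stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Evaluate a score model on abundance profiles
#'
#' Linear evaluation intercept + sum(coef * abundance). Model features
#' missing from the input are treated as zero abundance with a warning.
#'
#' @param model a \code{score_model}.
#' @param abundances named numeric vector (one sample), or a matrix /
#'   \code{abundance_matrix} with features in columns (one score per row).
#' @return numeric score(s).
#' @export
evaluate_score <- function(model, abundances) {
  stopifnot(inherits(model, "score_model"))
  if (inherits(abundances, "abundance_matrix")) abundances <- abundances$values
  feats <- names(model$coefficients)
  if (length(feats) == 0) {
    n <- if (is.matrix(abundances)) nrow(abundances) else 1L
    return(rep(model$intercept, n))
  }
  if (is.matrix(abundances)) {
    missing <- setdiff(feats, colnames(abundances))
    if (length(missing) > 0) {
      warning("features absent, treated as 0: ", paste(missing, collapse = ", "))
      pad <- matrix(0, nrow(abundances), length(missing),
                    dimnames = list(rownames(abundances), missing))
      abundances <- cbind(abundances, pad)
    }
    drop(model$intercept + abundances[, feats, drop = FALSE] %*% model$coefficients)
  } else {
    missing <- setdiff(feats, names(abundances))
    if (length(missing) > 0)
      warning("features absent, treated as 0: ", paste(missing, collapse = ", "))
    present <- intersect(feats, names(abundances))
    model$intercept + sum(model$coefficients[present] * abundances[present])
  }
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney probability that a positive-class score exceeds a
#' negative-class score (ties count one half). The 95 percent CI uses
#' DeLong's placement-value variance; the p-value tests AUC = 0.5 with the
#' same standard error.
#'
#' @param scores numeric vector of scores (higher = more AF-like).
#' @param labels 0/1 or CTR/AF labels; AF/1 is the positive class.
#' @return list with \code{auc}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{se}.
#' @export
roc_auc <- function(scores, labels) {
  y <- encode_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (length(unique(scores)) == 1) {
    warning("constant scores; AUC = 0.5 with degenerate CI")
    return(list(auc = 0.5, ci_low = 0.5, ci_high = 0.5, p = 1, se = 0))
  }
  # placement values (DeLong): V10_i = fraction of negatives below pos_i
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  auc <- mean(cmp)
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  se <- sqrt(s10 / n1 + s01 / n0)
  z <- stats::qnorm(0.975)
  ci_low <- max(0, auc - z * se)
  ci_high <- min(1, auc + z * se)
  p <- if (se == 0) {
    warning("degenerate DeLong variance; p undefined, reported as 0")
    0
  } else 2 * stats::pnorm(-abs(auc - 0.5) / se)
  list(auc = auc, ci_low = ci_low, ci_high = ci_high, p = p, se = se)
}

#' Nagelkerke pseudo R-squared
#'
#' R2 = (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n)) with L1 the binomial
#' likelihood of the fitted probabilities and L0 that of the intercept-only
#' (prevalence) model.
#'
#' @param labels 0/1 or CTR/AF outcomes.
#' @param fitted_probs fitted success probabilities in (0, 1).
#' @return scalar in [0, 1].
#' @export
nagelkerke_r2 <- function(labels, fitted_probs) {
  y <- encode_labels(labels)
  p <- fitted_probs
  if (any(p <= 0) || any(p >= 1)) {
    warning("probabilities at 0/1 clipped; possible perfect separation")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  n <- length(y)
  ll1 <- sum(y * log(p) + (1 - y) * log(1 - p))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  r2 <- (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
  min(1, max(0, r2))
}

#' Harrell bootstrap optimism correction for a LASSO score model
#'
#' The apparent AUC and Nagelkerke R2 come from fitting the full selection
#' plus model procedure on the complete cohort and evaluating on the same
#' cohort. For each of B bootstrap resamples the entire procedure is refit;
#' optimism is the bootstrap-model performance on the bootstrap sample minus
#' its performance on the original cohort, and the mean optimism is
#' subtracted from the apparent estimates.
#'
#' @param features matrix or \code{abundance_matrix} of candidate features.
#' @param labels outcome labels (taken from the matrix when absent).
#' @param B number of bootstrap resamples (default 500).
#' @param seed integer seed.
#' @param ... passed to \code{lasso_select} (cv_folds, lambda, standardize).
#' @return list with \code{apparent_auc}, \code{mean_optimism_auc},
#'   \code{corrected_auc}, \code{apparent_r2}, \code{corrected_r2},
#'   \code{B}, \code{redraws} (single-class resamples redrawn).
#' @export
bootstrap_optimism <- function(features, labels = NULL, B = 500, seed = 1, ...) {
  if (inherits(features, "abundance_matrix")) {
    x <- features$values
    if (is.null(labels)) labels <- features$group
  } else x <- as.matrix(features)
  y <- encode_labels(labels)
  n <- length(y)
  fit_and_probs <- function(xx, yy, sd) {
    m <- lasso_select(xx, yy, seed = sd, ...)
    list(model = m,
         score = function(xnew) suppressWarnings(evaluate_score(m, xnew)))
  }
  full <- fit_and_probs(x, y, seed)
  app_scores <- full$score(x)
  apparent_auc <- roc_auc(app_scores, y)$auc
  apparent_r2 <- nagelkerke_r2(y, stats::plogis(app_scores))
  set.seed(seed)
  opt_auc <- numeric(B); opt_r2 <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      redraws <- redraws + 1L
    }
    bf <- fit_and_probs(x[idx, , drop = FALSE], y[idx], seed + b)
    sb <- bf$score(x[idx, , drop = FALSE])
    so <- bf$score(x)
    auc_bb <- roc_auc(sb, y[idx])$auc
    auc_bo <- roc_auc(so, y)$auc
    opt_auc[b] <- auc_bb - auc_bo
    r2_bb <- nagelkerke_r2(y[idx], stats::plogis(sb))
    r2_bo <- nagelkerke_r2(y, stats::plogis(so))
    opt_r2[b] <- r2_bb - r2_bo
  }
  list(apparent_auc = apparent_auc,
       mean_optimism_auc = mean(opt_auc),
       corrected_auc = apparent_auc - mean(opt_auc),
       apparent_r2 = apparent_r2,
       mean_optimism_r2 = mean(opt_r2),
       corrected_r2 = apparent_r2 - mean(opt_r2),
       B = B, redraws = redraws)
}

#' Write a score model to JSON
#'
#' @param model a \code{score_model}.
#' @param path output path.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  jsonlite::write_json(list(name = model$name, intercept = model$intercept,
                            coefficients = as.list(model$coefficients),
                            meta = model$meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a score model from JSON
#'
#' @param path JSON file written by \code{write_score_model} (or a packaged
#'   model file).
#' @return a \code{score_model}.
#' @export
read_score_model <- function(path) {
  j <- jsonlite::read_json(path)
  score_model(j$name, j$intercept, unlist(j$coefficients),
              meta = if (is.null(j$meta)) list() else j$meta)
}

#' Load one of the published score models shipped with the package
#'
#' The three sparse logistic score models (KO, enzyme, species) transcribed
#' from the published study are packaged as JSON; their coefficients sit on
#' the raw relative-abundance scale.
#'
#' @param name \code{"KO"}, \code{"enzyme"} or \code{"species"}.
#' @return a \code{score_model}.
#' @export
published_score_model <- function(name = c("KO", "enzyme", "species")) {
  name <- match.arg(name)
  file <- c(KO = "ko_score_model.json", enzyme = "enzyme_score_model.json",
            species = "species_score_model.json")[[name]]
  path <- system.file("extdata", "published_models", file, package = "scfaflow")
  if (path == "") stop("packaged model not found: ", file)
  read_score_model(path)
}
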