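#' Spearman correlation with midrank ties and t-approximation p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho} and two-sided \code{p}.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Spearman correlation network over a variable table
#'
#' Computes tie-aware Spearman rho and a two-sided p-value for every
#' unordered variable pair, applies Benjamini-Hochberg correction across all
#' pairs, and flags the edges passing both the FDR and the absolute
#' correlation thresholds. Constant variables have undefined correlations;
#' their pairs are excluded and reported.
#'
#' @param table data.frame or matrix, samples x variables.
#' @param r_threshold minimum |rho| for a kept edge (default 0.15).
#' @param alpha FDR threshold on q (default 0.05).
#' @return data.frame of edges: \code{node_a}, \code{node_b}, \code{rho},
#'   \code{p}, \code{q}, \code{kept}; excluded variables are attached as
#'   attribute \code{"excluded"}.
#' @export
spearman_network <- function(table, r_threshold = 0.15, alpha = 0.05) {
  tab <- as.data.frame(table)
  if (nrow(tab) < 3) stop("need at least 3 samples")
  vars <- names(tab)
  constant <- vars[vapply(tab, function(v) stats::sd(v) == 0, logical(1))]
  if (length(constant) > 0)
    warning("constant variables excluded: ", paste(constant, collapse = ", "))
  vars <- setdiff(vars, constant)
  if (length(vars) < 2) stop("fewer than 2 non-constant variables")
  pairs <- utils::combn(vars, 2)
  res <- apply(pairs, 2, function(pr) {
    s <- spearman_cor(tab[[pr[1]]], tab[[pr[2]]])
    c(rho = s$rho, p = s$p)
  })
  edges <- data.frame(node_a = pairs[1, ], node_b = pairs[2, ],
                      rho = res["rho", ], p = res["p", ],
                      stringsAsFactors = FALSE)
  edges$q <- bh_adjust(edges$p)
  edges$kept <- edges$q < alpha & abs(edges$rho) > r_threshold
  attr(edges, "excluded") <- constant
  edges
}

#' Uni- or multivariable logistic regression with Wald intervals
#'
#' Maximum-likelihood logistic fits reporting odds ratios (exp(coef)) with
#' Wald 95 percent confidence intervals. In univariable mode each predictor
#' gets its own model; otherwise one joint model is fit. Quasi-complete
#' separation (detected from non-convergence or exploding coefficients) is
#' an error, with a pointer towards penalized fits.
#'
#' @param outcome binary vector (0/1 or CTR/AF; AF = 1).
#' @param predictors data.frame of predictors.
#' @param univariable fit one model per predictor (default TRUE).
#' @return data.frame with columns \code{term}, \code{odds_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{p}.
#' @export
logistic_fit <- function(outcome, predictors, univariable = TRUE) {
  y <- encode_labels(outcome)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  predictors <- as.data.frame(predictors)
  if (length(y) <= ncol(predictors) + 1)
    stop("need more observations than predictors")
  fit_one <- function(df) {
    fit <- stats::glm(y ~ ., data = cbind(y = y, df), family = stats::binomial())
    cf <- summary(fit)$coefficients
    slope_rows <- rownames(cf) != "(Intercept)"
    if (!fit$converged || any(abs(cf[slope_rows, "Estimate"]) > 15))
      stop("separation detected; consider a penalized (e.g. LASSO) fit")
    est <- cf[slope_rows, , drop = FALSE]
    z <- stats::qnorm(0.975)
    data.frame(term = rownames(est),
               odds_ratio = exp(est[, "Estimate"]),
               ci_low = exp(est[, "Estimate"] - z * est[, "Std. Error"]),
               ci_high = exp(est[, "Estimate"] + z * est[, "Std. Error"]),
               p = est[, "Pr(>|z|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (univariable) {
    do.call(rbind, lapply(names(predictors), function(v)
      fit_one(predictors[, v, drop = FALSE])))
  } else {
    fit_one(predictors)
  }
}
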