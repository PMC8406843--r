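#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value (via the null rank-sum distribution) when both samples are
#' small (min n <= \code{exact_max}) and tie-free; otherwise a tie-corrected
#' normal approximation without continuity correction. Returns the
#' Mann-Whitney U statistic for the first sample.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max largest min(n) for which the exact distribution is used.
#' @return list with \code{statistic} (U) and \code{p}.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("all pooled values identical; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  r <- rank(pooled)
  nx <- length(x); ny <- length(y); n <- nx + ny
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (!has_ties && min(nx, ny) <= exact_max) {
    # exact two-sided p from the null distribution of U
    p <- if (u > nx * ny / 2) {
      2 * (1 - stats::pwilcox(u - 1, nx, ny))
    } else {
      2 * stats::pwilcox(u, nx, ny)
    }
    p <- min(1, p)
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_i is the minimum over all p_(j) >= p_(i) of m * p_(j) / j, capped at 1;
#' monotone in the input and invariant to input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values aligned with \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
  q
}

#' Log2 fold change of group means
#'
#' log2((mean(af) + pseudo) / (mean(ctr) + pseudo)). A pseudo-count guards
#' against zero means; with both group means zero the fold change is 0.
#'
#' @param x_af values in the AF group.
#' @param y_ctr values in the CTR group.
#' @param pseudo pseudo-count added to both means (default 0).
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return scalar log2 fold change (AF over CTR).
#' @export
log2_fold_change <- function(x_af, y_ctr, pseudo = 0, center = c("mean", "median")) {
  center <- match.arg(center)
  f <- if (center == "mean") mean else stats::median
  a <- f(x_af); c <- f(y_ctr)
  if (a == 0 && c == 0) {
    warning("both group centers are zero; log2FC = 0")
    return(0)
  }
  if ((a + pseudo) <= 0 || (c + pseudo) <= 0)
    stop("non-positive center with pseudo = ", pseudo, "; supply pseudo > 0")
  log2((a + pseudo) / (c + pseudo))
}

#' Per-feature differential abundance table
#'
#' Wilcoxon rank-sum per feature (AF vs CTR), Benjamini-Hochberg correction
#' across features, and log2 fold change of group means with a zero-safe
#' pseudo-count (half the smallest nonzero value in the matrix). Features
#' with q below \code{alpha} are classified AF-enriched or AF-deficient by
#' the sign of the fold change; all others are NS.
#'
#' @param matrix an \code{abundance_matrix} containing both groups.
#' @param alpha significance threshold on q (default 0.05).
#' @param center passed to \code{log2_fold_change}.
#' @return data.frame with columns \code{feature_id}, \code{statistic},
#'   \code{p}, \code{q}, \code{log2fc}, \code{direction}.
#' @export
differential_table <- function(matrix, alpha = 0.05, center = "mean") {
  stopifnot(inherits(matrix, "abundance_matrix"))
  grp <- matrix$group
  if (nlevels(droplevels(grp)) < 2)
    stop("both groups (CTR, AF) must be present")
  vals <- matrix$values
  nz <- vals[vals > 0]
  pseudo <- if (length(nz) > 0) min(nz) / 2 else 1e-12
  af <- vals[grp == "AF", , drop = FALSE]
  ctr <- vals[grp == "CTR", , drop = FALSE]
  res <- lapply(seq_len(ncol(vals)), function(j) {
    w <- suppressWarnings(wilcoxon_rank_sum(af[, j], ctr[, j]))
    fc <- suppressWarnings(log2_fold_change(af[, j], ctr[, j],
                                            pseudo = pseudo, center = center))
    c(statistic = w$statistic, p = w$p, log2fc = fc)
  })
  res <- do.call(rbind, res)
  q <- bh_adjust(res[, "p"])
  direction <- ifelse(q < alpha,
                      ifelse(res[, "log2fc"] > 0, "AF-enriched", "AF-deficient"),
                      "NS")
  data.frame(feature_id = colnames(vals),
             statistic = res[, "statistic"],
             p = res[, "p"], q = q,
             log2fc = res[, "log2fc"],
             direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
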