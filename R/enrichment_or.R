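#' Pooled odds-ratio enrichment statistic for one feature
#'
#' For feature k the statistic pools abundance within each group:
#' OR(k) = [sum_{s in CTR} A_sk / sum_{s in CTR} sum_{i != k} A_si] /
#'         [sum_{s in AF}  A_sk / sum_{s in AF}  sum_{i != k} A_si].
#' Taken literally, the control group sits in the numerator, so OR > 1
#' means the feature carries relatively more mass in CTR. Because the
#' source material also uses the opposite reading (log2 OR > 0 labelled
#' AF-enriched), the labelling convention is exposed: \code{"formula"}
#' labels OR > 1 as CTR-enriched; \code{"af-positive"} flips the labels.
#'
#' @param matrix an \code{abundance_matrix} with both groups present.
#' @param k feature id.
#' @param pseudo added to any zero pooled sum (default 1e-12); nonzero
#'   sums are left exact.
#' @param convention \code{"formula"} (default) or \code{"af-positive"}.
#' @return list with \code{feature_id}, \code{or_value}, \code{log2_or},
#'   \code{label}.
#' @export
or_score <- function(matrix, k, pseudo = 1e-12,
                     convention = c("formula", "af-positive")) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  convention <- match.arg(convention)
  if (!(k %in% colnames(matrix$values)))
    stop("feature not in matrix: ", k)
  grp <- matrix$group
  if (!all(c("CTR", "AF") %in% as.character(unique(grp))))
    stop("both groups (CTR, AF) must be present")
  vals <- matrix$values
  kk <- which(colnames(vals) == k)
  sums <- function(g) {
    sub <- vals[grp == g, , drop = FALSE]
    c(feat = sum(sub[, kk]), rest = sum(sub[, -kk, drop = FALSE]))
  }
  ctr <- sums("CTR"); af <- sums("AF")
  guard <- function(x) if (x == 0) pseudo else x
  or_value <- (guard(ctr["feat"]) / guard(ctr["rest"])) /
              (guard(af["feat"]) / guard(af["rest"]))
  or_value <- unname(or_value)
  log2_or <- log2(or_value)
  label <- if (or_value == 1) "balanced"
           else if (xor(or_value > 1, convention == "af-positive"))
             "CTR-enriched" else "AF-enriched"
  list(feature_id = k, or_value = or_value, log2_or = log2_or, label = label)
}

#' Odds-ratio enrichment table over all features
#'
#' @param matrix an \code{abundance_matrix}.
#' @param pseudo,convention passed to \code{or_score}.
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{or_value}, \code{log2_or}, \code{label}.
#' @export
or_table <- function(matrix, pseudo = 1e-12, convention = "formula") {
  stopifnot(inherits(matrix, "abundance_matrix"))
  rows <- lapply(colnames(matrix$values), function(k)
    or_score(matrix, k, pseudo = pseudo, convention = convention))
  data.frame(feature_id = vapply(rows, `[[`, character(1), "feature_id"),
             or_value = vapply(rows, `[[`, numeric(1), "or_value"),
             log2_or = vapply(rows, `[[`, numeric(1), "log2_or"),
             label = vapply(rows, `[[`, character(1), "label"),
             stringsAsFactors = FALSE)
}
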