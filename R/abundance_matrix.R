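#' Construct a samples-by-features relative abundance matrix
#'
#' The central data container of the package: a numeric matrix with samples
#' in rows and features (genes, KOs, enzymes or species) in columns, plus a
#' two-level group factor (\code{CTR} vs \code{AF}) aligned with the rows.
#' Values are unitless relative abundances; complete (untruncated) profiles
#' sum to 1 per sample.
#'
#' @param values numeric matrix, samples x features, with row and column names.
#' @param group character or factor of length \code{nrow(values)} with levels
#'   \code{"CTR"} and \code{"AF"}.
#' @return an object of class \code{abundance_matrix}.
#' @export
abundance_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x features)")
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) stop("'values' must have feature (column) names")
  if (any(values < 0)) stop("abundances must be non-negative")
  group <- as.character(group)
  if (length(group) != nrow(values))
    stop("'group' must have one label per sample (row)")
  bad <- setdiff(unique(group), c("CTR", "AF"))
  if (length(bad) > 0)
    stop("group labels must be 'CTR' or 'AF'; found: ", paste(bad, collapse = ", "))
  structure(list(values = values,
                 group = factor(group, levels = c("CTR", "AF"))),
            class = "abundance_matrix")
}

#' @method print abundance_matrix
#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d features (%d CTR, %d AF)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "CTR"), sum(x$group == "AF")))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset the feature columns of an abundance matrix
#'
#' @param x an \code{abundance_matrix}.
#' @param features character vector of feature ids to keep.
#' @return an \code{abundance_matrix} restricted to \code{features}.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "abundance_matrix"))
  missing <- setdiff(features, colnames(x$values))
  if (length(missing) > 0)
    stop("features absent from matrix: ", paste(missing, collapse = ", "))
  abundance_matrix(x$values[, features, drop = FALSE], as.character(x$group))
}

#' Write an abundance matrix to TSV (samples in rows, feature header)
#'
#' A leading \code{sample_id} column and a \code{group} column are added so
#' the file round-trips through \code{read_abundance_tsv}.
#'
#' @param x an \code{abundance_matrix}.
#' @param path output file path.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(sample_id = rownames(x$values),
                   group = as.character(x$group),
                   x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix written by \code{write_abundance_tsv}
#'
#' @param path TSV file with \code{sample_id}, \code{group} and one column
#'   per feature.
#' @return an \code{abundance_matrix}.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("abundance TSV must contain 'sample_id' and 'group' columns")
  vals <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE])
  rownames(vals) <- df$sample_id
  abundance_matrix(vals, df$group)
}
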