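#' Length-normalized relative gene abundance
#'
#' Converts per-gene read counts into relative abundances by dividing each
#' count by gene length and closing the result to 1:
#' G_i = (r_i / L_i) / sum_j (r_j / L_j).
#' Genes with fewer than \code{min_reads} mapped reads are dropped before
#' normalization, so low-evidence genes contribute no mass.
#'
#' @param table data.frame with columns \code{gene_id}, \code{read_count}
#'   and \code{gene_length_bp}.
#' @param min_reads minimum mapped reads for a gene to be kept (default 2).
#' @return named numeric vector of relative abundances summing to 1.
#' @export
normalize_genes <- function(table, min_reads = 2) {
  required <- c("gene_id", "read_count", "gene_length_bp")
  if (!all(required %in% names(table)))
    stop("gene table needs columns: ", paste(required, collapse = ", "))
  if (any(table$gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (any(table$read_count < 0)) stop("read counts must be non-negative")
  keep <- table$read_count >= min_reads
  if (!any(keep))
    stop("no gene passes the minimum-read filter (min_reads = ", min_reads, ")")
  tab <- table[keep, , drop = FALSE]
  rate <- tab$read_count / tab$gene_length_bp
  g <- rate / sum(rate)
  names(g) <- tab$gene_id
  g
}

#' Aggregate gene abundances to features (KOs, enzymes, species)
#'
#' Sums the relative abundances of all genes annotated to the same feature.
#' The mapping may be partial; mass carried by unannotated genes is reported
#' separately so that total mass is conserved exactly.
#'
#' @param genes named numeric vector of gene abundances (as produced by
#'   \code{normalize_genes}).
#' @param mapping data.frame with columns \code{gene_id} and
#'   \code{feature_id}; genes absent from it are counted as unmapped. A gene
#'   mapped to several features contributes its full abundance to each.
#' @return list with \code{features} (named numeric vector) and
#'   \code{unmapped} (scalar mass of unannotated genes).
#' @export
aggregate_features <- function(genes, mapping) {
  if (is.null(names(genes))) stop("'genes' must be a named vector")
  if (!all(c("gene_id", "feature_id") %in% names(mapping)))
    stop("mapping needs columns gene_id, feature_id")
  mapping <- mapping[mapping$gene_id %in% names(genes), , drop = FALSE]
  if (nrow(mapping) == 0) {
    return(list(features = stats::setNames(numeric(0), character(0)),
                unmapped = sum(genes)))
  }
  contrib <- genes[mapping$gene_id]
  features <- vapply(split(contrib, mapping$feature_id), sum, numeric(1))
  unmapped <- sum(genes[!(names(genes) %in% mapping$gene_id)])
  list(features = features, unmapped = unmapped)
}

#' Build a per-sample feature abundance matrix from gene tables
#'
#' Applies \code{normalize_genes} then \code{aggregate_features} to each
#' sample's gene read table and assembles the results into an
#' \code{abundance_matrix} over the union of observed features.
#'
#' @param gene_tables named list of per-sample gene read tables (see
#'   \code{normalize_genes}).
#' @param mapping gene-to-feature annotation data.frame.
#' @param group group label per sample, aligned with \code{gene_tables}.
#' @param min_reads minimum-read filter passed to \code{normalize_genes}.
#' @return an \code{abundance_matrix}; per-sample unmapped mass is attached
#'   as attribute \code{"unmapped"}.
#' @export
feature_matrix_from_genes <- function(gene_tables, mapping, group, min_reads = 2) {
  per_sample <- lapply(gene_tables, function(tab) {
    aggregate_features(normalize_genes(tab, min_reads = min_reads), mapping)
  })
  feats <- sort(unique(unlist(lapply(per_sample, function(p) names(p$features)))))
  vals <- t(vapply(per_sample, function(p) {
    v <- stats::setNames(numeric(length(feats)), feats)
    v[names(p$features)] <- p$features
    v
  }, numeric(length(feats))))
  rownames(vals) <- names(gene_tables)
  out <- abundance_matrix(vals, group)
  attr(out, "unmapped") <- vapply(per_sample, `[[`, numeric(1), "unmapped")
  out
}
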