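#' Construct and validate a rooted taxonomy table
#'
#' NCBI-nodes-like representation: one row per taxon with a parent pointer.
#' The root is the unique taxon whose parent is itself or NA. Validation
#' rejects multiple roots, dangling parents and cycles.
#'
#' @param df data.frame with columns \code{taxon_id}, \code{parent_id},
#'   \code{rank}, \code{name}.
#' @return object of class \code{taxonomy_table}.
#' @export
taxonomy_table <- function(df) {
  required <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(required %in% names(df)))
    stop("taxonomy needs columns: ", paste(required, collapse = ", "))
  df$taxon_id <- as.character(df$taxon_id)
  df$parent_id <- as.character(df$parent_id)
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon ids in taxonomy")
  is_root <- is.na(df$parent_id) | df$parent_id == df$taxon_id
  if (sum(is_root) != 1)
    stop("taxonomy must have exactly one root (parent NA or self); found ",
         sum(is_root))
  dangling <- setdiff(df$parent_id[!is_root], df$taxon_id)
  if (length(dangling) > 0)
    stop("parent ids missing from taxonomy: ", paste(dangling, collapse = ", "))
  parent <- stats::setNames(df$parent_id, df$taxon_id)
  root <- df$taxon_id[is_root]
  parent[root] <- NA_character_
  # cycle check: every node must reach the root in <= n steps
  n <- nrow(df)
  for (t in df$taxon_id) {
    cur <- t
    steps <- 0L
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxon ", t)
    }
  }
  structure(list(df = df, parent = parent, root = root,
                 rank = stats::setNames(df$rank, df$taxon_id),
                 name = stats::setNames(df$name, df$taxon_id)),
            class = "taxonomy_table")
}

#' Read a taxonomy from a 4-column TSV
#'
#' @param path TSV with columns \code{taxon_id}, \code{parent_id},
#'   \code{rank}, \code{name}.
#' @return a \code{taxonomy_table}.
#' @export
read_taxonomy_tsv <- function(path) {
  taxonomy_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                   colClasses = "character"))
}

#' @method print taxonomy_table
#' @export
print.taxonomy_table <- function(x, ...) {
  cat(sprintf("taxonomy_table: %d taxa, root '%s'\n", nrow(x$df), x$root))
  invisible(x)
}

# root-to-node path, root first
taxon_path <- function(taxonomy, taxon) {
  path <- character(0)
  cur <- taxon
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- taxonomy$parent[[cur]]
  }
  path
}

#' Retain significant alignment hits for one gene
#'
#' Keeps hits whose e-value is at most \code{factor} times the best (lowest)
#' e-value among the gene's hits; the top hit is always retained, and the
#' operation is idempotent.
#'
#' @param hits_for_gene data.frame of hits for a single gene with at least
#'   an \code{e_value} column.
#' @param factor retention multiplier on the top e-value (default 10).
#' @return the retained rows of \code{hits_for_gene}.
#' @export
retain_significant <- function(hits_for_gene, factor = 10) {
  if (nrow(hits_for_gene) == 0) stop("no hits supplied")
  if (any(hits_for_gene$e_value <= 0)) stop("e-values must be positive")
  best <- min(hits_for_gene$e_value)
  hits_for_gene[hits_for_gene$e_value <= factor * best, , drop = FALSE]
}

#' Lowest common ancestor of a taxon set
#'
#' Returns the deepest taxonomy node that is ancestral to (or equal to)
#' every input taxon.
#'
#' @param taxa character vector of taxon ids (non-empty).
#' @param taxonomy a \code{taxonomy_table}.
#' @return a single taxon id.
#' @export
lca <- function(taxa, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0) stop("'taxa' must be non-empty")
  unknown <- setdiff(taxa, names(taxonomy$parent))
  if (length(unknown) > 0)
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  paths <- lapply(taxa, taxon_path, taxonomy = taxonomy)
  depth <- min(vapply(paths, length, integer(1)))
  anc <- taxonomy$root
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[[`, character(1), d)
    if (length(unique(level)) > 1) break
    anc <- level[1]
  }
  anc
}

#' Validate a hit table against a taxonomy
#'
#' @param hits data.frame with columns \code{gene_id}, \code{taxon_id},
#'   \code{e_value}, \code{bit_score}.
#' @param taxonomy a \code{taxonomy_table}.
#' @return the validated hit table (invisibly usable).
#' @export
validate_hit_table <- function(hits, taxonomy) {
  required <- c("gene_id", "taxon_id", "e_value", "bit_score")
  if (!all(required %in% names(hits)))
    stop("hit table needs columns: ", paste(required, collapse = ", "))
  if (any(hits$e_value <= 0)) stop("e-values must be positive")
  unknown <- setdiff(unique(hits$taxon_id), names(taxonomy$parent))
  if (length(unknown) > 0)
    stop("hit taxa absent from taxonomy: ", paste(unknown, collapse = ", "))
  hits
}

#' Assign each gene to a taxon via retention plus LCA
#'
#' For every gene, hits within 10x (by default) of the best e-value are
#' retained and the gene is placed at the lowest common ancestor of the
#' retained hit taxa.
#'
#' @param hits hit table (see \code{validate_hit_table}).
#' @param taxonomy a \code{taxonomy_table}.
#' @param factor e-value retention multiplier.
#' @return named character vector, gene id -> assigned taxon id.
#' @export
assign_gene_taxa <- function(hits, taxonomy, factor = 10) {
  validate_hit_table(hits, taxonomy)
  by_gene <- split(hits, hits$gene_id)
  vapply(by_gene, function(h) {
    kept <- retain_significant(h, factor = factor)
    lca(kept$taxon_id, taxonomy)
  }, character(1))
}

#' Species harboring enzyme genes, with abundance contributions
#'
#' A species harbors an enzyme if at least one gene is annotated to that
#' enzyme and taxonomically assigned to that species. Genes whose LCA lies
#' above species rank carry real abundance but no species assignment; they
#' are excluded from the species table and listed in the exclusion report.
#'
#' @param gene2enzyme data.frame with columns \code{gene_id},
#'   \code{feature_id} (enzyme).
#' @param gene2taxon named character vector from \code{assign_gene_taxa}.
#' @param abundance an \code{abundance_matrix} of gene abundances
#'   (samples x genes), or a named numeric vector for a single profile.
#' @param taxonomy a \code{taxonomy_table} (for rank lookup).
#' @return list with \code{species_enzyme} (species x enzyme matrix of
#'   summed abundance contributions), \code{species_counts} (data.frame
#'   enzyme, n_species) and \code{excluded} (data.frame of genes resolved
#'   above species rank).
#' @export
harboring_species <- function(gene2enzyme, gene2taxon, abundance, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  if (inherits(abundance, "abundance_matrix")) {
    gene_mass <- colSums(abundance$values)
  } else if (is.numeric(abundance) && !is.null(names(abundance))) {
    gene_mass <- abundance
  } else stop("'abundance' must be an abundance_matrix or named numeric vector")
  genes <- intersect(gene2enzyme$gene_id, names(gene2taxon))
  g2e <- gene2enzyme[gene2enzyme$gene_id %in% genes, , drop = FALSE]
  tax <- gene2taxon[g2e$gene_id]
  at_species <- taxonomy$rank[tax] == "species"
  excluded <- data.frame(gene_id = g2e$gene_id[!at_species],
                         enzyme = g2e$feature_id[!at_species],
                         taxon_id = unname(tax[!at_species]),
                         rank = unname(taxonomy$rank[tax[!at_species]]),
                         stringsAsFactors = FALSE)
  kept <- g2e[at_species, , drop = FALSE]
  ktax <- unname(tax[at_species])
  if (nrow(kept) == 0) {
    return(list(species_enzyme = matrix(numeric(0), 0, 0),
                species_counts = data.frame(enzyme = character(0),
                                            n_species = integer(0)),
                excluded = excluded))
  }
  species <- sort(unique(ktax))
  enzymes <- sort(unique(kept$feature_id))
  cells <- matrix(0, length(species), length(enzymes),
                  dimnames = list(species, enzymes))
  mass <- gene_mass[kept$gene_id]
  mass[is.na(mass)] <- 0
  for (i in seq_len(nrow(kept)))
    cells[ktax[i], kept$feature_id[i]] <- cells[ktax[i], kept$feature_id[i]] + mass[i]
  counts <- data.frame(
    enzyme = enzymes,
    n_species = vapply(enzymes, function(e)
      length(unique(ktax[kept$feature_id == e])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(species_enzyme = cells, species_counts = counts, excluded = excluded)
}
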