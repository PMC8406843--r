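#' Read a compound-to-KO mapping table
#'
#' The mapping links KEGG compound accessions (C#####) to the KEGG
#' orthologues (K#####) participating in their synthesis. An optional
#' \code{class} column distinguishes straight-chain SCFA compounds from
#' branched-chain (BCFA) ones; absent, all records are classed \code{SCFA}.
#'
#' @param path TSV with columns \code{compound_id}, \code{ko_id} and
#'   optionally \code{class}.
#' @return data.frame with validated accession patterns.
#' @export
read_compound_ko_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "ko_id") %in% names(df)))
    stop("compound-KO map needs columns compound_id, ko_id")
  if (is.null(df$class)) df$class <- "SCFA"
  validate_compound_ko_map(df)
  df
}

validate_compound_ko_map <- function(map) {
  bad_c <- !grepl("^C[0-9]{5}$", map$compound_id)
  if (any(bad_c))
    stop("invalid compound ids: ", paste(unique(map$compound_id[bad_c]), collapse = ", "))
  bad_k <- !grepl("^K[0-9]{5}$", map$ko_id)
  if (any(bad_k))
    stop("invalid KO ids: ", paste(unique(map$ko_id[bad_k]), collapse = ", "))
  invisible(map)
}

#' Build a KO catalog from a compound-to-KO map
#'
#' Takes the union of KOs mapped to the requested compounds and records, for
#' each KO, the exact set of compounds it participates in (the membership
#' used for the compound-combination distribution).
#'
#' @param map data.frame as returned by \code{read_compound_ko_map}.
#' @param compounds character vector of compound accessions to include.
#' @return an object of class \code{ko_catalog} with fields \code{ko_ids},
#'   \code{membership} (named list KO -> compound set), \code{classes}
#'   (named compound -> class) and \code{annotated_overlap} (empty until
#'   \code{intersect_annotated} is called).
#' @export
build_catalog <- function(map, compounds) {
  validate_compound_ko_map(map)
  if (length(compounds) == 0) stop("'compounds' must be non-empty")
  absent <- setdiff(compounds, map$compound_id)
  if (length(absent) > 0) {
    warning("compounds absent from map, skipped: ", paste(absent, collapse = ", "))
    compounds <- setdiff(compounds, absent)
  }
  sub <- map[map$compound_id %in% compounds, , drop = FALSE]
  if (nrow(sub) == 0) stop("no KOs mapped to any requested compound")
  membership <- lapply(split(sub$compound_id, sub$ko_id), function(x) sort(unique(x)))
  classes <- vapply(split(sub$class, sub$compound_id), function(x) x[1], character(1))
  structure(list(ko_ids = sort(names(membership)),
                 membership = membership,
                 classes = classes,
                 annotated_overlap = character(0)),
            class = "ko_catalog")
}

#' @method print ko_catalog
#' @export
print.ko_catalog <- function(x, ...) {
  cat(sprintf("ko_catalog: %d KOs over %d compounds; %d overlap annotated set\n",
              length(x$ko_ids), length(unique(unlist(x$membership))),
              length(x$annotated_overlap)))
  invisible(x)
}

#' Intersect a KO catalog with the cohort's annotated KOs
#'
#' Restricting the compound-derived catalog to KOs actually annotated in the
#' cohort gives the working feature set for differential analysis; the
#' original membership is kept untouched.
#'
#' @param catalog a \code{ko_catalog}.
#' @param annotated character vector of KO ids annotated in the cohort.
#' @return the catalog with \code{annotated_overlap} filled in.
#' @export
intersect_annotated <- function(catalog, annotated) {
  stopifnot(inherits(catalog, "ko_catalog"))
  if (length(annotated) == 0) stop("'annotated' must be non-empty")
  overlap <- intersect(catalog$ko_ids, annotated)
  if (length(overlap) == 0)
    warning("catalog and annotated KO set are disjoint")
  catalog$annotated_overlap <- sort(overlap)
  catalog
}

#' Distribution of KOs over exact compound combinations
#'
#' Groups a KO subset by the exact set of compounds each KO belongs to
#' (UpSet-plot style); every KO is counted exactly once, so the counts sum
#' to the subset size.
#'
#' @param catalog a \code{ko_catalog}.
#' @param ko_subset character vector of KO ids, a subset of the catalog.
#' @return data.frame with columns \code{compound_combination} (compound ids
#'   joined by \code{"+"}) and \code{count}, sorted by decreasing count.
#' @export
compound_distribution <- function(catalog, ko_subset) {
  stopifnot(inherits(catalog, "ko_catalog"))
  extra <- setdiff(ko_subset, catalog$ko_ids)
  if (length(extra) > 0)
    stop("KOs not in catalog: ", paste(extra, collapse = ", "))
  if (length(ko_subset) == 0)
    return(data.frame(compound_combination = character(0), count = integer(0)))
  combos <- vapply(catalog$membership[ko_subset],
                   function(x) paste(x, collapse = "+"), character(1))
  tab <- table(combos)
  out <- data.frame(compound_combination = names(tab),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$count, out$compound_combination), , drop = FALSE]
}

#' Write a KO catalog to TSV (one row per KO-compound membership)
#'
#' @param catalog a \code{ko_catalog}.
#' @param path output file path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "ko_catalog"))
  rows <- do.call(rbind, lapply(catalog$ko_ids, function(k) {
    data.frame(ko_id = k, compound_id = catalog$membership[[k]],
               annotated = k %in% catalog$annotated_overlap,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
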