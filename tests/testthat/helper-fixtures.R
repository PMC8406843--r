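# shared fixtures and independent oracles used across the suite

toy_matrix <- function(values, group = NULL) {
  if (is.null(group)) group <- rep(c("CTR", "AF"), length.out = nrow(values))
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  abundance_matrix(values, group)
}

random_closed_matrix <- function(n_samples, n_features) {
  v <- matrix(stats::rlnorm(n_samples * n_features), n_samples, n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  abundance_matrix(sweep(v, 1, rowSums(v), "/"),
                   rep(c("CTR", "AF"), length.out = n_samples))
}

# five-level hand-built tree: root -> k1 -> p1 -> g1 -> {sA, sB}; g2 -> sC
toy_taxonomy <- function() {
  taxonomy_table(data.frame(
    taxon_id  = c("root", "k1", "p1", "g1", "g2", "sA", "sB", "sC"),
    parent_id = c(NA,     "root", "k1", "p1", "p1", "g1", "g1", "g2"),
    rank      = c("root", "kingdom", "phylum", "genus", "genus",
                  "species", "species", "species"),
    name      = c("root", "K1", "P1", "G1", "G2", "SpA", "SpB", "SpC"),
    stringsAsFactors = FALSE))
}

# --- independent oracles ----------------------------------------------------

# LCA by explicit root-to-node path intersection
lca_oracle <- function(taxa, taxonomy) {
  path_of <- function(t) {
    p <- character(0)
    while (!is.na(t)) { p <- c(t, p); t <- taxonomy$parent[[t]] }
    p
  }
  paths <- lapply(unique(taxa), path_of)
  common <- Reduce(intersect, paths)
  # deepest common node = the one whose own path has maximal length
  depths <- vapply(common, function(t) length(path_of(t)), integer(1))
  common[which.max(depths)]
}

# AUC by brute-force comparison of every (positive, negative) pair
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# two-sided Wilcoxon p by exhaustive enumeration of group labelings
wilcoxon_enum_oracle <- function(x, y) {
  pooled <- c(x, y); nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- mean(u_all)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# OR(k) by direct transcription of the pooled-odds formula
or_oracle <- function(values, group, k) {
  ctr <- values[group == "CTR", , drop = FALSE]
  af <- values[group == "AF", , drop = FALSE]
  kk <- which(colnames(values) == k)
  (sum(ctr[, kk]) / sum(ctr[, -kk])) / (sum(af[, kk]) / sum(af[, -kk]))
}
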