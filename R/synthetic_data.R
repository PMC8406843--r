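#' Configuration for a synthetic two-group cohort
#'
#' Defaults state the emulated world: a 50 + 50 two-group cohort, 200
#' candidate KOs of which 10 carry a planted twofold (log2FC = 1) group
#' difference, 20 species harboring 7 SCFA-synthesis enzymes, and a
#' three-variable mediation structure (diversity -> hsCRP -> left-atrial
#' diameter) with path coefficients a = 0.8, b = 0.7, c' = 0.1 and residual
#' standard deviation 0.5.
#'
#' @param n_ctr,n_af samples per group.
#' @param n_ko number of KO features.
#' @param n_diff number of planted differential KOs (<= n_ko).
#' @param log2fc_planted planted log2 fold change (AF over CTR) applied to
#'   each planted KO before the profile is closed to the simplex.
#' @param species_count number of species.
#' @param harboring_matrix_density fraction of species x enzyme cells with a
#'   nonzero gene copy number.
#' @param mediation_paths list with elements \code{a}, \code{b},
#'   \code{c_direct}: structural coefficients of the clinical path model.
#' @param noise_sd residual standard deviation of the mediator and outcome
#'   equations.
#' @param seed integer seed; one stream drives every sub-generator.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_ctr = 50, n_af = 50, n_ko = 200, n_diff = 10,
                          log2fc_planted = 1, species_count = 20,
                          harboring_matrix_density = 0.3,
                          mediation_paths = list(a = 0.8, b = 0.7, c_direct = 0.1),
                          noise_sd = 0.5, seed = 1) {
  cfg <- list(n_ctr = n_ctr, n_af = n_af, n_ko = n_ko, n_diff = n_diff,
              log2fc_planted = log2fc_planted, species_count = species_count,
              harboring_matrix_density = harboring_matrix_density,
              mediation_paths = mediation_paths, noise_sd = noise_sd,
              seed = seed)
  for (f in c("n_ctr", "n_af", "n_ko", "species_count")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("invalid config field '", f, "': must be a positive integer count")
  }
  if (!is.numeric(n_diff) || n_diff < 0 || n_diff != round(n_diff))
    stop("invalid config field 'n_diff': must be a non-negative integer")
  if (n_diff > n_ko)
    stop("invalid config field 'n_diff': exceeds n_ko")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid config field 'noise_sd': must be >= 0")
  d <- harboring_matrix_density
  if (!is.numeric(d) || d < 0 || d > 1)
    stop("invalid config field 'harboring_matrix_density': must be in [0, 1]")
  if (!all(c("a", "b", "c_direct") %in% names(mediation_paths)))
    stop("invalid config field 'mediation_paths': needs a, b, c_direct")
  if (!is.numeric(seed) || seed != round(seed))
    stop("invalid config field 'seed': must be an integer")
  structure(cfg, class = "cohort_config")
}

#' The seven SCFA-synthesis enzyme genes tracked by the pipeline
#' @return character vector of enzyme gene names.
#' @export
scfa_enzymes <- function() {
  c("tesA", "tesB", "yciA", "menI",
    "propionyl CoA transferase",
    "CO dehydrogenase acetyl-CoA synthase complex",
    "butyrate acetoacetate CoA transferase")
}

# heavy-tailed compositional profiles: log-normal draws closed to the simplex
lognormal_profiles <- function(n_samples, feature_mu, sdlog, ids, sample_ids) {
  raw <- t(vapply(seq_len(n_samples), function(i)
    stats::rlnorm(length(feature_mu), meanlog = feature_mu, sdlog = sdlog),
    numeric(length(feature_mu))))
  dimnames(raw) <- list(sample_ids, ids)
  raw
}

close_rows <- function(m) sweep(m, 1, rowSums(m), "/")

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces (i) a compositional KO abundance matrix where the first
#' \code{n_diff} KOs are scaled in the AF group so the raw group-mean ratio
#' equals exactly 2^log2fc_planted before closure to the simplex, (ii) a
#' species abundance matrix and a species x enzyme gene copy-number
#' (harboring) matrix inducing enzyme abundances as species-abundance
#' weighted copy sums, (iii) a clinical table whose mediator (hsCRP) and
#' outcome (left-atrial diameter) follow a linear path model on the
#' standardized diversity exposure with Gaussian residuals, and (iv) a
#' truth record with the planted KOs, harboring matrix, structural and
#' standardized path coefficients, and the implied VAF.
#'
#' @param config a \code{cohort_config}.
#' @return object of class \code{synthetic_cohort}: list with
#'   \code{ko} (\code{abundance_matrix}), \code{species}
#'   (\code{abundance_matrix}), \code{enzymes} (\code{abundance_matrix},
#'   species-induced, not closed), \code{clinical} (data.frame) and
#'   \code{truth} (list).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_ctr + config$n_af
  group <- c(rep("CTR", config$n_ctr), rep("AF", config$n_af))
  sample_ids <- sprintf("%s%03d", ifelse(group == "CTR", "C", "A"),
                        c(seq_len(config$n_ctr), seq_len(config$n_af)))
  ko_ids <- sprintf("K9%04d", seq_len(config$n_ko))

  mu <- stats::rnorm(config$n_ko, 0, 1)
  raw <- lognormal_profiles(n, mu, sdlog = 0.5, ko_ids, sample_ids)
  planted <- if (config$n_diff > 0) ko_ids[seq_len(config$n_diff)] else character(0)
  af <- group == "AF"
  for (k in planted) {
    # scale AF so the raw group-mean ratio is exactly 2^log2fc
    target <- 2^config$log2fc_planted * mean(raw[!af, k])
    raw[af, k] <- raw[af, k] * target / mean(raw[af, k])
  }
  ko <- abundance_matrix(close_rows(raw), group)

  species_ids <- sprintf("species_%02d", seq_len(config$species_count))
  sp_mu <- stats::rnorm(config$species_count, 0, 1.5)
  sp_raw <- lognormal_profiles(n, sp_mu, sdlog = 0.5, species_ids, sample_ids)
  species <- abundance_matrix(close_rows(sp_raw), group)

  enz <- scfa_enzymes()
  harboring <- matrix(0L, config$species_count, length(enz),
                      dimnames = list(species_ids, enz))
  nonzero <- stats::runif(length(harboring)) < config$harboring_matrix_density
  harboring[nonzero] <- stats::rpois(sum(nonzero), 2) + 1L
  enzyme_vals <- species$values %*% harboring
  enzymes <- abundance_matrix(enzyme_vals, group)

  paths <- config$mediation_paths
  x <- stats::rnorm(n)
  m <- paths$a * x + config$noise_sd * stats::rnorm(n)
  y <- paths$b * m + paths$c_direct * x + config$noise_sd * stats::rnorm(n)
  clinical <- data.frame(
    sample_id = sample_ids, group = group,
    age = round(stats::rnorm(n, 60, 8)),
    BMI = round(stats::rnorm(n, 25, 3), 1),
    diversity = 2.5 + 0.5 * x,
    hsCRP = 3 + 1.5 * m,
    LA_diameter = 38 + 4 * y,
    stringsAsFactors = FALSE)

  s_m <- sqrt(paths$a^2 + config$noise_sd^2)
  s_y <- sqrt(paths$b^2 * s_m^2 + paths$c_direct^2 +
                2 * paths$a * paths$b * paths$c_direct + config$noise_sd^2)
  std_paths <- list(a = paths$a / s_m, b = paths$b * s_m / s_y,
                    c_direct = paths$c_direct / s_y)
  ab <- paths$a * paths$b
  truth <- list(diff_ko_ids = planted,
                log2fc_planted = config$log2fc_planted,
                harboring_matrix = harboring,
                true_paths = paths,
                true_paths_std = std_paths,
                true_vaf = ab / (ab + paths$c_direct))
  structure(list(ko = ko, species = species, enzymes = enzymes,
                 clinical = clinical, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d KOs (%d planted), %d species\n",
              nrow(x$ko$values), ncol(x$ko$values),
              length(x$truth$diff_ko_ids), ncol(x$species$values)))
  invisible(x)
}

#' Write a synthetic cohort to a directory (TSV + JSON truth record)
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ko = file.path(dir, "ko_matrix.tsv"),
             species = file.path(dir, "species_matrix.tsv"),
             enzymes = file.path(dir, "enzyme_matrix.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_abundance_tsv(cohort$ko, paths["ko"])
  write_abundance_tsv(cohort$species, paths["species"])
  write_abundance_tsv(cohort$enzymes, paths["enzymes"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$harboring_matrix <- as.data.frame(truth$harboring_matrix)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Generate a per-gene read-count table
#'
#' Read counts are negative-binomial (over-dispersed, as in shotgun gene
#' libraries) and gene lengths log-normal around typical prokaryotic ORF
#' sizes. When at least 10 genes are requested the first two genes are
#' pinned to 0 and 1 reads so the minimum-read filter is always exercised.
#'
#' @param n_genes number of genes (> 0).
#' @param seed integer seed.
#' @return data.frame with \code{gene_id}, \code{read_count},
#'   \code{gene_length_bp}.
#' @export
generate_gene_read_table <- function(n_genes, seed = 1) {
  if (n_genes < 1) stop("n_genes must be positive")
  set.seed(seed)
  counts <- stats::rnbinom(n_genes, size = 0.6, mu = 40)
  if (n_genes >= 10) counts[1:2] <- c(0L, 1L)
  data.frame(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
             read_count = counts,
             gene_length_bp = pmax(100L, round(stats::rlnorm(n_genes, log(900), 0.5))),
             stringsAsFactors = FALSE)
}

#' Generate a small rooted fixture taxonomy
#'
#' Root -> phyla -> genera -> species, with genera assigned to phyla and
#' species to genera uniformly at random.
#'
#' @param n_species number of species leaves.
#' @param n_genera number of genus nodes.
#' @param n_phyla number of phylum nodes.
#' @param seed integer seed.
#' @return a \code{taxonomy_table}.
#' @export
generate_taxonomy <- function(n_species = 20, n_genera = 6, n_phyla = 2, seed = 1) {
  set.seed(seed)
  rows <- data.frame(taxon_id = "root", parent_id = NA_character_,
                     rank = "root", name = "root", stringsAsFactors = FALSE)
  phyla <- sprintf("p%02d", seq_len(n_phyla))
  rows <- rbind(rows, data.frame(taxon_id = phyla, parent_id = "root",
                                 rank = "phylum", name = paste0("Phylum_", phyla),
                                 stringsAsFactors = FALSE))
  genera <- sprintf("g%02d", seq_len(n_genera))
  rows <- rbind(rows, data.frame(taxon_id = genera,
                                 parent_id = sample(phyla, n_genera, replace = TRUE),
                                 rank = "genus", name = paste0("Genus_", genera),
                                 stringsAsFactors = FALSE))
  species <- sprintf("s%03d", seq_len(n_species))
  rows <- rbind(rows, data.frame(taxon_id = species,
                                 parent_id = sample(genera, n_species, replace = TRUE),
                                 rank = "species", name = paste0("Species_", species),
                                 stringsAsFactors = FALSE))
  taxonomy_table(rows)
}

#' Generate an alignment hit table over a fixture taxonomy
#'
#' Each gene receives 1-10 hits against species-rank leaves. Hit e-values
#' are spread as the top e-value times 10^U(0, 2), so roughly half of the
#' secondary hits fall inside and half outside the 10x significant-match
#' retention boundary.
#'
#' @param taxonomy a rooted \code{taxonomy_table} containing species-rank
#'   taxa.
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return data.frame with \code{gene_id}, \code{taxon_id}, \code{e_value},
#'   \code{bit_score}.
#' @export
generate_hit_table <- function(taxonomy, n_genes, seed = 1) {
  if (!inherits(taxonomy, "taxonomy_table"))
    stop("'taxonomy' must be a validated (rooted) taxonomy_table")
  leaves <- taxonomy$df$taxon_id[taxonomy$df$rank == "species"]
  if (length(leaves) == 0) stop("taxonomy has no species-rank taxa")
  if (n_genes < 1) stop("n_genes must be positive")
  set.seed(seed)
  rows <- lapply(seq_len(n_genes), function(i) {
    k <- sample.int(10, 1)
    top_e <- 10^stats::runif(1, -30, -8)
    e <- c(top_e, top_e * 10^stats::runif(k - 1, 0, 2))
    data.frame(gene_id = sprintf("gene_%05d", i),
               taxon_id = sample(leaves, k, replace = TRUE),
               e_value = e,
               bit_score = round(-2 * log10(e) + stats::rnorm(k, 0, 3), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
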