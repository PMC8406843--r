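#' Default pipeline configuration
#'
#' Returns the demo configuration: a simulated cohort, the packaged
#' synthetic compound-to-KO map, a generated fixture taxonomy, and the
#' default thresholds (alpha = 0.05, |r| > 0.15, literal OR convention).
#'
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @return a named list understood by \code{run_pipeline}.
#' @export
default_pipeline_config <- function(out_dir = tempfile("scfaflow_run_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    alpha = 0.05,
    r_threshold = 0.15,
    or_convention = "formula",
    lasso = list(cv_folds = 10, lambda = "1se"),
    mediation_B = 200,
    optimism_B = 0,
    cohort = list(),
    compound_map = system.file("extdata", "compound_ko_map_synthetic.tsv",
                               package = "scfaflow"),
    compounds = NULL,
    taxonomy = "generate",
    n_genes = 200
  )
}

#' Run the end-to-end SCFA-function analysis pipeline
#'
#' Executes, in dependency order: simulate, catalog, taxa, diff, orscore,
#' score, mediate, assoc. Each stage writes machine-readable artifacts into
#' the output directory; a manifest records the configuration, seed, stage
#' outputs and their MD5 checksums, so a rerun with identical config and
#' seed is checksum-reproducible. A missing taxonomy input skips the taxa
#' stage (with a warning) without stopping downstream stages; any other
#' stage failure aborts with an error naming the stage.
#'
#' @param config list (see \code{default_pipeline_config}) or path to a
#'   YAML file with the same fields.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(default_pipeline_config(), user)
  } else {
    config <- utils::modifyList(default_pipeline_config(), config)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   seed = config$seed, stages = list())
  log_stage <- function(name, files, info = NULL) {
    manifest$stages[[name]] <<- list(
      outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))),
      info = info)
    message(sprintf("[%s] wrote %d file(s)", name, length(files)))
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate -------------------------------------------------------------
  cohort <- run_stage("simulate", function() {
    cfg <- utils::modifyList(list(seed = config$seed), config$cohort)
    co <- generate_cohort(do.call(cohort_config, cfg))
    paths <- write_cohort(co, out)
    log_stage("simulate", unname(paths),
              info = list(n_samples = nrow(co$ko$values),
                          n_ko = ncol(co$ko$values)))
    co
  })

  # -- catalog --------------------------------------------------------------
  catalog <- run_stage("catalog", function() {
    map <- read_compound_ko_map(config$compound_map)
    compounds <- if (is.null(config$compounds)) unique(map$compound_id)
                 else config$compounds
    cat <- build_catalog(map, compounds)
    cat <- suppressWarnings(intersect_annotated(cat, colnames(cohort$ko$values)))
    f1 <- file.path(out, "catalog.tsv")
    write_catalog_tsv(cat, f1)
    dist <- compound_distribution(cat, cat$ko_ids)
    f2 <- file.path(out, "distribution.tsv")
    utils::write.table(dist, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("catalog", c(f1, f2),
              info = list(n_ko = length(cat$ko_ids),
                          n_overlap = length(cat$annotated_overlap)))
    cat
  })

  # -- taxa (optional) ------------------------------------------------------
  if (is.null(config$taxonomy)) {
    warning("no taxonomy configured; skipping taxa / harboring-species stage")
    manifest$stages[["taxa"]] <- list(skipped = TRUE)
  } else {
    run_stage("taxa", function() {
      taxonomy <- if (identical(config$taxonomy, "generate"))
        generate_taxonomy(seed = config$seed)
      else read_taxonomy_tsv(config$taxonomy)
      hits <- generate_hit_table(taxonomy, config$n_genes, seed = config$seed)
      g2t <- assign_gene_taxa(hits, taxonomy)
      genes <- generate_gene_read_table(config$n_genes, seed = config$seed)
      gabund <- normalize_genes(genes)
      enz <- scfa_enzymes()
      g2e <- data.frame(gene_id = genes$gene_id,
                        feature_id = rep_len(enz, nrow(genes)),
                        stringsAsFactors = FALSE)
      harb <- harboring_species(g2e, g2t, gabund, taxonomy)
      f1 <- file.path(out, "gene_taxa.tsv")
      utils::write.table(data.frame(gene_id = names(g2t), taxon_id = unname(g2t)),
                         f1, sep = "\t", quote = FALSE, row.names = FALSE)
      f2 <- file.path(out, "species_enzyme_matrix.tsv")
      utils::write.table(data.frame(species = rownames(harb$species_enzyme),
                                    harb$species_enzyme, check.names = FALSE),
                         f2, sep = "\t", quote = FALSE, row.names = FALSE)
      f3 <- file.path(out, "enzyme_species_counts.tsv")
      utils::write.table(harb$species_counts, f3, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      log_stage("taxa", c(f1, f2, f3),
                info = list(n_excluded_above_species = nrow(harb$excluded)))
    })
  }

  # -- diff -----------------------------------------------------------------
  ko_sub <- if (length(catalog$annotated_overlap) >= 2)
    subset_features(cohort$ko, catalog$annotated_overlap) else cohort$ko
  diff <- run_stage("diff", function() {
    d <- differential_table(ko_sub, alpha = config$alpha)
    f <- file.path(out, "diff_results.tsv")
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("diff", f, info = list(n_significant = sum(d$direction != "NS")))
    d
  })

  # -- orscore --------------------------------------------------------------
  run_stage("orscore", function() {
    ors <- or_table(ko_sub, convention = config$or_convention)
    f <- file.path(out, "or_scores.tsv")
    utils::write.table(ors, f, sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("orscore", f)
  })

  # -- score ----------------------------------------------------------------
  scores <- run_stage("score", function() {
    sig <- diff$feature_id[diff$direction != "NS"]
    pool <- if (length(sig) >= 2) subset_features(cohort$ko, sig) else cohort$ko
    fit_nonempty <- function(feats, nm) {
      m <- lasso_select(feats, cv_folds = config$lasso$cv_folds,
                        lambda = config$lasso$lambda,
                        seed = config$seed, name = nm)
      if (length(m$coefficients) == 0) {
        # the 1-SE penalty can zero everything on small cohorts; fall back
        m <- lasso_select(feats, cv_folds = config$lasso$cv_folds,
                          lambda = "min", seed = config$seed, name = nm)
      }
      m
    }
    ko_model <- fit_nonempty(pool, "KO")
    sp_model <- fit_nonempty(cohort$species, "species")
    ko_score <- evaluate_score(ko_model, cohort$ko)
    sp_score <- evaluate_score(sp_model, cohort$species)
    roc <- roc_auc(ko_score, cohort$ko$group)
    f1 <- file.path(out, "ko_score_model.json")
    write_score_model(ko_model, f1)
    f2 <- file.path(out, "species_score_model.json")
    write_score_model(sp_model, f2)
    f3 <- file.path(out, "sample_scores.tsv")
    utils::write.table(data.frame(sample_id = rownames(cohort$ko$values),
                                  group = as.character(cohort$ko$group),
                                  ko_score = ko_score, species_score = sp_score),
                       f3, sep = "\t", quote = FALSE, row.names = FALSE)
    f4 <- file.path(out, "roc.json")
    jsonlite::write_json(roc, f4, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2, f3, f4)
    info <- list(ko_auc = roc$auc)
    if (config$optimism_B > 0) {
      opt <- bootstrap_optimism(pool, B = config$optimism_B, seed = config$seed,
                                cv_folds = config$lasso$cv_folds,
                                lambda = config$lasso$lambda)
      f5 <- file.path(out, "optimism.json")
      jsonlite::write_json(opt, f5, auto_unbox = TRUE, digits = NA)
      files <- c(files, f5)
      info$corrected_auc <- opt$corrected_auc
    }
    log_stage("score", files, info = info)
    list(ko = ko_score, species = sp_score)
  })

  # -- mediate --------------------------------------------------------------
  run_stage("mediate", function() {
    af01 <- as.integer(cohort$ko$group == "AF")
    clin <- cohort$clinical
    triples <- list(
      diversity_koScore_af = list(x = clin$diversity, m = scores$ko, y = af01),
      speciesScore_koScore_af = list(x = scores$species, m = scores$ko, y = af01),
      diversity_hsCRP_LAdiameter = list(x = clin$diversity, m = clin$hsCRP,
                                        y = clin$LA_diameter))
    reports <- lapply(triples, function(t) {
      tryCatch({
        fit <- bootstrap_mediation(t$x, t$m, t$y, B = config$mediation_B,
                                   seed = config$seed)
        list(a = fit$a, b = fit$b, c_direct = fit$c_direct, ide = fit$ide,
             total = fit$total, vaf = fit$vaf, inconsistent = fit$inconsistent,
             p = as.list(fit$boot$p))
      }, error = function(e) list(error = conditionMessage(e)))
    })
    f <- file.path(out, "mediation.json")
    jsonlite::write_json(reports, f, auto_unbox = TRUE, digits = NA)
    log_stage("mediate", f)
  })

  # -- assoc ----------------------------------------------------------------
  run_stage("assoc", function() {
    clin <- cohort$clinical
    tab <- data.frame(diversity = clin$diversity, hsCRP = clin$hsCRP,
                      LA_diameter = clin$LA_diameter,
                      ko_score = scores$ko, species_score = scores$species)
    edges <- spearman_network(tab, r_threshold = config$r_threshold,
                              alpha = config$alpha)
    f1 <- file.path(out, "edges.tsv")
    utils::write.table(edges, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    preds <- data.frame(age = clin$age, BMI = clin$BMI, ko_score = scores$ko)
    logit <- tryCatch(
      rbind(cbind(model = "univariable",
                  logistic_fit(clin$group, preds, univariable = TRUE)),
            cbind(model = "multivariable",
                  logistic_fit(clin$group, preds, univariable = FALSE))),
      error = function(e) {
        warning("logistic stage degraded: ", conditionMessage(e))
        data.frame(model = character(0), term = character(0),
                   odds_ratio = numeric(0), ci_low = numeric(0),
                   ci_high = numeric(0), p = numeric(0))
      })
    f2 <- file.path(out, "logistic_results.tsv")
    utils::write.table(logit, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("assoc", c(f1, f2))
  })

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{simulate}, \code{run} and \code{diff}.
#' Typical use from the installed package:
#' \code{Rscript -e 'scfaflow::scfa_cli()' run --out dir --seed 1}.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return exit status, invisibly.
#' @export
scfa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: scfa <simulate|run|diff> [options]",
    "  simulate --out DIR [--seed N]         generate a synthetic cohort",
    "  run      [--config cfg.yaml] [--out DIR] [--seed N]   full pipeline",
    "  diff     --matrix ko_matrix.tsv [--alpha A] [--out FILE]",
    sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  seed <- as.integer(opts[["seed"]] %||% "1")
  switch(cmd,
    simulate = {
      out <- opts[["out"]] %||% stop("simulate needs --out DIR")
      co <- generate_cohort(cohort_config(seed = seed))
      write_cohort(co, out)
      message("cohort written to ", out)
    },
    run = {
      cfg <- if (!is.null(opts[["config"]])) opts[["config"]]
             else default_pipeline_config(
               out_dir = opts[["out"]] %||% "scfaflow_run", seed = seed)
      if (is.list(cfg) && !is.null(opts[["out"]])) cfg$out_dir <- opts[["out"]]
      run_pipeline(cfg)
    },
    diff = {
      mat <- opts[["matrix"]] %||% stop("diff needs --matrix FILE")
      d <- differential_table(read_abundance_tsv(mat),
                              alpha = as.numeric(opts[["alpha"]] %||% "0.05"))
      out <- opts[["out"]] %||% "diff_results.tsv"
      utils::write.table(d, out, sep = "\t", quote = FALSE, row.names = FALSE)
      message("differential table written to ", out)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2
      } else { opts[[key]] <- "TRUE"; i <- i + 1 }
    } else i <- i + 1
  }
  opts
}
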