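# End-to-end orchestration: simulate (or load) inputs, run differential
# expression per sex, classify sex patterns, enrich, screen cell-cell
# communication, build per-sex GRNs, analyze proteomics, intersect omics,
# and correlate covariates - all from one validated config, writing
# provenance-stamped TSVs and a machine-readable manifest.

#' Default pipeline configuration
#'
#' Returns the demo configuration: a small synthetic cohort (24 control
#' and 24 AD subjects split over the disease stages, 50 cells each, 500
#' genes, 3 cell types) with planted sex-neutral, sex-specific, and
#' sex-dimorphic effects, the standard thresholds (FDR 0.05, |logFC| 0.25,
#' other-sex nominal p 0.1, expression fraction 0.10), and GA defaults.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param output_dir results directory.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, output_dir = "sexdim_results") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    simulate = list(
      group_sizes = list(control = c(12, 12), early_ad = c(4, 4),
                         intermediate_ad = c(4, 4), late_ad = c(4, 4)),
      cells_per_subject = 50L,
      n_genes = 500L,
      cell_types = c("astrocytes", "excitatory_neurons", "microglia"),
      dispersion = 0.25,
      n_planted_per_category = 5L,
      delta_logfc = 0.8,
      n_gene_sets = 30L,
      n_network_edges = 120L,
      frac_unknown_sign = 0.3,
      n_lr_pairs = 60L,
      proteomics_noise_sd = 0.5
    ),
    thresholds = list(fdr = 0.05, min_lfc = 0.25, nonsig_p = 0.1,
                      expr_frac = 0.10, min_pct = 0.1),
    cell_types = c("astrocytes", "excitatory_neurons"),
    comm = list(sender = "astrocytes", receiver = "excitatory_neurons",
                top_n_ligands = 30L),
    ga = list(population_size = 100L, max_generations = 200L,
              stagnation_limit = 30L, lambda_parsimony = 0.01)
  )
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges and the presence of a seed before any stage
#' runs; called by [run_pipeline()].
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed)) stop_sexdim("config$seed is mandatory")
  th <- config$thresholds
  for (f in c("fdr", "nonsig_p", "expr_frac", "min_pct")) {
    v <- th[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
      stop_sexdim(sprintf("config$thresholds$%s must lie in [0, 1]", f))
  }
  if (is.null(th$min_lfc) || th$min_lfc < 0)
    stop_sexdim("config$thresholds$min_lfc must be >= 0")
  if (is.null(config$output_dir)) stop_sexdim("config$output_dir is mandatory")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  validate_config(cfg)
  cfg
}

# stable digest of the config for provenance stamping; the output
# location is not part of the analysis identity
config_hash <- function(config) {
  config$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full sex-dependent analysis pipeline
#'
#' Executes the stages in dependency order: simulate inputs (cohort,
#' counts, gene sets, prior network, ligand-receptor pairs, proteomics),
#' per-sex differential expression per cell type, sex-pattern
#' classification, per-sex enrichment with term-level specificity labels,
#' cell-cell communication screening, per-sex GRN construction with
#' perturbagen/mediator ranking, per-sex protein differential abundance
#' and omics intersection, and sex-stratified covariate correlations.
#' Every output TSV carries a provenance header (tool version, config
#' hash, seed) and a `manifest.json` records checksums, so a rerun with
#' the same config is byte-identical.
#'
#' @param config configuration list ([default_pipeline_config()]) or a
#'   YAML path.
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  prov <- list(config_hash = hash, seed = config$seed)
  th <- config$thresholds
  seed <- config$seed
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out, name)
    write_result_table(df, path, provenance = prov)
    files <<- c(files, name)
    path
  }

  ## -- simulate ------------------------------------------------------------
  say("stage simulate")
  sim <- config$simulate
  spec <- cohort_spec(group_sizes = lapply(sim$group_sizes, as.integer))
  subjects <- generate_cohort(spec, seed = seed)
  genes <- sprintf("G%04d", seq_len(sim$n_genes))
  cts <- sim$cell_types
  plant_ct <- cts[1]
  npc <- sim$n_planted_per_category
  planted_genes <- split(genes[seq_len(4 * npc)],
                         rep(c("neutral", "male_specific", "female_specific",
                               "dimorphic"), each = npc))
  effects <- do.call(rbind, lapply(names(planted_genes), function(cat)
    effect_spec(planted_genes[[cat]], plant_ct, cat,
                delta_logfc = sim$delta_logfc,
                direction = rep_len(c(1L, -1L), npc))))
  gen <- generate_counts(subjects, sim$cells_per_subject, genes, cts,
                         effects = effects, dispersion = sim$dispersion,
                         seed = seed + 1L)
  write_counts(gen$counts, file.path(out, "matrix.mtx"),
               file.path(out, "genes.txt"), file.path(out, "cells.txt"))
  files <- c(files, "matrix.mtx", "genes.txt", "cells.txt")
  emit(subjects, "subjects.tsv")
  emit(gen$meta, "cells.tsv")
  planted_set <- list(PLANTED_MALE_SPECIFIC = planted_genes$male_specific)
  sets <- generate_gene_sets(genes, sim$n_gene_sets, planted = planted_set,
                             seed = seed + 2L)
  write_gmt(sets, file.path(out, "gene_sets.gmt"))
  files <- c(files, "gene_sets.gmt")
  # planted consistent regulatory chain through the male-specific genes
  pg <- planted_genes$male_specific
  planted_edges <- data.frame(source = pg[-length(pg)], target = pg[-1],
                              sign = 1L, stringsAsFactors = FALSE)
  prior <- generate_prior_network(genes, sim$n_network_edges,
                                  frac_unknown_sign = sim$frac_unknown_sign,
                                  planted_consistent = planted_edges,
                                  seed = seed + 3L)
  emit(prior, "edges.tsv")
  lr <- generate_lr_pairs(genes, sim$n_lr_pairs, seed = seed + 4L)
  # guarantee at least one expressed DEG ligand-receptor pair
  lr <- unique(rbind(data.frame(ligand = planted_genes$neutral[1],
                                receptor = planted_genes$neutral[2],
                                stringsAsFactors = FALSE), lr))
  emit(lr, "lr_pairs.tsv")
  shared <- effects[effects$category %in%
                      c("male_specific", "female_specific", "dimorphic"), ]
  prot <- generate_proteomics(subjects, genes[seq_len(100)],
                              shared_effects = shared[shared$gene %in%
                                                        genes[seq_len(100)], ],
                              noise_sd = sim$proteomics_noise_sd,
                              seed = seed + 5L)
  prot_df <- data.frame(protein = rownames(prot$abundance),
                        prot$abundance, check.names = FALSE,
                        stringsAsFactors = FALSE)
  emit(prot_df, "proteomics.tsv")
  emit(prot$samples, "samples.tsv")
  gt <- ground_truth(effects = effects, enriched_sets = names(planted_set),
                     grn_edges = planted_edges,
                     protein_effects = shared)
  write_ground_truth(gt, file.path(out, "ground_truth.json"))
  files <- c(files, "ground_truth.json")

  ## -- DE + classification + enrichment per cell type ----------------------
  patterns <- list(); de_runs <- list()
  for (ct in config$cell_types) {
    say("stage de/classify/enrich: %s", ct)
    de_m <- run_de(gen$counts, gen$meta, ct, "M", min_pct = th$min_pct)
    de_f <- run_de(gen$counts, gen$meta, ct, "F", min_pct = th$min_pct)
    de_runs[[ct]] <- list(M = de_m, F = de_f)
    emit(de_m, sprintf("de_%s_M.tsv", ct))
    emit(de_f, sprintf("de_%s_F.tsv", ct))
    pat <- classify_all(de_m, de_f, fdr = th$fdr, min_lfc = th$min_lfc,
                        nonsig_p = th$nonsig_p)
    patterns[[ct]] <- pat
    emit(pat, sprintf("patterns_%s.tsv", ct))
    universe <- union(de_m$gene, de_f$gene)
    enr <- lapply(c(male_specific = "male_specific",
                    female_specific = "female_specific"), function(cat)
      enrich_collection(intersect(pat$feature[pat$category == cat], universe),
                        sets, universe))
    emit(enr$male_specific, sprintf("enrich_%s_M.tsv", ct))
    emit(enr$female_specific, sprintf("enrich_%s_F.tsv", ct))
    emit(sex_specific_terms(enr$male_specific, enr$female_specific,
                            fdr = th$fdr, nonsig_p = th$nonsig_p),
         sprintf("enrich_terms_%s.tsv", ct))
  }

  ## -- cell-cell communication ---------------------------------------------
  say("stage comm")
  sender <- config$comm$sender; receiver <- config$comm$receiver
  pat_s <- patterns[[sender]] %||% patterns[[1]]
  deg_cats <- c("sex_neutral", "male_specific", "female_specific",
                "sex_dimorphic")
  degs_comm <- pat_s$feature[pat_s$category %in% deg_cats]
  exp_s <- filter_expressed(gen$counts, gen$meta, sender, th$expr_frac)
  exp_r <- filter_expressed(gen$counts, gen$meta, receiver, th$expr_frac)
  pairs <- intersect_degs_lr(degs_comm, lr, exp_s, exp_r)
  emit(pairs, "comm_pairs.tsv")
  net <- filter_interactions(prior)
  emit(rank_ligands(pairs, net, degs_comm, config$comm$top_n_ligands),
       "comm_ligands.tsv")
  endpoint <- intersect(unique(c(pairs$ligand, pairs$receptor)),
                        union(de_runs[[sender]]$M$gene,
                              de_runs[[sender]]$F$gene))
  emit(comm_enrichment(endpoint, sets,
                       union(de_runs[[sender]]$M$gene,
                             de_runs[[sender]]$F$gene)),
       "comm_enrich.tsv")

  ## -- GRN per sex ----------------------------------------------------------
  ct1 <- config$cell_types[1]
  for (sx in c("M", "F")) {
    say("stage grn: %s", sx)
    de <- de_runs[[ct1]][[sx]]
    degs <- de$gene[de$adj_p < th$fdr & abs(de$logfc) > th$min_lfc]
    cand <- net[net$source %in% degs & net$target %in% degs, , drop = FALSE]
    if (!nrow(cand)) {
      say("  no candidate edges among %s DEGs; skipping", sx)
      next
    }
    states <- booleanize(de, sort(unique(c(cand$source, cand$target))))
    gp <- do.call(ga_params, c(config$ga, list(seed = seed + 10L)))
    grn <- run_ga(cand, states, gp)
    emit(grn$edges, sprintf("grn_%s_edges.tsv", sx))
    emit(grn$states, sprintf("grn_%s_states.tsv", sx))
    emit(perturbagen_scores(grn), sprintf("grn_%s_perturbagens.tsv", sx))
    emit(mediator_scores(grn), sprintf("grn_%s_mediators.tsv", sx))
  }

  ## -- proteomics ------------------------------------------------------------
  say("stage proteomics")
  dep_m <- run_dep(prot$abundance, prot$samples, "M")
  dep_f <- run_dep(prot$abundance, prot$samples, "F")
  emit(dep_m, "dep_M.tsv")
  emit(dep_f, "dep_F.tsv")
  dep_pat <- classify_proteins(dep_m, dep_f, fdr = th$fdr,
                               nonsig_p = th$nonsig_p)
  emit(dep_pat, "dep_patterns.tsv")
  ov <- intersect_omics(patterns[[ct1]], dep_pat)
  emit(ov$overlaps, "omics_overlap.tsv")

  ## -- covariate correlations -------------------------------------------------
  say("stage correlate")
  pb <- suppressWarnings(pseudobulk(gen$counts, gen$meta, ct1))
  corr <- suppressWarnings(
    correlate_covariates(pb[seq_len(min(100, nrow(pb))), , drop = FALSE],
                         subjects))
  emit(corr, sprintf("corr_%s.tsv", ct1))

  ## -- manifest ---------------------------------------------------------------
  files <- sort(unique(files))
  sums <- tools::md5sum(file.path(out, files))
  manifest <- list(tool = paste0("sexdim ",
                                 as.character(packageVersion("sexdim"))),
                   seed = config$seed, config_hash = hash,
                   config = config,
                   files = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d files in %s", length(files) + 1L, out)
  invisible(manifest)
}
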