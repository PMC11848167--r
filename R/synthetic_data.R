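# Synthetic cohort / count / network / proteomics generators with planted
# effects. Every generator is a pure function of (spec, seed), so each
# downstream stage can be tested against a known ground truth.

.braak_defaults <- list(control = integer(0), early_ad = 0:2,
                        intermediate_ad = 3:4, late_ad = 5:6)

#' Specify a case-control cohort layout
#'
#' Defines group sizes (sex-stratified), the Braak-stage range each disease
#' group may draw from, the age distribution, and the MMSE rule (patients
#' score below 20, controls between 20 and 30). The defaults reproduce the
#' layout of a published aged prefrontal-cortex atlas cohort: 146 controls
#' (72 M, 74 F), 19 early AD (14 M, 5 F), 59 intermediate AD (37 M, 22 F),
#' and 82 late AD (28 M, 54 F) - 306 subjects in total.
#'
#' @param group_sizes named list mapping each of `control`, `early_ad`,
#'   `intermediate_ad`, `late_ad` to `c(male, female)` subject counts.
#' @param braak_ranges named list of allowed Braak stages (0-6) per group;
#'   controls have none (recorded as NA) and the disease ranges must be
#'   disjoint.
#' @param age_mean,age_sd age distribution in years.
#' @param mmse_patient_range,mmse_control_range inclusive integer MMSE
#'   ranges for patients and controls; they must not overlap.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = list(control = c(72, 74),
                                           early_ad = c(14, 5),
                                           intermediate_ad = c(37, 22),
                                           late_ad = c(28, 54)),
                        braak_ranges = .braak_defaults,
                        age_mean = 86, age_sd = 6,
                        mmse_patient_range = c(5L, 19L),
                        mmse_control_range = c(20L, 30L)) {
  groups <- c("control", "early_ad", "intermediate_ad", "late_ad")
  if (!setequal(names(group_sizes), groups))
    stop_sexdim("group_sizes must name exactly: ",
                paste(groups, collapse = ", "))
  sizes <- lapply(group_sizes, as.integer)
  if (any(unlist(sizes) < 0) || any(lengths(sizes) != 2L))
    stop_sexdim("each group size must be c(n_male, n_female) with counts >= 0")
  ad_groups <- setdiff(groups, "control")
  stages <- unlist(braak_ranges[ad_groups])
  if (any(!stages %in% 0:6))
    stop_sexdim("Braak stages must lie in 0..6")
  if (anyDuplicated(stages))
    stop_sexdim("Braak ranges must be disjoint across AD groups")
  if (any(lengths(braak_ranges[ad_groups]) == 0L))
    stop_sexdim("every AD group needs a non-empty Braak range")
  if (mmse_patient_range[2] >= mmse_control_range[1])
    stop_sexdim("patient and control MMSE ranges must not overlap")
  structure(list(group_sizes = sizes, braak_ranges = braak_ranges,
                 age_mean = age_mean, age_sd = age_sd,
                 mmse_patient_range = as.integer(mmse_patient_range),
                 mmse_control_range = as.integer(mmse_control_range)),
            class = "cohort_spec")
}

#' Generate a subject metadata table from a cohort specification
#'
#' One row per subject with id, group, AD/HC condition (AD iff the group is
#' not `control`), sex, Braak stage (NA for controls), age, and MMSE
#' following the case/control rule. Deterministic given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return A `data.frame` with columns `subject_id`, `group`, `condition`,
#'   `sex`, `braak`, `age`, `mmse`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    rows <- lapply(names(spec$group_sizes), function(g) {
      n <- spec$group_sizes[[g]]
      ntot <- sum(n)
      if (ntot == 0L) return(NULL)
      sex <- rep(c("M", "F"), n)
      is_ad <- g != "control"
      braak <- if (is_ad)
        sample(rep(spec$braak_ranges[[g]], length.out = max(ntot, 1)), ntot)
      else rep(NA_integer_, ntot)
      mmse_rng <- if (is_ad) spec$mmse_patient_range else spec$mmse_control_range
      data.frame(
        group = g,
        condition = if (is_ad) "AD" else "HC",
        sex = sex,
        braak = as.integer(braak),
        age = round(rnorm(ntot, spec$age_mean, spec$age_sd), 1),
        mmse = sample(seq(mmse_rng[1], mmse_rng[2]), ntot, replace = TRUE),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(group = character(), condition = character(),
                        sex = character(), braak = integer(),
                        age = numeric(), mmse = integer(),
                        stringsAsFactors = FALSE)
    out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)[
      , c("subject_id", "group", "condition", "sex", "braak", "age", "mmse")]
    rownames(out) <- NULL
    out
  })
}

#' Build a planted-effect registry
#'
#' Each planted gene perturbs AD cells of one cell type, with a
#' per-sex direction: sex-neutral effects share one direction, sex-specific
#' effects act in one sex only, and sex-dimorphic effects have opposite
#' signs in males and females.
#'
#' @param gene,cell_type character vectors (recycled to equal length).
#' @param category one of `neutral`, `male_specific`, `female_specific`,
#'   `dimorphic` per gene.
#' @param delta_logfc planted effect size on the natural-log scale.
#' @param direction sign (+1/-1) of the effect in the driving sex; for
#'   dimorphic effects this is the male direction.
#' @return A `data.frame` effect registry with per-sex directions.
#' @export
effect_spec <- function(gene, cell_type, category, delta_logfc = 0.8,
                        direction = 1L) {
  n <- max(length(gene), length(cell_type), length(category))
  df <- data.frame(gene = rep_len(as.character(gene), n),
                   cell_type = rep_len(as.character(cell_type), n),
                   category = rep_len(as.character(category), n),
                   delta_logfc = rep_len(as.numeric(delta_logfc), n),
                   direction = rep_len(as.integer(direction), n),
                   stringsAsFactors = FALSE)
  ok <- c("neutral", "male_specific", "female_specific", "dimorphic")
  if (any(!df$category %in% ok))
    stop_sexdim("category must be one of: ", paste(ok, collapse = ", "))
  if (any(!df$direction %in% c(-1L, 1L)))
    stop_sexdim("direction must be +1 or -1")
  df$direction_male <- ifelse(df$category == "female_specific", 0L, df$direction)
  df$direction_female <- ifelse(df$category == "male_specific", 0L,
                         ifelse(df$category == "dimorphic", -df$direction,
                                df$direction))
  df
}

#' Simulate a sparse count matrix with planted sex-dependent AD effects
#'
#' Counts are negative-binomial (Poisson when `dispersion = 0`) with a
#' log-link mean: a gene x cell-type baseline, a lognormal per-cell size
#' factor, and - for a planted gene in its target cell type - a
#' multiplicative AD effect `exp(direction_sex * delta_logfc)`.
#'
#' @param subjects subject table from [generate_cohort()].
#' @param cells_per_subject cells drawn per subject (split evenly across
#'   cell types).
#' @param genes character vector of gene symbols.
#' @param cell_types character vector of cell-type labels.
#' @param effects planted-effect registry from [effect_spec()], or NULL.
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   gene x cell-type baseline mean.
#' @param size_factor_sdlog lognormal sigma of the per-cell size factor.
#' @param seed integer RNG seed.
#' @return A list with the `count_matrix`, the per-cell metadata
#'   `data.frame`, a `ground_truth` registry recording the planted
#'   effects, and the true per-cell `size_factors`.
#' @export
generate_counts <- function(subjects, cells_per_subject, genes, cell_types,
                            effects = NULL, dispersion = 0.25,
                            baseline_meanlog = log(0.8),
                            baseline_sdlog = 0.7,
                            size_factor_sdlog = 0.3, seed = 1L) {
  if (dispersion < 0) stop_sexdim("dispersion must be >= 0")
  genes <- as.character(genes)
  if (!is.null(effects)) {
    absent <- setdiff(effects$gene, genes)
    if (length(absent))
      stop_sexdim("planted gene(s) absent from gene list: ",
                  paste(absent, collapse = ", "))
    if (any(!effects$cell_type %in% cell_types))
      stop_sexdim("planted effect targets unknown cell type")
  }
  with_seed(seed, {
    ns <- nrow(subjects)
    n_cells <- ns * cells_per_subject
    cell_subject <- rep(seq_len(ns), each = cells_per_subject)
    # even round-robin split of each subject's cells across cell types
    cell_type <- rep(rep_len(cell_types, cells_per_subject), ns)
    meta <- data.frame(
      cell_id = sprintf("C%06d", seq_len(n_cells)),
      subject_id = subjects$subject_id[cell_subject],
      cell_type = cell_type,
      condition = subjects$condition[cell_subject],
      sex = subjects$sex[cell_subject],
      braak = subjects$braak[cell_subject],
      age = subjects$age[cell_subject],
      mmse = subjects$mmse[cell_subject],
      stringsAsFactors = FALSE)
    G <- length(genes)
    base <- matrix(exp(rnorm(G * length(cell_types), baseline_meanlog,
                             baseline_sdlog)),
                   nrow = G, dimnames = list(genes, cell_types))
    sf <- exp(rnorm(n_cells, -size_factor_sdlog^2 / 2, size_factor_sdlog))
    counts <- matrix(0L, nrow = G, ncol = n_cells)
    for (ct in cell_types) {
      idx <- which(meta$cell_type == ct)
      if (!length(idx)) next
      mu <- base[, ct] %o% sf[idx]
      if (!is.null(effects)) {
        eff <- effects[effects$cell_type == ct, , drop = FALSE]
        for (i in seq_len(nrow(eff))) {
          g <- eff$gene[i]
          for (s in c("M", "F")) {
            dir_s <- if (s == "M") eff$direction_male[i] else eff$direction_female[i]
            if (dir_s == 0L) next
            cols <- which(meta$condition[idx] == "AD" & meta$sex[idx] == s)
            if (length(cols))
              mu[g, cols] <- mu[g, cols] * exp(dir_s * eff$delta_logfc[i])
          }
        }
      }
      y <- if (dispersion == 0) rpois(length(mu), mu)
           else rnbinom(length(mu), size = 1 / dispersion, mu = mu)
      counts[, idx] <- y
    }
    cm <- count_matrix(counts, genes, meta$cell_id)
    gt <- ground_truth(effects = effects)
    # expose the true per-cell exposures so calibration checks can use
    # known offsets rather than re-estimated ones
    list(counts = cm, meta = meta, ground_truth = gt, size_factors = sf)
  })
}

#' Assemble a ground-truth registry
#'
#' Records everything the generators planted (effects, enriched gene sets,
#' consistent network edges, shared protein effects) so recovery tests can
#' score pipeline output against the truth. Serializes to JSON and
#' round-trips via [read_ground_truth()].
#'
#' @param effects planted effect registry (or NULL).
#' @param enriched_sets character vector of planted enriched set names.
#' @param grn_edges data.frame of planted consistent edges (or NULL).
#' @param protein_effects planted protein effect registry (or NULL).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(effects = NULL, enriched_sets = character(),
                         grn_edges = NULL, protein_effects = NULL) {
  structure(list(effects = effects, enriched_sets = enriched_sets,
                 grn_edges = grn_edges, protein_effects = protein_effects),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @param x a `ground_truth` object.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(x, path) {
  stopifnot(inherits(x, "ground_truth"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(effects = x$effects,
               enriched_sets = as.character(x$enriched_sets %||% character()),
               grn_edges = x$grn_edges,
               protein_effects = x$protein_effects)
}

#' Generate a gene-set collection with planted enriched sets
#'
#' Produces `n_sets` sets in total: the planted sets (verbatim) plus random
#' background sets drawn from the gene universe.
#'
#' @param genes gene universe.
#' @param n_sets total number of sets (must be >= number planted).
#' @param planted named list of planted member vectors.
#' @param size_range background set size bounds (inclusive).
#' @param seed integer RNG seed.
#' @return Named list of gene sets (GMT-writable via [write_gmt()]).
#' @export
generate_gene_sets <- function(genes, n_sets, planted = list(),
                               size_range = c(10L, 50L), seed = 1L) {
  absent <- setdiff(unlist(planted), genes)
  if (length(absent))
    stop_sexdim("planted set member(s) absent from universe: ",
                paste(absent, collapse = ", "))
  if (n_sets < length(planted))
    stop_sexdim(sprintf("n_sets (%d) < number of planted sets (%d)",
                        n_sets, length(planted)))
  with_seed(seed, {
    n_bg <- n_sets - length(planted)
    bg <- lapply(seq_len(n_bg), function(i) {
      k <- sample(seq(size_range[1], min(size_range[2], length(genes))), 1)
      sort(sample(genes, k))
    })
    names(bg) <- sprintf("RANDOM_SET_%03d", seq_len(n_bg))
    c(planted, bg)
  })
}

#' Generate a partially signed prior regulatory network
#'
#' Random directed candidate interactions with mechanism and tissue labels.
#' Mechanisms are drawn from the five retained annotation classes (binding,
#' transcription regulation, influence on expression, co-regulation of
#' transcription, regulation) plus decoys that downstream filtering should
#' remove; a requested fraction of edges has sign `unknown`. If a planted
#' consistent edge set is supplied, those edges are always included with a
#' retained mechanism and brain tissue.
#'
#' @param genes gene universe for endpoints.
#' @param n_edges total number of edges (>= planted edge count).
#' @param frac_unknown_sign fraction of edges whose sign is masked to
#'   `unknown`.
#' @param planted_consistent optional data.frame with columns `source`,
#'   `target`, `sign` (+1/-1) of edges that must be present.
#' @param frac_decoy_mechanism,frac_decoy_tissue fractions of random edges
#'   given a non-retained mechanism / non-brain tissue label.
#' @param seed integer RNG seed.
#' @return Edge `data.frame` with columns `source`, `target`, `sign`
#'   (`+`, `-`, `unknown`), `mechanism`, `tissue`.
#' @export
generate_prior_network <- function(genes, n_edges, frac_unknown_sign = 0.3,
                                   planted_consistent = NULL,
                                   frac_decoy_mechanism = 0.15,
                                   frac_decoy_tissue = 0.1, seed = 1L) {
  assert_prob(frac_unknown_sign, "frac_unknown_sign")
  n_planted <- if (is.null(planted_consistent)) 0L else nrow(planted_consistent)
  if (n_edges < n_planted)
    stop_sexdim(sprintf("n_edges (%d) < planted edge count (%d)",
                        n_edges, n_planted))
  allowed <- allowed_mechanisms()
  decoys <- c("phosphorylation", "cleavage", "transport")
  with_seed(seed, {
    n_rand <- n_edges - n_planted
    src <- sample(genes, n_rand, replace = TRUE)
    tgt <- sample(genes, n_rand, replace = TRUE)
    loop <- src == tgt
    while (any(loop)) {   # resample self-loops
      tgt[loop] <- sample(genes, sum(loop), replace = TRUE)
      loop <- src == tgt
    }
    mech <- sample(allowed, n_rand, replace = TRUE)
    n_dm <- round(frac_decoy_mechanism * n_rand)
    if (n_dm) mech[sample(n_rand, n_dm)] <- sample(decoys, n_dm, replace = TRUE)
    tissue <- rep("brain", n_rand)
    n_dt <- round(frac_decoy_tissue * n_rand)
    if (n_dt) tissue[sample(n_rand, n_dt)] <- "liver"
    sgn <- sample(c("+", "-"), n_rand, replace = TRUE)
    df <- data.frame(source = src, target = tgt, sign = sgn,
                     mechanism = mech, tissue = tissue,
                     stringsAsFactors = FALSE)
    if (n_planted) {
      pl <- data.frame(source = planted_consistent$source,
                       target = planted_consistent$target,
                       sign = ifelse(planted_consistent$sign > 0, "+", "-"),
                       mechanism = sample(allowed, n_planted, replace = TRUE),
                       tissue = "brain", stringsAsFactors = FALSE)
      df <- rbind(pl, df)
    }
    n_unk <- round(frac_unknown_sign * nrow(df))
    if (n_unk) df$sign[sample(nrow(df), n_unk)] <- "unknown"
    rownames(df) <- NULL
    df
  })
}

#' Generate unique ligand-receptor pairs
#'
#' @param genes gene universe.
#' @param n_pairs number of unique ordered (ligand, receptor) pairs with
#'   ligand != receptor; must not exceed the number of such pairs.
#' @param seed integer RNG seed.
#' @return `data.frame` with columns `ligand`, `receptor`.
#' @export
generate_lr_pairs <- function(genes, n_pairs, seed = 1L) {
  g <- length(genes)
  if (n_pairs > g * (g - 1))
    stop_sexdim("n_pairs exceeds the number of distinct ordered pairs")
  with_seed(seed, {
    # sample indices of the g*(g-1) off-diagonal cells without replacement
    idx <- if (n_pairs == 0) integer(0)
           else sample(g * (g - 1), n_pairs)
    row <- (idx - 1) %% g + 1
    k <- (idx - 1) %/% g + 1
    col <- ifelse(k >= row, k + 1L, k)   # skip the diagonal
    data.frame(ligand = genes[row], receptor = genes[col],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a normalized proteomics abundance matrix
#'
#' Gaussian abundances around sex/condition means encoding the shared
#' planted effects, plus a linear age trend so the age covariate in the
#' downstream model is non-trivial.
#'
#' @param subjects subject table ([generate_cohort()]).
#' @param proteins protein identifiers (gene-symbol namespace).
#' @param shared_effects planted registry ([effect_spec()]); the
#'   `cell_type` field is ignored at the bulk protein level.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param age_slope abundance units per year of age (applied to all
#'   proteins, centered at the cohort mean age).
#' @param seed integer RNG seed.
#' @return A list with `abundance` (proteins x samples matrix) and
#'   `samples` metadata (`sample_id`, `condition`, `sex`, `age`).
#' @export
generate_proteomics <- function(subjects, proteins, shared_effects = NULL,
                                noise_sd = 0.5, age_slope = 0.02, seed = 1L) {
  if (noise_sd < 0) stop_sexdim("noise_sd must be >= 0")
  if (!is.null(shared_effects)) {
    absent <- setdiff(shared_effects$gene, proteins)
    if (length(absent))
      stop_sexdim("shared effect protein(s) absent: ",
                  paste(absent, collapse = ", "))
  }
  with_seed(seed, {
    n <- nrow(subjects)
    p <- length(proteins)
    base <- rnorm(p, 10, 1)
    mu <- matrix(base, nrow = p, ncol = n,
                 dimnames = list(proteins, subjects$subject_id))
    mu <- mu + matrix(age_slope * (subjects$age - mean(subjects$age)),
                      nrow = p, ncol = n, byrow = TRUE)
    if (!is.null(shared_effects)) {
      for (i in seq_len(nrow(shared_effects))) {
        pr <- shared_effects$gene[i]
        for (s in c("M", "F")) {
          dir_s <- if (s == "M") shared_effects$direction_male[i]
                   else shared_effects$direction_female[i]
          if (dir_s == 0L) next
          cols <- subjects$condition == "AD" & subjects$sex == s
          mu[pr, cols] <- mu[pr, cols] + dir_s * shared_effects$delta_logfc[i]
        }
      }
    }
    ab <- mu + matrix(rnorm(p * n, 0, noise_sd), nrow = p)
    samples <- data.frame(sample_id = subjects$subject_id,
                          condition = subjects$condition,
                          sex = subjects$sex, age = subjects$age,
                          stringsAsFactors = FALSE)
    list(abundance = ab, samples = samples)
  })
}
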