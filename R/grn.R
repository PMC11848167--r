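# Phenotype-specific signed gene regulatory networks over DEGs: filter
# candidate prior interactions, Booleanize expression states, select a
# consistent subnetwork with a genetic algorithm (jointly inferring the
# missing signs), and rank perturbagens and key mediators.

#' Mechanism annotations retained for regulatory interactions
#'
#' @return Character vector of the five retained mechanism classes.
#' @export
allowed_mechanisms <- function() {
  c("binding", "transcription regulation", "influence on expression",
    "co-regulation of transcription", "regulation")
}

#' Filter raw prior interactions to the candidate network
#'
#' Keeps edges whose mechanism is in the allowed vocabulary and whose
#' tissue matches, removes self-loops, and collapses duplicate
#' (source, target, sign) triples.
#'
#' @param raw edge `data.frame` (`source`, `target`, `sign`, `mechanism`,
#'   `tissue`).
#' @param mechanisms allowed mechanism labels (default
#'   [allowed_mechanisms()]).
#' @param tissue tissue label to retain (default "brain").
#' @return Filtered edge `data.frame`.
#' @export
filter_interactions <- function(raw, mechanisms = allowed_mechanisms(),
                                tissue = "brain") {
  keep <- raw$mechanism %in% mechanisms & raw$tissue == tissue &
    raw$source != raw$target
  out <- raw[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("source", "target", "sign")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Booleanize differential expression states
#'
#' Maps each network gene to binary phenotype states from its log fold
#' change: up in disease (`logfc > 0`) gives `b_ad = 1, b_ctrl = 0` and
#' vice versa. The network is built over DEGs, so every node must carry a
#' non-zero log fold change.
#'
#' @param de `data.frame` with a `gene` (or `feature`) column and a
#'   `logfc` column.
#' @param node_genes genes to Booleanize (the network's nodes).
#' @param logfc_col name of the log fold change column (default "logfc").
#' @return `data.frame` with `gene`, `b_ad`, `b_ctrl` in {0, 1}.
#' @export
booleanize <- function(de, node_genes, logfc_col = "logfc") {
  key <- if ("gene" %in% names(de)) de$gene else de$feature
  idx <- match(node_genes, key)
  if (anyNA(idx))
    stop_sexdim("no differential expression record for node gene(s): ",
                paste(node_genes[is.na(idx)], collapse = ", "))
  lfc <- de[[logfc_col]][idx]
  if (any(lfc == 0) || anyNA(lfc))
    stop_sexdim("node gene(s) with zero/NA logfc cannot be Booleanized: ",
                paste(node_genes[which(lfc == 0 | is.na(lfc))], collapse = ", "))
  b_ad <- as.integer(lfc > 0)
  data.frame(gene = node_genes, b_ad = b_ad, b_ctrl = 1L - b_ad,
             stringsAsFactors = FALSE)
}

#' Is a signed edge consistent with the Boolean states of one phenotype?
#'
#' An activation (+1) is consistent when source and target share the same
#' state; an inhibition (-1) when their states differ.
#'
#' @param sign +1 or -1 (an unresolved sign is an error).
#' @param b_source,b_target node states in {0, 1} for the phenotype.
#' @return Logical.
#' @export
edge_consistent <- function(sign, b_source, b_target) {
  if (!sign %in% c(-1, 1))
    stop_sexdim("edge sign must be resolved to +1 or -1 before checking")
  if (sign == 1) b_source == b_target else b_source != b_target
}

#' Genetic-algorithm parameters
#'
#' @param population_size,max_generations,stagnation_limit GA run sizes.
#' @param crossover_rate uniform-crossover probability per mating pair.
#' @param mutation_rate per-bit flip probability; `NULL` (default) means
#'   `1 / chromosome length`.
#' @param tournament_k tournament selection size.
#' @param elitism chromosomes copied unchanged each generation.
#' @param lambda_parsimony edge-count penalty weight (breaks ties toward
#'   sparse networks).
#' @param seed integer RNG seed.
#' @return A `ga_params` list.
#' @export
ga_params <- function(population_size = 200L, max_generations = 500L,
                      stagnation_limit = 50L, crossover_rate = 0.9,
                      mutation_rate = NULL, tournament_k = 3L,
                      elitism = 2L, lambda_parsimony = 0.01, seed = 1L) {
  assert_prob(crossover_rate, "crossover_rate")
  if (!is.null(mutation_rate)) assert_prob(mutation_rate, "mutation_rate")
  stopifnot(population_size >= 1, max_generations >= 1, tournament_k >= 1,
            elitism >= 0, lambda_parsimony >= 0)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 stagnation_limit = as.integer(stagnation_limit),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_k = as.integer(tournament_k),
                 elitism = as.integer(elitism),
                 lambda_parsimony = lambda_parsimony,
                 seed = as.integer(seed)),
            class = "ga_params")
}

# Precompute, per candidate edge and phenotype, whether the edge is
# consistent under a + and under a - sign, plus the target incidence
# matrix used to count explained targets.
.fitness_context <- function(candidate, states) {
  idx_s <- match(candidate$source, states$gene)
  idx_t <- match(candidate$target, states$gene)
  if (anyNA(idx_s) || anyNA(idx_t))
    stop_sexdim("candidate network contains nodes without Boolean states")
  eq_ad <- states$b_ad[idx_s] == states$b_ad[idx_t]
  eq_ct <- states$b_ctrl[idx_s] == states$b_ctrl[idx_t]
  sgn <- candidate$sign
  num_sign <- ifelse(sgn == "+", 1L, ifelse(sgn == "-", -1L, NA_integer_))
  targets <- sort(unique(candidate$target))
  M <- matrix(0L, nrow = nrow(candidate), ncol = length(targets))
  M[cbind(seq_len(nrow(candidate)), match(candidate$target, targets))] <- 1L
  list(cons_plus_ad = eq_ad, cons_minus_ad = !eq_ad,
       cons_plus_ct = eq_ct, cons_minus_ct = !eq_ct,
       fixed_sign = num_sign, unknown = which(is.na(num_sign)),
       n_edges = nrow(candidate), targets = targets, M = M)
}

# Evaluate fitness for a 0/1 population matrix (rows = chromosomes of
# length n_edges + n_unknown). Returns a numeric vector.
.fitness_pop <- function(pop, ctx, lambda) {
  E <- ctx$n_edges; U <- length(ctx$unknown)
  incl <- pop[, seq_len(E), drop = FALSE]
  plus <- matrix(rep(ctx$fixed_sign == 1L, each = nrow(pop)), nrow = nrow(pop))
  if (U) plus[, ctx$unknown] <- pop[, E + seq_len(U), drop = FALSE] == 1
  cons_ad <- ifelse(plus,
                    rep(ctx$cons_plus_ad, each = nrow(pop)),
                    rep(ctx$cons_minus_ad, each = nrow(pop)))
  cons_ct <- ifelse(plus,
                    rep(ctx$cons_plus_ct, each = nrow(pop)),
                    rep(ctx$cons_minus_ct, each = nrow(pop)))
  dim(cons_ad) <- dim(cons_ct) <- dim(incl)
  eff_ad <- incl * cons_ad
  eff_ct <- incl * cons_ct
  expl <- rowSums((eff_ad %*% ctx$M) > 0) + rowSums((eff_ct %*% ctx$M) > 0)
  expl / (2 * length(ctx$targets)) - lambda * rowSums(incl) / E
}

#' Fitness of one subnetwork chromosome
#'
#' A target node (any node with at least one candidate incoming edge) is
#' "explained" in a phenotype when at least one selected incoming edge is
#' consistent there. Fitness is the explained fraction summed over the two
#' phenotypes, normalized to [0, 1], minus `lambda` times the selected
#' edge fraction (a parsimony penalty).
#'
#' @param inclusion logical/0-1 vector, one bit per candidate edge.
#' @param sign_bits 0/1 vector, one bit per unknown-sign edge in candidate
#'   order (1 = activation); length must equal the number of unknown-sign
#'   edges.
#' @param candidate candidate edge `data.frame` ([filter_interactions()]).
#' @param states Boolean states ([booleanize()]).
#' @param lambda parsimony weight.
#' @return Scalar fitness.
#' @export
network_fitness <- function(inclusion, sign_bits, candidate, states,
                            lambda = 0.01) {
  ctx <- .fitness_context(candidate, states)
  if (length(inclusion) != ctx$n_edges)
    stop_sexdim("inclusion length must equal the candidate edge count")
  if (length(sign_bits) != length(ctx$unknown))
    stop_sexdim("sign_bits length must equal the number of unknown-sign edges")
  .fitness_pop(matrix(as.integer(c(inclusion, sign_bits)), nrow = 1),
               ctx, lambda)[1]
}

#' Select a phenotype-consistent subnetwork with a genetic algorithm
#'
#' The chromosome carries one inclusion bit per candidate edge plus one
#' sign bit per unknown-sign edge (fixed signs are immutable), so edge
#' selection and missing-sign deduction are optimized jointly. Evolution
#' uses tournament selection, uniform crossover, per-bit mutation, and
#' elitism, stopping at `max_generations` or after `stagnation_limit`
#' generations without improvement. Fully reproducible from the seed.
#'
#' @param candidate candidate edge `data.frame` (non-empty).
#' @param states Boolean states covering all candidate nodes.
#' @param params a [ga_params()] list.
#' @return A `phenotype_grn`: selected edges with resolved numeric signs,
#'   the achieved `fitness`, per-target explained flags per phenotype,
#'   `states`, and GA metadata.
#' @export
run_ga <- function(candidate, states, params = ga_params()) {
  if (!nrow(candidate)) stop_sexdim("candidate network is empty")
  ctx <- .fitness_context(candidate, states)
  E <- ctx$n_edges; U <- length(ctx$unknown); L <- E + U
  lambda <- params$lambda_parsimony
  pmut <- params$mutation_rate %||% (1 / L)
  with_seed(params$seed, {
    np <- params$population_size
    pop <- matrix(as.integer(runif(np * L) < 0.5), nrow = np)
    fit <- .fitness_pop(pop, ctx, lambda)
    best_fit <- -Inf; best <- NULL; stagnant <- 0L; gen <- 0L
    for (gen in seq_len(params$max_generations)) {
      if (max(fit) > best_fit + 1e-12) {
        best_fit <- max(fit); best <- pop[which.max(fit), ]; stagnant <- 0L
      } else stagnant <- stagnant + 1L
      if (stagnant >= params$stagnation_limit) break
      # tournament selection of np parents
      tourn <- matrix(sample.int(np, np * params$tournament_k, replace = TRUE),
                      nrow = np)
      parents <- apply(tourn, 1, function(ix) ix[which.max(fit[ix])])
      nxt <- pop[parents, , drop = FALSE]
      # uniform crossover on consecutive pairs
      for (i in seq(1, np - 1, by = 2)) {
        if (runif(1) < params$crossover_rate) {
          swap <- runif(L) < 0.5
          tmp <- nxt[i, swap]
          nxt[i, swap] <- nxt[i + 1, swap]
          nxt[i + 1, swap] <- tmp
        }
      }
      flip <- matrix(runif(np * L) < pmut, nrow = np)
      nxt[flip] <- 1L - nxt[flip]
      if (params$elitism > 0) {
        elite <- order(fit, decreasing = TRUE)[seq_len(min(params$elitism, np))]
        nxt[seq_along(elite), ] <- pop[elite, , drop = FALSE]
      }
      pop <- nxt
      fit <- .fitness_pop(pop, ctx, lambda)
    }
    if (max(fit) > best_fit + 1e-12) {
      best_fit <- max(fit); best <- pop[which.max(fit), ]
    }
    decode_grn(best, best_fit, candidate, states, ctx, params, gen)
  })
}

# Turn the winning chromosome into the selected signed edge table plus
# per-phenotype explained flags.
decode_grn <- function(chrom, fitness, candidate, states, ctx, params, gens) {
  E <- ctx$n_edges
  incl <- chrom[seq_len(E)] == 1L
  sign_num <- ctx$fixed_sign
  if (length(ctx$unknown))
    sign_num[ctx$unknown] <- ifelse(chrom[E + seq_along(ctx$unknown)] == 1L,
                                    1L, -1L)
  edges <- data.frame(source = candidate$source[incl],
                      target = candidate$target[incl],
                      sign = sign_num[incl],
                      sign_inferred = is.na(ctx$fixed_sign)[incl],
                      stringsAsFactors = FALSE)
  plus <- sign_num == 1L
  cons_ad <- ifelse(plus, ctx$cons_plus_ad, ctx$cons_minus_ad) & incl
  cons_ct <- ifelse(plus, ctx$cons_plus_ct, ctx$cons_minus_ct) & incl
  explained <- data.frame(
    target = ctx$targets,
    explained_ad = as.vector(crossprod(ctx$M, cons_ad) > 0),
    explained_ctrl = as.vector(crossprod(ctx$M, cons_ct) > 0),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, fitness = fitness, states = states,
                 explained = explained,
                 ga = list(seed = params$seed, generations = gens,
                           population = params$population_size,
                           lambda = params$lambda_parsimony)),
            class = "phenotype_grn")
}

#' @export
print.phenotype_grn <- function(x, ...) {
  cat(sprintf(
    "phenotype_grn: %d selected edges over %d nodes, fitness %.4f (GA seed %d)\n",
    nrow(x$edges), nrow(x$states), x$fitness, x$ga$seed))
  invisible(x)
}

.grn_graph <- function(grn) {
  igraph::graph_from_data_frame(
    grn$edges[, c("source", "target"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = grn$states$gene))
}

#' Rank perturbagens by downstream reach
#'
#' A node's perturbagen score is the number of other nodes reachable from
#' it by directed paths in the selected network (its downstream target
#' count). Nodes are ranked by decreasing score with symbol tiebreak.
#'
#' @param grn a `phenotype_grn` from [run_ga()].
#' @return `data.frame` with `gene`, `score`.
#' @export
perturbagen_scores <- function(grn) {
  g <- .grn_graph(grn)
  genes <- grn$states$gene
  score <- vapply(genes, function(v)
    length(igraph::subcomponent(g, v, mode = "out")) - 1L, 0L)
  out <- data.frame(gene = genes, score = score, stringsAsFactors = FALSE)
  out <- out[order_by(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank key mediators
#'
#' A mediator relays upstream changes to downstream targets; its score is
#' the number of its ancestors times the number of its descendants in the
#' selected network. The top-ranked node is the network's key mediator.
#'
#' @param grn a `phenotype_grn`.
#' @return `data.frame` with `gene`, `n_upstream`, `n_downstream`,
#'   `score`, ranked by decreasing score then symbol.
#' @export
mediator_scores <- function(grn) {
  g <- .grn_graph(grn)
  genes <- grn$states$gene
  up <- vapply(genes, function(v)
    length(igraph::subcomponent(g, v, mode = "in")) - 1L, 0L)
  down <- vapply(genes, function(v)
    length(igraph::subcomponent(g, v, mode = "out")) - 1L, 0L)
  out <- data.frame(gene = genes, n_upstream = up, n_downstream = down,
                    score = up * down, stringsAsFactors = FALSE)
  out <- out[order_by(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upstream-regulator subnetwork of a mediator
#'
#' Returns the union of directed paths ending at the named gene: the edges
#' whose target lies in the gene's ancestor closure (including the gene
#' itself) and whose source is an ancestor.
#'
#' @param grn a `phenotype_grn`.
#' @param gene mediator gene symbol.
#' @return Edge `data.frame` subset of `grn$edges`.
#' @export
mediator_subnetwork <- function(grn, gene) {
  if (!gene %in% grn$states$gene)
    stop_sexdim(sprintf("gene '%s' is not a network node", gene))
  g <- .grn_graph(grn)
  anc <- setdiff(igraph::subcomponent(g, gene, mode = "in")$name, gene)
  keep <- grn$edges$source %in% anc &
    grn$edges$target %in% c(anc, gene)
  out <- grn$edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
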