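# Independent oracles used across the suite. Each reimplements a quantity
# by brute force / enumeration, never by calling the code path it checks.

# Benjamini-Hochberg by the literal step-up definition:
# adj(i) = min over j >= i (in sorted order) of p(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by enumerating all C(N, n) draws.
ora_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)           # first K universe elements are the term
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

# Directed reachability from `from` by breadth-first search over an edge
# data.frame (source, target); excludes the start node.
bfs_reach <- function(edges, from) {
  frontier <- from
  seen <- character()
  while (length(frontier)) {
    nxt <- unique(edges$target[edges$source %in% frontier])
    nxt <- setdiff(nxt, c(seen, from))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

bfs_ancestors <- function(edges, of) {
  bfs_reach(data.frame(source = edges$target, target = edges$source,
                       stringsAsFactors = FALSE), of)
}

# Exhaustive search over every chromosome of a small candidate network;
# returns the maximum fitness.
ga_exhaustive <- function(candidate, states, lambda) {
  E <- nrow(candidate)
  U <- sum(candidate$sign == "unknown")
  L <- E + U
  stopifnot(L <= 14)
  best <- -Inf
  for (code in 0:(2^L - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(L)]
    f <- network_fitness(bits[seq_len(E)],
                         if (U) bits[E + seq_len(U)] else integer(0),
                         candidate, states, lambda)
    if (f > best) best <- f
  }
  best
}

# Greedy baseline: repeatedly add the single (edge, sign) choice with the
# largest fitness gain; stop when no addition improves fitness.
ga_greedy <- function(candidate, states, lambda) {
  E <- nrow(candidate)
  unknown <- which(candidate$sign == "unknown")
  U <- length(unknown)
  incl <- integer(E)
  sbits <- integer(U)
  cur <- network_fitness(incl, sbits, candidate, states, lambda)
  repeat {
    best_gain <- 0; best_mv <- NULL
    for (j in which(incl == 0L)) {
      u <- match(j, unknown)
      for (sb in if (is.na(u)) 0L else c(0L, 1L)) {
        incl2 <- incl; incl2[j] <- 1L
        sbits2 <- sbits
        if (!is.na(u)) sbits2[u] <- sb
        f <- network_fitness(incl2, sbits2, candidate, states, lambda)
        if (f - cur > best_gain + 1e-12) {
          best_gain <- f - cur; best_mv <- list(incl2, sbits2, f)
        }
      }
    }
    if (is.null(best_mv)) break
    incl <- best_mv[[1]]; sbits <- best_mv[[2]]; cur <- best_mv[[3]]
  }
  cur
}

# Random candidate network + coherent Boolean states for GA tests.
random_grn_instance <- function(n_nodes, n_edges, frac_unknown, seed) {
  genes <- sprintf("N%02d", seq_len(n_nodes))
  net <- generate_prior_network(genes, n_edges,
                                frac_unknown_sign = frac_unknown,
                                frac_decoy_mechanism = 0,
                                frac_decoy_tissue = 0, seed = seed)
  net <- filter_interactions(net)
  set.seed(seed + 1000)
  lfc <- sample(c(-1, 1), n_nodes, replace = TRUE) * runif(n_nodes, 0.3, 1)
  de <- data.frame(gene = genes, logfc = lfc, stringsAsFactors = FALSE)
  states <- booleanize(de, sort(unique(c(net$source, net$target))))
  list(candidate = net, states = states)
}

# Small deterministic synthetic dataset shared by several tests: two cell
# types, planted effects of every category in cell type "A".
tiny_dataset <- function(seed = 7L, delta = 1.2, cells_per_subject = 30L,
                         n_genes = 120L) {
  spec <- cohort_spec(group_sizes = list(control = c(6, 6),
                                         early_ad = c(0, 0),
                                         intermediate_ad = c(0, 0),
                                         late_ad = c(6, 6)))
  subjects <- generate_cohort(spec, seed = seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  eff <- rbind(
    effect_spec(genes[1:2], "A", "neutral", delta),
    effect_spec(genes[3:4], "A", "male_specific", delta),
    effect_spec(genes[5:6], "A", "female_specific", delta),
    effect_spec(genes[7:8], "A", "dimorphic", delta))
  gen <- generate_counts(subjects, cells_per_subject, genes, c("A", "B"),
                         effects = eff, dispersion = 0.1, seed = seed)
  c(gen, list(subjects = subjects, effects = eff, genes = genes))
}
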