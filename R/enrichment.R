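# Hypergeometric over-representation analysis (ORA) of category gene lists
# against gene-set collections, with a term-level sex-specificity rule.

#' Hypergeometric over-representation test for one gene set
#'
#' Computes the exact upper-tail probability `P(X >= k)` of drawing `k` or
#' more members of a `K`-gene term in a query of `n` genes from an
#' `N`-gene universe (X hypergeometric). The query must be a subset of the
#' universe; the term is intersected with the universe before testing.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param term_set character vector of the term's member genes.
#' @param universe character vector, the gene universe.
#' @return List with `k`, `K`, `n`, `N`, `p`, and `overlap` (the
#'   overlapping gene symbols, sorted).
#' @export
ora_test <- function(query, term_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_sexdim("universe must be non-empty")
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop_sexdim("query genes must be a subset of the universe")
  term <- intersect(unique(term_set), universe)
  overlap <- sort(intersect(query, term))
  k <- length(overlap); K <- length(term)
  n <- length(query); N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p, overlap = overlap)
}

#' Over-representation analysis across a gene-set collection
#'
#' Applies [ora_test()] to each set, skipping sets whose size after
#' universe intersection falls outside `[min_set, max_set]`, adjusts p
#' across the tested sets with Benjamini-Hochberg, and sorts by adjusted p,
#' then p, then term name.
#'
#' @param query query gene vector (subset of `universe`).
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe gene universe; by convention the genes actually tested
#'   in the stratum's differential run.
#' @param min_set,max_set post-intersection set size bounds (defaults 5 and
#'   500).
#' @return `data.frame` with columns `term`, `k`, `K`, `n`, `N`, `p`,
#'   `adj_p`, `overlap` (comma-separated symbols).
#' @export
enrich_collection <- function(query, collection, universe, min_set = 5L,
                              max_set = 500L) {
  universe <- unique(universe)
  sizes <- vapply(collection, function(s)
    length(intersect(unique(s), universe)), 0L)
  keep <- which(sizes >= min_set & sizes <= max_set)
  rows <- lapply(keep, function(i) {
    r <- ora_test(query, collection[[i]], universe)
    data.frame(term = names(collection)[i], k = r$k, K = r$K, n = r$n,
               N = r$N, p = r$p,
               overlap = paste(r$overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(term = character(), k = integer(), K = integer(),
                         n = integer(), N = integer(), p = numeric(),
                         overlap = character(), stringsAsFactors = FALSE)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order_by(out$adj_p, out$p, out$term),
             c("term", "k", "K", "n", "N", "p", "adj_p", "overlap")]
  rownames(out) <- NULL
  out
}

#' Label enriched terms as sex-specific or shared
#'
#' A term is male-specific when it is significant in males (adjusted p <
#' `fdr`) while its nominal p in females exceeds `nonsig_p` (and
#' symmetrically for female-specific); it is shared when significant in
#' both sexes; otherwise it is left unlabeled. A term tested in only one
#' sex is treated as nominal p = 1 in the missing sex and flagged.
#'
#' @param male_enrich,female_enrich [enrich_collection()] outputs computed
#'   against the same collection.
#' @param fdr adjusted-p significance threshold (default 0.05).
#' @param nonsig_p other-sex nominal-p specificity threshold (default 0.1).
#' @return `data.frame` with `term`, per-sex `p_*`/`adj_p_*`, `label` in
#'   `{male_specific, female_specific, shared, none}`, and
#'   `tested_one_sex`.
#' @export
sex_specific_terms <- function(male_enrich, female_enrich, fdr = 0.05,
                               nonsig_p = 0.1) {
  terms <- sort(union(male_enrich$term, female_enrich$term))
  im <- match(terms, male_enrich$term)
  fi <- match(terms, female_enrich$term)
  p_m <- ifelse(is.na(im), 1, male_enrich$p[im])
  p_f <- ifelse(is.na(fi), 1, female_enrich$p[fi])
  ap_m <- ifelse(is.na(im), 1, male_enrich$adj_p[im])
  ap_f <- ifelse(is.na(fi), 1, female_enrich$adj_p[fi])
  sig_m <- ap_m < fdr; sig_f <- ap_f < fdr
  label <- rep("none", length(terms))
  label[sig_m & sig_f] <- "shared"
  label[sig_m & !sig_f & p_f > nonsig_p] <- "male_specific"
  label[sig_f & !sig_m & p_m > nonsig_p] <- "female_specific"
  data.frame(term = terms, p_male = p_m, adj_p_male = ap_m,
             p_female = p_f, adj_p_female = ap_f, label = label,
             tested_one_sex = is.na(im) | is.na(fi),
             stringsAsFactors = FALSE)
}
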