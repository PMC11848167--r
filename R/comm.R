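# Cell-cell communication layer: expression filtering of sender/receiver
# genes, DEG x ligand-receptor intersection, prior-network ligand influence
# ranking, and enrichment of the intersection genes.

#' Genes expressed above a detection threshold in one cell type
#'
#' Returns the genes whose fraction of cells with non-zero counts, among
#' the cells of the given type, is strictly greater than `threshold`
#' (strict, matching the "> 10% of cells" convention).
#'
#' @param counts a [count_matrix()].
#' @param meta per-cell metadata aligned with `counts`.
#' @param cell_type cell type label (must be present in `meta`).
#' @param threshold detection fraction (default 0.10).
#' @return Character vector of expressed gene symbols.
#' @export
filter_expressed <- function(counts, meta, cell_type, threshold = 0.10) {
  stopifnot(inherits(counts, "count_matrix"))
  sel <- meta$cell_type == cell_type
  if (!any(sel))
    stop_sexdim(sprintf("cell type '%s' not present in metadata", cell_type))
  frac <- Matrix::rowMeans(counts$counts[, sel, drop = FALSE] > 0)
  counts$genes[frac > threshold]
}

#' Intersect DEGs with expressed ligand-receptor pairs
#'
#' Keeps the ligand-receptor pairs whose ligand is expressed in the sender
#' cell type, whose receptor is expressed in the receiver cell type, and
#' where at least one endpoint is a differentially expressed gene of the
#' requested category; each endpoint's DEG status is recorded.
#'
#' @param degs character vector of DEGs (e.g., one category of a sex
#'   pattern table).
#' @param lr ligand-receptor `data.frame` (`ligand`, `receptor`).
#' @param expressed_sender,expressed_receiver expressed gene sets from
#'   [filter_expressed()].
#' @return Candidate pair `data.frame` with `ligand`, `receptor`,
#'   `ligand_deg`, `receptor_deg`.
#' @export
intersect_degs_lr <- function(degs, lr, expressed_sender, expressed_receiver) {
  keep <- lr$ligand %in% expressed_sender & lr$receptor %in% expressed_receiver
  out <- lr[keep, c("ligand", "receptor"), drop = FALSE]
  out$ligand_deg <- out$ligand %in% degs
  out$receptor_deg <- out$receptor %in% degs
  out <- out[out$ligand_deg | out$receptor_deg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate ligands by downstream DEG influence
#'
#' Scores each candidate ligand by the number of DEGs reachable from it by
#' directed paths in the prior regulatory network (a plumbing stand-in for
#' model-based ligand-activity ranking: the "most relevant" ligands are
#' those that can influence the most differentially expressed targets).
#' Ligands absent from the network score 0 and are flagged.
#'
#' @param pairs candidate table from [intersect_degs_lr()].
#' @param prior edge `data.frame` with `source`, `target` columns.
#' @param degs character vector of DEGs.
#' @param top_n ligands to return (default 30).
#' @return `data.frame` `ligand`, `score`, `in_network`, sorted by
#'   decreasing score then symbol.
#' @export
rank_ligands <- function(pairs, prior, degs, top_n = 30L) {
  ligands <- sort(unique(pairs$ligand))
  nodes <- unique(c(prior$source, prior$target))
  g <- igraph::graph_from_data_frame(
    prior[, c("source", "target"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = nodes))
  score <- vapply(ligands, function(l) {
    if (!l %in% nodes) return(0L)
    reach <- igraph::subcomponent(g, l, mode = "out")$name
    length(intersect(setdiff(reach, l), degs))
  }, 0L)
  out <- data.frame(ligand = ligands, score = score,
                    in_network = ligands %in% nodes,
                    stringsAsFactors = FALSE)
  out <- out[order_by(-out$score, out$ligand), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}

#' Enrichment of communication-intersection genes
#'
#' Delegates to [enrich_collection()] on the endpoint genes of the
#' candidate pairs and marks terms passing the nominal p < `p_cutoff`
#' significance rule used for communication pathways (the nominal, not
#' adjusted, threshold).
#'
#' @param endpoint_genes gene set (ligands and receptors of retained
#'   pairs, intersected with the universe upstream).
#' @param collection,universe,min_set,max_set as in [enrich_collection()].
#' @param p_cutoff nominal significance threshold (default 0.05).
#' @return [enrich_collection()] output with an extra logical column
#'   `significant`.
#' @export
comm_enrichment <- function(endpoint_genes, collection, universe,
                            min_set = 5L, max_set = 500L, p_cutoff = 0.05) {
  if (!length(unique(endpoint_genes)))
    collection <- list()   # nothing to test against
  res <- enrich_collection(endpoint_genes, collection, universe,
                           min_set = min_set, max_set = max_set)
  res$significant <- res$p < p_cutoff
  res
}
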