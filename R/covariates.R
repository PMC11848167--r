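# Sex-stratified Spearman correlations between per-subject expression
# summaries and the clinical covariates (age, Braak stage, MMSE).

#' Per-subject pseudobulk expression
#'
#' For the cells of one cell type, averages size-factor-normalized counts
#' within each subject; subjects contributing fewer than `min_cells` cells
#' are dropped with a warning. Subject-level summaries avoid treating
#' cells of one donor as independent replicates.
#'
#' @param counts a [count_matrix()].
#' @param meta per-cell metadata aligned with `counts`.
#' @param cell_type cell type label.
#' @param min_cells minimum cells per subject (default 3).
#' @return Genes x subjects numeric matrix.
#' @export
pseudobulk <- function(counts, meta, cell_type, min_cells = 3L) {
  stopifnot(inherits(counts, "count_matrix"))
  sel <- meta$cell_type == cell_type
  if (!any(sel))
    stop_sexdim(sprintf("cell type '%s' not present", cell_type))
  sf <- size_factors(counts)
  subj <- meta$subject_id[sel]
  keep_subj <- names(which(table(subj) >= min_cells))
  dropped <- setdiff(unique(subj), keep_subj)
  if (length(dropped))
    warning(sprintf("dropping %d subject(s) with < %d cells of type %s",
                    length(dropped), min_cells, cell_type), call. = FALSE)
  if (!length(keep_subj))
    stop_sexdim("no subjects with enough cells of the requested type")
  idx <- which(sel)[subj %in% keep_subj]
  norm <- sweep(as.matrix(counts$counts[, idx, drop = FALSE]), 2, sf[idx], "/")
  groups <- factor(meta$subject_id[idx], levels = sort(keep_subj))
  agg <- t(rowsum(t(norm), groups) / as.vector(table(groups)))
  rownames(agg) <- counts$genes
  agg
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the p-value comes from the t-approximation on `n - 2` degrees of
#' freedom, or from exact enumeration of all rank permutations when
#' `exact = TRUE` (supported for n <= 8).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use the exact permutation null (default FALSE).
#' @return List with `rho`, `p`, `n`; `rho` is NA (flagged via
#'   `degenerate`) when either vector has zero rank variance.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3)
    stop_sexdim("x and y must have equal length >= 3")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) stop_sexdim("fewer than 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 8) stop_sexdim("exact permutation p supported for n <= 8")
    perms <- .all_perms(n)
    null_rho <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    if (abs(rho) == 1) p <- 2 * pt(-Inf, n - 2)  # 0 by convention
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

.all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Sex-stratified covariate correlations of pseudobulk expression
#'
#' For each gene, covariate, and (optionally) sex, computes the Spearman
#' correlation between the subjects' pseudobulk expression and the
#' covariate, with Benjamini-Hochberg adjustment within each covariate x
#' sex block. Subjects with a missing covariate value (e.g., controls'
#' undefined Braak stage) are excluded from that covariate's correlations.
#'
#' @param expr genes x subjects pseudobulk matrix ([pseudobulk()]).
#' @param subjects subject metadata (`subject_id`, `sex`, plus covariate
#'   columns).
#' @param covariates covariate column names (default age, braak, mmse).
#' @param stratify_by_sex compute within each sex (default TRUE) or pooled.
#' @param min_n minimum subjects per correlation (default 3).
#' @return `data.frame` with `gene`, `covariate`, `sex`, `rho`, `p`,
#'   `adj_p`, `n`.
#' @export
correlate_covariates <- function(expr, subjects,
                                 covariates = c("age", "braak", "mmse"),
                                 stratify_by_sex = TRUE, min_n = 3L) {
  sub <- subjects[match(colnames(expr), subjects$subject_id), , drop = FALSE]
  if (anyNA(sub$subject_id))
    stop_sexdim("pseudobulk columns missing from subject metadata")
  strata <- if (stratify_by_sex) c("M", "F") else "all"
  blocks <- list()
  for (sx in strata) {
    in_sex <- if (sx == "all") rep(TRUE, nrow(sub)) else sub$sex == sx
    for (cv in covariates) {
      if (!cv %in% names(sub)) {
        warning(sprintf("covariate '%s' missing; skipped", cv), call. = FALSE)
        next
      }
      v <- sub[[cv]][in_sex]
      usable <- !is.na(v)
      if (sum(usable) < min_n) {
        warning(sprintf("covariate '%s' (%s): < %d usable subjects; skipped",
                        cv, sx, min_n), call. = FALSE)
        next
      }
      e <- expr[, in_sex, drop = FALSE][, usable, drop = FALSE]
      vv <- v[usable]
      res <- lapply(seq_len(nrow(e)), function(i)
        spearman_cor(e[i, ], vv))
      blk <- data.frame(gene = rownames(expr),
                        covariate = cv, sex = sx,
                        rho = vapply(res, `[[`, 0, "rho"),
                        p = vapply(res, `[[`, 0, "p"),
                        n = vapply(res, `[[`, 0L, "n"),
                        stringsAsFactors = FALSE)
      blk$adj_p <- NA_real_
      ok <- !is.na(blk$p)
      blk$adj_p[ok] <- bh_adjust(blk$p[ok])
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks)
         else data.frame(gene = character(), covariate = character(),
                         sex = character(), rho = numeric(), p = numeric(),
                         n = integer(), adj_p = numeric(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("gene", "covariate", "sex", "rho", "p", "adj_p", "n")]
}
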