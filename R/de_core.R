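# Per-stratum (cell type x sex) AD-vs-control differential expression:
# Poisson GLM likelihood-ratio tests with per-cell exposure offsets and
# Benjamini-Hochberg correction within the stratum.

#' Per-cell size factors
#'
#' Total counts per cell divided by their median; enters the Poisson GLM as
#' a log offset (exposure).
#'
#' @param counts a [count_matrix()] or a matrix.
#' @return Numeric vector, one positive size factor per cell.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) stop_sexdim("cells with zero total counts cannot be normalized")
  med <- stats::median(tot)
  tot / med
}

#' Fraction of cells expressing a gene
#'
#' @param counts_row numeric count vector for one gene.
#' @param cell_mask logical or integer index selecting >= 1 cell.
#' @return Fraction of the selected cells with count > 0.
#' @export
pct_expressed <- function(counts_row, cell_mask) {
  sel <- counts_row[cell_mask]
  if (!length(sel)) stop_sexdim("cell mask selects no cells")
  mean(sel > 0)
}

#' Log fold change of size-factor-normalized means
#'
#' `ln((mean normalized AD count + pseudocount) / (mean normalized HC count
#' + pseudocount))`. The pseudocount keeps one-sided zeros finite.
#'
#' @param counts_row numeric counts for one gene.
#' @param mask_ad,mask_hc non-empty cell selections for the two conditions.
#' @param size_factors positive per-cell size factors (same length as the
#'   row).
#' @param pseudocount added to both normalized means (default 1).
#' @return Natural-log fold change (AD vs HC).
#' @export
compute_logfc <- function(counts_row, mask_ad, mask_hc, size_factors,
                          pseudocount = 1) {
  if (any(size_factors <= 0)) stop_sexdim("size factors must be positive")
  norm <- counts_row / size_factors
  a <- norm[mask_ad]; h <- norm[mask_hc]
  if (!length(a) || !length(h)) stop_sexdim("both condition masks must be non-empty")
  log((mean(a) + pseudocount) / (mean(h) + pseudocount))
}

#' Poisson likelihood-ratio test for a two-condition comparison
#'
#' Full model: Poisson log-link with intercept, condition indicator, and a
#' fixed log-exposure offset; the null drops the indicator. With a single
#' binary covariate the MLE is available in closed form - each group's
#' fitted rate is its total count divided by its total exposure - so the
#' deviance `D = 2 (l_full - l_null)` is computed exactly and compared to a
#' chi-squared distribution with 1 df. An all-zero row is returned as the
#' defined degenerate result (deviance 0, p 1) with `degenerate = TRUE`.
#'
#' @param counts_row numeric counts for one gene.
#' @param condition logical/character vector: TRUE (or "AD") marks the
#'   case condition; both conditions must be represented.
#' @param offsets log size factors (default all zero).
#' @return List with `p`, `deviance`, `rate_case`, `rate_control`,
#'   `degenerate`.
#' @export
poisson_lrt <- function(counts_row, condition, offsets = NULL) {
  is_case <- if (is.logical(condition)) condition else condition %in% c("AD", "case")
  if (!any(is_case) || all(is_case))
    stop_sexdim("both conditions must be represented")
  if (is.null(offsets)) offsets <- numeric(length(counts_row))
  d <- poisson_lrt_vec(matrix(counts_row, nrow = 1), is_case, offsets)
  list(p = d$p[1], deviance = d$deviance[1],
       rate_case = d$rate_case[1], rate_control = d$rate_control[1],
       degenerate = d$degenerate[1])
}

# Vectorized closed-form two-group Poisson LRT over the rows of a matrix.
# exposures e_i = exp(offset_i); group MLE rate r_g = sum(y)/sum(e);
# D = 2 * [Y1 log(r1/r0) + Y0 log(r0g/r0)] with 0 log 0 := 0.
poisson_lrt_vec <- function(counts, is_case, offsets) {
  e <- exp(offsets)
  y1 <- as.numeric(counts %*% ifelse(is_case, 1, 0))
  y0 <- as.numeric(counts %*% ifelse(is_case, 0, 1))
  s1 <- sum(e[is_case]); s0 <- sum(e[!is_case])
  r1 <- y1 / s1; r0g <- y0 / s0; r0 <- (y1 + y0) / (s1 + s0)
  term <- function(y, r) ifelse(y > 0, y * log(r / r0), 0)
  dev <- 2 * (term(y1, r1) + term(y0, r0g))
  dev <- pmax(dev, 0)            # guard tiny negative rounding
  degenerate <- (y1 + y0) == 0
  dev[degenerate] <- 0
  p <- pchisq(dev, df = 1, lower.tail = FALSE)
  p[degenerate] <- 1
  list(p = p, deviance = dev, rate_case = r1, rate_control = r0g,
       degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj(i) = min_{j >= i} p(j) * m / j` in sorted
#' order, capped at 1, returned in input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  assert_prob(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Run differential expression for one (cell type, sex) stratum
#'
#' Selects the stratum's cells, filters genes detected in fewer than
#' `min_pct` of cells in both conditions, applies the closed-form Poisson
#' likelihood-ratio test per gene with log size-factor offsets, adjusts p
#' across the tested genes with Benjamini-Hochberg, and sorts by adjusted
#' p, then decreasing |logFC|, then gene symbol.
#'
#' @param counts a [count_matrix()].
#' @param meta per-cell metadata (columns `cell_id`, `cell_type`,
#'   `condition`, `sex`).
#' @param cell_type,sex stratum selectors.
#' @param min_pct detection filter: genes with `max(pct_ad, pct_hc) <
#'   min_pct` are excluded before testing (default 0.1).
#' @param min_cells minimum cells per condition in the stratum (default 3).
#' @param pseudocount for the logFC (default 1).
#' @param logfc_base base of the reported log fold change; default the
#'   natural log (`exp(1)`), under which the conventional 0.25 effect-size
#'   threshold is defined.
#' @param size_factors optional externally supplied per-cell size factors
#'   (one per matrix column, e.g. the true exposures of a simulation); by
#'   default they are estimated as median-normalized total counts.
#' @return `data.frame` with columns `gene`, `logfc`, `pct_ad`, `pct_hc`,
#'   `p`, `adj_p`, `n_ad`, `n_hc`, `cell_type`, `sex`.
#' @export
run_de <- function(counts, meta, cell_type, sex, min_pct = 0.1,
                   min_cells = 3L, pseudocount = 1, logfc_base = exp(1),
                   size_factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!identical(counts$cells, meta$cell_id))
    stop_sexdim("metadata rows must align with matrix cells")
  in_stratum <- meta$cell_type == cell_type & meta$sex == sex
  is_ad <- in_stratum & meta$condition == "AD"
  is_hc <- in_stratum & meta$condition == "HC"
  if (sum(is_ad) < min_cells || sum(is_hc) < min_cells)
    stop_sexdim(sprintf(
      "stratum (%s, %s) has too few cells: %d AD, %d HC (min %d per condition)",
      cell_type, sex, sum(is_ad), sum(is_hc), min_cells))
  sf <- if (is.null(size_factors)) sexdim::size_factors(counts)
        else {
          if (length(size_factors) != length(counts$cells) ||
              any(size_factors <= 0))
            stop_sexdim("size_factors must be positive, one per cell")
          size_factors
        }
  keep <- which(in_stratum)
  m <- as.matrix(counts$counts[, keep, drop = FALSE])
  case <- meta$condition[keep] == "AD"
  sfk <- sf[keep]
  pct_ad <- rowMeans(m[, case, drop = FALSE] > 0)
  pct_hc <- rowMeans(m[, !case, drop = FALSE] > 0)
  tested <- pmax(pct_ad, pct_hc) >= min_pct
  m <- m[tested, , drop = FALSE]
  lrt <- poisson_lrt_vec(m, case, log(sfk))
  norm <- sweep(m, 2, sfk, "/")
  lfc <- log((rowMeans(norm[, case, drop = FALSE]) + pseudocount) /
             (rowMeans(norm[, !case, drop = FALSE]) + pseudocount)) /
         log(logfc_base)
  res <- data.frame(gene = counts$genes[tested], logfc = lfc,
                    pct_ad = pct_ad[tested], pct_hc = pct_hc[tested],
                    p = lrt$p, adj_p = bh_adjust(lrt$p),
                    n_ad = sum(case), n_hc = sum(!case),
                    cell_type = cell_type, sex = sex,
                    stringsAsFactors = FALSE)
  res <- res[order_by(res$adj_p, -abs(res$logfc), res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
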