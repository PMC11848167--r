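# Classification of features into sex-dependent change categories from
# paired per-sex differential results (genes or proteins).

.categories <- c("sex_neutral", "male_specific", "female_specific",
                 "sex_dimorphic", "ambiguous", "not_significant")

#' Classify one feature's sex-dependent change pattern
#'
#' A sex is "significant" when its adjusted p is below `fdr` and its
#' |logFC| exceeds `min_lfc`. Rules, in order: both significant with the
#' same sign -> sex_neutral; both significant with opposite signs ->
#' sex_dimorphic; exactly one significant and the other sex's nominal p
#' above `nonsig_p` -> that sex's specific category; exactly one
#' significant but the other sex's nominal p at or below `nonsig_p` ->
#' ambiguous (too close to the significance threshold to call specific);
#' neither significant -> not_significant. A feature with no test in one
#' sex is classified ambiguous and flagged: absence of a test is not
#' evidence of non-significance.
#'
#' @param male,female lists (or one-row data.frames) with elements `logfc`,
#'   `p`, `adj_p`; pass NULL if the feature was not tested in that sex.
#' @param fdr adjusted-p significance threshold (default 0.05).
#' @param min_lfc absolute logFC floor for the significant sex (default
#'   0.25; use 0 for proteins).
#' @param nonsig_p nominal-p non-significance threshold in the other sex
#'   (default 0.1).
#' @return Character scalar: one of `sex_neutral`, `male_specific`,
#'   `female_specific`, `sex_dimorphic`, `ambiguous`, `not_significant`.
#' @export
classify_feature <- function(male, female, fdr = 0.05, min_lfc = 0.25,
                             nonsig_p = 0.1) {
  missing_m <- is.null(male) || anyNA(c(male$p, male$adj_p, male$logfc))
  missing_f <- is.null(female) || anyNA(c(female$p, female$adj_p, female$logfc))
  if (missing_m || missing_f) return("ambiguous")
  assert_prob(c(male$p, male$adj_p, female$p, female$adj_p), "p")
  sig_m <- male$adj_p < fdr && abs(male$logfc) > min_lfc
  sig_f <- female$adj_p < fdr && abs(female$logfc) > min_lfc
  if (sig_m && sig_f) {
    if (sign(male$logfc) == sign(female$logfc)) "sex_neutral" else "sex_dimorphic"
  } else if (sig_m) {
    if (female$p > nonsig_p) "male_specific" else "ambiguous"
  } else if (sig_f) {
    if (male$p > nonsig_p) "female_specific" else "ambiguous"
  } else "not_significant"
}

#' Classify all features from paired per-sex result tables
#'
#' Takes the male and female result tables for the same comparison (e.g.,
#' one cell type's AD-vs-control run per sex) and assigns each feature of
#' the union a sex-pattern category. Features present in only one table are
#' flagged `tested_one_sex` and classified ambiguous.
#'
#' @param male_res,female_res result `data.frame`s with columns `gene` (or
#'   `feature`), `logfc`, `p`, `adj_p`.
#' @param fdr,min_lfc,nonsig_p thresholds; see [classify_feature()].
#' @return A `data.frame` with one row per feature: `feature`, `category`,
#'   per-sex `logfc_*`, `p_*`, `adj_p_*`, and `tested_one_sex`.
#' @export
classify_all <- function(male_res, female_res, fdr = 0.05, min_lfc = 0.25,
                         nonsig_p = 0.1) {
  key <- function(df) if ("gene" %in% names(df)) df$gene else df$feature
  km <- key(male_res); kf <- key(female_res)
  if (anyDuplicated(km) || anyDuplicated(kf))
    stop_sexdim("features must be unique within each input table")
  feats <- sort(union(km, kf))
  im <- match(feats, km); fi <- match(feats, kf)
  out <- data.frame(
    feature = feats,
    logfc_male = male_res$logfc[im], p_male = male_res$p[im],
    adj_p_male = male_res$adj_p[im],
    logfc_female = female_res$logfc[fi], p_female = female_res$p[fi],
    adj_p_female = female_res$adj_p[fi],
    tested_one_sex = is.na(im) | is.na(fi),
    stringsAsFactors = FALSE)
  out$category <- vapply(seq_len(nrow(out)), function(i) {
    m <- if (is.na(im[i])) NULL else
      list(logfc = out$logfc_male[i], p = out$p_male[i],
           adj_p = out$adj_p_male[i])
    f <- if (is.na(fi[i])) NULL else
      list(logfc = out$logfc_female[i], p = out$p_female[i],
           adj_p = out$adj_p_female[i])
    classify_feature(m, f, fdr = fdr, min_lfc = min_lfc, nonsig_p = nonsig_p)
  }, "")
  out[, c("feature", "category", "logfc_male", "p_male", "adj_p_male",
          "logfc_female", "p_female", "adj_p_female", "tested_one_sex")]
}

#' Summarize a sex-pattern table
#'
#' Per-category counts plus the top-k features per category ranked by the
#' maximum |logFC| across sexes, ties broken by the smaller of the two
#' adjusted p-values, then by feature symbol.
#'
#' @param table output of [classify_all()].
#' @param k top features to report per category (default 10).
#' @return List with `counts` (named integer vector over all categories)
#'   and `top` (data.frame of the ranked head of each category).
#' @export
summarize_patterns <- function(table, k = 10L) {
  counts <- setNames(integer(length(.categories)), .categories)
  tab <- base::table(factor(table$category, levels = .categories))
  counts[names(tab)] <- as.integer(tab)
  score <- pmax(abs(table$logfc_male), abs(table$logfc_female), na.rm = TRUE)
  score[is.infinite(score)] <- NA
  best_p <- pmin(table$adj_p_male, table$adj_p_female, na.rm = TRUE)
  top <- do.call(rbind, lapply(.categories, function(cat) {
    rows <- which(table$category == cat)
    if (!length(rows)) return(NULL)
    rows <- rows[order_by(-score[rows], best_p[rows], table$feature[rows])]
    rows <- head(rows, k)
    cbind(table[rows, , drop = FALSE],
          max_abs_logfc = score[rows], min_adj_p = best_p[rows])
  }))
  if (!is.null(top)) rownames(top) <- NULL
  list(counts = counts, top = top)
}
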