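# Per-sex AD-vs-control linear modeling of protein abundances with an age
# covariate and empirical-Bayes variance moderation, sex-pattern
# classification of proteins, and transcript-protein intersection.

#' Per-protein linear model fit
#'
#' Least-squares fit of `abundance ~ intercept + condition (+ age)` on the
#' complete-case samples of one protein; the reported effect is the
#' AD-minus-control coefficient. A rank-deficient design (e.g., constant
#' age) drops the age term with a warning.
#'
#' @param abundance_row numeric abundances, one per sample (NA allowed;
#'   complete cases are used).
#' @param condition character/logical per sample; `"AD"`/TRUE is the case
#'   level.
#' @param age optional numeric covariate.
#' @param min_per_group minimum complete samples per condition (default 3).
#' @return List with `effect`, `se`, `df` (residual), `s2` (residual
#'   variance), `t`, `p` (ordinary two-sided), `n`.
#' @export
fit_protein_model <- function(abundance_row, condition, age = NULL,
                              min_per_group = 3L) {
  is_case <- if (is.logical(condition)) condition else condition == "AD"
  ok <- !is.na(abundance_row)
  y <- abundance_row[ok]; case <- is_case[ok]
  a <- if (is.null(age)) NULL else age[ok]
  if (sum(case) < min_per_group || sum(!case) < min_per_group)
    stop_sexdim(sprintf("need >= %d complete samples per condition (have %d AD, %d control)",
                        min_per_group, sum(case), sum(!case)))
  X <- cbind(intercept = 1, condition = as.numeric(case))
  if (!is.null(a)) X <- cbind(X, age = a)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient design; dropping the age covariate", call. = FALSE)
    X <- X[, 1:2, drop = FALSE]
    qr_x <- qr(X)
  }
  fit <- lm.fit(X, y)
  df <- length(y) - qr_x$rank
  s2 <- sum(fit$residuals^2) / df
  # snap numerically-zero residual variance and effect to exact zero so a
  # perfect fit reports t = 0, p = 1 instead of rounding-noise ratios
  scale2 <- mean(y^2) + 1
  if (s2 < 1e-20 * scale2) s2 <- 0
  effect <- unname(fit$coefficients["condition"])
  if (abs(effect) < 1e-10 * sqrt(scale2)) effect <- 0
  xtxi <- chol2inv(qr.R(qr_x))
  v_cond <- xtxi[2, 2]
  se <- sqrt(s2 * v_cond)
  tstat <- if (se == 0) {
    if (effect == 0) 0 else sign(effect) * Inf
  } else effect / se
  list(effect = effect, se = se, df = df, s2 = s2, t = tstat,
       p = 2 * pt(-abs(tstat), df), n = length(y), v_cond = v_cond)
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits a scaled inverse-chi-squared prior (prior df `d0`, prior scale
#' `s0^2`) to the observed residual variances by the closed-form
#' method of moments on `log s^2`, then shrinks each variance to its
#' posterior `(d0 s0^2 + df s^2) / (d0 + df)`. Moderated t-statistics use
#' the posterior variance with `df + d0` degrees of freedom. When all
#' variances are equal the prior df is infinite (complete pooling),
#' flagged in the result.
#'
#' @param s2 residual variances (>= 2 positive values).
#' @param df residual degrees of freedom (scalar or per-protein vector).
#' @param d0 optional prior df override: 0 disables moderation, `Inf`
#'   pools completely; `NULL` (default) estimates it from the data.
#' @return List with `posterior_s2`, `d0`, `s0_2`, `pooled` flag.
#' @export
moderate_variances <- function(s2, df, d0 = NULL) {
  if (sum(s2 > 0, na.rm = TRUE) < 2)
    stop_sexdim("need at least 2 positive variances to moderate")
  df <- rep_len(df, length(s2))
  if (is.null(d0)) {
    fd <- limma::fitFDist(s2, df1 = df)
    d0 <- fd$df2
    s0_2 <- fd$scale
  } else if (d0 == 0) {
    s0_2 <- NA_real_
    return(list(posterior_s2 = s2, d0 = 0, s0_2 = s0_2, pooled = FALSE))
  } else {
    s0_2 <- if (is.finite(d0)) limma::fitFDist(s2, df1 = df)$scale
            else mean(s2)
  }
  post <- if (is.infinite(d0)) rep(s0_2, length(s2))
          else (d0 * s0_2 + df * s2) / (d0 + df)
  list(posterior_s2 = post, d0 = d0, s0_2 = s0_2,
       pooled = is.infinite(d0))
}

#' Per-sex differential protein abundance with moderated t-statistics
#'
#' For the samples of one sex, fits each protein's abundance on condition
#' and age, moderates the residual variances across proteins, and tests
#' the AD-minus-control effect with moderated t on `df + d0` degrees of
#' freedom; Benjamini-Hochberg across all tested proteins.
#'
#' @param abundance proteins x samples numeric matrix (rownames = protein
#'   ids, colnames = sample ids).
#' @param samples sample metadata (`sample_id`, `condition`, `sex`,
#'   `age`).
#' @param sex `"M"` or `"F"`.
#' @param use_age include the age covariate (default TRUE).
#' @param d0 prior df override passed to [moderate_variances()].
#' @param min_per_group minimum complete samples per condition.
#' @return `data.frame` with `protein`, `effect`, `t`, `p`, `adj_p`,
#'   `df_total`, `s2`, `posterior_s2`, `n`, `sex`, sorted by `adj_p`,
#'   |effect|, protein.
#' @export
run_dep <- function(abundance, samples, sex, use_age = TRUE, d0 = NULL,
                    min_per_group = 3L) {
  if (!identical(colnames(abundance), samples$sample_id))
    stop_sexdim("abundance columns must align with sample metadata")
  sel <- samples$sex == sex
  ab <- abundance[, sel, drop = FALSE]
  cond <- samples$condition[sel]
  age <- if (use_age) samples$age[sel] else NULL
  fits <- lapply(seq_len(nrow(ab)), function(i)
    fit_protein_model(ab[i, ], cond, age, min_per_group = min_per_group))
  s2 <- vapply(fits, `[[`, 0, "s2")
  dfs <- vapply(fits, `[[`, 0, "df")
  mod <- moderate_variances(s2, dfs, d0 = d0)
  eff <- vapply(fits, `[[`, 0, "effect")
  vc <- vapply(fits, `[[`, 0, "v_cond")
  mod_se <- sqrt(mod$posterior_s2 * vc)
  tmod <- ifelse(mod_se == 0, 0, eff / mod_se)
  # total df capped at the pooled residual df (the moderation convention:
  # shrinkage cannot manufacture more information than the data carry)
  df_total <- pmin(dfs + mod$d0, sum(dfs))
  p <- 2 * pt(-abs(tmod), df_total)
  out <- data.frame(protein = rownames(abundance), effect = eff, t = tmod,
                    p = p, adj_p = bh_adjust(p), df_total = df_total,
                    s2 = s2, posterior_s2 = mod$posterior_s2,
                    n = vapply(fits, `[[`, 0, "n"), sex = sex,
                    stringsAsFactors = FALSE)
  out <- out[order_by(out$adj_p, -abs(out$effect), out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sex-pattern classification of proteins
#'
#' Applies the transcriptomic sex-pattern rules ([classify_all()]) to the
#' per-sex protein results, with the effect sign playing the log fold
#' change role and no effect-size floor by default (protein abundance is
#' on a different scale).
#'
#' @param male_dep,female_dep [run_dep()] outputs.
#' @param fdr,nonsig_p thresholds; see [classify_feature()].
#' @param min_effect absolute effect floor (default 0).
#' @return Sex-pattern `data.frame` (see [classify_all()]).
#' @export
classify_proteins <- function(male_dep, female_dep, fdr = 0.05,
                              nonsig_p = 0.1, min_effect = 0) {
  as_de <- function(df) data.frame(feature = df$protein, logfc = df$effect,
                                   p = df$p, adj_p = df$adj_p,
                                   stringsAsFactors = FALSE)
  classify_all(as_de(male_dep), as_de(female_dep), fdr = fdr,
               min_lfc = min_effect, nonsig_p = nonsig_p)
}

#' Intersect transcript- and protein-level sex patterns
#'
#' For each matched category (male_specific, female_specific,
#' sex_dimorphic), lists and counts the features assigned that category at
#' both the transcript and the protein level. Identifiers are assumed to
#' share a namespace; an optional two-column map (`gene`, `protein`)
#' translates first, and unmapped identifiers are reported, not silently
#' dropped.
#'
#' @param deg_patterns transcript sex-pattern table ([classify_all()]).
#' @param dep_patterns protein sex-pattern table ([classify_proteins()]).
#' @param map optional `data.frame` with columns `gene`, `protein`.
#' @return List with `overlaps` (data.frame `category`, `n`, `members`)
#'   and `unmapped` (gene symbols without a protein mapping).
#' @export
intersect_omics <- function(deg_patterns, dep_patterns, map = NULL) {
  genes <- deg_patterns$feature
  if (!is.null(map)) {
    prot <- map$protein[match(genes, map$gene)]
    unmapped <- genes[is.na(prot)]
    genes <- ifelse(is.na(prot), genes, prot)
  } else unmapped <- character()
  cats <- c("male_specific", "female_specific", "sex_dimorphic")
  rows <- lapply(cats, function(cat) {
    a <- genes[deg_patterns$category == cat]
    b <- dep_patterns$feature[dep_patterns$category == cat]
    ov <- sort(intersect(a, b))
    data.frame(category = cat, n = length(ov),
               members = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  list(overlaps = do.call(rbind, rows), unmapped = unmapped)
}
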