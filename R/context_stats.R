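# Context-enrichment statistics: Wilcoxon group-median shifts, High/Low
# chi-square goodness-of-fit enrichment, chi-square independence residuals,
# and Spearman correlation analyses.

#' Median readthrough shift per feature level
#'
#' For each level of a categorical feature, reports the group median log2 RE
#' minus the overall sample median, with a two-sample Wilcoxon rank-sum test
#' of the level's genes against all remaining genes (default), or a
#' one-sample signed-rank test against the sample median
#' (`variant = "signed_rank"`). Levels with fewer than `min_n` genes are
#' flagged; empty levels are skipped.
#'
#' @param data Tibble with a finite readthrough column and the feature.
#' @param feature Name of the categorical feature column.
#' @param re_col Name of the readthrough column (default `"log2_re"`).
#' @param variant `"rank_sum"` (default) or `"signed_rank"`.
#' @param min_n Minimum group size before flagging (default 5).
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble of class `rt_shifts`: `feature`, `level`, `n_genes`,
#'   `delta_median`, `p_value`, `significant`, `flagged_small`.
#' @export
group_median_shifts <- function(data, feature, re_col = "log2_re",
                                variant = c("rank_sum", "signed_rank"),
                                min_n = 5L, alpha = 0.05) {
  variant <- match.arg(variant)
  vals <- data[[re_col]]
  keep <- is.finite(vals) & !is.na(data[[feature]])
  vals <- vals[keep]
  lev <- as.character(data[[feature]][keep])
  overall <- median(vals)
  out <- purrr::map(sort(unique(lev)), function(l) {
    x <- vals[lev == l]
    y <- vals[lev != l]
    p <- if (variant == "rank_sum") {
      if (length(y) == 0) 1 else
        suppressWarnings(wilcox.test(x, y)$p.value)
    } else {
      if (all(x == overall)) 1 else
        suppressWarnings(wilcox.test(x - overall)$p.value)
    }
    tibble(feature = feature, level = l, n_genes = length(x),
           delta_median = median(x) - overall, p_value = p,
           significant = p < alpha, flagged_small = length(x) < min_n)
  })
  out <- bind_rows(out)
  class(out) <- c("rt_shifts", class(out))
  out
}

#' High/Low enrichment of feature levels against the reference
#'
#' For each group (`High`, `Low`) and each feature, compares the group's
#' level counts to expected counts derived from the reference gene set's
#' level frequencies with a chi-square goodness-of-fit test; p-values are
#' Bonferroni-adjusted over `bonferroni_family` tests (default: the number of
#' feature positions tested, per group). Per level, the log2 ratio of group
#' fraction to reference fraction is reported; levels absent from a group are
#' flagged `zero_observation` (no log2 value).
#'
#' @param data Tibble containing the feature columns for the reference gene
#'   set, with a `group` column assigning `High`/`Low` (other rows form part
#'   of the reference only).
#' @param features Character vector of categorical feature columns to test.
#' @param bonferroni_family Size of the Bonferroni family (default
#'   `length(features)`).
#' @param min_expected Levels of the reference with expected count below this
#'   in a group are dropped from that group's test (logged; default 0 keeps
#'   all levels with nonzero reference frequency).
#' @return Tibble of class `rt_enrichment`: `feature`, `group`, `level`,
#'   `n_group`, `group_fraction`, `ref_fraction`, `log2_ratio`,
#'   `zero_observation`, `p_value` (adjusted, per feature x group).
#' @export
high_low_enrichment <- function(data, features,
                                bonferroni_family = length(features),
                                min_expected = 0) {
  out <- list()
  for (f in features) {
    ref <- data[[f]][!is.na(data[[f]])]
    ref_tab <- table(ref)
    ref_frac <- ref_tab / sum(ref_tab)
    for (g in c("High", "Low")) {
      gv <- data[[f]][data$group %in% g & !is.na(data[[f]])]
      if (length(gv) == 0) next
      obs <- table(factor(gv, levels = names(ref_tab)))
      expected <- ref_frac * length(gv)
      keep_lv <- expected >= min_expected & ref_tab > 0
      if (any(!keep_lv)) {
        inform(paste0("dropping level(s) with tiny expected counts for ",
                      f, "/", g, ": ",
                      paste(names(ref_tab)[!keep_lv], collapse = ", ")))
      }
      p_raw <- suppressWarnings(
        chisq.test(x = as.vector(obs[keep_lv]),
                   p = as.vector(ref_frac[keep_lv]) /
                     sum(ref_frac[keep_lv]))$p.value
      )
      p_adj <- min(1, p_raw * bonferroni_family)
      grp_frac <- as.vector(obs) / length(gv)
      out[[length(out) + 1L]] <- tibble(
        feature = f, group = g, level = names(ref_tab),
        n_group = as.vector(obs),
        group_fraction = grp_frac,
        ref_fraction = as.vector(ref_frac),
        log2_ratio = ifelse(as.vector(obs) == 0, NA_real_,
                            log2(grp_frac / as.vector(ref_frac))),
        zero_observation = as.vector(obs) == 0,
        p_value = p_adj
      )
    }
  }
  out <- bind_rows(out)
  class(out) <- c("rt_enrichment", class(out))
  out
}

#' Chi-square independence residuals between two categorical features
#'
#' Tests independence of two features on their contingency table and reports
#' per-cell Pearson residuals `(O - E) / sqrt(E)`: positive residuals mark
#' attraction between levels, negative residuals repulsion. Warns when any
#' expected count is below 5 (small-sample caution).
#'
#' @param data Tibble containing both feature columns.
#' @param feat_a,feat_b Names of the two categorical feature columns.
#' @return List of class `rt_association`: `table` (observed), `expected`,
#'   `residuals`, `p_value`, `statistic`, `tidy` (long tibble of cells).
#' @export
association_residuals <- function(data, feat_a, feat_b) {
  keep <- !is.na(data[[feat_a]]) & !is.na(data[[feat_b]])
  tab <- table(data[[feat_a]][keep], data[[feat_b]][keep])
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("degenerate contingency table: need at least 2 x 2 levels")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    warn("some expected counts are below 5; interpret residuals with caution")
  }
  tidy_cells <- as_tibble(as.table(ct$residuals), .name_repair = "minimal")
  names(tidy_cells) <- c("level_a", "level_b", "residual")
  tidy_cells$observed <- as.vector(tab)
  tidy_cells$expected <- as.vector(ct$expected)
  structure(list(table = tab, expected = ct$expected,
                 residuals = ct$residuals,
                 p_value = ct$p.value, statistic = unname(ct$statistic),
                 tidy = tidy_cells),
            class = "rt_association")
}

#' @export
print.rt_association <- function(x, ...) {
  cat("Chi-square test of independence: X-squared =",
      format(x$statistic, digits = 4), ", p =",
      format(x$p_value, digits = 4), "\nPearson residuals:\n")
  print(round(x$residuals, 3))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with a two-sided p-value.
#'
#' @param x,y Paired numeric vectors (pairs with `NA` are dropped;
#'   at least 4 complete pairs required).
#' @return Tibble `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4) abort("need at least 4 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("constant vector: Spearman correlation undefined")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Pairwise Spearman correlation matrix
#'
#' Symmetric matrix of pairwise-complete Spearman correlations between
#' per-gene variables (e.g. log2 RE, expression, translation efficiency,
#' lengths, tAI).
#'
#' @param data Tibble of aligned per-gene variables.
#' @param vars Character vector of numeric columns (default: all numeric).
#' @return Numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[purrr::map_lgl(data, is.numeric)]
  }
  m <- as.matrix(data[, vars, drop = FALSE])
  m[!is.finite(m)] <- NA
  out <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  diag(out) <- 1
  out
}

#' Translation efficiency
#'
#' Ribosome density divided by gene expression level.
#'
#' @param ribo_density Per-gene ribosome density (e.g. CDS RPKM of
#'   footprints).
#' @param expression Per-gene expression level (e.g. RNA-seq RPKM/TPM).
#' @return Numeric vector; `NA` where expression is zero or missing.
#' @export
translation_efficiency <- function(ribo_density, expression) {
  ifelse(is.na(expression) | expression <= 0, NA_real_,
         ribo_density / expression)
}
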