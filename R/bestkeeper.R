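#' BestKeeper descriptive stability analysis
#'
#' BestKeeper works directly on raw crossing-point (CP/Ct) values, never on
#' relative quantities. Per gene it reports descriptive statistics, flags
#' genes with SD > `sd_threshold` cycles as too variable to serve as
#' references, computes all pairwise Pearson correlations between genes,
#' builds the BestKeeper index (per-sample geometric mean CP over the
#' retained genes) and correlates every gene against that index.
#'
#' The dispersion measure is the mean absolute deviation of CP about the
#' per-gene geometric mean (`sd_cp`), not the root-mean-square SD; the
#' fold-change translations use `xfold_base^deviation` with the sign
#' indicating regulation below (-) or above (+) the geometric mean.
#'
#' @param x A [ct_matrix()] or numeric genes x samples matrix of raw Ct;
#'   at least 2 samples (3 for correlation p-values).
#' @param sd_threshold Exclusion cutoff on `sd_cp`, in cycles (default 1).
#' @param xfold_base Base for fold-change translation (default 2; a
#'   per-gene amplification factor may be supplied as a named vector).
#' @param index_genes `"retained"` (default) builds the index over genes
#'   surviving the SD filter; `"all"` forces all genes in.
#'
#' @return An object of class `bestkeeper`:
#' \describe{
#'   \item{stats}{data.frame per gene: `n`, `geo_mean`, `ar_mean`,
#'     `min_cp`, `max_cp`, `sd_cp`, `cv_pct` (= 100 sd_cp / ar_mean),
#'     `min_xfold` (negative), `max_xfold`, `sd_xfold` (= base^sd_cp).}
#'   \item{retained, excluded}{gene identifiers by the SD filter.}
#'   \item{pair_r, pair_p}{symmetric matrices of pairwise Pearson r and
#'     two-sided p-values over all genes (diagonal NA); a zero-variance
#'     gene yields NA with a warning.}
#'   \item{index}{per-sample BestKeeper index.}
#'   \item{index_r, index_p}{per-gene correlation with the index.}
#'   \item{ranking}{genes ascending by `sd_cp`.}
#' }
#' @details p-values come from the t statistic
#'   `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom,
#'   two-sided, uncorrected (see [pearson_p()]).
#' @examples
#' bk <- bestkeeper(subset_group(ladakh_pbmc(), "LAC"))
#' round(bk$stats["GAPDH", "sd_cp"], 3)
#' @export
bestkeeper <- function(x, sd_threshold = 1, xfold_base = 2,
                       index_genes = c("retained", "all")) {
  x <- as_ct_input(x)
  index_genes <- match.arg(index_genes)
  m <- as.matrix(x)
  if (any(m <= 0)) stopf("BestKeeper requires positive CP values")
  if (ncol(m) < 2L) stopf("BestKeeper requires at least 2 samples")
  genes <- rownames(m)
  n <- ncol(m)
  base <- expand_xfold_base(xfold_base, genes)

  geo <- apply(m, 1, geo_mean)
  ar <- rowMeans(m)
  sd_cp <- rowMeans(abs(m - geo))
  stats_df <- data.frame(
    n = n,
    geo_mean = geo,
    ar_mean = ar,
    min_cp = apply(m, 1, min),
    max_cp = apply(m, 1, max),
    sd_cp = sd_cp,
    cv_pct = 100 * sd_cp / ar,
    row.names = genes)
  stats_df$min_xfold <- -base^(geo - stats_df$min_cp)
  stats_df$max_xfold <- base^(stats_df$max_cp - geo)
  stats_df$sd_xfold <- base^sd_cp

  retained <- genes[sd_cp <= sd_threshold]
  excluded <- setdiff(genes, retained)
  if (!length(retained))
    stopf("all genes exceed the SD threshold of %g cycles", sd_threshold)

  zero_var <- genes[apply(m, 1, function(v) sd1(v) == 0)]
  if (length(zero_var))
    warning("zero-variance gene(s), correlations undefined: ",
            paste(zero_var, collapse = ", "), call. = FALSE)
  pair_r <- suppressWarnings(stats::cor(t(m)))
  diag(pair_r) <- NA_real_
  pair_p <- pearson_p(pair_r, n)

  idx_set <- if (index_genes == "all") genes else retained
  index <- apply(m[idx_set, , drop = FALSE], 2, geo_mean)
  index_r <- suppressWarnings(
    vapply(genes, function(g) stats::cor(m[g, ], index), numeric(1)))
  index_p <- pearson_p(index_r, n)

  structure(list(stats = stats_df, retained = retained, excluded = excluded,
                 sd_threshold = sd_threshold,
                 pair_r = pair_r, pair_p = pair_p,
                 index = index, index_genes = idx_set,
                 index_r = index_r, index_p = index_p,
                 ranking = genes[order(sd_cp)]),
            class = "bestkeeper")
}

expand_xfold_base <- function(base, genes) {
  if (length(base) == 1L && is.null(names(base)))
    return(stats::setNames(rep(base, length(genes)), genes))
  expand_efficiency(base, genes)
}

#' Two-sided p-value of a Pearson correlation
#'
#' Closed form used by BestKeeper-style reporting: the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' n - 2 degrees of freedom, two-sided. Identical to the p-value of
#' [stats::cor.test()]. `|r| = 1` yields p = 0.
#'
#' @param r Pearson correlation(s), vector or matrix in \[-1, 1\].
#' @param n Sample size (>= 3).
#' @return p-value(s), same shape as `r`.
#' @examples
#' pearson_p(0.9, 5)  # ~0.0374
#' @export
pearson_p <- function(r, n) {
  if (n < 3L) stopf("p-values need at least 3 samples")
  p <- r
  one <- abs(r) >= 1 - 1e-15
  t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[] <- 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  p[one & !is.na(one)] <- 0
  p
}

#' @export
print.bestkeeper <- function(x, digits = 3, ...) {
  cat(sprintf("BestKeeper analysis: %d genes, %d samples\n",
              nrow(x$stats), x$stats$n[1]))
  df <- data.frame(rank = seq_along(x$ranking), gene = x$ranking,
                   sd_cp = round(x$stats[x$ranking, "sd_cp"], digits),
                   cv_pct = round(x$stats[x$ranking, "cv_pct"], digits),
                   index_r = round(x$index_r[x$ranking], digits),
                   retained = x$ranking %in% x$retained)
  print(df, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded (SD >", x$sd_threshold, "):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
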