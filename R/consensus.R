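#' Per-method integer ranks for the consensus
#'
#' Extracts one rank vector per algorithm: geNorm genes are ranked by their
#' position in the stepwise-exclusion order (the tied final pair share the
#' top rank), NormFinder by stability value, BestKeeper by `sd_cp` and the
#' delta-Ct method by mean SD, all ascending. Ties share the minimum
#' (competition) rank under the default policy, or the average rank.
#'
#' @param genorm A `genorm` fit.
#' @param normfinder A `normfinder` fit.
#' @param bestkeeper A `bestkeeper` fit.
#' @param deltact A `delta_ct` fit.
#' @param ties `"min"` (default) or `"average"`.
#' @return Numeric matrix genes x methods (`genorm`, `normfinder`,
#'   `bestkeeper`, `deltact`), genes in the geNorm input order.
#' @export
rank_methods <- function(genorm, normfinder, bestkeeper, deltact,
                         ties = c("min", "average")) {
  ties <- match.arg(ties)
  stopifnot(inherits(genorm, "genorm"), inherits(normfinder, "normfinder"),
            inherits(bestkeeper, "bestkeeper"), inherits(deltact, "delta_ct"))
  genes <- genorm$genes
  others <- list(normfinder = names(normfinder$stability),
                 bestkeeper = rownames(bestkeeper$stats),
                 deltact = names(deltact$mean_sd))
  for (meth in names(others))
    if (!setequal(genes, others[[meth]]))
      stopf("gene sets differ between geNorm and %s results", meth)

  # geNorm: exclusion-order positions, final pair tied at the top
  pos <- match(genes, genorm$ranking)
  pos[pos == 2L] <- 1L
  gn_rank <- rank(pos, ties.method = ties)

  cbind(genorm = gn_rank,
        normfinder = rank(normfinder$stability[genes], ties.method = ties),
        bestkeeper = rank(bestkeeper$stats[genes, "sd_cp"], ties.method = ties),
        deltact = rank(deltact$mean_sd[genes], ties.method = ties))
}

#' Geometric mean of per-method ranks
#'
#' @param ranks Numeric matrix genes x methods as from [rank_methods()].
#' @return Named numeric vector: per gene, the geometric mean of its ranks
#'   across methods (bounded by their min and max).
#' @examples
#' geomean_rank(rbind(gA = c(1, 1, 4, 1), gB = c(10, 10, 10, 10)))
#' @export
geomean_rank <- function(ranks) {
  stopifnot(is.matrix(ranks), all(ranks >= 1))
  apply(ranks, 1, geo_mean)
}

#' RefFinder-style consensus ranking
#'
#' Aggregates the four stability algorithms into one comprehensive score
#' per gene: the geometric mean of the gene's ranks under geNorm,
#' NormFinder, BestKeeper and the delta-Ct method. Lower is better; the
#' score is bounded between 1 and the number of genes.
#'
#' @inheritParams rank_methods
#' @return An object of class `consensus`: list with `method_ranks`
#'   (genes x 4 matrix), `score` (named, full precision; round to 2
#'   decimals for reporting), and `ranking` (genes ascending by score,
#'   ties by input order).
#' @examples
#' lac <- subset_group(ladakh_pbmc(), "LAC")
#' cons <- consensus_ranking(genorm(lac), normfinder(lac),
#'                           bestkeeper(lac), delta_ct(lac))
#' round(cons$score[cons$ranking[1]], 2)
#' @export
consensus_ranking <- function(genorm, normfinder, bestkeeper, deltact,
                              ties = c("min", "average")) {
  ranks <- rank_methods(genorm, normfinder, bestkeeper, deltact, ties)
  score <- geomean_rank(ranks)
  structure(list(method_ranks = ranks, score = score,
                 ranking = rownames(ranks)[order(score)]),
            class = "consensus")
}

#' @export
print.consensus <- function(x, digits = 2, ...) {
  cat("RefFinder-style consensus (geometric mean of method ranks)\n")
  df <- data.frame(final_rank = seq_along(x$ranking), gene = x$ranking,
                   x$method_ranks[x$ranking, , drop = FALSE],
                   score = round(x$score[x$ranking], digits))
  print(df, row.names = FALSE)
  invisible(x)
}
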