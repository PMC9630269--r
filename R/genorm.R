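#' Pairwise variation between two genes
#'
#' The building block of the geNorm M value: the sample standard deviation
#' (denominator n - 1) across samples of `log2(q_j / q_k)`. Two genes that
#' respond identically to every sample have a constant log ratio and a
#' pairwise SD of 0 no matter their absolute expression levels.
#'
#' @param qm A `quantity_matrix` from [relative_quantity()] (or a Ct input,
#'   transformed with E = 2).
#' @param gene_j,gene_k Two distinct gene identifiers.
#' @return The pairwise SD, in log2 units (cycles when E = 2).
#' @export
pairwise_sd <- function(qm, gene_j, gene_k) {
  qm <- as_quantity(qm)
  if (identical(gene_j, gene_k)) stopf("gene_j and gene_k must differ")
  lq <- qm$log2q
  if (!all(c(gene_j, gene_k) %in% rownames(lq)))
    stopf("unknown gene(s): %s",
          paste(setdiff(c(gene_j, gene_k), rownames(lq)), collapse = ", "))
  if (ncol(lq) < 2L) stopf("pairwise SD needs at least 2 samples")
  sd1(lq[gene_j, ] - lq[gene_k, ])
}

#' geNorm M values on a gene subset
#'
#' The expression-stability measure M of gene j is the arithmetic mean of
#' its pairwise variations [pairwise_sd()] with every other gene in the
#' subset; lower M means more stable.
#'
#' @inheritParams pairwise_sd
#' @param genes Genes to evaluate (default: all); at least 2.
#' @return Named numeric vector of M values in `genes` order.
#' @export
m_values <- function(qm, genes = NULL) {
  qm <- as_quantity(qm)
  lq <- qm$log2q
  if (is.null(genes)) genes <- rownames(lq)
  if (length(genes) < 2L) stopf("M values need at least 2 genes")
  lq <- lq[genes, , drop = FALSE]
  vapply(genes, function(j)
    mean(vapply(setdiff(genes, j),
                function(k) sd1(lq[j, ] - lq[k, ]), numeric(1))),
    numeric(1))
}

#' geNorm stability analysis
#'
#' Full geNorm procedure on one panel: compute M values, repeatedly exclude
#' the least stable gene (largest M) until two remain, and derive the
#' pairwise-variation series V(n/n+1) that indicates how many reference
#' genes to combine into a normalization factor.
#'
#' @param x A [ct_matrix()] / numeric matrix of Ct values, or a
#'   `quantity_matrix` from [relative_quantity()]. At least 3 genes and 2
#'   samples.
#' @param efficiency Amplification factor(s) for the Ct -> quantity
#'   transform (ignored when `x` is already a `quantity_matrix`).
#' @param threshold Pairwise-variation cutoff below which adding a further
#'   reference gene is considered unnecessary (the conventional 0.15).
#'
#' @return An object of class `genorm` with elements:
#' \describe{
#'   \item{ranking}{genes from most to least stable; the final surviving
#'     pair occupies positions 1-2 (tied, ordered by input position).}
#'   \item{m_value}{per gene, the average M of the panel still in play at
#'     the step where the gene was excluded — the increasing series that
#'     geNorm charts report; the final pair share their common M.}
#'   \item{m_gene}{per gene, its own M at the exclusion step.}
#'   \item{v}{pairwise variation V(n/n+1) for n = 2 .. g-1, named by n:
#'     the sample SD of `log2(NF_n / NF_{n+1})` where NF_n is the
#'     per-sample geometric mean quantity of the n top-ranked genes.}
#'   \item{n_recommended}{smallest n with V(n/n+1) below `threshold`; g
#'     (flagged via `all_above`) if none.}
#' }
#' @details Ties in the exclusion step (equal largest M) are broken by
#'   excluding the gene later in input order, making the procedure
#'   deterministic.
#' @examples
#' gn <- genorm(subset_group(ladakh_pbmc(), "LAC"))
#' gn$ranking[1:2]          # most stable pair
#' round(gn$m_value[1:2], 3)
#' @export
genorm <- function(x, efficiency = 2, threshold = 0.15) {
  qm <- as_quantity(x, efficiency)
  lq <- qm$log2q
  g <- nrow(lq)
  if (g < 3L) stopf("geNorm requires at least 3 genes")
  if (ncol(lq) < 2L) stopf("geNorm requires at least 2 samples")

  remaining <- rownames(lq)          # kept in input order throughout
  excluded <- character(0)
  m_gene <- m_avg <- numeric(0)
  while (length(remaining) > 2L) {
    M <- m_values(qm, remaining)
    worst <- remaining[max(which(M == max(M)))]   # tie: later input position
    excluded <- c(worst, excluded)
    m_gene <- c(stats::setNames(M[[worst]], worst), m_gene)
    m_avg <- c(stats::setNames(mean(M), worst), m_avg)
    remaining <- setdiff(remaining, worst)
  }
  M2 <- m_values(qm, remaining)      # final pair: equal by construction
  ranking <- c(remaining, names(m_gene))
  m_gene <- c(M2, m_gene)
  m_avg <- c(stats::setNames(rep(mean(M2), 2L), remaining), m_avg)

  # normalization factors over the top-n ranked genes
  v <- vapply(2:(g - 1L), function(n) {
    nf_n <- apply(qm$q[ranking[seq_len(n)], , drop = FALSE], 2, geo_mean)
    nf_n1 <- apply(qm$q[ranking[seq_len(n + 1L)], , drop = FALSE], 2, geo_mean)
    sd1(log2(nf_n / nf_n1))
  }, numeric(1))
  names(v) <- as.character(2:(g - 1L))

  out <- structure(list(ranking = ranking, m_value = m_avg, m_gene = m_gene,
                        v = v, threshold = threshold,
                        genes = rownames(lq), n_samples = ncol(lq)),
                   class = "genorm")
  out$n_recommended <- recommend_n(out, threshold)
  out
}

#' Recommended number of reference genes from a V series
#'
#' The smallest n whose pairwise variation V(n/n+1) falls below the
#' threshold; combining that many top-ranked genes into a geometric-mean
#' normalization factor is considered sufficient. If no V is below the
#' threshold, the total gene count is returned with attribute
#' `all_above = TRUE`.
#'
#' @param v A `genorm` fit or a numeric V series named by n.
#' @param threshold V cutoff (default 0.15).
#' @return Integer n (with attribute `all_above` when no V passes).
#' @export
recommend_n <- function(v, threshold = 0.15) {
  if (inherits(v, "genorm")) v <- v$v
  if (!length(v)) stopf("empty V series")
  n_vals <- as.integer(names(v))
  ok <- which(v < threshold)
  if (length(ok)) return(n_vals[min(ok)])
  structure(max(n_vals) + 1L, all_above = TRUE)
}

#' @export
print.genorm <- function(x, digits = 3, ...) {
  cat(sprintf("geNorm stability analysis: %d genes, %d samples\n",
              length(x$genes), x$n_samples))
  df <- data.frame(rank = c(1L, 1L, 3:length(x$ranking)),
                   gene = x$ranking,
                   M = round(x$m_value[x$ranking], digits))
  print(df, row.names = FALSE)
  cat(sprintf("\nPairwise variation V(n/n+1): %s\n",
              paste(sprintf("V%s/%d=%.*f", names(x$v),
                            as.integer(names(x$v)) + 1L, digits, x$v),
                    collapse = "  ")))
  n <- x$n_recommended
  cat(sprintf("recommended number of reference genes: %d%s\n", n,
              if (isTRUE(attr(n, "all_above")))
                " (no V below threshold)" else ""))
  invisible(x)
}
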