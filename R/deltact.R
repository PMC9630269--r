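#' Comparative delta-Ct stability analysis
#'
#' Ranks genes by the mean standard deviation of their pairwise Ct
#' differences: for gene j, `mean_sd[j]` is the average over all other
#' genes k of the sample SD (n - 1) of `Ct_j - Ct_k`. A gene whose Ct
#' tracks every other gene up to a constant offset scores 0.
#'
#' The method operates on raw Ct, its published definition; with an
#' amplification factor of 2 it is algebraically identical to the
#' full-panel geNorm M value, since `SD(Ct_j - Ct_k) = SD(log2(q_j/q_k))`.
#'
#' @param x A [ct_matrix()] or numeric genes x samples matrix; at least 3
#'   genes and 2 samples.
#' @return An object of class `delta_ct`: list with `mean_sd` (named, in
#'   input gene order, cycles) and `ranking` (genes ascending by
#'   `mean_sd`).
#' @examples
#' dct <- delta_ct(subset_group(ladakh_pbmc(), "LAC"))
#' dct$ranking[1]
#' @export
delta_ct <- function(x) {
  x <- as_ct_input(x)
  m <- as.matrix(x)
  if (nrow(m) < 3L) stopf("the delta-Ct method requires at least 3 genes")
  if (ncol(m) < 2L) stopf("the delta-Ct method requires at least 2 samples")
  genes <- rownames(m)
  mean_sd <- vapply(genes, function(j)
    mean(vapply(setdiff(genes, j),
                function(k) sd1(m[j, ] - m[k, ]), numeric(1))),
    numeric(1))
  structure(list(mean_sd = mean_sd,
                 ranking = genes[order(mean_sd)]),
            class = "delta_ct")
}

#' @export
print.delta_ct <- function(x, digits = 3, ...) {
  cat("comparative delta-Ct stability analysis\n")
  print(data.frame(rank = seq_along(x$ranking), gene = x$ranking,
                   mean_sd = round(x$mean_sd[x$ranking], digits)),
        row.names = FALSE)
  invisible(x)
}
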