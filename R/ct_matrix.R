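#' Construct a Ct matrix
#'
#' A `ct_matrix` is a numeric genes x samples matrix of quantification-cycle
#' (Ct/Cq) values with a group (e.g. species) label attached to every sample.
#' It is the input container for all stability algorithms in this package.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names. All entries must be finite and positive:
#'   the algorithms assume a complete matrix and missing values are a hard
#'   error, never imputed.
#' @param group Sample group labels: either a single label recycled to all
#'   samples, an unnamed vector in column order, or a vector named by sample.
#'   Defaults to `"all"`.
#' @param min_samples,min_genes Minimum panel dimensions accepted without
#'   error. The stability algorithms themselves need at least 3 genes
#'   (NormFinder's variance correction divides by g - 2) and 2 samples;
#'   these guards reject degenerate input early.
#'
#' @return An object of class `ct_matrix`: the numeric matrix with a
#'   `"group"` attribute (character, named by sample).
#' @seealso [read_ct()], [ladakh_pbmc()], [subset_group()]
#' @examples
#' ct <- ct_matrix(matrix(c(20, 21, 22, 25, 26, 27), nrow = 2, byrow = TRUE,
#'                        dimnames = list(c("gA", "gB"), c("s1", "s2", "s3"))))
#' ct_groups(ct)
#' @export
ct_matrix <- function(values, group = NULL, min_samples = 1L, min_genes = 1L) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' needs gene row names and sample column names")
  genes <- rownames(values)
  samples <- colnames(values)
  if (anyDuplicated(genes))
    stopf("duplicated gene identifiers: %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stopf("duplicated sample identifiers: %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stopf("missing Ct value for gene '%s', sample '%s'",
          genes[idx[1]], samples[idx[2]])
  }
  if (any(!is.finite(values)) || any(values <= 0))
    stopf("all Ct values must be finite and > 0")
  if (nrow(values) < min_genes)
    stopf("need at least %d genes, got %d", min_genes, nrow(values))
  if (ncol(values) < min_samples)
    stopf("need at least %d samples, got %d", min_samples, ncol(values))

  if (is.null(group)) group <- "all"
  nm <- names(group)
  group <- as.character(group)
  names(group) <- nm
  if (length(group) == 1L) group <- rep(group, ncol(values))
  if (!is.null(names(group))) {
    missing <- setdiff(samples, names(group))
    if (length(missing))
      stopf("no group label for sample(s): %s", paste(missing, collapse = ", "))
    group <- group[samples]
  } else if (length(group) != ncol(values)) {
    stopf("'group' must have one label per sample (%d), got %d",
          ncol(values), length(group))
  }
  if (anyNA(group)) stopf("every sample needs exactly one group label")
  names(group) <- samples
  structure(values, group = group, class = c("ct_matrix", class(values)))
}

#' Sample group labels of a Ct matrix
#'
#' @param x A [ct_matrix()].
#' @return Character vector of group labels, named by sample.
#' @export
ct_groups <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  attr(x, "group")
}

#' Restrict a Ct matrix to one sample group
#'
#' Returns the panel of samples carrying the given group label, with gene
#' order preserved. This is how a per-species analysis panel is obtained
#' from a multi-species data set.
#'
#' @param x A [ct_matrix()].
#' @param group A single group label present in `ct_groups(x)`.
#' @return A `ct_matrix` containing only that group's samples.
#' @examples
#' lac <- subset_group(ladakh_pbmc(), "LAC")
#' ncol(lac)  # 6 samples
#' @export
subset_group <- function(x, group) {
  g <- ct_groups(x)
  if (length(group) != 1L || !group %in% g)
    stopf("unknown group '%s'; available: %s",
          as.character(group)[1], paste(unique(g), collapse = ", "))
  keep <- names(g)[g == group]
  ct_matrix(unclass(x)[, keep, drop = FALSE], group = g[keep])
}

#' @export
print.ct_matrix <- function(x, ...) {
  g <- ct_groups(x)
  cat(sprintf("ct_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  tab <- table(factor(g, levels = unique(g)))
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("Ct range: %.3f - %.3f\n", min(x), max(x)))
  invisible(x)
}

#' @export
`[.ct_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  ct_matrix(out, group = attr(x, "group")[colnames(out)])
}

#' @export
as.matrix.ct_matrix <- function(x, ...) {
  matrix(unclass(x), nrow(x), ncol(x), dimnames = dimnames(x))
}
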