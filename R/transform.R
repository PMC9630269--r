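#' Relative quantities from Ct values
#'
#' Applies the comparative-Ct transform used as input for geNorm and
#' NormFinder: for each gene g with amplification factor E_g,
#' `q[g, s] = E_g ^ (min_s' Ct[g, s'] - Ct[g, s])`, so that the most
#' expressed sample of every gene has quantity exactly 1 and all other
#' quantities lie in (0, 1]. `log2q` is the base-2 log of `q`; with E = 2
#' it equals `minCt - Ct` exactly.
#'
#' @param x A [ct_matrix()] or numeric genes x samples matrix.
#' @param efficiency Per-cycle amplification factor(s): a single number
#'   applied to all genes (default 2, i.e. perfect doubling) or a vector
#'   named by gene. Must lie in (1, 3].
#' @return An object of class `quantity_matrix`: a list with elements
#'   `q`, `log2q` (both genes x samples), `efficiency` (named per gene),
#'   and `group`.
#' @examples
#' ct <- ct_matrix(matrix(c(20, 21, 22), 1, dimnames = list("g", paste0("s", 1:3))))
#' relative_quantity(ct)$q   # 1, 0.5, 0.25
#' @export
relative_quantity <- function(x, efficiency = 2) {
  x <- as_ct_input(x)
  m <- as.matrix(x)
  eff <- expand_efficiency(efficiency, rownames(m))
  dct <- apply(m, 1, min) - m              # minCt - Ct, genes x samples
  log2q <- dct * log2(eff)                 # recycled per gene (rows)
  structure(list(q = 2^log2q, log2q = log2q,
                 efficiency = eff, group = ct_groups(x)),
            class = "quantity_matrix")
}

expand_efficiency <- function(efficiency, genes) {
  if (length(efficiency) == 1L && is.null(names(efficiency)))
    efficiency <- stats::setNames(rep(efficiency, length(genes)), genes)
  if (!is.null(names(efficiency))) {
    missing <- setdiff(genes, names(efficiency))
    if (length(missing))
      stopf("no amplification factor for gene(s): %s",
            paste(missing, collapse = ", "))
    efficiency <- efficiency[genes]
  } else if (length(efficiency) != length(genes)) {
    stopf("'efficiency' must be a single value or one per gene")
  }
  names(efficiency) <- genes
  check_efficiency(efficiency)
  efficiency
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("quantity_matrix: %d genes x %d samples (per-gene max q = 1)\n",
              nrow(x$q), ncol(x$q)))
  effs <- unique(round(x$efficiency, 4))
  cat("amplification factor:",
      if (length(effs) == 1L) effs else sprintf("per gene (%s)",
                                                paste(effs, collapse = ", ")),
      "\n")
  invisible(x)
}

as_quantity <- function(x, efficiency = 2) {
  if (inherits(x, "quantity_matrix")) x else relative_quantity(x, efficiency)
}

#' Amplification efficiency from a standard-curve slope
#'
#' Converts the slope of a log10(dilution) vs Ct standard curve to the
#' per-cycle amplification factor `10^(-1/slope)`. A slope of -3.3219
#' corresponds to perfect doubling (E = 2, 100% efficiency).
#'
#' @param slope Standard-curve slope; must be negative.
#' @param as_percent If `TRUE`, return the efficiency as a percentage,
#'   `(factor - 1) * 100`, the convention used when reporting primer
#'   performance.
#' @return The amplification factor (or percent efficiency).
#' @examples
#' efficiency_from_slope(-3.3219, as_percent = TRUE)  # ~100%
#' @export
efficiency_from_slope <- function(slope, as_percent = FALSE) {
  if (any(!is.finite(slope)) || any(slope >= 0))
    stopf("standard-curve slope must be negative")
  factor <- 10^(-1 / slope)
  if (as_percent) (factor - 1) * 100 else factor
}
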