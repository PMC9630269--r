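#' Fit a reference-gene stability analysis
#'
#' The main entry point: runs any subset of the four stability algorithms
#' (geNorm, NormFinder, BestKeeper, comparative delta-Ct) plus the
#' RefFinder-style consensus on every sample group of a Ct matrix, one
#' panel per group.
#'
#' @param x A [ct_matrix()] (groups taken from it) or a numeric
#'   genes x samples matrix.
#' @param group Optional group labels when `x` is a plain matrix.
#' @param methods Algorithms to run; `"consensus"` requires the other
#'   four. Default: everything.
#' @param efficiency Amplification factor(s) for the Ct -> quantity
#'   transform feeding geNorm and NormFinder (default 2; BestKeeper and
#'   delta-Ct always use raw Ct).
#' @param v_threshold geNorm pairwise-variation cutoff (default 0.15).
#' @param sd_threshold BestKeeper SD exclusion cutoff in cycles (default 1).
#' @param ties Rank tie policy for the consensus, `"min"` or `"average"`.
#'
#' @return An object of class `refstab`: a list with `panels` (one sub-list
#'   per group holding the panel `ct` and the fitted `genorm`,
#'   `normfinder`, `bestkeeper`, `deltact`, `consensus` objects that were
#'   requested), plus the call and parameters. Methods: [print.refstab()],
#'   [summary.refstab()], [coef.refstab()], [plot.refstab()].
#' @examples
#' fit <- refstab(ladakh_pbmc())
#' summary(fit)
#' @export
refstab <- function(x, group = NULL,
                    methods = c("genorm", "normfinder", "bestkeeper",
                                "deltact", "consensus"),
                    efficiency = 2, v_threshold = 0.15, sd_threshold = 1,
                    ties = c("min", "average")) {
  ties <- match.arg(ties)
  if (!length(methods)) stopf("'methods' must name at least one algorithm")
  methods <- match.arg(methods, several.ok = TRUE)
  if (v_threshold <= 0 || sd_threshold <= 0)
    stopf("thresholds must be > 0")
  base <- c("genorm", "normfinder", "bestkeeper", "deltact")
  if ("consensus" %in% methods && !all(base %in% methods))
    stopf("the consensus requires all four methods: %s",
          paste(base, collapse = ", "))
  ct <- as_ct_input(x, group)

  panels <- list()
  for (grp in unique(ct_groups(ct))) {
    panel <- subset_group(ct, grp)
    if (nrow(panel) < 3L || ncol(panel) < 3L)
      stopf("group '%s' needs at least 3 genes and 3 samples", grp)
    qm <- relative_quantity(panel, efficiency)
    res <- list(ct = panel)
    if ("genorm" %in% methods)
      res$genorm <- genorm(qm, threshold = v_threshold)
    if ("normfinder" %in% methods)
      res$normfinder <- normfinder(qm)
    if ("bestkeeper" %in% methods)
      res$bestkeeper <- bestkeeper(panel, sd_threshold = sd_threshold)
    if ("deltact" %in% methods)
      res$deltact <- delta_ct(panel)
    if ("consensus" %in% methods)
      res$consensus <- consensus_ranking(res$genorm, res$normfinder,
                                         res$bestkeeper, res$deltact,
                                         ties = ties)
    panels[[grp]] <- res
  }
  structure(list(panels = panels, methods = methods,
                 efficiency = efficiency, v_threshold = v_threshold,
                 sd_threshold = sd_threshold, ties = ties,
                 call = match.call()),
            class = "refstab")
}

#' @export
print.refstab <- function(x, ...) {
  cat("Reference-gene stability analysis\n")
  cat("methods:", paste(x$methods, collapse = ", "), "\n\n")
  for (grp in names(x$panels)) {
    p <- x$panels[[grp]]
    top <- if (!is.null(p$consensus)) p$consensus$ranking[1:3]
           else if (!is.null(p$genorm)) p$genorm$ranking[1:3]
           else if (!is.null(p$normfinder)) p$normfinder$ranking[1:3]
           else if (!is.null(p$deltact)) p$deltact$ranking[1:3]
           else p$bestkeeper$ranking[1:3]
    cat(sprintf("%s (%d samples): top genes %s\n", grp, ncol(p$ct),
                paste(top, collapse = ", ")))
  }
  invisible(x)
}

#' Summarise a stability fit
#'
#' One row per group: panel size, the most stable gene under each fitted
#' method, the consensus top-3 and the geNorm-recommended number of
#' reference genes.
#'
#' @param object A `refstab` fit.
#' @param ... Unused.
#' @return A data.frame of class `summary.refstab`.
#' @export
summary.refstab <- function(object, ...) {
  rows <- lapply(names(object$panels), function(grp) {
    p <- object$panels[[grp]]
    data.frame(
      group = grp, n_samples = ncol(p$ct), n_genes = nrow(p$ct),
      genorm_top = if (is.null(p$genorm)) NA_character_ else
        paste(sort(p$genorm$ranking[1:2]), collapse = "/"),
      genorm_n = if (is.null(p$genorm)) NA_integer_ else
        as.integer(p$genorm$n_recommended),
      normfinder_top = if (is.null(p$normfinder)) NA_character_ else
        p$normfinder$ranking[1],
      bestkeeper_top = if (is.null(p$bestkeeper)) NA_character_ else
        p$bestkeeper$ranking[1],
      deltact_top = if (is.null(p$deltact)) NA_character_ else
        p$deltact$ranking[1],
      consensus_top3 = if (is.null(p$consensus)) NA_character_ else
        paste(p$consensus$ranking[1:3], collapse = ", "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.refstab", class(out))
  out
}

#' @export
print.summary.refstab <- function(x, ...) {
  cat("Reference-gene stability summary\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Consensus scores (or one method's scores) per gene and group
#'
#' @param object A `refstab` fit.
#' @param method Which score to extract: `"consensus"` (geometric-mean
#'   rank), `"genorm"` (reported M value), `"normfinder"` (stability),
#'   `"bestkeeper"` (sd_cp) or `"deltact"` (mean SD).
#' @param ... Unused.
#' @return Numeric matrix genes x groups.
#' @export
coef.refstab <- function(object, method = c("consensus", "genorm",
                                            "normfinder", "bestkeeper",
                                            "deltact"), ...) {
  method <- match.arg(method)
  if (!method %in% object$methods)
    stopf("method '%s' was not fitted", method)
  genes <- rownames(object$panels[[1]]$ct)
  vapply(object$panels, function(p) {
    switch(method,
           consensus = p$consensus$score[genes],
           genorm = p$genorm$m_value[genes],
           normfinder = p$normfinder$stability[genes],
           bestkeeper = stats::setNames(p$bestkeeper$stats[genes, "sd_cp"],
                                        genes),
           deltact = p$deltact$mean_sd[genes])
  }, numeric(length(genes)))
}

#' Plot a stability fit
#'
#' Bar chart of one group's per-gene scores, genes ordered most to least
#' stable: the geNorm reported M series (default) or the consensus
#' geometric-mean ranks.
#'
#' @param x A `refstab` fit.
#' @param group Group to plot (default: first).
#' @param method `"genorm"` or `"consensus"`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted values.
#' @export
plot.refstab <- function(x, group = names(x$panels)[1],
                         method = c("genorm", "consensus"), ...) {
  method <- match.arg(method)
  p <- x$panels[[group]]
  if (is.null(p)) stopf("unknown group '%s'", group)
  if (is.null(p[[method]])) stopf("method '%s' was not fitted", method)
  vals <- if (method == "genorm") {
    v <- p$genorm$m_value[p$genorm$ranking]
    graphics::barplot(v, las = 2,
                      ylab = "average expression stability M",
                      main = sprintf("%s: geNorm (most to least stable)", group),
                      ...)
    v
  } else {
    v <- p$consensus$score[p$consensus$ranking]
    graphics::barplot(v, las = 2, ylab = "geometric mean rank",
                      main = sprintf("%s: consensus ranking", group), ...)
    v
  }
  invisible(vals)
}
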