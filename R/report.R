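#' Run the full analysis and write per-species report tables
#'
#' Fits [refstab()] on the requested species subsets of a Ct matrix and
#' writes one set of CSV tables per group into `out_dir`:
#' `<group>_genorm_m.csv` (rank, gene, M), `<group>_genorm_v.csv` (n, V),
#' `<group>_deltact.csv`, `<group>_normfinder.csv`,
#' `<group>_bestkeeper_stats.csv` (the descriptive row structure of the
#' BestKeeper tables), `<group>_bestkeeper_correlations.csv`
#' (gene_a, gene_b, r, p), `<group>_bestkeeper_index.csv` (gene, r, p)
#' and `<group>_consensus.csv` (gene, one rank column per method,
#' geomean_score, final_rank), plus a machine-readable `summary.csv`
#' listing the top-2 genes per method and a human-readable `summary.txt`
#' from [summarize_panel()]. Numbers are written at full precision;
#' rounding is a display concern only. Output is deterministic: two runs
#' on the same input produce byte-identical tables.
#'
#' @param x A [ct_matrix()].
#' @param out_dir Output directory (created if absent).
#' @param species Group labels to analyse (default: all groups present).
#' @inheritParams refstab
#' @return Invisibly, a list with the `refstab` fit and the written file
#'   paths.
#' @export
run_report <- function(x, out_dir, species = NULL,
                       methods = c("genorm", "normfinder", "bestkeeper",
                                   "deltact", "consensus"),
                       efficiency = 2, v_threshold = 0.15, sd_threshold = 1,
                       ties = c("min", "average")) {
  ct <- as_ct_input(x)
  if (!is.null(species)) {
    g <- ct_groups(ct)
    bad <- setdiff(species, g)
    if (length(bad))
      stopf("species not in annotation: %s (available: %s)",
            paste(bad, collapse = ", "), paste(unique(g), collapse = ", "))
    keep <- names(g)[g %in% species]
    ct <- ct_matrix(unclass(ct)[, keep, drop = FALSE], group = g[keep])
  }
  fit <- refstab(ct, methods = methods, efficiency = efficiency,
                 v_threshold = v_threshold, sd_threshold = sd_threshold,
                 ties = ties)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    files <<- c(files, path)
  }

  summary_rows <- list()
  for (grp in names(fit$panels)) {
    p <- fit$panels[[grp]]
    if (!is.null(p$genorm)) {
      gn <- p$genorm
      emit(data.frame(rank = c(1L, 1L, 3:length(gn$ranking)),
                      gene = gn$ranking, M = gn$m_value[gn$ranking]),
           sprintf("%s_genorm_m.csv", grp))
      emit(data.frame(n = as.integer(names(gn$v)), V = unname(gn$v)),
           sprintf("%s_genorm_v.csv", grp))
    }
    if (!is.null(p$deltact))
      emit(data.frame(rank = seq_along(p$deltact$ranking),
                      gene = p$deltact$ranking,
                      mean_sd = p$deltact$mean_sd[p$deltact$ranking]),
           sprintf("%s_deltact.csv", grp))
    if (!is.null(p$normfinder))
      emit(data.frame(rank = seq_along(p$normfinder$ranking),
                      gene = p$normfinder$ranking,
                      stability = p$normfinder$stability[p$normfinder$ranking]),
           sprintf("%s_normfinder.csv", grp))
    if (!is.null(p$bestkeeper)) {
      bk <- p$bestkeeper
      emit(data.frame(gene = rownames(bk$stats), bk$stats,
                      retained = rownames(bk$stats) %in% bk$retained),
           sprintf("%s_bestkeeper_stats.csv", grp))
      genes <- rownames(bk$pair_r)
      pairs <- which(upper.tri(bk$pair_r), arr.ind = TRUE)
      emit(data.frame(gene_a = genes[pairs[, 1]], gene_b = genes[pairs[, 2]],
                      r = bk$pair_r[pairs], p = bk$pair_p[pairs]),
           sprintf("%s_bestkeeper_correlations.csv", grp))
      emit(data.frame(gene = names(bk$index_r), r = unname(bk$index_r),
                      p = unname(bk$index_p)),
           sprintf("%s_bestkeeper_index.csv", grp))
    }
    if (!is.null(p$consensus)) {
      cons <- p$consensus
      emit(data.frame(gene = cons$ranking,
                      cons$method_ranks[cons$ranking, , drop = FALSE],
                      geomean_score = cons$score[cons$ranking],
                      final_rank = seq_along(cons$ranking)),
           sprintf("%s_consensus.csv", grp))
    }
    for (meth in intersect(c("genorm", "normfinder", "bestkeeper", "deltact",
                             "consensus"), names(p))) {
      top2 <- p[[meth]]$ranking[1:2]
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(group = grp, method = meth,
                   top1 = top2[1], top2 = top2[2])
    }
  }
  emit(do.call(rbind, summary_rows), "summary.csv")
  txt <- summarize_panel(fit)
  txt_path <- file.path(out_dir, "summary.txt")
  writeLines(txt, txt_path, useBytes = TRUE)
  files <- c(files, txt_path)
  invisible(list(fit = fit, files = files))
}

#' One-line per-species panel summary
#'
#' For each group, names the consensus top genes (falling back to the
#' geNorm ranking when no consensus was fitted) and the geNorm-recommended
#' number of reference genes, e.g.
#' `"LAY: GAPDH, RPS9, ACTB; use 3 genes"`.
#'
#' @param fit A `refstab` fit.
#' @param top How many top genes to name (default 3).
#' @return Character vector, one line per group.
#' @export
summarize_panel <- function(fit, top = 3) {
  stopifnot(inherits(fit, "refstab"))
  vapply(names(fit$panels), function(grp) {
    p <- fit$panels[[grp]]
    ranking <- if (!is.null(p$consensus)) p$consensus$ranking
               else if (!is.null(p$genorm)) p$genorm$ranking
               else if (!is.null(p$normfinder)) p$normfinder$ranking
               else if (!is.null(p$deltact)) p$deltact$ranking
               else p$bestkeeper$ranking
    n_use <- if (!is.null(p$genorm))
      sprintf("; use %d genes", as.integer(p$genorm$n_recommended)) else ""
    sprintf("%s: %s%s", grp,
            paste(ranking[seq_len(min(top, length(ranking)))],
                  collapse = ", "), n_use)
  }, character(1), USE.NAMES = FALSE)
}
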