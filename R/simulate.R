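#' Specification for a synthetic Ct matrix
#'
#' Describes the generative model the four stability algorithms assume:
#' `Ct[g, s] = baseline_ct[g] + b_s + e_gs` with a per-sample loading
#' shift `b_s ~ Normal(0, sample_effect_sd)` (additive on the Ct scale,
#' i.e. multiplicative on the quantity scale, which is what geometric-mean
#' normalization factors remove) and per-gene technical/biological noise
#' `e_gs ~ Normal(0, gene_noise_sd[g])`, all independent.
#'
#' Defaults mirror the packaged study data: 10 genes by 6 samples,
#' baselines drawn uniformly on 14-30 cycles (the observed Ct range), a
#' 0.5-cycle sample effect, and per-gene noise SDs spread evenly from a
#' near-perfect 0.05 cycles up to a clearly unstable 1 cycle.
#'
#' @param n_genes,n_samples Panel dimensions.
#' @param baseline_ct Per-gene baseline Ct (cycles); `NULL` draws them
#'   uniformly on 14-30 under the spec's seed.
#' @param sample_effect_sd SD of the per-sample loading shift, cycles
#'   (>= 0).
#' @param gene_noise_sd Per-gene noise SD, cycles (>= 0); a single value
#'   is recycled.
#' @param efficiency Per-gene amplification factor (recorded for
#'   downstream transforms; the generator itself works on the Ct scale).
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `ct_sim_spec`.
#' @seealso [simulate_ct()], [recovery_experiment()]
#' @export
ct_sim_spec <- function(n_genes = 10, n_samples = 6, baseline_ct = NULL,
                        sample_effect_sd = 0.5,
                        gene_noise_sd = seq(0.05, 1, length.out = n_genes),
                        efficiency = 2, seed = 1L) {
  if (n_genes < 1 || n_samples < 1) stopf("dimensions must be positive")
  if (length(gene_noise_sd) == 1L)
    gene_noise_sd <- rep(gene_noise_sd, n_genes)
  if (length(gene_noise_sd) != n_genes)
    stopf("'gene_noise_sd' must have one value per gene")
  if (sample_effect_sd < 0 || any(gene_noise_sd < 0))
    stopf("noise SDs must be >= 0")
  if (!is.null(baseline_ct) && length(baseline_ct) != n_genes)
    stopf("'baseline_ct' must have one value per gene")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 baseline_ct = baseline_ct,
                 sample_effect_sd = sample_effect_sd,
                 gene_noise_sd = gene_noise_sd,
                 efficiency = efficiency,
                 seed = as.integer(seed)),
            class = "ct_sim_spec")
}

#' Generate a synthetic Ct matrix
#'
#' Draws one Ct matrix from the model described by a [ct_sim_spec()];
#' deterministic given the spec's seed.
#'
#' @param spec A [ct_sim_spec()].
#' @return A [ct_matrix()] (genes `G01`, `G02`, ..., samples `S01`, ...,
#'   group `"SIM"`) with the spec attached as attribute `"sim_spec"`.
#' @examples
#' ct <- simulate_ct(ct_sim_spec(n_genes = 4, n_samples = 8, seed = 42))
#' dim(ct)
#' @export
simulate_ct <- function(spec) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes
  n <- spec$n_samples
  baseline <- spec$baseline_ct
  if (is.null(baseline)) baseline <- stats::runif(g, 14, 30)
  b <- stats::rnorm(n, 0, spec$sample_effect_sd)
  e <- matrix(stats::rnorm(g * n, 0, rep(spec$gene_noise_sd, n)), g, n)
  m <- baseline + rep(b, each = g) + e
  dimnames(m) <- list(sprintf("G%02d", seq_len(g)),
                      sprintf("S%02d", seq_len(n)))
  out <- ct_matrix(m, group = "SIM")
  attr(out, "sim_spec") <- spec
  out
}

#' Parameter-recovery experiment over simulated panels
#'
#' Repeatedly simulates a panel, runs all four stability algorithms on
#' each replicate, and summarises how well the injected per-gene noise
#' SDs are recovered: per-gene mean rank under each method and the
#' per-replicate Spearman correlation between the injected SDs and each
#' method's stability score (higher noise should score worse).
#'
#' @param spec A [ct_sim_spec()]; replicate r uses seed `spec$seed + r - 1`.
#' @param n_reps Number of replicates (>= 1).
#' @return An object of class `recovery_experiment`: list with
#'   `mean_rank` (genes x methods), `spearman` (replicates x methods),
#'   `spec` and `n_reps`.
#' @examples
#' rec <- recovery_experiment(ct_sim_spec(n_samples = 10, seed = 7), n_reps = 3)
#' colMeans(rec$spearman)
#' @export
recovery_experiment <- function(spec, n_reps = 50) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  if (n_reps < 1) stopf("'n_reps' must be >= 1")
  methods <- c("genorm", "normfinder", "bestkeeper", "deltact")
  rank_sum <- matrix(0, spec$n_genes, length(methods),
                     dimnames = list(sprintf("G%02d", seq_len(spec$n_genes)),
                                     methods))
  rho <- matrix(NA_real_, n_reps, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    rspec <- spec
    rspec$seed <- spec$seed + r - 1L
    ct <- simulate_ct(rspec)
    qm <- relative_quantity(ct, spec$efficiency)
    scores <- cbind(
      genorm = m_values(qm),                       # full-panel M
      normfinder = normfinder(qm)$stability,
      bestkeeper = bestkeeper(ct)$stats$sd_cp,
      deltact = delta_ct(ct)$mean_sd)
    rank_sum <- rank_sum + apply(scores, 2, rank, ties.method = "average")
    rho[r, ] <- apply(scores, 2, function(s)
      stats::cor(spec$gene_noise_sd, s, method = "spearman"))
  }
  structure(list(mean_rank = rank_sum / n_reps, spearman = rho,
                 spec = spec, n_reps = n_reps),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("recovery experiment: %d replicates, %d genes x %d samples\n",
              x$n_reps, x$spec$n_genes, x$spec$n_samples))
  cat("mean Spearman(injected SD, score):\n")
  print(round(colMeans(x$spearman), digits))
  invisible(x)
}
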