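#' NormFinder model-based stability analysis (single group)
#'
#' Estimates a per-gene expression variance after removing gene and sample
#' main effects from the log-quantity matrix, following the single-group
#' form of the NormFinder model (each species panel here is one condition
#' with no subgroup structure). On `y = log2(q)`:
#'
#' 1. double-centred residuals `z_ij = y_ij - mean_i - mean_j + mean`,
#' 2. raw per-gene residual variance `u_i = sum_j z_ij^2 / (n - 1)`,
#' 3. corrected variance
#'    `sigma2_i = max(0, (u_i - U / (g (g - 1))) * g / (g - 2))`
#'    with `U = sum_i u_i` (negative estimates truncate to 0, which can
#'    happen at small g),
#' 4. stability value `sqrt(sigma2_i)`; lower is more stable.
#'
#' @param x A [ct_matrix()] / Ct matrix or `quantity_matrix`; at least 3
#'   genes (the correction divides by g - 2) and 2 samples, complete.
#' @param efficiency Amplification factor(s) for the Ct -> quantity
#'   transform (default 2).
#' @return An object of class `normfinder`: list with `stability` (named,
#'   input gene order, log2 scale, >= 0) and `ranking` (ascending).
#' @examples
#' nf <- normfinder(subset_group(ladakh_pbmc(), "LAC"))
#' nf$ranking[1]
#' @export
normfinder <- function(x, efficiency = 2) {
  qm <- as_quantity(x, efficiency)
  y <- qm$log2q
  g <- nrow(y)
  n <- ncol(y)
  if (g <= 2L) stopf("NormFinder requires >= 3 genes")
  if (n < 2L) stopf("NormFinder requires at least 2 samples")
  z <- y - rowMeans(y) - rep(colMeans(y), each = g) + mean(y)
  u <- rowSums(z^2) / (n - 1)
  U <- sum(u)
  sigma2 <- (u - U / (g * (g - 1))) * g / (g - 2)
  sigma2[sigma2 < 0] <- 0            # negative corrected variances truncate
  stability <- sqrt(sigma2)
  structure(list(stability = stability,
                 ranking = rownames(y)[order(stability)]),
            class = "normfinder")
}

#' @export
print.normfinder <- function(x, digits = 3, ...) {
  cat("NormFinder stability analysis (single group)\n")
  print(data.frame(rank = seq_along(x$ranking), gene = x$ranking,
                   stability = round(x$stability[x$ranking], digits)),
        row.names = FALSE)
  invisible(x)
}
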