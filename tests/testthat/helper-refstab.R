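# shared fixtures and independent reference values for the test suite

species_codes <- c("LAC", "LAY", "LAD", "CHG", "DHC", "ZAP")

# small deterministic Ct panel used where the packaged data set is overkill
toy_panel <- function(n_genes = 4, n_samples = 6, seed = 11, noise = 0.2) {
  set.seed(seed)
  base <- seq(16, 28, length.out = n_genes)
  load <- rnorm(n_samples, 0, 0.5)
  m <- base + rep(load, each = n_genes) +
    matrix(rnorm(n_genes * n_samples, 0, noise), n_genes, n_samples)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n_samples)))
  ct_matrix(m)
}

# published per-species geNorm column (average expression stability M at
# each exclusion step, most to least stable), as printed
published_genorm_m <- list(
  LAC = c(EEF1A1 = 0.147, RPL4 = 0.147, RPS23 = 0.186, RPS9 = 0.267,
          UXT = 0.322, B2M = 0.413, GAPDH = 0.512, RPS15 = 0.563,
          HPRT1 = 0.605, ACTB = 0.689),
  LAY = c(GAPDH = 0.223, RPS9 = 0.223, ACTB = 0.386, RPS23 = 0.507,
          HPRT1 = 0.595, UXT = 0.708, B2M = 0.892, EEF1A1 = 0.992,
          RPL4 = 1.121, RPS15 = 1.242),
  LAD = c(HPRT1 = 0.250, B2M = 0.250, RPS23 = 0.571, ACTB = 0.612,
          EEF1A1 = 0.751, GAPDH = 0.857, UXT = 0.984, RPL4 = 1.090,
          RPS15 = 1.233, RPS9 = 1.405),
  CHG = c(RPS9 = 0.378, HPRT1 = 0.378, ACTB = 0.434, RPS23 = 0.636,
          EEF1A1 = 0.803, UXT = 0.973, GAPDH = 1.066, RPL4 = 1.254,
          RPS15 = 1.474, B2M = 1.721),
  DHC = c(B2M = 0.600, RPS9 = 0.600, HPRT1 = 0.664, ACTB = 0.680,
          RPS23 = 0.747, EEF1A1 = 0.794, UXT = 0.860, GAPDH = 0.992,
          RPL4 = 1.180, RPS15 = 1.352),
  ZAP = c(RPS9 = 0.135, RPL4 = 0.135, RPS23 = 0.142, EEF1A1 = 0.194,
          UXT = 0.249, RPS15 = 0.411, HPRT1 = 0.824, ACTB = 1.136,
          B2M = 1.394, GAPDH = 1.712))

# published per-species min/max Ct rows of the BestKeeper descriptive
# tables, in fixture gene order
fixture_gene_order <- c("GAPDH", "ACTB", "RPS9", "EEF1A1", "RPS15",
                        "RPS23", "UXT", "RPL4", "B2M", "HPRT1")
published_min_cp <- list(
  LAC = c(21.870, 22.640, 19.870, 16.900, 19.210, 13.940, 23.860, 19.610, 17.740, 27.950),
  LAY = c(17.34, 19.62, 21.06, 19.57, 29.06, 14.37, 22.22, 23.71, 18.11, 24.33),
  LAD = c(20.73, 19.97, 19.70, 17.94, 31.86, 13.86, 21.45, 20.55, 16.69, 24.79),
  CHG = c(14.35, 17.09, 19.15, 17.75, 30.18, 13.63, 20.44, 20.01, 26.70, 24.36),
  DHC = c(20.41, 18.37, 18.55, 16.87, 30.62, 16.05, 18.19, 18.23, 19.24, 21.93),
  ZAP = c(19.69, 16.40, 19.84, 18.81, 33.61, 16.47, 26.17, 17.55, 16.06, 22.06))
published_max_cp <- list(
  LAC = c(22.530, 24.900, 22.400, 18.810, 19.790, 15.930, 26.070, 21.560, 19.360, 30.180),
  LAY = c(19.20, 22.12, 23.42, 23.62, 33.82, 17.51, 23.04, 25.65, 22.95, 25.41),
  LAD = c(24.53, 21.09, 24.16, 20.65, 35.47, 14.84, 23.92, 23.17, 18.58, 26.04),
  CHG = c(17.40, 18.64, 19.79, 20.64, 34.92, 15.23, 22.62, 23.87, 33.05, 25.45),
  DHC = c(24.13, 20.00, 20.83, 17.93, 34.90, 17.98, 20.89, 22.32, 21.40, 22.78),
  ZAP = c(25.66, 19.94, 21.45, 20.50, 36.06, 18.13, 27.41, 19.21, 20.49, 26.81))

# published top gene of the BestKeeper column and the consensus column
published_bestkeeper_top <- c(LAC = "RPS15", LAY = "UXT", LAD = "ACTB",
                              CHG = "RPS9", DHC = "HPRT1", ZAP = "UXT")
published_consensus_top <- c(LAC = "EEF1A1", LAY = "GAPDH", LAD = "HPRT1",
                             CHG = "RPS9", DHC = "HPRT1", ZAP = "RPS9")

# published NormFinder column: most/least stable two genes per species
published_normfinder_top2 <- list(
  LAC = c("EEF1A1", "RPL4"), LAY = c("GAPDH", "RPS9"),
  LAD = c("HPRT1", "B2M"), CHG = c("RPS9", "RPS23"),
  DHC = c("HPRT1", "ACTB"), ZAP = c("EEF1A1", "UXT"))
published_normfinder_bottom2 <- list(
  LAC = c("HPRT1", "ACTB"), LAY = c("RPS15", "RPL4"),
  LAD = c("RPS15", "RPS9"), CHG = c("RPS15", "B2M"),
  DHC = c("RPL4", "RPS15"), ZAP = c("B2M", "GAPDH"))

# independent geNorm oracle: greedy stepwise exclusion recomputed directly
# from raw Ct differences (E = 2 identity), no shared code with genorm()
oracle_stepwise <- function(ct) {
  m <- as.matrix(ct)
  remaining <- rownames(m)
  order_out <- character(0)
  pair_sd <- function(j, k) sd(m[j, ] - m[k, ])
  while (length(remaining) > 2) {
    M <- sapply(remaining, function(j)
      mean(sapply(setdiff(remaining, j), pair_sd, j = j)))
    worst <- remaining[max(which(M == max(M)))]
    order_out <- c(worst, order_out)
    remaining <- setdiff(remaining, worst)
  }
  list(ranking = c(remaining, order_out),
       final_m = mean(sapply(remaining[1], pair_sd, k = remaining[2])))
}

# independent NormFinder oracle: two-way ANOVA residuals via lm()
oracle_normfinder <- function(y) {
  g <- nrow(y); n <- ncol(y)
  df <- data.frame(y = as.vector(y),
                   gene = factor(rep(rownames(y), n)),
                   sample = factor(rep(colnames(y), each = g)))
  z <- matrix(residuals(lm(y ~ gene + sample, data = df)), g, n,
              dimnames = dimnames(y))
  u <- rowSums(z^2) / (n - 1)
  s2 <- (u - sum(u) / (g * (g - 1))) * g / (g - 2)
  s2[s2 < 0] <- 0
  sqrt(s2)
}
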