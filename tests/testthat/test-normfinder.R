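test_that("copies of one gene all have zero stability", {
  base <- c(20, 22, 21, 23, 20.5)
  m <- rbind(gA = base, gB = base + 2, gC = base - 1, gD = base + 4)
  colnames(m) <- paste0("s", 1:5)
  nf <- normfinder(ct_matrix(m))
  expect_equal(unname(nf$stability), rep(0, 4))
})

test_that("the estimator matches an independent two-way ANOVA oracle", {
  for (seed in 1:5) {
    ct <- toy_panel(n_genes = 6, n_samples = 8, seed = seed, noise = 0.4)
    y <- relative_quantity(ct)$log2q
    expect_equal(normfinder(ct)$stability, oracle_normfinder(y),
                 tolerance = 1e-10)
  }

  # fixed small matrix with one high-variance gene
  y <- rbind(g1 = c(20.0, 20.1, 19.9, 20.0),
             g2 = c(25.1, 25.0, 25.0, 24.9),
             g3 = c(18.0, 21.0, 17.5, 22.0))
  colnames(y) <- paste0("s", 1:4)
  nf <- normfinder(ct_matrix(y))
  expect_equal(names(which.max(nf$stability)), "g3")
  expect_equal(nf$stability, oracle_normfinder(relative_quantity(y)$log2q),
               tolerance = 1e-10)
})

test_that("negative corrected variances truncate to zero", {
  # the LAY panel is a real case: the two most stable genes fall below the
  # shared-noise subtraction U/(g(g-1)) and their corrected variance is
  # negative, so the reported stability is exactly 0
  lay <- subset_group(ladakh_pbmc(), "LAY")
  nf <- normfinder(lay)
  expect_equal(unname(nf$stability[c("GAPDH", "RPS9")]), c(0, 0))
  expect_true(all(nf$stability[setdiff(names(nf$stability),
                                       c("GAPDH", "RPS9"))] > 0))
  # ...even though their raw residual variances are positive
  y <- relative_quantity(lay)$log2q
  z <- y - rowMeans(y) - rep(colMeans(y), each = nrow(y)) + mean(y)
  expect_true(all(rowSums(z^2) > 0))
})

test_that("stability is invariant to gene and sample offsets", {
  ct <- toy_panel(5, 7, seed = 13, noise = 0.3)
  ref <- normfinder(ct)$stability
  m <- as.matrix(ct)
  m["g2", ] <- m["g2", ] + 5            # per-gene constant
  m <- m + rep(seq(0.1, 0.7, by = 0.1), each = nrow(m))  # per-sample constant
  expect_equal(normfinder(ct_matrix(m))$stability, ref, tolerance = 1e-10)
})

test_that("per-species rankings agree with the published NormFinder column", {
  ct <- ladakh_pbmc()
  for (sp in species_codes) {
    nf <- normfinder(subset_group(ct, sp))
    s <- sort(nf$stability)
    # ties (truncated zeros) make the order within the top pair arbitrary
    expect_setequal(names(s)[1:2], published_normfinder_top2[[sp]])
    expect_setequal(names(s)[9:10], published_normfinder_bottom2[[sp]])
  }
  lac <- normfinder(subset_group(ct, "LAC"))
  expect_equal(lac$ranking[1], "EEF1A1")
  expect_equal(lac$ranking[10], "ACTB")
  expect_equal(unname(lac$stability["EEF1A1"]), 0.171, tolerance = 0.05 / 0.171)
})

test_that("injected noise SDs are recovered in rank (parameter recovery)", {
  spec <- ct_sim_spec(n_genes = 10, n_samples = 20, sample_effect_sd = 0.5,
                      gene_noise_sd = seq(0.05, 1, length.out = 10),
                      seed = 2024L)
  rec <- recovery_experiment(spec, n_reps = 50)
  rho <- rec$spearman[, "normfinder"]
  expect_gte(sum(rho > 0.8), 45)
  expect_gt(mean(rho), 0.8)
})

test_that("NormFinder rejects panels with fewer than 3 genes", {
  expect_error(normfinder(toy_panel(2, 6)), ">= 3 genes")
})
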