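test_that("descriptive statistics reproduce hand-verified published values", {
  bk <- bestkeeper(subset_group(ladakh_pbmc(), "LAC"))
  expect_equal(bk$stats["GAPDH", "sd_cp"], 0.163, tolerance = 0.001 / 0.163)
  expect_equal(bk$stats["ACTB", "sd_cp"], 0.812, tolerance = 0.001 / 0.812)
  # sd_xfold = 2^sd_cp exactly; at the published display precision
  # 2^0.163 = 1.120, the printed x-fold entry
  expect_equal(bk$stats$sd_xfold, 2^bk$stats$sd_cp)
  expect_equal(round(2^round(bk$stats["GAPDH", "sd_cp"], 3), 3), 1.120)
  # descriptive invariant: min <= geo mean <= max, geo <= arithmetic
  expect_true(all(bk$stats$min_cp <= bk$stats$geo_mean))
  expect_true(all(bk$stats$geo_mean <= bk$stats$max_cp))
  expect_true(all(bk$stats$geo_mean <= bk$stats$ar_mean))
})

test_that("a constant gene has zero dispersion and unit fold-change", {
  m <- rbind(flat = rep(20, 5), wob = c(18, 19, 20, 21, 22))
  colnames(m) <- paste0("s", 1:5)
  bk <- suppressWarnings(bestkeeper(ct_matrix(m)))
  expect_equal(bk$stats["flat", "sd_cp"], 0)
  expect_equal(bk$stats["flat", "sd_xfold"], 1)
  expect_equal(bk$stats["flat", "min_xfold"], -1)
  expect_equal(bk$stats["flat", "max_xfold"], 1)
})

test_that("the SD > 1 filter excludes the published genes", {
  ct <- ladakh_pbmc()
  lac <- bestkeeper(subset_group(ct, "LAC"))
  expect_length(lac$excluded, 0)
  lay <- bestkeeper(subset_group(ct, "LAY"))
  expect_setequal(lay$excluded, c("B2M", "EEF1A1", "RPS15"))

  set.seed(2)
  m <- rbind(quiet = 20 + rnorm(10, 0, 0.1), loud = 25 + rnorm(10, 0, 2.5))
  colnames(m) <- paste0("s", 1:10)
  bk <- bestkeeper(ct_matrix(m))
  expect_identical(bk$excluded, "loud")
  expect_error(bestkeeper(ct_matrix(m), sd_threshold = 1e-6),
               "all genes exceed")
})

test_that("the most stable gene per species matches the published column", {
  ct <- ladakh_pbmc()
  for (sp in species_codes)
    expect_equal(bestkeeper(subset_group(ct, sp))$ranking[1],
                 unname(published_bestkeeper_top[sp]), info = sp)
})

test_that("pairwise correlations match published values and cor.test", {
  lac <- subset_group(ladakh_pbmc(), "LAC")
  bk <- bestkeeper(lac)
  expect_equal(bk$pair_r["EEF1A1", "RPS9"], 0.970, tolerance = 0.001 / 0.97)
  expect_lt(bk$pair_p["EEF1A1", "RPS9"], 0.005)
  ref <- cor.test(as.matrix(lac)["EEF1A1", ], as.matrix(lac)["RPS9", ])
  expect_equal(bk$pair_r["EEF1A1", "RPS9"], unname(ref$estimate))
  expect_equal(bk$pair_p["EEF1A1", "RPS9"], ref$p.value)
  expect_true(all(abs(bk$pair_r) <= 1, na.rm = TRUE))
  expect_true(all(bk$pair_p >= 0 & bk$pair_p <= 1, na.rm = TRUE))
})

test_that("the closed-form correlation p-value matches cor.test", {
  # independent oracle across sample sizes and correlation strengths
  set.seed(8)
  for (n in c(4, 5, 6, 12)) {
    x <- rnorm(n)
    y <- 0.8 * x + rnorm(n, 0, 0.6)
    ref <- cor.test(x, y)
    expect_equal(pearson_p(cor(x, y), n), ref$p.value, tolerance = 1e-12)
  }
  expect_equal(round(pearson_p(0.9, 5), 4), 0.0374)
  expect_equal(pearson_p(1, 10), 0)
  expect_error(pearson_p(0.5, 2), "at least 3 samples")
})

test_that("a gene correlated with its copy gives r = 1; zero variance warns", {
  base <- c(18, 19, 20, 21)
  m <- rbind(gA = base, gB = base + 2, flat = rep(25, 4))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(bk <- bestkeeper(ct_matrix(m)), "zero-variance")
  expect_equal(bk$pair_r["gA", "gB"], 1)
  expect_true(is.na(bk$pair_r["gA", "flat"]))
})

test_that("the BestKeeper index behaves as a geometric-mean consensus signal", {
  # single retained gene: index is that gene's CP, r = 1
  set.seed(6)
  m <- rbind(quiet = 20 + rnorm(8, 0, 0.2), loud = 30 + rnorm(8, 0, 3))
  colnames(m) <- paste0("s", 1:8)
  bk <- bestkeeper(ct_matrix(m))
  expect_identical(bk$index_genes, "quiet")
  expect_equal(unname(bk$index), unname(as.matrix(ct_matrix(m))["quiet", ]))
  expect_equal(bk$index_r[["quiet"]], 1)

  # LAC: genes most correlated with the index are EEF1A1 and RPS9
  lac <- bestkeeper(subset_group(ladakh_pbmc(), "LAC"))
  expect_setequal(names(sort(lac$index_r, decreasing = TRUE))[1:2],
                  c("EEF1A1", "RPS9"))

  # shared sample loading + tiny noise: every gene tracks the index
  # (sample loading inflates per-gene SD, so lift the exclusion filter)
  spec <- ct_sim_spec(n_genes = 6, n_samples = 12, sample_effect_sd = 1.5,
                      gene_noise_sd = 0.05, seed = 99L)
  bk2 <- bestkeeper(simulate_ct(spec), sd_threshold = 10)
  expect_true(all(bk2$index_r > 0.99))
})

test_that("sd_cp survives sample permutation; shifts move the mean not r", {
  ct <- toy_panel(4, 8, seed = 17, noise = 0.5)
  bk <- bestkeeper(ct)
  set.seed(2)
  perm <- as.matrix(ct)[, sample(ncol(ct))]
  expect_equal(bestkeeper(ct_matrix(perm))$stats$sd_cp, bk$stats$sd_cp)

  shifted <- as.matrix(ct)
  shifted["g1", ] <- shifted["g1", ] + 0.5
  bk2 <- bestkeeper(ct_matrix(shifted))
  expect_equal(bk2$stats["g1", "geo_mean"], bk$stats["g1", "geo_mean"] + 0.5,
               tolerance = 1e-3)
  expect_equal(bk2$pair_r["g1", "g2"], bk$pair_r["g1", "g2"])
})
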