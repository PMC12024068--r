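test_that("sim_config validates and carries the unbalanced default design", {
  cfg <- sim_config()
  expect_equal(cfg$n_per_group, c(3, 4, 8, 8))
  expect_equal(cfg$blocks$shared_signal_strength, c(1.0, 0.7, 0.4, 0.1))
  expect_error(sim_config(censor_quantile = 0.9), "censor_quantile")
  expect_error(sim_config(n_per_group = 0), "n_per_group")
  expect_error(sim_config(group_factors = list(genotype = "AKR",
                                               treatment = c("v", "R")),
                          effect_factor = "genotype"), "2 levels")
})

test_that("simulate_multiblock is seed-deterministic and leaves RNG alone", {
  s1 <- simulate_multiblock(sim_config(seed = 9))
  s2 <- simulate_multiblock(sim_config(seed = 9))
  expect_identical(lapply(s1$dataset$blocks, `[[`, "matrix"),
                   lapply(s2$dataset$blocks, `[[`, "matrix"))
  expect_identical(s1$truth$t, s2$truth$t)
  s3 <- simulate_multiblock(sim_config(seed = 10))
  expect_false(identical(s1$truth$t, s3$truth$t))
  # caller RNG untouched
  set.seed(77)
  r1 <- runif(1)
  set.seed(77)
  invisible(simulate_multiblock(sim_config(seed = 9)))
  expect_identical(runif(1), r1)
})

test_that("simulated blocks look like censored MS intensity tables", {
  sim <- simulate_multiblock(sim_config(seed = 12))
  n <- sum(sim$dataset$metadata$sample_ids != "")
  expect_equal(n, 3 + 4 + 8 + 8)
  for (b in sim$dataset$blocks) {
    expect_equal(b$state, "raw")
    expect_true(all(b$matrix >= 0))           # censored entries exactly zero
    frac0 <- mean(b$matrix == 0)
    expect_gt(frac0, 0.05)
    expect_lt(frac0, 0.15)
  }
  # noise-only marginals are right-skewed (log-normal intensities)
  cfg0 <- sim_config(seed = 13, censor_quantile = 0,
                     blocks = data.frame(name = "noise", n_features = 200,
                                         shared_signal_strength = 0,
                                         noise_sd = 0.3),
                     nuisance_strength = 0)
  b0 <- simulate_multiblock(cfg0)$dataset$blocks[[1]]
  x <- as.vector(b0$matrix)
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 0)
})

test_that("group separation flows through the latent score", {
  sim <- simulate_multiblock(sim_config(seed = 14, n_per_group = 10))
  g <- sim$dataset$metadata$factors$genotype
  expect_gt(mean(sim$truth$t[g == "SAMP"]) - mean(sim$truth$t[g == "AKR"]),
            0.5)
})

test_that("null config gives ~alpha Wilcoxon type-I error downstream", {
  cfg <- sim_config(seed = 15, n_per_group = 10, effect_size = 0,
                    nuisance_strength = 0, censor_quantile = 0,
                    blocks = data.frame(name = "null", n_features = 400,
                                        shared_signal_strength = 0,
                                        noise_sd = 0.3))
  sim <- simulate_multiblock(cfg)
  b <- preprocess_block(sim$dataset$blocks[[1]], seed = 1, log10 = FALSE)
  tab <- wilcoxon_screen(b, sim$dataset$metadata, "genotype")
  expect_lt(abs(mean(tab$p < 0.05) - 0.05), 0.03)
})

test_that("a silent block gets the smallest component-1 salience", {
  hits <- 0L
  for (s in 1:7) {
    cfg <- sim_config(seed = 100 + s, n_per_group = 8,
                      censor_quantile = 0, nuisance_strength = 0,
                      blocks = data.frame(
                        name = c("on1", "on2", "off"),
                        n_features = 100,
                        shared_signal_strength = c(1, 1, 0),
                        noise_sd = 0.3))
    sim <- simulate_multiblock(cfg)
    procd <- lapply(sim$dataset$blocks, function(b)
      autoscale(log10_transform(impute_censored(
        median_normalize(filter_features(b, 0)), seed = 1))))
    ds <- structure(list(blocks = procd, metadata = sim$dataset$metadata),
                    class = "multiblock_dataset")
    res <- fit_comdim(frobenius_scale(ds), n_components = 1)
    if (which.min(res$saliences[, 1]) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("truth_eval scores recovery, identity, and univariate screens", {
  cfg <- sim_config(seed = 16, n_per_group = 10, effect_size = 3,
                    censor_quantile = 0, nuisance_strength = 0,
                    affected_fraction = 1,    # strong-signal configuration
                    blocks = data.frame(name = "strong", n_features = 120,
                                        shared_signal_strength = 1,
                                        noise_sd = 0.1))
  sim <- simulate_multiblock(cfg)
  b <- autoscale(log10_transform(impute_censored(median_normalize(
    filter_features(sim$dataset$blocks[[1]], 0)), seed = 1)))
  ds <- structure(list(blocks = list(strong = b),
                       metadata = sim$dataset$metadata),
                  class = "multiblock_dataset")
  res <- fit_comdim(frobenius_scale(ds), n_components = 1)
  ev <- truth_eval(res, sim$truth)
  expect_gt(ev$score_cor, 0.95)
  # perfect oracle input: feed truth back as scores
  oracle <- res
  oracle$scores[, 1] <- sim$truth$t[oracle$sample_ids]
  expect_equal(truth_eval(oracle, sim$truth)$score_cor, 1)
  # univariate route reports sensitivity and FDP against the affected set
  tab <- wilcoxon_screen(make_block(sim$dataset$blocks[[1]]$matrix,
                                    "strong", state = "imputed"),
                         sim$dataset$metadata, "genotype")
  ev2 <- truth_eval(tab, sim$truth)
  expect_gt(ev2$sensitivity, 0.3)
  if (ev2$n_discoveries > 0) expect_lt(ev2$fdp, 0.3)
  # mismatched sample ids are fatal
  bad <- res
  bad$sample_ids <- rev(bad$sample_ids)
  rownames(bad$scores) <- bad$sample_ids
  expect_error(truth_eval(bad, sim$truth), "match")
})

test_that("write_simulation emits readable CSV blocks, TSV metadata, JSON truth", {
  sim <- simulate_multiblock(sim_config(seed = 17))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_length(paths$blocks, 4)
  b <- read_feature_table(paths$blocks[[1]],
                          name = sim$dataset$blocks[[1]]$name)
  expect_equal(b$matrix, sim$dataset$blocks[[1]]$matrix)
  md <- read_sample_metadata(paths$metadata)
  expect_equal(md$sample_ids, sim$dataset$metadata$sample_ids)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(unlist(truth$t), sim$truth$t, tolerance = 1e-12)
  expect_setequal(truth$affected$metabolomics_pos,
                  sim$truth$affected$metabolomics_pos)
})
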