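test_that("bh_adjust matches the step-up closed form and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  # order preservation and q >= p, q monotone in p-order
  set.seed(41)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"))       # independent route
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]|NA")
})

test_that("BH never gains discoveries when any p increases", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(30)
    j <- sample(30, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1) * (1 - p[j]))
    n1 <- sum(bh_adjust(p) <= 0.05)
    n2 <- sum(bh_adjust(p2) <= 0.05)
    expect_lte(n2, n1)
  }
})

test_that("wilcoxon exact p agrees with brute-force enumeration", {
  # complete separation of {1,2,3} vs {4,5,6}: p = 2/20
  tab <- wilcoxon_screen(block_from_groups(1:3, 4:6), md2g(3, 3), "grp")
  expect_equal(tab$p, 0.1)
  expect_true(tab$statistic %in% c(0, 9))   # U at an extreme
  expect_equal(tab$direction, 1)
  # 100 random no-tie instances, group sizes <= 6
  set.seed(43)
  for (i in 1:100) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, mean = rnorm(1))
    tab <- wilcoxon_screen(block_from_groups(x, y), md2g(n1, n2), "grp")
    expect_equal(tab$p, wilcox_enum_p(x, y), tolerance = 1e-12)
    expect_equal(tab$statistic, wilcox_u(x, y))
  }
})

test_that("wilcoxon handles ties, symmetry, and is log-invariant", {
  # identical groups (full ties): p = 1 under the tie-corrected normal path
  tab <- wilcoxon_screen(block_from_groups(c(1, 2, 3), c(1, 2, 3)),
                         md2g(3, 3), "grp")
  expect_equal(tab$p, 1, tolerance = 1e-12)
  # rank test is invariant to the monotone log transform
  set.seed(44)
  m <- matrix(10^rnorm(12 * 20, 2, 1), 12, 20)
  b_pre <- make_block(m, "pre", state = "imputed")
  b_post <- make_block(log10(m), "post", state = "log10")
  md <- md2g(6, 6)
  expect_equal(wilcoxon_screen(b_pre, md, "grp")$p,
               wilcoxon_screen(b_post, md, "grp")$p, tolerance = 1e-12)
  # state gate and level validation
  expect_error(wilcoxon_screen(make_block(m, "r"), md, "grp"), "imputed")
  expect_error(wilcoxon_screen(b_pre, md, "grp", levels = c("g1", "gX")),
               "gX")
  expect_error(wilcoxon_screen(b_pre, md, "nope"), "nope")
})

test_that("welch_screen: statistic, Satterthwaite df, degenerate flags", {
  # equal means and variances -> t = 0, p = 1
  b <- block_from_groups(c(1, 2, 3, 4), c(4, 3, 2, 1))
  tab <- welch_screen(b, md2g(4, 4), "grp")
  expect_equal(tab$statistic, 0)
  expect_equal(tab$p, 1)
  # Satterthwaite df = 2n - 2 for equal n and equal sample variances
  x <- c(1, 2, 3, 4, 5)
  y <- c(11, 12, 13, 14, 15)
  ht <- t.test(x, y, var.equal = FALSE)
  expect_equal(unname(ht$parameter), 2 * 5 - 2)
  tab2 <- welch_screen(block_from_groups(x, y), md2g(5, 5), "grp")
  expect_equal(tab2$statistic, unname(ht$statistic))
  expect_equal(tab2$p, ht$p.value)
  expect_equal(tab2$direction, 1)
  # degenerate: zero variance in both groups
  tabc <- welch_screen(block_from_groups(c(2, 2, 2), c(2, 2, 2)),
                       md2g(3, 3), "grp")
  expect_equal(tabc$p, 1)
  expect_true(tabc$degenerate)
  tabd <- welch_screen(block_from_groups(c(2, 2, 2), c(5, 5, 5)),
                       md2g(3, 3), "grp")
  expect_equal(tabd$p, 0)
  expect_true(tabd$degenerate)
})

test_that("welch type-I error under the null is near alpha", {
  set.seed(45)
  m <- matrix(rnorm(20 * 1000), 20, 1000)
  tab <- welch_screen(make_block(m, "null", state = "imputed"),
                      md2g(10, 10), "grp")
  expect_lt(abs(mean(tab$p < 0.05) - 0.05), 0.02)
})

test_that("top_k_heatmap_matrix selects, truncates and row-normalizes", {
  set.seed(46)
  n <- 12
  nf <- 80
  shifted <- 1:60                     # features with a real group shift
  m <- matrix(rnorm(n * nf), n, nf, dimnames = list(NULL, paste0("f", 1:nf)))
  m[7:12, shifted] <- m[7:12, shifted] + 3
  b <- make_block(m, "hm", state = "imputed")
  md <- md2g(6, 6)
  tab <- wilcoxon_screen(b, md, "grp")
  expect_gte(sum(tab$p < 0.05), 55)   # most shifted features pass
  hm <- top_k_heatmap_matrix(tab, b, k = 50, alpha = 0.05)
  expect_equal(nrow(hm$matrix), 50)
  # the kept features are the 50 smallest p among passers
  passers <- tab$feature_id[tab$p < 0.05]
  best50 <- tab$feature_id[order(tab$p)][1:50]
  expect_setequal(rownames(hm$matrix), best50)
  # rows normalized to mean 0 / unit variance
  expect_lt(max(abs(rowMeans(hm$matrix))), 1e-10)
  expect_lt(max(abs(apply(hm$matrix, 1, var) - 1)), 1e-10)
  # deterministic row order
  hm2 <- top_k_heatmap_matrix(tab, b, k = 50, alpha = 0.05)
  expect_identical(hm$row_order, hm2$row_order)
  # k larger than passers returns all passers
  hm3 <- top_k_heatmap_matrix(tab, b, k = 1000, alpha = 0.05)
  expect_equal(nrow(hm3$matrix), length(passers))
  # nothing passes: empty matrix with warning
  tab0 <- tab
  tab0$p[] <- 0.9
  tab0$q[] <- 0.95
  expect_warning(hm0 <- top_k_heatmap_matrix(tab0, b), "no feature")
  expect_equal(nrow(hm0$matrix), 0)
  # q-gating mode
  hmq <- top_k_heatmap_matrix(tab, b, k = 50, alpha = 0.25, use_q = TRUE)
  expect_true(all(tab$q[match(rownames(hmq$matrix), tab$feature_id)] < 0.25))
})

test_that("univariate tables carry q >= p and write as TSV", {
  set.seed(47)
  m <- matrix(rnorm(10 * 30), 10, 30)
  b <- make_block(m, "w", state = "imputed")
  tab <- wilcoxon_screen(b, md2g(5, 5), "grp")
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_univariate_table(tab, path)
  reread <- read.delim(path)
  expect_equal(reread$feature_id, tab$feature_id)
  expect_equal(reread$p, tab$p, tolerance = 1e-12)
})
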