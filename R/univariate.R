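#' Benjamini-Hochberg step-up FDR adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, m \, p_{(j)} / j)} over the sorted
#' p-values, returned in the input order. Monotone non-decreasing in the
#' p-ordering and never below the raw p.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]} (no `NA`).
#' @return vector of BH-adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

## Internal: two-group split of one block feature by a metadata factor.
split_groups <- function(block, metadata, factor, levels) {
  f <- get_factor(metadata, factor)[block$sample_ids]
  if (any(is.na(f)))
    stop("metadata does not cover every sample of block '", block$name, "'")
  if (is.null(levels)) {
    levels <- sort(unique(f))
    if (length(levels) != 2)
      stop("factor '", factor, "' has ", length(levels),
           " levels; supply 'levels' as the pair to compare")
  }
  missing_lv <- setdiff(levels, unique(f))
  if (length(missing_lv) > 0)
    stop("level(s) absent from factor '", factor, "': ",
         paste(missing_lv, collapse = ", "))
  g1 <- which(f == levels[1])
  g2 <- which(f == levels[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("both levels need >= 2 samples (got ", length(g1), " and ",
         length(g2), ")")
  list(g1 = g1, g2 = g2, levels = levels)
}

## Internal: assemble the per-feature result table.
univariate_table <- function(block, stat, p, m1, m2, levels, statistic_name,
                             degenerate = rep(FALSE, length(p))) {
  tab <- data.frame(
    feature_id = block$feature_ids,
    statistic = stat, p = p, q = bh_adjust(p),
    direction = sign(m2 - m1),
    stringsAsFactors = FALSE)
  tab[[paste0("mean_", levels[1])]] <- m1
  tab[[paste0("mean_", levels[2])]] <- m2
  tab$degenerate <- degenerate
  attr(tab, "statistic_name") <- statistic_name
  attr(tab, "levels") <- levels
  attr(tab, "block") <- block$name
  attr(tab, "tested_state") <- block$state
  class(tab) <- c("univariate_table", "data.frame")
  tab
}

#' Wilcoxon rank-sum (Mann-Whitney U) screen
#'
#' Two-sided Mann-Whitney test per feature between two factor levels. The
#' exact null distribution is used when the smaller group has at most 8
#' samples and the feature has no ties; otherwise the normal approximation
#' with tie correction and continuity correction. Being rank-based, the
#' test is invariant to any monotone transform, so p-values are identical
#' pre- and post-log; by convention it runs on the imputed (pre-log) scale.
#'
#' @param block an `omics_block` in state `"imputed"` or later.
#' @param metadata a `sample_metadata`.
#' @param factor metadata factor name.
#' @param levels character pair of levels to compare (`direction` is the
#'   sign of mean(level 2) - mean(level 1)); defaults to the factor's two
#'   levels in sorted order.
#' @param exact_max_n exact-path threshold on the smaller group size.
#' @return a `univariate_table` data.frame: `feature_id`, `statistic` (U of
#'   level 1, in \eqn{[0, n_1 n_2]}), raw two-sided `p`, BH `q`,
#'   `direction`, group means.
#' @export
wilcoxon_screen <- function(block, metadata, factor, levels = NULL,
                            exact_max_n = 8) {
  if (match(block$state, BLOCK_STATES) < match("imputed", BLOCK_STATES))
    stop("wilcoxon_screen requires state 'imputed' or later; block '",
         block$name, "' is '", block$state, "'")
  gr <- split_groups(block, metadata, factor, levels)
  m <- block$matrix
  res <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[gr$g1, j]
    y <- m[gr$g2, j]
    use_exact <- min(length(x), length(y)) <= exact_max_n &&
      !any(duplicated(c(x, y)))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                         correct = TRUE))
    c(unname(ht$statistic), min(1, ht$p.value), mean(x), mean(y))
  }, numeric(4))
  univariate_table(block, stat = res[1, ], p = res[2, ], m1 = res[3, ],
                   m2 = res[4, ], levels = gr$levels, statistic_name = "U")
}

#' Welch two-sample t screen
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom per
#' feature, intended for (e.g. genus-level) relative-abundance tables.
#' Degenerate features where both groups have zero variance get `p = 1`
#' when the means are equal and `p = 0` otherwise, flagged in the
#' `degenerate` column.
#'
#' @inheritParams wilcoxon_screen
#' @return a `univariate_table` with Welch `t` statistics.
#' @export
welch_screen <- function(block, metadata, factor, levels = NULL) {
  gr <- split_groups(block, metadata, factor, levels)
  m <- block$matrix
  res <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[gr$g1, j]
    y <- m[gr$g2, j]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      equal <- isTRUE(all.equal(mean(x), mean(y)))
      return(c(if (equal) 0 else Inf, if (equal) 1 else 0,
               mean(x), mean(y), 1))
    }
    ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
    c(unname(ht$statistic), ht$p.value, mean(x), mean(y), 0)
  }, numeric(5))
  univariate_table(block, stat = res[1, ], p = res[2, ], m1 = res[3, ],
                   m2 = res[4, ], levels = gr$levels, statistic_name = "t",
                   degenerate = res[5, ] == 1)
}

#' Top-k row-normalized heatmap matrix
#'
#' Selects the features with `p < alpha` (raw p by default, matching the
#' "top significantly modulated" convention; set `use_q = TRUE` to gate on
#' BH q instead), keeps the `k` smallest, and returns a features x samples
#' matrix with every row independently scaled to zero mean and unit
#' variance, plus a deterministic average-linkage/Euclidean hierarchical
#' clustering row order.
#'
#' @param table a `univariate_table` from a screen on `block`.
#' @param block the `omics_block` supplying the intensities to display.
#' @param k maximum number of features (default 50).
#' @param alpha significance gate on the raw p (or q), default 0.05.
#' @param use_q gate on BH q instead of raw p.
#' @return list with `matrix` (row-normalized, row-ordered by clustering),
#'   `row_order` (feature ids in display order), `col_order` (sample ids),
#'   `selected` (the selection table rows). Zero passing features yields an
#'   empty matrix with a warning.
#' @export
top_k_heatmap_matrix <- function(table, block, k = 50, alpha = 0.05,
                                 use_q = FALSE) {
  stopifnot(inherits(table, "univariate_table"))
  crit <- if (use_q) table$q else table$p
  pass <- which(crit < alpha)
  if (length(pass) == 0) {
    warning("no feature passes ", if (use_q) "q" else "p", " < ", alpha)
    return(list(matrix = matrix(0, 0, nrow(block$matrix),
                                dimnames = list(NULL, block$sample_ids)),
                row_order = character(0), col_order = block$sample_ids,
                selected = table[0, ]))
  }
  pass <- pass[order(table$p[pass])]
  pass <- utils::head(pass, k)
  ids <- table$feature_id[pass]
  m <- t(block$matrix[, ids, drop = FALSE])   # features x samples
  mu <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  sds[sds == 0] <- 1
  m <- sweep(sweep(m, 1, mu, "-"), 1, sds, "/")
  row_order <- seq_len(nrow(m))
  if (nrow(m) >= 3) {
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    row_order <- hc$order
  }
  m <- m[row_order, , drop = FALSE]
  list(matrix = m, row_order = rownames(m), col_order = colnames(m),
       selected = table[pass[row_order], ])
}

#' Render a heatmap matrix to PNG
#'
#' Minimal base-graphics rendering of [top_k_heatmap_matrix()] output; the
#' matrix itself (the reproducible artifact) should be written as CSV.
#'
#' @param hm result of [top_k_heatmap_matrix()].
#' @param path output PNG path.
#' @export
render_heatmap <- function(hm, path) {
  if (nrow(hm$matrix) == 0) {
    warning("empty heatmap matrix; nothing rendered")
    return(invisible(NULL))
  }
  grDevices::png(path, width = 900, height = 200 + 14 * nrow(hm$matrix))
  on.exit(grDevices::dev.off())
  m <- hm$matrix[rev(seq_len(nrow(hm$matrix))), , drop = FALSE]
  graphics::par(mar = c(6, 10, 2, 1))
  graphics::image(t(m), axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"))
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rownames(m), las = 2, cex.axis = 0.6)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.7)
  invisible(path)
}

#' Write a univariate table as TSV
#' @param table a `univariate_table`.
#' @param path output path.
#' @export
write_univariate_table <- function(table, path) {
  utils::write.table(format(as.data.frame(table), digits = 15), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
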