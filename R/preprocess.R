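#' Prevalence filter
#'
#' Keeps features observed (non-missing and non-zero) in at least
#' `min_prevalence` of the samples. Low-prevalence features carry mostly
#' limit-of-detection censoring and would make the column minimum used by
#' [impute_censored()] meaningless.
#'
#' @param block an `omics_block` in state `"raw"`.
#' @param min_prevalence required fraction of observed entries, in
#'   \eqn{[0, 1]}; the boundary is inclusive. Default 0.5.
#' @return the filtered block, state `"filtered"`. Dropped feature ids are
#'   attached as attribute `"dropped_features"` and reported via `message()`.
#' @export
filter_features <- function(block, min_prevalence = 0.5) {
  stopifnot(is.numeric(min_prevalence), length(min_prevalence) == 1,
            min_prevalence >= 0, min_prevalence <= 1)
  m <- block$matrix
  prevalence <- colMeans(!is.na(m) & m != 0)
  keep <- prevalence >= min_prevalence
  if (!any(keep))
    stop("prevalence filter at ", min_prevalence,
         " would drop every feature of block '", block$name, "'")
  dropped <- block$feature_ids[!keep]
  if (length(dropped) > 0)
    message("filter_features: dropping ", length(dropped),
            " feature(s) from '", block$name, "': ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  block$matrix <- m[, keep, drop = FALSE]
  block$feature_ids <- block$feature_ids[keep]
  block <- advance_state(block, "filtered", "raw")
  attr(block, "dropped_features") <- dropped
  block
}

#' Per-sample median normalization
#'
#' Divides every entry by the median intensity of its sample, so that
#' inter-sample loading/injection differences cancel. Because zeros in MS
#' feature tables are censoring artifacts rather than measurements, the
#' median is by default taken over the positive non-missing entries of the
#' sample; zeros stay zero and missing stays missing.
#'
#' @param block an `omics_block` in state `"filtered"`.
#' @param median_over `"positive"` (default) or `"all"` (median over all
#'   non-missing entries, zeros included).
#' @return the normalized block, state `"median_normalized"`; each sample's
#'   median of positive entries equals 1 afterwards (in `"positive"` mode).
#' @export
median_normalize <- function(block, median_over = c("positive", "all")) {
  median_over <- match.arg(median_over)
  m <- block$matrix
  meds <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    x <- if (median_over == "positive") x[!is.na(x) & x > 0] else x[!is.na(x)]
    if (length(x) == 0 || all(x == 0)) NA_real_ else stats::median(x)
  }, numeric(1))
  if (any(is.na(meds) | meds <= 0))
    stop("sample(s) with no positive entries in block '", block$name, "': ",
         paste(block$sample_ids[is.na(meds) | meds <= 0], collapse = ", "))
  block <- set_block_matrix(block, m / meds)
  advance_state(block, "median_normalized", "filtered")
}

#' Impute censored (zero or missing) entries
#'
#' Replaces every missing or exactly-zero entry of column \eqn{j} by
#' \eqn{u \cdot m_j / 5}, where \eqn{m_j} is the smallest non-zero value of
#' that column and \eqn{u \sim \mathrm{Uniform}(0, 1]} from a seeded
#' generator, emulating small below-limit-of-detection intensities. The
#' half-open interval guarantees strictly positive output so the
#' downstream log10 is defined. Deterministic for a fixed seed; the global
#' RNG state is left untouched.
#'
#' @param block an `omics_block` in state `"median_normalized"`.
#' @param seed integer seed (mandatory: the step is stochastic and must be
#'   reproducible).
#' @return the imputed block, state `"imputed"`, strictly positive.
#' @export
impute_censored <- function(block, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("impute_censored() requires a single integer 'seed'")
  m <- block$matrix
  no_signal <- vapply(seq_len(ncol(m)), function(j)
    all(is.na(m[, j]) | m[, j] == 0), logical(1))
  if (any(no_signal))
    stop("column(s) with no non-zero entries in block '", block$name,
         "' (run filter_features first): ",
         paste(block$feature_ids[no_signal], collapse = ", "))
  m <- with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      target <- is.na(col) | col == 0
      if (any(target)) {
        mj <- min(col[!is.na(col) & col > 0])
        u <- 1 - stats::runif(sum(target))   # Uniform(0, 1]
        m[target, j] <- u * mj / 5
      }
    }
    m
  })
  block <- set_block_matrix(block, m)
  advance_state(block, "imputed", "median_normalized")
}

## Internal: evaluate `expr` under a private RNG stream, restoring the
## caller's .Random.seed (or its absence) afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Base-10 logarithm transform
#'
#' @param block an `omics_block` in state `"imputed"` (strictly positive;
#'   a non-positive entry signals that imputation was skipped and is a hard
#'   error).
#' @return the transformed block, state `"log10"`.
#' @export
log10_transform <- function(block) {
  m <- block$matrix
  if (any(is.na(m)) || any(m <= 0))
    stop("log10_transform requires strictly positive, complete data; ",
         "block '", block$name, "' has non-positive or missing entries ",
         "(was impute_censored skipped?)")
  block <- set_block_matrix(block, log10(m))
  advance_state(block, "log10", "imputed")
}

#' Autoscale (unit-variance scale) every feature
#'
#' Centers each column to mean zero and scales to unit variance (sample
#' standard deviation, denominator \eqn{n - 1}). Constant columns are
#' centered and left at zero with a warning.
#'
#' @param block an `omics_block` in state `"log10"` or `"epo"`.
#' @return the autoscaled block, state `"autoscaled"`.
#' @export
autoscale <- function(block) {
  block <- advance_state(block, "autoscaled", c("log10", "epo"))
  m <- block$matrix
  mu <- colMeans(m)
  m <- sweep(m, 2, mu, "-")
  sds <- apply(m, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("constant column(s) in block '", block$name,
            "' left at zero after centering: ",
            paste(block$feature_ids[const], collapse = ", "))
    sds[const] <- 1
  }
  set_block_matrix(block, sweep(m, 2, sds, "/"))
}

#' Run the per-block preprocessing chain
#'
#' Convenience wrapper: prevalence filter, per-sample median normalization
#' and censored-value imputation (the stages univariate screening runs on),
#' optionally followed by log10.
#'
#' @inheritParams filter_features
#' @inheritParams impute_censored
#' @param log10 also apply [log10_transform()]? Default `TRUE`.
#' @return the processed block.
#' @export
preprocess_block <- function(block, seed, min_prevalence = 0.5,
                             log10 = TRUE) {
  block <- filter_features(block, min_prevalence)
  block <- median_normalize(block)
  block <- impute_censored(block, seed)
  if (log10) block <- log10_transform(block)
  block
}
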