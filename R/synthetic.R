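#' Simulation configuration
#'
#' Describes a synthetic multiblock cohort with the structure the fusion
#' analysis assumes: a shared latent sample score carrying a group effect,
#' a nuisance latent tied to a second factor, per-block signal strengths,
#' log-normal MS intensity scales and limit-of-detection censoring.
#'
#' Defaults emulate a four-block stool metabolomics/lipidomics design on a
#' genotype (AKR/SAMP) x treatment (vehicle/RED) cohort with unbalanced
#' cell sizes 3/4/8/8, an age nuisance factor, and shared-signal strengths
#' (1.0, 0.7, 0.4, 0.1) across blocks.
#'
#' @param n_per_group integer vector of group cell sizes, recycled over the
#'   crossed design cells.
#' @param group_factors named list of factor levels crossed to form the
#'   design (each cell gets its own sample count).
#' @param effect_factor factor carrying the group effect on the shared
#'   latent score.
#' @param effect_size difference in latent-score means between the two
#'   levels of `effect_factor` (latent noise is standard normal).
#' @param nuisance_factor,nuisance_levels extra factor (assigned
#'   alternately, so roughly balanced across groups) driving the nuisance
#'   latent.
#' @param nuisance_strength per-block weight of the nuisance latent
#'   (scalar or one per block).
#' @param blocks data.frame with columns `name`, `n_features`,
#'   `shared_signal_strength`, `noise_sd`.
#' @param affected_fraction fraction of each block's features loading on
#'   the shared latent score.
#' @param censor_quantile per-feature fraction of lowest intensities set
#'   to zero (limit-of-detection censoring), in \eqn{[0, 0.5]}.
#' @param intensity_location,intensity_scale location/scale (log10 units)
#'   of the per-feature baseline intensity.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(3, 4, 8, 8),
                       group_factors = list(genotype = c("AKR", "SAMP"),
                                            treatment = c("vehicle", "RED")),
                       effect_factor = "genotype",
                       effect_size = 2,
                       nuisance_factor = "age",
                       nuisance_levels = c("5w", "15w"),
                       nuisance_strength = 0.5,
                       blocks = data.frame(
                         name = c("metabolomics_pos", "metabolomics_neg",
                                  "lipidomics_pos", "lipidomics_neg"),
                         n_features = c(150, 120, 100, 80),
                         shared_signal_strength = c(1.0, 0.7, 0.4, 0.1),
                         noise_sd = 0.3),
                       affected_fraction = 0.3,
                       censor_quantile = 0.1,
                       intensity_location = 5,
                       intensity_scale = 1,
                       seed = 1) {
  stopifnot(all(n_per_group >= 1),
            censor_quantile >= 0, censor_quantile <= 0.5,
            all(blocks$n_features >= 1),
            all(blocks$shared_signal_strength >= 0),
            all(blocks$noise_sd > 0),
            effect_factor %in% names(group_factors),
            affected_fraction > 0, affected_fraction <= 1)
  if (anyDuplicated(blocks$name)) stop("block names must be unique")
  if (length(group_factors[[effect_factor]]) != 2)
    stop("effect_factor must have exactly 2 levels")
  blocks$nuisance_strength <- rep(nuisance_strength,
                                  length.out = nrow(blocks))
  structure(list(n_per_group = n_per_group, group_factors = group_factors,
                 effect_factor = effect_factor, effect_size = effect_size,
                 nuisance_factor = nuisance_factor,
                 nuisance_levels = nuisance_levels, blocks = blocks,
                 affected_fraction = affected_fraction,
                 censor_quantile = censor_quantile,
                 intensity_location = intensity_location,
                 intensity_scale = intensity_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multiblock dataset with ground truth
#'
#' Per sample i, a shared latent score
#' \eqn{t_i = \mathrm{effect}_i + N(0, 1)} and a nuisance latent
#' \eqn{u_i = \mathrm{nuisance\ level\ effect}_i + N(0, 0.2^2)}. Per block
#' b, the log10-intensity matrix is
#' \deqn{L_b = 1 \mu_b^\top + s_b\, t\, p_b^\top + \nu_b\, u\, r_b^\top
#'   + E_b,}
#' with sparse shared loadings \eqn{p_b} (standard-normal on an
#' `affected_fraction` support), a dense unit-norm nuisance direction
#' \eqn{r_b} orthogonalized against \eqn{p_b} and scaled to
#' \eqn{\|p_b\|}, i.i.d. noise \eqn{E_b}, and per-feature log-normal
#' baselines \eqn{\mu_b}. Intensities are \eqn{10^{L_b}}; finally the
#' lowest `censor_quantile` of each feature's values is set to exactly
#' zero, emulating limit-of-detection censoring.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a `multiblock_dataset`, blocks in state
#'   `"raw"`) and `truth`: latents `t` and `u`, per-block loadings
#'   `p`/`r`, per-block `affected` feature ids, and the block strength
#'   vector `s`.
#' @export
simulate_multiblock <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    cells <- expand.grid(config$group_factors, stringsAsFactors = FALSE)
    sizes <- rep(config$n_per_group, length.out = nrow(cells))
    factors <- cells[rep(seq_len(nrow(cells)), sizes), , drop = FALSE]
    n <- nrow(factors)
    sample_ids <- sprintf("S%02d", seq_len(n))
    factors[[config$nuisance_factor]] <-
      config$nuisance_levels[(seq_len(n) %% length(config$nuisance_levels)) + 1]
    rownames(factors) <- NULL
    metadata <- sample_metadata(sample_ids, factors)

    eff_lv <- config$group_factors[[config$effect_factor]]
    g <- ifelse(factors[[config$effect_factor]] == eff_lv[2], 0.5, -0.5)
    t_lat <- config$effect_size * g + stats::rnorm(n)
    nu_lv2 <- config$nuisance_levels[2]
    u_lat <- ifelse(factors[[config$nuisance_factor]] == nu_lv2, 0.5, -0.5) +
      stats::rnorm(n, sd = 0.2)

    blocks <- list()
    truth_p <- truth_r <- affected <- list()
    for (b in seq_len(nrow(config$blocks))) {
      spec <- config$blocks[b, ]
      nf <- spec$n_features
      fid <- sprintf("%s_f%04d", spec$name, seq_len(nf))
      n_aff <- max(1L, round(config$affected_fraction * nf))
      support <- sort(sample.int(nf, n_aff))
      p <- numeric(nf)
      p[support] <- stats::rnorm(n_aff)
      r <- stats::rnorm(nf)
      if (sum(p^2) > 0) r <- r - p * sum(r * p) / sum(p^2)
      r <- r / sqrt(sum(r^2)) * sqrt(sum(p^2))   # comparable scale to p
      mu <- stats::rnorm(nf, config$intensity_location,
                         config$intensity_scale)
      L <- matrix(mu, n, nf, byrow = TRUE) +
        spec$shared_signal_strength * tcrossprod(t_lat, p) +
        spec$nuisance_strength * tcrossprod(u_lat, r) +
        matrix(stats::rnorm(n * nf, sd = spec$noise_sd), n, nf)
      X <- 10^L
      if (config$censor_quantile > 0) {
        for (j in seq_len(nf)) {
          thr <- stats::quantile(X[, j], config$censor_quantile,
                                 names = FALSE)
          X[X[, j] < thr, j] <- 0
        }
      }
      dimnames(X) <- list(sample_ids, fid)
      blocks[[spec$name]] <- omics_block(X, name = spec$name)
      names(p) <- names(r) <- fid
      truth_p[[spec$name]] <- p
      truth_r[[spec$name]] <- r
      affected[[spec$name]] <- fid[support]
    }
    dataset <- suppressWarnings(align_blocks(blocks, metadata))
    truth <- list(t = stats::setNames(t_lat, sample_ids),
                  u = stats::setNames(u_lat, sample_ids),
                  p = truth_p, r = truth_r, affected = affected,
                  s = stats::setNames(config$blocks$shared_signal_strength,
                                      config$blocks$name))
    list(dataset = dataset, truth = truth)
  })
}

#' Evaluate a fitted result against simulation ground truth
#'
#' For a `comdim_result`: the absolute correlation between component-1
#' scores and the true latent `t`, and the Kendall tau between component-1
#' saliences and the true per-block strengths. For a `univariate_table`:
#' sensitivity and false-discovery proportion of the `q < alpha` screen
#' against the truly affected features of that block.
#'
#' @param result a `comdim_result` or `univariate_table`.
#' @param truth the `truth` element of [simulate_multiblock()]'s output.
#' @param alpha discovery threshold on BH q for the univariate case.
#' @return named list of metrics.
#' @export
truth_eval <- function(result, truth, alpha = 0.05) {
  if (inherits(result, "comdim_result")) {
    if (!identical(result$sample_ids, names(truth$t)))
      stop("sample ids of result and ground truth do not match")
    tau <- if (length(unique(truth$s[result$block_names])) > 1)
      stats::cor(result$saliences[, 1], truth$s[result$block_names],
                 method = "kendall")
    else NA_real_
    list(score_cor = abs(stats::cor(result$scores[, 1], truth$t)),
         salience_tau = tau)
  } else if (inherits(result, "univariate_table")) {
    block <- attr(result, "block")
    if (!block %in% names(truth$affected))
      stop("block '", block, "' not present in ground truth")
    disc <- result$feature_id[result$q < alpha]
    aff <- truth$affected[[block]]
    list(n_discoveries = length(disc),
         sensitivity = if (length(aff)) mean(aff %in% disc) else NA_real_,
         fdp = if (length(disc)) mean(!disc %in% aff) else NA_real_)
  } else stop("unsupported result type")
}

#' Write a simulated dataset to disk
#'
#' Writes one CSV per block, the metadata TSV, and a ground-truth JSON —
#' the on-disk layout [run_pipeline()] consumes.
#'
#' @param sim output of [simulate_multiblock()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of file paths (blocks, metadata, truth).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(sim$dataset$blocks, function(b) {
    p <- file.path(dir, paste0(b$name, ".csv"))
    write_feature_table(b, p, id_header = "sample_id")
    p
  })
  md_path <- file.path(dir, "metadata.tsv")
  write_sample_metadata(sim$dataset$metadata, md_path)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(t = as.list(sim$truth$t), u = as.list(sim$truth$u),
         affected = sim$truth$affected, s = as.list(sim$truth$s)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(blocks = paths, metadata = md_path, truth = truth_path))
}
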