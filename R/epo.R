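#' Build an interference matrix for EPO from a nuisance factor
#'
#' External Parameter Orthogonalization needs a matrix D whose row space
#' spans the detrimental variation. When the nuisance is a known sample
#' grouping (age, cage, batch, ...), the standard recipe is the matrix of
#' per-level feature means, centered on the grand mean of the levels: its
#' leading singular vectors are the feature-space directions along which
#' the nuisance levels differ.
#'
#' @param block an `omics_block` in state `"log10"`.
#' @param metadata a `sample_metadata` covering the block's samples.
#' @param nuisance_factor metadata factor name with >= 2 levels; every
#'   level must have at least one sample.
#' @return numeric matrix, levels x features, with level names as rownames.
#' @export
build_interference_matrix <- function(block, metadata, nuisance_factor) {
  if (block$state != "log10")
    stop("interference matrix is built on log10 data; block '", block$name,
         "' is in state '", block$state, "'")
  f <- get_factor(metadata, nuisance_factor)[block$sample_ids]
  if (any(is.na(f)))
    stop("metadata does not cover every sample of block '", block$name, "'")
  levels <- sort(unique(f))
  D <- t(vapply(levels, function(lv)
    colMeans(block$matrix[f == lv, , drop = FALSE]),
    numeric(ncol(block$matrix))))
  D <- sweep(D, 2, colMeans(D), "-")
  rownames(D) <- levels
  colnames(D) <- block$feature_ids
  D
}

#' Fit an External Parameter Orthogonalization model
#'
#' Column-centers the interference matrix `D`, takes its first `k` right
#' singular vectors as an orthonormal basis `V` of the detrimental
#' subspace, and implies the projector \eqn{P = I - V V^\top} applied by
#' [apply_epo()].
#'
#' @param D interference matrix (rows: interference observations or
#'   nuisance-level means; columns: features).
#' @param k number of detrimental components to remove (>= 0).
#' @param source free-text description of how `D` was built, kept for
#'   provenance.
#' @return an object of class `epo_model` with fields `k`, `loadings`
#'   (features x k, orthonormal columns), `feature_ids`, `source`.
#' @export
fit_epo <- function(D, k, source = "user-supplied interference matrix") {
  D <- as.matrix(D)
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k == round(k))
  feature_ids <- colnames(D)
  Dc <- sweep(D, 2, colMeans(D), "-")
  if (k == 0) {
    V <- matrix(0, nrow = ncol(D), ncol = 0)
  } else {
    if (k > min(dim(D)))
      stop("k = ", k, " exceeds the dimensions of D (", nrow(D), " x ",
           ncol(D), ")")
    sv <- svd(Dc, nu = 0, nv = min(dim(Dc)))
    rank <- sum(sv$d > max(dim(Dc)) * .Machine$double.eps * max(sv$d, 0))
    if (k > rank)
      stop("k = ", k, " exceeds the rank of the centered interference ",
           "matrix; achievable rank is ", rank)
    V <- sv$v[, seq_len(k), drop = FALSE]
  }
  rownames(V) <- feature_ids
  if (k > 0) colnames(V) <- paste0("EPO", seq_len(k))
  structure(list(k = as.integer(k), loadings = V, feature_ids = feature_ids,
                 source = source),
            class = "epo_model")
}

#' @export
print.epo_model <- function(x, ...) {
  cat(sprintf("<epo_model> k = %d detrimental component(s), %d features\n",
              x$k, nrow(x$loadings)))
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Apply an EPO model to a block
#'
#' Projects the block onto the orthogonal complement of the detrimental
#' subspace: \eqn{X \leftarrow X (I - V V^\top)}. A `k = 0` model is the
#' identity; the projection is idempotent and a Frobenius contraction.
#'
#' @param block an `omics_block` in state `"log10"`.
#' @param model an `epo_model` whose feature ids match the block's.
#' @return the corrected block, state `"epo"`.
#' @export
apply_epo <- function(block, model) {
  stopifnot(inherits(model, "epo_model"))
  if (!is.null(model$feature_ids) &&
      !identical(model$feature_ids, block$feature_ids))
    stop("feature ids of block '", block$name,
         "' do not match the EPO model's")
  if (nrow(model$loadings) != ncol(block$matrix))
    stop("EPO model has ", nrow(model$loadings), " features; block '",
         block$name, "' has ", ncol(block$matrix))
  m <- block$matrix
  if (model$k > 0) {
    V <- model$loadings
    m <- m - (m %*% V) %*% t(V)
  }
  block <- set_block_matrix(block, m)
  advance_state(block, "epo", "log10")
}

#' Write / read an EPO model as a loadings CSV plus JSON sidecar
#'
#' @param model an `epo_model`.
#' @param prefix path prefix; writes `<prefix>_loadings.csv` and
#'   `<prefix>.json`.
#' @return `read_epo_model()` returns the `epo_model`.
#' @export
write_epo_model <- function(model, prefix) {
  loadings_path <- paste0(prefix, "_loadings.csv")
  utils::write.csv(as.data.frame(model$loadings), loadings_path,
                   row.names = TRUE)
  jsonlite::write_json(
    list(k = model$k, source = model$source,
         loadings_file = basename(loadings_path)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epo_model
#' @export
read_epo_model <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(prefix, "_loadings.csv"), row.names = 1,
                         check.names = FALSE)
  V <- as.matrix(tab)
  structure(list(k = as.integer(meta$k), loadings = V,
                 feature_ids = rownames(V), source = meta$source),
            class = "epo_model")
}
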