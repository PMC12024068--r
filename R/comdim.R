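#' Frobenius-norm block scaling
#'
#' Divides each block matrix by its Frobenius norm so every block enters
#' the fusion with total variance one, preventing large blocks from
#' dominating the common components.
#'
#' @param dataset a `multiblock_dataset` whose blocks are in state
#'   `"autoscaled"`.
#' @return the dataset with every block at unit Frobenius norm, state
#'   `"block_scaled"`.
#' @export
frobenius_scale <- function(dataset) {
  map_blocks(dataset, function(b) {
    fn <- sqrt(sum(b$matrix^2))
    if (fn == 0)
      stop("block '", b$name, "' has zero Frobenius norm")
    b <- set_block_matrix(b, b$matrix / fn)
    advance_state(b, "block_scaled", "autoscaled")
  })
}

#' ComDim / CCSWA multiblock fusion
#'
#' Common Components and Specific Weights Analysis extracts components
#' shared across several sample-matched data blocks. For each component it
#' alternates between (i) the dominant eigenvector `q` of the salience-
#' weighted sum of block association matrices
#' \eqn{W = \sum_b \lambda_b X_b X_b^\top} and (ii) the salience update
#' \eqn{\lambda_b = q^\top X_b X_b^\top q}, until the saliences stabilize;
#' all blocks are then deflated by `q` and the next component is
#' extracted. The salience \eqn{\lambda_b \ge 0} quantifies how strongly
#' block `b` expresses that component.
#'
#' @param dataset a `multiblock_dataset` in state `"block_scaled"` (use
#'   [frobenius_scale()] first so blocks are comparable).
#' @param n_components number of common components, at most
#'   `n_samples - 1`. Default 2 (a 2-D score plot).
#' @param tol convergence tolerance on the max absolute salience change.
#' @param max_iter maximum iterations per component; non-convergence is
#'   recorded (and warned), not fatal.
#' @param score_scaling `"sqrt_eigenvalue"` (default; score columns carry
#'   the square root of the fused eigenvalue, so distances in score plots
#'   reflect explained variation) or `"unit"` (unit-norm scores).
#' @return an object of class `comdim_result`:
#' \describe{
#'   \item{scores}{samples x components matrix; each column's sign is fixed
#'     so its largest-magnitude entry is positive.}
#'   \item{saliences}{blocks x components matrix of non-negative weights.}
#'   \item{block_loadings}{named list, per block a features x components
#'     matrix \eqn{X_b^\top q}.}
#'   \item{explained}{per component, fraction of the total fused variance
#'     \eqn{\sum_b \|X_b\|_F^2} captured (\eqn{\sum_b \lambda_b} / total).}
#'   \item{convergence}{data.frame with iterations, final delta,
#'     convergence flag per component, plus the per-iteration objective
#'     \eqn{\sum_b \lambda_b^2} trajectories as attribute `"objective"`.}
#' }
#' @export
fit_comdim <- function(dataset, n_components = 2, tol = 1e-10,
                       max_iter = 200,
                       score_scaling = c("sqrt_eigenvalue", "unit")) {
  score_scaling <- match.arg(score_scaling)
  states <- vapply(dataset$blocks, `[[`, "", "state")
  if (!all(states == "block_scaled"))
    stop("fit_comdim requires all blocks in state 'block_scaled' ",
         "(run frobenius_scale); got: ", paste(unique(states), collapse = ", "))
  X <- lapply(dataset$blocks, `[[`, "matrix")
  B <- length(X)
  n <- nrow(X[[1]])
  block_names <- names(dataset$blocks)
  stopifnot(n_components >= 1)
  if (n_components > n - 1)
    stop("n_components = ", n_components, " exceeds n_samples - 1 = ", n - 1)

  total_var <- sum(vapply(X, function(x) sum(x^2), numeric(1)))
  scores <- matrix(0, n, n_components,
                   dimnames = list(rownames(X[[1]]), paste0("CC", seq_len(n_components))))
  saliences <- matrix(0, B, n_components,
                      dimnames = list(block_names, colnames(scores)))
  loadings <- lapply(X, function(x)
    matrix(0, ncol(x), n_components, dimnames = list(colnames(x), colnames(scores))))
  conv <- data.frame(component = seq_len(n_components), iterations = 0L,
                     delta = NA_real_, converged = NA)
  objective <- vector("list", n_components)

  for (comp in seq_len(n_components)) {
    W <- lapply(X, tcrossprod)
    lambda <- rep(1, B)
    obj <- numeric(0)
    delta <- Inf
    iter <- 0L
    q <- NULL
    mu <- NA_real_
    while (iter < max_iter) {
      iter <- iter + 1L
      Wg <- Reduce(`+`, Map(`*`, W, lambda))
      eg <- eigen(Wg, symmetric = TRUE)
      q <- eg$vectors[, 1]
      mu <- eg$values[1]
      new_lambda <- vapply(W, function(w) drop(crossprod(q, w %*% q)),
                           numeric(1))
      delta <- max(abs(new_lambda - lambda))
      lambda <- new_lambda
      obj <- c(obj, sum(lambda^2))
      if (delta < tol) break
    }
    converged <- delta < tol
    if (!converged)
      warning("component ", comp, " did not converge in ", max_iter,
              " iterations (delta = ", format(delta), ")")
    i_max <- which.max(abs(q))
    if (q[i_max] < 0) q <- -q
    scores[, comp] <- if (score_scaling == "sqrt_eigenvalue")
      q * sqrt(max(mu, 0)) else q
    saliences[, comp] <- lambda
    for (b in seq_len(B)) loadings[[b]][, comp] <- drop(crossprod(X[[b]], q))
    X <- lapply(X, function(x) x - q %*% crossprod(q, x))
    conv$iterations[comp] <- iter
    conv$delta[comp] <- delta
    conv$converged[comp] <- converged
    objective[[comp]] <- obj
  }
  explained <- colSums(saliences) / total_var
  names(explained) <- colnames(scores)
  attr(conv, "objective") <- objective
  structure(list(scores = scores, saliences = saliences,
                 block_loadings = loadings, explained = explained,
                 convergence = conv, total_variance = total_var,
                 score_scaling = score_scaling,
                 sample_ids = rownames(scores), block_names = block_names),
            class = "comdim_result")
}

#' @export
print.comdim_result <- function(x, ...) {
  cat(sprintf("<comdim_result> %d common component(s), %d block(s), %d samples\n",
              ncol(x$scores), nrow(x$saliences), nrow(x$scores)))
  tab <- rbind(x$saliences, explained = x$explained)
  print(round(tab, 4))
  invisible(x)
}

#' Salience table
#'
#' Blocks x components table of saliences with the per-component explained
#' variance fraction appended as the last row.
#'
#' @param result a `comdim_result`.
#' @param path optional CSV path to write the table to.
#' @return a data.frame (invisibly when `path` is given).
#' @export
salience_table <- function(result, path = NULL) {
  stopifnot(inherits(result, "comdim_result"))
  tab <- as.data.frame(rbind(result$saliences,
                             explained_fraction = result$explained))
  tab <- cbind(block = rownames(tab), tab)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(format(tab, digits = 15), path, row.names = FALSE,
                     quote = FALSE)
    return(invisible(tab))
  }
  tab
}
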