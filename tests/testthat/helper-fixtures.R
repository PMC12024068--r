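# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Forge a block at an arbitrary pipeline state (tests of mid-pipeline ops
# construct their inputs directly rather than replaying the whole chain).
make_block <- function(m, name = "blk", state = "raw") {
  omics_block(as.matrix(m), name = name, state = state)
}

# A multiblock dataset from a named list of matrices, all at one state.
make_dataset <- function(mats, state = "block_scaled",
                         factors = NULL) {
  n <- nrow(mats[[1]])
  ids <- sprintf("S%02d", seq_len(n))
  blocks <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    rownames(m) <- ids
    if (is.null(colnames(m))) colnames(m) <- paste0(nm, "_f", seq_len(ncol(m)))
    make_block(m, name = nm, state = state)
  })
  names(blocks) <- names(mats)
  if (is.null(factors))
    factors <- data.frame(group = rep(c("A", "B"), length.out = n))
  md <- sample_metadata(ids, factors)
  structure(list(blocks = blocks, metadata = md),
            class = "multiblock_dataset")
}

# Brute-force two-sided Mann-Whitney p by enumerating all C(n1+n2, n1)
# group assignments of the observed values (independent of pwilcox).
wilcox_enum_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  us <- utils::combn(nx + ny, nx, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Observed U statistic of group x (first group), for oracle comparisons.
wilcox_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Two-group metadata and a one-feature block for univariate tests; ids
# match omics_block's defaults for rowname-less matrices ("s1", "s2", ...).
md2g <- function(n1, n2) {
  ids <- paste0("s", seq_len(n1 + n2))
  sample_metadata(ids, data.frame(grp = rep(c("g1", "g2"), c(n1, n2))))
}

block_from_groups <- function(x, y) {
  m <- matrix(c(x, y), ncol = 1, dimnames = list(NULL, "f1"))
  make_block(m, "u", state = "imputed")
}

# Random strictly-positive raw block with planted zeros/missing.
random_raw_block <- function(n = 8, p = 12, seed = 1, zero_frac = 0.1,
                             na_frac = 0.05, name = "raw") {
  set.seed(seed)
  m <- matrix(10^rnorm(n * p, 3, 1), n, p,
              dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:p)))
  idx <- sample(length(m), round(zero_frac * length(m)))
  m[idx] <- 0
  idx2 <- sample(setdiff(seq_along(m), idx), round(na_frac * length(m)))
  m[idx2] <- NA
  make_block(m, name = name)
}
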