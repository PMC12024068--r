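#' @keywords internal
"_PACKAGE"

## Processing states, in pipeline order. Transitions may skip states but
## never go backwards.
BLOCK_STATES <- c("raw", "filtered", "median_normalized", "imputed",
                  "log10", "epo", "autoscaled", "block_scaled")

#' Construct an omics block
#'
#' An `omics_block` is one platform's samples x features intensity matrix
#' (e.g. lipidomics in positive ionization mode) together with its block
#' name and a processing-state flag that enforces the preprocessing order.
#'
#' @param matrix numeric matrix, samples in rows, features in columns.
#'   `NA` entries denote missing (censored) measurements.
#' @param name block identifier, e.g. `"lipidomics_pos"`.
#' @param sample_ids,feature_ids unique character vectors; default to
#'   dimnames of `matrix`.
#' @param state processing state, one of
#'   `r paste0('"', BLOCK_STATES, '"', collapse = ", ")`.
#' @return an object of class `omics_block`.
#' @export
omics_block <- function(matrix, name,
                        sample_ids = rownames(matrix),
                        feature_ids = colnames(matrix),
                        state = "raw") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(matrix)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(matrix)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  state <- match.arg(state, BLOCK_STATES)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in block '", name, "': ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids in block '", name, "': ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (nrow(matrix) != length(sample_ids) || ncol(matrix) != length(feature_ids))
    stop("matrix shape does not match id lengths in block '", name, "'")
  if (state == "raw" && any(matrix[!is.na(matrix)] < 0))
    stop("raw intensities must be non-negative in block '", name, "'")
  dimnames(matrix) <- list(sample_ids, feature_ids)
  structure(
    list(name = as.character(name), matrix = matrix,
         sample_ids = sample_ids, feature_ids = feature_ids,
         state = state),
    class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block '%s'> %d samples x %d features, state = %s\n",
              x$name, nrow(x$matrix), ncol(x$matrix), x$state))
  n_na <- sum(is.na(x$matrix))
  n_zero <- sum(x$matrix == 0, na.rm = TRUE)
  cat(sprintf("  missing: %d, zeros: %d\n", n_na, n_zero))
  invisible(x)
}

## Internal: enforce the forward-only state machine.
advance_state <- function(block, new_state, allowed_from) {
  if (!block$state %in% allowed_from)
    stop("block '", block$name, "' is in state '", block$state,
         "'; this step requires state ",
         paste0("'", allowed_from, "'", collapse = " or "),
         " (pipeline order: ", paste(BLOCK_STATES, collapse = " -> "), ")")
  if (match(new_state, BLOCK_STATES) <= match(block$state, BLOCK_STATES))
    stop("state transition '", block$state, "' -> '", new_state,
         "' would move backwards in the pipeline")
  block$state <- new_state
  block
}

## Internal: replace a block's matrix keeping ids consistent.
set_block_matrix <- function(block, m) {
  dimnames(m) <- list(block$sample_ids, block$feature_ids)
  block$matrix <- m
  block
}

#' Construct sample metadata
#'
#' @param sample_ids unique character vector; its order is the canonical
#'   sample order for all downstream outputs.
#' @param factors data.frame of categorical factors (one row per sample),
#'   e.g. genotype (AKR/SAMP), age (5w/15w), treatment (vehicle/RED).
#' @return an object of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_ids, factors) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in metadata: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != length(sample_ids))
    stop("factors must have one row per sample")
  factors[] <- lapply(factors, as.character)
  rownames(factors) <- sample_ids
  structure(list(sample_ids = sample_ids, factors = factors),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("<sample_metadata> %d samples, factors: %s\n",
              length(x$sample_ids), paste(names(x$factors), collapse = ", ")))
  invisible(x)
}

## Internal: fetch one factor as a character vector, validating levels.
get_factor <- function(metadata, factor, min_levels = 2L) {
  if (!factor %in% names(metadata$factors))
    stop("factor '", factor, "' not present in metadata (available: ",
         paste(names(metadata$factors), collapse = ", "), ")")
  f <- metadata$factors[[factor]]
  names(f) <- metadata$sample_ids
  if (length(unique(f)) < min_levels)
    stop("factor '", factor, "' has fewer than ", min_levels, " levels")
  f
}

#' Read a delimited feature table into an omics block
#'
#' Reads a CSV/TSV intensity table with one header row of ids and one id
#' column. Empty cells, `"NA"` and `"NaN"` parse as missing; exact zeros
#' are kept as zeros (both are later handled by [impute_censored()], but
#' they must survive parsing distinguishably).
#'
#' @param path file path; delimiter auto-detected from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `delim` is given.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"features_in_rows"`.
#' @param name block name; defaults to the file name without extension.
#' @param delim field delimiter override.
#' @param missing_values character sentinels parsed as missing.
#' @return an `omics_block` in state `"raw"`.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows",
                                               "features_in_rows"),
                               name = NULL, delim = NULL,
                               missing_values = c("", "NA", "NaN")) {
  orientation <- match.arg(orientation)
  if (is.null(delim))
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, sep = delim, header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE,
                           na.strings = character(0))   # sentinels handled below
  row_ids <- raw[[1]]
  col_ids <- colnames(raw)[-1]
  if (anyDuplicated(row_ids))
    stop("duplicate id in '", path, "': ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  if (anyDuplicated(col_ids))
    stop("duplicate id in '", path, "': ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  is_missing <- body %in% missing_values
  dim(is_missing) <- dim(body)
  num <- suppressWarnings(as.numeric(body))
  dim(num) <- dim(body)
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell in '", path, "' at row '", row_ids[bad[1, 1]],
         "', column '", col_ids[bad[1, 2]], "': \"",
         body[bad[1, 1], bad[1, 2]], "\"")
  num[is_missing] <- NA_real_
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "features_in_rows") num <- t(num)
  omics_block(num, name = name)
}

#' Write an omics block to a delimited file
#'
#' Inverse of [read_feature_table()]: values round-trip to printed
#' precision (15 significant digits) and missing entries are written as
#' empty cells.
#'
#' @inheritParams read_feature_table
#' @param block an `omics_block`.
#' @param id_header header for the id column.
#' @export
write_feature_table <- function(block, path,
                                orientation = c("samples_in_rows",
                                                "features_in_rows"),
                                delim = NULL, id_header = "id") {
  orientation <- match.arg(orientation)
  if (is.null(delim))
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  m <- block$matrix
  if (orientation == "features_in_rows") m <- t(m)
  chr <- formatC(m, digits = 15, format = "g")
  chr[is.na(m)] <- ""
  dim(chr) <- dim(m)
  out <- cbind(rownames(m), chr)
  header <- paste(c(id_header, colnames(m)), collapse = delim)
  lines <- c(header, apply(out, 1, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' TSV with a header line; the first column must be `sample_id`, remaining
#' columns are categorical factors.
#'
#' @param path file path.
#' @return a `sample_metadata` object.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (colnames(tab)[1] != "sample_id")
    stop("metadata file must have 'sample_id' as its first column")
  sample_metadata(tab$sample_id, tab[, -1, drop = FALSE])
}

#' Write a sample-metadata table
#' @param metadata a `sample_metadata` object.
#' @param path file path (TSV).
#' @export
write_sample_metadata <- function(metadata, path) {
  tab <- cbind(sample_id = metadata$sample_ids, metadata$factors)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align blocks on a shared sample index
#'
#' Restricts every block to the samples common to all blocks, ordered as in
#' the metadata (the canonical order). Samples missing from any block are
#' dropped with a warning naming them.
#'
#' @param blocks list of `omics_block` objects with unique names.
#' @param metadata a `sample_metadata` covering every block's samples.
#' @return a `multiblock_dataset`: list with elements `blocks` (named list)
#'   and `metadata` (subset to the shared samples).
#' @export
align_blocks <- function(blocks, metadata) {
  stopifnot(length(blocks) >= 1)
  nms <- vapply(blocks, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("block names must be unique: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  for (b in blocks) {
    extra <- setdiff(b$sample_ids, metadata$sample_ids)
    if (length(extra) > 0)
      stop("block '", b$name, "' contains samples absent from metadata: ",
           paste(extra, collapse = ", "))
  }
  shared <- metadata$sample_ids
  for (b in blocks) shared <- intersect(shared, b$sample_ids)
  if (length(shared) == 0)
    stop("no sample is present in every block: empty intersection")
  shared <- metadata$sample_ids[metadata$sample_ids %in% shared]
  universe <- unique(c(metadata$sample_ids,
                       unlist(lapply(blocks, `[[`, "sample_ids"))))
  dropped <- setdiff(universe, shared)
  if (length(dropped) > 0)
    warning("dropping samples missing from at least one block: ",
            paste(dropped, collapse = ", "))
  blocks <- lapply(blocks, function(b) {
    b$matrix <- b$matrix[shared, , drop = FALSE]
    b$sample_ids <- shared
    b
  })
  names(blocks) <- nms
  keep <- metadata$sample_ids %in% shared
  md <- sample_metadata(metadata$sample_ids[keep],
                        metadata$factors[keep, , drop = FALSE])
  structure(list(blocks = blocks, metadata = md),
            class = "multiblock_dataset")
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat(sprintf("<multiblock_dataset> %d blocks, %d shared samples\n",
              length(x$blocks), length(x$metadata$sample_ids)))
  for (b in x$blocks)
    cat(sprintf("  %-18s %4d features  [%s]\n", b$name, ncol(b$matrix),
                b$state))
  invisible(x)
}

## Internal: apply a block-level function to every block of a dataset.
map_blocks <- function(dataset, f, ...) {
  dataset$blocks <- lapply(dataset$blocks, f, ...)
  dataset
}
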