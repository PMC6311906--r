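#' Construct a per-mark peak matrix
#'
#' Binary N x T matrix: rows are cell types, columns are genome bins; entry
#' (i, j) is 1 iff cell type i has a peak of this mark on bin j.
#'
#' @param mat binary matrix (cells x bins).
#' @param mark mark identifier.
#' @param cells character vector of cell type names (row order is shared
#'   across all marks).
#' @return object of class `peak_matrix`.
#' @export
peak_matrix <- function(mat, mark, cells = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(cells)) stop2("cell names are required")
  if (!is_binary(mat)) stop2("peak matrix must be binary")
  storage.mode(mat) <- "integer"
  rownames(mat) <- cells
  structure(list(mark = mark, cells = cells, mat = mat),
            class = "peak_matrix")
}

#' Specificity transform of a peak matrix
#'
#' For each bin, if no more than `s` cell types carry a peak of the mark, the
#' column is kept as-is (those cell types are "specific" there); otherwise
#' the column is zeroed. All-zero columns are kept so the model sees the
#' whole genome.
#'
#' @param P a [peak_matrix].
#' @param s maximum number of cell types allowed to share a bin (default 2).
#' @return object of class `specificity_matrix` with fields `mark`, `cells`,
#'   `mat`, `s`.
#' @export
specificity_transform <- function(P, s = 2) {
  stopifnot(inherits(P, "peak_matrix"))
  N <- nrow(P$mat)
  if (s < 1 || s > N) stop2("s must be between 1 and the number of cells")
  mat <- P$mat
  drop <- colSums(mat) > s
  if (any(drop)) mat[, drop] <- 0L
  structure(list(mark = P$mark, cells = P$cells, mat = mat, s = s),
            class = "specificity_matrix")
}

#' Stack per-mark specificity matrices into the HMM observation matrix
#'
#' Rows are cell-mark combinations, mark-major: all cells of mark 1, then
#' all cells of mark 2, and so on. Columns are genome bins.
#'
#' @param S_list list of [specificity_transform] results in fixed mark order.
#' @return object of class `observation_matrix`: list with the binary matrix
#'   `mat` (R x T, R = M*N) and `row_labels`, a data frame of (mark, cell)
#'   per row.
#' @export
stack_observations <- function(S_list) {
  stopifnot(length(S_list) >= 1)
  cells <- S_list[[1]]$cells
  T_ <- ncol(S_list[[1]]$mat)
  for (S in S_list) {
    if (!identical(S$cells, cells))
      stop2("cell order mismatch in mark '", S$mark, "'")
    if (ncol(S$mat) != T_)
      stop2("bin count mismatch in mark '", S$mark, "'")
  }
  mat <- do.call(rbind, lapply(S_list, `[[`, "mat"))
  row_labels <- data.frame(
    mark = rep(vapply(S_list, `[[`, "", "mark"), each = length(cells)),
    cell = rep(cells, times = length(S_list)),
    stringsAsFactors = FALSE)
  rownames(mat) <- paste(row_labels$mark, row_labels$cell, sep = ":")
  structure(list(mat = mat, row_labels = row_labels),
            class = "observation_matrix")
}

#' Split an observation matrix back into per-mark matrices
#'
#' Inverse of [stack_observations] using the recorded row labels.
#'
#' @param O an `observation_matrix`.
#' @return named list of binary cells x bins matrices, one per mark.
#' @export
unstack_observations <- function(O) {
  marks <- unique(O$row_labels$mark)
  lapply(stats::setNames(marks, marks), function(m) {
    rows <- which(O$row_labels$mark == m)
    sub <- O$mat[rows, , drop = FALSE]
    rownames(sub) <- O$row_labels$cell[rows]
    sub
  })
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat(sprintf("observation_matrix: %d cell-mark rows x %d bins (%d marks, %d cells)\n",
              nrow(x$mat), ncol(x$mat), length(unique(x$row_labels$mark)),
              length(unique(x$row_labels$cell))))
  invisible(x)
}

#' Serialize an observation matrix per chromosome in the binarized dialect
#'
#' One file per chromosome named `<name>_<chrom>_binary.txt`, column labels
#' `mark:cell`.
#'
#' @param O an `observation_matrix`.
#' @param bins a [genome_bins] with `n_total == ncol(O$mat)`.
#' @param dir output directory.
#' @param name sample name for the header (default "obs").
#' @return character vector of written paths.
#' @export
write_observations <- function(O, bins, dir, name = "obs") {
  stopifnot(ncol(O$mat) == bins$n_total)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- chrom_bin_index(bins)
  labels <- paste(O$row_labels$mark, O$row_labels$cell, sep = ":")
  paths <- character(0)
  for (ch in bins$chrom_order) {
    m <- t(O$mat[, idx[[ch]], drop = FALSE])
    colnames(m) <- labels
    p <- file.path(dir, sprintf("%s_%s_binary.txt", name, ch))
    write_binarized(m, name, ch, p)
    paths <- c(paths, p)
  }
  paths
}

#' Read per-chromosome binarized files back into an observation matrix
#'
#' @param paths files written by [write_observations], in chromosome order.
#' @return an `observation_matrix`.
#' @export
read_observations <- function(paths) {
  parts <- lapply(paths, read_binarized)
  labels <- colnames(parts[[1]]$mat)
  for (p in parts)
    if (!identical(colnames(p$mat), labels))
      stop2("inconsistent column labels across binarized files")
  mat <- t(do.call(rbind, lapply(parts, `[[`, "mat")))
  split_lab <- strsplit(labels, ":", fixed = TRUE)
  row_labels <- data.frame(
    mark = vapply(split_lab, `[`, "", 1),
    cell = vapply(split_lab, `[`, "", 2),
    stringsAsFactors = FALSE)
  rownames(mat) <- labels
  structure(list(mat = mat, row_labels = row_labels),
            class = "observation_matrix")
}
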