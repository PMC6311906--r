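#' Tile a genome into fixed-width bins
#'
#' Divides each chromosome into non-overlapping `bin_size`-bp windows
#' (0-based, half-open), left to right. The last bin of a chromosome may be
#' truncated. Bins carry a single global 1-based index, chromosome-major in
#' the order of `chrom_sizes`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp, or a
#'   two-column data frame (chrom, size).
#' @param bin_size bin width in bp (default 200).
#' @return An object of class `genome_bins` with elements `chrom_order`,
#'   `chrom_sizes`, `bin_size`, `n_bins` (per chromosome), `n_total`, and
#'   `offset` (0-based global bin offset per chromosome).
#' @examples
#' bins <- genome_bins(c(chr1 = 1000, chr2 = 450))
#' bins$n_bins   # chr1: 5 bins, chr2: 3 bins (last truncated to 50 bp)
#' @export
genome_bins <- function(chrom_sizes, bin_size = 200) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.numeric(chrom_sizes[[2]])
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop2("chrom_sizes must be named by chromosome")
  if (any(chrom_sizes <= 0)) stop2("chromosome sizes must be positive")
  if (bin_size <= 0) stop2("bin_size must be positive")
  n_bins <- as.integer(ceiling(chrom_sizes / bin_size))
  offset <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(offset) <- names(chrom_sizes)
  structure(list(
    chrom_order = names(chrom_sizes),
    chrom_sizes = chrom_sizes,
    bin_size    = bin_size,
    n_bins      = stats::setNames(n_bins, names(chrom_sizes)),
    n_total     = sum(n_bins),
    offset      = offset
  ), class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d chromosomes, %d bins of %d bp\n",
              length(x$chrom_order), x$n_total, as.integer(x$bin_size)))
  invisible(x)
}

#' Read a chromosome-sizes table
#'
#' Two-column whitespace/tab separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of sizes.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop2("chrom sizes file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop2("chrom sizes file must have two columns")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

## Global 1-based bin index of position `pos` (0-based bp) on `chrom`.
coord_to_bin <- function(bins, chrom, pos) {
  idx <- match(chrom, bins$chrom_order)
  if (anyNA(idx)) stop2("unknown chromosome: ",
                        paste(unique(chrom[is.na(idx)]), collapse = ", "))
  unname(bins$offset[idx] + floor(pos / bins$bin_size) + 1L)
}

## data.frame(chrom, start, end) for global bin indices (all bins by default).
bin_coords <- function(bins, index = seq_len(bins$n_total)) {
  chrom_id <- findInterval(index - 1L, c(0L, cumsum(bins$n_bins))[-1],
                           left.open = TRUE) + 1L
  chrom <- bins$chrom_order[chrom_id]
  local <- index - bins$offset[chrom_id] - 1L
  start <- local * bins$bin_size
  end <- pmin(start + bins$bin_size, bins$chrom_sizes[chrom_id])
  data.frame(chrom = chrom, start = start, end = end)
}

## List of global column index vectors, one per chromosome, in order.
chrom_bin_index <- function(bins) {
  lapply(stats::setNames(bins$chrom_order, bins$chrom_order), function(ch) {
    off <- bins$offset[[ch]]
    seq.int(off + 1L, off + bins$n_bins[[ch]])
  })
}
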