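#' Bin aligned reads by extended-fragment midpoint
#'
#' Each read is extended `ext_len` bp from its 5' end in the 3' direction
#' (leftward for minus-strand reads), clipped to the chromosome, and assigned
#' to the bin containing the midpoint of the extended interval.
#'
#' @param reads data frame with columns `chrom`, `pos` (0-based 5' position)
#'   and `strand` (`+`/`-`).
#' @param bins a [genome_bins] object.
#' @param ext_len extension length in bp (default 200).
#' @param cell,mark optional track identifiers stored on the result.
#' @return A `binned_track`: list with `cell`, `mark`, `values` (integer
#'   counts, one per global bin) and `bins`. The number of reads rejected for
#'   unknown chromosomes is stored in attribute `n_rejected`.
#' @export
bin_reads <- function(reads, bins, ext_len = 200, cell = NA_character_,
                      mark = NA_character_) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(reads)))
  if (nrow(reads) > 0 && any(reads$pos < 0))
    stop2("negative read positions are not allowed")
  if (nrow(reads) > 0 && !all(reads$strand %in% c("+", "-")))
    stop2("strand must be '+' or '-'")
  known <- reads$chrom %in% bins$chrom_order
  n_rej <- sum(!known)
  if (n_rej > 0) {
    warning(sprintf("rejected %d read(s) on unknown chromosomes", n_rej),
            call. = FALSE)
    reads <- reads[known, , drop = FALSE]
  }
  values <- integer(bins$n_total)
  if (nrow(reads) > 0) {
    size <- bins$chrom_sizes[match(reads$chrom, bins$chrom_order)]
    start <- ifelse(reads$strand == "+", reads$pos, reads$pos - ext_len)
    end <- start + ext_len
    start <- pmax(start, 0)
    end <- pmin(end, size)
    mid <- floor((start + end) / 2)
    idx <- coord_to_bin(bins, reads$chrom, mid)
    tab <- tabulate(idx, nbins = bins$n_total)
    values <- as.integer(tab)
  }
  structure(list(cell = cell, mark = mark, values = values, bins = bins),
            class = "binned_track", n_rejected = n_rej)
}

#' Merge replicate count tracks by summation
#'
#' @param tracks list of `binned_track` objects over the same bins.
#' @return a single `binned_track` with summed counts.
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  out <- tracks[[1]]
  for (tr in tracks[-1]) {
    stopifnot(length(tr$values) == length(out$values))
    out$values <- out$values + tr$values
  }
  out
}

#' Call peaks against a Poisson background
#'
#' The background rate lambda is the mean count over all bins genome-wide.
#' The cutoff is the smallest count c with P(X >= c) < alpha under
#' X ~ Poisson(lambda); a bin is a peak iff its count >= c.
#'
#' @param track a `binned_track` of integer counts (or a plain count vector).
#' @param alpha Poisson tail threshold (default 1e-4).
#' @return integer 0/1 vector over bins, with attributes `lambda` and
#'   `cutoff`.
#' @export
call_peaks_poisson <- function(track, alpha = 1e-4) {
  counts <- if (inherits(track, "binned_track")) track$values else track
  if (length(counts) < 1) stop2("track has no bins")
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("counts must be non-negative integers")
  if (alpha <= 0 || alpha >= 1) stop2("alpha must be in (0, 1)")
  lambda <- mean(counts)
  if (lambda == 0) {
    warning("all-zero track: no peaks called", call. = FALSE)
    return(structure(integer(length(counts)), lambda = 0, cutoff = NA_integer_))
  }
  cutoff <- 0L
  ## P(X >= c) = ppois(c - 1, lower.tail = FALSE); scan up from 0
  while (stats::ppois(cutoff - 1L, lambda, lower.tail = FALSE) >= alpha)
    cutoff <- cutoff + 1L
  structure(as.integer(counts >= cutoff), lambda = lambda, cutoff = cutoff)
}

#' Binarize a real-valued signal track at a fixed threshold
#'
#' Intended for per-bin averages of -log10(P) signal tracks; the boundary is
#' inclusive (signal >= threshold is a peak). NaN/NA values count as 0.
#'
#' @param track a `binned_track` with real values (or a numeric vector).
#' @param threshold binarization threshold (default 2).
#' @return integer 0/1 vector over bins.
#' @export
binarize_signal <- function(track, threshold = 2) {
  values <- if (inherits(track, "binned_track")) track$values else track
  bad <- !is.finite(values)
  if (any(bad)) {
    message(sprintf("binarize_signal: %d non-finite value(s) treated as 0",
                    sum(bad)))
    values[bad] <- 0
  }
  as.integer(values >= threshold)
}

#' Average bedGraph-style interval signal onto genome bins
#'
#' Per-bin value is the length-weighted mean of overlapping interval values;
#' uncovered base pairs contribute 0. Overlapping input intervals sum.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open coordinates).
#' @param bins a [genome_bins] object.
#' @param cell,mark optional identifiers for the resulting track.
#' @return a `binned_track` with real values.
#' @export
average_signal_to_bins <- function(intervals, bins, cell = NA_character_,
                                   mark = NA_character_) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (nrow(intervals) > 0) {
    if (any(intervals$start < 0) || any(intervals$end < intervals$start))
      stop2("intervals must have 0 <= start <= end")
    if (!all(intervals$chrom %in% bins$chrom_order))
      stop2("intervals on unknown chromosomes")
  }
  bs <- bins$bin_size
  acc <- numeric(bins$n_total)
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    s <- intervals$start[i]
    e <- min(intervals$end[i], bins$chrom_sizes[[ch]])
    if (e <= s) next
    b0 <- floor(s / bs)
    b1 <- floor((e - 1) / bs)
    b <- b0:b1
    ov <- pmin((b + 1) * bs, e) - pmax(b * bs, s)
    gi <- bins$offset[[ch]] + b + 1L
    acc[gi] <- acc[gi] + ov * intervals$value[i]
  }
  coords <- bin_coords(bins)
  width <- coords$end - coords$start
  structure(list(cell = cell, mark = mark, values = acc / width, bins = bins),
            class = "binned_track")
}

#' Read a BED-like interval file
#'
#' Accepts >= 3 tab/whitespace separated columns (chrom, start, end,
#' optionally name, score, strand). Coordinates are 0-based half-open.
#' Malformed lines raise an error naming the offending line.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop2("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  parts <- strsplit(lines, "[ \t]+")
  ncols <- lengths(parts)
  bad <- which(ncols < 3)
  if (length(bad))
    stop2("malformed BED line ", bad[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end < start)
  if (length(bad))
    stop2("malformed BED line ", bad[1], ": invalid coordinates")
  out <- data.frame(chrom = vapply(parts, `[`, "", 1), start = start,
                    end = end, stringsAsFactors = FALSE)
  if (all(ncols >= 4)) out$name <- vapply(parts, `[`, "", 4)
  if (all(ncols >= 5))
    out$score <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 5)))
  if (all(ncols >= 6)) out$strand <- vapply(parts, `[`, "", 6)
  out
}

#' Rasterize intervals onto bins by >= 1 bp overlap
#'
#' @param intervals data frame with `chrom`, `start`, `end`.
#' @param bins a [genome_bins] object.
#' @return integer 0/1 vector over global bins.
#' @export
intervals_to_bin_vector <- function(intervals, bins) {
  v <- integer(bins$n_total)
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    if (!ch %in% bins$chrom_order)
      stop2("interval on unknown chromosome: ", ch)
    s <- max(0, intervals$start[i])
    e <- min(intervals$end[i], bins$chrom_sizes[[ch]])
    if (e <= s) next
    b0 <- floor(s / bins$bin_size)
    b1 <- floor((e - 1) / bins$bin_size)
    v[bins$offset[[ch]] + (b0:b1) + 1L] <- 1L
  }
  v
}

#' Read BED peaks directly as a bin-level 0/1 vector
#'
#' @inheritParams intervals_to_bin_vector
#' @param path BED file path.
#' @export
read_peaks_bed <- function(path, bins) {
  intervals_to_bin_vector(read_bed(path), bins)
}

#' Write intervals as BED
#'
#' Records are sorted by (chrom in input factor order of `chrom`, start).
#'
#' @param intervals data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`, `itemRgb` columns.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[order(match(intervals$chrom, unique(intervals$chrom)),
                        intervals$start), , drop = FALSE]
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand", "thickStart", "thickEnd",
                  "itemRgb")) {
    if (extra %in% names(df)) cols <- c(cols, extra) else break
  }
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a bin-level 0/1 vector back to maximal intervals
#'
#' @param v integer 0/1 vector over global bins.
#' @param bins a [genome_bins] object.
#' @return data frame `chrom`, `start`, `end` of maximal runs of 1s.
#' @export
bin_vector_to_intervals <- function(v, bins) {
  stopifnot(length(v) == bins$n_total)
  res <- list()
  for (ch in bins$chrom_order) {
    idx <- chrom_bin_index(bins)[[ch]]
    r <- rle(as.integer(v[idx]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values == 1L)
    if (length(on))
      res[[ch]] <- data.frame(
        chrom = ch,
        start = (starts[on] - 1) * bins$bin_size,
        end = pmin(ends[on] * bins$bin_size, bins$chrom_sizes[[ch]]))
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## ---- binarized text dialect -------------------------------------------
## Interchange format per (sample, chromosome):
##   line 1: sample<TAB>chrom
##   line 2: tab-separated column labels
##   then one 0/1 row per bin.

#' Write a binarized matrix in the two-header-line text dialect
#'
#' @param mat integer 0/1 matrix, bins in rows, tracks in columns.
#' @param sample sample identifier for the first header line.
#' @param chrom chromosome name for the first header line.
#' @param path output path.
#' @export
write_binarized <- function(mat, sample, chrom, path) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sample, chrom, sep = "\t"), con)
  writeLines(paste(colnames(mat), collapse = "\t"), con)
  utils::write.table(mat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the binarized text dialect
#'
#' @param path file written by [write_binarized].
#' @return list with `sample`, `chrom` and the integer matrix `mat`
#'   (bins x tracks, labelled columns).
#' @export
read_binarized <- function(path) {
  if (!file.exists(path)) stop2("binarized file not found: ", path)
  header <- readLines(path, n = 2)
  if (length(header) < 2) stop2("binarized file truncated: ", path)
  meta <- strsplit(header[1], "\t")[[1]]
  if (length(meta) != 2)
    stop2("malformed binarized header line 1 (expect sample<TAB>chrom)")
  labels <- strsplit(header[2], "\t")[[1]]
  mat <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                     skip = 2))
  if (ncol(mat) != length(labels))
    stop2("binarized file column count does not match label row")
  dimnames(mat) <- list(NULL, labels)
  if (!is_binary(mat)) stop2("binarized file contains non 0/1 values")
  storage.mode(mat) <- "integer"
  list(sample = meta[1], chrom = meta[2], mat = mat)
}
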