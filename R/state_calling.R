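#' Specific cell-mark combinations of one state by the max-gap rule
#'
#' Emission probabilities are sorted decreasingly and the largest drop
#' between consecutive values located; `p_s` is the probability just above
#' that drop. A combination is specific iff its probability is `>= p_s` and
#' strictly `> p0`. Ties at the maximal gap resolve to the earliest gap
#' (fewer, stronger combinations); for a flat profile every gap is 0, so
#' `p_s` is the maximum and the `p0` floor governs.
#'
#' @param probs length-R emission probability vector of one state.
#' @param row_labels data frame (mark, cell) describing the R entries.
#' @param p0 absolute floor on specific emissions (default 0.3).
#' @return list with `combinations` (data frame mark, cell, prob; possibly
#'   zero rows) and `p_s`.
#' @export
specific_combinations <- function(probs, row_labels, p0 = 0.3) {
  R <- length(probs)
  if (R < 2) stop2("need at least 2 cell-mark combinations")
  stopifnot(nrow(row_labels) == R)
  q <- sort(probs, decreasing = TRUE)
  gaps <- q[-R] - q[-1]
  jstar <- which.max(gaps)          # ties -> smallest j
  p_s <- q[jstar]
  sel <- probs >= p_s & probs > p0
  comb <- data.frame(mark = row_labels$mark[sel], cell = row_labels$cell[sel],
                     prob = probs[sel], stringsAsFactors = FALSE)
  comb <- comb[order(-comb$prob), , drop = FALSE]
  rownames(comb) <- NULL
  list(combinations = comb, p_s = p_s)
}

#' Classify HMM states as specific or non-specific and name them
#'
#' Applies [specific_combinations] to every emission row. A state with at
#' least one specific combination is a specific state; its name is the
#' unique cell types of its combinations (ordered as in the observation
#' cell order) joined by "_", with an ordinal suffix distinguishing states
#' sharing the same cell set (ascending state index). States with no
#' specific combination are named with the prefix "Non". States whose
#' specific combinations include the designated control track are flagged
#' (`contains_wce`): specificity in a whole-cell extract control indicates
#' copy-number or repeat artifacts rather than regulation; such states are
#' reported, not dropped.
#'
#' @param params a fitted [hmm_params].
#' @param row_labels data frame (mark, cell); defaults to
#'   `params$row_labels`.
#' @param p0 absolute emission floor (default 0.3).
#' @param control_mark name of the control track (default `"WCE"`).
#' @return object of class `state_classes`: list with `table` (data frame:
#'   state, name, specific, p_s, cells, contains_wce) and `combinations`
#'   (per-state list of combination data frames), plus `p0`.
#' @export
classify_states <- function(params, row_labels = params$row_labels,
                            p0 = 0.3, control_mark = "WCE") {
  if (is.null(row_labels)) stop2("row_labels are required")
  cell_order <- unique(row_labels$cell)
  K <- params$K
  res <- lapply(seq_len(K), function(k)
    specific_combinations(params$E[k, ], row_labels, p0 = p0))
  cells_of <- lapply(res, function(r) {
    cl <- unique(r$combinations$cell)
    cl[order(match(cl, cell_order))]
  })
  specific <- vapply(res, function(r) nrow(r$combinations) > 0, logical(1))
  base <- ifelse(specific,
                 vapply(cells_of, paste, "", collapse = "_"),
                 "Non")
  ordinal <- stats::ave(seq_len(K), base, FUN = seq_along)
  name <- paste0(base, "_", ordinal)
  tab <- data.frame(
    state = seq_len(K),
    name = name,
    specific = specific,
    p_s = vapply(res, `[[`, numeric(1), "p_s"),
    cells = vapply(cells_of, paste, "", collapse = ","),
    contains_wce = vapply(res, function(r)
      any(r$combinations$mark == control_mark), logical(1)),
    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 combinations = lapply(res, `[[`, "combinations"),
                 p0 = p0),
            class = "state_classes")
}

#' @export
print.state_classes <- function(x, ...) {
  n_spec <- sum(x$table$specific)
  cat(sprintf("state_classes: %d states, %d specific (p0 = %g)\n",
              nrow(x$table), n_spec, x$p0))
  print(x$table[, c("state", "name", "specific", "p_s", "cells")])
  invisible(x)
}

#' Extract CSREs from a decoded state path
#'
#' Run-length encodes the path per chromosome and emits one CSRE per
#' maximal run of each specific state; runs of non-specific states are
#' ignored. Abutting runs of two different specific states yield two CSREs
#' sharing a boundary. Single-bin runs are emitted (no minimum length).
#'
#' @param path a `state_path` from [decode] (or any integer state vector of
#'   length `bins$n_total` wrapped in such an object).
#' @param classes a `state_classes` from [classify_states].
#' @param bins a [genome_bins].
#' @return data frame with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `name` (state name), `state`, `cells`, sorted by
#'   (chromosome order, start).
#' @export
extract_csres <- function(path, classes, bins) {
  states <- if (inherits(path, "state_path")) path$states else path
  stopifnot(length(states) == bins$n_total)
  tab <- classes$table
  spec_states <- tab$state[tab$specific]
  idx <- chrom_bin_index(bins)
  out <- list()
  for (ch in bins$chrom_order) {
    lab <- states[idx[[ch]]]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values %in% spec_states
    if (!any(keep)) next
    st <- r$values[keep]
    out[[ch]] <- data.frame(
      chrom = ch,
      start = (starts[keep] - 1) * bins$bin_size,
      end = pmin(ends[keep] * bins$bin_size, bins$chrom_sizes[[ch]]),
      name = tab$name[st],
      state = st,
      cells = tab$cells[st],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      state = integer(), cells = character()))
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, bins$chrom_order), res$start), ]
  rownames(res) <- NULL
  res
}

#' Per-state CSRE summary statistics
#'
#' @param csres data frame from [extract_csres].
#' @return data frame: `name`, `n` (CSRE count), `median_length` (bp),
#'   `bp_covered`.
#' @export
csre_summary <- function(csres) {
  if (nrow(csres) == 0)
    return(data.frame(name = character(), n = integer(),
                      median_length = numeric(), bp_covered = numeric()))
  len <- csres$end - csres$start
  agg <- lapply(split(len, csres$name), function(l)
    c(n = length(l), median_length = stats::median(l), bp_covered = sum(l)))
  out <- data.frame(name = names(agg), do.call(rbind, agg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$n <- as.integer(out$n)
  out
}

#' Base-pair Jaccard index between two interval sets
#'
#' Intersection bp over union bp, after collapsing each set to its covered
#' base pairs. Used to compare recovered CSREs with a planted truth.
#'
#' @param a,b data frames with `chrom`, `start`, `end`.
#' @return scalar in \[0, 1\] (1 when both sets are empty).
#' @export
csre_jaccard <- function(a, b) {
  chroms <- unique(c(a$chrom, b$chrom))
  to_gr <- function(df) GenomicRanges::reduce(GenomicRanges::GRanges(
    factor(df$chrom, levels = chroms),
    IRanges::IRanges(start = df$start + 1, end = df$end)))
  ga <- to_gr(a)
  gb <- to_gr(b)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) return(1)
  inter / uni
}

#' Write CSREs as BED4 or BED9
#'
#' BED9 assigns each state name a colour from a fixed palette so tracks
#' render consistently in a genome browser.
#'
#' @param csres data frame from [extract_csres].
#' @param path output path.
#' @param format `"bed4"` (default) or `"bed9"`.
#' @export
write_csre_bed <- function(csres, path, format = c("bed4", "bed9")) {
  format <- match.arg(format)
  df <- csres[, c("chrom", "start", "end", "name")]
  if (format == "bed9") {
    states <- sort(unique(csres$name))
    cols <- grDevices::col2rgb(grDevices::hcl.colors(max(length(states), 2),
                                                     "Dark 3")[seq_along(states)])
    rgbs <- apply(cols, 2, paste, collapse = ",")
    df$score <- 0L
    df$strand <- "."
    df$thickStart <- df$start
    df$thickEnd <- df$end
    df$itemRgb <- rgbs[match(csres$name, states)]
  }
  write_bed(df, path)
}

#' Export the emission matrix as a flat table with specific combinations flagged
#'
#' One row per state (named), one column per cell-mark combination; values
#' are emission probabilities, with `*` appended where the combination is
#' specific for that state.
#'
#' @param params a fitted [hmm_params].
#' @param classes a `state_classes`.
#' @param path output TSV path.
#' @export
export_emission_table <- function(params, classes, path) {
  rl <- params$row_labels
  labels <- paste(rl$cell, rl$mark, sep = ".")
  mat <- matrix("", params$K, params$R, dimnames = list(classes$table$name,
                                                        labels))
  for (k in seq_len(params$K)) {
    comb <- classes$combinations[[k]]
    flag <- paste(rl$cell, rl$mark) %in% paste(comb$cell, comb$mark)
    mat[k, ] <- paste0(formatC(params$E[k, ], digits = 4, format = "f"),
                       ifelse(flag, "*", ""))
  }
  utils::write.table(data.frame(state = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
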