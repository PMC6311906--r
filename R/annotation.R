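## Downstream characterization of CSREs: genomic-feature assignment,
## proximal genes, TSS distances, overlap enrichment against repositioned
## null elements, expression specificity and gene-set enrichment.
##
## All public coordinates are 0-based half-open; GRanges (1-based closed)
## are used internally for interval algebra.

FEATURE_PRIORITY <- c("promoter", "utr5", "utr3", "exon", "intron")
PROMOTER_FLANK <- 2000

df_to_gr <- function(df, chroms = NULL) {
  sq <- if (is.null(chroms)) df$chrom else factor(df$chrom, levels = chroms)
  GenomicRanges::GRanges(sq,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read gene models from GTF/GFF or BED12
#'
#' GTF/GFF files are parsed with rtracklayer; exon records define transcript
#' bounds and CDS records (when present) delimit the UTRs. BED12 blocks are
#' exons and the thick range is the CDS. Transcripts can be restricted to an
#' accession prefix (e.g. `"NM"` to keep curated protein-coding models).
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"` or `"bed12"`.
#' @param tx_prefix optional transcript-id prefix filter.
#' @return object of class `gene_models`: list of data frames `transcripts`
#'   (tx_id, gene, chrom, strand, start, end), `exons` and `cds` (tx_id,
#'   chrom, strand, start, end), 0-based half-open.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "gff3", "bed12"),
                             tx_prefix = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("annotation file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gtf = "gtf", gff = "gff3", gff3 = "gff3", bed = "bed12",
                     stop2("cannot guess annotation format from extension: ",
                           path))
  }
  if (format %in% c("gtf", "gff3")) {
    gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf"
                              else "gff3")
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    tx_id <- as.character(md$transcript_id)
    gene <- if (!is.null(md$gene_name)) as.character(md$gene_name)
            else as.character(md$gene_id)
    base <- data.frame(type = type, tx_id = tx_id, gene = gene,
                       chrom = as.character(GenomicRanges::seqnames(gr)),
                       strand = as.character(GenomicRanges::strand(gr)),
                       start = GenomicRanges::start(gr) - 1,
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
    exons <- base[base$type == "exon", , drop = FALSE]
    cds <- base[base$type == "CDS", , drop = FALSE]
    if (nrow(exons) == 0) stop2("no exon records in ", path)
    tx <- do.call(rbind, lapply(split(exons, exons$tx_id), function(e)
      data.frame(tx_id = e$tx_id[1], gene = e$gene[1], chrom = e$chrom[1],
                 strand = e$strand[1], start = min(e$start), end = max(e$end),
                 stringsAsFactors = FALSE)))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- as.character(S4Vectors::mcols(gr)$name)
    tx <- data.frame(tx_id = nm, gene = nm,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start = GenomicRanges::start(gr) - 1,
                     end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
    blocks <- S4Vectors::mcols(gr)$blocks
    exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      data.frame(tx_id = nm[i], gene = nm[i], chrom = tx$chrom[i],
                 strand = tx$strand[i],
                 start = tx$start[i] + IRanges::start(b) - 1,
                 end = tx$start[i] + IRanges::end(b),
                 stringsAsFactors = FALSE)
    }))
    thick <- S4Vectors::mcols(gr)$thick
    cds <- data.frame(tx_id = nm, gene = nm, chrom = tx$chrom,
                      strand = tx$strand,
                      start = IRanges::start(thick) - 1,
                      end = IRanges::end(thick), stringsAsFactors = FALSE)
    cds <- cds[cds$end > cds$start, , drop = FALSE]
  }
  if (!is.null(tx_prefix)) {
    keep <- startsWith(tx$tx_id, tx_prefix)
    tx <- tx[keep, , drop = FALSE]
    exons <- exons[exons$tx_id %in% tx$tx_id, , drop = FALSE]
    cds <- cds[cds$tx_id %in% tx$tx_id, , drop = FALSE]
  }
  rownames(tx) <- rownames(exons) <- NULL
  structure(list(transcripts = tx,
                 exons = exons[, c("tx_id", "chrom", "strand", "start", "end")],
                 cds = cds[, c("tx_id", "chrom", "strand", "start", "end"),
                           drop = FALSE]),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d transcripts, %d genes\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene))))
  invisible(x)
}

## Strand-aware TSS position (0-based bp) per transcript.
tss_positions <- function(genes) {
  tx <- genes$transcripts
  ifelse(tx$strand == "-", tx$end - 1, tx$start)
}

## Promoter = TSS +/- 2000 bp inclusive, rendered half-open, clipped at 0.
promoter_df <- function(genes) {
  tx <- genes$transcripts
  tss <- tss_positions(genes)
  data.frame(chrom = tx$chrom, start = pmax(0, tss - PROMOTER_FLANK),
             end = tss + PROMOTER_FLANK + 1, stringsAsFactors = FALSE)
}

## GRanges per feature class across all transcripts.
feature_ranges <- function(genes) {
  tx <- genes$transcripts
  exons <- genes$exons
  cds <- genes$cds
  prom <- df_to_gr(promoter_df(genes))
  exon_gr <- df_to_gr(exons)
  utr5 <- utr3 <- intron <- list()
  for (i in seq_len(nrow(tx))) {
    id <- tx$tx_id[i]
    ex <- exons[exons$tx_id == id, , drop = FALSE]
    ex_ir <- IRanges::IRanges(ex$start + 1, ex$end)
    gaps <- IRanges::setdiff(IRanges::IRanges(tx$start[i] + 1, tx$end[i]),
                             ex_ir)
    if (length(gaps))
      intron[[length(intron) + 1L]] <- data.frame(
        chrom = tx$chrom[i], start = IRanges::start(gaps) - 1,
        end = IRanges::end(gaps))
    cd <- cds[cds$tx_id == id, , drop = FALSE]
    if (nrow(cd) == 0) next       # non-coding transcript: no UTRs
    cstart <- min(cd$start)
    cend <- max(cd$end)
    left <- IRanges::intersect(ex_ir,
                               IRanges::IRanges(tx$start[i] + 1, cstart))
    right <- IRanges::intersect(ex_ir,
                                IRanges::IRanges(cend + 1, tx$end[i]))
    if (tx$strand[i] == "-") { tmp <- left; left <- right; right <- tmp }
    if (length(left))
      utr5[[length(utr5) + 1L]] <- data.frame(
        chrom = tx$chrom[i], start = IRanges::start(left) - 1,
        end = IRanges::end(left))
    if (length(right))
      utr3[[length(utr3) + 1L]] <- data.frame(
        chrom = tx$chrom[i], start = IRanges::start(right) - 1,
        end = IRanges::end(right))
  }
  from_list <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(df_to_gr(do.call(rbind, lst)))
  }
  list(promoter = GenomicRanges::reduce(prom),
       utr5 = from_list(utr5),
       utr3 = from_list(utr3),
       exon = GenomicRanges::reduce(exon_gr),
       intron = from_list(intron))
}

#' Assign each CSRE to a single genomic feature class
#'
#' Among the feature classes the CSRE overlaps by at least 1 bp across all
#' transcripts, the highest-priority one wins:
#' promoter > 5'UTR > 3'UTR > exon > intron > intergenic.
#'
#' @param csres data frame with `chrom`, `start`, `end`.
#' @param genes a [read_gene_models] result.
#' @return factor of feature classes, one per CSRE.
#' @export
assign_feature <- function(csres, genes) {
  fr <- feature_ranges(genes)
  lv <- c(FEATURE_PRIORITY, "intergenic")
  if (nrow(csres) == 0) return(factor(character(), levels = lv))
  gr <- df_to_gr(csres)
  out <- rep("intergenic", nrow(csres))
  assigned <- logical(nrow(csres))
  for (cl in FEATURE_PRIORITY) {
    if (length(fr[[cl]]) == 0) next
    hit <- IRanges::overlapsAny(gr, fr[[cl]])
    take <- hit & !assigned
    out[take] <- cl
    assigned <- assigned | hit
  }
  factor(out, levels = lv)
}

#' CSRE proximal genes of one specific state
#'
#' A gene qualifies when, for at least one of its transcripts, the union of
#' the state's CSREs restricted to the transcript's promoter-plus-body
#' region contains a contiguous stretch of at least `min_stretch` bp.
#'
#' @param csres CSREs of a single specific state (`chrom`, `start`, `end`).
#' @param genes a [read_gene_models] result.
#' @param min_stretch required contiguous covered length in bp
#'   (default 3000).
#' @return sorted character vector of gene symbols.
#' @export
proximal_genes <- function(csres, genes, min_stretch = 3000) {
  if (nrow(csres) == 0) return(character(0))
  tx <- genes$transcripts
  chroms <- unique(c(csres$chrom, tx$chrom))
  csre_gr <- GenomicRanges::reduce(df_to_gr(csres, chroms))
  prom <- promoter_df(genes)
  region <- GenomicRanges::GRanges(
    factor(tx$chrom, levels = chroms),
    IRanges::IRanges(start = pmin(tx$start, prom$start) + 1,
                     end = pmax(tx$end, prom$end)))
  hits <- vapply(seq_len(nrow(tx)), function(i) {
    cov <- GenomicRanges::intersect(csre_gr, region[i])
    length(cov) > 0 && max(GenomicRanges::width(cov)) >= min_stretch
  }, logical(1))
  sort(unique(tx$gene[hits]))
}

#' Distances from intergenic CSREs to their nearest TSS, with random controls
#'
#' The distance is the bp gap between the nearest TSS and the closest CSRE
#' edge. For every CSRE, `n_random` control elements of the same length are
#' placed uniformly on the same chromosome and measured identically.
#'
#' @param csres data frame with `chrom`, `start`, `end` (intergenic CSREs).
#' @param genes a [read_gene_models] result.
#' @param chrom_sizes named vector of chromosome sizes (bp) for control
#'   placement.
#' @param n_random controls per CSRE (default 1).
#' @param seed RNG seed for control placement.
#' @return list with numeric vectors `true` and `random`; CSREs on
#'   chromosomes without any TSS are skipped (with a message).
#' @export
nearest_tss_distances <- function(csres, genes, chrom_sizes, n_random = 1,
                                  seed = 1) {
  tss <- data.frame(chrom = genes$transcripts$chrom,
                    pos = tss_positions(genes))
  tss_by_chrom <- lapply(split(tss$pos, tss$chrom), sort)
  dist_one <- function(chrom, start, end) {
    p <- tss_by_chrom[[chrom]]
    inside <- any(p >= start & p < end)
    if (inside) return(0)
    left <- p[p < start]
    right <- p[p >= end]
    min(c(if (length(left)) start - max(left),
          if (length(right)) min(right) - (end - 1)))
  }
  has_tss <- csres$chrom %in% names(tss_by_chrom)
  if (any(!has_tss)) {
    message(sprintf("nearest_tss_distances: skipped %d CSRE(s) on chromosomes without a TSS",
                    sum(!has_tss)))
    csres <- csres[has_tss, , drop = FALSE]
  }
  true <- vapply(seq_len(nrow(csres)), function(i)
    dist_one(csres$chrom[i], csres$start[i], csres$end[i]), numeric(1))
  random <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(csres)), function(i) {
      len <- csres$end[i] - csres$start[i]
      size <- chrom_sizes[[csres$chrom[i]]]
      vapply(seq_len(n_random), function(j) {
        s <- floor(stats::runif(1, 0, max(size - len, 1)))
        dist_one(csres$chrom[i], s, s + len)
      }, numeric(1))
    }))
  })
  list(true = true, random = random)
}

#' Peak-overlap enrichment of CSREs against repositioned null elements
#'
#' The observed statistic is the number of CSREs overlapping at least 1 bp
#' of any peak. Each of `n_sim` simulations repositions every CSRE uniformly
#' on its own chromosome (length preserved) and recounts, giving a
#' genome-wide background. Significance is reported both as a one-sample
#' Wilcoxon signed-rank p of (null - observed) against 0 and as the
#' empirical p `(1 + #{null >= observed}) / (n_sim + 1)`.
#'
#' @param csres CSREs of one state (`chrom`, `start`, `end`).
#' @param peaks peak intervals (`chrom`, `start`, `end`).
#' @param chrom_sizes named vector of chromosome sizes in bp.
#' @param n_sim number of null sets (default 1000).
#' @param seed RNG seed.
#' @return object of class `enrichment_result`: `observed`, `null` (length
#'   `n_sim`), `p_empirical`, `p_wilcoxon`, `seed`.
#' @export
overlap_enrichment <- function(csres, peaks, chrom_sizes, n_sim = 1000,
                               seed = 1) {
  if (n_sim < 1) stop2("n_sim must be >= 1")
  peak_gr <- if (nrow(peaks)) GenomicRanges::reduce(df_to_gr(peaks))
             else GenomicRanges::GRanges()
  ## disjoint sorted peaks per chromosome (0-based half-open) so the
  ## resampling loop can count overlaps by boundary bisection
  peak_idx <- local({
    df <- gr_to_df(peak_gr)
    lapply(split(df[c("start", "end")], df$chrom), function(d)
      list(start = d$start[order(d$start)], end = d$end[order(d$start)]))
  })
  count_overlaps <- function(chrom, start, end) {
    hit <- logical(length(start))
    for (ch in unique(chrom)) {
      pk <- peak_idx[[ch]]
      sel <- chrom == ch
      if (is.null(pk)) next
      # peak with the largest start < end; overlap iff its end > start
      i <- findInterval(end[sel] - 1, pk$start)
      hit[sel] <- i >= 1 & pk$end[pmax(i, 1)] > start[sel]
    }
    sum(hit)
  }
  observed <- count_overlaps(csres$chrom, csres$start, csres$end)
  len <- csres$end - csres$start
  size <- unname(chrom_sizes[csres$chrom])
  fixed <- size - len < 1
  if (any(fixed))
    message(sprintf("overlap_enrichment: %d CSRE(s) longer than their chromosome kept in place",
                    sum(fixed)))
  null <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      start <- ifelse(fixed, csres$start,
                      floor(stats::runif(nrow(csres), 0,
                                         pmax(size - len, 1))))
      count_overlaps(csres$chrom, start, start + len)
    }, integer(1))
  })
  p_emp <- (1 + sum(null >= observed)) / (n_sim + 1)
  diffs <- null - observed
  if (all(diffs == 0)) {
    message("overlap_enrichment: degenerate null (all counts equal observed)")
    p_wil <- 1
  } else {
    p_wil <- stats::wilcox.test(diffs, mu = 0, exact = FALSE,
                                correct = FALSE)$p.value
  }
  structure(list(observed = observed, null = null, p_empirical = p_emp,
                 p_wilcoxon = p_wil, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("overlap enrichment: observed %d vs null mean %.2f (n_sim = %d); empirical p = %.4g, Wilcoxon p = %.4g\n",
              x$observed, mean(x$null), length(x$null), x$p_empirical,
              x$p_wilcoxon))
  invisible(x)
}

#' Quantile normalization of an expression matrix
#'
#' Standard rank-mean quantile normalization across columns (ties share the
#' mean of their rank range), so every column ends with the identical sorted
#' value vector.
#'
#' @param expr numeric matrix, genes x cell types.
#' @return normalized matrix with the input dimnames.
#' @export
quantile_normalize <- function(expr) {
  out <- limma::normalizeQuantiles(as.matrix(expr), ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Gene specificity z-scores
#'
#' Per gene, `z = (x - mean) / sd` across cell types with the sample
#' (n - 1) standard deviation. Constant genes get all-zero rows.
#'
#' @param expr numeric matrix, genes x cell types (normalized).
#' @return z-score matrix of the same shape.
#' @export
specificity_zscores <- function(expr) {
  expr <- as.matrix(expr)
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    message(sprintf("specificity_zscores: %d constant gene(s) set to 0",
                    sum(flat)))
    sd[flat] <- 1
  }
  z <- (expr - mu) / sd
  z[flat, ] <- 0
  z
}

#' Two-sample rank-sum comparison
#'
#' Wilcoxon rank-sum (Mann-Whitney) test, two-sided: exact enumeration when
#' both samples have at most 8 untied values, otherwise the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param values_a,values_b numeric samples.
#' @return two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b) {
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && length(values_a) <= 8 && length(values_b) <= 8
  stats::wilcox.test(values_a, values_b, exact = exact,
                     correct = FALSE)$p.value
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: term, description, then member genes, tab
#'   separated.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop2("malformed GMT line ", bad[1])
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, "", 1))
}

#' Gene-set enrichment by one-sided Fisher exact tests
#'
#' Terms are intersected with the universe and filtered to
#' \[`min_size`, `max_size`\] member genes; each surviving term is tested for
#' over-representation of the query by a one-sided Fisher exact test, and
#' p-values are Benjamini-Hochberg corrected across the tested terms of this
#' query.
#'
#' @param query character vector of genes (members outside the universe are
#'   dropped with a message).
#' @param sets named list of gene sets (e.g. from [read_gmt]).
#' @param universe character vector of all genes under consideration.
#' @param min_size,max_size term-size filter after intersection with the
#'   universe (defaults 5 and 500).
#' @return data frame: `term`, `n_term`, `n_overlap`, `p`, `q`,
#'   `overlap_genes` (comma-joined), sorted by p.
#' @export
gene_set_enrichment <- function(query, sets, universe, min_size = 5,
                                max_size = 500) {
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(sprintf("gene_set_enrichment: dropped %d query gene(s) outside the universe",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0)
    return(data.frame(term = character(), n_term = integer(),
                      n_overlap = integer(), p = numeric(), q = numeric(),
                      overlap_genes = character()))
  sets <- lapply(sets, intersect, universe)
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  if (length(sets) == 0)
    return(data.frame(term = character(), n_term = integer(),
                      n_overlap = integer(), p = numeric(), q = numeric(),
                      overlap_genes = character()))
  U <- length(universe)
  res <- lapply(names(sets), function(tm) {
    tset <- sets[[tm]]
    ov <- intersect(query, tset)
    a <- length(ov)
    tab <- matrix(c(a, length(tset) - a,
                    length(query) - a,
                    U - length(tset) - length(query) + a), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, n_term = length(tset), n_overlap = a, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), c("term", "n_term", "n_overlap", "p", "q",
                             "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Cell type-specific peaks by bp-level subtraction
#'
#' For each cell type, removes every base pair covered by any other cell
#' type's peaks and returns the remaining sub-intervals.
#'
#' @param peaks_by_cell named list of peak data frames (`chrom`, `start`,
#'   `end`), one per cell type.
#' @return named list of data frames of the same form.
#' @export
cell_specific_peaks <- function(peaks_by_cell) {
  stopifnot(length(peaks_by_cell) >= 1)
  chroms <- unique(unlist(lapply(peaks_by_cell, function(df) df$chrom)))
  grs <- lapply(peaks_by_cell, function(df)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(df$chrom, levels = chroms),
      IRanges::IRanges(start = df$start + 1, end = df$end))))
  out <- lapply(seq_along(grs), function(i) {
    others <- grs[-i]
    other_union <- if (length(others))
      GenomicRanges::reduce(do.call(c, unname(others)))
    else GenomicRanges::GRanges(factor(character(), levels = chroms),
                                IRanges::IRanges())
    gr_to_df(GenomicRanges::setdiff(grs[[i]], other_union))
  })
  names(out) <- names(peaks_by_cell)
  out
}
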