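## Seeded synthetic multi-cell-type epigenomes with planted specific states.
##
## The generator emulates the structure the model assumes: a background
## state with uniformly low peak probability, plus specific states each
## carrying a small set of planted (cell, mark) combinations with high peak
## probability. Segment lengths are geometric (Markov-consistent); specific
## segments average `mean_seg_bins` bins and background segments
## `bg_mean_seg_bins`, so specific states jointly cover about
## mean_seg / (mean_seg + bg_mean_seg) of the genome.

#' Build a simulation configuration
#'
#' Either supply `true_params` (an [hmm_params]; observations are drawn from
#' it directly) or let the planted-state defaults build one: state 1 is
#' non-specific background at `bg_prob` everywhere; states 2..K each carry
#' planted (cell, mark) pairs at `fg_prob`. By default state k gets one
#' planted pair, cycling through cells and marks, and the last state gets a
#' two-cell pair (when N >= 2 and s >= 2) to exercise shared-state naming.
#'
#' @param N,M,K cell types, marks, hidden states (defaults 4, 3, 4).
#' @param s specificity cap (default 2).
#' @param chrom_lengths named bp lengths (default two 5-Mb chromosomes,
#'   i.e. 50,000 200-bp bins).
#' @param bin_size bin width in bp (default 200).
#' @param cells,marks identifier vectors (defaults `cell1..`, `mark1..`).
#' @param fg_prob,bg_prob planted foreground/background peak probabilities
#'   (defaults 0.9 and 0.05).
#' @param mean_seg_bins mean specific-segment length in bins (default 5,
#'   about 1 kb at 200-bp bins, near the typical sub-kb CSRE scale).
#' @param bg_mean_seg_bins mean background-segment length (default 20).
#' @param cooccur_rate per-bin rate at which one mark is set in every cell
#'   regardless of state, exercising the specificity zeroing path
#'   (default 0.002).
#' @param mu_fg,mu_bg Poisson read rates per peak/background bin for
#'   read-level emission (defaults 50 and 0.5).
#' @param planted optional list, one element per state, each a data frame
#'   (cell, mark) of planted pairs (empty data frame = non-specific state).
#' @param true_params optional [hmm_params] overriding the planted
#'   construction.
#' @param seed root seed (default 1).
#' @return object of class `sim_config`; `$true_params` always holds the
#'   generating [hmm_params] and `$bins` the [genome_bins].
#' @export
sim_config <- function(N = 4, M = 3, K = 4, s = 2,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       bin_size = 200,
                       cells = paste0("cell", seq_len(N)),
                       marks = paste0("mark", seq_len(M)),
                       fg_prob = 0.9, bg_prob = 0.05,
                       mean_seg_bins = 5, bg_mean_seg_bins = 20,
                       cooccur_rate = 0.002,
                       mu_fg = 50, mu_bg = 0.5,
                       planted = NULL, true_params = NULL, seed = 1) {
  stopifnot(N >= 1, M >= 1, K >= 2, s >= 1, s <= N,
            fg_prob > 0, fg_prob < 1, bg_prob > 0, bg_prob < 1,
            all(chrom_lengths > 0), mean_seg_bins >= 1)
  bins <- genome_bins(chrom_lengths, bin_size)
  row_labels <- data.frame(mark = rep(marks, each = N),
                           cell = rep(cells, times = M),
                           stringsAsFactors = FALSE)
  if (is.null(planted) && is.null(true_params)) {
    planted <- vector("list", K)
    planted[[1]] <- data.frame(cell = character(), mark = character())
    for (k in 2:K) {
      ci <- (k - 2) %% N + 1
      mi <- (k - 2) %% M + 1
      cls <- cells[ci]
      if (k == K && N >= 2 && s >= 2)
        cls <- c(cls, cells[ci %% N + 1])
      planted[[k]] <- data.frame(cell = rep(cls, each = 1),
                                 mark = marks[mi],
                                 stringsAsFactors = FALSE)
    }
  }
  if (is.null(true_params)) {
    E <- matrix(bg_prob, K, N * M)
    for (k in seq_len(K)) {
      pl <- planted[[k]]
      if (is.null(pl) || nrow(pl) == 0) next
      for (j in seq_len(nrow(pl))) {
        per_mark <- sum(pl$mark == pl$mark[j])
        if (per_mark > s)
          stop2("state ", k, " plants more than s cells for mark ",
                pl$mark[j])
        r <- (match(pl$mark[j], marks) - 1) * N + match(pl$cell[j], cells)
        E[k, r] <- fg_prob
      }
    }
    stay_bg <- 1 - 1 / bg_mean_seg_bins
    stay_fg <- 1 - 1 / mean_seg_bins
    A <- matrix(0, K, K)
    A[1, 1] <- stay_bg
    A[1, 2:K] <- (1 - stay_bg) / (K - 1)
    for (k in 2:K) {
      A[k, k] <- stay_fg
      A[k, 1] <- 1 - stay_fg
    }
    frac_fg <- mean_seg_bins / (mean_seg_bins + bg_mean_seg_bins)
    pi0 <- c(1 - frac_fg, rep(frac_fg / (K - 1), K - 1))
    true_params <- hmm_params(pi0, A, E, row_labels = row_labels)
  }
  structure(list(N = N, M = M, K = true_params$K, s = s, bins = bins,
                 cells = cells, marks = marks, row_labels = row_labels,
                 fg_prob = fg_prob, bg_prob = bg_prob,
                 cooccur_rate = cooccur_rate, mu_fg = mu_fg, mu_bg = mu_bg,
                 planted = planted, true_params = true_params, seed = seed),
            class = "sim_config")
}

#' Simulate the true hidden state path
#'
#' A Markov chain per chromosome from the configuration's true initial and
#' transition probabilities; a pure function of (config, seed).
#'
#' @param config a [sim_config].
#' @return a `state_path` (truth labels over all bins).
#' @export
simulate_state_path <- function(config) {
  bins <- config$bins
  p <- config$true_params
  states <- with_seed(config$seed, {
    out <- integer(bins$n_total)
    pos <- 1L
    for (ch in bins$chrom_order) {
      Tc <- bins$n_bins[[ch]]
      s <- integer(Tc)
      s[1] <- sample.int(p$K, 1, prob = p$pi)
      t <- 2L
      while (t <= Tc) {
        ## geometric dwell in the current state, then one jump
        stay <- p$A[s[t - 1], s[t - 1]]
        run <- if (stay >= 1) Tc else if (stay > 0)
          stats::rgeom(1, 1 - stay) else 0
        run <- min(run, Tc - t + 1L)
        if (run > 0) {
          s[t:(t + run - 1L)] <- s[t - 1L]
          t <- t + run
        }
        if (t > Tc) break
        others <- p$A[s[t - 1L], ]
        others[s[t - 1L]] <- 0
        s[t] <- if (sum(others) > 0)
          sample.int(p$K, 1, prob = others) else s[t - 1L]
        t <- t + 1L
      }
      out[pos:(pos + Tc - 1L)] <- s
      pos <- pos + Tc
    }
    out
  })
  structure(list(states = states, bins = bins, method = "truth",
                 posterior = NULL),
            class = "state_path")
}

#' Simulate per-mark peak matrices given the truth path
#'
#' Each (cell, mark, bin) is a Bernoulli draw from the generating emission
#' probability of the bin's true state. A small co-occurrence rate
#' additionally sets a mark in every cell at random bins, so downstream
#' specificity zeroing is exercised.
#'
#' @param config a [sim_config].
#' @param path truth `state_path` from [simulate_state_path].
#' @return list of [peak_matrix] objects, one per mark.
#' @export
simulate_peak_matrices <- function(config, path) {
  bins <- config$bins
  E <- config$true_params$E
  T_ <- bins$n_total
  N <- config$N
  with_seed(config$seed + 1L, {
    mats <- lapply(seq_len(config$M), function(m) {
      P <- matrix(0L, N, T_)
      for (i in seq_len(N)) {
        r <- (m - 1) * N + i
        pr <- E[path$states, r]
        P[i, ] <- as.integer(stats::runif(T_) < pr)
      }
      if (config$cooccur_rate > 0) {
        hit <- stats::runif(T_) < config$cooccur_rate
        P[, hit] <- 1L
      }
      peak_matrix(P, mark = config$marks[m], cells = config$cells)
    })
    names(mats) <- config$marks
    mats
  })
}

#' Simulate read records from peak matrices
#'
#' Per (cell, mark) track, each peak bin receives Poisson(`mu_fg`) reads and
#' each background bin Poisson(`mu_bg`); 5' positions are uniform within the
#' bin, strands random. Intended for small toy genomes to exercise
#' [bin_reads] and [call_peaks_poisson] end to end.
#'
#' @param config a [sim_config].
#' @param peak_mats list from [simulate_peak_matrices].
#' @return named list (`cell|mark`) of read data frames
#'   (`chrom`, `pos`, `strand`).
#' @export
simulate_reads <- function(config, peak_mats) {
  bins <- config$bins
  coords <- bin_coords(bins)
  with_seed(config$seed + 2L, {
    out <- list()
    for (m in seq_len(config$M)) {
      P <- peak_mats[[m]]$mat
      for (i in seq_len(config$N)) {
        rate <- ifelse(P[i, ] == 1L, config$mu_fg, config$mu_bg)
        n <- stats::rpois(length(rate), rate)
        rep_bin <- rep.int(seq_along(n), n)
        width <- coords$end[rep_bin] - coords$start[rep_bin]
        ## fragment centres uniform in the bin; the 5' end sits half an
        ## extension upstream so the extended-fragment midpoint falls back
        ## on the centre (reads flank the signal, as in real fragments)
        centre <- coords$start[rep_bin] +
          floor(stats::runif(length(rep_bin)) * width)
        strand <- sample(c("+", "-"), length(rep_bin), replace = TRUE)
        size <- config$bins$chrom_sizes[match(coords$chrom[rep_bin],
                                              config$bins$chrom_order)]
        pos <- ifelse(strand == "+", centre - 100, centre + 100)
        pos <- pmin(pmax(pos, 0), size - 1)
        key <- paste(config$cells[i], config$marks[m], sep = "|")
        out[[key]] <- data.frame(
          chrom = coords$chrom[rep_bin], pos = pos, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    out
  })
}

#' Simulate companion annotation data around the planted CSREs
#'
#' Builds toy gene models, an expression matrix, per-cell peak files and a
#' gene-set collection that are all consistent with the planted truth, so
#' every downstream annotation operation can be validated end to end:
#'
#' * per specific state, up to `genes_per_state` genes whose bodies exactly
#'   cover that state's longest CSREs of at least 3 kb (so they are CSRE
#'   proximal by construction), plus background genes placed away from any
#'   qualifying stretch;
#' * expression where planted proximal genes are elevated in their state's
#'   cell types, making their specificity z-scores high there;
#' * per-cell peak sets co-located with the planted CSREs of states specific
#'   to that cell;
#' * a GMT where each specific state has one term equal to its planted
#'   genes, plus random background terms.
#'
#' @param config a [sim_config].
#' @param path truth `state_path`.
#' @param genes_per_state planted genes per specific state (default 6).
#' @param n_background_genes background genes (default 30).
#' @param dir optional directory; when given, writes `genes.gtf`,
#'   `expression.tsv`, `peaks_<cell>.bed`, `genesets.gmt` and
#'   `truth.json`.
#' @return list with `genes` (a `gene_models`), `expression`, `peaks_by_cell`,
#'   `gene_sets`, `universe`, `planted_genes` (per state name), `csres`,
#'   `classes`, and `paths` when `dir` was given.
#' @export
simulate_companions <- function(config, path, genes_per_state = 6,
                                n_background_genes = 30, dir = NULL) {
  bins <- config$bins
  classes <- classify_states(config$true_params, config$row_labels)
  csres <- extract_csres(path, classes, bins)
  spec_names <- classes$table$name[classes$table$specific]
  with_seed(config$seed + 3L, {
    tx <- list()
    planted_genes <- stats::setNames(vector("list", length(spec_names)),
                                     spec_names)
    gid <- 0L
    for (nm in spec_names) {
      cs <- csres[csres$name == nm, , drop = FALSE]
      cs <- cs[order(-(cs$end - cs$start)), , drop = FALSE]
      cs <- cs[cs$end - cs$start >= 3000, , drop = FALSE]
      take <- utils::head(seq_len(nrow(cs)), genes_per_state)
      for (i in take) {
        gid <- gid + 1L
        g <- sprintf("GENE%03d", gid)
        tx[[length(tx) + 1L]] <- data.frame(
          tx_id = paste0("NM_", g), gene = g, chrom = cs$chrom[i],
          strand = "+", start = cs$start[i], end = cs$end[i],
          state = nm, stringsAsFactors = FALSE)
        planted_genes[[nm]] <- c(planted_genes[[nm]], g)
      }
    }
    ## background genes: 2-kb bodies, rejected if any state's CSREs cover a
    ## contiguous 3 kb of their promoter-plus-body region
    csre_gr <- if (nrow(csres)) GenomicRanges::reduce(df_to_gr(csres))
               else GenomicRanges::GRanges()
    n_bg <- 0L
    tries <- 0L
    while (n_bg < n_background_genes && tries < 50 * n_background_genes) {
      tries <- tries + 1L
      ch <- sample(bins$chrom_order, 1)
      size <- bins$chrom_sizes[[ch]]
      s <- floor(stats::runif(1, PROMOTER_FLANK, size - 2000 - PROMOTER_FLANK))
      region <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(s - PROMOTER_FLANK + 1, s + 2000 + PROMOTER_FLANK))
      cov <- GenomicRanges::intersect(csre_gr, region)
      if (length(cov) && max(GenomicRanges::width(cov)) >= 3000) next
      gid <- gid + 1L
      n_bg <- n_bg + 1L
      g <- sprintf("GENE%03d", gid)
      tx[[length(tx) + 1L]] <- data.frame(
        tx_id = paste0("NM_", g), gene = g, chrom = ch, strand = "+",
        start = s, end = s + 2000, state = NA_character_,
        stringsAsFactors = FALSE)
    }
    txdf <- do.call(rbind, tx)
    genes <- structure(list(
      transcripts = txdf[, c("tx_id", "gene", "chrom", "strand", "start",
                             "end")],
      exons = data.frame(tx_id = txdf$tx_id, chrom = txdf$chrom,
                         strand = txdf$strand, start = txdf$start,
                         end = txdf$end, stringsAsFactors = FALSE),
      cds = data.frame(tx_id = txdf$tx_id, chrom = txdf$chrom,
                       strand = txdf$strand,
                       start = pmin(txdf$start + 300, txdf$end - 1),
                       end = pmax(txdf$end - 300, txdf$start + 1),
                       stringsAsFactors = FALSE)),
      class = "gene_models")
    ## expression: baseline noise, +4 in the cells of the gene's state
    all_genes <- txdf$gene
    expr <- matrix(stats::rnorm(length(all_genes) * config$N, mean = 8,
                                sd = 0.5),
                   nrow = length(all_genes),
                   dimnames = list(all_genes, config$cells))
    state_cells <- strsplit(classes$table$cells, ",")
    names(state_cells) <- classes$table$name
    for (i in seq_len(nrow(txdf))) {
      nm <- txdf$state[i]
      if (is.na(nm)) next
      expr[txdf$gene[i], state_cells[[nm]]] <- expr[txdf$gene[i],
                                                    state_cells[[nm]]] + 4
    }
    ## per-cell peaks: the CSRE intervals of states specific to the cell,
    ## plus shared peaks present in every cell
    peaks_by_cell <- lapply(stats::setNames(config$cells, config$cells),
                            function(cl) {
      own <- csres[vapply(strsplit(csres$cells, ","),
                          function(cc) cl %in% cc, logical(1)),
                   c("chrom", "start", "end"), drop = FALSE]
      rownames(own) <- NULL
      own
    })
    shared <- data.frame(chrom = bins$chrom_order[1],
                         start = c(0, 10000), end = c(1000, 11000))
    peaks_by_cell <- lapply(peaks_by_cell, function(df)
      rbind(df, shared))
    ## gene sets: one planted term per specific state + random terms
    gene_sets <- lapply(planted_genes, function(g) unique(g))
    names(gene_sets) <- paste0("PLANTED_", spec_names)
    for (i in 1:3) {
      gene_sets[[paste0("RANDOM_", i)]] <-
        sample(all_genes, min(8, length(all_genes)))
    }
    out <- list(genes = genes, expression = expr,
                peaks_by_cell = peaks_by_cell, gene_sets = gene_sets,
                universe = all_genes, planted_genes = planted_genes,
                csres = csres, classes = classes)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$paths <- write_companions(out, config, dir)
    }
    out
  })
}

## Write companion objects in their on-disk formats.
write_companions <- function(comp, config, dir) {
  gtf <- file.path(dir, "genes.gtf")
  tx <- comp$genes$transcripts
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene[i],
                     tx$tx_id[i])
    ex <- comp$genes$exons[comp$genes$exons$tx_id == tx$tx_id[i], ,
                           drop = FALSE]
    cd <- comp$genes$cds[comp$genes$cds$tx_id == tx$tx_id[i], ,
                         drop = FALSE]
    fmt <- function(type, s, e)
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", tx$chrom[i], type,
              as.integer(s + 1), as.integer(e), tx$strand[i], attrs)
    lines <- c(lines,
               fmt("transcript", tx$start[i], tx$end[i]),
               unlist(Map(fmt, "exon", ex$start, ex$end)),
               unlist(Map(fmt, "CDS", cd$start, cd$end)))
  }
  writeLines(lines, gtf)
  expr_path <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene = rownames(comp$expression),
                                comp$expression, check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  peak_paths <- vapply(names(comp$peaks_by_cell), function(cl) {
    p <- file.path(dir, sprintf("peaks_%s.bed", cl))
    write_bed(comp$peaks_by_cell[[cl]], p)
    p
  }, "")
  gmt <- file.path(dir, "genesets.gmt")
  writeLines(vapply(names(comp$gene_sets), function(tm)
    paste(c(tm, "synthetic", comp$gene_sets[[tm]]), collapse = "\t"), ""),
    gmt)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(planted_genes = comp$planted_genes,
                            states = comp$classes$table,
                            seed = config$seed),
                       truth, digits = NA, auto_unbox = TRUE)
  c(gtf = gtf, expression = expr_path, peak_paths,
    gmt = gmt, truth = truth)
}

#' One-call synthetic dataset
#'
#' Runs [simulate_state_path] and [simulate_peak_matrices], applies the real
#' [specificity_transform] and [stack_observations], and returns everything
#' a full pipeline run needs.
#'
#' @param config a [sim_config].
#' @return list with `config`, `truth` (state path), `peak_mats`, `O`
#'   (observation matrix) and `bins`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_state_path(config)
  peak_mats <- simulate_peak_matrices(config, truth)
  S <- lapply(peak_mats, specificity_transform, s = config$s)
  O <- stack_observations(S)
  list(config = config, truth = truth, peak_mats = peak_mats, O = O,
       bins = config$bins)
}
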