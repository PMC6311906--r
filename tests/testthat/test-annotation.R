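test_that("feature assignment follows the priority order", {
  genes <- toy_genes()
  cs <- data.frame(
    chrom = "chrT",
    start = c(9000,   # promoter (TSS 10000 +/- 2000) and 5'UTR -> promoter
              13000,  # intron only
              18500,  # CDS exon interior -> exon
              90000), # nothing -> intergenic
    end = c(11000, 14000, 18800, 90400))
  f <- assign_feature(cs, genes)
  expect_equal(as.character(f), c("promoter", "intron", "exon",
                                  "intergenic"))
  # 5'UTR beats 3'UTR and exon when outside the promoter:
  # plus-strand UTR5 is [10000,11000); promoter reaches 12001
  cs2 <- data.frame(chrom = "chrT", start = 12500, end = 19500)
  expect_equal(as.character(assign_feature(cs2, genes)), "utr3")
  # every CSRE gets exactly one class
  set.seed(9)
  cs3 <- data.frame(chrom = "chrT", start = seq(0, 99000, by = 3000))
  cs3$end <- cs3$start + 1000
  f3 <- assign_feature(cs3, genes)
  expect_equal(length(f3), nrow(cs3))
  expect_false(anyNA(f3))
  expect_equal(sum(table(f3)), nrow(cs3))
})

test_that("minus-strand transcripts get a strand-aware TSS", {
  genes <- toy_genes()
  # NR_B is minus strand over [50000,60000): TSS at 59999
  cs <- data.frame(chrom = "chrT", start = 61500, end = 61900)
  expect_equal(as.character(assign_feature(cs, genes)), "promoter")
  cs <- data.frame(chrom = "chrT", start = 49000, end = 49500)
  expect_equal(as.character(assign_feature(cs, genes)), "intergenic")
})

test_that("proximal genes require a contiguous 3-kb covered stretch", {
  genes <- toy_genes()
  # single 3.4-kb CSRE inside the gene body -> qualifies
  cs <- data.frame(chrom = "chrT", start = 12000, end = 15400)
  expect_equal(proximal_genes(cs, genes), "GENEA")
  # 2 kb + 2 kb with a 200-bp gap -> no contiguous 3 kb -> excluded
  cs <- data.frame(chrom = "chrT", start = c(12000, 14200),
                   end = c(14000, 16200))
  expect_equal(proximal_genes(cs, genes), character(0))
  # CSREs on another chromosome -> excluded
  cs <- data.frame(chrom = "chrZ", start = 0, end = 5000)
  expect_equal(proximal_genes(cs, genes), character(0))
  # adding CSREs never removes a gene (monotonicity)
  base <- data.frame(chrom = "chrT", start = 12000, end = 15400)
  more <- rbind(base, data.frame(chrom = "chrT", start = 30000, end = 30400))
  expect_true(all(proximal_genes(base, genes) %in%
                    proximal_genes(more, genes)))
})

test_that("nearest-TSS distances use the closest edge and seeded controls", {
  genes <- structure(list(
    transcripts = data.frame(tx_id = c("t1", "t2"), gene = c("g1", "g2"),
                             chrom = "chrT", strand = "+",
                             start = c(5000, 10000), end = c(6000, 11000)),
    exons = data.frame(tx_id = c("t1", "t2"), chrom = "chrT", strand = "+",
                       start = c(5000, 10000), end = c(6000, 11000)),
    cds = data.frame(tx_id = character(), chrom = character(),
                     strand = character(), start = numeric(),
                     end = numeric())), class = "gene_models")
  sizes <- c(chrT = 1e5)
  # TSS at 5000, CSRE [6000,6600) -> 1000
  d <- nearest_tss_distances(data.frame(chrom = "chrT", start = 6000,
                                        end = 6600), genes, sizes, seed = 1)
  expect_equal(d$true, 1000)
  # TSSs at 5000 and 10000, CSRE [7000,7200): left gap 2000 < right gap
  d <- nearest_tss_distances(data.frame(chrom = "chrT", start = 7000,
                                        end = 7200), genes, sizes, seed = 1)
  expect_equal(d$true, 2000)
  # identical seed -> identical control placements
  cs <- data.frame(chrom = "chrT", start = c(20000, 40000),
                   end = c(20600, 40600))
  d1 <- nearest_tss_distances(cs, genes, sizes, n_random = 3, seed = 7)
  d2 <- nearest_tss_distances(cs, genes, sizes, n_random = 3, seed = 7)
  expect_identical(d1$random, d2$random)
  expect_length(d1$random, 6)
  # chromosome without any TSS is skipped with a message
  expect_message(
    d3 <- nearest_tss_distances(data.frame(chrom = "chrZ", start = 0,
                                           end = 600), genes, sizes),
    "skipped")
  expect_length(d3$true, 0)
})

test_that("overlap enrichment counts CSREs and handles degenerate nulls", {
  sizes <- c(chr1 = 1e6)
  cs <- data.frame(chrom = "chr1", start = seq(0, 90000, by = 10000))
  cs$end <- cs$start + 600
  # no peaks: observed 0, empirical p = 1
  er <- overlap_enrichment(cs, data.frame(chrom = character(),
                                          start = numeric(),
                                          end = numeric()),
                           sizes, n_sim = 20, seed = 1)
  expect_equal(er$observed, 0L)
  expect_equal(er$p_empirical, 1)
  # peaks covering the whole genome: saturation, p = 1
  expect_message(
    er <- overlap_enrichment(cs, data.frame(chrom = "chr1", start = 0,
                                            end = 1e6),
                             sizes, n_sim = 20, seed = 1),
    "degenerate")
  expect_equal(er$observed, nrow(cs))
  expect_equal(er$p_empirical, 1)
  expect_equal(er$p_wilcoxon, 1)
  # peaks exactly on the true CSREs of a long chromosome -> minimal p
  er <- overlap_enrichment(cs, cs, sizes, n_sim = 199, seed = 5)
  expect_equal(er$observed, nrow(cs))
  expect_equal(er$p_empirical, 1 / 200)
  expect_error(overlap_enrichment(cs, cs, sizes, n_sim = 0), "n_sim")
})

test_that("empirical enrichment p is super-uniform under its own null", {
  sizes <- c(chr1 = 2e5)
  set.seed(123)
  peaks <- data.frame(chrom = "chr1", start = sort(sample(0:1950, 10)) * 100)
  peaks$end <- peaks$start + 400
  ps <- vapply(1:200, function(rep) {
    start <- sample(0:(2e5 - 600), 5)
    cs <- data.frame(chrom = "chr1", start = start, end = start + 600)
    overlap_enrichment(cs, peaks, sizes, n_sim = 99,
                       seed = 1000 + rep)$p_empirical
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2), b = c(3, 4))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2, 3), c(2, 3)))
  # identical columns unchanged
  m2 <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2)
  # all columns share the sorted vector; idempotent
  set.seed(2)
  m3 <- matrix(rnorm(40), 10, 4)
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1)], ignore_attr = TRUE)
  expect_equal(quantile_normalize(qn3), qn3, tolerance = 1e-12)
})

test_that("specificity z-scores center and scale per gene", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(4, 4, 4))
  expect_message(z <- specificity_zscores(m), "constant")
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))   # sample sd = 1
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  set.seed(3)
  m2 <- matrix(rnorm(30), 5, 6)
  z2 <- specificity_zscores(m2)
  expect_true(all(abs(rowSums(z2)) < 1e-12))
})

test_that("rank-sum comparison is exact for small untied samples", {
  expect_equal(compare_groups(1:3, 4:6), 0.1)
  expect_equal(compare_groups(1:3, 4:6), ranksum_oracle(1:3, 4:6))
  expect_equal(compare_groups(4:6, 1:3), compare_groups(1:3, 4:6))
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), 1)
  # larger tied samples use the normal approximation and stay in (0, 1]
  set.seed(4)
  a <- sample(1:5, 30, replace = TRUE)
  b <- sample(1:5, 30, replace = TRUE)
  p <- compare_groups(a, b)
  expect_true(p > 0 && p <= 1)
})

test_that("gene-set enrichment matches the hypergeometric tail", {
  universe <- paste0("g", 1:10)
  sets <- list(term5 = paste0("g", 1:5), term4 = paste0("g", 1:4))
  res <- gene_set_enrichment(paste0("g", 1:5), sets, universe)
  # 4-gene term filtered out by the 5..500 size rule
  expect_equal(res$term, "term5")
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p, fisher_oracle(5, 5, 5, 10), tolerance = 1e-12)
  # genes outside the universe are dropped with a message
  expect_message(
    res2 <- gene_set_enrichment(c(paste0("g", 1:5), "gX"), sets, universe),
    "outside")
  expect_equal(res2$p, res$p)
  # empty query -> empty result
  expect_equal(nrow(gene_set_enrichment(character(0), sets, universe)), 0)
})

test_that("Fisher p-values match enumeration on random small tables", {
  set.seed(5)
  for (i in 1:25) {
    U <- sample(10:30, 1)
    universe <- paste0("g", seq_len(U))
    term <- sample(universe, sample(5:min(9, U), 1))
    query <- sample(universe, sample(3:U, 1))
    res <- gene_set_enrichment(query, list(t = term), universe,
                               min_size = 1, max_size = 500)
    want <- fisher_oracle(length(intersect(query, term)), length(query),
                          length(term), U)
    expect_equal(res$p, want, tolerance = 1e-10)
  }
})

test_that("BH correction matches the step-up formula", {
  res <- stats::p.adjust(c(0.01, 0.02, 0.03), method = "BH")
  expect_equal(res, rep(0.03, 3))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }
  # q-values in enrichment output are BH across tested terms
  universe <- paste0("g", 1:20)
  sets <- list(a = paste0("g", 1:6), b = paste0("g", 3:10),
               c = paste0("g", 11:18))
  res <- gene_set_enrichment(paste0("g", 1:6), sets, universe)
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
})

test_that("cell-specific peaks are the bp-level set difference", {
  # single cell: unchanged
  one <- cell_specific_peaks(list(A = data.frame(chrom = "c", start = 0,
                                                 end = 300)))
  expect_equal(one$A$start, 0)
  expect_equal(one$A$end, 300)
  # identical peaks in two cells: both empty
  same <- data.frame(chrom = "c", start = 0, end = 300)
  two <- cell_specific_peaks(list(A = same, B = same))
  expect_equal(nrow(two$A), 0)
  expect_equal(nrow(two$B), 0)
  # partial overlap splits the remainder
  res <- cell_specific_peaks(list(
    A = data.frame(chrom = "c", start = 0, end = 300),
    B = data.frame(chrom = "c", start = 100, end = 200)))
  expect_equal(res$A$start, c(0, 200))
  expect_equal(res$A$end, c(100, 300))
  expect_equal(nrow(res$B), 0)
})

test_that("GMT files round-trip and malformed lines are reported", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tg1\tg2\tg3", "term2\tdesc\tg4\tg5"), tmp)
  sets <- read_gmt(tmp)
  expect_equal(sets$term1, c("g1", "g2", "g3"))
  expect_equal(sets$term2, c("g4", "g5"))
  writeLines("term1\tonly-desc", tmp)
  expect_error(read_gmt(tmp), "line 1")
})

test_that("gene models parse from GTF with UTRs derived from CDS", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "GENEA"; transcript_id "NM_A";'
  writeLines(c(
    paste0("chrT\tsrc\texon\t10001\t12000\t.\t+\t.\t", attrs),
    paste0("chrT\tsrc\texon\t18001\t20000\t.\t+\t.\t", attrs),
    paste0("chrT\tsrc\tCDS\t11001\t19000\t.\t+\t.\t", attrs)), tmp)
  g <- read_gene_models(tmp)
  expect_equal(g$transcripts$start, 10000)
  expect_equal(g$transcripts$end, 20000)
  expect_equal(nrow(g$exons), 2)
  # UTR5 = exonic bp before the CDS on the plus strand
  fr <- csrehmm:::feature_ranges(g)
  expect_equal(GenomicRanges::start(fr$utr5), 10001)
  expect_equal(GenomicRanges::end(fr$utr5), 11000)
  expect_equal(GenomicRanges::start(fr$utr3), 19001)
  expect_equal(GenomicRanges::start(fr$intron), 12001)
  # transcript prefix filter
  g2 <- read_gene_models(tmp, tx_prefix = "XR")
  expect_equal(nrow(g2$transcripts), 0)
})
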