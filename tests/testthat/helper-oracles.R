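## Independent oracles used across the suite. These deliberately use the
## slowest, most literal formulations (explicit path enumeration, pmf
## summation, rank-assignment enumeration) so they share no code with the
## implementation they check.

## Exhaustive HMM inference by summing over all K^T hidden paths.
enum_hmm <- function(obs, params) {
  K <- params$K
  Tc <- ncol(obs)
  E <- params$E
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tc)))
  emit <- function(k, t) prod(E[k, ]^obs[, t] * (1 - E[k, ])^(1 - obs[, t]))
  probs <- apply(paths, 1, function(s) {
    p <- params$pi[s[1]] * emit(s[1], 1)
    if (Tc > 1) {
      for (t in 2:Tc) p <- p * params$A[s[t - 1], s[t]] * emit(s[t], t)
    }
    p
  })
  posterior <- vapply(seq_len(Tc), function(t)
    vapply(seq_len(K), function(k) sum(probs[paths[, t] == k]), numeric(1)),
    numeric(K))
  posterior <- matrix(posterior, nrow = K) / sum(probs)
  list(loglik = log(sum(probs)), posterior = posterior,
       map_path = paths[which.max(probs), ])
}

## Smallest c with P(X >= c) < alpha by direct pmf summation.
poisson_cutoff_oracle <- function(lambda, alpha) {
  cc <- 0
  repeat {
    tail <- 1 - sum(stats::dpois(0:(cc - 1), lambda))
    if (cc == 0) tail <- 1
    if (tail < alpha) return(as.integer(cc))
    cc <- cc + 1
  }
}

## Hypergeometric tail by explicit enumeration of overlap counts.
fisher_oracle <- function(overlap, query_size, term_size, universe_size) {
  ks <- overlap:min(query_size, term_size)
  sum(choose(term_size, ks) * choose(universe_size - term_size,
                                     query_size - ks)) /
    choose(universe_size, query_size)
}

## BH step-up by the literal formula.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

## Two-sided exact rank-sum p by enumerating all rank assignments.
ranksum_oracle <- function(a, b) {
  n <- length(a)
  all <- c(a, b)
  ranks <- rank(all)
  W_obs <- sum(ranks[seq_len(n)])
  combs <- utils::combn(length(all), n)
  Ws <- apply(combs, 2, function(ix) sum(ranks[ix]))
  mu <- n * (length(all) + 1) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu))
}

## Shared tiny fixtures -------------------------------------------------

toy_bins <- function(sizes = c(chrA = 1000, chrB = 600), bin_size = 200) {
  genome_bins(sizes, bin_size)
}

## Observation matrix with two clearly separated column patterns.
two_block_obs <- function(n_each = 20) {
  a <- matrix(rep(c(1L, 1L, 0L, 0L), n_each), nrow = 4)
  b <- matrix(rep(c(0L, 0L, 1L, 1L), n_each), nrow = 4)
  mat <- cbind(a, b)
  rownames(mat) <- paste0("m1:", c("c1", "c2", "c3", "c4"))
  structure(list(mat = mat,
                 row_labels = data.frame(mark = "m1",
                                         cell = c("c1", "c2", "c3", "c4"))),
            class = "observation_matrix")
}

random_obs <- function(R, T_, seed, p = 0.3) {
  set.seed(seed)
  mat <- matrix(as.integer(runif(R * T_) < p), R, T_)
  structure(list(mat = mat,
                 row_labels = data.frame(mark = "m1",
                                         cell = paste0("c", seq_len(R)))),
            class = "observation_matrix")
}

random_params <- function(K, R, seed) init_random(K, R, seed)

## Single-chromosome genome sized to an observation matrix.
bins_for <- function(O, bin_size = 200) {
  genome_bins(c(chr1 = ncol(O$mat) * bin_size), bin_size)
}

## Toy gene models on one 100-kb chromosome:
##   plus-strand tx  [10000, 20000), exons [10000,12000) + [18000,20000),
##   CDS [11000, 19000) -> 5'UTR [10000,11000), 3'UTR [19000,20000),
##   intron [12000, 18000)
##   minus-strand tx [50000, 60000), single exon, no CDS
toy_genes <- function() {
  structure(list(
    transcripts = data.frame(
      tx_id = c("NM_A", "NR_B"), gene = c("GENEA", "GENEB"),
      chrom = "chrT", strand = c("+", "-"),
      start = c(10000, 50000), end = c(20000, 60000),
      stringsAsFactors = FALSE),
    exons = data.frame(
      tx_id = c("NM_A", "NM_A", "NR_B"), chrom = "chrT",
      strand = c("+", "+", "-"),
      start = c(10000, 18000, 50000), end = c(12000, 20000, 60000),
      stringsAsFactors = FALSE),
    cds = data.frame(
      tx_id = "NM_A", chrom = "chrT", strand = "+",
      start = 11000, end = 19000, stringsAsFactors = FALSE)),
    class = "gene_models")
}
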