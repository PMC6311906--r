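## Multivariate Bernoulli HMM over stacked cell-mark observations.
##
## Each genome bin carries a binary vector of R cell-mark combinations,
## modelled as independent Bernoulli draws given the hidden state. The
## likelihood factorizes over chromosomes: each chromosome is an independent
## sequence sharing pi, A and the emission matrix E.

EMISSION_EPS <- 1e-6

#' Construct and validate HMM parameters
#'
#' @param pi length-K vector of initial state probabilities (one simplex,
#'   shared by all chromosomes).
#' @param A K x K row-stochastic transition matrix.
#' @param E K x R Bernoulli emission matrix; entries are clamped to
#'   \[1e-6, 1 - 1e-6\].
#' @param row_labels optional data frame (mark, cell) describing the R
#'   observation rows.
#' @return object of class `hmm_params` with fields `K`, `R`, `pi`, `A`,
#'   `E`, `row_labels`.
#' @export
hmm_params <- function(pi, A, E, row_labels = NULL) {
  pi <- as.numeric(pi)
  A <- as.matrix(A)
  E <- as.matrix(E)
  K <- length(pi)
  if (!all(dim(A) == c(K, K))) stop2("A must be K x K")
  if (nrow(E) != K) stop2("E must have K rows")
  if (abs(sum(pi) - 1) > 1e-9) stop2("pi must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-9)) stop2("rows of A must sum to 1")
  if (any(pi < 0) || any(A < 0)) stop2("probabilities must be non-negative")
  E <- pmin(pmax(E, EMISSION_EPS), 1 - EMISSION_EPS)
  if (!is.null(row_labels) && nrow(row_labels) != ncol(E))
    stop2("row_labels must have one row per emission column")
  structure(list(K = K, R = ncol(E), pi = pi, A = A, E = E,
                 row_labels = row_labels),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: K = %d states, R = %d cell-mark combinations\n",
              x$K, x$R))
  invisible(x)
}

## Per-state log emission probabilities for every column of obs (R x T).
## Returns K x T. Uses log E - log(1-E) factorization so cost is one K x R
## by R x T product.
log_emissions <- function(params, obs) {
  l1 <- log(params$E)
  l0 <- log1p(-params$E)
  (l1 - l0) %*% obs + rowSums(l0)
}

## Scaled forward pass. Returns list(alpha, cvec, bmax, loglik, B).
forward_pass <- function(logB, pi, A) {
  K <- nrow(logB)
  Tc <- ncol(logB)
  bmax <- apply(logB, 2, max)
  B <- exp(sweep(logB, 2, bmax, "-"))
  alpha <- matrix(0, K, Tc)
  cvec <- numeric(Tc)
  a <- pi * B[, 1]
  cvec[1] <- sum(a)
  alpha[, 1] <- a / cvec[1]
  if (Tc > 1) {
    tA <- t(A)
    for (t in 2:Tc) {
      a <- (tA %*% alpha[, t - 1]) * B[, t]
      cvec[t] <- sum(a)
      alpha[, t] <- a / cvec[t]
    }
  }
  list(alpha = alpha, cvec = cvec, bmax = bmax,
       loglik = sum(log(cvec)) + sum(bmax), B = B)
}

## Forward-backward on one chromosome given precomputed logB.
## Returns gamma (K x Tc posteriors), xi (K x K summed pairwise
## expectations) and the sequence log-likelihood.
fb_core <- function(logB, pi, A) {
  fw <- forward_pass(logB, pi, A)
  K <- nrow(logB)
  Tc <- ncol(logB)
  alpha <- fw$alpha
  B <- fw$B
  cvec <- fw$cvec
  beta <- matrix(0, K, Tc)
  beta[, Tc] <- 1
  xi <- matrix(0, K, K)
  if (Tc > 1) {
    for (t in (Tc - 1):1) {
      bb <- B[, t + 1] * beta[, t + 1]
      xi <- xi + (alpha[, t] %*% t(bb)) * A / cvec[t + 1]
      beta[, t] <- (A %*% bb) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  list(gamma = gamma, xi = xi, loglik = fw$loglik)
}

#' Forward-backward smoothing for one observation sequence
#'
#' @param obs_seq binary R x T matrix for a single chromosome.
#' @param params an [hmm_params].
#' @return list with `posterior` (K x T, columns sum to 1), `xi_sum`
#'   (K x K summed pairwise state expectations) and `loglik`.
#' @export
forward_backward <- function(obs_seq, params) {
  obs_seq <- as.matrix(obs_seq)
  if (nrow(obs_seq) != params$R) stop2("observation rows must equal R")
  res <- fb_core(log_emissions(params, obs_seq), params$pi, params$A)
  list(posterior = res$gamma, xi_sum = res$xi, loglik = res$loglik)
}

## Split an observation matrix into per-chromosome matrices.
split_obs <- function(O, bins) {
  if (ncol(O$mat) != bins$n_total)
    stop2("observation matrix has ", ncol(O$mat), " bins but genome has ",
          bins$n_total)
  idx <- chrom_bin_index(bins)
  lapply(idx, function(i) O$mat[, i, drop = FALSE])
}

#' Total log-likelihood of all chromosomes
#'
#' The likelihood is a product over chromosomes of the marginal over hidden
#' paths; this returns its natural log via the scaled forward recursion.
#'
#' @param O an `observation_matrix` whose columns follow `bins`.
#' @param bins a [genome_bins].
#' @param params an [hmm_params] with `R == nrow(O$mat)`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(O, bins, params) {
  if (nrow(O$mat) != params$R) stop2("observation rows must equal R")
  chunks <- split_obs(O, bins)
  sum(vapply(chunks, function(oc) {
    forward_pass(log_emissions(params, oc), params$pi, params$A)$loglik
  }, numeric(1)))
}

#' Deterministic entropy-based initialization
#'
#' Top-down divisive scheme: starting from one cluster holding every bin,
#' repeatedly pick the cluster with the largest total binary entropy (the
#' sum of per-feature Bernoulli entropies of its feature means, weighted by
#' cluster size, i.e. the bits needed to encode the cluster), and split it
#' on its highest-entropy feature (bins with the feature present vs
#' absent), until K clusters exist. Emission rows are the
#' per-cluster feature means; transitions and initial probabilities are
#' estimated from the induced hard labelling of the genome (with a 1e-2
#' smoothing count so every row is a valid distribution). Ties break on the
#' lowest feature/cluster index, so the result is fully deterministic.
#'
#' If fewer than K distinct splits exist, remaining states start at the
#' global feature mean plus a tiny deterministic perturbation.
#'
#' @param O an `observation_matrix`.
#' @param bins a [genome_bins].
#' @param K number of states.
#' @return an [hmm_params].
#' @export
init_entropy <- function(O, bins, K) {
  if (K < 1) stop2("K must be >= 1")
  X <- O$mat
  T_ <- ncol(X)
  clusters <- list(seq_len(T_))
  cluster_means <- function(idx) rowMeans(X[, idx, drop = FALSE])
  means <- list(cluster_means(clusters[[1]]))
  while (length(clusters) < K) {
    tot <- vapply(seq_along(means), function(i)
      length(clusters[[i]]) * sum(binary_entropy(means[[i]])), numeric(1))
    ci <- which.max(tot)            # ties -> lowest cluster index
    if (tot[ci] <= 0) break         # all clusters pure; cannot split further
    feat_h <- binary_entropy(means[[ci]])
    f <- which.max(feat_h)          # ties -> lowest feature index
    idx <- clusters[[ci]]
    on <- idx[X[f, idx] == 1L]
    off <- idx[X[f, idx] == 0L]
    clusters[[ci]] <- off
    clusters[[length(clusters) + 1L]] <- on
    means[[ci]] <- cluster_means(off)
    means[[length(means) + 1L]] <- cluster_means(on)
  }
  n_found <- length(clusters)
  E <- matrix(0, K, nrow(X))
  for (k in seq_len(n_found)) E[k, ] <- means[[k]]
  if (n_found < K) {
    message(sprintf(
      "init_entropy: only %d distinct clusters for K = %d; filling remaining states at the global mean",
      n_found, K))
    gm <- rowMeans(X)
    for (k in (n_found + 1):K)
      E[k, ] <- pmin(gm + 1e-3 * k, 1)
  }
  labels <- integer(T_)
  for (k in seq_len(n_found)) labels[clusters[[k]]] <- k
  idx_by_chrom <- chrom_bin_index(bins)
  sm <- 1e-2
  trans <- matrix(sm, K, K)
  pi0 <- rep(sm, K)
  for (ch in bins$chrom_order) {
    lab <- labels[idx_by_chrom[[ch]]]
    pi0[lab[1]] <- pi0[lab[1]] + 1
    if (length(lab) > 1) {
      from <- lab[-length(lab)]
      to <- lab[-1]
      for (k in seq_len(K)) {
        sel <- from == k
        if (any(sel)) trans[k, ] <- trans[k, ] + tabulate(to[sel], nbins = K)
      }
    }
  }
  hmm_params(pi0 / sum(pi0), trans / rowSums(trans), E,
             row_labels = O$row_labels)
}

#' Random initialization
#'
#' Emissions uniform on (0.1, 0.9); `pi` and the rows of `A` from a
#' symmetric Dirichlet(1). Reproducible for a given seed; the caller's RNG
#' state is left untouched.
#'
#' @param K number of states.
#' @param R number of cell-mark combinations.
#' @param seed integer seed.
#' @return an [hmm_params].
#' @export
init_random <- function(K, R, seed) {
  with_seed(seed, {
    E <- matrix(stats::runif(K * R, 0.1, 0.9), K, R)
    A <- matrix(stats::rgamma(K * K, 1), K, K)
    A <- A / rowSums(A)
    pi0 <- stats::rgamma(K, 1)
    hmm_params(pi0 / sum(pi0), A, E)
  })
}

## M-step from accumulated sufficient statistics. Tiny negative entries can
## arise from cancellation when incremental EM subtracts a chromosome's old
## contribution; clamp them to zero.
m_step <- function(stats, old, pseudocount) {
  stats$pi <- pmax(stats$pi, 0)
  stats$A <- pmax(stats$A, 0)
  stats$Enum <- pmax(stats$Enum, 0)
  stats$den <- pmax(stats$den, 0)
  pi0 <- stats$pi / sum(stats$pi)
  A <- old$A
  rs <- rowSums(stats$A)
  nz <- rs > 0
  A[nz, ] <- stats$A[nz, , drop = FALSE] / rs[nz]
  E <- (stats$Enum + pseudocount) / (stats$den + 2 * pseudocount)
  hmm_params(pi0, A, E, row_labels = old$row_labels)
}

zero_stats <- function(K, R) {
  list(pi = numeric(K), A = matrix(0, K, K), Enum = matrix(0, K, R),
       den = numeric(K))
}

add_stats <- function(a, b, sign = 1) {
  list(pi = a$pi + sign * b$pi, A = a$A + sign * b$A,
       Enum = a$Enum + sign * b$Enum, den = a$den + sign * b$den)
}

## E-step on one chromosome: sufficient statistics and log-likelihood.
e_step_chrom <- function(obs, tobs, params) {
  res <- fb_core(log_emissions(params, obs), params$pi, params$A)
  list(stats = list(pi = res$gamma[, 1],
                    A = res$xi,
                    Enum = res$gamma %*% tobs,
                    den = rowSums(res$gamma)),
       loglik = res$loglik)
}

#' Fit the Bernoulli HMM by expectation-maximization
#'
#' Batch mode is the standard Baum-Welch update: one E-step over all
#' chromosomes, then one M-step. Incremental mode (Neal-Hinton style)
#' re-estimates the parameters after each chromosome's E-step by replacing
#' that chromosome's previous sufficient-statistic contribution, which
#' typically converges in fewer sweeps on multi-sequence data. One
#' "iteration" is one sweep over all chromosomes in either mode.
#'
#' Emission sufficient statistics receive a pseudocount of `pseudocount`
#' (Beta-style: added to the success count, twice to the total) and are
#' clamped away from 0/1.
#'
#' @param O an `observation_matrix`.
#' @param bins a [genome_bins].
#' @param K number of states; ignored when `init` is supplied.
#' @param init optional [hmm_params] starting point; defaults to
#'   [init_entropy].
#' @param mode `"incremental"` (default) or `"batch"`.
#' @param max_iter maximum number of sweeps (default 300).
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param min_iter sweeps to run before the convergence test is applied
#'   (default 20, capped at `max_iter`); guards against stopping on the
#'   flat stretch EM often crosses before states differentiate.
#' @param pseudocount emission pseudocount (default 1e-2).
#' @param verbose print per-iteration log-likelihood.
#' @return list with `params` (fitted [hmm_params]) and `trace` (class
#'   `em_trace`: per-iteration log-likelihood, iteration count, `converged`,
#'   `mode`).
#' @export
em_fit <- function(O, bins, K = NULL, init = NULL,
                   mode = c("incremental", "batch"), max_iter = 300,
                   tol = 1e-6, min_iter = 20, pseudocount = 1e-2,
                   verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(init)) {
    if (is.null(K)) stop2("supply K or an explicit init")
    init <- init_entropy(O, bins, K)
  }
  params <- init
  if (nrow(O$mat) != params$R) stop2("observation rows must equal R")
  chunks <- split_obs(O, bins)
  tchunks <- lapply(chunks, t)
  C <- length(chunks)
  K <- params$K
  R <- params$R
  ll_trace <- numeric(0)
  converged <- FALSE
  per_chrom <- vector("list", C)
  totals <- zero_stats(K, R)
  for (iter in seq_len(max_iter)) {
    ll <- 0
    if (mode == "batch") {
      acc <- zero_stats(K, R)
      for (ci in seq_len(C)) {
        es <- e_step_chrom(chunks[[ci]], tchunks[[ci]], params)
        acc <- add_stats(acc, es$stats)
        ll <- ll + es$loglik
      }
      if (!is.finite(ll))
        stop2("non-finite likelihood at iteration ", iter)
      params <- m_step(acc, params, pseudocount)
    } else {
      for (ci in seq_len(C)) {
        es <- e_step_chrom(chunks[[ci]], tchunks[[ci]], params)
        if (!is.finite(es$loglik))
          stop2("non-finite likelihood at iteration ", iter,
                ", chromosome ", ci)
        if (!is.null(per_chrom[[ci]]))
          totals <- add_stats(totals, per_chrom[[ci]], sign = -1)
        per_chrom[[ci]] <- es$stats
        totals <- add_stats(totals, es$stats)
        params <- m_step(totals, params, pseudocount)
        ll <- ll + es$loglik
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (verbose) message(sprintf("iter %d: loglik %.6f", iter, ll))
    if (iter > max(1, min(min_iter, max_iter - 1))) {
      prev <- ll_trace[iter - 1]
      if (abs(ll - prev) / max(1, abs(prev)) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  trace <- structure(list(loglik = ll_trace, iterations = length(ll_trace),
                          converged = converged, mode = mode),
                     class = "em_trace")
  list(params = params, trace = trace)
}

#' @export
print.em_trace <- function(x, ...) {
  cat(sprintf("em_trace (%s): %d iteration(s), %sconverged, final loglik %.4f\n",
              x$mode, x$iterations, if (x$converged) "" else "NOT ",
              x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Decode the hidden state path
#'
#' Posterior decoding assigns each bin the state maximizing its smoothed
#' posterior (the default; suits bin-level specific-state runs). Viterbi
#' returns the jointly most probable path. All ties resolve to the lowest
#' state index.
#'
#' @param O an `observation_matrix`.
#' @param bins a [genome_bins].
#' @param params an [hmm_params].
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @param keep_posterior store the K x T posterior matrix on the result
#'   (posterior method only).
#' @return object of class `state_path`: list with `states` (integer vector
#'   over global bins, values in 1..K), `bins`, `method` and optionally
#'   `posterior`.
#' @export
decode <- function(O, bins, params, method = c("posterior", "viterbi"),
                   keep_posterior = FALSE) {
  method <- match.arg(method)
  chunks <- split_obs(O, bins)
  states <- integer(bins$n_total)
  post <- if (keep_posterior && method == "posterior")
    matrix(NA_real_, params$K, bins$n_total) else NULL
  idx <- chrom_bin_index(bins)
  for (ch in bins$chrom_order) {
    obs <- chunks[[ch]]
    if (method == "posterior") {
      g <- fb_core(log_emissions(params, obs), params$pi, params$A)$gamma
      states[idx[[ch]]] <- max.col(t(g), ties.method = "first")
      if (!is.null(post)) post[, idx[[ch]]] <- g
    } else {
      states[idx[[ch]]] <- viterbi_chrom(log_emissions(params, obs),
                                         params$pi, params$A)
    }
  }
  structure(list(states = states, bins = bins, method = method,
                 posterior = post),
            class = "state_path")
}

## Log-space Viterbi for one chromosome; ties to lowest state index.
viterbi_chrom <- function(logB, pi, A) {
  K <- nrow(logB)
  Tc <- ncol(logB)
  logA <- log(pmax(A, 1e-300))
  delta <- log(pmax(pi, 1e-300)) + logB[, 1]
  back <- matrix(0L, K, Tc)
  if (Tc > 1) {
    for (t in 2:Tc) {
      M <- delta + logA                       # M[i, j] = delta_i + log a_ij
      best <- max.col(t(M), ties.method = "first")
      back[, t] <- best
      delta <- M[cbind(best, seq_len(K))] + logB[, t]
    }
  }
  path <- integer(Tc)
  path[Tc] <- which.max(delta)
  if (Tc > 1)
    for (t in (Tc - 1):1) path[t] <- back[path[t + 1], t + 1]
  path
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("state_path (%s decoding): %d bins, %d states observed\n",
              x$method, length(x$states), length(unique(x$states))))
  invisible(x)
}

#' Write a fitted model to versioned JSON
#'
#' Full double precision; [read_hmm_model] round-trips bit-exactly.
#'
#' @param params an [hmm_params].
#' @param path output path.
#' @export
write_hmm_model <- function(params, path) {
  obj <- list(format = "csrehmm-model", version = 1L,
              K = params$K, R = params$R,
              row_labels = params$row_labels,
              pi = params$pi,
              A = params$A,
              E = params$E)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by [write_hmm_model]
#'
#' @param path JSON model path.
#' @return an [hmm_params].
#' @export
read_hmm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "csrehmm-model"))
    stop2("not a model file: ", path)
  rl <- obj$row_labels
  if (!is.null(rl)) rl <- as.data.frame(rl, stringsAsFactors = FALSE)
  hmm_params(obj$pi, obj$A, obj$E, row_labels = rl)
}
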