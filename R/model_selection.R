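#' Free-parameter count of a K-state model
#'
#' (K - 1) initial probabilities + K(K - 1) transition probabilities +
#' K * N * M emission probabilities.
#'
#' @param K number of states.
#' @param N number of cell types.
#' @param M number of marks.
#' @return integer parameter count.
#' @export
n_parameters <- function(K, N, M) {
  if (any(c(K, N, M) < 1)) stop2("K, N, M must be positive")
  as.integer((K - 1) + K * (K - 1) + K * N * M)
}

#' Bayesian information criterion
#'
#' `BIC = ln(n_bins) * n_params - 2 * loglik`, with `loglik` the natural-log
#' likelihood.
#'
#' @param loglik model log-likelihood.
#' @param n_bins number of observations (genome bins).
#' @param n_params free-parameter count from [n_parameters].
#' @export
bic <- function(loglik, n_bins, n_params) {
  log(n_bins) * n_params - 2 * loglik
}

#' Akaike information criterion
#'
#' `AIC = 2 * n_params - 2 * loglik`.
#'
#' @inheritParams bic
#' @export
aic <- function(loglik, n_params) {
  2 * n_params - 2 * loglik
}

#' Recovery score of a state in another model
#'
#' Maximum Pearson correlation between the state's emission vector and any
#' state of the other model; measures whether a state is re-found across
#' refits. A constant vector on either side contributes correlation 0.
#'
#' @param state_emissions length-R emission vector of the state.
#' @param other an [hmm_params] with the same R.
#' @return scalar in \[-1, 1\].
#' @export
recovery_score <- function(state_emissions, other) {
  if (length(state_emissions) != other$R)
    stop2("emission vector length must equal the other model's R")
  if (stats::sd(state_emissions) == 0) {
    message("recovery_score: constant emission vector, correlation taken as 0")
    return(0)
  }
  cors <- apply(other$E, 1, function(e) {
    if (stats::sd(e) == 0) 0 else stats::cor(state_emissions, e)
  })
  max(cors)
}

#' Recovery-score matrix of one model against several others
#'
#' @param model an [hmm_params] (the reference model).
#' @param others list of [hmm_params].
#' @return matrix, states x other models.
#' @export
recovery_matrix <- function(model, others) {
  m <- vapply(others, function(h)
    vapply(seq_len(model$K), function(k) recovery_score(model$E[k, ], h),
           numeric(1)),
    numeric(model$K))
  m <- matrix(m, nrow = model$K)
  dimnames(m) <- list(paste0("state", seq_len(model$K)),
                      paste0("model", seq_along(others)))
  m
}

## Arbitrary-precision helpers on little-endian base-1e4 digit vectors.
big_from_int <- function(x) {
  d <- integer(0)
  while (x > 0) {
    d <- c(d, x %% 10000)
    x <- x %/% 10000
  }
  if (!length(d)) d <- 0L
  d
}

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    res[i:(i + length(b) - 1)] <- res[i:(i + length(b) - 1)] + a[i] * b
  }
  carry <- 0
  for (i in seq_along(res)) {
    v <- res[i] + carry
    res[i] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) {
    res <- c(res, carry %% 10000)
    carry <- carry %/% 10000
  }
  while (length(res) > 1 && res[length(res)] == 0)
    res <- res[-length(res)]
  res
}

big_to_string <- function(d) {
  n <- length(d)
  paste0(d[n], paste(sprintf("%04d", rev(d[-n])), collapse = ""))
}

#' Size of the observation space
#'
#' Number of distinct observation vectors the specificity transform can
#' produce: `(sum_{i=1}^{s} C(N, i))^M`, evaluated exactly with
#' arbitrary-precision integer arithmetic.
#'
#' @param N number of cell types.
#' @param s specificity cap.
#' @param M number of marks.
#' @return object of class `obs_space_size`: list with `exact` (decimal
#'   digit string), `value` (numeric approximation), and the inputs.
#' @export
observation_space_size <- function(N, s, M) {
  if (s < 1 || s > N || M < 1) stop2("need 1 <= s <= N and M >= 1")
  base <- sum(choose(N, seq_len(s)))
  big <- big_from_int(1)
  base_big <- big_from_int(base)
  for (i in seq_len(M)) big <- big_mul(big, base_big)
  exact <- big_to_string(big)
  structure(list(exact = exact, value = as.numeric(exact),
                 N = N, s = s, M = M, per_mark = base),
            class = "obs_space_size")
}

#' @export
print.obs_space_size <- function(x, ...) {
  cat(sprintf("observation space: (sum_{i<=%d} C(%d,i))^%d = %s (~%.3g)\n",
              x$s, x$N, x$M, x$exact, x$value))
  invisible(x)
}

#' Model-score table across state counts
#'
#' @param fits named list of [em_fit] results (or lists with `params` and
#'   `trace`).
#' @param O,bins the data the models were fitted to (used for `n_bins` and
#'   to recompute the final log-likelihood).
#' @param N,M cell and mark counts for [n_parameters].
#' @return data frame: K, loglik, n_params, BIC, AIC, n_bins.
#' @export
score_table <- function(fits, O, bins, N, M) {
  rows <- lapply(fits, function(f) {
    p <- f$params
    ll <- log_likelihood(O, bins, p)
    np <- n_parameters(p$K, N, M)
    data.frame(K = p$K, loglik = ll, n_params = np,
               BIC = bic(ll, bins$n_total, np), AIC = aic(ll, np),
               n_bins = bins$n_total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$K), ]
}
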