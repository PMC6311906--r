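test_that("parameter container validates shapes and simplexes", {
  expect_error(hmm_params(c(0.5, 0.6), diag(2), matrix(0.5, 2, 3)), "sum")
  expect_error(hmm_params(c(0.5, 0.5), matrix(1, 2, 2), matrix(0.5, 2, 3)),
               "rows of A")
  p <- hmm_params(c(0.5, 0.5), diag(2), matrix(c(0, 1, 0.5, 0.5), 2, 2))
  # emissions clamped away from 0/1
  expect_true(all(p$E >= 1e-6 & p$E <= 1 - 1e-6))
})

test_that("single-state log-likelihood has the closed form", {
  O <- random_obs(3, 25, seed = 1)
  bins <- bins_for(O)
  p <- hmm_params(1, matrix(1, 1, 1), matrix(c(0.2, 0.6, 0.9), 1, 3))
  want <- sum(O$mat * log(p$E[1, ]) + (1 - O$mat) * log(1 - p$E[1, ]))
  expect_equal(log_likelihood(O, bins, p), want, tolerance = 1e-12)
})

test_that("log-likelihood factorizes over chromosomes", {
  O <- random_obs(4, 30, seed = 2)
  p <- random_params(3, 4, seed = 3)
  bins2 <- genome_bins(c(chr1 = 18 * 200, chr2 = 12 * 200), 200)
  bins1a <- genome_bins(c(chr1 = 18 * 200), 200)
  bins1b <- genome_bins(c(chr2 = 12 * 200), 200)
  Oa <- O; Oa$mat <- O$mat[, 1:18]
  Ob <- O; Ob$mat <- O$mat[, 19:30]
  expect_equal(log_likelihood(O, bins2, p),
               log_likelihood(Oa, bins1a, p) + log_likelihood(Ob, bins1b, p),
               tolerance = 1e-10)
})

test_that("forward-backward matches explicit path enumeration", {
  # small fixed case: K = 2, T = 3, R = 2
  p <- hmm_params(c(0.7, 0.3), rbind(c(0.9, 0.1), c(0.2, 0.8)),
                  rbind(c(0.8, 0.1), c(0.3, 0.6)))
  obs <- rbind(c(1L, 0L, 1L), c(0L, 0L, 1L))
  oracle <- enum_hmm(obs, p)
  fb <- forward_backward(obs, p)
  expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-12)
  expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-10)
  # K = 3, T = 4 random parameters
  set.seed(14)
  p <- random_params(3, 2, seed = 21)
  obs <- matrix(as.integer(runif(8) < 0.5), 2, 4)
  oracle <- enum_hmm(obs, p)
  fb <- forward_backward(obs, p)
  expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
  expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-10)
})

test_that("posteriors are normalized and consistent with pairwise sums", {
  p <- random_params(4, 3, seed = 8)
  set.seed(8)
  obs <- matrix(as.integer(runif(3 * 40) < 0.4), 3, 40)
  fb <- forward_backward(obs, p)
  expect_equal(colSums(fb$posterior), rep(1, 40), tolerance = 1e-12)
  # pairwise expectations: total transitions = T - 1
  expect_equal(sum(fb$xi_sum), 39, tolerance = 1e-9)
  # single-bin sequence: posterior proportional to pi * emission
  o1 <- obs[, 1, drop = FALSE]
  fb1 <- forward_backward(o1, p)
  w <- p$pi * apply(p$E, 1, function(e) prod(e^o1 * (1 - e)^(1 - o1)))
  expect_equal(fb1$posterior[, 1], w / sum(w), tolerance = 1e-12)
})

test_that("entropy initialization is deterministic and recovers blocks", {
  O <- two_block_obs()
  bins <- bins_for(O)
  p1 <- init_entropy(O, bins, K = 2)
  p2 <- init_entropy(O, bins, K = 2)
  expect_identical(p1, p2)
  got <- p1$E[order(p1$E[, 1]), ]
  eps <- 1e-6
  want <- rbind(c(eps, eps, 1 - eps, 1 - eps),
                c(1 - eps, 1 - eps, eps, eps))
  expect_equal(unname(got), want, tolerance = 1e-9)
  # K = 1: emission row is the global feature mean
  p <- init_entropy(O, bins, K = 1)
  expect_equal(unname(p$E[1, ]), unname(rowMeans(O$mat)), tolerance = 1e-12)
  expect_equal(p$pi, 1)
  expect_equal(unname(p$A), matrix(1, 1, 1))
})

test_that("entropy initialization fills states beyond the distinct columns", {
  # only 2 distinct column patterns but K = 4 requested
  O <- two_block_obs(n_each = 5)
  bins <- bins_for(O)
  expect_message(p <- init_entropy(O, bins, K = 4), "distinct")
  expect_equal(p$K, 4)
  expect_true(all(is.finite(p$E)))
  expect_equal(rowSums(p$A), rep(1, 4), tolerance = 1e-12)
})

test_that("random initialization is seed-reproducible and stochastic", {
  a <- init_random(3, 5, seed = 10)
  b <- init_random(3, 5, seed = 10)
  d <- init_random(3, 5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$E, d$E))
  expect_true(all(a$E > 0.1 & a$E < 0.9))
  expect_equal(rowSums(a$A), rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(a$pi), 1, tolerance = 1e-12)
})

test_that("single-state EM recovers empirical frequencies", {
  O <- random_obs(4, 60, seed = 4)
  bins <- bins_for(O)
  fit <- em_fit(O, bins, K = 1, mode = "batch", max_iter = 10)
  pc <- 1e-2
  want <- (rowSums(O$mat) + pc) / (60 + 2 * pc)
  expect_equal(unname(fit$params$E[1, ]), unname(want), tolerance = 1e-9)
})

test_that("batch EM log-likelihood is non-decreasing", {
  for (seed in c(2, 5, 9)) {
    O <- random_obs(4, 80, seed = seed)
    bins <- genome_bins(c(chr1 = 50 * 200, chr2 = 30 * 200), 200)
    fit <- em_fit(O, bins, init = init_random(3, 4, seed + 100),
                  mode = "batch", max_iter = 40)
    expect_true(all(diff(fit$trace$loglik) >= -1e-8))
  }
})

test_that("incremental EM reaches the batch solution on easy data", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 3e5, chr2 = 3e5), seed = 2)
  ds <- simulate_dataset(cfg)
  fb <- em_fit(ds$O, ds$bins, K = 4, mode = "batch", max_iter = 150)
  fi <- em_fit(ds$O, ds$bins, K = 4, mode = "incremental", max_iter = 150)
  llb <- log_likelihood(ds$O, ds$bins, fb$params)
  lli <- log_likelihood(ds$O, ds$bins, fi$params)
  expect_lt(abs(llb - lli) / abs(llb), 1e-3)
  expect_true(fi$trace$converged)
})

test_that("label permutation of the init permutes the fit identically", {
  O <- random_obs(3, 60, seed = 6)
  bins <- bins_for(O)
  init <- init_random(3, 3, seed = 17)
  perm <- c(2, 3, 1)
  init_p <- hmm_params(init$pi[perm], init$A[perm, perm],
                       init$E[perm, , drop = FALSE])
  f1 <- em_fit(O, bins, init = init, mode = "batch", max_iter = 15)
  f2 <- em_fit(O, bins, init = init_p, mode = "batch", max_iter = 15)
  expect_equal(f2$params$E, f1$params$E[perm, , drop = FALSE],
               tolerance = 1e-8)
  expect_equal(f2$params$A, f1$params$A[perm, perm], tolerance = 1e-8)
  expect_equal(f2$trace$loglik, f1$trace$loglik, tolerance = 1e-8)
})

test_that("decoding agrees with enumeration on near-deterministic chains", {
  p <- hmm_params(c(0.99, 0.01), rbind(c(0.95, 0.05), c(0.05, 0.95)),
                  rbind(c(0.95, 0.95), c(0.05, 0.05)))
  obs <- rbind(c(1L, 1L, 0L, 0L, 1L), c(1L, 1L, 0L, 0L, 1L))
  O <- structure(list(mat = obs,
                      row_labels = data.frame(mark = "m",
                                              cell = c("c1", "c2"))),
                 class = "observation_matrix")
  bins <- bins_for(O)
  oracle <- enum_hmm(obs, p)
  post <- decode(O, bins, p, method = "posterior")
  vit <- decode(O, bins, p, method = "viterbi")
  want <- apply(oracle$posterior, 2, which.max)
  expect_equal(post$states, want)
  expect_equal(vit$states, unname(oracle$map_path))
})

test_that("decoding ties resolve to the lowest state index", {
  K <- 3
  p <- hmm_params(rep(1 / K, K), matrix(1 / K, K, K), matrix(0.5, K, 2))
  O <- structure(list(mat = matrix(0L, 2, 6),
                      row_labels = data.frame(mark = "m",
                                              cell = c("c1", "c2"))),
                 class = "observation_matrix")
  bins <- bins_for(O)
  expect_true(all(decode(O, bins, p, "posterior")$states == 1L))
  expect_true(all(decode(O, bins, p, "viterbi")$states == 1L))
  # single-bin chromosome, posterior method = argmax pi * emission
  O1 <- O; O1$mat <- matrix(c(1L, 0L), 2, 1)
  b1 <- genome_bins(c(chr1 = 200), 200)
  p2 <- hmm_params(c(0.2, 0.8), matrix(0.5, 2, 2),
                   rbind(c(0.9, 0.1), c(0.2, 0.2)))
  w <- p2$pi * apply(p2$E, 1, function(e) e[1] * (1 - e[2]))
  expect_equal(decode(O1, b1, p2, "posterior")$states, which.max(w))
})

test_that("model JSON round-trips at full precision", {
  p <- init_random(3, 5, seed = 23)
  p$row_labels <- data.frame(mark = rep("m", 5), cell = paste0("c", 1:5))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hmm_model(p, tmp)
  q <- read_hmm_model(tmp)
  expect_identical(q$pi, p$pi)
  expect_identical(unname(q$A), unname(p$A))
  expect_identical(unname(q$E), unname(p$E))
  expect_equal(q$row_labels, p$row_labels)
})
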