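# Forward-backward: exactness against path enumeration, locus skipping,
# and meta-locus compression.

rand_hmm <- function(S, D, seed) {
  withr::with_seed(seed, {
    A <- matrix(rexp(S * S), S); A <- A / rowSums(A)
    B <- matrix(rexp(S * D), S, D); B <- B / rowSums(B)
    Pi <- rexp(S); Pi <- Pi / sum(Pi)
    list(A = A, B = B, Pi = Pi)
  })
}

enumerate_oracle <- function(d, A, B, Pi) {
  S <- nrow(A); L <- length(d)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), L)))
  lik <- 0; xi <- matrix(0, S, S); em <- matrix(0, S, ncol(B)); init <- numeric(S)
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    w <- Pi[p[1]] * B[p[1], d[1] + 1]
    if (L > 1) for (l in 2:L) w <- w * A[p[l - 1], p[l]] * B[p[l], d[l] + 1]
    lik <- lik + w
    if (L > 1) for (l in 2:L) xi[p[l - 1], p[l]] <- xi[p[l - 1], p[l]] + w
    for (l in 1:L) em[p[l], d[l] + 1] <- em[p[l], d[l] + 1] + w
    init[p[1]] <- init[p[1]] + w
  }
  list(loglik = log(lik), trans = xi / lik, emis = em / lik, init = init / lik)
}

test_that("forward-backward equals exhaustive path enumeration", {
  for (seed in 1:3) {
    h <- rand_hmm(2, 2, seed)
    d <- withr::with_seed(seed + 100, sample(0:1, 3, replace = TRUE))
    oracle <- enumerate_oracle(d, h$A, h$B, h$Pi)
    st <- forward_backward(chmm_obs(d, rep(1, 3), n = 2), h$A, h$B, h$Pi)
    expect_equal(st$loglik, oracle$loglik, tolerance = 1e-12)
    expect_equal(st$trans, oracle$trans, tolerance = 1e-12)
    expect_equal(st$emis, oracle$emis, tolerance = 1e-12)
    expect_equal(st$init, oracle$init, tolerance = 1e-12)
  }
  # longer sequence, more states
  h <- rand_hmm(3, 2, 7)
  d <- withr::with_seed(7, sample(0:1, 6, replace = TRUE))
  oracle <- enumerate_oracle(d, h$A, h$B, h$Pi)
  st <- forward_backward(obs_compress(d, n = 2), h$A, h$B, h$Pi)
  expect_equal(st$loglik, oracle$loglik, tolerance = 1e-10)
  expect_equal(st$trans, oracle$trans, tolerance = 1e-10)
})

test_that("single-state chain reduces to independent emissions", {
  B <- matrix(c(0.9, 0.1), 1, 2)
  A <- matrix(1, 1, 1)
  d <- c(0L, 1L, 0L, 0L, 1L)
  st <- forward_backward(obs_compress(d, n = 2), A, B, 1)
  expect_equal(st$loglik, sum(log(B[1, d + 1])))
})

test_that("posterior marginals normalize at every locus", {
  h <- rand_hmm(4, 3, 11)
  d <- withr::with_seed(12, sample(0:2, 50, replace = TRUE, prob = c(.8, .1, .1)))
  st <- forward_backward(obs_compress(d, n = 4), h$A, h$B, h$Pi, posterior = TRUE)
  post <- attr(st, "posterior")
  expect_equal(rowSums(post), rep(1, 50), tolerance = 1e-12)
})

test_that("locus skipping equals the naive recursion", {
  # randomized instances (property check)
  for (seed in 1:12) {
    S <- withr::with_seed(seed, sample(2:6, 1))
    D <- withr::with_seed(seed + 1, sample(2:4, 1))
    h <- rand_hmm(S, D, seed)
    d <- withr::with_seed(seed + 2,
      sample(0:(D - 1), 400, replace = TRUE,
             prob = c(0.9, rep(0.1 / (D - 1), D - 1))))
    obs <- obs_compress(d, n = D)
    a <- forward_backward(obs, h$A, h$B, h$Pi)
    b <- forward_backward_skipping(obs, h$A, h$B, h$Pi)
    expect_lt(abs(a$loglik - b$loglik), 1e-6)
    expect_lt(max(abs(a$trans - b$trans)), 1e-5)
    expect_lt(max(abs(a$emis - b$emis)), 1e-5)
    expect_lt(max(abs(a$init - b$init)), 1e-8)
  }
})

test_that("locus skipping handles very long invariant runs", {
  h <- rand_hmm(5, 3, 42)
  d <- rep(0L, 1e5)
  snp_at <- withr::with_seed(43, sort(sample(1e5, 10)))
  d[snp_at] <- withr::with_seed(44, sample(1:2, 10, replace = TRUE))
  obs <- obs_compress(d, n = 3)
  a <- forward_backward(obs, h$A, h$B, h$Pi)
  b <- forward_backward_skipping(obs, h$A, h$B, h$Pi)
  expect_lt(abs(a$loglik - b$loglik), 1e-6)
  expect_lt(max(abs(a$trans - b$trans)), 1e-5)
  expect_lt(max(abs(a$emis - b$emis)), 1e-5)
  # run of length 1 everywhere reduces to the standard recursion
  d1 <- withr::with_seed(45, sample(0:2, 30, replace = TRUE))
  obs1 <- chmm_obs(d1, rep(1, 30), n = 3)
  expect_lt(abs(forward_backward_skipping(obs1, h$A, h$B, h$Pi)$loglik -
                forward_backward(obs1, h$A, h$B, h$Pi)$loglik), 1e-9)
})

test_that("expected counts satisfy the counting identities", {
  h <- rand_hmm(4, 3, 5)
  d <- withr::with_seed(6, sample(0:2, 5000, replace = TRUE, prob = c(.95, .02, .03)))
  obs <- obs_compress(d, n = 4)
  st <- forward_backward_skipping(obs, h$A, h$B, h$Pi)
  expect_equal(sum(st$trans), 5000 - 1, tolerance = 1e-6)
  expect_equal(sum(st$emis), 5000, tolerance = 1e-6)
  expect_equal(sum(st$init), 1, tolerance = 1e-9)
  # statistics are additive across chromosomes
  st2 <- add_suffstats(st, st)
  expect_equal(st2$loglik, 2 * st$loglik)
  expect_equal(sum(st2$emis), 2 * 5000, tolerance = 1e-6)
})

test_that("observation compression round-trips", {
  d <- withr::with_seed(2, sample(0:3, 500, replace = TRUE, prob = c(.9, .05, .03, .02)))
  obs <- obs_compress(d, n = 5)
  expect_identical(obs_expand(obs), d)
  expect_identical(obs_compress(obs_expand(obs), n = 5)$len, obs$len)
  expect_equal(total_loci(obs), 500)
})

test_that("meta-locus compression: window 1 is exact, bookkeeping conserved", {
  h <- rand_hmm(4, 3, 8)
  d <- withr::with_seed(9, sample(0:2, 600, replace = TRUE, prob = c(.9, .06, .04)))
  obs <- obs_compress(d, n = 3)
  naive <- forward_backward(obs, h$A, h$B, h$Pi)
  meta1 <- meta_locus_compress(obs, 1)
  st1 <- forward_backward_meta(meta1, h$A, h$B, h$Pi)
  expect_lt(abs(st1$loglik - naive$loglik), 1e-9)
  # SNP counts conserved under any window size
  for (w in c(7, 50)) {
    meta <- meta_locus_compress(obs, w)
    per_window_d <- vapply(meta$key_def[meta$key_idx],
                           function(kd) sum(kd$snps), 0)
    expect_equal(sum(per_window_d), sum(d))
    lens <- vapply(meta$key_def[meta$key_idx], function(kd) kd$len, 0L)
    expect_equal(sum(lens), 600)
  }
})

test_that("meta-locus EM self-consistency at moderate windows", {
  # constant-size synthetic data: lambda inferred through w = 100 windows
  # is close to the exact w = 1 inference
  m <- const_model()
  disc <- tmrca_discretization(8, 2, m)
  pr <- build_chmm_probs(m, 2, disc, "tmrca")
  obs <- sample_from_chmm(pr$A, pr$B, pr$Pi, 2e5, seed = 77)
  w <- 100
  meta <- meta_locus_compress(obs, w)
  ll_at <- function(lam, use_meta) {
    mm <- const_model(lam)
    p <- build_chmm_probs(mm, 2, disc, "tmrca", rho = rho_rate(m),
                          theta = theta_rate(m))
    if (use_meta) {
      trm <- build_transition_tmrca(mm, 2, disc, rho = w * rho_rate(m))
      forward_backward_meta(meta, trm$A, p$B, trm$Pi)$loglik
    } else {
      forward_backward_skipping(obs, p$A, p$B, p$Pi)$loglik
    }
  }
  lams <- seq(0.7, 1.4, by = 0.05)
  opt_exact <- lams[which.max(vapply(lams, ll_at, 0, use_meta = FALSE))]
  opt_meta <- lams[which.max(vapply(lams, ll_at, 0, use_meta = TRUE))]
  expect_lt(abs(opt_meta / opt_exact - 1), 0.1 + 1e-9)
})

test_that("run-level posterior decoding normalizes and tracks SNPs", {
  m <- const_model()
  disc <- tmrca_discretization(6, 2, m)
  pr <- build_chmm_probs(m, 2, disc, "tmrca")
  obs <- sample_from_chmm(pr$A, pr$B, pr$Pi, 5e4, seed = 3)
  post <- decode_runs(obs, pr$A, pr$B, pr$Pi)
  pm <- as.matrix(post[, grep("^state_", names(post))])
  expect_equal(rowSums(pm), rep(1, nrow(post)), tolerance = 1e-9)
  expect_equal(post$end[nrow(post)], 5e4)
  expect_true(all(post$end > post$start))
})
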