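# Composite-likelihood subsets, the expected log-likelihood objective, the
# Nelder-Mead M-step, and the pseudo-haploid emission layer.

test_that("subset schemes count and partition correctly", {
  # all overlapping pairs from 10 haplotypes (explicit mode)
  pairs <- combn(10, 2, identity, simplify = FALSE)
  sc <- build_subsets(10, subsets = pairs)
  expect_length(sc$subsets, 45)
  # non-overlapping by-sizes: 200 / c(2, 5, 10) -> 100 + 40 + 20
  sc2 <- build_subsets(200, sizes = c(2, 5, 10), seed = 3)
  expect_length(sc2$subsets, 160)
  for (sz in c(2, 5, 10)) {
    members <- unlist(sc2$subsets[sc2$sizes == sz])
    expect_false(any(duplicated(members)))   # disjoint within a size class
  }
  # full sample as a single subset
  sc3 <- build_subsets(10, sizes = 10)
  expect_length(sc3$subsets, 1)
  expect_equal(sc3$subsets[[1]], 1:10)
  # remainder discarded
  sc4 <- build_subsets(7, sizes = 3, seed = 1)
  expect_length(sc4$subsets, 2)
  expect_error(build_subsets(4, sizes = 5), "exceeds")
  expect_error(build_subsets(4, sizes = 1))
  # seeded determinism
  expect_identical(build_subsets(20, sizes = c(2, 5), seed = 9)$subsets,
                   build_subsets(20, sizes = c(2, 5), seed = 9)$subsets)
})

test_that("subset files parse into explicit schemes", {
  f <- withr::local_tempfile(lines = c("1 2", "2 3", " 4  5 "))
  sc <- read_subset_file(f, 5)
  expect_length(sc$subsets, 3)
  expect_equal(sc$subsets[[2]], c(2L, 3L))
  expect_equal(sc$mode, "explicit")
})

test_that("q_function reduces to single-term forms and respects c12", {
  m <- const_model()
  disc <- tmrca_discretization(4, 2, m)
  builder <- function(params, k) {
    mm <- m; mm$log_rates <- params
    build_chmm_probs(mm, 2, disc, "tmrca", rho = rho_rate(m),
                     theta = theta_rate(m))
  }
  probs <- builder(0, 1)
  # stats concentrated on one transition cell
  st <- coalsize:::new_suffstats(
    trans = matrix(c(0, 3, 0, 0, rep(0, 12)), 4, 4), emis = matrix(0, 4, 2),
    init = rep(0, 4), loglik = 0, n_s = 2, total_loci = 4)
  expect_equal(q_function(0, list(st), builder), 3 * log(probs$A[2, 1]))
  expect_equal(q_function(0, list(st), builder, c12 = 0),
               q_function(0, list(st), builder))
  # penalty on adjacent log-rate differences
  m2 <- coal_model(c(0, 0.5), change_points = 1)
  builder2 <- function(params, k) {
    mm <- m2; mm$log_rates <- params
    build_chmm_probs(mm, 2, disc, "tmrca", rho = rho_rate(m2),
                     theta = theta_rate(m2))
  }
  q0 <- q_function(c(0, 0.5), list(st), builder2, c12 = 0)
  q1 <- q_function(c(0, 0.5), list(st), builder2, c12 = 10)
  expect_equal(q0 - q1, 10 * 0.25)
})

test_that("q at the generating parameters beats perturbations", {
  m <- const_model()
  disc <- tmrca_discretization(8, 2, m)
  probs <- build_chmm_probs(m, 2, disc, "tmrca")
  obs <- sample_from_chmm(probs$A, probs$B, probs$Pi, 2e5, seed = 21)
  st <- forward_backward_skipping(obs, probs$A, probs$B, probs$Pi)
  builder <- function(params, k) {
    mm <- m; mm$log_rates <- params
    build_chmm_probs(mm, 2, disc, "tmrca", rho = rho_rate(m),
                     theta = theta_rate(m))
  }
  q_true <- q_function(0, list(st), builder)
  perturb <- withr::with_seed(5, runif(10, -1, 1))
  perturb <- perturb[abs(perturb) > 0.1]
  for (p in perturb) {
    expect_gt(q_true, q_function(p, list(st), builder))
  }
})

test_that("m_step recovers rates from expected statistics and stays at optima", {
  m <- const_model()
  disc <- tmrca_discretization(8, 2, m)
  probs <- build_chmm_probs(m, 2, disc, "tmrca")
  L <- 1e6
  # expected (infinite-data) sufficient statistics under the model itself
  st <- coalsize:::new_suffstats(
    trans = (L - 1) * probs$Pi * probs$A,
    emis = L * probs$Pi * probs$B,
    init = probs$Pi, loglik = 0, n_s = 2, total_loci = L)
  builder <- function(params, k) {
    mm <- m; mm$log_rates <- params
    build_chmm_probs(mm, 2, disc, "tmrca", rho = rho_rate(m),
                     theta = theta_rate(m))
  }
  cfg <- em_config()
  par1 <- m_step(list(st), current_params = log(0.7), builder, cfg)
  expect_lt(abs(par1 - 0), 0.05)   # true log-rate is 0
  # starting at the optimum does not move away
  par2 <- m_step(list(st), current_params = as.numeric(par1), builder, cfg)
  expect_lt(abs(par2 - par1), cfg$nm_xtol * 2)
})

test_that("initial simplex follows the two-regime rule", {
  cfg <- em_config(simplex_offset = 0.3, simplex_frac = 0.05)
  s3 <- coalsize:::initial_simplex(c(0.1, -0.2, 0.4), cfg)
  expect_equal(dim(s3), c(4, 3))
  expect_equal(s3[2, 1] - 0.1, 0.3)     # alternating +/- fixed offsets
  expect_equal(s3[3, 2] - (-0.2), -0.3)
  expect_equal(s3[4, 3] - 0.4, 0.3)
  x0 <- c(1, -2, 0.5, 3, -1, 2)
  s6 <- coalsize:::initial_simplex(x0, cfg)
  expect_equal(dim(s6), c(7, 6))
  for (i in 1:6) {
    expect_equal(s6[i + 1, i], x0[i] * 1.05)   # relative perturbation
  }
})

test_that("pseudo-haploid emission downsamples hypergeometrically", {
  # 2n = 4, d' = 2, n = 2: P(1) = 2/3, P(0) = P(2) = 1/6
  expect_equal(dhyper(0:2, m = 2, n = 2, k = 2), c(1 / 6, 2 / 3, 1 / 6))
  B4 <- diag(4)[, 1:4]   # rows concentrated on d' = 0..3
  rownames(B4) <- NULL
  Bp <- pseudo_haploid_emission(B4, 2)
  expect_equal(dim(Bp), c(4, 2))
  expect_equal(Bp[1, ], c(1, 0))             # d' = 0 -> d = 0 surely
  expect_equal(Bp[3, ], c(1 / 6, 2 / 3) / (1 / 6 + 2 / 3))  # d' = 2, truncated at d = 2
  expect_equal(rowSums(Bp), rep(1, 4), tolerance = 1e-10)
  m <- const_model()
  em4 <- build_emission_tmrca(m, 4, tmrca_discretization(6, 4, m),
                              theta = 5e-4)
  emp <- pseudo_haploid_emission(em4, 2)
  expect_equal(rowSums(emp$B), rep(1, 6), tolerance = 1e-10)
})

test_that("EM increases the composite likelihood and finds the MLE", {
  m <- const_model()
  disc <- tmrca_discretization(12, 2, m)
  probs <- build_chmm_probs(m, 2, disc, "tmrca")
  obs <- sample_from_chmm(probs$A, probs$B, probs$Pi, 4e5, seed = 31)
  m0 <- const_model(0.6)
  fit <- run_em(obs, m0, S = 12, config = em_config(max_iters = 25))
  ll <- fit$trajectory$loglik
  expect_true(all(diff(ll) > -1e-4))   # monotone up to M-step tolerance
  # EM lands on the maximum-likelihood rate located by direct search
  # (run on the same discretization the EM machinery uses)
  disc0 <- tmrca_discretization(12, 2, m0)
  ll_of <- function(loglam) {
    mm <- m; mm$log_rates <- loglam
    p <- build_chmm_probs(mm, 2, disc0, "tmrca", rho = rho_rate(m),
                          theta = theta_rate(m))
    forward_backward_skipping(obs, p$A, p$B, p$Pi)$loglik
  }
  opt <- optimize(ll_of, c(-1, 1), maximum = TRUE, tol = 1e-4)
  expect_lt(abs(fit$model$log_rates - opt$maximum), 0.02)
  expect_equal(nrow(tidy(fit)), 1)
  expect_true(glance(fit)$iterations <= 25)
})

test_that("EM is deterministic given data and configuration", {
  m <- const_model()
  disc <- tmrca_discretization(8, 2, m)
  probs <- build_chmm_probs(m, 2, disc, "tmrca")
  obs <- sample_from_chmm(probs$A, probs$B, probs$Pi, 1e5, seed = 8)
  f1 <- run_em(obs, const_model(0.8), S = 8, config = em_config(max_iters = 3))
  f2 <- run_em(obs, const_model(0.8), S = 8, config = em_config(max_iters = 3))
  expect_identical(f1$model$log_rates, f2$model$log_rates)
  expect_identical(f1$trajectory$loglik, f2$trajectory$loglik)
})

test_that("composite likelihood prefers the truth over a misspecified size", {
  m <- const_model()
  disc <- tmrca_discretization(8, 2, m)
  probs <- build_chmm_probs(m, 2, disc, "tmrca")
  obs <- sample_from_chmm(probs$A, probs$B, probs$Pi, 3e5, seed = 13)
  ll_of <- function(lam) {
    mm <- const_model(lam)
    p <- build_chmm_probs(mm, 2, disc, "tmrca", rho = rho_rate(m),
                          theta = theta_rate(m))
    forward_backward_skipping(obs, p$A, p$B, p$Pi)$loglik
  }
  expect_gt(ll_of(1), ll_of(0.5))   # 2x misspecified population size
  expect_gt(ll_of(1), ll_of(2))
})
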