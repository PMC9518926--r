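# State enumeration, rate matrices, and the CHMM probability sets for the
# TMRCA hidden state.

test_that("two-locus state space matches hand enumeration", {
  sp <- rho_process(2)
  keys <- apply(sp$states, 1, paste, collapse = ",")
  expect_setequal(keys, c("2,0,0,0", "1,0,0,0", "1,1,1,1", "1,0,1,1",
                          "1,1,0,1", "1,0,0,1"))
  # independent brute-force closure for n = 3: states (k,0,0,0) for k=1..3
  # plus, after one recombination, (k, a, b, 1) with k=1,2 and a,b in {0,1}
  sp3 <- rho_process(3)
  brute <- c("3,0,0,0", "2,0,0,0", "1,0,0,0",
             apply(expand.grid(k = 1:2, a = 0:1, b = 0:1), 1,
                   function(r) paste(r["k"], r["a"], r["b"], 1, sep = ",")))
  expect_setequal(apply(sp3$states, 1, paste, collapse = ","), brute)
  expect_error(rho_process(1))
})

test_that("every non-absorbing two-locus state can leave, absorbing cannot", {
  for (n in c(2, 3, 5)) {
    sp <- rho_process(n)
    m <- coal_model(0)
    Q <- rho_rate_matrix(sp, m, 0, rho = 0.1)
    outrate <- -diag(Q)
    expect_true(all(outrate[-sp$absorbing] > 0))
    expect_equal(outrate[sp$absorbing], c(0, 0))
    expect_lt(max(abs(rowSums(Q))), 1e-14)
  }
})

test_that("two-locus rates follow the transition table", {
  sp <- rho_process(2)
  m <- coal_model(0)
  Q <- rho_rate_matrix(sp, m, 0, rho = 0.1)
  i <- function(k) sp$index[[k]]
  expect_equal(Q[i("2,0,0,0"), i("1,0,0,0")], 1)        # lambda * C(2,2... pairs)
  expect_equal(Q[i("2,0,0,0"), i("1,1,1,1")], 0.1)      # k_ab * rho / 2
  expect_equal(Q[i("1,1,1,1"), i("1,0,1,1")], 1)        # k_a * k_ab * lambda
  expect_equal(Q[i("1,0,1,1"), i("1,0,0,1")], 1)
  # no recombination once kappa = 1
  sp3 <- rho_process(3)
  Q3 <- rho_rate_matrix(sp3, m, 0, rho = 0.2)
  kap1 <- which(sp3$states[, "kappa"] == 1)
  kap_of_target <- sp3$states[, "kappa"]
  for (s in kap1) {
    tg <- which(Q3[s, ] > 0)
    expect_true(all(kap_of_target[setdiff(tg, s)] == 1))
  }
  # time dependence through lambda(t)
  m2 <- coal_model(c(0, log(2)), change_points = 1)
  Q2 <- rho_rate_matrix(rho_process(2), m2, 1.5, rho = 0)
  expect_equal(Q2[i("2,0,0,0"), i("1,0,0,0")], 2)
})

test_that("single-locus mutation state space matches hand enumeration", {
  sp2 <- theta_process(2)
  expect_setequal(paste(sp2$states[, 1], sp2$states[, 2], sep = ","),
                  c("2,-1", "1,-1", "2,2", "1,2"))
  sp3 <- theta_process(3)
  expect_setequal(paste(sp3$states[, 1], sp3$states[, 2], sep = ","),
                  c("3,-1", "2,-1", "1,-1", "3,3", "2,3", "1,3", "2,2", "1,2"))
  expect_false("1,1" %in% paste(sp3$states[, 1], sp3$states[, 2], sep = ","))
  expect_error(theta_process(1))
})

test_that("mutation process rates follow the transition table", {
  sp <- theta_process(3)
  m <- coal_model(0)
  Q <- theta_rate_matrix(sp, m, 0, theta = 0.002)
  i <- function(k) sp$index[[k]]
  expect_equal(Q[i("3,-1"), i("2,-1")], 3)
  expect_equal(Q[i("3,-1"), i("3,3")], 0.003)
  expect_equal(sum(abs(Q[i("1,-1"), ])), 0)   # absorbing
  # once mutated, no further mutation anywhere: (k, k*>=2) rows only coalesce
  mutated <- which(sp$states[, 2] >= 2)
  for (s in mutated) {
    tg <- which(Q[s, ] > 0)
    expect_true(all(sp$states[tg, 2] == sp$states[s, 2]))
  }
})

test_that("forward equation solution matches closed forms and conserves mass", {
  m <- const_model()
  sp <- rho_process(2)
  tt <- c(0.2, 0.7, 1.5, 3)
  g <- rho_state_probs(sp, m, tt, rho = 0)
  expect_equal(g[, sp$s_1000], 1 - exp(-tt), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(g) - 1)), 1e-7)
  # piecewise-constant rate: survival uses the integrated rate
  m2 <- coal_model(c(0, log(3)), change_points = 0.5)
  g2 <- rho_state_probs(rho_process(2), m2, 1.2, rho = 0)
  expect_equal(g2[1, sp$s_1000],
               1 - exp(-integrated_rate(m2, 0, 1.2)), tolerance = 1e-9)
  # infinite horizon: all mass absorbed
  ginf <- rho_state_probs(sp, m, Inf, rho = 0.3)
  expect_equal(sum(ginf[1, sp$absorbing]), 1, tolerance = 1e-9)
})

test_that("state probabilities match the Gillespie oracle", {
  reps <- 4e4
  for (n in c(2, 3)) {
    sp <- rho_process(n)
    sim <- gillespie_rho_oracle(n, lambda = 1, rho = 0.3, reps = reps,
                                seed = 20 + n)
    # compare absorbing masses at a time point via the oracle's TMRCAs
    for (tq in c(0.5, 1.5)) {
      g <- rho_state_probs(sp, const_model(), tq, rho = 0.3)[1, ]
      p_model <- sum(g[sp$absorbing])
      p_mc <- mean(sim[, "Ta"] <= tq & sim[, "Tb"] <= tq)
      expect_lt(abs(p_model - p_mc), mc_tol(p_model, reps))
    }
  }
})

test_that("derived-allele probabilities match the combinatorial formula", {
  expect_equal(derived_allele_prob(4, 2, 1:3), rep(1 / 3, 3))
  expect_equal(derived_allele_prob(4, 4, 1), 1)
  expect_equal(derived_allele_prob(4, 4, 2), 0)
  expect_error(derived_allele_prob(4, 2, 0), "d = 0")
  for (n in 2:12) {
    for (ks in 2:n) {
      expect_equal(sum(derived_allele_prob(n, ks, seq_len(n - 1))), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("TMRCA transition set has the exact analytic limits", {
  m <- const_model()
  disc <- coal_disc(c(0, log(2), Inf))
  tr <- build_transition_tmrca(m, 2, disc, rho = 0)
  expect_equal(tr$Pi, c(0.5, 0.5), tolerance = 1e-6)
  expect_lt(max(abs(tr$A - diag(2))), 1e-6)
  # rho -> 0 on a finer grid and larger n
  tr10 <- build_transition_tmrca(m, 10, tmrca_discretization(12, 10, m),
                                 rho = 0)
  expect_lt(max(abs(tr10$A - diag(12))), 1e-5)
})

test_that("joint TMRCA CDF is symmetric, monotone, and oracle-consistent", {
  m <- const_model()
  sp <- rho_process(2)
  expect_equal(joint_tmrca_cdf(m, 2, log(2), log(2), rho = 0, spec = sp), 0.5,
               tolerance = 1e-7)
  expect_equal(joint_tmrca_cdf(m, 2, 0.5, 1.5, rho = 0.05, spec = sp),
               joint_tmrca_cdf(m, 2, 1.5, 0.5, rho = 0.05, spec = sp))
  grid <- c(0.3, 0.8, 1.4, 2.5)
  vals <- outer(grid, grid, Vectorize(function(a, b)
    joint_tmrca_cdf(m, 2, a, b, rho = 0.05, spec = sp)))
  expect_true(all(diff(vals) > 0), info = "monotone in each argument")
  expect_true(all(t(diff(t(vals))) > 0))
})

test_that("TMRCA transitions and marginals agree across machinery", {
  # Pi from the two-locus joint equals the single-locus interval masses
  m <- sawtooth_model()
  for (n in c(2, 5)) {
    disc <- tmrca_discretization(10, n, m)
    tr <- build_transition_tmrca(m, n, disc, rho = 5e-4)
    marg <- diff(tmrca_cdf(m, n, disc$boundaries))
    expect_lt(max(abs(tr$Pi - marg)), 1e-5)
    expect_lt(max(abs(rowSums(tr$A) - 1)), 1e-8)
    expect_lt(max(abs(tr$A_pmf - t(tr$A_pmf))), 1e-6)
  }
})

test_that("TMRCA emission set behaves in the small-theta regime", {
  m <- const_model()
  disc <- tmrca_discretization(10, 2, m)
  em0 <- build_emission_tmrca(m, 2, disc, theta = 0)
  expect_true(all(em0$B[, 1] > 1 - 1e-7))
  em <- build_emission_tmrca(m, 2, disc, theta = 0.001)
  expect_lt(max(abs(rowSums(em$B) - 1)), 1e-8)
  expect_equal(sum(em$B_cdf[nrow(em$B_cdf), ]), 1, tolerance = 1e-6)
  tr <- build_transition_tmrca(m, 2, disc, rho = 0)
  p1 <- sum(tr$Pi * em$B[, 2])
  expect_lt(abs(p1 / 0.001 - 1), 0.05)   # P[d = 1] ~ theta E[L] / 2 = theta
  # emission CDF classes match the mutation-process oracle
  reps <- 4e4
  sim <- gillespie_theta_oracle(3, lambda = 1, theta = 0.5, reps = reps,
                                seed = 9)
  sp <- theta_process(3)
  g <- theta_state_probs(sp, m, 1.0, theta = 0.5)[1, ]
  for (ks in c(-1, 2, 3)) {
    p_model <- if (ks == -1) g[sp$absorbed_nomut]
               else g[sp$index[[paste(1, ks, sep = ",")]]]
    p_mc <- mean(sim[, "T"] <= 1.0 & sim[, "k_star"] == ks)
    expect_lt(abs(p_model - p_mc), mc_tol(p_model, reps))
  }
})

test_that("row-stochasticity holds across sample sizes and models", {
  for (m in list(const_model(), sawtooth_model())) {
    for (n in c(2, 3, 5, 10)) {
      disc <- tmrca_discretization(8, n, m)
      tr <- build_transition_tmrca(m, n, disc, rho = 5e-4)
      em <- build_emission_tmrca(m, n, disc, theta = 5e-4)
      expect_lt(max(abs(rowSums(tr$A) - 1)), 1e-8)
      expect_lt(max(abs(rowSums(em$B) - 1)), 1e-8)
      expect_equal(sum(tr$Pi), 1, tolerance = 1e-8)
    }
  }
})
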