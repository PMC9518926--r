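# Independent Monte-Carlo oracles: direct Gillespie simulation of the
# augmented ancestral processes from their transition-rate tables, with
# branch-length accumulation. These deliberately do not reuse the package's
# rate matrices or solvers.

# two-locus process with at most one recombination; constant coalescent
# rate. Returns per replicate the locus TMRCAs and accumulated lengths.
gillespie_rho_oracle <- function(n, lambda, rho, reps, seed = 1) {
  withr::with_seed(seed, {
    out <- matrix(NA_real_, reps, 4,
                  dimnames = list(NULL, c("Ta", "Tb", "La", "Lb")))
    for (r in seq_len(reps)) {
      k_ab <- n; k_a <- 0L; k_b <- 0L; kap <- 0L
      t <- 0; Ta <- NA_real_; Tb <- NA_real_; La <- 0; Lb <- 0
      repeat {
        if (k_ab == 1 && k_a == 0 && k_b == 0) break
        va <- k_ab + k_a; if (va <= 1) va <- 0
        vb <- k_ab + k_b; if (vb <= 1) vb <- 0
        rates <- c(lambda * choose(k_ab, 2),
                   lambda * (choose(k_a, 2) + k_a * k_ab),
                   lambda * (choose(k_b, 2) + k_b * k_ab),
                   if (kap == 0) k_ab * rho / 2 else 0)
        tot <- sum(rates)
        dt <- rexp(1, tot)
        t <- t + dt; La <- La + va * dt; Lb <- Lb + vb * dt
        ev <- sample.int(4, 1, prob = rates)
        if (ev == 1) k_ab <- k_ab - 1
        else if (ev == 2) k_a <- k_a - 1
        else if (ev == 3) k_b <- k_b - 1
        else { k_ab <- k_ab - 1; k_a <- k_a + 1; k_b <- k_b + 1; kap <- 1L }
        if (is.na(Ta) && k_ab + k_a == 1) Ta <- t
        if (is.na(Tb) && k_ab + k_b == 1) Tb <- t
      }
      if (is.na(Ta)) Ta <- t
      if (is.na(Tb)) Tb <- t
      out[r, ] <- c(Ta, Tb, La, Lb)
    }
    out
  })
}

# single-locus process with at most one mutation; returns the TMRCA, the
# lineage count at the mutation (-1 when none), and the accumulated length.
gillespie_theta_oracle <- function(n, lambda, theta, reps, seed = 1) {
  withr::with_seed(seed, {
    out <- matrix(NA_real_, reps, 3,
                  dimnames = list(NULL, c("T", "k_star", "L")))
    for (r in seq_len(reps)) {
      k <- n; ks <- -1L; t <- 0; L <- 0
      while (k > 1) {
        rates <- c(lambda * choose(k, 2), if (ks == -1) k * theta / 2 else 0)
        dt <- rexp(1, sum(rates))
        t <- t + dt; L <- L + k * dt
        if (sample.int(2, 1, prob = c(rates, 0)[1:2]) == 1) k <- k - 1
        else ks <- k
      }
      out[r, ] <- c(t, ks, L)
    }
    out
  })
}

# three-sigma binomial tolerance for an empirical probability
mc_tol <- function(p, reps) 3 * sqrt(pmax(p * (1 - p), 1e-12) / reps)

const_model <- function(lambda = 1, N0 = 1e4, mu = 1.25e-8, r = 1.25e-8) {
  coal_model(log(lambda), N0 = N0, mu = mu, r = r)
}

# a sawtooth-like piecewise model exercising several epochs
sawtooth_model <- function(N0 = 1e4) {
  coal_model(log(c(1, 1 / 3, 2, 1 / 2)), change_points = c(0.1, 0.5, 1.5),
             N0 = N0, mu = 1.25e-8, r = 1.25e-8)
}
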