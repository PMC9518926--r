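# Transition and emission probabilities of the CHMM with the TMRCA as the
# hidden state, derived from the augmented ancestral processes.

#' Joint CDF of the TMRCAs at two adjacent loci
#'
#' Computes `P[T_a <= tau_a, T_b <= tau_b]` for two loci separated by scaled
#' recombination rate `rho`, from the absorbing-state probabilities of the
#' two-locus ancestral process: with `tau_a` the smaller argument, the joint
#' CDF is the absorbed mass at `tau_a` plus the probability that locus a is
#' absorbed while locus b still has two lineages, times the probability that
#' the remaining pair coalesces before `tau_b`.
#'
#' @param model A `coal_model`.
#' @param n Sample size.
#' @param tau_a,tau_b Evaluation times (either may be `Inf`).
#' @param rho Scaled recombination rate between the loci.
#' @param spec Optional pre-built [rho_process()] for `n`.
#' @return A probability.
#' @export
joint_tmrca_cdf <- function(model, n, tau_a, tau_b, rho = rho_rate(model),
                            spec = rho_process(n)) {
  stopifnot(tau_a >= 0, tau_b >= 0)
  lo <- min(tau_a, tau_b); hi <- max(tau_a, tau_b)
  g <- rho_state_probs(spec, model, lo, rho = rho)[1, ]
  joint_cdf_from_g(spec, model, g, lo, hi)
}

joint_cdf_from_g <- function(spec, model, g_lo, lo, hi) {
  if (lo == 0) return(0)
  absorbed <- g_lo[spec$s_1000] + g_lo[spec$s_1001]
  if (hi <= lo) return(absorbed)
  cross <- if (is.na(spec$s_1011)) 0 else g_lo[spec$s_1011]
  absorbed + cross * (1 - exp(-integrated_rate(model, lo, hi)))
}

#' Marginal CDF of the TMRCA of a sample
#'
#' Pure-coalescence absorption probability (single-locus ancestral process).
#'
#' @param model A `coal_model`.
#' @param n Sample size.
#' @param t Times (vectorized; entries may be `Inf`).
#' @return `P[TMRCA <= t]`.
#' @export
tmrca_cdf <- function(model, n, t) {
  spec <- theta_process(n)
  g <- theta_state_probs(spec, model, t, theta = 0)
  unname(g[, spec$absorbed_nomut])
}

#' CHMM transition set for the TMRCA hidden state
#'
#' Evaluates the joint TMRCA CDF at all pairs of discretization boundaries,
#' takes the two-dimensional finite difference to obtain the joint interval
#' probabilities, and conditions on the current state to obtain the
#' transition matrix `A`; the marginal `Pi` is the row sum of the joint PMF.
#' Infinite boundaries are handled analytically via the absorbing
#' distribution of the ancestral process.
#'
#' @param model A `coal_model`.
#' @param n Sample size.
#' @param disc A `coal_disc` hidden-state discretization.
#' @param rho Scaled recombination rate between adjacent sites (defaults to
#'   the model's per-base `4 N0 r`).
#' @param spec Optional pre-built [rho_process()].
#' @return An object of class `chmm_transition` with elements `A` (S x S,
#'   row-stochastic), `A_pmf`, `A_cdf` ((S+1) x (S+1)), `Pi`, and metadata.
#' @export
build_transition_tmrca <- function(model, n, disc, rho = rho_rate(model),
                                   spec = rho_process(n)) {
  stopifnot(inherits(disc, "coal_disc"))
  b <- disc$boundaries
  S <- disc$S
  g <- rho_state_probs(spec, model, b[-(S + 1)], rho = rho)
  a_cdf <- matrix(0, S + 1, S + 1)
  for (i in seq_len(S + 1)) {
    for (j in i:(S + 1)) {
      v <- if (i == S + 1) 1 else joint_cdf_from_g(spec, model, g[i, ], b[i], b[j])
      a_cdf[i, j] <- v
      a_cdf[j, i] <- v
    }
  }
  finish_transition(a_cdf, disc, hidden_state = "tmrca", n = n, rho = rho)
}

# Shared tail of the transition construction: 2D differencing of the CDF,
# clipping of floating-point noise, row normalization, marginal.
finish_transition <- function(a_cdf, disc, hidden_state, n, rho) {
  S <- disc$S
  pmf <- a_cdf[-1, -1, drop = FALSE] - a_cdf[-(S + 1), -1, drop = FALSE] -
    a_cdf[-1, -(S + 1), drop = FALSE] + a_cdf[-(S + 1), -(S + 1), drop = FALSE]
  clip <- -min(0, min(pmf))
  if (clip > 1e-6) {
    warning(sprintf("transition PMF clipped by %.2e", clip))
  }
  pmf[pmf < 0] <- 0
  pmf <- pmf / sum(pmf)
  Pi <- rowSums(pmf)
  if (any(Pi < 1e-12)) {
    stop("degenerate discretization: a hidden state has vanishing marginal probability")
  }
  A <- pmf / Pi
  structure(list(A = A, A_pmf = pmf, A_cdf = a_cdf, Pi = Pi, disc = disc,
                 hidden_state = hidden_state, n = n, rho = rho),
            class = "chmm_transition")
}

#' @export
print.chmm_transition <- function(x, ...) {
  cat(sprintf("<chmm_transition> hidden state: %s, S = %d, n = %d, rho = %g\n",
              x$hidden_state, x$disc$S, x$n, x$rho))
  invisible(x)
}

#' Probability that a mutation on k* lineages yields d derived alleles
#'
#' The probability that the mutated lineage (one of `k_star` lineages
#' present when the single mutation occurred) subtends `d` of the `n`
#' leaves: `choose(n - d - 1, k_star - 2) / choose(n - 1, k_star - 1)`.
#'
#' @param n Sample size.
#' @param k_star Number of lineages at the mutation event (`2..n`).
#' @param d Number of derived alleles (`1..n-1`, vectorized).
#' @return Probabilities summing to 1 over `d`.
#' @export
derived_allele_prob <- function(n, k_star, d) {
  stopifnot(k_star >= 2, k_star <= n)
  if (any(d < 1 | d > n - 1)) {
    stop("derived_allele_prob: d must lie in 1..n-1 (d = 0 has no mutation)")
  }
  num <- ifelse(n - d - 1 >= k_star - 2, choose(n - d - 1, k_star - 2), 0)
  num / choose(n - 1, k_star - 1)
}

#' CHMM emission set for the TMRCA hidden state
#'
#' Joint CDF of the TMRCA and the emitted derived-allele count from the
#' single-mutation ancestral process: `d = 0` corresponds to absorption
#' without mutation, `d >= 1` weights the absorbing states `(1, k_star)` by
#' the derived-allele probabilities. Time-differencing and row normalization
#' yield the emission matrix `B` over `d` in `0..n-1`.
#'
#' @param model A `coal_model`.
#' @param n Sample size.
#' @param disc A `coal_disc`.
#' @param theta Scaled per-site mutation rate (defaults to `4 N0 mu`).
#' @param spec Optional pre-built [theta_process()].
#' @return An object of class `chmm_emission` with `B` (S x n), `B_pmf`,
#'   `B_cdf` ((S+1) x n) and metadata.
#' @export
build_emission_tmrca <- function(model, n, disc, theta = theta_rate(model),
                                 spec = theta_process(n)) {
  stopifnot(inherits(disc, "coal_disc"))
  b <- disc$boundaries
  S <- disc$S
  g <- theta_state_probs(spec, model, b, theta = theta)
  finish_emission(emission_cdf_from_g(spec, g, n), disc, n = n, theta = theta,
                  hidden_state = "tmrca")
}

# B_CDF rows from absorbing-state probabilities: one row per boundary time.
emission_cdf_from_g <- function(spec, g, n) {
  b_cdf <- matrix(0, nrow(g), n)
  b_cdf[, 1] <- g[, spec$absorbed_nomut]
  if (n >= 2) {
    W <- vapply(2:n, function(ks) derived_allele_prob(n, ks, seq_len(n - 1)),
                numeric(n - 1)) # (n-1) x (n-1): d by k_star
    b_cdf[, -1] <- g[, spec$absorbed_mut, drop = FALSE] %*% t(W)
  }
  b_cdf
}

finish_emission <- function(b_cdf, disc, n, theta, hidden_state) {
  S <- disc$S
  pmf <- b_cdf[-1, , drop = FALSE] - b_cdf[-(S + 1), , drop = FALSE]
  clip <- -min(0, min(pmf))
  if (clip > 1e-6) warning(sprintf("emission PMF clipped by %.2e", clip))
  pmf[pmf < 0] <- 0
  rs <- rowSums(pmf)
  if (any(rs < 1e-12)) {
    stop("degenerate discretization: a hidden state has vanishing emission mass")
  }
  B <- pmf / rs
  structure(list(B = B, B_pmf = pmf, B_cdf = b_cdf, disc = disc, n = n,
                 theta = theta, hidden_state = hidden_state),
            class = "chmm_emission")
}

#' @export
print.chmm_emission <- function(x, ...) {
  cat(sprintf("<chmm_emission> hidden state: %s, S = %d, n = %d, theta = %g\n",
              x$hidden_state, x$disc$S, x$n, x$theta))
  invisible(x)
}
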