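#' Piecewise-constant demographic model
#'
#' Represents a time-varying coalescent rate \eqn{\lambda(t)} as a
#' piecewise-constant function of time measured in coalescent units of
#' \eqn{2 N_0} generations. The relative population size is
#' \eqn{\eta(t) = 1/\lambda(t)}, so the diploid population size \eqn{k}
#' generations before present is \eqn{N(k) = N_0 / \lambda(k / (2 N_0))}.
#' \eqn{\lambda} is right-continuous at its change points: at a change point
#' the rate of the epoch that begins there (going backward in time) applies.
#'
#' Rates are stored on the log scale, which keeps them positive by
#' construction and is the scale on which the EM algorithm optimizes them.
#'
#' @param log_rates Numeric vector, one log coalescent rate per epoch.
#' @param change_points Strictly increasing epoch start times in coalescent
#'   units (the first epoch implicitly starts at 0); length
#'   `length(log_rates) - 1`.
#' @param N0 Reference diploid population size (individuals).
#' @param mu Per-generation per-site mutation probability.
#' @param r Per-generation per-site recombination probability.
#' @return An object of class `coal_model`.
#' @examples
#' m <- coal_model(log_rates = c(0, log(2)), change_points = 1,
#'                 N0 = 1e4, mu = 1.25e-8, r = 1.25e-8)
#' coal_rate(m, c(0.5, 1, 2))
#' @export
coal_model <- function(log_rates, change_points = numeric(0), N0 = 1e4,
                       mu = 1.25e-8, r = 1.25e-8) {
  stopifnot(is.numeric(log_rates), length(log_rates) >= 1,
            all(is.finite(log_rates)),
            length(change_points) == length(log_rates) - 1)
  if (length(change_points) > 0) {
    stopifnot(all(change_points > 0), !is.unsorted(change_points, strictly = TRUE))
  }
  stopifnot(N0 > 0, mu >= 0, r >= 0)
  structure(
    list(log_rates = as.numeric(log_rates),
         change_points = as.numeric(change_points),
         N0 = N0, mu = mu, r = r),
    class = "coal_model"
  )
}

#' Build a model from diploid sizes at generation-scale change points
#'
#' Convenience constructor: sizes `N` are diploid population sizes per epoch,
#' `change_points_gen` the epoch start times in generations before present.
#' Internally sizes are converted to coalescent rates relative to `N0`
#' (default `N[1]`): \eqn{\lambda = N_0 / N}.
#'
#' @param N Diploid sizes, one per epoch.
#' @param change_points_gen Epoch start times in generations (length
#'   `length(N) - 1`).
#' @param N0 Reference size; defaults to the present-day size `N[1]`.
#' @inheritParams coal_model
#' @return A `coal_model`.
#' @export
coal_model_sizes <- function(N, change_points_gen = numeric(0), N0 = N[1],
                             mu = 1.25e-8, r = 1.25e-8) {
  stopifnot(all(N > 0))
  coal_model(log_rates = log(N0 / N),
             change_points = change_points_gen / (2 * N0),
             N0 = N0, mu = mu, r = r)
}

#' @export
print.coal_model <- function(x, ...) {
  cat(sprintf("<coal_model> %d epoch(s), N0 = %g, mu = %g, r = %g\n",
              length(x$log_rates), x$N0, x$mu, x$r))
  print(size_history(x), ...)
  invisible(x)
}

# epoch index for each time (right-continuous: change point belongs to the
# newer epoch going backward, i.e. the epoch that starts there)
epoch_index <- function(model, t) {
  findInterval(t, c(0, model$change_points), rightmost.closed = FALSE)
}

#' Coalescent rate at a time point
#'
#' @param model A `coal_model`.
#' @param t Time(s) in coalescent units, `t >= 0`.
#' @return `exp(log_rates[epoch(t)])`, vectorized over `t`.
#' @export
coal_rate <- function(model, t) {
  stopifnot(inherits(model, "coal_model"))
  if (any(t < 0)) stop("coal_rate: t must be nonnegative")
  exp(model$log_rates[epoch_index(model, t)])
}

#' Integrated coalescent rate over an interval
#'
#' Computes \eqn{\int_{t_{lo}}^{t_{hi}} \lambda(t)\,dt} exactly by summing
#' rate times overlap over the epochs. `t_hi = Inf` returns `Inf` whenever
#' the terminal rate is positive.
#'
#' @param model A `coal_model`.
#' @param t_lo,t_hi Interval bounds in coalescent units, `0 <= t_lo <= t_hi`.
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
integrated_rate <- function(model, t_lo, t_hi) {
  stopifnot(inherits(model, "coal_model"))
  if (t_lo < 0 || t_lo > t_hi) stop("integrated_rate: need 0 <= t_lo <= t_hi")
  rates <- exp(model$log_rates)
  if (is.infinite(t_hi)) {
    if (rates[length(rates)] > 0) return(Inf)
    t_hi <- max(t_lo, utils::tail(model$change_points, 1) %||% t_lo)
  }
  starts <- c(0, model$change_points)
  ends <- c(model$change_points, Inf)
  overlap <- pmax(0, pmin(ends, t_hi) - pmax(starts, t_lo))
  sum(rates * overlap)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Scaled mutation and recombination rates
#'
#' \eqn{\theta = 4 N_0 \mu} and \eqn{\rho = 4 N_0 r}, the per-site
#' population-scaled rates used by the hidden Markov machinery.
#'
#' @param model A `coal_model`.
#' @return A scalar.
#' @export
theta_rate <- function(model) 4 * model$N0 * model$mu

#' @rdname theta_rate
#' @export
rho_rate <- function(model) 4 * model$N0 * model$r

#' Population size history as a table
#'
#' @param model A `coal_model`.
#' @return A tibble with columns `generation_start`, `generation_end`,
#'   `N_diploid`, one row per epoch (times in generations before present).
#' @export
size_history <- function(model) {
  stopifnot(inherits(model, "coal_model"))
  starts <- c(0, model$change_points) * 2 * model$N0
  tibble::tibble(
    generation_start = starts,
    generation_end = c(starts[-1], Inf),
    N_diploid = model$N0 / exp(model$log_rates)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.coal_model <- function(x, ...) size_history(x)

#' Diploid size at a generation before present
#'
#' @param model A `coal_model`.
#' @param k Generations before present (vectorized).
#' @return `N0 / lambda(k / (2 N0))`.
#' @export
pop_size_at <- function(model, k) {
  model$N0 / coal_rate(model, k / (2 * model$N0))
}

#' Expected pairwise coalescent time under the model
#'
#' \eqn{E[T_2] = \int_0^\infty \exp(-\int_0^t \lambda) dt}, computed in
#' closed form per epoch. Its inverse serves as the harmonic-mean coalescent
#' rate used by the discretization heuristics.
#'
#' @param model A `coal_model`.
#' @return Expected pairwise TMRCA in coalescent units.
#' @export
expected_pairwise_tmrca <- function(model) {
  rates <- exp(model$log_rates)
  starts <- c(0, model$change_points)
  ends <- c(model$change_points, Inf)
  acc <- 0           # integral so far
  surv <- 0          # integrated rate up to epoch start
  for (e in seq_along(rates)) {
    len <- ends[e] - starts[e]
    lam <- rates[e]
    if (lam == 0) {
      if (is.infinite(len)) return(Inf)
      acc <- acc + exp(-surv) * len
    } else {
      acc <- acc + exp(-surv) * (1 - exp(-lam * min(len, Inf))) / lam
    }
    if (is.finite(len)) surv <- surv + lam * len
  }
  acc
}

#' Initialize a constant-size model by Watterson's estimator
#'
#' Uses the number of segregating sites `S` in `seq_len` sites of `n`
#' haplotypes: \eqn{\hat\theta = S / (L \sum_{i=1}^{n-1} 1/i)} per site and
#' \eqn{N_0 = \hat\theta / (4\mu)}. Returns the constant-size model
#' (\eqn{\lambda \equiv 1}) used to start the EM iterations.
#'
#' @param seg_sites Number of segregating sites.
#' @param n Number of haplotypes (`>= 2`).
#' @param seq_len Number of sites surveyed.
#' @param mu Per-generation per-site mutation probability.
#' @param r Per-generation per-site recombination probability.
#' @return A constant-size `coal_model`.
#' @export
watterson_init <- function(seg_sites, n, seq_len, mu, r = mu) {
  stopifnot(n >= 2, seq_len > 0)
  if (seg_sites <= 0) {
    stop("watterson_init: no segregating sites; supply an initial model explicitly")
  }
  a_n <- sum(1 / seq.int(1, n - 1))
  theta_hat <- seg_sites / (seq_len * a_n)
  coal_model(log_rates = 0, N0 = theta_hat / (4 * mu), mu = mu, r = r)
}

# ---- hidden-state discretizations ------------------------------------------

#' Hidden-state discretization
#'
#' `S + 1` boundaries `0 = t_0 < t_1 < ... < t_S = Inf` partitioning the
#' positive reals into `S` hidden-state intervals.
#'
#' @param boundaries Increasing numeric vector starting at 0 and ending at
#'   `Inf`.
#' @return An object of class `coal_disc`.
#' @export
coal_disc <- function(boundaries) {
  stopifnot(length(boundaries) >= 3, boundaries[1] == 0,
            is.infinite(boundaries[length(boundaries)]),
            all(is.finite(boundaries[-c(1, length(boundaries))])),
            !is.unsorted(boundaries, strictly = TRUE))
  structure(list(boundaries = as.numeric(boundaries),
                 S = length(boundaries) - 1L),
            class = "coal_disc")
}

#' @export
print.coal_disc <- function(x, ...) {
  cat(sprintf("<coal_disc> %d states; finite boundaries: %s\n", x$S,
              paste(signif(x$boundaries[-c(1, x$S + 1)], 3), collapse = ", ")))
  invisible(x)
}

#' Interval index of a value under a discretization
#'
#' Returns the unique `i` with `t_{i-1} <= v < t_i` (1-based).
#'
#' @param disc A `coal_disc`.
#' @param v Nonnegative value(s).
#' @return Integer state index in `1..S`.
#' @export
disc_index <- function(disc, v) {
  stopifnot(inherits(disc, "coal_disc"), all(v >= 0))
  findInterval(v, disc$boundaries[-(disc$S + 1)])
}

#' TMRCA discretization, equidistant on a log scale
#'
#' Places the `S - 1` finite boundaries geometrically between `t_min` and
#' `t_max`. By default the endpoints bracket the bulk of the TMRCA
#' distribution of `n` samples under the model: the 0.5% and 99.5%
#' quantiles, found by bisection on the single-locus TMRCA CDF. This keeps
#' every hidden state's marginal probability bounded away from zero for any
#' sample size. Both endpoints can be overridden.
#'
#' @param S Number of hidden states (`>= 2`).
#' @param n Sample size the discretization is intended for.
#' @param model A `coal_model` supplying the time scale.
#' @param t_min,t_max Optional overrides of the finite boundary range
#'   (coalescent units).
#' @return A `coal_disc`.
#' @export
tmrca_discretization <- function(S, n, model, t_min = NULL, t_max = NULL) {
  stopifnot(S >= 2, n >= 2)
  if (is.null(t_min) || is.null(t_max)) {
    q <- tmrca_quantiles(model, n, c(0.005, 0.995))
    if (is.null(t_min)) t_min <- q[1]
    if (is.null(t_max)) t_max <- q[2]
  }
  stopifnot(t_min > 0, t_max > t_min)
  finite <- if (S == 2) sqrt(t_min * t_max)
            else t_min * (t_max / t_min)^((seq_len(S - 1) - 1) / (S - 2))
  coal_disc(c(0, finite, Inf))
}

# quantiles of the single-locus TMRCA distribution by bisection on the CDF
tmrca_quantiles <- function(model, n, probs) {
  spec <- theta_process(n)
  cdf <- function(t) {
    g <- theta_state_probs(spec, model, t, theta = 0)
    g[, spec$absorbed_nomut]
  }
  # bracket: expand upper end until the largest quantile is covered
  hi <- 2 * expected_pairwise_tmrca(model)
  while (cdf(hi) < max(probs)) hi <- hi * 2
  vapply(probs, function(p) {
    lo <- 0; up <- hi
    for (i in 1:60) {
      mid <- (lo + up) / 2
      if (cdf(mid) < p) lo <- mid else up <- mid
      if (up - lo < 1e-12 * hi) break
    }
    (lo + up) / 2
  }, 0)
}

#' Total branch length discretization with uniform marginal occupancy
#'
#' Boundaries are the `i/S` quantiles (`i = 1..S-1`) of the total tree
#' length of `n` lineages under a constant-size coalescent at the model's
#' harmonic-mean rate. The length is hypoexponential,
#' \eqn{L = \sum_{k=2}^n k T_k} with \eqn{T_k \sim Exp(\lambda k(k-1)/2)},
#' whose CDF has the closed form \eqn{(1 - e^{-\lambda x / 2})^{n-1}}; the
#' quantile function inverts it directly, so the marginal distribution over
#' hidden states is uniform by construction under a constant history.
#'
#' @inheritParams tmrca_discretization
#' @return A `coal_disc`.
#' @export
length_discretization <- function(S, n, model) {
  stopifnot(S >= 2, n >= 2)
  lbar <- 1 / expected_pairwise_tmrca(model)
  q <- seq_len(S - 1) / S
  finite <- -(2 / lbar) * log(1 - q^(1 / (n - 1)))
  coal_disc(c(0, finite, Inf))
}
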