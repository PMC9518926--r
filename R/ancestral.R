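# Augmented ancestral processes: two-locus process with at most one
# recombination (A_rho) and single-locus process with at most one mutation
# (A_theta). Both are finite continuous-time Markov chains whose generator is
# lambda(t) * Q_coal + Q_event; with piecewise-constant lambda the
# distribution at any time is an exact product of matrix exponentials.

mat_expm <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE)))

#' Enumerate the two-locus ancestral recombination process
#'
#' States are tuples `(k_ab, k_a, k_b, kappa)`: lineages ancestral to both
#' loci, to locus a only, to locus b only, and the number of recombination
#' events so far (capped at 1). The process starts at `(n, 0, 0, 0)` and is
#' absorbed in `(1, 0, 0, 0)` or `(1, 0, 0, 1)`. The generator splits into a
#' coalescence part (proportional to the coalescent rate) and a
#' recombination part (proportional to `rho / 2`); both are returned as
#' unit-rate matrices.
#'
#' @param n Sample size (`>= 2`).
#' @return A list with `states` (matrix with columns k_ab, k_a, k_b, kappa,
#'   ordered lexicographically), `Q_coal` and `Q_rec` (unit-rate generator
#'   parts), index vectors `absorbing`, and the indices of the states
#'   entering the joint TMRCA distribution.
#' @export
rho_process <- function(n) {
  stopifnot(n >= 2)
  key <- function(s) paste(s, collapse = ",")
  seen <- new.env(parent = emptyenv())
  queue <- list(c(n, 0L, 0L, 0L))
  assign(key(queue[[1]]), TRUE, envir = seen)
  states <- list()
  while (length(queue) > 0) {
    s <- queue[[1]]; queue <- queue[-1]
    states[[length(states) + 1]] <- s
    for (t in rho_moves(s)$to) {
      k <- key(t)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        queue <- c(queue, list(t))
      }
    }
  }
  st <- do.call(rbind, states)
  ord <- order(st[, 1], st[, 2], st[, 3], st[, 4])
  st <- st[ord, , drop = FALSE]
  colnames(st) <- c("k_ab", "k_a", "k_b", "kappa")
  ns <- nrow(st)
  idx <- stats::setNames(seq_len(ns), apply(st, 1, key))
  Qc <- matrix(0, ns, ns)
  Qr <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    mv <- rho_moves(st[i, ])
    for (j in seq_along(mv$to)) {
      jj <- idx[[key(mv$to[[j]])]]
      if (mv$type[j] == "coal") Qc[i, jj] <- Qc[i, jj] + mv$rate[j]
      else Qr[i, jj] <- Qr[i, jj] + mv$rate[j]
    }
  }
  diag(Qc) <- -rowSums(Qc)
  diag(Qr) <- -rowSums(Qr)
  list(n = n, states = st, index = idx, Q_coal = Qc, Q_rec = Qr,
       absorbing = unname(c(idx[["1,0,0,0"]], idx[["1,0,0,1"]])),
       s_1000 = unname(idx[["1,0,0,0"]]),
       s_1001 = unname(idx[["1,0,0,1"]]),
       s_1011 = if (!is.null(idx[["1,0,1,1"]])) unname(idx[["1,0,1,1"]]) else NA_integer_,
       s_1101 = if (!is.null(idx[["1,1,0,1"]])) unname(idx[["1,1,0,1"]]) else NA_integer_,
       init = unname(idx[[key(c(n, 0L, 0L, 0L))]]))
}

# transitions out of one state; coalescence rates are per unit lambda,
# recombination rates per unit rho/2. The two fully coalesced states are
# absorbing: no moves out (post-MRCA recombination cannot change marginal
# TMRCAs).
rho_moves <- function(s) {
  k_ab <- s[1]; k_a <- s[2]; k_b <- s[3]; kap <- s[4]
  to <- list(); rate <- numeric(0); type <- character(0)
  if (k_ab == 1 && k_a == 0 && k_b == 0) {
    return(list(to = to, rate = rate, type = type))
  }
  if (k_ab >= 2) {
    to <- c(to, list(c(k_ab - 1, k_a, k_b, kap)))
    rate <- c(rate, choose(k_ab, 2)); type <- c(type, "coal")
  }
  if (k_a >= 1) {
    to <- c(to, list(c(k_ab, k_a - 1, k_b, kap)))
    rate <- c(rate, choose(k_a, 2) + k_a * k_ab); type <- c(type, "coal")
  }
  if (k_b >= 1) {
    to <- c(to, list(c(k_ab, k_a, k_b - 1, kap)))
    rate <- c(rate, choose(k_b, 2) + k_b * k_ab); type <- c(type, "coal")
  }
  if (kap == 0 && k_ab >= 2) {
    to <- c(to, list(c(k_ab - 1, k_a + 1, k_b + 1, 1)))
    rate <- c(rate, k_ab); type <- c(type, "rec")
  }
  list(to = to, rate = rate, type = type)
}

#' Enumerate the single-locus ancestral process with one mutation
#'
#' States are `(k, k_star)`: active lineages and the number of lineages at
#' the time of the (single permitted) mutation, `k_star = -1` before any
#' mutation. Starts at `(n, -1)`; absorbing states are `(1, k_star)`.
#'
#' @param n Sample size (`>= 2`).
#' @return A list with `states` (matrix with columns k, k_star), unit-rate
#'   generator parts `Q_coal` (per unit coalescent rate) and `Q_mut` (per
#'   unit `theta / 2`), and index bookkeeping.
#' @export
theta_process <- function(n) {
  stopifnot(n >= 2)
  st <- rbind(
    cbind(k = seq_len(n), k_star = -1L),
    do.call(rbind, lapply(2:n, function(ks) cbind(k = seq_len(ks), k_star = ks)))
  )
  ord <- order(st[, "k_star"], st[, "k"])
  st <- st[ord, , drop = FALSE]
  ns <- nrow(st)
  key <- function(k, ks) paste(k, ks, sep = ",")
  idx <- stats::setNames(seq_len(ns), key(st[, 1], st[, 2]))
  Qc <- matrix(0, ns, ns)
  Qm <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    k <- st[i, 1]; ks <- st[i, 2]
    if (k >= 2) {
      Qc[i, idx[[key(k - 1, ks)]]] <- choose(k, 2)
      if (ks == -1) Qm[i, idx[[key(k, k)]]] <- k
    }
  }
  diag(Qc) <- -rowSums(Qc)
  diag(Qm) <- -rowSums(Qm)
  list(n = n, states = st, index = idx, Q_coal = Qc, Q_mut = Qm,
       init = unname(idx[[key(n, -1L)]]),
       absorbed_nomut = unname(idx[[key(1, -1L)]]),
       absorbed_mut = unname(idx[paste(1, 2:n, sep = ",")]))
}

#' Generator of the recombination process at a time point
#'
#' `lambda(t) * Q_coal + (rho / 2) * Q_rec` with rates from the transition
#' table of the two-locus process.
#'
#' @param spec Output of [rho_process()].
#' @param model A `coal_model`.
#' @param t Time (coalescent units).
#' @param rho Scaled recombination rate between the two loci; defaults to
#'   the model's per-base `4 N0 r`.
#' @return Square rate matrix.
#' @export
rho_rate_matrix <- function(spec, model, t, rho = rho_rate(model)) {
  if (t < 0) stop("rho_rate_matrix: t must be nonnegative")
  coal_rate(model, t) * spec$Q_coal + (rho / 2) * spec$Q_rec
}

#' @rdname rho_rate_matrix
#' @param theta Scaled per-locus mutation rate; defaults to `4 N0 mu`.
#' @export
theta_rate_matrix <- function(spec, model, t, theta = theta_rate(model)) {
  if (t < 0) stop("theta_rate_matrix: t must be nonnegative")
  coal_rate(model, t) * spec$Q_coal + (theta / 2) * spec$Q_mut
}

# Propagate the distribution of a CTMC with generator
# lambda(t) * Qc + w * Qe through time. Exact for piecewise-constant lambda:
# segments between requested times and change points use one matrix
# exponential each. Returns length(times) x nstates matrix of probabilities.
propagate_ctmc <- function(Qc, Qe, w, model, times, init_index) {
  stopifnot(all(is.finite(times)), !is.unsorted(times))
  ns <- nrow(Qc)
  g <- numeric(ns); g[init_index] <- 1
  out <- matrix(NA_real_, length(times), ns)
  rates <- exp(model$log_rates)
  cuts <- model$change_points
  t_cur <- 0
  for (k in seq_along(times)) {
    t_next <- times[k]
    if (t_next > t_cur) {
      brk <- cuts[cuts > t_cur & cuts < t_next]
      segs <- cbind(c(t_cur, brk), c(brk, t_next))
      for (r in seq_len(nrow(segs))) {
        lam <- rates[epoch_index(model, segs[r, 1])]
        Q <- lam * Qc + w * Qe
        g <- as.numeric(g %*% mat_expm(Q * (segs[r, 2] - segs[r, 1])))
      }
      g <- pmax(g, 0)
      s <- sum(g)
      if (abs(s - 1) > 1e-7) stop(sprintf(
        "propagate_ctmc: mass not conserved at t = %g (sum = %.10f)", t_next, s))
      g <- g / s
      t_cur <- t_next
    }
    out[k, ] <- g
  }
  out
}

# Absorbing distribution at t = Inf given the distribution at the last
# finite time: route remaining transient mass with the final-epoch generator
# (absorption probabilities from the linear system -Q_TT^-1 Q_TA).
ctmc_absorb_inf <- function(Qc, Qe, w, model, g_last) {
  lam <- exp(model$log_rates[length(model$log_rates)])
  Q <- lam * Qc + w * Qe
  abs_idx <- which(apply(Q, 1, function(r) all(r == 0)))
  trans <- setdiff(seq_len(nrow(Q)), abs_idx)
  g_inf <- numeric(length(g_last))
  g_inf[abs_idx] <- g_last[abs_idx]
  if (length(trans) > 0 && sum(g_last[trans]) > 0) {
    Btt <- solve(-Q[trans, trans, drop = FALSE], Q[trans, abs_idx, drop = FALSE])
    g_inf[abs_idx] <- g_inf[abs_idx] + as.numeric(g_last[trans] %*% Btt)
  }
  g_inf
}

#' State probabilities of the recombination process over time
#'
#' Solves the forward equation of the two-locus ancestral process (the ODE
#' system `d/dt g = g Q(t)`) exactly at the requested times. `Inf` entries
#' are handled analytically through the absorbing distribution of the final
#' epoch.
#'
#' @inheritParams rho_rate_matrix
#' @param times Nondecreasing nonnegative times (last entries may be `Inf`).
#' @return Matrix `length(times) x nstates`; rows are probability vectors.
#' @export
rho_state_probs <- function(spec, model, times, rho = rho_rate(model)) {
  fin <- is.finite(times)
  out <- matrix(NA_real_, length(times), nrow(spec$Q_coal))
  tf <- times[fin]
  if (any(fin)) {
    out[fin, ] <- propagate_ctmc(spec$Q_coal, spec$Q_rec, rho / 2, model, tf,
                                 spec$init)
  }
  if (any(!fin)) {
    g_last <- if (any(fin)) out[max(which(fin)), ] else {
      g0 <- numeric(nrow(spec$Q_coal)); g0[spec$init] <- 1; g0
    }
    out[!fin, ] <- rep(ctmc_absorb_inf(spec$Q_coal, spec$Q_rec, rho / 2, model,
                                       g_last),
                       each = sum(!fin))
  }
  out
}

#' @rdname rho_state_probs
#' @export
theta_state_probs <- function(spec, model, times, theta = theta_rate(model)) {
  fin <- is.finite(times)
  out <- matrix(NA_real_, length(times), nrow(spec$Q_coal))
  if (any(fin)) {
    out[fin, ] <- propagate_ctmc(spec$Q_coal, spec$Q_mut, theta / 2, model,
                                 times[fin], spec$init)
  }
  if (any(!fin)) {
    g_last <- if (any(fin)) out[max(which(fin)), ] else {
      g0 <- numeric(nrow(spec$Q_coal)); g0[spec$init] <- 1; g0
    }
    out[!fin, ] <- rep(ctmc_absorb_inf(spec$Q_coal, spec$Q_mut, theta / 2,
                                       model, g_last),
                       each = sum(!fin))
  }
  out
}
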