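# CHMM probabilities with the total branch length as hidden state.
#
# The accumulated-length distributions F_sigma(t, x[, y]) = P[process in
# sigma, accumulated length <= x (and <= y at the second locus)] satisfy
# linear transport PDEs with state-wise integer velocities (the number of
# active lineages at the locus) and source coupling through the generator of
# the ancestral process. With the grid chosen so that dt = dx, the advection
# step is an exact integer-cell shift per state; source coupling uses the
# full-step matrix exponential with transfers deposited along their mean
# characteristic segment (see build_transfer_plan).

#' Branch-length accumulation velocity of a state
#'
#' For the two-locus process the velocity at locus `a` (or `b`) is the
#' number of lineages ancestral to that locus, `k_ab + k_l`, zeroed once
#' only a single lineage remains (the locus MRCA is reached). For the
#' single-locus mutation process the velocity is the lineage count `k`,
#' zeroed at `k = 1`.
#'
#' @param states State matrix from [rho_process()] or [theta_process()].
#' @param locus `"a"` or `"b"` for the two-locus process; ignored for the
#'   single-locus process (detected by its two-column state matrix).
#' @return Integer velocity per state.
#' @export
accum_velocity <- function(states, locus = c("a", "b")) {
  if (ncol(states) == 2) {  # theta process (k, k_star)
    k <- states[, 1]
    return(as.integer(k * (k > 1)))
  }
  locus <- match.arg(locus)
  k <- states[, "k_ab"] + states[, if (locus == "a") "k_a" else "k_b"]
  as.integer(k * (k > 1))
}

# One-step transfer plans. The full-step propagator E = expm(Q dt) gives the
# transfer mass between states; mass staying in state i advects exactly
# vel[i] cells (dt = dx). Mass transferring i -> j at time tau within the
# step advects along the segment from the j-velocity offset (tau = 0) to the
# i-velocity offset (tau = dt); the transfer time is uniform to first order,
# so the deposit is spread along that segment by a midpoint rule with one
# node per traversed cell. Fractional positions deposit at the ceiling node:
# the node values of the CDF then agree exactly with the uniform spread for
# front-concentrated mass, eliminating staircase bias at the moving fronts
# (verified against closed forms and refinement tests).
build_transfer_plan <- function(E, vel_a, vel_b = NULL) {
  ns <- nrow(E)
  plan <- list()
  ceil_pos <- function(p) as.integer(ceiling(p - 1e-9))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (E[i, j] < 1e-14) next
      if (is.null(vel_b)) {
        if (i == j) {
          s <- vel_a[i]; wts <- E[i, j]
        } else {
          K <- max(abs(vel_a[i] - vel_a[j]), 1)
          mid <- (seq_len(K) - 0.5) / K
          s <- ceil_pos(vel_a[j] + (vel_a[i] - vel_a[j]) * mid)
          wts <- rep(E[i, j] / K, K)
        }
        plan[[length(plan) + 1]] <- list(i = i, j = j, sa = s, wa = wts)
      } else {
        if (i == j) {
          sa <- vel_a[i]; sb <- vel_b[i]; wts <- E[i, j]
        } else {
          K <- max(abs(vel_a[i] - vel_a[j]), abs(vel_b[i] - vel_b[j]), 1)
          mid <- (seq_len(K) - 0.5) / K
          sa <- ceil_pos(vel_a[j] + (vel_a[i] - vel_a[j]) * mid)
          sb <- ceil_pos(vel_b[j] + (vel_b[i] - vel_b[j]) * mid)
          wts <- rep(E[i, j] / K, K)
        }
        plan[[length(plan) + 1]] <- list(i = i, j = j, sa = sa, sb = sb,
                                         wa = wts)
      }
    }
  }
  plan
}

# Epoch-wise full-step propagators and transfer plans.
epoch_plans <- function(Qc, Qe, w, model, dt, vel_a, vel_b = NULL) {
  lapply(exp(model$log_rates), function(lam) {
    E <- mat_expm((lam * Qc + w * Qe) * dt)
    build_transfer_plan(E, vel_a, vel_b)
  })
}

shift_vec <- function(x, s) {
  if (s == 0) return(x)
  n <- length(x)
  c(numeric(s), x[seq_len(n - s)])
}

# 1D accumulated-length solver. Queries default to (t = x/2, x) for x in
# `query_x` (finite, > 0); an explicit vector of query times can be given.
# Returns a length(query_x) x nstates matrix of F values.
solve_accum_1d <- function(Qc, Qe, w, model, init, vel, query_x, grid_n = 512,
                           query_t = NULL) {
  stopifnot(all(is.finite(query_x)), all(query_x > 0))
  ns <- nrow(Qc)
  x_max <- max(query_x)
  dx <- x_max / grid_n
  dt <- dx
  plans <- epoch_plans(Qc, Qe, w, model, dt, vel)
  # the queried (absorbing, zero-velocity) states are constant in t beyond
  # x / 2; evaluating a few steps later avoids sampling exactly at the
  # moving front of the still-active states
  if (is.null(query_t)) query_t <- query_x / 2 + 3 * dt
  ord <- order(query_t)
  qx <- query_x[ord]
  qt <- query_t[ord]
  out <- matrix(NA_real_, length(qx), ns)
  F_cur <- matrix(0, grid_n + 1, ns)
  F_cur[, init] <- 1
  t_cur <- 0
  qi <- 1
  n_steps <- ceiling(max(qt) / dt) + 1
  for (step in seq_len(n_steps)) {
    F_prev <- F_cur
    plan <- plans[[epoch_index(model, t_cur + dt / 2)]]
    F_new <- matrix(0, grid_n + 1, ns)
    for (p in plan) {
      for (u in seq_along(p$sa)) {
        F_new[, p$j] <- F_new[, p$j] + p$wa[u] * shift_vec(F_cur[, p$i], p$sa[u])
      }
    }
    F_cur <- F_new
    t_new <- t_cur + dt
    while (qi <= length(qt) && qt[qi] <= t_new + 1e-12) {
      wt <- (qt[qi] - t_cur) / dt
      Fq <- (1 - wt) * F_prev + wt * F_cur
      xi <- qx[qi] / dx
      i0 <- min(floor(xi), grid_n - 1)
      fr <- xi - i0
      out[qi, ] <- (1 - fr) * Fq[i0 + 1, ] + fr * Fq[i0 + 2, ]
      qi <- qi + 1
    }
    t_cur <- t_new
    if (qi > length(qt)) break
  }
  out[order(ord), , drop = FALSE]
}

# 2D accumulated-length solver for the two-locus process. `bnd` are the
# finite positive discretization boundaries; returns the matrix of
# P[L_a <= bnd_i, L_b <= bnd_j] (sum over the two fully absorbed states,
# evaluated at t = max(bnd_i, bnd_j) / 2).
solve_accum_2d <- function(spec, model, rho, bnd, grid_n = 256) {
  stopifnot(all(is.finite(bnd)), all(bnd > 0), !is.unsorted(bnd))
  ns <- nrow(spec$Q_coal)
  va <- accum_velocity(spec$states, "a")
  vb <- accum_velocity(spec$states, "b")
  abs_states <- c(spec$s_1000, spec$s_1001)
  x_max <- max(bnd)
  dx <- x_max / grid_n
  dt <- dx
  plans <- epoch_plans(spec$Q_coal, spec$Q_rec, rho / 2, model, dt, va, vb)
  np <- grid_n + 1
  F_cur <- array(0, dim = c(np, np, ns))
  F_cur[, , spec$init] <- 1
  nb <- length(bnd)
  out <- matrix(NA_real_, nb, nb)
  qt <- bnd / 2 + 3 * dt  # absorbed mass is constant in t past bnd[k] / 2
  t_cur <- 0
  qi <- 1
  n_steps <- ceiling(max(qt) / dt) + 1
  interp2 <- function(M, xi, yi) {
    i0 <- min(floor(xi), grid_n - 1); fx <- xi - i0
    j0 <- min(floor(yi), grid_n - 1); fy <- yi - j0
    (1 - fx) * ((1 - fy) * M[i0 + 1, j0 + 1] + fy * M[i0 + 1, j0 + 2]) +
      fx * ((1 - fy) * M[i0 + 2, j0 + 1] + fy * M[i0 + 2, j0 + 2])
  }
  shift_mat <- function(M, sa, sb) {
    if (sa == 0 && sb == 0) return(M)
    out <- matrix(0, np, np)
    out[(sa + 1):np, (sb + 1):np] <- M[seq_len(np - sa), seq_len(np - sb)]
    out
  }
  for (step in seq_len(n_steps)) {
    F_prev <- F_cur
    plan <- plans[[epoch_index(model, t_cur + dt / 2)]]
    F_new <- array(0, dim = c(np, np, ns))
    for (p in plan) {
      Msrc <- F_cur[, , p$i]
      for (u in seq_along(p$sa)) {
        F_new[, , p$j] <- F_new[, , p$j] +
          p$wa[u] * shift_mat(Msrc, p$sa[u], p$sb[u])
      }
    }
    F_cur <- F_new
    t_new <- t_cur + dt
    while (qi <= nb && qt[qi] <= t_new + 1e-12) {
      wt <- (qt[qi] - t_cur) / dt
      Mq <- (1 - wt) * (F_prev[, , spec$s_1000] + F_prev[, , spec$s_1001]) +
        wt * (F_cur[, , spec$s_1000] + F_cur[, , spec$s_1001])
      for (i in seq_len(qi)) {
        v <- if (i == qi) {
          # the joint CDF has a kink along x = y (mass from unrecombined
          # histories); interpolate along the grid diagonal, where it is
          # smooth, instead of across the kink
          dg <- diag(Mq)
          xi <- bnd[qi] / dx
          i0 <- min(floor(xi), grid_n - 1)
          (1 - (xi - i0)) * dg[i0 + 1] + (xi - i0) * dg[i0 + 2]
        } else {
          interp2(Mq, bnd[i] / dx, bnd[qi] / dx)
        }
        out[i, qi] <- v
        out[qi, i] <- v
      }
      qi <- qi + 1
    }
    t_cur <- t_new
    if (qi > nb) break
  }
  out
}

#' Marginal CDF of the total branch length at a single locus
#'
#' Solves the one-locus accumulated-length transport system and sums the
#' states whose locus-a genealogy has fully coalesced, evaluated at
#' `t = x / 2` (beyond which any un-coalesced locus accumulates more than
#' `x`).
#'
#' @param model A `coal_model`.
#' @param n Sample size.
#' @param x Evaluation lengths (finite, positive; vectorized).
#' @param grid_n Number of grid cells for the transport solver.
#' @return `P[L <= x]` for each `x`.
#' @export
length_marginal_cdf <- function(model, n, x, grid_n = 512) {
  spec <- theta_process(n)
  vel <- accum_velocity(spec$states)
  Fq <- solve_accum_1d(spec$Q_coal, spec$Q_mut, 0, model, spec$init, vel, x,
                       grid_n = grid_n)
  unname(Fq[, spec$absorbed_nomut])
}

#' CHMM transition set for the total branch length hidden state
#'
#' Joint CDF of the branch lengths at two adjacent loci from the two-locus
#' accumulated-length PDE system, differenced and row-normalized exactly as
#' for the TMRCA hidden state. Infinite boundaries use the single-locus
#' marginal length CDF and total absorption.
#'
#' @inheritParams build_transition_tmrca
#' @param grid_n Grid cells for the 2D transport solver (the 1D marginal
#'   solver uses `2 * grid_n`).
#' @return A `chmm_transition` (hidden state `"length"`).
#' @export
build_transition_length <- function(model, n, disc, rho = rho_rate(model),
                                    spec = rho_process(n), grid_n = 256) {
  stopifnot(inherits(disc, "coal_disc"))
  b <- disc$boundaries
  S <- disc$S
  fin <- b[2:S]
  a_cdf <- matrix(0, S + 1, S + 1)
  marg <- length_marginal_cdf(model, n, fin, grid_n = 2 * grid_n)
  if (rho == 0) {
    # perfectly linked loci share one genealogy: the joint CDF is the
    # marginal at the smaller argument, and A is exactly the identity
    a_cdf[2:S, 2:S] <- outer(seq_len(S - 1), seq_len(S - 1),
                             function(i, j) marg[pmin(i, j)])
  } else {
    a_cdf[2:S, 2:S] <- solve_accum_2d(spec, model, rho, fin, grid_n = grid_n)
  }
  # infinite boundary: joint with L_b <= Inf is the marginal for locus a
  a_cdf[2:S, S + 1] <- marg
  a_cdf[S + 1, 2:S] <- marg
  a_cdf[S + 1, S + 1] <- 1
  finish_transition(a_cdf, disc, hidden_state = "length", n = n, rho = rho)
}

#' CHMM emission set for the total branch length hidden state
#'
#' Joint CDF of the branch length and the emitted derived-allele count from
#' the single-locus single-mutation accumulated-length PDE, combined with
#' the derived-allele probabilities and normalized as for the TMRCA case.
#'
#' @inheritParams build_emission_tmrca
#' @param grid_n Grid cells for the transport solver.
#' @return A `chmm_emission` (hidden state `"length"`).
#' @export
build_emission_length <- function(model, n, disc, theta = theta_rate(model),
                                  spec = theta_process(n), grid_n = 512) {
  stopifnot(inherits(disc, "coal_disc"))
  b <- disc$boundaries
  S <- disc$S
  vel <- accum_velocity(spec$states)
  Fq <- solve_accum_1d(spec$Q_coal, spec$Q_mut, theta / 2, model, spec$init,
                       vel, b[2:S], grid_n = grid_n)
  g_inf <- theta_state_probs(spec, model, Inf, theta = theta)
  g_all <- rbind(matrix(0, 1, nrow(spec$Q_coal)), Fq, g_inf)
  g_all[1, spec$init] <- 1  # at x = 0 no length accumulated yet, no mutation
  b_cdf <- emission_cdf_from_g(spec, g_all, n)
  b_cdf[1, ] <- 0  # P[L <= 0] = 0
  finish_emission(b_cdf, disc, n = n, theta = theta, hidden_state = "length")
}
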