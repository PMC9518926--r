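# EM estimation of the coalescent-rate parameters: E-step via the scaled
# forward-backward over composite-likelihood subsets, M-step by Nelder-Mead
# maximization of the expected log-likelihood in log coalescent-rate space.

#' Composite-likelihood subset scheme
#'
#' Either draws, for each requested size, a uniformly random partition of
#' the sample into non-overlapping subsets of that size (a remainder smaller
#' than the size is discarded), or accepts an explicit list of (possibly
#' overlapping) subsets.
#'
#' @param n Number of haplotypes available.
#' @param sizes Integer vector of subset sizes (each `>= 2`, `<= n`).
#' @param subsets Explicit list of haplotype index vectors (overrides
#'   `sizes`).
#' @param seed RNG seed for the random partition.
#' @return A `chmm_subsets` object.
#' @export
build_subsets <- function(n, sizes = NULL, subsets = NULL, seed = 1) {
  if (is.null(subsets)) {
    stopifnot(!is.null(sizes), all(sizes >= 2))
    if (any(sizes > n)) stop("build_subsets: subset size exceeds sample size")
    subsets <- list()
    for (sz in sizes) {
      perm <- withr::with_seed(seed, sample.int(n))
      k <- floor(n / sz)
      for (i in seq_len(k)) {
        subsets[[length(subsets) + 1]] <- sort(perm[((i - 1) * sz + 1):(i * sz)])
      }
      seed <- seed + 1
    }
    mode <- "by-sizes"
  } else {
    stopifnot(all(vapply(subsets, length, 1L) >= 2),
              all(unlist(subsets) >= 1), all(unlist(subsets) <= n))
    mode <- "explicit"
  }
  structure(list(subsets = subsets,
                 sizes = vapply(subsets, length, 1L),
                 mode = mode, n = n, seed = seed),
            class = "chmm_subsets")
}

#' @export
print.chmm_subsets <- function(x, ...) {
  cat(sprintf("<chmm_subsets> %d subsets of %d haplotypes (%s): sizes %s\n",
              length(x$subsets), x$n, x$mode,
              paste(sort(unique(x$sizes)), collapse = ",")))
  invisible(x)
}

#' Read an explicit subset file
#'
#' One subset per line, whitespace-separated 1-based haplotype indices.
#'
#' @param path File path.
#' @param n Number of haplotypes available.
#' @return A `chmm_subsets`.
#' @export
read_subset_file <- function(path, n) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  subsets <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
  build_subsets(n, subsets = subsets)
}

#' EM configuration
#'
#' @param max_iters Maximum EM iterations; defaults to 25 for the TMRCA
#'   hidden state and 15 for the branch-length hidden state.
#' @param tol Relative change in the composite log-likelihood below which EM
#'   stops.
#' @param nm_maxit Maximum Nelder-Mead function evaluations per M-step.
#' @param nm_xtol,nm_ftol Nelder-Mead convergence tolerances on the simplex
#'   spread and the objective spread.
#' @param simplex_offset Absolute log-rate offset for the initial simplex
#'   when fewer than 5 parameters are optimized.
#' @param simplex_frac Relative coordinate perturbation for the initial
#'   simplex with 5 or more parameters.
#' @param c12 Regularization weight on squared differences of adjacent log
#'   coalescent rates (0 disables).
#' @param seed RNG seed (subset scheme construction).
#' @return List of class `em_config`.
#' @export
em_config <- function(max_iters = NULL, tol = 1e-6, nm_maxit = 300,
                      nm_xtol = 1e-4, nm_ftol = 1e-7, simplex_offset = 0.3,
                      simplex_frac = 0.05, c12 = 0, seed = 1) {
  stopifnot(tol > 0, nm_xtol > 0, nm_ftol > 0, is.null(max_iters) || max_iters >= 1)
  structure(list(max_iters = max_iters, tol = tol, nm_maxit = nm_maxit,
                 nm_xtol = nm_xtol, nm_ftol = nm_ftol,
                 simplex_offset = simplex_offset, simplex_frac = simplex_frac,
                 c12 = c12, seed = seed),
            class = "em_config")
}

#' Hypergeometric downsampling of an emission set for pseudo-haploid data
#'
#' For `n` pseudo-haploid samples, the hidden state is the TMRCA of the
#' underlying `2n` haplotypes; the first emission layer produces a derived
#' count `d'` among the `2n` haplotypes, the second layer downsamples to the
#' observed count among the `n` pseudo-haploids with hypergeometric
#' probabilities (draw `n` without replacement from `2n` of which `d'` are
#' derived). Counts of `n` (all pseudo-haploids derived) fall outside the
#' observable alphabet and are folded into the row renormalization,
#' consistent with treating fixed-derived sites as unobservable.
#'
#' @param B_2n Emission matrix or `chmm_emission` built for sample size
#'   `2 * n`.
#' @param n Number of pseudo-haploid samples.
#' @return Emission matrix (or `chmm_emission`) over `d = 0..n-1`.
#' @export
pseudo_haploid_emission <- function(B_2n, n) {
  obj <- NULL
  if (inherits(B_2n, "chmm_emission")) {
    obj <- B_2n
    B_2n <- obj$B
  }
  stopifnot(ncol(B_2n) == 2 * n)
  H <- outer(0:(2 * n - 1), 0:(n - 1),
             function(dp, d) dhyper(d, m = dp, n = 2 * n - dp, k = n))
  Bp <- B_2n %*% H
  Bp <- Bp / rowSums(Bp)
  if (!is.null(obj)) {
    obj$B <- Bp
    obj$pseudo_n <- n
    return(obj)
  }
  Bp
}

# Build the CHMM probability set (A, B, Pi) for a machinery sample size.
# For pseudo-haploid data the machinery runs at twice the observed sample
# size and the emission is downsampled.
build_chmm_probs <- function(model, n_obs, disc, hidden_state = "tmrca",
                             pseudo = FALSE, specs = NULL,
                             rho = rho_rate(model), theta = theta_rate(model),
                             grid_n = 192) {
  n_mach <- if (pseudo) 2L * n_obs else n_obs
  if (is.null(specs)) {
    specs <- list(rho = rho_process(n_mach), theta = theta_process(n_mach))
  }
  if (hidden_state == "tmrca") {
    tr <- build_transition_tmrca(model, n_mach, disc, rho = rho, spec = specs$rho)
    em <- build_emission_tmrca(model, n_mach, disc, theta = theta,
                               spec = specs$theta)
  } else {
    tr <- build_transition_length(model, n_mach, disc, rho = rho,
                                  spec = specs$rho, grid_n = grid_n)
    em <- build_emission_length(model, n_mach, disc, theta = theta,
                                spec = specs$theta, grid_n = 2 * grid_n)
  }
  B <- if (pseudo) pseudo_haploid_emission(em$B, n_obs) else em$B
  list(A = tr$A, B = B, Pi = tr$Pi, trans = tr, emis = em)
}

#' Expected complete-data log-likelihood of candidate rates
#'
#' Rebuilds the initial, transition, and emission probabilities at the
#' candidate log coalescent rates for every subset size present in the
#' statistics and accumulates the expected log-likelihood: initial counts
#' against `log Pi`, transition counts against `log A`, emission counts
#' against `log B`, minus the optional smoothness penalty
#' `c12 * sum(diff(params)^2)`.
#'
#' @param params Candidate log coalescent rates (one per epoch).
#' @param stats_by_size List of `chmm_suffstats`, one per subset size.
#' @param builder Function `(params, size_index)` returning `list(A, B, Pi)`
#'   for the statistics at that position.
#' @param c12 Regularization weight.
#' @return Scalar objective (`-Inf` when the candidate yields invalid
#'   probabilities).
#' @export
q_function <- function(params, stats_by_size, builder, c12 = 0) {
  if (any(!is.finite(params))) return(-Inf)
  total <- 0
  for (k in seq_along(stats_by_size)) {
    st <- stats_by_size[[k]]
    probs <- tryCatch(builder(params, k), error = function(e) NULL)
    if (is.null(probs) || any(!is.finite(probs$A)) || any(!is.finite(probs$B))) {
      return(-Inf)
    }
    term <- function(counts, p) {
      use <- counts > 0
      if (any(p[use] <= 0)) return(-Inf)
      sum(counts[use] * log(p[use]))
    }
    if (isTRUE(attr(st, "meta"))) {
      E <- meta_emission_matrix(structure(list(key_def = attr(st, "key_def")),
                                          class = "chmm_meta_obs"), probs$B)
      total <- total + term(st$init, probs$Pi) + term(st$trans, probs$A) +
        term(st$emis, E)
    } else {
      total <- total + term(st$init, probs$Pi) + term(st$trans, probs$A) +
        term(st$emis, probs$B)
    }
    if (!is.finite(total)) return(-Inf)
  }
  if (c12 > 0 && length(params) > 1) {
    total <- total - c12 * sum(diff(params)^2)
  }
  total
}

# Nelder-Mead with an explicit initial simplex (the simplex construction is
# part of the M-step contract, which optim() does not expose). Minimizes fn.
nelder_mead <- function(fn, simplex, maxit = 300, xtol = 1e-4, ftol = 1e-7) {
  p <- ncol(simplex)
  fv <- apply(simplex, 1, fn)
  nf <- length(fv)
  evals <- nf
  while (evals < maxit) {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    if (max(abs(fv[-1] - fv[1])) < ftol &&
        max(abs(sweep(simplex[-1, , drop = FALSE], 2, simplex[1, ]))) < xtol) {
      break
    }
    centroid <- colMeans(simplex[-nf, , drop = FALSE])
    xr <- centroid + (centroid - simplex[nf, ])
    fr <- fn(xr); evals <- evals + 1
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - simplex[nf, ])
      fe <- fn(xe); evals <- evals + 1
      if (fe < fr) { simplex[nf, ] <- xe; fv[nf] <- fe }
      else { simplex[nf, ] <- xr; fv[nf] <- fr }
    } else if (fr < fv[nf - 1]) {
      simplex[nf, ] <- xr; fv[nf] <- fr
    } else {
      if (fr < fv[nf]) {
        xc <- centroid + 0.5 * (xr - centroid)
      } else {
        xc <- centroid - 0.5 * (centroid - simplex[nf, ])
      }
      fc <- fn(xc); evals <- evals + 1
      if (fc < min(fr, fv[nf])) {
        simplex[nf, ] <- xc; fv[nf] <- fc
      } else {
        for (i in 2:nf) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- fn(simplex[i, ])
        }
        evals <- evals + nf - 1
      }
    }
  }
  ord <- order(fv)
  list(par = simplex[ord[1], ], value = fv[ord[1]], evals = evals,
       converged = evals < maxit)
}

# initial simplex per the two-regime rule: fixed +/- offsets along the
# coordinate axes for < 5 parameters, relative perturbations otherwise
initial_simplex <- function(x0, config) {
  p <- length(x0)
  simplex <- matrix(rep(x0, each = p + 1), p + 1, p)
  for (i in seq_len(p)) {
    if (p < 5) {
      simplex[i + 1, i] <- x0[i] + config$simplex_offset * (-1)^(i - 1)
    } else {
      simplex[i + 1, i] <- if (abs(x0[i]) > 1e-12) {
        x0[i] * (1 + config$simplex_frac)
      } else {
        config$simplex_frac * 0.005
      }
    }
  }
  simplex
}

#' M-step: maximize the expected log-likelihood over log coalescent rates
#'
#' @inheritParams q_function
#' @param current_params Log coalescent rates from the previous iteration
#'   (the simplex is centered here).
#' @param config An [em_config()].
#' @return Updated log-rate vector with attributes `q_value` and `evals`.
#' @export
m_step <- function(stats_by_size, current_params, builder, config = em_config()) {
  stopifnot(all(is.finite(current_params)))
  neg_q <- function(par) -q_function(par, stats_by_size, builder, config$c12)
  simplex <- initial_simplex(current_params, config)
  res <- nelder_mead(neg_q, simplex, maxit = config$nm_maxit,
                     xtol = config$nm_xtol, ftol = config$nm_ftol)
  if (!res$converged) {
    warning("m_step: Nelder-Mead evaluation budget reached; using best point seen")
  }
  # never move to a point worse than the current one
  f0 <- neg_q(current_params)
  par <- if (res$value <= f0) res$par else current_params
  structure(as.numeric(par), q_value = -min(res$value, f0), evals = res$evals)
}

#' Fit a population size history by EM
#'
#' Iterates expectation (scaled forward-backward with locus skipping over
#' every composite-likelihood subset and chromosome) and maximization
#' (Nelder-Mead over log coalescent rates) until the composite
#' log-likelihood stabilizes. Change points of the model are fixed; the
#' per-epoch rates are estimated and returned both as coalescent rates and
#' as diploid population sizes.
#'
#' @param data Observations: a `chmm_obs`, a list of `chmm_obs` (one per
#'   chromosome), a `hap_data` from [read_vcf_haplotypes()] /
#'   [simulate_smc()], or a list of `hap_data`.
#' @param model0 Initial `coal_model` (e.g. from [watterson_init()]); its
#'   change points define the epochs that are estimated.
#' @param scheme A `chmm_subsets` (required for `hap_data` input with
#'   composite likelihood; defaults to the full sample as one subset).
#' @param hidden_state `"tmrca"` or `"length"`.
#' @param S Number of hidden states.
#' @param config An [em_config()].
#' @param pseudo_haploid Treat haplotype columns as pseudo-haploid samples
#'   (hidden state built at twice the subset size, hypergeometric second
#'   emission layer).
#' @param grid_n Transport-solver grid size (branch-length hidden state
#'   only).
#' @param verbose Print per-iteration progress.
#' @return A `coalsize_fit`: the fitted model, the iteration log, and the
#'   configuration. Methods: [tidy()], [glance()], `autoplot()`.
#' @export
run_em <- function(data, model0, scheme = NULL,
                   hidden_state = c("tmrca", "length"), S = 16,
                   config = em_config(), pseudo_haploid = FALSE,
                   grid_n = 192, verbose = FALSE) {
  hidden_state <- match.arg(hidden_state)
  stopifnot(inherits(model0, "coal_model"))
  if (is.null(config$max_iters)) {
    config$max_iters <- if (hidden_state == "tmrca") 25 else 15
  }
  groups <- em_obs_groups(data, scheme, pseudo_haploid)
  # fixed per-size machinery: specs and discretization from the initial model
  machinery <- lapply(groups, function(g) {
    n_mach <- if (pseudo_haploid) 2L * g$n_obs else g$n_obs
    disc <- if (hidden_state == "tmrca") {
      tmrca_discretization(S, n_mach, model0)
    } else {
      length_discretization(S, n_mach, model0)
    }
    list(n_obs = g$n_obs, disc = disc,
         specs = list(rho = rho_process(n_mach), theta = theta_process(n_mach)))
  })
  builder <- function(params, k) {
    mch <- machinery[[k]]
    mod <- model0
    mod$log_rates <- params
    build_chmm_probs(mod, mch$n_obs, mch$disc, hidden_state,
                     pseudo = pseudo_haploid, specs = mch$specs,
                     rho = rho_rate(model0), theta = theta_rate(model0),
                     grid_n = grid_n)
  }
  params <- model0$log_rates
  traj <- list()
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(config$max_iters)) {
    stats_by_size <- vector("list", length(groups))
    ll <- 0
    for (k in seq_along(groups)) {
      probs <- builder(params, k)
      st <- NULL
      for (obs in groups[[k]]$obs_list) {
        s1 <- forward_backward_skipping(obs, probs$A, probs$B, probs$Pi)
        st <- if (is.null(st)) s1 else add_suffstats(st, s1)
      }
      stats_by_size[[k]] <- st
      ll <- ll + st$loglik
    }
    traj[[iter]] <- tibble::tibble(iteration = iter, loglik = ll,
                                   params = list(params))
    if (verbose) {
      message(sprintf("EM iter %d: composite loglik %.4f", iter, ll))
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < config$tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    if (iter == config$max_iters) break
    params <- m_step(stats_by_size, params, builder, config)
  }
  fitted <- model0
  fitted$log_rates <- as.numeric(params)
  structure(list(model = fitted, model0 = model0,
                 trajectory = dplyr::bind_rows(traj),
                 converged = converged, hidden_state = hidden_state,
                 pseudo_haploid = pseudo_haploid, S = S, config = config),
            class = "coalsize_fit")
}

# normalize the accepted data shapes into per-size groups of observation
# sequences
em_obs_groups <- function(data, scheme, pseudo_haploid) {
  as_list <- function(x, cls) {
    if (inherits(x, cls)) list(x)
    else if (is.list(x) && all(vapply(x, inherits, TRUE, cls))) x
    else NULL
  }
  obs_list <- as_list(data, "chmm_obs")
  if (!is.null(obs_list)) {
    ns <- unique(vapply(obs_list, function(o) attr(o, "n"), 1L))
    stopifnot(length(ns) == 1)
    return(list(list(n_obs = ns, obs_list = obs_list)))
  }
  hap_list <- as_list(data, "hap_data")
  if (is.null(hap_list)) {
    stop("run_em: data must be chmm_obs, hap_data, or a list of either")
  }
  n_hap <- unique(vapply(hap_list, function(h) ncol(h$hap), 1L))
  stopifnot(length(n_hap) == 1)
  if (is.null(scheme)) scheme <- build_subsets(n_hap, sizes = n_hap)
  sizes <- sort(unique(scheme$sizes))
  lapply(sizes, function(sz) {
    subs <- scheme$subsets[scheme$sizes == sz]
    obs_list <- list()
    for (sub in subs) {
      for (h in hap_list) {
        obs_list[[length(obs_list) + 1]] <- observations_from_haplotypes(h, sub)
      }
    }
    list(n_obs = sz, obs_list = obs_list)
  })
}

#' @export
print.coalsize_fit <- function(x, ...) {
  cat(sprintf("<coalsize_fit> hidden state: %s, %d EM iterations, %s\n",
              x$hidden_state, nrow(x$trajectory),
              if (x$converged) "converged" else "iteration limit reached"))
  print(size_history(x$model))
  invisible(x)
}

#' @export
tidy.coalsize_fit <- function(x, ...) size_history(x$model)

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.coalsize_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$trajectory$loglik[nrow(x$trajectory)],
    iterations = nrow(x$trajectory),
    converged = x$converged,
    hidden_state = x$hidden_state,
    n_epochs = length(x$model$log_rates)
  )
}
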