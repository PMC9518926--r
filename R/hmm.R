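# Observation sequences and the scaled forward-backward machinery.

#' Run-length encoded observation sequence
#'
#' Stores per-locus derived-allele counts as runs `(d, len)`; invariant
#' stretches are runs of `d = 0`. The result is a tibble with columns `d`
#' and `len` carrying the sample size and chromosome label as attributes.
#'
#' @param d Integer vector of derived-allele counts per run (`0..n-1`).
#' @param len Run lengths (`>= 1`).
#' @param n Number of haplotypes.
#' @param chrom Chromosome label.
#' @return A `chmm_obs` tibble.
#' @export
chmm_obs <- function(d, len, n, chrom = "1") {
  stopifnot(length(d) == length(len), all(len >= 1), all(d >= 0),
            all(d <= n - 1), n >= 2)
  # merge adjacent equal symbols so compression is canonical
  if (length(d) > 1) {
    grp <- cumsum(c(TRUE, d[-1] != d[-length(d)]))
    len <- as.numeric(rowsum(as.numeric(len), grp)[, 1])
    d <- d[!duplicated(grp)]
  }
  out <- tibble::tibble(d = as.integer(d), len = as.numeric(len))
  attr(out, "n") <- as.integer(n)
  attr(out, "chrom") <- chrom
  class(out) <- c("chmm_obs", class(out))
  out
}

#' @export
print.chmm_obs <- function(x, ...) {
  cat(sprintf("<chmm_obs> chrom %s, n = %d, %d runs, %g loci, %d segregating\n",
              attr(x, "chrom"), attr(x, "n"), nrow(x), total_loci(x),
              sum(x$len[x$d > 0])))
  invisible(x)
}

#' Total number of loci spanned by an observation sequence
#' @param obs A `chmm_obs`.
#' @return Number of loci (sum of run lengths).
#' @export
total_loci <- function(obs) sum(obs$len)

#' Expand an observation sequence to one emission per locus
#' @param obs A `chmm_obs`.
#' @return Integer vector of per-locus derived-allele counts.
#' @export
obs_expand <- function(obs) rep(obs$d, times = obs$len)

#' Compress a per-locus count vector into a `chmm_obs`
#' @param d_vec Integer vector of per-locus counts.
#' @inheritParams chmm_obs
#' @return A `chmm_obs`.
#' @export
obs_compress <- function(d_vec, n, chrom = "1") {
  r <- rle(d_vec)
  chmm_obs(r$values, r$lengths, n = n, chrom = chrom)
}

new_suffstats <- function(trans, emis, init, loglik, n_s, total_loci) {
  structure(list(trans = trans, emis = emis, init = init, loglik = loglik,
                 n_s = n_s, total_loci = total_loci),
            class = "chmm_suffstats")
}

#' @export
print.chmm_suffstats <- function(x, ...) {
  cat(sprintf("<chmm_suffstats> n_s = %d, loci = %g, loglik = %.4f\n",
              x$n_s, x$total_loci, x$loglik))
  invisible(x)
}

#' Add sufficient statistics across chromosomes or subsets
#'
#' Statistics computed at the same subset size and discretization are
#' additive.
#'
#' @param x,y `chmm_suffstats` objects with equal `n_s` and dimensions.
#' @return Combined `chmm_suffstats`.
#' @export
add_suffstats <- function(x, y) {
  stopifnot(x$n_s == y$n_s, all(dim(x$trans) == dim(y$trans)),
            all(dim(x$emis) == dim(y$emis)))
  new_suffstats(x$trans + y$trans, x$emis + y$emis, x$init + y$init,
                x$loglik + y$loglik, x$n_s, x$total_loci + y$total_loci)
}

check_hmm_inputs <- function(obs, A, B, Pi) {
  S <- nrow(A)
  stopifnot(ncol(A) == S, nrow(B) == S, length(Pi) == S)
  if (max(abs(rowSums(A) - 1)) > 1e-6 || abs(sum(Pi) - 1) > 1e-6 ||
      max(abs(rowSums(B) - 1)) > 1e-6) {
    stop("forward_backward: A and B must be row-stochastic and Pi a distribution")
  }
  if (max(obs$d) >= ncol(B)) {
    stop("forward_backward: observation alphabet exceeds emission columns")
  }
  invisible(S)
}

#' Scaled forward-backward algorithm
#'
#' Exact per-locus scaled forward-backward over the expanded observation
#' sequence, returning the log-likelihood and the expected transition,
#' emission, and initial-state counts (the sufficient statistics of the EM
#' algorithm).
#'
#' @param obs A `chmm_obs` (or a `chmm_transition`/`chmm_emission` pair's
#'   alphabet-compatible sequence).
#' @param A Row-stochastic transition matrix (S x S).
#' @param B Row-stochastic emission matrix (S x D).
#' @param Pi Initial distribution (length S).
#' @param posterior If `TRUE`, also return per-locus posterior state
#'   marginals (memory grows with the number of loci).
#' @return A `chmm_suffstats`; with `posterior = TRUE` the matrix of
#'   posterior marginals is attached as attribute `"posterior"`.
#' @export
forward_backward <- function(obs, A, B, Pi, posterior = FALSE) {
  check_hmm_inputs(obs, A, B, Pi)
  d <- obs_expand(obs)
  res <- fb_naive_cpp(d, A, B, Pi, posterior)
  out <- new_suffstats(res$trans, res$emis, res$init, res$loglik,
                       attr(obs, "n"), length(d))
  if (posterior) attr(out, "posterior") <- res$posterior
  out
}

# eigenstructure cache for M = A diag(b); returns NULL if ill-conditioned
run_eigen <- function(M) {
  eg <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  W <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  if (is.null(W)) return(NULL)
  cond <- sqrt(sum(Mod(eg$vectors)^2) * sum(Mod(W)^2))  # Frobenius bound
  if (!is.finite(cond) || cond > 1e8) return(NULL)
  list(V = eg$vectors, W = W, d = eg$values)
}

# spectral computation of within-run quantities for a homogeneous run:
# expected transitions/occupancies (posterior-normalized) plus the advanced
# forward vector. Returns NULL if numerically unreliable.
run_spectral <- function(eg, x0, ym, A, b, m) {
  r <- max(abs(eg$d))
  if (r == 0) return(NULL)
  dh <- eg$d / r
  p <- as.vector(x0 %*% eg$V)
  q <- as.vector(eg$W %*% ym)
  dm <- dh^m
  Zh <- sum(p * dm * q)
  if (!is.finite(Re(Zh)) || Re(Zh) <= 0) return(NULL)
  dd <- outer(dh, dh, "-")
  Smat <- ifelse(abs(dd) > 1e-9,
                 outer(dm, dm, "-") / dd,
                 m * outer(dh^(pmax(m - 1, 0)), rep(1, length(dh))))
  G <- outer(p, q)
  X <- t(eg$W) %*% (G * Smat) %*% t(eg$V)
  Etr <- Re(X) * A * rep(b, each = nrow(A)) / (r * Re(Zh))
  H <- (G * Smat) * dh  # rows scaled by dh_k
  Y <- Re(diag(t(eg$W) %*% H %*% t(eg$V))) / Re(Zh)
  xv <- Re(as.vector((p * dm) %*% eg$W))
  if (any(!is.finite(Etr)) || any(!is.finite(Y)) || any(!is.finite(xv)) ||
      min(xv) < -1e-9 * max(xv)) {
    return(NULL)
  }
  xv <- pmax(xv, 0)
  list(trans = Etr, emis_occ = Y, x_out = xv, x_log = m * log(r))
}

#' Forward-backward with locus skipping
#'
#' Computes the same sufficient statistics as [forward_backward()] but
#' advances through homogeneous runs (typically the invariant stretches
#' between segregating sites) in closed form: the run propagator
#' `M = A diag(B[, d])` is powered through its eigendecomposition, and the
#' expected within-run transition and occupancy counts are accumulated by
#' the corresponding spectral sums. Falls back to an exact per-locus
#' recursion for runs where the eigendecomposition is unreliable.
#'
#' @inheritParams forward_backward
#' @param max_run Runs longer than this are processed in chunks (bounds the
#'   fallback's memory).
#' @return A `chmm_suffstats`, equal to the naive algorithm's output up to
#'   numerical tolerance.
#' @export
forward_backward_skipping <- function(obs, A, B, Pi, max_run = 1e6) {
  S <- check_hmm_inputs(obs, A, B, Pi)
  D <- ncol(B)
  # chunk very long runs (keeps the fallback bounded)
  ds <- obs$d; ls <- obs$len
  if (any(ls > max_run)) {
    sp <- lapply(seq_along(ds), function(i) {
      k <- ceiling(ls[i] / max_run)
      lens <- rep(floor(ls[i] / k), k)
      lens[seq_len(ls[i] - sum(lens))] <- lens[seq_len(ls[i] - sum(lens))] + 1
      cbind(d = ds[i], len = lens)
    })
    sp <- do.call(rbind, sp)
    ds <- sp[, 1]; ls <- sp[, 2]
  }
  R <- length(ds)
  eigens <- vector("list", D)
  Ms <- vector("list", D)
  get_M <- function(d) {
    if (is.null(Ms[[d + 1]])) Ms[[d + 1]] <<- A * rep(B[, d + 1], each = S)
    Ms[[d + 1]]
  }
  get_eigen <- function(d) {
    if (is.null(eigens[[d + 1]])) {
      eigens[[d + 1]] <<- run_eigen(get_M(d))
      if (is.null(eigens[[d + 1]])) eigens[[d + 1]] <<- list(bad = TRUE)
    }
    eigens[[d + 1]]
  }
  # advance a backward vector m steps through a homogeneous run of symbol d
  backward_advance <- function(y, d, m) {
    eg <- get_eigen(d)
    if (is.null(eg$bad) && m > 1) {
      dh <- eg$d / max(abs(eg$d))
      bv <- Re(as.vector(eg$V %*% (dh^m * (eg$W %*% y))))
      if (all(is.finite(bv)) && max(bv) > 0) return(pmax(bv, 0) / max(bv))
    }
    bv <- y
    M <- get_M(d)
    for (u in seq_len(m)) {
      bv <- as.vector(M %*% bv)
      mx <- max(bv)
      if (mx <= 0) stop("zero mass in backward pass")
      bv <- bv / mx
    }
    bv
  }
  # backward vectors at the last locus of each run (normalized)
  betas <- matrix(NA_real_, R, S)
  betas[R, ] <- rep(1, S)
  if (R > 1) {
    for (r in R:2) {
      betas[r - 1, ] <- backward_advance(betas[r, ], ds[r], ls[r])
    }
  }
  # forward sweep with within-run count accumulation
  trans <- matrix(0, S, S)
  emis <- matrix(0, S, D)
  b1 <- B[, ds[1] + 1]
  alpha1 <- Pi * b1
  c1 <- sum(alpha1)
  loglik <- log(c1)
  alpha1 <- alpha1 / c1
  # posterior at locus 1 needs the backward vector at locus 1
  beta_loc1 <- if (ls[1] > 1) backward_advance(betas[1, ], ds[1], ls[1] - 1)
               else betas[1, ]
  Z1 <- sum(alpha1 * beta_loc1)
  init <- alpha1 * beta_loc1 / Z1
  emis[, ds[1] + 1] <- emis[, ds[1] + 1] + init
  advance <- function(x0, ym, d, m) {
    # returns list(trans, emis_occ, x_out normalized, ll increment)
    eg <- get_eigen(d)
    res <- NULL
    if (is.null(eg$bad)) {
      res <- run_spectral(eg, x0, ym, A, B[, d + 1], m)
    }
    if (is.null(res)) {
      res <- fb_run_exact_cpp(x0, ym, A, B[, d + 1], m)
    }
    s <- sum(res$x_out)
    list(trans = res$trans, emis_occ = res$emis_occ, x_out = res$x_out / s,
         ll = res$x_log + log(s))
  }
  alpha <- alpha1
  if (ls[1] > 1) {
    res <- advance(alpha1, betas[1, ], ds[1], ls[1] - 1)
    trans <- trans + res$trans
    emis[, ds[1] + 1] <- emis[, ds[1] + 1] + res$emis_occ
    alpha <- res$x_out
    loglik <- loglik + res$ll
  }
  if (R > 1) {
    for (r in 2:R) {
      res <- advance(alpha, betas[r, ], ds[r], ls[r])
      trans <- trans + res$trans
      emis[, ds[r] + 1] <- emis[, ds[r] + 1] + res$emis_occ
      alpha <- res$x_out
      loglik <- loglik + res$ll
    }
  }
  new_suffstats(trans, emis, init, loglik, attr(obs, "n"), sum(ls))
}

#' Group loci into meta-loci
#'
#' Partitions the sequence into windows of `w` loci; each window emits the
#' multiset of its derived-allele counts under a single hidden state
#' (emission probability is the product of the per-site emissions), and
#' adjacent windows are linked by a transition set built with the
#' recombination rate scaled by `w`. `w = 1` recovers the exact model.
#'
#' @param obs A `chmm_obs`.
#' @param w Window size in loci (`>= 1`).
#' @return A `chmm_meta_obs`: window emission keys plus the key definitions
#'   needed to rebuild window emissions from any per-site emission matrix,
#'   and the factor by which to scale rho when building transitions.
#' @export
meta_locus_compress <- function(obs, w) {
  stopifnot(w >= 1)
  n <- attr(obs, "n")
  d_vec <- obs_expand(obs)
  L <- length(d_vec)
  n_win <- ceiling(L / w)
  win <- rep(seq_len(n_win), each = w)[seq_len(L)]
  win_len <- tabulate(win, n_win)
  # key: window length and its nonzero symbol multiset
  seg <- d_vec > 0
  idx_by_win <- split(d_vec[seg], win[seg])
  key_str <- paste0(win_len, ":")
  if (length(idx_by_win) > 0) {
    kk <- vapply(idx_by_win, function(v) paste(sort(v), collapse = ","), "")
    key_str[as.integer(names(idx_by_win))] <-
      paste0(key_str[as.integer(names(idx_by_win))], kk)
  }
  keys <- unique(key_str)
  key_idx <- match(key_str, keys)
  key_def <- lapply(keys, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    len <- as.integer(parts[1])
    snps <- if (length(parts) > 1 && nzchar(parts[2])) {
      as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    } else integer(0)
    list(len = len, snps = snps)
  })
  structure(list(key_idx = key_idx, key_def = key_def, w = w, n = n,
                 total_loci = L, chrom = attr(obs, "chrom")),
            class = "chmm_meta_obs")
}

#' @export
print.chmm_meta_obs <- function(x, ...) {
  cat(sprintf("<chmm_meta_obs> %d windows of %d loci (%d emission classes)\n",
              length(x$key_idx), x$w, length(x$key_def)))
  invisible(x)
}

#' Window emission matrix for meta-loci
#'
#' Builds the per-window emission matrix from a per-site emission matrix:
#' each window's emission is the product over its sites of the per-site
#' emission probabilities.
#'
#' @param meta A `chmm_meta_obs`.
#' @param B Per-site emission matrix (S x n).
#' @return Matrix S x (number of distinct window classes), rows are the
#'   (unnormalized) window emission likelihoods.
#' @export
meta_emission_matrix <- function(meta, B) {
  logB0 <- log(B[, 1])
  vapply(meta$key_def, function(kd) {
    lp <- (kd$len - length(kd$snps)) * logB0
    for (d in kd$snps) lp <- lp + log(B[, d + 1])
    exp(lp)
  }, numeric(nrow(B)))
}

#' Forward-backward over meta-loci
#'
#' @param meta A `chmm_meta_obs` from [meta_locus_compress()].
#' @param A_meta Transition matrix built with `rho` scaled by the window
#'   size.
#' @param B Per-site emission matrix.
#' @param Pi Initial distribution.
#' @return A `chmm_suffstats` over windows: `trans` counts window-to-window
#'   transitions, `emis` counts expected occupancies per window class
#'   (columns are window classes, with the class definitions attached).
#' @export
forward_backward_meta <- function(meta, A_meta, B, Pi) {
  E <- meta_emission_matrix(meta, B)
  res2 <- fb_meta_exact(meta$key_idx, E, A_meta, Pi)
  out <- new_suffstats(res2$trans, res2$emis, res2$init, res2$loglik,
                       meta$n, meta$total_loci)
  attr(out, "key_def") <- meta$key_def
  attr(out, "meta") <- TRUE
  out
}

# scaled forward-backward with arbitrary nonnegative emission columns
fb_meta_exact <- function(key_idx, E, A, Pi) {
  L <- length(key_idx)
  S <- nrow(A)
  alpha <- matrix(0, L, S)
  cs <- numeric(L)
  a <- Pi * E[, key_idx[1]]
  cs[1] <- sum(a)
  alpha[1, ] <- a / cs[1]
  for (l in seq_len(L - 1) + 1) {
    a <- as.vector(alpha[l - 1, ] %*% A) * E[, key_idx[l]]
    cs[l] <- sum(a)
    if (cs[l] <= 0) stop(sprintf("zero emission probability at window %d", l))
    alpha[l, ] <- a / cs[l]
  }
  loglik <- sum(log(cs))
  beta <- rep(1, S)
  trans <- matrix(0, S, S)
  emis <- matrix(0, S, ncol(E))
  emis[, key_idx[L]] <- emis[, key_idx[L]] + alpha[L, ]
  for (l in rev(seq_len(L - 1))) {
    bnext <- E[, key_idx[l + 1]] * beta
    trans <- trans + (alpha[l, ] %o% bnext) * A / cs[l + 1]
    beta <- as.vector(A %*% bnext) / cs[l + 1]
    g <- alpha[l, ] * beta
    emis[, key_idx[l]] <- emis[, key_idx[l]] + g
  }
  list(trans = trans, emis = emis, init = alpha[1, ] * beta / sum(alpha[1, ] * beta),
       loglik = loglik)
}
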