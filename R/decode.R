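# Posterior decoding at run resolution.

#' Posterior hidden-state distributions per run
#'
#' Computes the posterior state distribution at the last locus of every run
#' of the observation sequence (segregating sites are their own runs, so
#' every SNP gets an exact per-locus posterior; invariant stretches are
#' summarized by their endpoint). Intervals are reported 0-based,
#' half-open.
#'
#' @inheritParams forward_backward
#' @return A tibble with `start`, `end` (0-based, half-open), `d`, and one
#'   `state_i` column per hidden state.
#' @export
decode_runs <- function(obs, A, B, Pi) {
  S <- check_hmm_inputs(obs, A, B, Pi)
  R <- nrow(obs)
  M_of <- function(d) A * rep(B[, d + 1], each = S)
  # backward vectors at run ends
  betas <- matrix(NA_real_, R, S)
  betas[R, ] <- 1
  if (R > 1) {
    for (r in R:2) {
      bv <- betas[r, ]
      M <- M_of(obs$d[r])
      eg <- run_eigen(M)
      if (!is.null(eg)) {
        dh <- eg$d / max(abs(eg$d))
        bv <- Re(as.vector(eg$V %*% (dh^obs$len[r] * (eg$W %*% bv))))
        bv <- pmax(bv, 0)
      } else {
        for (u in seq_len(obs$len[r])) bv <- as.vector(M %*% bv) / max(M %*% bv)
      }
      betas[r - 1, ] <- bv / max(bv)
    }
  }
  # forward vectors at run ends
  gam <- matrix(NA_real_, R, S)
  alpha <- Pi * B[, obs$d[1] + 1]
  alpha <- alpha / sum(alpha)
  advance <- function(alpha, d, m) {
    M <- M_of(d)
    eg <- run_eigen(M)
    if (!is.null(eg)) {
      dh <- eg$d / max(abs(eg$d))
      v <- Re(as.vector((alpha %*% eg$V) * dh^m) %*% eg$W)
      v <- pmax(as.vector(v), 0)
      if (sum(v) > 0) return(v / sum(v))
    }
    for (u in seq_len(m)) {
      alpha <- as.vector(alpha %*% M)
      alpha <- alpha / sum(alpha)
    }
    alpha
  }
  for (r in seq_len(R)) {
    if (r == 1) {
      if (obs$len[1] > 1) alpha <- advance(alpha, obs$d[1], obs$len[1] - 1)
    } else {
      alpha <- advance(alpha, obs$d[r], obs$len[r])
    }
    g <- alpha * betas[r, ]
    gam[r, ] <- g / sum(g)
  }
  ends <- cumsum(obs$len)
  out <- tibble::tibble(start = ends - obs$len, end = ends, d = obs$d)
  colnames(gam) <- paste0("state_", seq_len(S))
  dplyr::bind_cols(out, tibble::as_tibble(gam))
}
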