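# Synthetic data at two fidelities: sampling directly from the CHMM
# matrices (model-exact, for mismatch-free EM recovery checks), and a
# sequentially Markovian coalescent sequence simulator with recombination
# and infinite-sites mutations (writes VCF).

#' Sample an observation sequence from CHMM matrices
#'
#' Draws a hidden path from `(Pi, A)` and emissions from `B`; the emitted
#' derived-allele counts are returned run-length encoded. This sampler is
#' exact under the model, so EM on its output is a pure parameter-recovery
#' exercise with no model mismatch.
#'
#' @param A,B,Pi CHMM matrices (e.g. from [build_transition_tmrca()] and
#'   [build_emission_tmrca()]).
#' @param n_loci Number of loci to sample.
#' @param seed RNG seed.
#' @param chrom Chromosome label for the output.
#' @return A `chmm_obs` with `n = ncol(B)`.
#' @export
sample_from_chmm <- function(A, B, Pi, n_loci, seed = 1, chrom = "sim") {
  stopifnot(nrow(A) == ncol(A), nrow(B) == nrow(A), length(Pi) == nrow(A))
  d <- withr::with_seed(seed, sample_hmm_cpp(A, B, Pi, as.integer(n_loci)))
  obs_compress(d, n = ncol(B), chrom = chrom)
}

# sample the next coalescence time after t0 for a pair-rate multiplier c
# under the model's piecewise-constant rate (inversion of the integrated
# hazard)
sample_event_time <- function(model, t0, c) {
  target <- rexp(1)
  rates <- exp(model$log_rates)
  cuts <- c(model$change_points, Inf)
  e <- epoch_index(model, t0)
  t <- t0
  repeat {
    lam <- rates[e] * c
    seg_end <- cuts[e]
    need <- target / lam
    if (t + need < seg_end) return(t + need)
    target <- target - lam * (seg_end - t)
    t <- seg_end
    e <- e + 1
  }
}

# sample an initial coalescent tree for n tips under the model; returns
# parent/time vectors (tips 1..n, internals n+1..2n-1, root parent 0)
sample_coal_tree <- function(model, n) {
  parent <- integer(2 * n - 1)
  node_time <- numeric(2 * n - 1)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1
  while (length(active) > 1) {
    k <- length(active)
    t <- sample_event_time(model, t, choose(k, 2))
    pair <- sample(active, 2)
    parent[pair] <- nxt
    node_time[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1
  }
  list(parent = parent, time = node_time, n = n)
}

tree_edges <- function(tree) {
  root <- which(tree$parent == 0)
  nodes <- setdiff(seq_along(tree$parent), root)
  lens <- tree$time[tree$parent[nodes]] - tree$time[nodes]
  list(child = nodes, len = lens, root = root,
       total = sum(lens), tmrca = tree$time[root])
}

tips_under <- function(tree, node) {
  n <- tree$n
  if (node <= n) return(node)
  kids <- which(tree$parent == node)
  unlist(lapply(kids, function(k) tips_under(tree, k)))
}

nodes_under <- function(tree, node) {
  kids <- which(tree$parent == node)
  c(node, unlist(lapply(kids, function(k) nodes_under(tree, k))))
}

# one SMC update: detach the lineage above a uniformly chosen point on the
# tree and re-coalesce it into the remaining lineages under the model
smc_recombine <- function(tree, model) {
  ed <- tree_edges(tree)
  pick <- sample.int(length(ed$child), 1, prob = ed$len)
  c_node <- ed$child[pick]
  t_r <- tree$time[c_node] + runif(1) * ed$len[pick]
  p <- tree$parent[c_node]
  # splice out p: its other child joins p's parent
  q <- setdiff(which(tree$parent == p), c_node)
  tree$parent[q] <- tree$parent[p]
  tree$parent[p] <- 0L
  tree$parent[c_node] <- 0L
  # the whole floating subtree (c_node and everything below it) leaves the
  # remaining tree
  float_nodes <- nodes_under(tree, c_node)
  float_tips <- float_nodes[float_nodes <= tree$n]
  # lineage count of the remaining tree as a function of time: internal
  # node times of the remaining tree
  rem_children <- setdiff(which(tree$parent != 0), float_nodes)
  rem_internal_times <- sort(tree$time[unique(tree$parent[rem_children])])
  n_rem_tips <- tree$n - length(float_tips)
  k_at <- function(t) max(1L, n_rem_tips - sum(rem_internal_times <= t))
  # sample the re-coalescence time: intensity lambda(t) * k(t)
  brks <- sort(unique(c(rem_internal_times[rem_internal_times > t_r],
                        model$change_points[model$change_points > t_r])))
  target <- rexp(1)
  t <- t_r
  t_new <- NA_real_
  for (b in c(brks, Inf)) {
    if (is.finite(b)) {
      seg <- (b - t)
      amount <- coal_rate(model, t) * k_at(t) * seg
      if (target <= amount) { t_new <- t + target / (coal_rate(model, t) * k_at(t)); break }
      target <- target - amount
      t <- b
    } else {
      t_new <- t + target / (coal_rate(model, t) * k_at(t))
      break
    }
  }
  # choose uniformly one of the remaining lineages present at t_new
  spanning <- rem_children[tree$time[rem_children] <= t_new &
                           tree$time[tree$parent[rem_children]] > t_new]
  rem_root <- setdiff(which(tree$parent == 0), c(p, c_node))
  if (tree$time[rem_root] <= t_new) spanning <- c(spanning, rem_root)
  z <- if (length(spanning) == 1) spanning else sample(spanning, 1)
  # reuse p as the new coalescence node
  tree$time[p] <- t_new
  tree$parent[c_node] <- p
  tree$parent[p] <- if (z == rem_root && tree$time[rem_root] <= t_new) 0L else tree$parent[z]
  tree$parent[z] <- p
  tree
}

#' Simulate polymorphism data under the sequentially Markovian coalescent
#'
#' The genealogy at the first base is drawn from the coalescent with the
#' model's time-varying rate. Moving along the sequence, recombination
#' events occur at rate `rho / 2` per unit branch length per base; at each
#' event the branch above a uniformly chosen point is detached and the
#' freed lineage re-coalesces into the remaining tree, giving the next
#' marginal genealogy. Mutations are laid down as a Poisson process with
#' rate `theta / 2` per unit branch length per base under the infinite
#' sites model (at most one mutation per base), and each segregating site
#' records which haplotypes carry the derived allele.
#'
#' @param model A `coal_model` (mu, r, and N0 set the per-base theta and
#'   rho).
#' @param n Number of haplotypes.
#' @param seq_len Sequence length in base pairs.
#' @param seed RNG seed.
#' @param chrom Chromosome label.
#' @return A `hap_data` with the simulated genotypes; the per-segment truth
#'   track (start, end, tmrca, total branch length, both in coalescent
#'   units) is attached as attribute `"truth"`.
#' @export
simulate_smc <- function(model, n, seq_len, seed = 1, chrom = "sim1") {
  stopifnot(n >= 2, seq_len >= 1)
  theta <- theta_rate(model)
  rho <- rho_rate(model)
  withr::with_seed(seed, {
    tree <- sample_coal_tree(model, n)
    pos_list <- list()
    der_list <- list()
    truth <- list()
    pos <- 1
    while (pos <= seq_len) {
      ed <- tree_edges(tree)
      seg_len <- if (rho > 0) {
        max(1, ceiling(rexp(1, rate = rho / 2 * ed$total)))
      } else {
        seq_len
      }
      seg_end <- min(pos + seg_len - 1, seq_len)
      width <- seg_end - pos + 1
      n_mut <- rpois(1, theta / 2 * ed$total * width)
      n_mut <- min(n_mut, width)  # infinite sites at base resolution
      if (n_mut > 0) {
        mp <- pos - 1 + sample.int(width, n_mut)
        for (j in seq_len(n_mut)) {
          e <- sample.int(length(ed$child), 1, prob = ed$len)
          tips <- tips_under(tree, ed$child[e])
          if (length(tips) < n) {  # mutations above the MRCA cannot occur;
            pos_list[[length(pos_list) + 1]] <- mp[j]
            der_list[[length(der_list) + 1]] <- tips
          }
        }
      }
      truth[[length(truth) + 1]] <-
        c(start = pos, end = seg_end, tmrca = ed$tmrca, length = ed$total)
      pos <- seg_end + 1
      if (pos <= seq_len) tree <- smc_recombine(tree, model)
    }
    pos_vec <- unlist(pos_list)
    ord <- order(pos_vec)
    hap <- matrix(0L, length(pos_vec), n)
    for (i in seq_along(ord)) {
      hap[i, der_list[[ord[i]]]] <- 1L
    }
    truth_tb <- tibble::as_tibble(do.call(rbind, truth))
    structure(list(chrom = chrom, pos = pos_vec[ord], hap = hap,
                   ploidy = rep(2L, floor(n / 2)),
                   seq_start = 1L, seq_end = as.integer(seq_len),
                   truth = truth_tb),
              class = "hap_data")
  })
}

#' Write haplotype data as a plain-text VCF
#'
#' Emits biallelic SNP records with `AA` (ancestral allele) INFO tags;
#' haplotypes are paired into diploid samples with phased genotypes (the
#' method ignores phase, so the pairing is only a formatting choice), or
#' written as haploid samples if `diploid = FALSE` or the haplotype count
#' is odd.
#'
#' @param hap A `hap_data`.
#' @param path Output file.
#' @param diploid Pair haplotype columns into diploid samples.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hap, path, diploid = TRUE) {
  stopifnot(inherits(hap, "hap_data"))
  n <- ncol(hap$hap)
  diploid <- diploid && n %% 2 == 0
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##contig=<ID=%s,length=%d>", hap$chrom, hap$seq_end)
  )
  samples <- if (diploid) paste0("ind", seq_len(n / 2)) else paste0("hap", seq_len(n))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
  gt <- if (diploid) {
    odd <- hap$hap[, seq(1, n, 2), drop = FALSE]
    even <- hap$hap[, seq(2, n, 2), drop = FALSE]
    matrix(paste0(odd, "|", even), nrow = nrow(hap$hap))
  } else {
    matrix(as.character(hap$hap), nrow = nrow(hap$hap))
  }
  rows <- vapply(seq_along(hap$pos), function(i) {
    paste(c(hap$chrom, hap$pos[i], ".", "A", "T", ".", "PASS", "AA=A", "GT",
            gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Accuracy of estimated size histories: mean signed error and its integral
#'
#' For `m` replicate estimates, the mean signed error at generation `k` is
#' the average absolute log-ratio of estimated to true size,
#' `Delta(k) = mean_j |log(Nhat_j(k) / N_true(k))|`, and the summary
#' `phi = int Delta(k) / k dk` integrates it on a logarithmic time axis
#' (computed by the trapezoid rule in `log k`).
#'
#' @param estimates A `coal_model`, `coalsize_fit`, or list of either (one
#'   per replicate).
#' @param truth The true `coal_model`.
#' @param k_min,k_max Integration range in generations. Defaults to the
#'   estimated model's change-point range widened by one logarithmic
#'   discretization step on each side.
#' @param n_grid Number of evaluation points (log-spaced).
#' @return A list with `delta` (tibble of `k`, `delta`) and the scalar
#'   `phi`.
#' @export
mean_signed_error <- function(estimates, truth, k_min = NULL, k_max = NULL,
                              n_grid = 257) {
  as_model <- function(x) {
    if (inherits(x, "coalsize_fit")) x$model
    else { stopifnot(inherits(x, "coal_model")); x }
  }
  models <- if (inherits(estimates, c("coal_model", "coalsize_fit"))) {
    list(as_model(estimates))
  } else {
    lapply(estimates, as_model)
  }
  cp_gen <- models[[1]]$change_points * 2 * models[[1]]$N0
  if (is.null(k_min) || is.null(k_max)) {
    if (length(cp_gen) < 2) {
      stop("mean_signed_error: supply k_min and k_max for models without a change-point grid")
    }
    step <- exp(mean(diff(log(cp_gen))))
    if (is.null(k_min)) k_min <- cp_gen[1] / step
    if (is.null(k_max)) k_max <- cp_gen[length(cp_gen)] * step
  }
  stopifnot(k_min > 0, k_max > k_min)
  k <- exp(seq(log(k_min), log(k_max), length.out = n_grid))
  nt <- pop_size_at(truth, k)
  if (any(nt <= 0)) stop("mean_signed_error: nonpositive true sizes")
  abs_err <- vapply(models, function(m) {
    nh <- pop_size_at(m, k)
    if (any(nh <= 0)) stop("mean_signed_error: nonpositive estimated sizes")
    abs(log(nh / nt))
  }, numeric(length(k)))
  delta <- rowMeans(abs_err)
  lk <- log(k)
  phi <- sum(diff(lk) * (delta[-1] + delta[-length(delta)]) / 2)
  list(delta = tibble::tibble(k = k, delta = delta), phi = phi)
}
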