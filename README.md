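# coalsize

Inference of piecewise-constant population size histories from genomic
polymorphism data with a coalescent hidden Markov model (CHMM).

## What it does

The genealogy of a sample of `n` haplotypes varies along the genome because
of recombination; how fast it varies, and how many mutations each local
genealogy collects, both depend on the history of the effective population
size `N(k)` (diploids, `k` generations before present). `coalsize` models
the sequence of local genealogies as a hidden Markov chain over a
one-dimensional summary of the local tree — either the time to the most
recent common ancestor (TMRCA) or the total branch length `L` — discretized
into `S` intervals. The emission at each site is the number of derived
alleles `d` among the `n` haplotypes, so the method needs neither phasing
nor, in its pseudo-haploid mode, reliable diploid genotype calls.

The model works in coalescent time (units of `2 N0` generations) with a
piecewise-constant coalescent rate `lambda(t) = N0 / N(2 N0 t)` and scaled
rates `theta = 4 N0 mu`, `rho = 4 N0 r` per site. Transition probabilities
come from a two-locus ancestral process that tracks lineage configurations
`(k_ab, k_a, k_b, kappa)` with at most one recombination between adjacent
sites; emission probabilities come from a single-locus process `(k, k*)`
with at most one mutation. For the TMRCA state these finite-state processes
are solved exactly by matrix exponentials; for the branch-length state the
joint distributions of accumulated length solve small transport PDE systems,
handled by an exact-advection characteristic scheme. Parameters (one log
coalescent rate per epoch, change points fixed) are estimated by EM: the
E-step is a scaled forward-backward with closed-form skipping across
invariant stretches, the M-step maximizes the expected log-likelihood

    Q(lambda) = sum_i E[s1 = i] log Pi_i(lambda)
              + sum_ij E[# i -> j] log A_ij(lambda)
              + sum_id E[# i emits d] log B_id(lambda)

by Nelder-Mead in log-rate space. A composite likelihood multiplies across
haplotype subsets of one or several sizes (e.g. all non-overlapping subsets
of sizes 2, 5, and 10), which concentrates information from different time
depths and keeps the state spaces small.

The package also ships a sequentially Markovian coalescent (SMC) simulator
that writes plain-text VCF together with the true local TMRCA/branch-length
track, and the accuracy metrics `Delta(k)` (mean absolute log-ratio of
estimated to true size at generation `k`) and `phi` (its integral on a
log-time axis).

## Worked example

Simulate a bottleneck (10,000 diploids dropping to 2,000 at 4,000
generations before present), then re-infer the two epoch sizes from the
sequence data alone:

```r
library(coalsize)

truth <- coal_model_sizes(c(10000, 2000), change_points_gen = 4000,
                          N0 = 10000, mu = 1.25e-8, r = 1.25e-8)
sim <- simulate_smc(truth, n = 10, seq_len = 1e7, seed = 42)

obs <- observations_from_haplotypes(sim)
S_obs <- sum(obs$len[obs$d > 0])
init <- watterson_init(S_obs, n = 10, seq_len = 1e7, mu = 1.25e-8)
model0 <- coal_model(c(0, 0), change_points = 4000 / (2 * init$N0),
                     N0 = init$N0, mu = 1.25e-8, r = 1.25e-8)

fit <- run_em(sim, model0, scheme = build_subsets(10, sizes = c(2, 5, 10)),
              hidden_state = "tmrca", S = 16)
tidy(fit)
#> # A tibble: 2 x 3
#>   generation_start generation_end N_diploid
#>              <dbl>          <dbl>     <dbl>
#> 1                0           4000    10198.
#> 2             4000            Inf     1962.
```

The recent epoch is recovered at about 10,200 diploids and the ancestral
epoch at about 1,960 — within 2% of the simulated truth on this replicate.
`autoplot(fit, truth = truth)` overlays the fitted and true histories;
`mean_signed_error(fit, truth, k_min = 500, k_max = 40000)$phi` summarizes
the discrepancy on a log-time axis.

The same analysis runs from the shell via the bundled script
(`inst/scripts/coalsize`): `coalsize simulate ... | coalsize infer --vcf ...
--subset-sizes 2,5,10 --mu 1.25e-8 --rec-rate 1.25e-8`.

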