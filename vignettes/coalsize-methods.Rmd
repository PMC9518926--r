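---
title: "Population size histories from a coalescent HMM: models, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population size histories from a coalescent HMM: models, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`coalsize` infers a piecewise-constant history of the diploid effective
population size $N(k)$ ($k$ generations before present) from the
polymorphism pattern of $n$ haplotypes. Time is measured in coalescent
units of $2N_0$ generations, with $N_0$ an arbitrary reference size; the
model parameter is the coalescent rate $\lambda(t) = N_0 / N(2N_0 t)$, one
constant per epoch, optimized on the log scale so rates stay positive. The
scaled per-site mutation and recombination rates are $\theta = 4 N_0 \mu$
and $\rho = 4 N_0 r$.

Under the sequentially Markovian coalescent, the local genealogy changes
along the genome only at recombination events, so the sequence of local
trees is a Markov chain. The package collapses each local tree to a
one-dimensional summary — the TMRCA $T$ or the total branch length $L$ —
discretized into $S$ intervals $0 = t_0 < t_1 < \dots < t_S = \infty$, and
treats the interval index as the hidden state of an HMM whose emission at
each site is the derived-allele count $d \in \{0, \dots, n-1\}$. Because
only counts enter, phase is irrelevant by construction. Sites where all
$n$ haplotypes carry the same allele are $d = 0$; a site at which every
sampled haplotype carries the derived allele is also coded $d = 0$, since a
mutation above the sample's MRCA is outside the model.

### Transition probabilities

Transitions couple two adjacent sites. The two-locus ancestral process
follows lineage configurations $(k_{ab}, k_a, k_b, \kappa)$ — lineages
ancestral to both loci, to locus $a$ only, to locus $b$ only, and the
number of recombination events so far, capped at one because $\rho$ per
base is tiny. Coalescence moves are proportional to $\lambda(t)$
(with multiplicities $\binom{k_{ab}}{2}$, $\binom{k_a}{2} + k_a k_{ab}$,
$\binom{k_b}{2} + k_b k_{ab}$), and the recombination move
$(k_{ab}, k_a, k_b, 0) \to (k_{ab}-1, k_a+1, k_b+1, 1)$ carries rate
$k_{ab}\rho/2$. The states $(1,0,0,0)$ and $(1,0,0,1)$ are absorbing; the
formally possible recombination out of $(1,0,0,0)$ is disabled because
post-MRCA recombination cannot alter either marginal TMRCA. The joint CDF
of the two TMRCAs evaluates, for $\tau_a \le \tau_b$, to the absorbed mass
at $\tau_a$ plus the mass of the "locus $a$ done, locus $b$ pending" state
times the probability that the remaining pair coalesces before $\tau_b$,
$1 - e^{-\int_{\tau_a}^{\tau_b}\lambda}$. Differencing this CDF on the
boundary grid gives the joint interval masses $A^{PMF}$, conditioning on
the row gives $A$, and row sums give the stationary marginal $\Pi$.

Because $\lambda(t)$ is piecewise constant, the forward equation
$\dot g = g\,Q(t)$ has an exact solution as a product of matrix
exponentials over epoch segments; no numerical integrator is involved. For
large state spaces (the pseudo-haploid mode runs the machinery at $2n$)
the exponential action is computed by uniformization, which is exact up to
a Poisson-tail truncation below $10^{-15}$. The $t_S = \infty$ boundary is
handled analytically: remaining transient mass is routed to the absorbing
states by solving $-Q_{TT}^{-1} Q_{TA}$ under the final epoch's generator.

### Emission probabilities

A single-locus process $(k, k^*)$ tracks the lineage count and the number
of lineages present when the single permitted mutation (rate $k\theta/2$
while unmutated) occurred, $k^* = -1$ before any mutation. Absorption in
$(1, -1)$ emits $d = 0$; absorption in $(1, k^*)$ emits $d$ with the
classical probability $\binom{n-d-1}{k^*-2}/\binom{n-1}{k^*-1}$ that the
mutated lineage subtends $d$ leaves. Evaluating at the boundaries,
differencing in time, and row-normalizing yields $B$.

### The branch-length hidden state

For $L$ as the hidden state the same processes are augmented with
accumulated length: each state advances $L_a$ at integer velocity
$v_a = (k_{ab}+k_a)\,\mathbf 1\{k_{ab}+k_a > 1\}$ (and likewise $v_b$,
or $v = k\,\mathbf 1\{k>1\}$ for the mutation process), giving linear
transport PDEs such as
$\partial_t F + \partial_x F V_a + \partial_y F V_b = F\,Q(t)$ for
$F_\sigma(t,x,y) = P[\text{state }\sigma, L_a \le x, L_b \le y]$. The
joint length CDF is read off the absorbed states at $t = \max(x,y)/2$:
beyond that time any locus that has not coalesced has already accumulated
more than $x$ (at least two lineages accumulate at least two units of
length per unit time), so the absorbed mass is constant in $t$ there.

## Numerical scheme for the transport systems

The published description of the PDE solver behind the branch-length state
is not available in detail, so the package uses a scheme chosen for being
exactly analyzable: the grid is built with $\Delta t = \Delta x$, so pure
advection moves every state's profile by exactly $v$ cells per step (no
numerical diffusion), and the source coupling applies the full-step matrix
exponential $e^{Q\Delta t}$, with mass transferring between states
deposited along its mean characteristic segment (one node per traversed
cell, fractional positions assigned to the ceiling node so that node
values of the CDF reproduce a uniform spread across the traversed cells).
Queried values are read a few steps after the critical time — legitimate
because the queried absorbing states are constant in $t$ past it — which
avoids sampling exactly at the moving front. Joint-CDF queries on the
diagonal $x = y$ interpolate along the grid diagonal because the CDF has a
kink across it (the unrecombined histories put an atom of probability on
$L_a = L_b$). With $\rho = 0$ the two loci share one genealogy and the
joint CDF is computed exactly from the single-locus marginal, making
$A = I$ exact in that limit.

Default resolutions are 512 cells for the one-dimensional systems and 256
for the two-dimensional one; accuracy is anchored by closed forms (for
constant rate, $P[L \le x] = (1 - e^{-\lambda x/2})^{n-1}$), by
grid-refinement checks, and by an independent Gillespie simulation of the
two-locus process with length accumulation.

## Discretization of the hidden state

For the TMRCA state the $S-1$ finite boundaries are geometric between the
0.5% and 99.5% quantiles of the single-locus TMRCA distribution under the
current model, found by bisection on its CDF. (A lower endpoint tied to
the first-coalescence scale $0.1/\binom{n}{2}$ was considered and
rejected: the TMRCA of $n \ge 5$ samples carries essentially no mass
there, which produces empty hidden states.) For the branch-length state
the boundaries are the $i/S$ quantiles of the hypoexponential total length
under a constant-rate model matched to the mean pairwise coalescent time,
available in closed form; the hidden-state occupancy is then uniform by
construction under a constant history. Both ranges can be overridden.
$S$ defaults to 16 in the fitting interface.

## Estimation

EM with composite likelihood. For each subset size $n_s$ in the scheme the
package builds one $(A, B, \Pi)$ set per iteration and runs the scaled
forward–backward over every subset and chromosome, accumulating expected
initial, transition, and emission counts; statistics are additive within a
size class, and the objective sums across classes — algebraically the same
as summing per-subset EM objectives. Invariant stretches are skipped in
closed form: a run of $m$ identical symbols advances the forward vector by
$M^m$ with $M = A\,\mathrm{diag}(B_{\cdot d})$, powered through the
eigendecomposition of $M$, and the within-run expected transition and
occupancy counts come from the corresponding spectral sums
$\sum_{u} D^u G D^{m-1-u}$, which have closed forms in the eigenvalues. If
the eigenvector matrix is ill-conditioned (Frobenius condition estimate
above $10^8$) the run falls back to an exact per-locus recursion;
correctness is preferred over speed, and the fallback is exercised in
tests.

The M-step maximizes the expected complete-data log-likelihood with a
Nelder–Mead search in log-rate space (reflection/expansion/contraction
coefficients 1, 2, 0.5). The initial simplex follows a two-regime rule:
with fewer than 5 parameters, fixed offsets of 0.3 log units are added and
subtracted alternately along the coordinate axes; with 5 or more, each
coordinate is perturbed by 5% of its value (0.0000125 absolute for zero
coordinates, mirroring common practice). The regime magnitudes are package
choices; only the rule's structure is prescribed by the method. The M-step
never returns a point worse than its start, so the EM objective is
monotone up to the optimizer's tolerance. Iterations stop when the
relative change of the composite log-likelihood drops below $10^{-6}$, or
after 25 iterations for the TMRCA state and 15 for the branch-length state
(whose probability sets are much more expensive). An optional ridge
penalty $c_{12}\sum_i(\Delta_i \log\lambda)^2$ on adjacent log rates is
available for noisy real-data fits (disabled by default; the squared-
difference form is this package's reconstruction of a smoothness
penalty).

Initialization uses Watterson's estimator,
$\hat\theta = S/(L\sum_{i<n} 1/i)$ per site, giving $N_0 =
\hat\theta/4\mu$ and a constant-rate starting model. $N_0$, $\theta$, and
$\rho$ stay fixed during EM; only the relative rates move, and the output
converts back to diploid sizes $N = N_0/\lambda$ with epoch boundaries in
generations.

### Pseudo-haploid data

For $n$ pseudo-haploid samples (one allele drawn at random per individual
per site) the hidden state is the TMRCA of the underlying $2n$ haplotypes.
The emission is layered: the $2n$-sample emission produces $d'$, and a
hypergeometric draw of $n$ from $2n$ maps $d'$ to the observed $d$.
Counts of $d = n$ (all pseudo-haploids derived) are not observable —
such sites are coded invariant — so that column is folded into the row
renormalization.

## The synthetic-data generators

Two fidelities. `sample_from_chmm()` draws directly from $(\Pi, A, B)$;
EM on its output is a pure parameter-recovery exercise with zero model
mismatch, used to validate the estimation loop. `simulate_smc()` generates
sequence data under the generative model itself: the first tree from the
time-varying coalescent; recombination along the sequence at $\rho/2$ per
unit branch length per base; at each event the branch above a uniform
point is detached and the freed lineage re-coalesces at rate
$\lambda(t)\,k(t)$ into the remaining tree (SMC, not SMC'); mutations
Poisson at $\theta/2$ per unit branch length per base with at most one
mutation per base (infinite sites at base resolution). Defaults mirror a
human-like setting: $\mu = r = 1.25\times 10^{-8}$ per generation per
site and baseline $N_0 = 10^4$. The simulator reproduces Watterson's
expected segregating-site count, mean pairwise diversity, and the
stationary TMRCA interval occupancy within Monte-Carlo error, and it
writes plain-text VCF (with `AA` ancestral-allele tags) plus the true
per-segment TMRCA/length track.

What the simulator does not emulate: SMC' back-coalescence, gene
conversion, recombination-rate heterogeneity, mutation-rate
heterogeneity, sequencing error, or missing data. Passing tests on this
generator therefore demonstrates correctness of the inference machinery
under its own assumptions, not robustness to the additional noise of real
data.

## Accuracy metrics

For $m$ replicate estimates, $\Delta(k) = \frac1m\sum_j
|\log(\hat N^{(j)}(k)/N_{true}(k))|$ and $\phi = \int \Delta(k)\,k^{-1}dk$,
computed by the trapezoid rule on a logarithmic $k$ grid. By default the
integration range is the estimate's change-point range widened by one
logarithmic step on each side.

## Problem sizes used in the checks

The validation suite runs, as this package's chosen study sizes: Monte
Carlo oracles at $10^5$ (acceptance) or $4\times 10^4$ (unit tests)
Gillespie replicates for $n \in \{2, 3\}$ at $\rho = 0.05$;
constant-rate EM recovery on twelve model-exact chromosomes of $10^6$
sites each at $n_s = 2$ (the replication is set so the estimator's
sampling standard deviation, about 2% here, is well inside the 5% check —
a single $10^6$-site sequence carries only ~500 segregating sites and its
maximum-likelihood rate alone varies by ~6%); and sequence-level recovery
of a bottleneck (10,000 to 2,000 diploids at 4,000 generations) from
$n = 10$ haplotypes over 10 Mb with the 2,5,10 composite scheme, plus a
pseudo-haploid comparison (10 pseudo-haploids from 20 haplotypes, 8 Mb)
against naively treating the pseudo-haploids as haploids. These are
scaled-down analogues of the full simulation study design (hundreds of
haplotypes over hundreds of Mb), sized for a single CPU.

### A note on the pseudo-haploid comparison

Because the CHMM consumes only derived-allele counts, drawing one random
allele per individual per site commutes with counting: at every site the
pseudo-haploid counts are distributed exactly as a random $n$-of-$2n$
subsample, so a "naive" fit that treats the $n$ pseudo-haploids as ordinary
haplotypes has an exactly correct per-site emission model and errs only in
the sequence correlation of the hidden chain. In the package's own checks
(2-epoch bottleneck, 6–8 Mb, one CPU) that residual misspecification is
below replicate noise, and the naive fit matches or beats the two-layer
model, whose larger $2n$ hidden machinery yields slightly noisier
estimates; both recover the epoch sizes to within a few percent. The
two-layer model is the structurally correct likelihood and is expected to
matter for many-epoch histories and for methods or regimes where phase or
within-individual information enters; the validation suite reports both
fits' $\phi$ values as computed.

## Known limitations

- At most one recombination between adjacent sites and one mutation per
  site; with high per-site rates (large $N_0\mu$) trees are inferred too
  short, biasing sizes downward.
- Folded (minor-allele) emissions are not supported; ancestral alleles
  must be known or assumed (REF-ancestral or `AA` tag).
- The branch-length hidden state is substantially slower than the TMRCA
  state (PDE solves inside every M-step evaluation) and in our checks not
  more accurate; it is provided for completeness and research use.
- Change points are fixed during EM; model selection over change-point
  placement is out of scope.
- The meta-locus acceleration assumes one hidden state per window and
  scales $\rho$ by the window size; it is exact at window size 1 and a
  documented approximation otherwise.
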