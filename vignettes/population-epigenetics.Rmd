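---
title: "Population epigenetics of methylome site frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population epigenetics of methylome site frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(epimsfs)
```

## The model

Cytosine methylation at a short locus — here a 100-bp tile — behaves like a
heritable biallelic polymorphism with unusually high mutation rates: tiles
gain methylation (forward epimutation, rate $\mu$ per tile per generation)
and lose it (backward epimutation, rate $\nu$) orders of magnitude faster
than point mutations arise. Because the rates are high, every locus is
expected to be at mutation–selection–drift equilibrium, and the population
frequency $q$ of the methylated epiallele has the Wright-type stationary
density for hypermutable loci

$$\phi(q) \;=\; C\, e^{\gamma q}\, (1-q)^{\alpha - 1}\, q^{\beta - 1},
\qquad \alpha = 4N_e\mu,\; \beta = 4N_e\nu,\; \gamma = 4N_e s ,$$

where $s$ is the selection coefficient favouring (or disfavouring) the
methylated state, $N_e$ the effective population size, and $C$ normalizes
the density on $(0,1)$. Two modelling facts drive everything downstream:

* Only the **scaled** parameters $(\alpha, \beta, \gamma)$ are identifiable
  from frequency data. $N_e$ must be assumed; fitting the same spectrum
  across a grid of $N_e$ values leaves $4N_e\mu$, $4N_e\nu$ and
  $N_e s$ invariant while the raw rates scale as $1/N_e$. `ne_grid_fit()`
  exposes exactly this check.
* The exponent assignment in the density above is kept exactly as used in
  the maize analysis this package re-implements: the gain rate scales the
  exponent on $1-q$ and the loss rate the exponent on $q$. That is at odds
  with the conventional mutation–drift notation, where the rate of mutation
  *toward* an allele scales the exponent on that allele's frequency.
  Because the intent of the original cannot be established from the
  printed equation alone, `model_params(swap_exponents = TRUE)` provides
  the conventional assignment; nothing is silently corrected. With the
  default assignment the generating values used throughout
  ($\alpha = 0.72, \beta = 0.036, \gamma = 8$) put most mass near $q = 0$
  with a second mode pushed toward $q = 1$ by selection.

The data are a **methylome site frequency spectrum (mSFS)**: across tiles,
the count $k$ of methylated epialleles among $m$ sampled ($m = 2n$ for $n$
outbred diploids). Under binomial sampling from the stationary density the
bin probabilities are

$$p_k = \int_0^1 \binom{m}{k} q^k (1-q)^{m-k}\, \phi(q)\, dq ,$$

and an observed spectrum contributes a multinomial log-likelihood
$\sum_k n_k \log p_k$. Cohorts with different $m$ are combined as a list of
spectra sharing parameters, not pooled.

## Numerical evaluation

$\phi$ is singular at both endpoints whenever $\alpha < 1$ or $\beta < 1$ —
and the interesting regime ($\beta \approx 0.04$) is deeply singular at
$q = 0$. Two complementary evaluations are implemented:

* **Gauss–Jacobi quadrature** (`normalization_constant()`,
  `expected_sfs(method = "quadrature")`): the weight
  $(1-q)^{\alpha-1} q^{\beta-1}$ is absorbed exactly into an order-128 rule
  (order 256 when $|\gamma| > 50$), leaving only the smooth factor
  $e^{\gamma q}$ — times a degree-$m$ polynomial for $p_k$ — to be
  approximated. Nodes are cached per $(\alpha, \beta)$. Tests pin this
  against a $10^6$-point brute-force grid with substitutions
  $q = t^{1/\beta}$, $1-q = t^{1/\alpha}$ that remove the singularities.
* **Confluent-hypergeometric series** (`expected_sfs(method = "series")`):
  the integrals have the closed form
  $p_k \propto \binom{m}{k} B(\beta + k, \alpha + m - k)\,
  M(\beta + k;\, \alpha + \beta + m;\, \gamma)$, with Kummer's $M$ evaluated
  by its exact power series under overflow renormalization (Kummer
  transform for $\gamma < 0$). This route needs no nodes, so its cost does
  not depend on $(\alpha, \beta)$; the sampler uses it because recomputing
  Jacobi nodes at every proposal would dominate the runtime of a
  200,000-iteration chain. Both routes agree to relative $10^{-8}$ across
  the tested parameter box, and the agreement is asserted in the suite.

Inside the likelihood, $\log p_k$ is kept at its exact finite value even
when $p_k$ underflows double precision (only a true $-\infty$ is clamped).
This matters: a chain initialized at the prior means starts at
$\gamma = 4 N_e s_{\text{init}}$, which can be in the thousands, and a
likelihood flattened by clamping leaves the sampler without a gradient to
descend — with exact log-scale values, convergence from such starts is
routine at both $N_e = 5\times10^4$ and $10^6$.

```{r density}
p <- params_from_scaled(alpha = 0.72, beta = 0.036, gamma = 8, ne = 5e4)
p
curve(exp(log_density(x, p)), 0.001, 0.999, n = 512, log = "y",
      xlab = "methylated epiallele frequency q", ylab = "density")
```

## Inference

`run_mcmc()` is a Metropolis–Hastings sampler over $(\mu, \nu, s)$ with
$N_e$ fixed:

* **Proposals**: each rate is multiplied by $e^{\lambda z}$,
  $z \sim N(0,1)$ — a log-normal random walk that keeps rates positive.
  The walk is asymmetric, so the Hastings correction
  $\sum \log(\theta'/\theta)$ enters the acceptance ratio; a regression
  test shows that omitting it collapses a prior-only chain toward zero.
  $\lambda$ defaults to 0.05, from the published grid
  $\{0.01, 0.05, 0.1\}$.
* **Priors**: independent exponentials. The published prior constants
  $10^2 \ldots 10^{10}$ are interpreted as *rates* (prior means
  $10^{-2} \ldots 10^{-10}$): the reported convergence difficulty only at
  extremely large constants is what one expects from ever-tighter priors,
  not from ever-larger prior means. Defaults: rate $10^5$ for $\mu$ and
  $\nu$ (prior mean $10^{-5}$, near the genome-wide estimates), rate
  $10^2$ for $s$. Selection is non-negative by default, matching the
  exponential prior; `prior_spec(s_support = "signed")` switches to a
  symmetric two-sided exponential with an occasional sign-flip move.
* **Chain design**: 1,000,000 iterations, first 20% discarded, thinning
  500 — retaining exactly 1600 samples, the count the original analysis
  reports per posterior summary. Thinning was derived from those three
  published facts. Chains start at the prior means and are bit-reproducible
  given a seed.

Posterior summaries report each rate and the scaled parameters
($4N_e\mu$, $4N_e\nu$, $N_e s$ computed per sample). A compact
demonstration at reduced scale (5,000 tiles, 40,000 iterations — the full
acceptance runs use 50,000 tiles and 200,000 iterations):

```{r mcmc, cache = FALSE}
q <- simulate_tile_frequencies(p, 5000, seed = 11)
k <- local({ set.seed(12); rbinom(5000, 40, q) })
spectrum <- msfs(40, tabulate(k + 1, nbins = 41))
fit <- run_mcmc(spectrum, prior_spec(),
                mcmc_config(n_iter = 4e4, thin = 25, seed = 13, ne = 5e4))
fit$summary[, c("parameter", "mean", "sd")]
```

The posterior means land near the generating values
($\mu = 3.6\times10^{-6}$, $\nu = 1.8\times10^{-7}$, $N_e s = 2$).

## From bisulfite calls to spectra

`read_cytosine_report()` reads Bismark-style per-cytosine reports and
applies the coverage filter — a site must have more than three mapped
reads, i.e. $n \ge 4$ (a strict reading of the rule). `aggregate_tiles()`
averages the per-site levels $n_{\text{meth}}/n_{\text{total}}$ of the
covered cytosines in each 100-bp tile (reference-anchored at multiples of
100); the unweighted mean is the default because the source procedure
defines only per-site levels, with read-pooling behind
`weighted = TRUE`. Tiles with fewer than `min_sites = 3` covered
cytosines are treated as missing — no per-tile minimum is stated for
calling, so a conservative small default is used. CHH tiles are refused:
the context is almost entirely unmethylated and is excluded from
population-genetic analysis. Symmetric CpG pairs are *not* merged across
strands, since no such merging is stated.

Discrete epigenotypes come from thresholding: pooled tile levels are
modelled as a normal mixture (unmethylated / heterozygous / methylated for
outbred diploids; two components for inbreds), fitted by EM
(`fit_mixture()`: quantile-spread initialization, variance floor
$10^{-4}$, convergence at a $10^{-6}$ log-likelihood gain).
`derive_thresholds()` places cutoffs at the crossings of adjacent weighted
component densities. The defaults, however, are the fixed published
cutoffs — calls of 2/1/0 at $>0.7$ / between / $<0.3$ for outbred samples
and 1/0 at 0.5 for inbreds, with strict inequalities so boundary values
fall to the middle or unmethylated class — because it cannot be
established whether the original final calls used EM-derived crossings;
the EM route is provided and tested but optional.
`cutoff_sensitivity()` quantifies what the original reported qualitatively:
on well-separated data, total-variation distance between spectra built
with cutoffs $(0.2, 0.8)$ versus $(0.3, 0.7)$ stays below 0.01.

`build_msfs()` counts methylated alleles per tile (a heterozygote
contributes exactly one methylated and one unmethylated allele). Tiles
with missing calls are dropped by default — the source is silent on
missing data — with hypergeometric projection to a common $m$ available
for sparse data. `classify_tiles()` applies the frequency categories
(invariant / $<10\%$ / 10–90% / $>90\%$ / invariant methylated);
`stratify_by_feature()` assigns tiles to genomic features by a
$\ge 50\%$-overlap rule with an explicit precedence (default
exon > intron > up5k > down5k > TE > intergenic — no precedence is stated
in the source, so one is fixed and documented); and
`polarize_by_ancestral_state()` takes the outgroup (teosinte) majority
epiallele as ancestral, excluding exact ties as ambiguous.

## The synthetic cohort generator

Real WGBS data for this design are not redistributable at package scale,
so every input is generated:

* **Frequencies** by inverse-CDF sampling of $\phi$ on a dense (order-512)
  Gauss–Jacobi grid. Draws falling below the smallest node are clamped to
  it; with $\beta \ll 1$ an appreciable fraction of *probability* mass
  lies at frequencies below $10^{-5}$, but every such frequency yields
  $k = 0$ methylated alleles in any realistic sample, so spectra are
  unaffected — the clamping is invisible downstream, which the
  goodness-of-fit acceptance check confirms.
* **Genotypes** by Hardy–Weinberg sampling, $\text{Binomial}(2, q)$ per
  diploid individual ($\text{Bernoulli}(q)$ for inbreds).
* **Tile levels** from beta distributions shaped around the class centres
  0 / 0.5 / 1. Beta noise respects the $[0,1]$ support of methylation
  levels, a deliberate divergence from the normal-mixture assumption of
  the caller; `level_noise("normal")` gives truncated-normal noise for
  strict parity. Defaults (concentrations 50/100/50, heterozygous
  sd $= 0.05$) make the mixture cleanly separable — mis-call rates below
  1% — which is the regime the published fixed cutoffs presuppose.
* **Per-cytosine reports** with evenly spaced sites per tile, negative-
  binomial depth (mean 20, dispersion 5 by default, anchoring the ~20x
  coverage of the study design) and binomial methylated counts.
* **SNPs in tunable LD** with a tile's methylation state by per-allele
  copy-with-error (copy probability $\sqrt{r^2_{\text{target}}}$), and
  interval sets in which a stated fraction of DMRs carry an overlapping
  sweep, for exercising the permutation statistics.

What the generator does *not* emulate: linkage between tiles, shared
demography across loci, non-equilibrium dynamics, context-dependent
coverage, bisulfite conversion failure, or mapping artefacts. Passing
tests therefore demonstrate that the estimator recovers the parameters of
its own generating model at realistic sizes — the standard simulation
check for this model class — not that real maize data would yield the
published point estimates.

## Interval and association statistics

`merge_outlier_windows()` reproduces the genome-scan post-processing:
windows in the upper 10% tail are merged when overlapping or book-ended
(merged regions take their maximum member score) and the upper 0.5%
quantile of window scores is then applied. By construction a quantile rule
returns about 0.5% of windows; on planted-cluster fixtures the procedure
matches an independent scan-and-merge reference exactly.

`overlap_permutation_test()` counts query intervals touching a target set
and compares against uniform length-preserving re-placement within the
mappable universe (within-chromosome by default — the more conservative
null — with a genome-wide mode available), self-overlap excluded by
rejection. Empirical p-values use the add-one rule, so the minimum is
$1/(n_{\text{perm}}+1)$ and $p = 0$ is unattainable; 999 permutations by
default, consistent with the smallest reported p of 0.001.

`dmr_snp_ld_test()` operationalizes "significant correlation" as squared
Pearson correlation between SNP genotype and DMR state (the statistic is
not named in the source), with a permutation null sharing one permutation
stream across the SNPs of a DMR so their p-values are comparable, and the
published decision rule: at least three SNPs at $p < 0.01$ declare the DMR
in LD. No multiple-testing correction is applied inside the rule — the
$\ge 3$ requirement *is* the decision device. `candidate_enrichment()` is
the standard upper-tail hypergeometric test.

## Problem sizes and runtime choices

The simulation studies in the test-suite use 50,000 tiles and $m = 40$ at
200,000 iterations (thinning 100) for the headline recovery checks — at
these sizes posterior means land within a few percent of the generating
values — and reduced sizes (2,000–20,000 tiles, 20,000–60,000 iterations)
for property checks, chosen so the whole suite completes in minutes while
leaving wide margins to the tolerances. Calibration checks use 500 null
replicates at 99 permutations, making nominal 5% rejection exactly
attainable. The acceptance script fits three full chains; the published
full-length chain design (10^6 iterations) is exercised in prior-only
mode, where it retains exactly its 1600 samples.

## Known limitations

* $N_e$ is never estimated; all conclusions about raw rates inherit the
  assumed $N_e$ linearly, which is precisely why scaled parameters are the
  primary output.
* The multinomial SFS likelihood treats tiles as independent; linkage
  between nearby tiles would shrink the effective number of independent
  loci and make credible intervals anti-conservative on real data.
* The exponent-assignment ambiguity above cannot be resolved from the
  printed material; both variants are available and clearly labelled.
* EM-derived thresholds fall back to the fixed cutoffs when component
  crossings do not exist inside $(0,1)$ (e.g. extreme weight imbalance);
  a warning reports the fallback.
* The permutation null for interval overlap re-places intervals
  independently; spatial clustering of real genomic features is only
  captured insofar as the mappable universe excludes unassayable space.
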