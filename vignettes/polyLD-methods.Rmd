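---
title: "Models and methods behind polyLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyLD)
```

# The data model: collapsed three-class genotypes

`polyLD` analyses biallelic SNP genotypes from panels mixing diploid and
autotetraploid individuals. Array scoring of autotetraploids can in
principle distinguish five dosage classes (AAAA, AAAB, AABB, ABBB, BBBB),
but reliable five-cluster calling is rare in practice, and mixed panels
are routinely scored with three classes in which every heterozygous
dosage becomes a single AB call. That collapse is the founding assumption
of this package: a `genotype_panel` stores only AA / AB / BB / missing,
and the collapse is applied at ingest (`read_panel_vcf()` maps any mixed
tetraploid GT to AB). Dosage is unobservable downstream by construction;
no function in the package may depend on it.

Two consequences of the collapse run through everything else:

- **Allele frequencies are biased toward 0.5 in tetraploids.**
  `allele_freqs()` counts every sample as diploid-equivalent
  (freq A = (2 n~AA~ + n~AB~) / (2 n~called~)). For a tetraploid at
  Hardy–Weinberg frequency p the expected diploid-equivalent estimate is
  not p; heterozygous-dosage samples all contribute a single allele each
  way. We keep this convention deliberately — it is what three-class
  scoring implies, and what any downstream tool fed such calls would do —
  and document rather than correct the bias.
- **Heterozygosity is much higher in tetraploids.** The probability of a
  heterozygous call at frequency p is 1 − p² − q² for diploids but
  1 − p⁴ − q⁴ when four alleles are collapsed; at p = 0.5 that is 50%
  versus 87.5%. The test suite checks both closed forms by simulation.

Coordinates are 1-based bp on a reference genome (VCF convention); pair
distances are |pos~i~ − pos~j~| within a chromosome, inter-chromosome
distances are undefined, and SNPs without coordinates are excluded from
LD with a logged count.

# Synthetic data: what the generators emulate

The original genotype matrices such analyses are run on are typically not
redistributable, so the package carries two generators that make every
stage verifiable against known truth.

**Wright–Fisher forward simulation** (`simulate_wf()`). A pool of
2 n~e~ haplotypes evolves for a configured number of generations; each
offspring haplotype recombines two uniformly drawn parents with an
independent Bernoulli(c~k~) crossover per adjacent-locus interval
(c~k~ = `rec_rate` × interval length; no interference, no mutation, no
migration after the split). Founders are drawn in linkage equilibrium
with allele frequencies from a uniform law (default U(0.1, 0.9),
mimicking an ascertained array MAF spectrum). After `split_generation`
the pool is copied into K pools that drift independently — the structure
signal. Run for about 4 n~e~ generations and beyond, within-pool LD
approaches the drift–recombination equilibrium
E(r²) ≈ 1/(1 + 4 n~e~ c) + 1/(2 n~e~), which is exactly the regime the
decay-fitting module assumes; the equilibrium is verified in the test
suite (20 seeds, n~e~ = 100, 400 generations, 200 loci, binned
recombination fractions 10⁻⁴–10⁻², ±30% per bin). Truth r² for oracle
tests is computed from the phased pool (`pool_ld_pairs()`), not from
sampled genotypes, separating sampling noise from estimator error.
`sample_panel()` then draws `ploidy` haplotypes per sample with
replacement, collapses to three classes, and injects i.i.d. missingness
(default 1%, matching the mostly-sub-1% missingness of real array
panels). One master seed drives a documented splittable stream (offsets
0 / 10⁶ / 2×10⁶ for simulation, sampling, missingness), so fixtures are
byte-reproducible stage by stage.

**Balding–Nichols panels** (`balding_nichols_panel()`). For clustering
tests linkage is a nuisance, so this generator draws each
subpopulation's allele frequency from Beta(p(1−F)/F, (1−p)(1−F)/F)
around an ancestral p (across-population variance p(1−p)F), samples
genotypes binomially at the configured ploidy, and assigns every locus
its own chromosome so no LD pair can be formed.

What the generators do *not* emulate: mutation, selection, migration,
ascertainment of SNPs on a discovery panel, genotype-calling error, and
within-cultivar family structure beyond what finite-pool sampling
induces. Passing tests therefore demonstrate correctness of the
estimators under the stated models, not robustness to every artefact of
real array data.

# Preprocessing

Each SNP contributes two presence/absence columns (AA → (1,0),
AB → (1,1), BB → (0,1)); missing calls leave both columns missing until
`impute_mean()` replaces them by the marker's mean across individuals.
Mean imputation preserves column means and is the standard minimal
choice ahead of PCA; it shrinks missing samples toward the centroid and
so, at the 0–10% missingness this package targets, biases structure
conservatively. An all-missing marker is an error naming the SNP rather
than a silent drop.

The MAF filter removes SNPs whose minor allele frequency is *strictly
below* the threshold (default 5%) — a SNP at exactly 5% is retained —
and is computed within the group being analysed, not panel-wide, because
LD is estimated per cluster and a SNP common in one cluster may be rare
in another. `maf_filter(group = ...)` exposes the choice.

# Structure

PCA is the covariance (unscaled) eigendecomposition of the
column-centred encoded matrix, the `prcomp()` default. Component signs
are fixed by making each loading vector's largest-magnitude entry
positive, so results are reproducible across BLAS implementations. Five
PCs feed clustering by default — the classic scree-based choice for
array panels of a few hundred samples — exposed as `n_pcs`.

`fit_gmm_bic()` fits Gaussian mixtures by EM for every K in the search
range crossed with three covariance models (spherical, diagonal, full —
a tractable subset of the mclust family that spans the selection
behaviour that matters here), each initialized from a fixed-seed k-means
partition, and selects the fit maximizing BIC = 2 logL − m log n (the
mclust orientation, m the free-parameter count). Numerical choices: EM
stops at a relative log-likelihood change of 10⁻⁸ or 500 iterations
(best iterate returned with a warning); covariances are
ridge-regularized on the diagonal (10⁻⁶ of the mean data variance) when
singular; hard labels are maximum posterior. The per-iteration
log-likelihood trace is retained and its monotonicity — the defining EM
property — is asserted in the tests; model selection is cross-checked
against `mclust` on a clear three-cluster dataset.

Nei's (1972) standard distance is computed in the GenAlex convention:
J~XY~ = Σ~loci~ Σ~alleles~ x y, J~X~ = Σ x², J~Y~ = Σ y², summed across
loci *before* the ratio, D = −ln(J~XY~/√(J~X~ J~Y~)). A consequence
worth knowing: adding loci monomorphic for the same allele in both
populations adds equal mass to all three sums and pulls D toward zero.
That is the documented behaviour of this estimator, not a defect, and a
test pins it down. Complete divergence (J~XY~ = 0) yields +Inf with a
log message.

Neighbor joining uses the Saitou–Nei agglomeration (via `ape::nj`),
which is exact on additive matrices; the rare negative branch-length
estimates on non-additive input are clamped to zero with the deficit
moved to an adjacent edge at the same node, keeping path lengths between
the affected neighbours and making the emitted Newick printable.

# Linkage disequilibrium

**r² between unphased loci.** Under the collapsed coding every sample is
treated as diploid-equivalent and the two-locus haplotype frequencies
(p~AB~, p~Ab~, p~aB~, p~ab~) are estimated by EM: all genotype
configurations except the double heterozygote determine their haplotypes,
and double heterozygotes are split between coupling and repulsion by the
posterior under the current estimate. The EM starts from linkage
equilibrium, runs to 10⁻¹⁰ on the frequencies (cap 1000 iterations), and
returns r² = D²/(p~A~ p~a~ p~B~ p~b~). With no double heterozygotes the
fixed point equals phased counting (tested); against a brute-force
coarse-to-fine likelihood grid over the haplotype simplex the EM agrees
to better than 10⁻³ on random datasets (tested, 100 datasets). Missing
data are deleted pairwise per SNP pair, maximizing the per-pair n as LD
software conventionally does. Feeding collapsed tetraploid calls to a
diploid estimator understates true gametic LD; we reproduce that
convention deliberately, since it is how three-class mixed panels are
analysed in practice.

**Decay fitting.** `ld_decay_fit()` regresses observed r² on physical
distance d by nonlinear least squares under either the
drift–recombination-equilibrium expectation E(r²) = 1/(1+C), C = 4ad
(variant `sved`), or the low-mutation finite-sample form
E(r²) = [(10+C)/((2+C)(11+C))]·[1 + ((3+C)(12+12C+C²))/(n(2+C)(11+C))]
(variant `hill_weir_n`, n the gamete count). Pairs enter unbinned — one
residual per pair — because binning destroys information and the
appropriate bin width is arbitrary; `bin_ld_pairs()` provides geometric
bins for plotting only. The single parameter a is initialized from the
sved closed form through the median observation, optimized by
Levenberg–Marquardt with a Brent fallback, and polished by damped
Gauss–Newton to a relative tolerance of 10⁻¹² — on noiseless data the
generator coefficient is recovered to machine accuracy. The decay
distance at a target t is d = (1/t − 1)/(4a) for sved and a `uniroot`
solve for the finite-sample curve (which starts below 1 at d = 0, so
targets above its intercept are reported as no-crossing). A fit is
rejected if a ≤ 0 at the optimum.

**Cross-population consistency.** `ld_consistency()` correlates the r²
values of SNP pairs present in both populations' tables within distance
windows (defaults 0.1, 0.2, 1.0 Mbp), reporting r_LD and the pair count
per window; Pearson is the default with a Spearman flag, since the
correlation type behind published r_LD values is usually unstated.
Identical inputs give r_LD = 1, independent permutations give
|r_LD| < 3/√n, and in a two-population Wright–Fisher split r_LD falls
with divergence time — all asserted in the tests.

# Orchestration and reproducibility

`pipeline_simulate()` and `pipeline_analyze()` run the stages from a
flat key = value configuration (diff-able provenance, echoed verbatim
into each output directory), write every numeric result as TSV, and log
seeds and the input/output counts of every filter. The `exec/polyld`
script exposes the same flow as shell subcommands. A run is reproducible
from the config echo plus the seed alone.

# Problem sizes

The routine test suite and the acceptance script are sized for a single
CPU: the equilibrium check uses 20 Wright–Fisher replicates of 200
haplotypes × 200 loci × 400 generations; structure recovery uses 20
Balding–Nichols panels of 90 samples × 1000 loci; the EM–oracle
comparison uses 100 datasets of 200 samples; the demo panel is 75
samples × 150 loci. These sizes were chosen so each check's sampling
error is well inside its assertion tolerance while the whole suite runs
in a couple of minutes; all of them scale up linearly if heavier
verification is wanted.

# Known limitations

- Collapsed tetraploid calls understate allele-frequency spread and
  gametic LD; none of the estimators attempt dosage-aware corrections.
- The Wright–Fisher generator has no mutation, so very long runs lose
  polymorphism; configurations beyond ~4 n~e~ generations trade realism
  of the MAF spectrum for closeness to LD equilibrium.
- The GMM covariance family is the three-model subset; mclust's shared
  shape/orientation variants are out of scope.
- Nei distances of +Inf (complete divergence) cannot enter
  neighbor-joining; the tree builder requires finite matrices.
- The finite-sample decay expectation implemented is the standard
  Hill–Weir (1988) form; published analyses sometimes display minor
  typographic variants of it.
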