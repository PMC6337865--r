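---
title: "Evaluating whole-genome sequence imputation with wgsimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating whole-genome sequence imputation with wgsimpute}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package does

`wgsimpute` evaluates how well genotypes can be imputed from SNP-array
density up to whole-genome sequence (WGS) density in a structured,
multi-breed population, and how the quality of that imputation propagates
into downstream genomic prediction. Because deep multi-breed sequence
panels are rarely shareable, the package is driven entirely by a seeded
synthetic-population generator: every claim the test suite makes is a
property of the method that can be recomputed from scratch on any machine.

The pipeline is the classic masking design. Sequenced individuals are split
into five folds; in each fold the held-out 20% have their genotypes masked
down to the positions of a SNP array, are imputed back to full sequence
density from the remaining 80% (plus any other breeds) acting as the
reference panel, and the imputed values are compared with the masked truth.

## The haplotype-copying model

Imputation uses the Li–Stephens haplotype-copying hidden Markov model. A
target haplotype is modelled as an imperfect mosaic of the `H` reference
haplotypes: the hidden state at variant `j` is the reference haplotype
being copied; between adjacent variants at map distance `d` Morgans the
chain stays on its haplotype with probability `exp(-lambda*d) +
(1 - exp(-lambda*d))/H` and switches to each specific other haplotype with
probability `(1 - exp(-lambda*d))/H`; typed (array) positions emit the
observed allele with probability `1 - epsilon` on match and `epsilon` on
mismatch, and untyped positions are uninformative. Posterior copying
probabilities come from a scaled forward–backward pass (per-site
normalisation, so chromosomes of 10^4+ variants run without underflow;
independent chromosomes are joined with a switch probability of 1). The
posterior allele dosage of a haplotype at a variant is the
posterior-weighted mean of the reference alleles; a diploid individual's
genotype dosage is the sum over its two haplotypes, and the most-likely
genotype is that dosage rounded half-to-even and clamped to {0, 1, 2} — a
single declared rounding rule rather than a per-genotype argmax, because it
is easy to state and to test.

Untyped sites sit in the HMM lattice with uniform emissions. Production
imputation engines instead run the HMM on the typed grid and interpolate
state probabilities into the gaps; the two formulations agree in the limit
of dense typed sites and the lattice form is directly checkable against
exhaustive hidden-path enumeration, which the test suite does to 1e-10 on
small instances.

Defaults: `error_rate = 1e-3` (allele mismatch; absorbs genotyping error
and mutation), `switch_scale = 100` expected switches per Morgan and
`cm_per_mb = 1`, so the expected number of copying switches is about one
per Mb — a scale at which a few-hundred-haplotype reference panel neither
freezes onto a single haplotype nor diffuses to the panel frequency. All
three are exposed through `hmm_params()`.

## The dosage R² quality statistic

For each variant the package reports the Minimac-style quality statistic:
with haplotype dosages `d_1..d_{2N}` and estimated allele frequency
`p = mean(d)`,

    rsq = PopVar(d) / (p * (1 - p)),

where `PopVar` divides by the haplotype count. Fully shrunk dosages (all
equal) give 0; fully confident 0/1 dosages give 1. The raw value can
marginally exceed 1 and is retained; clamping to [0, 1] is applied only for
binning and reporting. When cross-validation folds are pooled, one R² per
variant is recomputed from the pooled haplotype dosages of all folds
(production tools report it per run; pooling keeps the statistic aligned
with the pooled empirical accuracy it is compared against).

Empirical accuracy is the Pearson correlation between imputed values
(dosages, or most-likely genotypes) and the true genotypes across all
held-out individuals, pooled over folds, per variant. Typed positions and
variants that are monomorphic on either side are flagged and counted, never
silently dropped, so every summary reconciles exactly with the variant
total. Threshold policies follow the usual naming: `thr4` retains variants
with R² strictly above 0.4, `thr8` above 0.8, `thr0-4` the complement
(R² ≤ 0.4), `thr0` everything.

## The synthetic population generator

The generator produces phased multi-breed panels with the statistical
structure the evaluation needs, not a demographic reconstruction:

* **Ancestral pool.** `n_ancestral_haps` haplotypes with independent sites
  whose derived-allele frequencies follow a `1/f`-type spectrum
  (`spectrum_skew = 1`), so the realised site-frequency spectrum is
  strongly rare-skewed (more than 40% of variants below 5% MAF, as in
  sequence data).
* **Breeds.** Each breed draws a founder bottleneck from the pool and then
  descends for `n_gen` generations at population size `ne_haps`. The
  descent is simulated in condensed form: founder-lineage proportions
  undergo generation-by-generation Wright–Fisher drift (so breeds diverge,
  with Hudson Fst increasing in `n_gen`), and each present-day haplotype is
  drawn as a founder mosaic whose recombination-breakpoint intensity is the
  per-meiosis rate accumulated over the `n_gen` generations. This is
  equivalent in LD phenomenology to an explicit generation loop but runs in
  `O(ne * M)` rather than `O(ne * n_gen * M)`.
* **Crossbreds** take one haplotype from each parent breed (F1).
* **Arrays** are ascertained with a MAF floor and a `uniform_maf` scheme
  that balances selection across MAF deciles, flattening the array spectrum
  relative to sequence exactly as commercial chips are; nested LD ⊂ 50k ⊂
  HD hierarchies are built densest-first so the subset relation is exact.
* **Annotation classes** are simulated labels (63% intergenic, 30%
  intronic, 6.4% up/downstream, 0.3% missense, 0.3% UTR by default), with
  class-specific rare-allele enrichment induced by weighted sampling
  (weight `exp(-bias * maf)`), so missense variants end up with the largest
  low-MAF share. The labels carry no functional meaning.
* **Low-fidelity regions** emulate segmental-duplication/misassembly
  regions: within a window, variant density is multiplied (new variants get
  random haplotype assignments, i.e. no LD) and existing alleles are
  flipped at a chosen error rate, which degrades local haplotype sharing
  and produces the poorly imputed windows and the low-R² variant stratum.
* **Phenotypes** are `y = TBV + e` with a chosen number of causal variants;
  the residual is orthogonalised against the TBV and variance-matched so
  the realised heritability equals the target exactly, which makes
  heritability-recovery tests sharp.

### Default study conditions

The default `sim_config()` describes a desk-scale genome standing in for a
whole-genome multi-breed reference: 2 chromosomes × 20 Mb, 52,000 variants,
an ancestral pool of 320 haplotypes, and 160 individuals — a large main
breed (80, founder bottleneck 240 haplotypes), two satellite breeds (30 and
25, bottleneck 100), and 25 F1 crossbreds — each breed with 100 divergence
generations at `ne = 6 ×` its founder count; recombination at 1.2e-8 per bp
per meiosis; arrays of 250 / 800 / 2,000 SNPs (LD/50k/HD). Under these
conditions the fivefold HD→WGS evaluation scores roughly 23,000 variants
and lands where real multi-breed sheep panels do: dosage accuracy ≈ 0.95,
hard-call accuracy ≈ 0.94, and a near-perfect rank relationship between
R²-bin and bin-mean accuracy. These sizes were chosen once as the package's
reference conditions; every dimension scales up or down through the config.

### What the generator does not emulate

Sites in the ancestral pool are independent, so long-range LD exists only
through the founder mosaic structure; there is no mutation after the
ancestral pool, no gene conversion, no selection and no phasing error
(targets are generated and kept phased, treating pre-phasing as solved
preprocessing). Two desk-scale consequences matter when reading results.
First, with ~300 reference haplotypes the MAC ≥ 5 reference filter sits at
MAF ≈ 1.7%, so the very-rare, very-poorly-imputed tail that dominates
genome-scale low-R² mass is thin here; the poorly imputed stratum used in
the prediction experiment is therefore generated by injected low-fidelity
regions rather than by rare variants alone. Second, accuracy differences
between MAF bands are a few 0.001 rather than a few 0.01, so band-ordering
checks operate close to their noise floor.

## Cross-validation bookkeeping

`make_fold_plan()` partitions individuals into folds differing by at most
one in size. Each fold's reference is MAC-filtered (MAC ≥ 5) after removing
the held-out targets; array positions are exempt from that filter because
the array scaffold must remain in the imputation scope even if rare in a
reduced reference. Results are pooled on the variant scope shared by all
folds' filtered references. Windows are half-open 1-Mb bins; R² bins are
100 half-open bins of width 0.01 with the last closed at 1; the default
MAF-band ladder is the contiguous 0.01–0.02 … 0.08–0.10, 0.10–0.50
(`maf_bands_preset("printed")` reproduces the conventional published
ladder, which skips 0.04–0.05 and lists both 0.06–0.07 and 0.06–0.08).
Per-chromosome and per-window means weight variants equally.

## BayesR and the R²-stratified prediction experiment

`bayesr()` fits the four-component mixture model by single-site Gibbs
sampling: each variant effect is null or normal with variance 1e-4, 1e-3 or
1e-2 times the genetic variance `sigma_g^2`; mixing proportions get a flat
Dirichlet(1,1,1,1) prior updated from class counts; both variances get
scaled inverse chi-square priors (df 4, scale half the phenotypic variance)
and are sampled — `sigma_g^2` from the class-scaled sum of squared effects,
`sigma_e^2` from the residuals. Genotype dosages are centred by
training-set column means and not standardised, keeping effects on the
allele-count scale the mixture variances presume. The per-iteration genomic
heritability is `Var(X beta) / Var(y)` on the training individuals —  the
proportion of phenotypic variance explained by the fitted variant set — and
posterior summaries use post-burn-in draws only. The desk schedule is
4,000 iterations with 2,000 burn-in; `bayesr_config(preset = "full")`
switches to the full 40,000/20,000 with five chains.

Two behaviours of this (fully declared) model are worth knowing. With
mixing proportions pinned to a single nonzero component and fixed
variances, the posterior mean collapses to the ridge-regression solution,
which the tests verify against the closed form. And the mixture's Occam
penalty scales with the training size, so with only a few hundred training
individuals and more variants than records a pure-noise phenotype retains a
visible noise floor (posterior h² around 0.2 at n = 300, m = 500, confirmed
with an independent re-implementation); from about a thousand records the
null collapses as expected (h² < 0.05). Heritability comparisons should
therefore be made between strata at equal n, as the stratified experiment
does, rather than read as absolute calibration at small n.

The stratified experiment mirrors the standard design: within each quality
stratum (`thr0-4`, `thr4`, `thr8`) it draws allele-frequency-matched
variant sets (fixed per-AF-bin quotas from the pool histogram, so the
per-bin counts are identical across sets by construction; sets are disjoint
whenever the pool allows and any forced overlap is reported), fits several
chains per set on training individuals disjoint from the targets, averages
h² and GEBV accuracy over chains within sets, and reports per-stratum means
with the standard error over sets (`sd / sqrt(n_sets)`). Prediction
accuracy is `cor(GEBV, y_adj) / sqrt(h2)`; by default the h² in the
denominator is the mean posterior genomic heritability across the run's
analyses, mirroring the use of a single trait-level estimate, and can be
supplied explicitly.

## Problem sizes used by the test and acceptance runs

The package's own evaluation runs at the default conditions above for the
fivefold accuracy analyses, ~9,000-variant single-chromosome populations
for the paired stepwise-vs-direct and multi-breed-vs-single-breed
comparisons (3 seeds each), ten ~5,000-variant runs for the low-fidelity
region analysis, n = 1,000 × m = 2,000 for heritability recovery, and a
120-individual, 8,000-variant population with two injected low-fidelity
regions for the stratified prediction experiment. These sizes were chosen
so the full suite reruns comfortably on a laptop core while keeping each
check's statistic well inside its decision margin.

## Known limitations

* The generator's difficulty is governed by the ratio of local haplotype
  diversity (ancestral pool and founder counts) to reference size and by
  array SNPs per founder segment; it emulates the phenomenology of
  imputation accuracy, not any particular genome's LD map.
* Phasing error is not modelled; accuracies are conditional on correct
  phase.
* The R² statistic is computed from haplotype-level dosages; engines that
  define it from genotype dosages differ by at most the within-individual
  dosage covariance, which is negligible at the panel sizes used here.
* BayesR heritability at small n (a few hundred) carries the noise floor
  described above.
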