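---
title: "Methods: cross-dataset cis-QTL mapping, fine mapping and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset cis-QTL mapping, fine mapping and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlcompendium)
```

## Scope and design

`qtlcompendium` implements a uniform multi-dataset cis-eQTL analysis as a
sequence of testable stages: synthetic-data generation, genotype and
expression QC/normalization, nominal cis association with permutation-based
empirical p-values, single-effect Bayesian fine mapping, cross-dataset
harmonization of independent signals, effect-size sharing with non-metric
MDS, and approximate-Bayes-factor (ABF) colocalization summarized over LD
blocks. Individual-level human eQTL data are controlled-access, so the
package is organized around a generator with known ground truth: every
downstream claim made by the test suite is a recovery statement about
planted structure, and the numbered scripts under `analysis/` narrate one
complete synthetic study.

## The synthetic-data generator

**Genotypes.** Haplotypes follow a first-order Markov copying process: the
allele at variant $j$ copies variant $j-1$ with probability $\rho$ and is
otherwise drawn fresh as Bernoulli(MAF). With equal adjacent MAFs the
adjacent-haplotype correlation is exactly $\rho$, giving a closed-form LD
target with none of the machinery of coalescent simulators. Dosages are the
sum of two independent haplotypes, hence hard calls in $\{0,1,2\}$. This is
sufficient for fine-mapping and colocalization tests, where what matters is
a tunable correlation ladder around the causal variant; it does not model
recombination hotspots, demography, admixture or imputation error, so
conclusions about those features of real data are out of reach by design.

**Expression.** A trait is `beta * dosage + loadings * covariates + noise`
with Gaussian noise (default sd 1, the scale of an inverse-normal-transformed
trait). Effect sizes for planted cis-QTLs default to sd 0.6 in the worked
study — with $n = 150$ per dataset that yields power around 0.5 at
FDR 0.05, deliberately in the regime where permutation calibration matters.

**Cross-dataset sharing.** The literature's sharing models (multivariate
shrinkage, matrix factorization) are descriptive, not generative, so the
generator uses an explicit stand-in: each signal belongs to one dataset
group and is, with probability $f$, active with an *identical* effect in
every group member, otherwise private to one member. Inactive entries are
explicit `NA`s; the zero-substitution convention is applied only by
`build_effect_matrix()`/`as_effect_matrix()`, mirroring the analysis
pipeline rather than the truth. Note a denominator subtlety: the pairwise
sharing estimator divides by signals measured in *at least one* of the two
datasets, so for groups of size two the within-group estimate is unbiased
for $f$, while for larger groups private signals in *other* members drop
out of the denominator and the estimate exceeds $f$
($f / (f + 2(1-f)/s)$ for group size $s$). Recovery checks therefore use
groups of two; the MDS separation check uses three groups of four, where
only the contrast between within- and between-group sharing matters.

**Seeds.** All randomness flows from one integer master seed through a
counter-based split (`split_seed()`), so each stage and replicate can be
regenerated independently; identical seeds give byte-identical output.

## QC and normalization choices

* Variant filters use the conventional thresholds (Hardy–Weinberg
  $p < 10^{-6}$ by the asymptotic 1-df chi-square test, missingness
  $> 0.05$, MAF $< 0.01$ pre-imputation; MAF $< 0.01$ or imputation
  $R^2 < 0.4$ post-imputation). All are strict inequalities; boundary
  values are retained. The exact HWE test would be preferable at small
  counts but the pipeline's filter only needs the far tail.
* LD pruning is the greedy windowed scan (window 50,000 variants, step
  200, $r^2 > 0.05$ drops the later variant), matching PLINK's
  `--indep-pairwise` semantics and verified against a brute-force greedy
  oracle.
* Superpopulation assignment computes, over the first three genotype PCs,
  the mean Euclidean distance from a sample to each labeled reference
  cluster, and assigns the closest label only when the second-closest
  distance is at least 1.7 times larger (inclusive at exactly 1.7; a
  single-population panel assigns unconditionally, treating the ratio as
  infinite). At cluster separation of ten within-cluster standard
  deviations roughly one call per thousand falls inside the ratio margin;
  the "every call correct" regime used for validation is separation
  twenty.
* Expression: TPM columns sum to $10^6$ by construction; traits with TPM
  below 1 in at least 95% of samples (inclusive) are dropped; median
  profiles for dataset similarity drop genes with median TPM below 1 and
  use $\log_2(x+1)$ (pseudocount 1 chosen for the zero-heavy TPM scale).
  Usage ratios divide each transcript/event by its group total, with a
  zero group total producing missing usages. The inverse normal transform
  maps averaged ranks through $\Phi^{-1}((r - 0.5)/n)$; the Blom constant
  (3/8) would change values by well under the noise scale and is not
  offered. Sex inference thresholds (`xist_cut`, `y_cut`, both 1) are
  configuration, since the reference procedure is a visual call.

## Association testing and permutations

The nominal scan is per-variant OLS of trait on dosage with an intercept
and covariates (six genotype plus six phenotype PCs in the full design),
computed via Frisch–Waugh residualization so a whole cis window
($\pm$1 Mb, inclusive, anchored at the gene start) is one matrix
operation. Traits with fewer than five cis variants or zero variance are
skipped with machine-readable reasons.

Empirical p-values use direct permutation counting rather than a fitted
tail approximation: the group statistic is the minimum nominal p over all
variants and all traits of a gene, sample labels of the trait matrix are
permuted jointly (preserving cross-trait correlation — the "group-best"
scheme), and $p_{emp} = (1 + \#\{p^{perm}_{min} \le p^{obs}_{min}\}) /
(B + 1)$ with $B = 1000$ by default. Permuting phenotypes rather than
genotypes is a documented choice; under exchangeability they are
equivalent. Gene-level discovery applies Benjamini–Hochberg to the
empirical p-values. Calibration is checked on 1000 null genes
($n = 200$, 50 variants, 200 permutations): the empirical p-values must
pass a KS uniformity test at $p > 0.01$ with a sub-0.05 fraction in
$[0.03, 0.07]$.

## Fine mapping

Fine mapping is a single-effect ABF model: per-variant Wakefield log
Bayes factors
$\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 z^2 r$,
$r = W^2/(se^2+W^2)$, with prior effect sd $W = 0.15$ on the INT scale;
posterior inclusion probabilities are the softmax of the log-ABFs under a
uniform prior over a single causal variant, and the 95% credible set is
the smallest PIP-ranked prefix reaching 0.95 (ties broken by position,
then alleles). Inputs are covariate-residualized traits and genotypes.
This deliberately replaces multi-effect models: the downstream
harmonization consumes only credible sets with PIPs, and a single-effect
model is exactly calibrated on single-causal simulations (coverage
$\ge 0.93$ at $n = 500$, 200 variants, $\rho = 0.9$, 5% variance
explained — measured ~0.99). Regions with several independent causal
variants will yield one blended set; that is the main known limitation
and the reason multi-signal simulations are not part of the validation
claims.

## Harmonizing independent signals across datasets

Credible sets are filtered to size < 30 and maximal univariate $|z| > 3$
(both strict); a set associated with $k$ genes becomes $k$ records. Per
gene, sets from different datasets sharing at least one variant join the
same connected component (union–find; verified against an $O(n^2)$
transitive-closure oracle on random instances). Within a component the
candidate variants are those contained in member sets of the largest
number of datasets, and the lead is the candidate with the largest
$|\beta|$ across datasets — reading "largest effect" as largest absolute
effect, since signs are arbitrary across datasets — with position/allele
tie-breaks added for determinism. Components whose candidates have no
measured effect anywhere are dropped with a reason and counted; components
supported by a single dataset are retained and flagged via their support
count. The transcript-level path (exon/transcript/event traits are highly
correlated within a gene) instead takes the smallest per-dataset set (tie:
largest member PIP), draws one set per gene at random under the master
seed, and applies the same lead rule; with a single selected set the
dataset-support restriction is vacuous, so the lead is effectively the
largest $|\beta|$ member.

The effect matrix has lead variants as rows and datasets as columns;
entries missing from a dataset's summary statistics become $\beta = 0$,
$se = 1$, with the missingness mask kept so sharing denominators can be
policy-controlled ("measured in at least one" by default, "both"
selectable).

## Sharing and MDS

Two effects are shared when they have the same non-zero sign and their
magnitudes differ by at most a factor of two (inclusive); substituted
zeros are never shared. Dataset similarity uses $1 - r$ distances
(Pearson for expression profiles, Spearman for effect columns). The 2-D
embedding is Kruskal non-metric MDS minimizing stress-1, with isotonic
regression of embedded distances on dissimilarity ranks
(pool-adjacent-violators via `isoreg`; primary tie treatment) alternating
with Guttman-transform updates from a classical-scaling start. Iterations
are accepted only while stress decreases (tolerance $10^{-9}$, cap 500),
so the reported trace is non-increasing by construction; the all-zero
distance matrix returns the zero embedding with zero stress rather than
erroring. On three planted groups of four datasets the embedding reaches
stress $< 10^{-3}$ with silhouette $\approx 1$ on the true labels.

## Colocalization

`coloc_abf()` matches variants on chromosome and position, flips the
second trait's $\beta$ when ref/alt are swapped, and drops
strand-palindromic (A/T, C/G) variants at MAF > 0.4 — the standard
conservative treatment where strand cannot be resolved. Hypothesis
weights follow the ABF decomposition (priors fixed at the conventional
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, configurable), all sums in log
space, with the two-distinct-variants term computed exactly as the
off-diagonal log-sum-exp of the pairwise log-ABF matrix so that a single
dominant shared variant cannot cancel catastrophically. GWAS prior sd is
0.15 for quantitative and 0.2 (log-odds) for binary traits. Posteriors
match a brute-force enumeration over causal configurations to $10^{-10}$
on regions of up to ten variants.

Strong colocalizations ($PP_4 \ge 0.8$, inclusive) are summarized over
approximately independent LD blocks (BED convention: 0-based, half-open;
1-based lead positions converted explicitly; a window spanning several
blocks is assigned by its lead). Non-reference datasets below $n = 150$
are excluded, a block is novel when no reference dataset colocalizes in
it, and the novelty score divides a dataset's novel blocks by its sample
size. Method-overlap counting buckets blocks by the subset of
quantification methods detecting them, with "transcript-level only"
meaning no gene-level support; for transcript-level methods the analysis
is restricted to significant lead QTLs at group-level FDR < 0.01,
matching the group-best permutation scheme.

### Recovery at the reference study conditions

The validation conditions for mode recovery are $n = 500$ per cohort, 200
variants, $\rho = 0.9$, causal variant explaining 5% of variance — i.e. a
causal z-score around $\sqrt{500 \cdot 0.05/0.95} \approx 5.1$. Null
regions are called correctly ($PP_0 > 0.9$) in ~98% of replicates and the
posterior arithmetic is oracle-exact, but confident mode recovery is
prior-limited at this signal strength: with
$\log \sum ABF \approx 10$ per trait, the two-distinct-variants weight
$\log(p_1 p_2) + 2\log\sum ABF$ sits near the single-trait weights, so
the median $PP_3$ in distinct-mode replicates is ~0.5 and the
$PP_3 > 0.8$ rate is ~0.2–0.35; shared-mode $PP_4 > 0.8$ is reached in
~0.7–0.9 of replicates. At 8% variance explained ($z \approx 6.6$) all
three modes are recovered confidently (the regime the unit tests assert).
These rates are reported as measured; neither the simulation conditions
nor the thresholds were adjusted to them.

## Problem sizes

The shipped validation uses: 100 oracle regions of up to 10 variants; 50
replicates per colocalization mode; 200 fine-mapping replicates; 1000
null genes with 200 permutations; 200 connected-component instances of up
to 50 sets; 2000 signals per sharing fraction; 12 datasets in the MDS
panel; 1000 reference-panel test samples. These sizes keep the whole
suite around half a minute on one core while leaving binomial error well
inside the asserted tolerances; the worked study in `analysis/` (4
datasets, 40 genes, 150 samples) is sized the same way.

## Known limitations

* Single-effect fine mapping blends multi-signal regions into one set.
* The LD model has no long-range structure, so "distinct" causal pairs
  are easy to separate once their $r^2$ bound holds; real loci with
  extended haplotypes are harder.
* The sharing generator is a stand-in with binary activity and identical
  within-group effects; it cannot emulate graded tissue hierarchies.
* GC-content (conditional quantile) normalization of counts is replaced
  by TPM plus the inverse normal transform; conclusions about
  GC-sensitive quantification differences are out of scope.
* No genotype phasing/imputation, liftover, read alignment or
  quantification: the pipeline starts from dosage and count/TPM matrices.
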