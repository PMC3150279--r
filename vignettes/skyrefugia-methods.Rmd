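---
title: "Coalescent refugium tests for sky-island birds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent refugium tests for sky-island birds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skyrefugia)
```

## The question the package answers

High-elevation "sky island" populations alternate between isolation on
mountain tops during warm periods and connectivity during cool periods, when
suitable habitat descends into the valleys. Given mitochondrial sequences
and microsatellite genotypes sampled from such a system — here, ten
populations of a montane bird distributed over three ecological subregions —
the package asks whether the sampled gene genealogy is compatible with (i) a
single panmictic refugium, (ii) two refugia (southern versus north-eastern),
or (iii) three refugia (southern, eastern, northern, with the
eastern/northern split nested inside the north-eastern branch). Around that
central test it provides the standard descriptive statistics of such a
study: sequence diversity and neutrality tests, microsatellite summaries and
assignment tests, landscape-genetic regression on environmental predictor
sets, and genealogy-based demographic inference.

## The sorting statistic and the simulation test

The degree to which a genealogy is geographically sorted is measured by the
Slatkin–Maddison statistic S: the minimum number of state changes of the
"sampling population" character on the tree, computed by Fitch's bottom-up
set intersection/union pass (`fitch_steps()`). Perfectly sorted data need
k − 1 changes for k populations; incomplete lineage sorting or migration
inflates S.

Each refugium hypothesis is expressed as a population tree whose branches
carry absolute effective sizes (`build_model()`). Gene trees are simulated
within it by a structured Kingman coalescent (`simulate_gene_tree()`): within
a branch of size $N_e$, each pair of lineages coalesces at rate $1/N_e$ per
generation, and lineages surviving at an internal node are pooled into the
parent branch. There is no migration between contemporaneous branches, and
the root branch runs until the final coalescence. The S values of (by
default) 10,000 simulated genealogies form the null distribution
(`null_distribution()`); an observed genealogy *more sorted* than the model
predicts rejects it, with the add-one, tie-inclusive one-tailed p-value

$$p = \frac{1 + \#\{S_{\mathrm{sim}} \le S_{\mathrm{obs}}\}}{n_{\mathrm{sims}} + 1}.$$

Because S is integer-valued with heavy ties, this p-value is conservative
(valid but not exactly uniform under the null); the test suite checks the
calibration property $P(p \le \alpha) \le \alpha$ rather than exact
uniformity. A topological deep-coalescence count (`deep_coalescence()`,
extra lineages of the gene tree within the population tree) is available as
a secondary statistic; it is degenerate for the single-branch panmictic
model, which is why the deme-character S is the headline statistic.

### Time and size conventions

All rates are interpreted on the maternal-locus scale implied by
$\theta = 2 N_e \mu$: the expected pairwise coalescence time equals $N_e$
generations. Divergence times in years convert to generations through the
generation time (1 year by default, `rate_set()`). The default total
effective size derives from a mitochondrial $\theta_{\mathrm{total}} =
0.0467$ and a clock of $0.78 \times 10^{-8}$ substitutions/site/year — the
conventional avian cytochrome-b clock of $10^{-8}$ rescaled by the ratio of
mean pairwise distance in the full concatenation to that in cytochrome b
alone (`modulate_rate()`), giving $N_e \approx 2.99\times 10^6$
(`theta_to_ne()`). Scaled divergence times from isolation-with-migration
software convert via `scaled_time_to_years()`: sequence times by
$t/(\mu_{\mathrm{site}} L)$, microsatellite times by
$(t/\mu_{\mathrm{msat}})\times$ generation time.

### Branch sizes of the population trees

Per-population $N_e$ shares are free parameters of such an analysis (the
underlying per-population $\theta$ estimates are rarely published). The
package defaults to sample-size shares of the total $N_e$, a neutral choice
that can be overridden with explicit proportions. Ancestral ("refugial")
branches default to the sum of their descendants' shares;
`refugial_proportions` instead constrains them to the share of the
populations sampled at putative refugium sites — for the three-refugia
model, the north-eastern refugial branch is sized by the YA + MK share
(22/80) in the reproduction scripts, since those populations sit at the
putative refugium sites. The root branch's size never affects S: once all
lineages are pooled in a single panmictic ancestor, the topology above that
point is exchangeable.

### Why the null genealogies carry 67 haplotype-level tips

The observed genealogy in a study of this design is a tree of *distinct
haplotypes* (67 here), not of the 80 sampled individuals: identical
sequences collapse to one tip before tree estimation. Under panmixia the
distribution of S depends only on the tip configuration — the coalescent
topology law is exchangeable and has no free parameter — so simulated trees
are only comparable with the observed one if they carry the same tips.
Simulating 80 individual-level tips yields a panmictic mean S near 56.5
regardless of any rate or size setting, which cannot be compared with an
observed haplotype-level tree; the 67-tip configuration
(`study_haplotype_counts()`) reproduces the expected panmictic mean near 47.
Per-population distinct-haplotype counts follow the study design's haplotype
table, with the three between-population shared haplotypes counted once and
removed from the admixture-zone populations (BC, YA, MK) where sharing
concentrates. Which population loses a shared tip shifts mean S by under
0.2 units, well inside simulation noise.

```{r sorting, eval = TRUE}
ne <- theta_to_ne(0.0467, 0.78e-8)
m_single <- build_model("single", total_ne = ne)
nd <- null_distribution(m_single, study_haplotype_counts(),
                        n_sims = 300, seed = 1)
test_model(40, nd)
```

(The reproduction scripts use 10,000 simulations per model; 300 here keeps
the vignette light.)

## Sequence statistics

`polymorphism_summary()` reports segregating sites S, haplotype count, the
unbiased haplotype diversity $H_d = n(1-\sum p_i^2)/(n-1)$, per-site
nucleotide diversity $\pi$ (mean pairwise differences over retained sites)
and the per-locus Watterson estimator $S/a_{n-1}$. Columns containing any
gap or ambiguity are removed before all statistics (complete deletion), the
simplest fully reproducible convention; haplotypes are exact string matches
on the retained columns.

`fu_fs()` implements Fs $= \ln(S'/(1-S'))$, with $S' = \Pr(K \ge
k_{\mathrm{obs}})$ under the Ewens sampling distribution at
$\hat\theta = \hat\pi$ (per locus). The Ewens probabilities use an unsigned
Stirling-number recursion carried entirely in log space, so samples in the
hundreds of sequences are safe. For $n = 2$ the definition collapses to
$\ln\hat\theta$, which the tests verify. Large negative Fs indicates an
excess of rare haplotypes, the signature of growth.

`fu_li_d()` contrasts total mutations $\eta$ with external-branch
(singleton) mutations using the published variance coefficients: variant
`"D"` orients singletons against a designated outgroup (a derived allele
observed once); variant `"D_star"` is outgroup-free and counts alleles
observed once. Both are provided because either may be reported in
practice; the numerators are exactly mean-zero under neutrality, which the
calibration tests exploit.

`mk_test()` tabulates synonymous/nonsynonymous × polymorphic/fixed changes
against the ingroup consensus codon (one mutation per extra allele, fixed
differences against the outgroup majority allele), translates with either
the standard or — the default for mitochondrial fragments — the vertebrate
mitochondrial genetic code, and applies the two-sided Fisher exact test. A
table with an empty margin carries no evidence and returns P = 1 by
convention.

`distance_matrices()` provides between-population mean p-distance and
pairwise $\Phi_{ST}$ from AMOVA variance components, treating pairwise
nucleotide differences as squared distances (the standard convention for
haplotype data) and truncating at zero. Populations with fewer than two
sequences are excluded with a warning.

## Microsatellite statistics

`locus_summaries()` reports, per population × locus: allele count, allelic
richness rarefied to the smallest per-population gene count at that locus
(`sum over alleles of 1 - C(N - N_a, g)/C(N, g)`), observed heterozygosity,
the unbiased expected heterozygosity $(2n/(2n-1))(1-\sum p^2)$, and
$F_{IS} = 1 - H_O/H_E$ (undefined at $H_E = 0$). `hwe_exact()` is the
Monte-Carlo exact test: the conditional probability of the genotype array
given allele counts, with the null built by shuffling gene copies.
`genetic_distances()` implements Nei's standard distance (gene identities
averaged arithmetically across loci) and the Weir–Cockerham variance-
component $F_{ST}$ summed over loci and alleles, truncated at zero.

`assignment_exclusion()` mirrors the frequency-based assignment/exclusion
procedure: genotype log-likelihoods from population allele frequencies under
Hardy–Weinberg, unobserved alleles floored at $1/(2n+1)$ (configurable),
assignment to the most likely population, and exclusion when the genotype's
likelihood falls below the $\alpha$ quantile (default 0.01) of 1,000
genotypes simulated by gamete resampling from the population's frequencies.
The null likelihoods are compared over exactly the loci the individual was
typed at.

## Landscape genetics (dbRDA)

`gower_center()` forms $G = -\tfrac12 J D^2 J$. Genetic distance matrices
($\Phi_{ST}$, $F_{ST}$) are generally non-Euclidean; the package computes
the McArdle–Anderson trace statistics on $G$ directly, without a
negative-eigenvalue correction (a square-root transform flag is available).
`marginal_test()` uses pseudo-$F = [\mathrm{tr}(HGH)/m] /
[\mathrm{tr}((I-H)G(I-H))/(n-m-1)]$ with the intercept always included and
$m$ the rank of the centred predictor set — one-hot sets (five vegetation
classes, three subregions) enter whole and lose exactly one column to the
intercept by design. Significance comes from simultaneous row/column
permutation of the distance matrix. `forward_selection()` adds the best
remaining set conditional on those included, with conditional p-values by
permutation of the residual matrix under the reduced model (Freedman–Lane
on $G$), and reports marginal tests, selection order, cumulative explained
variation and the predictor correlation matrix as a collinearity check. On
univariate Euclidean data the pseudo-F is exactly the one-way ANOVA F, and
on Euclidean distances the explained fractions equal classical RDA — both
verified in the tests.

## Demography

`classic_skyline()` estimates $\hat N_i = i(i-1)w_i/2$ from the coalescent
interval with $i$ lineages and duration $w_i$, pooling adjacent intervals
into a configurable number of composite intervals (default 10, the usual
grouping for mitochondrial genealogies) by their pooled maximum-likelihood
value. `exp_growth_ml()` maximizes the exact inhomogeneous-coalescent
log-likelihood of the intervals under $N(t) = N_0 e^{-g t}$ over
$(\log N_0, g)$, Nelder–Mead, initialized at the constant-size estimator
with time rescaled by the tree height for conditioning; non-finite
likelihood evaluations (overflow at extreme $g$) are penalized so the
optimizer stays in the valid region. At $g = 0$ the profile maximum is the
harmonic constant-size estimator, and the free fit can only improve the
likelihood — both verified to tight tolerance, and the likelihood itself is
checked against numerical quadrature.

Growth estimated from a single fixed genealogy is *upward biased*: the
information about $g$ at the deep end of the tree comes from a handful of
long intervals however many tips are sampled, and the measured null bias
(about $+1/T_{\mathrm{root}}$ per generation) does not vanish with sample
size. This is precisely why the conservative decision rule exists:
`growth_significance()` declares growth only when the mean of replicate
estimates exceeds three times their standard deviation. The package states
this bias openly rather than hiding it; the false-positive rate of the
conservative rule on constant-size data is at most a few percent in the
tests.

## The synthetic-data generator

`synthetic_study_config()` fixes the study design: the ten named
populations with sample sizes 11, 14, 7, 5, 5, 7, 8, 14, 7, 2 across three
subregions, a 4,029-site mitochondrial locus with per-site
$\theta = 0.004$ (matching observed per-population diversities of
0.003–0.005), ten microsatellite loci under the strict stepwise mutation
model at $10^{-5}$ per generation — the conventional avian dinucleotide
rate — with a reflecting allele range of nine repeat states (so allele
counts stay within the observed 1–9), and 2% missing genotypes.
`simulate_sequences()` drops Jukes–Cantor mutations on a simulated gene
tree (Poisson per branch, uniform site, uniform alternative base); an
infinite-sites mode assigns every mutation a fresh column for calibration
work where recurrent hits would bias segregating-site counts.
`simulate_microsats()` evolves allele sizes by ±1 steps with reflecting
boundaries — the endpoint of a reflected ±1 walk equals the folded endpoint
of the free walk, which is how it is drawn. `simulate_env_table()` ties
subregion membership (and latitude) to a single latent geographic gradient
with a tunable `effect` in [0, 1]: at 0 the subregions are independent of
the gradient (the size-calibration condition), at 1 they are its exact
tertiles (the power condition).

What the generator deliberately does not emulate: migration between
contemporaneous refugia, recombination (the mitochondrial locus is one
non-recombining block), selection, spatially explicit habitat, and
mutation-model complexity beyond Jukes–Cantor/SSM. Passing tests therefore
demonstrate that the statistics and tests behave correctly under the
isolation-divergence model they implement — not that real data meet those
assumptions; in particular, gene flow after divergence would also depress
S, and the sorting test cannot distinguish retained ancestral polymorphism
from migration.

## Determinism and problem sizes

Every stochastic function takes a `seed`; the pipeline
(`run_pipeline()`) derives all stage seeds from one master seed and
reproduces byte-identical reports for identical configuration. The test
suite uses 150–500 replicate simulations for calibration checks (all
three-standard-error comparisons state the Monte-Carlo error explicitly)
and the reproduction scripts use 10,000 simulated genealogies per refugium
model and 67-tip trees, sizes chosen to hold Monte-Carlo error on mean S
near 0.02 units.

## Known limitations

* Branch $N_e$ shares default to sample-size proportions; where true
  per-population diversities are very uneven this is a coarse surrogate, and
  the two- and three-refugia null means shift by a few units across
  plausible share choices.
* The sorting test conditions on a single observed genealogy and ignores
  phylogenetic uncertainty; a bootstrap over input trees can be layered on
  top by calling `observed_s()` per tree.
* $\Phi_{ST}$/F_{ST}$ matrices are non-Euclidean in general; dbRDA traces on
  direct $G$ may include small negative parts, the price of analysing the
  stated distance rather than a corrected embedding.
* The skyline and growth estimators treat the genealogy as known; they are
  desk-scale complements to, not substitutes for, full Bayesian
  genealogy-integrating methods.
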