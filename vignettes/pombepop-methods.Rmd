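---
title: "Models and methods in pombepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pombepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombepop)
```

`pombepop` analyses haploid microbial strain collections along two axes:
multi-locus sequence diversity and growth-curve trait variation. This
vignette explains the statistical models behind each stage, the tunable
parameters and their defaults, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was
genuinely open.

## Sequence data model

Input is one multiple sequence alignment per locus (aligned FASTA, one
row per strain, characters `A/C/G/T/-/N`), plus locus definitions with
**end-exclusive** genome coordinates, so a locus spans `end - start`
base pairs. For the seven loci of the fission-yeast isolate survey this
convention makes the printed intervals sum to exactly 5,777 bp, which is
the arithmetic check that fixed it:

```{r}
total_locus_span(pombe_loci())
```

### Site filtering

Sanger-derived alignments of natural isolates contain indels and
repetitive tracts whose alignment is unreliable. `site_filter()`
implements complete deletion: any column containing at least one gap is
dropped when `drop_indel_columns = TRUE`, explicitly configured column
ranges (micro/minisatellites) are removed, and columns containing `N`
are dropped by default. Treating ambiguous bases like gaps is a
conservative choice for identity-based haplotype collapse — an `N` can
never silently merge two haplotypes or split one; the cost is a slightly
shorter analysed length. Filtering commutes with concatenation, so
per-locus filtering followed by concatenation equals filtering the
concatenated alignment column-wise.

### Haplotype collapse

`collapse_haplotypes()` concatenates the filtered per-locus sequences of
each strain and groups strains whose concatenated strings are exactly
identical. Identity (not distance) is the right notion here: the
collections of interest are clonally structured, and the analysis
question is "how many distinct multi-locus genotypes were sampled".
Group ids are 1-based in first-occurrence order over the input strain
order; the partition — though not the numbering — is invariant under
strain reordering, and the compound partition always refines each
per-locus partition. Downstream diversity statistics are computed over
one representative per compound haplotype by default
(`diversity_table(collapse = TRUE)`): de-duplicating clones avoids
weighting the estimators by collection effort. Set `collapse = FALSE`
to use all strains.

## Diversity and neutrality statistics

For an alignment of $n$ sequences and $L$ sites with $S$ segregating
sites:

* nucleotide diversity $\pi$ is the mean number of differences over all
  $\binom{n}{2}$ unordered pairs (per sequence), divided by $L$ (per
  site). The implementation counts alleles per column —
  $\binom{n_v}{2} - \sum_b \binom{n_b}{2}$ differing pairs per column —
  which is algebraically identical to the all-pairs double loop the test
  suite uses as its oracle;
* Watterson's estimator is $\hat\theta_W = S/a_1$ per sequence,
  $a_1 = \sum_{i=1}^{n-1} 1/i$ computed by direct summation;
* Tajima's $D = (\pi - S/a_1)\,/\,\sqrt{e_1 S + e_2 S(S-1)}$ with the
  standard coefficient chain
  $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$. $D$ is undefined at $S=0$
  (returned as `NaN` with a warning) and its sign always equals the sign
  of $\pi - \hat\theta_W$;
* the reported standard deviations of $\pi$ and $\hat\theta_W$ use
  Tajima's total-variance formulas (evolutionary plus sampling
  variance), evaluated at the respective estimate. Different programs
  use different variance conventions, so these columns are indicative
  rather than canonical;
* the haploid effective population size is $N_e = \pi/(2u)$ per site.
  The default mutation rate `mu = 0.33e-9` per bp per generation is the
  budding-yeast rate commonly borrowed for fission yeast; the headline
  reporting helper rounds to one significant figure, the precision such
  an estimate deserves.

```{r}
watterson_theta(S = 21, n = 40, L = 719)$theta_site * 1e3
tajimas_d(pi_seq = 1.603e-3 * 743, S = 12, n = 40)
effective_population_size(7e-3)$ne_rounded
```

## Population structure

`pairwise_fst()` defaults to the Hudson/AMOVA pairwise-difference form
on each population pair:
$F_{st} = (\bar\pi_{between} - \bar\pi_{within})/\bar\pi_{between}$,
with $\bar\pi_{within}$ the unweighted mean of the two within-population
mean pairwise differences. This is the estimator family used by
haplotype-level AMOVA software, and it legitimately produces small
negative values when within-population diversity exceeds
between-population diversity — those are retained, not truncated. A
Weir–Cockerham per-site variance-components option is provided because
the literature is often ambiguous about which "F statistic" a study
used; neither is asserted to be the published one. Note a finite-sample
subtlety: feeding the estimator two literal copies of the same sequence
set yields a negative value (cross-population pairs then include
zero-distance self-matches), whereas two independent samples from one
population give values scattered around zero — the meaningful null.

A sequence may be assigned to more than one population
(`population_map()`), contributing one sequence to each: haplotypes
whose members have different known origins are counted in every origin,
so population sizes may sum past the haplotype count. Populations with
fewer than two sequences are excluded with a warning.

## Linkage disequilibrium

`informative_snps()` keeps biallelic columns whose minor allele count is
at least 2 (parsimony-informative sites); singletons carry no linkage
information and three-allele columns violate the biallelic 2×2 model.
For each marker pair, with gamete frequency $p_{AB}$ and allele
frequencies $p_A, p_B$ over pairwise-complete sequences:

$$D = p_{AB} - p_A p_B,\qquad
  D' = D / D_{max},\qquad
  r = \frac{D}{\sqrt{p_A q_A p_B q_B}},\qquad
  \chi^2 = n r^2 .$$

No continuity correction is applied: the uncorrected form satisfies
$\chi^2 = n r^2$ exactly (a perfectly associated pair across 40
sequences gives $\chi^2 = 40$; $r = 0.85$ gives $40 \times 0.85^2 =
28.9$), and the test suite verifies the identity against the direct
2×2 Pearson statistic. Stars mark the df = 1 thresholds at 0.05, 0.01
and 0.001. The four-gamete test calls a pair recombinant iff all four
gametic types are observed — impossible when $|D'| = 1$ — and the
Hudson–Kaplan bound `rm` counts disjoint incompatible marker intervals
by the greedy smallest-right-endpoint rule.

## Growth phenomics

### The three-phase curve model

`simulate_growth_curve()` generates OD at `sample_interval_min` (default
20 min, the microcultivation standard) over `duration_h` (48–72 h):
flat at `od_start` until `lag_h`, exponential at `mu_max`, then capped
at `od_final`. The saturation phase is a hard plateau rather than a
logistic tail: with a logistic tail the initial log-slope is
$\mu(1 - OD_0/K)$, i.e. the ground-truth growth rate would not be the
model parameter, while the capped form makes log(OD) exactly piecewise
linear so lag, rate and efficiency have analytic true values — the
property a test bed needs most. Additive Gaussian noise
(`noise_sd`, default 0.01 OD) is applied and values floored at 0.001 so
downstream logs stay finite. The generator emulates the sampling grid,
noise scale and dynamic range of real microcultivation; it does not
emulate diauxic shifts, death phases, OD nonlinearity at high density,
or plate effects — so passing recovery tests demonstrate correctness of
the extraction logic, not robustness to every real-world pathology.

### Component extraction

`extract_fitness()` computes, on lightly smoothed log OD (running
median, window 3):

1. local slopes by least squares in a sliding window (5 points ≈ 80 min
   at 20-min sampling);
2. the maximum slope among *qualified* windows — those whose mean OD
   exceeds the baseline by at least 3 baseline standard deviations.
   This guard matters because the log transform amplifies measurement
   noise at baseline OD, where spurious steep window slopes otherwise
   dominate the maximum;
3. a single refit of log OD over the contiguous band around the best
   window where OD is above the baseline threshold and below 90% of the
   maximum — under the three-phase model exactly the exponential phase.
   The refit removes the upward bias of taking a maximum over many
   noisy short-window slopes; on noise-free curves it reproduces
   `mu_max` exactly.

Doubling time is $\ln 2 / \mu_{max}$; lag is where the fitted
exponential line crosses the baseline log OD (tangent construction);
efficiency is max OD minus initial OD. Curves with no qualified window
or no positive slope are flagged non-growers and excluded downstream.
Window sizes are configurable; the defaults suit 20-min sampling.

### The LSC relative-fitness score

For strain $i$, trait $j$ and runs $r$:

$$LSC_{ij} = \sum_r \Big[\tfrac1m \sum_{k=1}^m \log(wt_{kjr}) -
\log(x_{ijr})\Big]^2,$$

the summed squared deviation of the strain's log measurement from the
reference log-mean per run (typically $m = 10$ reference replicates and
2 runs). It is zero iff the strain matches the reference log-mean in
every run, invariant to permuting reference replicates, and monotone in
the per-run deviation. Efficiency is inverted (reciprocal before log)
in `fitness_components()` so that larger values mean worse-than-
reference for all three components; the formula is applied literally as
a sum over available runs when a run is missing.

## Trait profiles

`build_trait_matrix()` forms traits as component × environment and
entries as log2(strain/reference) — three components over 42
environments give the 126-trait scale of a full phenomics screen.
Downstream:

* **clustering** uses distance $1 - r$ (centered Pearson — ordinary
  mean-centred correlation, not the uncentered cosine variant — over
  pairwise-complete shared traits) and average linkage via
  `stats::hclust`. Pairs sharing fewer than 3 traits, or constant
  profiles (the reference's own all-zero row), are an explicit error:
  their correlation is undefined and silently dropping rows would be
  worse. The pipeline excludes constant profiles with a message;
* **group similarity** splits all strain pairs into same-group and
  different-group sets and compares the two sets of correlations with a
  two-sample t-test. Welch is the default (robust to unequal spread);
  a pooled-variance Student option is provided, and with very few
  replicates the pooled form is the powered choice;
* **atypicality** ranks strains by correlation with the per-trait mean
  profile, most atypical first;
* **per-trait deviation** tests the focal strain's replicates against
  all other strains' values per trait, adjusts by Benjamini–Hochberg,
  and reports the significant fraction at the chosen FDR (default 5%).

## Synthetic-data generators and what they validate

The coalescent simulator draws exponential coalescence times (rate
$\binom{k}{2}$ in units of $2N$ generations), places Poisson mutations
at rate $\theta/2$ per unit branch length, and assigns each mutation a
distinct site (infinite sites — every segregating site biallelic), so
$E[S] = \theta a_1$ and $E[\pi] = \theta$ hold exactly and the
estimators can be validated against closed forms. The island model adds
per-lineage migration at the scaled rate among equal-sized demes by
standard rate competition. Two choices are worth flagging: with
`migration_rate = 0` isolated demes would never share an ancestor, so
the simulator merges the remaining lineages into one ancestral deme at
a fixed deep time (20 coalescent units), giving the expected
$F_{st} \to 1$ limit; and mutation count is capped at `seq_length`
(irrelevant in practice at desk scales). The simulator deliberately
omits recombination within loci, selection and realistic demography —
it is an oracle for the estimators, not a model of the species.

The planted trait-matrix generator adds per-group trait means
($N(0, \texttt{group\_effect\_sd})$), strain noise
($N(0, \texttt{noise\_sd})$), and for designated outliers shifts a
fraction of traits by `outlier_shift` (default 5) noise SDs — large
enough that an outlier is separable in principle, which is what the
atypicality and FDR machinery is tested against.

The synthetic 84-strain collection reproduces the published strain
names, origins and 40-group compound-haplotype partition; its bases are
random (none of the real sequences are public), with each per-locus
haplotype carrying a dedicated diagnostic mutation so locus haplotypes
are pairwise distinct and group assignments are re-drawn until jointly
distinctive. Only the partition and metadata are faithful; diversity
levels in the synthetic bases are arbitrary.

## Problem sizes and determinism

The validation suite runs at desk scale by design: coalescent checks
use 1,000 replicates at $n = 40$, $\theta = 5$ (enough for the
mean-$S$ and mean-$D$ tolerances of 5% and ±0.1), growth-recovery
batches use 200 curves at noise 0.01, and planted-structure checks use
matrices around 20–40 strains × 60–126 traits. All generators accept a
seed and are bit-reproducible given one; pipeline runs with identical
config and seed produce byte-identical reports.

## Known limitations

* F_st and LD on the real published tables cannot be reproduced exactly
  because the underlying sequences were never deposited; the package
  validates those statistics on synthetic data and identities instead.
* Tajima's variance-based SD columns follow one convention among
  several; do not compare them across programs without checking.
* The growth model's hard saturation cap means the extracted efficiency
  equals the plateau minus baseline; on instruments with OD
  nonlinearity a calibration step (not included) would be needed.
* The per-trait deviation test inherits the weakness of tiny replicate
  numbers; with $n \le 3$ replicates prefer `var_equal = TRUE`.
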