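---
title: "Genetic distance and heterosis in NC II panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic distance and heterosis in NC II panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdheterosis)
```

This vignette explains the statistical machinery behind the package: the two
genetic-distance estimators, the heterosis statistics, the grouping and
association procedures, and the generative model of the synthetic panel that
the test suite validates everything against. It also records the design
decisions that were genuinely open, and what the passing tests do and do not
demonstrate about real data.

## The analysis problem

An NC II (North Carolina II) factorial crosses every one of $m$ male testers
with every one of $f$ female lines, giving $m \times f$ F1 hybrids. Breeders
want to know, before making crosses, whether the marker-based genetic
distance between two parents predicts the performance or heterosis of their
hybrid. The chain of computation is: genotype QC, pairwise parental GD,
per-cross GD lookup, multi-environment trait means, mid-/best-parent
heterosis, heterotic grouping, and correlation of GD with outcome within
each male population.

## Genetic distance

**SSR band-sharing.** An SSR call is a set of one (homozygote) or two
(heterozygote) fragment-length bands. Over the markers scored in *both*
accessions, let $N_a$ and $N_b$ be the band totals of accessions $a$ and $b$
and $N_{ab}$ the number of shared bands, counted marker by marker and summed
over the panel. Then
$$\mathrm{GD}_{\mathrm{SSR}} = 1 - \frac{2N_{ab}}{N_a + N_b}.$$
A note on the counting unit: similarity of this form is sometimes described
over "markers amplified in both samples", which for multi-allelic SSRs is
ambiguous; this package counts *bands* (distinct alleles), the standard
Nei–Li reading, so a heterozygote contributes two countable units.

**SNP identity-by-state.** Diploid biallelic calls are stored as
alternate-allele dosages $d \in \{0, 1, 2\}$. Two genotypes share
$2 - |d_1 - d_2|$ allele copies, so the per-site similarity is $1$, $0.5$ or
$0$; IBS is the mean over sites called in both accessions and
$\mathrm{GD}_{\mathrm{SNP}} = 1 - \mathrm{IBS}$. No allele-frequency
weighting is applied: the estimator is the plain proportion of shared state,
so it is symmetric, bounded in $[0,1]$ and zero on self-comparison.

**Missing data.** Both estimators use pairwise-complete deletion: a marker
or site missing in either member of a pair is excluded for that pair only.
The per-pair support (number of markers/sites actually used) is carried in
the distance object so users can threshold on it; a pair with no shared data
becomes an explicit `NA`, never a silent zero. For fully inbred parents the
SNP distance between the two parents of a cross equals the expected
heterozygosity of their F1 over the same sites — an identity the test suite
checks exactly.

## Genotype quality control

SNP sites are retained when the missing-call fraction is $\le$ `max_missing`
(default 0.30) and the minor allele frequency is $\ge$ `min_maf` (default
0.05), with MAF computed on non-missing *allele* counts (two per called
accession). Both boundaries are inclusive on the retained side: a site at
exactly 5% MAF survives, because the elimination rule is "less than 5%".
Monomorphic sites have MAF 0 and fall out of any positive MAF threshold;
monomorphic SSR markers (fewer than two observed alleles) are dropped by a
dedicated filter. Raising `min_maf` or lowering `max_missing` can only
shrink the retained set — a monotonicity property the tests assert.

## Heterosis

Phenotypes arrive as one record per entity × trait × year × site. They are
aggregated to entity × trait means by an unweighted arithmetic mean first,
and heterosis is computed once per cross × trait — not per environment and
then averaged — so each cross has a single MPH/BPH value per trait. With
$F_1$ the hybrid mean, $P_1, P_2$ the parental means,
$\mathrm{MP} = (P_1+P_2)/2$ and $\mathrm{HP} = \max(P_1, P_2)$:
$$\mathrm{MPH} = \frac{F_1 - \mathrm{MP}}{\mathrm{MP}} \times 100\%,
\qquad
\mathrm{BPH} = \frac{F_1 - \mathrm{HP}}{\mathrm{HP}} \times 100\%.$$
For strictly positive parental values $\mathrm{MPH} \ge \mathrm{BPH}$
always, and both are invariant to swapping the parents and to rescaling a
trait by any positive constant; all three identities are asserted over
simulated tables. Ratio heterosis is ill-behaved at non-positive
denominators, so rows with $\mathrm{MP} = 0$ or $\mathrm{HP} = 0$ are
flagged undefined and rows with a negative denominator carry a
`nonpositive_parent` caution rather than a silently misleading sign.
Percentages are kept at full precision internally and rounded only in
written reports (2 decimals).

## Heterotic grouping

Grouping is UPGMA (average linkage) on the GD matrix, which yields an
ultrametric tree with non-decreasing merge heights, making a cut into $k$
groups well defined. The algorithm choice was open — germplasm studies
rarely state one — and UPGMA is the conventional choice for distance-based
germplasm grouping. Two determinism measures are built in: labels are
sorted lexicographically before clustering, so the result cannot depend on
input order even under tied distances, and group ids are reassigned by
decreasing group size (ties broken by the lexicographically smallest
member), so "group 1" is always the largest. $k$ is a parameter (defaults:
5 for SNP trees, 3 for SSR trees), not automatically selected.

Distance is defined between parents, not crosses, so the package clusters
the *female* parents and lets every F1 inherit its female parent's group; in
a complete factorial each F1 group is then exactly (females in group) ×
(number of males) large. This mirrors how factorial panels are grouped in
practice: all F1-group sizes are forced to be multiples of the male count.

## Association analysis

Correlations are sample Pearson coefficients on pairwise-complete pairs,
with two-sided p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of
freedom, flagged `*` at $p<0.05$ and `**` at $p<0.01$. Strata with fewer
than three complete pairs or zero variance yield explicit "undefined" rows
rather than NaNs. All GD–outcome correlations are computed *within each
male population*: the male parent is a design factor, and pooling across
males would confound tester effects with distance effects.

Group comparisons of trait distributions use all pairwise Welch two-sample
t-tests with Holm adjustment within each trait (family-wise $\alpha$ 0.05).
Welch + Holm was an open choice; it is robust to the unequal group sizes and
variances that GD-derived groups always have, and Holm controls the
family-wise error without the independence assumptions of sharper methods.

## The synthetic panel generator

The generator exists so that every downstream stage can be tested against
known truth. Its defaults describe the study conditions the package is
organised around: 4 elite male testers and 282 females (286 parents in
three origin classes — elite, historic, exotic — sized 136/103/47, males
elite), 198 SSR markers with 1–10 alleles each, biallelic SNPs, ten trait
codes (PH, BW, LP, BN, FL, FS, MIC, FU, FE, SCI) measured over 2 years × 2
sites. The default SNP count is 5,000 — a deliberate desk-scale panel;
because GD is a per-site average, its distribution is shape-stable in the
number of sites, and tests that need specific marker:QTL ratios set their
own counts.

**Genotypes.** Parents are fully inbred (homozygous), matching selfing
cultivar lines and making F1 derivation deterministic: the F1 dosage is the
parental mean, heterozygous exactly where the parents differ, missing where
either parent is missing. SNP alternate-allele frequencies follow the
Balding–Nichols construction: an ancestral frequency $p \sim U(0.05, 0.95)$
per site and subpopulation frequencies
$\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, all equal
to $p$ at $F=0$. SSR allele frequencies are ancestral Dirichlet weights
perturbed per subpopulation by the analogous Dirichlet construction. The
default divergence $F_{ST}=0.15$ reflects a moderately structured cultivar
panel; tests of subpopulation recovery and of the GD–heterosis mechanism use
$F_{ST}=0.4$, the strongly structured regime in which subpopulations are
separable at 500 SNPs. Missing calls are injected independently per call
(defaults 5% SNP, 2% SSR); dropout is not marker-clustered because only
aggregate rates are ever specified for such panels.

**Phenotypes.** For entity $i$, trait $t$ and each year × site environment,
$$y_{it} = \mu_t + \sum_l a_l x_{il} + \sum_l d_l h_{il} + \varepsilon,$$
with QTL genotype code $x \in \{-1, 0, +1\}$ (dosage − 1), heterozygosity
indicator $h \in \{0,1\}$, and $\varepsilon \sim N(0, \sigma_e^2)$ i.i.d.
per environment. Per-trait QTL (default 20) are drawn uniformly from the
SNP panel; additive effects $a_l \sim N(0, 0.5)$, dominance effects
$d_l \sim N(0.3, 0.1)$ (trait units), baseline $\mu_t = 50$, $\sigma_e = 1$.
With these scales the simulated mean MPH lands in the few-percent range
typical of yield-trait heterosis in inbred-line crops. Directional
(positive-mean) dominance is the mechanism that links GD to heterosis: the
more distant two parents, the more QTL are heterozygous in their F1, and
each heterozygous QTL adds $d_l$ to the hybrid but nothing to either parent.
Setting the dominance scale to zero makes expected MPH exactly zero — the
additive limit — and the tests verify both regimes.

Phenotypes are generated from the *complete* pre-dropout genotypes, which
the truth object retains; missing marker calls are an assay artifact and
should not delete trait values. When `simulate_phenotypes()` is handed
genotypes that do contain missing QTL calls, it flags the affected
entity × trait values as missing rather than imputing.

**One seed, one stream.** All randomness flows from a single RNG stream
seeded once per simulation, with a documented consumption order
(subpopulation assignment, SNP frequencies, SNP genotypes, SNP dropout,
site metadata, SSR panel, SSR dropout, trait architecture, then phenotype
noise at generation time), so every output is bit-identical under a fixed
seed.

## What the tests show — and what they cannot

The test suite validates the machinery at these problem sizes, chosen to
exercise each property at the smallest scale where it is meaningful:
6 × 20 instances for exact oracle equivalence of both distance estimators
(50 random instances, $10^{-12}$ tolerance); 4 × 50 factorials over 20
seeded runs for the zero-dominance limit (per-trait mean MPH within 2
standard errors of zero, with the SE taken across the 20 independent runs
because crosses within a run share parents); 100 parents in 5
subpopulations at $F_{ST}=0.4$ and 500 SNPs over 20 seeded runs for
cluster recovery (adjusted Rand index $\ge 0.9$); and full 4 × 282
factorials at 500 SNPs and 20 uniformly dominant QTL for mechanism
recovery.

Two honest caveats. First, the simulator has no linkage: sites are
independent, so the correlation between genome-wide GD and the heterozygous
burden at a 20-QTL subset is bounded near $\sqrt{20/500} \approx 0.2$
within a subpopulation, plus a between-subpopulation component whose sign
can fluctuate for an individual male × trait cell when only 20 causal sites
are sampled. In real genomes LD ties causal sites to the genome-wide
background far more tightly; the simulated mechanism-recovery rate is
therefore conservative, and one should not expect *every* male population
to clear a $p<0.01$ bar in *every* simulated replicate. Second, the
generator omits G×E beyond i.i.d. noise, epistasis, multi-generation
breeding and marker-clustered dropout, so passing tests demonstrate the
correctness of the estimators and the qualitative mechanism — not the
effect sizes any particular real panel will show. Real-panel correlation
magnitudes depend on trait architecture and panel structure and cannot be
reproduced from synthetic data.

## Numerical and degenerate-input conventions

* VCF positions are 1-based on disk and converted to 0-based half-open
  coordinates for windowed summaries; density windows are
  $[kw, (k+1)w)$ with $w$ = 500 kb by default.
* Undefined quantities (distance without shared data, correlation without
  variance, heterosis without a positive denominator) propagate as flagged
  `NA`, never as 0, and never abort a whole table.
* An all-site-removing filter returns an empty set with a warning, not an
  error, so pipelines can report rather than crash.
* Heights from UPGMA are checked non-decreasing; cutting at $k$ and $k+1$
  produces nested partitions (refinement), which the tests assert.
* The pipeline writes a manifest (package version, parameters, input
  checksums) sufficient to reproduce a bundle byte-for-byte; no timestamps
  or hidden state enter any output.

## Interfaces

The stage functions are the API; `run_pipeline()` orchestrates them over
files (VCF v4.2 for SNPs; a documented TSV dialect for SSR profiles with
cells `"152"`, `"150/154"` or `"."`; long-format TSV phenotypes; a
cross/male/female design TSV) and `run_demo()` wires the simulator to the
pipeline in one call. These two functions, plus the per-stage exports, are
the package's command surface; scripted use is a one-line `Rscript -e`
around either.
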