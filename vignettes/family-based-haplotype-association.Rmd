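---
title: "Family-based haplotype association with case-parent triads and control-mother dyads"
author: "triadscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based haplotype association with case-parent triads and control-mother dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadscan)
```

## The problem

Perinatal phenotypes such as spontaneous preterm delivery can be driven by
two genomes: the child's own genotype (a *fetal* effect) and the mother's
genotype acting through the intrauterine environment (a *maternal*
effect).  Case-control designs cannot separate the two, and are exposed to
population stratification.  Family-based designs can: a *case-parent
triad* (affected child plus both parents) carries information about both
transmission distortion and parental genotype enrichment, and a *hybrid
design* adds unaffected *control-mother dyads*, which pin down the
population haplotype frequencies and raise power.

`triadscan` implements the full pipeline around this idea: a synthetic
generator that emulates the family structure of a candidate-gene study
(196 case triads, 211 control dyads, ~5% of case fathers without DNA),
the quality-control cascade such studies apply, a full-likelihood
estimator of haplotype frequencies and fetal/maternal relative risks, a
sliding-window scan with gene-level multiplicity correction, pathway
combination against a candidate-gene background, and QQ summaries.

## The likelihood model

Within a marker window of $L$ SNPs (here $L \le 3$), let $p_h$ be the
population frequency of haplotype $h$.  We assume random mating, mating
symmetry and Hardy-Weinberg equilibrium for the parents, fair transmission
within the family, and a **multiplicative gene-dose model**: every copy of
haplotype $h$ carried by the child multiplies disease risk by the fetal
relative risk $F_h$, every copy carried by the mother multiplies it by the
maternal relative risk $M_h$.  Both are fixed at 1 for the *reference
haplotype*, the most frequent one (ties broken lexicographically by allele
string) — the ascertainment normalisation makes a common rescaling of all
$F_h$ (or $M_h$) unidentifiable, so a reference constraint is required.

A case triad with maternal haplotypes $(m_1, m_2)$, paternal $(f_1, f_2)$
and transmitted pair $(t_m, t_f)$ contributes

$$P(\text{genotypes} \mid \text{case}) \;=\;
\frac{\sum_{\text{compatible}} p_{m_1} p_{m_2} p_{f_1} p_{f_2}
      \tfrac14\, F_{t_m} F_{t_f} M_{m_1} M_{m_2}}
     {\left(\sum_h p_h F_h\right)\left(\sum_h p_h M_h\right)
      \left(\sum_h p_h F_h M_h\right)},$$

where the sum runs over every haplotype configuration compatible with the
observed (unphased, possibly missing) genotypes, and the denominator is
the same sum over *all* configurations, which collapses to the closed
form shown.  A wholly missing father is marginalised analytically — only
his transmitted haplotype remains, drawn from $p$ — which gives an
identical normalisation, so case-mother dyads and triads mix freely.
Control dyads contribute the population probability of the mother-child
pair (paternal transmission marginalised) with **no risk terms**: controls
inform the frequencies only.  This is the standard rare-disease
approximation for hybrid designs; the generator's default baseline risk of
1% keeps the study inside it, and the generator refuses configurations in
which the multiplicative risk exceeds 1 in more than 1% of draws.

Phase ambiguity and missing genotypes are handled exactly, by summation
over compatible configurations — conceptually an EM-style marginalisation,
but the maximisation itself is direct: frequencies are softmax-parametrised,
risks are log-parametrised, and a quasi-Newton (BFGS) iteration with
analytic gradients maximises the joint likelihood from the null start
(smoothed empirical haplotype frequencies, all log-RR zero).  One
optimiser serves every design (`triad`, `hybrid`) and effect combination
(`fetal`, `maternal`, `both`).

### Inference

* **Overall window p-value**: likelihood-ratio test of the fitted model
  against the no-effect null, $\chi^2$ with one degree of freedom per free
  log-RR (for a joint fetal+maternal fit over $K$ effect classes,
  $2(K-1)$).
* **Per-haplotype p-values and 95% CIs**: Wald, on the log-RR scale, from
  the inverse observed information (`optimHess`), back-transformed.
* **Second-genome Wald test** (`wald_second_genome`): joint nullity of
  one component's log-RRs in the joint fit, using the corresponding block
  of the inverse information — "does the second genome add anything?".

### Numerical choices

* Convergence: relative log-likelihood tolerance `1e-8`, at most 200
  BFGS iterations; both configurable.
* Haplotypes with estimated null frequency below 0.1% (about one
  chromosome at study scale) are treated as absent: their frequencies stay
  free but their relative risk is tied to the reference rather than
  spending an uninformative parameter.  Haplotypes between 0.1% and the
  pooling threshold (default 1%) share one pooled effect class — rare
  haplotypes otherwise produce unstable risk estimates — while keeping
  separate frequencies.
* An estimate with $|\log RR| > 10$ is reported as a boundary
  (separation) with a one-sided interval and a warning.
* Families Mendelian-incompatible at a window (post-QC residue) are
  dropped from that window only, with a warning.
* Degenerate inputs: monomorphic windows return a valid fit with
  $p = 1$ and zero degrees of freedom.

### Why the joint model matters: confounding by the maternal genome

Under a pure maternal effect, case mothers are enriched for the risk
haplotype and the child inherits half its genome from the mother, so the
child is enriched too.  In the *hybrid* design the control dyads pin the
haplotype frequencies, and a fetal-only model must attribute that child
enrichment to a spurious fetal effect — in our simulations a maternal RR
of 2 induces a fetal-only log-RR bias of about 0.2, while the joint model's
fetal estimate stays centred at zero ("adjusted for each other").
Interestingly, in the *triad-only* full-likelihood fit the bias largely
vanishes: the frequency parameters are free and absorb the mother-father
asymmetry, and the fetal effect is identified from transmission, which a
maternal effect does not distort.  The acceptance suite therefore tests
the confounding separation under the hybrid design, where the
case-control-style information that creates the confounding is present.

## The synthetic-data generator

`simulate_dataset()` draws nuclear families forward from the model:
parental haplotypes i.i.d. from the configured per-gene frequencies (no
recombination within a gene — windows are three physically tight SNPs),
fair transmission, disease by the multiplicative risk with baseline 1%,
case families by rejection sampling on disease, controls from the
non-diseased (at a 1% baseline the difference from pure population
sampling is negligible).  Case families become triads, with the father
masked entirely with probability 5%; controls are emitted as
mother-child dyads, mirroring the study structure.  After sampling,
each genotype call is masked with probability 0.5% and each transmitted
child allele is substituted by a uniformly drawn allele with probability
0.1% (the Mendelian-error process; child-only, which keeps its
detectable-error rate analytically boundable).  One RNG stream per
dataset, with per-family sub-streams derived from the seed, makes output
byte-for-byte reproducible and single families independently
regenerable.

What the generator does *not* emulate: population stratification (the
robustness argument for triads is structural, not simulated),
recombination within genes, X-linked transmission (X SNPs are generated
only to be removed by QC), genotyping batch effects, and
linkage disequilibrium *between* genes.  Tests passing on this generator
therefore validate the estimator and its calibration under the model's
own assumptions — they cannot certify behaviour under model violations
real cohorts may show.

## Quality control

Marker filters are applied sequentially, each SNP counted under the first
rule it fails, in the order: call-rate $\ge$ 90% (over all genotyped
individuals) → X chromosome → exact Hardy-Weinberg test in **control
mothers** at $p < 0.01$ → founder minor allele frequency $\ge$ 5%.
Control mothers (rather than mothers plus children) enter the HWE test
because mother and child are relatives and pooling them would break the
test's independence assumption; founders for the MAF computation are case
parents plus control mothers.  Family filters: Mendelian-inconsistency
rate above 1% removes the family; mother or child call-rate below 95%
removes the family; a father below 95% is dropped individually while the
family remains.  Remaining single-SNP Mendelian clashes in retained
families are set to missing so the likelihood never sees an impossible
configuration.  The exact HWE test enumerates the conditional
heterozygote-count distribution given the allele counts, the standard
choice at these sample sizes.

`simulate_qc_benchmark()` constructs a deterministic 1,443-SNP panel in
which exactly 31 X-linked, 18 HWE-failing and 68 low-MAF SNPs (disjoint
categories covering 8 of 167 genes completely) are planted; the cascade
must retain exactly 1,326 SNPs in 159 genes — an auditable accounting
check of every marker rule at once.

## Scans and the gene-level p-value

`make_windows()` slides a window of width 1 (single locus) or 3
(haplotypes) across each gene with stride one, never crossing gene
boundaries; genes smaller than the width are analysed as one all-SNP
window rather than skipped.  `run_scan()` fits every window and records
failures without aborting.

To correct for multiple testing within a gene we use a **min-p parametric
bootstrap** (`gene_pvalue`): the observed statistic is the smallest
overall p across the gene's windows; null datasets are simulated from the
windows' null-fitted haplotype frequencies with the observed family
structure and missingness preserved, and the min-p statistic is
recomputed on each, giving $p_{gene} = (1 + \#\{p^{*}_{\min} \le
p_{\min}\})/(B+1)$.  Overlapping windows are resampled from a common
stitched haplotype distribution (first window drawn from its fitted
frequencies, each subsequent window extending one SNP conditional on the
overlap — an order-$(w-1)$ Markov approximation, exact within any single
window), so perfectly redundant windows incur *no* multiplicity penalty,
unlike Bonferroni, while independent windows are penalised fully.  The
original study used a score-test-based within-gene correction whose
formulas are not published; the bootstrap is our fully specified,
design-agnostic substitute, and its null uniformity is verified by
simulation in the test suite.  Long-range LD beyond the window width is
only approximated by the Markov stitching; that is the price of never
having to phase whole genes.

## Pathway combination

Gene-level p-values $p_1, \dots, p_k$ of a pathway are combined by
Fisher's method, $X = -2\sum_i \ln p_i \sim \chi^2_{2k}$ under
independence.  Because a candidate-gene panel is not a random draw from
the genome, significance is additionally judged against the **candidate
-gene background**: the observed statistic is compared with 10,000
statistics obtained by drawing $k$ genes at random *from the study's own
gene set* (without replacement — the natural reading of "the same number
of genes", and the only option for small pools), with
$p = (1 + \#\{X^{*} \ge X\})/(n_{sims}+1)$, never exactly zero.  If every
candidate gene carries signal, Fisher's p collapses while the resampling p
stays near uniform — the two agree only when gene p-values look uniform,
which is itself a diagnostic the suite asserts.  Per-pathway resampling
seeds are derived from the gene-set content, so identically composed
pathways get identical results regardless of labelling.  Dependence
between genes of a pathway is ignored by Fisher's formula (acknowledged
in the field); the resampling p is the corrective.  Pathways reduced to a
single study gene are flagged: their combined p is just that gene's p.

## QQ summaries

Under a global null the $i$-th smallest of $n$ p-values follows
$\mathrm{Beta}(i, n-i+1)$; `qq_data()` pairs observed order statistics
with Beta medians and a 95% pointwise envelope from the 2.5%/97.5% Beta
quantiles, on the $-\log_{10}$ scale (raw-scale columns are included).
The envelope is exact pointwise, not simultaneous: under uniformity each
rank escapes with 5% probability, and neighbouring ranks are strongly
correlated.  `render_qq()` draws one panel per design × model
combination.

## Problem sizes used in the packaged checks

The simulation-based checks run at deliberately chosen desk scales: null
calibration of the window LRT uses 500 replicates at the full study
structure (196 triads + 211 dyads); gene-level bootstrap uniformity uses
150 replicates of 60 + 60 families with $B = 119$; parameter recovery
uses one dataset of 2,000 triads for the point estimate and 200 replicates
of 500 triads for CI coverage; power comparison uses 200 replicates at the
study size; grid-search oracle checks use 20-25 complete triads where
exhaustive enumeration is feasible.  These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances while keeping
the whole suite reproducible on a laptop.

## Known limitations

* Control dyads carry no penetrance model; if controls were ascertained
  on a correlated phenotype (e.g. strictly term births) rather than
  population-sampled, the frequency-only treatment is an approximation.
* Wald intervals can be poor near separation; profile intervals are not
  implemented.
* No parent-of-origin, imprinting, X-linked or gene-environment models,
  and no covariate adjustment — all outside this pipeline's scope.
* The gene-level bootstrap honours LD only to the window width via the
  Markov stitching.
* The QQ envelope is pointwise; it is a reading aid, not a global test.
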