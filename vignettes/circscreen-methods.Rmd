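---
title: "Methods: backsplice-junction quantification and prognostic screening of circRNAs"
author: "circscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backsplice-junction quantification and prognostic screening of circRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscreen)
```

# The problem

Circular RNAs (circRNAs) arise from backsplicing: a downstream splice donor
is joined to an upstream acceptor, producing a covalently closed transcript.
Because the body of a circRNA is shared with its linear host transcript, the
only sequence that identifies the circular isoform in short-read RNA-seq is
the backsplice junction (BSJ) — the point where the transcript's end is
ligated to its beginning. circRNAs resist 3'->5' exonucleolytic degradation
(RNase R), which is the standard biochemical evidence of circularity, and
their stability makes them attractive prognostic biomarkers.

`circscreen` implements the computational arm of a circRNA biomarker study:
junction reference construction, junction read counting, RNase R enrichment
testing, a per-circRNA relapse-free-survival (RFS) screen, and
circRNA–miRNA–mRNA / circRNA–RBP network assembly, together with a
synthetic-data generator that makes every stage testable against known
ground truth.

# Junction reference and k-mer counting

## Junction construction

For a circRNA transcript of length $L \geq 16$ the junction string is

$$ j = s_{L-14..L} \,\Vert\, s_{1..16}, $$

the last 15 nt ligated to the first 16 nt — 31 nt in total, i.e. exactly one
k-mer at the conventional pseudoalignment k-mer length $k = 31$. Transcripts
with $16 \le L < 31$ are retained (suffix and prefix then overlap in the
middle; the construction is still well defined) and flagged in the skip
report; $L < 16$ is skipped as `too_short`, and an ambiguous base (N) inside
the junction window skips the record as `ambiguous_base` — N elsewhere in
the transcript is harmless and does not disqualify it.

Distinct circRNAs can share an identical junction string (same first 16 and
last 15 nt). Such records are experimentally indistinguishable at the
junction, so they are merged into a single *collision class* that is counted
once and reported with all member ids; silently keeping duplicates would
double-count every matching read.

## Counting model

The detection criterion is exact containment of the full 31-mer (forward or
reverse complement) in either mate of a fragment. This mirrors
pseudoalignment with $k = 31$ against a 31-nt target, where a single k-mer
is the entire evidence, and it implies a minimum overlap of 15 nt on one
side of the backsplice and 16 nt on the other. Matching is implemented with
a constant-width `Biostrings::PDict`; an independent brute-force counter
(`brute_force_assign`, plain substring scanning) applies the same assignment
rule and is used as the test oracle.

Assignment is exclusive and prioritized: junction evidence first (fragments
hitting $\ge 2$ collision classes are counted `ambiguous` and excluded from
class counts rather than fractionally split — deterministic and
conservative); fragments without junction evidence are `linear_assigned` if
either mate (or its reverse complement) occurs verbatim in any linear
transcript; the remainder is `unassigned`. Per-transcript linear abundance
is deliberately not estimated: the linear transcriptome serves only as the
normalization denominator.

With no sequencing-error model, exact matching gives recall 1 for fragments
carrying the full k-mer and zero false junction calls from linear-only
templates (up to the astronomically unlikely chance of a random 31-mer
collision); both properties are asserted in the test suite.

# Enrichment statistics

## Normalization

Counts are normalized as counts per million,
$\mathrm{CPM} = c_i / N \times 10^6$, with the linear-assigned fragment
count as the default library size $N$, and displayed/compared on the
$\log_2(\mathrm{CPM} + c)$ scale. The pseudocount defaults to $c = 1$; it is
configurable and logged, since different DE front-ends choose different
values and the choice matters only for near-zero counts.

## The exact conditional test

RNase R enrichment is tested per feature conditional on its combined count.
If the treated sample(s) contribute a share $p_1$ of the summed library
sizes, then with no enrichment the treated total $a$ out of the feature
total $n$ is $\mathrm{Binomial}(n, p_1)$; the two-sided p-value doubles the
smaller tail (so 40 treated vs 0 control at equal libraries gives
$p = 2 \cdot 0.5^{40}$). This is the same conditioning idea as the exact
tests used for count data in DE packages, but stated in a directly
enumerable form that an independent oracle can verify term by term.

With overdispersion $\phi > 0$ the binomial kernel is replaced by a
beta-binomial with the same mean and intra-class correlation
$\rho = \phi / (1 + \phi)$ (shape scale $\theta = 1/\phi$), which collapses
to the exact binomial as $\phi \to 0$. $\phi$ comes from a deliberately
simple method-of-moments estimator: the median over features of the
group-wise $\max(0, (s^2 - \mu)/\mu^2)$ on library-size-scaled counts. This
estimator needs several degrees of freedom per group to be near-unbiased
(the median of $\phi\,\chi^2_{m-1}/(m-1)$ shrinks toward 0 for small group
size $m$); with duplicate libraries it is only a Poisson-or-not fallback,
which is why the dispersion-recovery test uses 10 samples per group.

Fold change is the ratio of group mean $(\mathrm{CPM} + c)$, stable at zero
counts; multiplicity is controlled by Benjamini–Hochberg step-up FDR; the
enrichment call uses a fold-change cutoff of 2.0 (boundary inclusive: FC
exactly 2.0 passes) and FDR < 0.05. qPCR confirmation data are summarized by
the $2^{-\Delta\Delta C_t}$ method relative to a linear housekeeping gene.

# The survival screen

For each expressed circRNA (default filter: nonzero expression in $\ge 25\%$
of samples — the threshold is configurable because "expressed" is rarely
defined identically across cohorts):

1. patients are split at the **median** of log2 expression; ties at the
   median go to *low* (deterministic; no optimal-cutpoint search);
2. a two-group **log-rank** test compares the arms, with the Kaplan–Meier
   product-limit curves as the display;
3. a univariate **Cox** fit on the high-vs-low indicator (partial
   likelihood, Newton–Raphson, Efron ties) supplies the hazard ratio
   $\mathrm{HR} = e^{\hat\beta}$ with Wald CI, so the HR describes exactly
   the contrast the KM display shows;
4. classification: `worse` iff $\mathrm{HR} > 1$ and log-rank $p < 0.05$;
   `better` iff $\mathrm{HR} < 1$ and $p < 0.05$. The raw p-value is the
   screening criterion (as is conventional for survival screens); BH
   q-values are reported alongside but not used for the call.

Follow-up is truncated at 120 months (events beyond the cap are censored at
the cap) for the ten-year RFS analysis. Covariate adjustment (age, grade,
molecular subtype) is available as a flag and reported alongside the
univariate HR rather than replacing it. Since the median split depends only
on ranks, the classification is invariant to strictly monotone transforms
of expression — a property the tests assert.

KM, log-rank and Cox computations are delegated to the `survival` package;
the tests check them against hand-computed product-limit rationals, a
permutation-null log-rank, a closed-form four-patient partial-likelihood
optimum, and the identity between the Cox score test at $\beta = 0$ and the
log-rank statistic in the absence of ties. Perfect separation (monotone
partial likelihood) is flagged and the HR reported as unbounded rather than
as a spuriously huge number.

# Network assembly

The ceRNA logic is pure set algebra, and that is the point: the upstream
predictors (miRNA binding-site algorithms, target-filter tools, RBP
databases) are consumed as TSV contracts, not wrapped. A circRNA–miRNA pair
survives only if predicted by **both** algorithms (ids matched
case-insensitively with any `hsa-` prefix stripped); a triplet
$(c, m, g)$ is emitted iff $m$ is an intersected prediction for $c$, $m$ is
upregulated upon knockdown of $c$ (consistent with sponge release), $(m, g)$
is in the target table and $g$ is downregulated. Dropping any filter can
only enlarge the triplet list (monotonicity, asserted in tests). Venn
partitions are computed over all $2^n - 1$ disjoint regions and always sum
to the union. Bundled fixture tables reproduce the reported
pairs for circ_0001522 / circ_0001278 / circ_0001801; the per-circRNA RBP
assignment in `rbp_interactions_synthetic.tsv` and the miRNA→gene map in
`targets_synthetic.tsv` are synthetic stand-ins (marked so in their file
names) that encode the published shared-RBP set and key targets without
claiming the full database content.

# The synthetic-data generator

## What it emulates

* a transcriptome mixing circular and linear molecules with uniform-random
  sequence, lengths uniform on `length_range` (default 300–1500 nt) and
  within-class relative abundances from a symmetric Dirichlet with
  concentration 5 (moderate variability, CV ≈ 0.45 — enough spread to be
  non-trivial without starving any transcript of reads);
* paired-end 2 × 75 bp fragments (FR orientation, fixed 50 nt inner
  distance). Circular templates are drawn with wrap-around — the sequence is
  tiled and a start position uniform on the circumference is chosen — so a
  mate spans the backsplice with probability $(\ell - 1)/L$ for read length
  $\ell$ and circumference $L$, and *contains* the full 31-mer with
  probability $(\ell - 31 + 1)/L$;
* RNase R treatment as a reweighting of sampling mass: linear mass divided
  by `depletion_factor`, circular mass multiplied by `circ_retention`,
  renormalized. Applying the effect to weights rather than per-read
  rejection makes the expected enrichment exactly the depletion factor,
  which the analytic tests exploit. The untreated circular share of read
  mass is `circ_frac` (default 0.05, reflecting the minor circRNA fraction
  of rRNA-depleted libraries); the effective depletion magnitude of RNase R
  is biologically uncertain, so it is an explicit free parameter (default
  50) rather than an asserted literature value;
* a survival cohort (default 96 patients, the typical FFPE cohort size)
  with Gaussian log2 expression (mean 5, sd 2), proportional hazards
  $h_i = h_0 \exp(\sum_f \beta_f z_{fi})$ on z-scored log2 expression,
  exponential event and censoring times, and administrative censoring at
  120 months. Defaults $h_0 = 0.015$/month and censor rate 0.003/month give
  a realistic ten-year event fraction (~75–80%) for an aggressive-disease
  cohort. Age, grade and subtype are drawn effect-free so they can serve as
  adjustment covariates without confounding the planted truth.

Seeds are explicit everywhere (`with_seed` restores the caller's RNG
state), and identical seed + configuration gives byte-identical FASTA/FASTQ
/TSV output.

## What it does not emulate

No sequencing errors or quality-score variation (constant Q40), no fragment
-length distribution, no FFPE degradation or GC bias, no shared sequence
between circRNAs and their linear hosts (host/circle ambiguity is therefore
untested), no correlation structure between features in the cohort. Passing
tests demonstrate the *logic* of the pipeline under its stated model — exact
matching, conditional testing, proportional hazards — not robustness to the
noise of real libraries; with error-free reads, exact 31-mer matching is
lossless, whereas on real data it trades sensitivity for specificity.

# Numerical choices and degenerate inputs

* Two-sided exact p doubles the smaller tail and caps at 1; features with
  zero total count get $p = 1$, $\log_2\mathrm{FC} = 0$.
* Beta-binomial tails are computed by direct summation of the pmf via
  `lchoose`/`lbeta`; dispersions below ~1e-6 are numerically
  indistinguishable from the binomial.
* RC-folding of the k-mer index uses the lexicographic minimum of a
  junction and its reverse complement as the canonical key; classes sharing
  a key after folding are merged with a logged message. An RC-palindromic
  junction (possible only at even k) contributes a single key.
* Median ties go to "low"; constant expression vectors are flagged
  degenerate and excluded from the screen.
* Cox fits with $|\hat\beta| > 15$ or exploding standard errors are treated
  as separation and reported unbounded.
* Reads shorter than k cannot carry junction evidence and are counted
  unassigned with a summary warning.

# Problem sizes in the test suite

The tests run the full pipeline at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances while remaining quick to execute: 1000
random transcripts for junction-construction exactness, 50 simulated read
sets of 1e3–1e4 fragments for the counting oracle, a 2e5-fragment
treated/control pair at depletion factor 50 for enrichment recovery
(expected mean $\log_2\mathrm{FC} = \log_2 50 \approx 5.64$), 2000 features
for test calibration, and 50 cohorts of n = 500 for Cox hazard-ratio
recovery. The same computations, re-run from scratch, are what
`scripts/acceptance.R` reports.

# Known limitations

* The enrichment engine is an exact conditional test, not a quantile-
  adjusted negative-binomial fit; with many replicates and strong
  biological variability a dedicated DE package is preferable.
* Linear assignment is membership, not abundance: transcripts sharing
  sequence are not disambiguated, and the library size is a single number.
* The screen tests one feature at a time; no multivariable feature
  selection, time-varying covariates or competing risks.
* Collision classes make junction-identical circRNAs inseparable by design;
  reports carry all member ids so downstream interpretation can take this
  into account.
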