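# circscreen

Backsplice-junction quantification and prognostic screening of circular
RNAs (circRNAs) from bulk RNA-seq, for transcriptomics researchers who want
a transparent, fully testable implementation of the standard circRNA
biomarker workflow.

## The science

circRNAs are covalently closed transcripts produced by backsplicing. Their
body is shared with the linear host transcript, so in short reads the only
identifying sequence is the **backsplice junction (BSJ)**: for a circRNA
sequence *s* of length *L*, the junction is the last 15 nt ligated to the
first 16 nt,

    j = s[L-14..L] || s[1..16]        (31 nt — exactly one k-mer at k = 31)

`circscreen` covers the computational workflow around this construct:

* **juncref / juncquant** — builds the 31-nt junction pseudo-reference
  (identical junctions merged into collision classes) and counts a
  fragment as junction-derived iff either mate contains the exact 31-mer
  (forward or reverse complement); fragments matching two classes are
  reported ambiguous, fragments found verbatim in a linear transcriptome
  are `linear_assigned` and form the normalization denominator.
* **destats** — CPM / log2(CPM+c) normalization, replicate correlation, an
  exact conditional binomial (optionally beta-binomial) test for RNase R
  enrichment with BH-FDR, enrichment calls at fold-change ≥ 2.0 and FDR <
  0.05, and 2^-ΔΔCt summaries for qPCR confirmation. Under the null the
  treated total *a* of a feature total *n* is Binomial(*n*, *p₁*) with *p₁*
  the treated share of library sizes; the two-sided p doubles the smaller
  tail.
* **survscreen** — per-circRNA ten-year relapse-free-survival screen:
  median dichotomization, Kaplan–Meier curves, log-rank tests, Cox hazard
  ratios (via the `survival` package); `worse` iff HR > 1 and p < 0.05,
  `better` iff HR < 1 and p < 0.05, follow-up capped at 120 months.
* **netreport** — circRNA–miRNA prediction intersection (a pair counts only
  if both algorithms predict it), ceRNA triplet assembly
  (circRNA → sponged miRNA → de-repressed target), circRNA–RBP edge lists
  and Venn partitions.
* **simdata** — a seeded generator for mixed circular/linear
  transcriptomes, paired-end 2 × 75 bp read sets with a tunable RNase R
  depletion effect applied to sampling mass, and proportional-hazards
  survival cohorts (default 96 patients) with planted ground truth.

## Worked example

```r
library(circscreen)

cfg <- sim_config(n_circ = 8, n_linear = 12, length_range = c(300, 800),
                  n_reads = 50000, circ_frac = 0.05, depletion_factor = 50,
                  seed = 101)
tx  <- simulate_transcriptome(cfg)
ref <- build_junction_reference(tx$circ)
idx <- build_kmer_index(ref)
ctrl <- assign_reads(simulate_read_set(tx, treated = FALSE)$reads, idx, tx$linear)
trt  <- assign_reads(simulate_read_set(tx, treated = TRUE)$reads,  idx, tx$linear)
ctrl; trt
#> sample_counts [control]: 50000 fragments; 334 junction, 47589 linear, 0 ambiguous, 2077 unassigned
#> sample_counts [treated]: 50000 fragments; 5495 junction, 13786 linear, 0 ambiguous, 30719 unassigned
```

RNase R divides linear sampling mass by 50, so junction reads jump from 334
to 5495 while the linear denominator collapses. The exact conditional test
recovers that enrichment per circRNA:

```r
counts <- cbind(control = ctrl$junction_counts, treated = trt$junction_counts)
et <- enrichment_test(counts, c(ctrl$linear_assigned, trt$linear_assigned),
                      factor(c("control", "treated"),
                             levels = c("control", "treated")))
head(et[, c("feature", "mean_cpm_control", "mean_cpm_treated",
            "log2fc", "q", "call")], 4)
#>            feature mean_cpm_control mean_cpm_treated log2fc q     call
#> 1 hsa_circ_0000001             1366            74496   5.77 0 enriched
#> 2 hsa_circ_0000002              777            39098   5.65 0 enriched
#> 3 hsa_circ_0000003              357            21761   5.92 0 enriched
#> 4 hsa_circ_0000004              252            18497   6.19 0 enriched
mean(et$log2fc)      # ~ log2(50) = 5.64, the planted depletion factor
#> [1] 5.88
```

The survival screen recovers a circRNA planted with a 2.5-fold hazard in a
96-patient cohort (HR is the high-vs-low Cox estimate; p is the log-rank
test):

```r
co <- simulate_cohort(cohort_config(n_patients = 96, n_features = 100,
                                    effect = c(feat_0007 = log(2.5)),
                                    seed = 303))
st <- survival_screen(co$expr, co$clinical)
st[st$feature == "feat_0007", c("feature", "n_low", "n_high", "hr", "p", "class")]
#>     feature n_low n_high   hr       p class
#> 7 feat_0007    48     48 7.08 2.1e-12 worse
table(st$class)
#> better     ns  worse
#>      4     92      4
```

(The remaining `worse`/`better` calls are the expected ~2.5% false
positives per direction of a raw p < 0.05 screen over 100 null features.)

A thin command-line wrapper for the shell-run steps (simulate / build-ref /
quantify) is installed at `inst/scripts/circscreen`.

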