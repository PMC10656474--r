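# panrep — phage-display biopanning repertoire analysis

`panrep` analyses in vivo phage-display selection campaigns of VHH
(nanobody) libraries read out by paired-end amplicon sequencing. It is
written for groups who pan a diverse single-domain antibody library against
sorted immune-cell subtypes across several biopanning rounds (BP0–BP4) and
need to go from raw MiSeq read pairs to a ranked, subtype-annotated list of
candidate binders.

The package covers the full chain:

* **Simulation** — a stochastic generator of the whole experiment: a naive
  library with realistic CDR loops (CDR3 length median 18 aa, range 1–36),
  planted binders with lognormal affinity multipliers κ, multinomial capture
  and noisy amplification per round, and paired FASTQ reads with a
  position-dependent substitution-error model. Ground-truth tables make
  every downstream stage testable.
* **Read processing** — quality-aware overlap merging of read pairs, length
  and quality filtering, primer excision, and scaffold-anchored FR/CDR
  annotation of the reconstructed VHH (conserved Cys/Trp/Cys anchors and the
  `[WF]GxG` J-motif); partial records are dropped.
* **Repertoire statistics** — clonotype tables with deterministic ordering,
  top-clone / rare-clone clonality summaries, Shannon and Simpson indices,
  Hill numbers *D<sub>q</sub>* = (Σ p<sub>i</sub><sup>q</sup>)<sup>1/(1−q)</sup>,
  exact hypergeometric rarefaction and Chao1-style extrapolation.
* **Enrichment & selectivity** — clone tracking across rounds, a
  late-over-early enrichment filter
  (p<sub>BP3</sub>+p<sub>BP4</sub>)/(p<sub>BP1</sub>+p<sub>BP2</sub>) with
  pseudocounts, a clones × subtypes selectivity share matrix (rows sum
  to 1), venn-style overlap sets, and Sanger-vs-NGS concordance at the CDR3
  level.

See the methods vignette
(`vignettes/biopanning-repertoire-analysis.Rmd`) for the model, every
default, and known limitations.

## Worked example

Simulate a small campaign (1,000 clones, 5 planted binders per sorted
subtype, 1,000 read pairs per sample), run the full pipeline, and look at
the CD11c stream:

```r
library(panrep)
cfg <- pipeline_config(simulation_config(
  n_clones = 1000, n_binders_per_subtype = 5, reads_per_sample = 1000,
  capture_size = 5e4, n_replicates = 1, seed = 42))
res <- run_pipeline(cfg)
res
#> panrep pipeline run (seed 42): 25 samples
#>   reads: 25000 total, 24740 complete VHH
#>   enrichment: 28 clone(s) pass in >=1 subtype

subset(res$report$diversity, subtype == "CD11c",
       c(round, n, s_obs, d1, percent_unique))
#>  round   n s_obs         d1 percent_unique
#>    BP1 991   495 265.643763      49.949546
#>    BP2 987   179  24.011166      18.135765
#>    BP3 987    50   8.613890       5.065856
#>    BP4 986    46   7.412386       4.665314
```

Of 25,000 simulated read pairs, 24,740 merge, pass the length/quality
filters and annotate as complete VHHs. The CD11c stream shows the expected
selection signature: the effective number of clonotypes (`d1`, the Hill
number of order 1) collapses from ~266 after BP1 to ~7 by BP4, and the
percentage of unique VHHs falls from 50% to below 5%.

The enrichment filter and selectivity matrix then rank candidates:

```r
head(res$enrichment[["CD11c"]][, c("late_count", "enrichment_ratio",
                                   "passes_filter")], 3)
#>  late_count enrichment_ratio passes_filter
#>          10         5.514485          TRUE
#>          51         2.741418          TRUE
#>          40         2.566462          TRUE
```

Each passing clone gets a share-of-total row across the five sorted
subtypes (rows sum to 1; `selectivity_score` is the winning share). Against
the simulator's ground truth, 25 of the 28 passing clones are planted
binders and all 25 planted binders are recovered.

A thin command-line wrapper (`inst/scripts/panrep`) exposes the same steps
as `simulate`, `annotate`, `tabulate`, `diversity` and `run` subcommands.

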