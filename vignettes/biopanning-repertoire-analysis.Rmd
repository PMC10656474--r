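---
title: "Methods: simulated in vivo biopanning and VHH repertoire analysis"
author: "panrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated in vivo biopanning and VHH repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrep)
```

## The problem panrep addresses

In vivo phage-display selection of single-domain antibodies (VHH,
"nanobodies") injects a highly diverse library into a tumor-bearing animal,
recovers phage bound to sorted immune-cell subtypes over several rounds of
biopanning (BP0–BP4), and reads each round out by paired-end amplicon
sequencing. The analysis questions are always the same: which clones exist
in each sample and at what abundance, how fast does the repertoire's
diversity collapse under selection, which clones are genuinely enriched by
late rounds, and which of those are selective for one cell subtype rather
than sticky everywhere.

panrep implements that entire analysis chain, plus a stochastic simulator of
the selection experiment itself. Real phage-display sequencing data of this
kind are rarely public; the simulator provides ground-truth libraries,
selection dynamics and paired FASTQ reads so that every downstream stage is
testable end to end, with known answers.

## The selection model

A library of $N$ clones starts at frequencies $f_i$ drawn lognormal and
normalized. Each clone has a capture weight ("affinity") per cell subtype:
background $1$ for non-binders, and a multiplier $\kappa_i$ drawn
lognormal($\ln 8$, $0.3$) for planted binders. One biopanning round for
subtype $s$ is

1. **capture**: a multinomial draw of `capture_size` phage with
   probabilities $\propto f_i \,\kappa_{i,s}$;
2. **amplification**: captured counts perturbed clone-wise by
   $\exp\{\mathcal N(0, \sigma_a)\}$ and renormalized.

The input pool for round $r+1$ is the amplified *bulk* (CD45) pool of round
$r$; the five sorted subtype streams are measurements of that lineage, not
lineages themselves. Because the bulk CD45 pool physically contains the
target cells, a planted binder's capture weight is elevated in the bulk pool
as well as in its own subtype stream — without this, selection could not
compound across rounds at all.

Sequencing replicates are modeled as independent multinomial read draws from
the same captured pool (library-prep replicates of one selection lineage).
Modeling per-animal lineages would fork the ground truth per replicate and
make recovery bookkeeping ambiguous, so it is deliberately out of scope.

### Generator parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_clones` | 5,000 | clones | desk-scale stand-in for a $10^9$-clone library |
| `abundance_law` | lognormal(0, 1) | — | heavy-tailed naive abundances |
| `cdr3_length_law` | see below | aa | median 18, support 1–36 |
| `cdr1_length_range`, `cdr2_length_range` | 6–10, 5–9 | aa | typical VHH loop lengths |
| `n_binders_per_subtype` | 20 | clones | sparse true binders, disjoint across subtypes |
| `affinity_law` | lognormal($\ln 8$, 0.3) | fold | order-of-magnitude capture advantage |
| `amplification_noise_sd` | 0.15 | log-scale | per-round clone-level amplification bias, CV ≈ 15% |
| `capture_size` | drawn in $[4\times10^6, 6\times10^7] \times$ `scale_factor` | phage | reported phage recovery range, desk-scaled |
| `reads_per_sample` | 450,000 × `scale_factor` | pairs | study depth, desk-scaled |
| `read_length` | 300 | nt | MiSeq PE300 |
| `seq_error_rate` | $10^{-3}$ | per base | realistic raw MiSeq substitution rate |
| `n_rounds`, `n_replicates` | 4, 3 | — | study design |

`scale_factor` (default 0.01) shrinks capture sizes and sequencing depth
together so a full campaign simulates in seconds to minutes on one core.

The CDR3 length law is a shifted binomial (size 35, p = 17/35, +1) mixed
with 2% uniform mass over 1–36. The binomial core puts the median at 18 aa;
the uniform component reproduces the long observed tails out to lengths 1
and 36, which a pure binomial never visits at realistic library sizes.

The amplification noise level was calibrated jointly with the rest of the
default scenario: at $\sigma_a = 0.15$ the documented selective scenario
(5,000 clones, 20 binders per subtype, seed 1) shows strictly increasing
mean binder frequency across rounds in the tracked stream, which is the
behavior the generator is specified to exhibit. Larger values (≥ 0.3) let
round-to-round amplification noise mask the small late-round increments
that remain once binders dominate the pool.

### Sequencing error model

Substitutions are independent per base with a per-cycle probability that
declines in quality along the read: Phred 38 at cycle 1 down to Phred 22 at
cycle 300, rescaled so the mean equals `seq_error_rate`. The emitted quality
strings encode exactly these per-cycle error rates. This matters for
merging: in the overlapped region the two mates read the same template at
opposite ends of their quality profiles, so quality-aware consensus
genuinely corrects most late-cycle errors, as it does for real data.

## Read processing

**Merging.** Read 2 is reverse-complemented and every overlap of at least
`min_overlap` (20 nt) is scored; the offset with the lowest mismatch rate
wins (ties to the longer overlap), and the pair merges if that rate is at
most `max_mismatch_rate` (0.05). Disagreements resolve toward the higher
Phred value, ties toward read 1. These are conventional short-read merging
defaults; indel-aware merging is out of scope.

**Length window.** `length_filter()` defaults to the 550–850 bp gel window
used when a sequencing library is size-selected from an agarose band. The
simulator's amplicons (primer + CDS + primer) run ≈ 310–460 bp — note that a
600 bp-plus amplicon cannot be overlap-merged from 2×300 nt reads at all, so
any merge-based pipeline implies amplicons below ≈ 580 bp. The pipeline
driver therefore derives its window from the design instead:
`[read_length, 2 × read_length − min_overlap]`.

**Quality.** Merged amplicons with mean Phred < 20 are dropped; the
threshold is declared, not inferred, and configurable.

**Annotation.** The paper-scale alternative here would be a germline-database
aligner (MiXCR against the alpaca IG reference). panrep replaces it with a
single-scaffold anchored annotator: translation in the primer-anchored
frame, FR1 pinned at the start, FR2/FR3/FR4 each placed by a banded ungapped
scan within the admissible CDR-length windows (the substitution-only
equivalent of a semi-global alignment whose CDR segments are free-gap
regions), and four hallmark anchors verified — Cys closing FR1, Trp opening
FR2, Cys closing FR3, `[WF]GxG` opening FR4. A record is complete only if
all anchors match, every framework placement stays under a 20% mismatch
rate, no internal stop codon occurs, no ambiguous residue falls in a CDR,
and the CDR3 length lies in 1–36 aa. Records failing any test are "partial"
and removed, mirroring the removal of partially assembled VHHs. Real-data
use would re-insert a germline aligner at exactly this stage; everything
downstream is unchanged.

**Error-variant collapsing.** Repertoire aligners correct sequencing errors
during clonotype assembly; panrep does the equivalent at the clonotype
level: a minor key within one substitution of a ≥ 20× more abundant
same-length key is absorbed into it (`denoise_clonotypes()`). Without this,
every abundant clone sprays spurious low-count "late-only" clonotypes that
contaminate enrichment calls.

## Repertoire statistics

Clonotype keys default to the full amino-acid sequence; CDR3-amino-acid
keying exists for comparison with Sanger-picked clones, which are matched at
the CDR3 level. Replicates are collapsed by summation before any statistic.

Diversity is reported as Shannon entropy $H$ (nats), Simpson concentration
$\sum p_i^2$, and Hill numbers
$D_q = (\sum p_i^q)^{1/(1-q)}$ with $D_1 = e^H$ — the "effective number of
equally abundant types". Rarefaction uses the exact hypergeometric
expectation $E[S(m)] = S_{obs} - \sum_i \binom{n-x_i}{m}/\binom{n}{m}$
evaluated in log space; extrapolation beyond the observed depth uses the
Chao1 unseen-richness estimate
$\hat f_0 = \frac{n-1}{n} \frac{f_1^2}{2 f_2}$ and its standard depth curve,
capped at $2n$ by convention (configurable). The two branches meet
continuously at $m = n$.

Rank bins (1–10, 11–100, …) and count bins (1, 2–3, 4–10, …) for the
top-clone and rare-clone proportion summaries follow common
repertoire-analysis convention and are configurable; ties in rank are broken
lexicographically so all tables are deterministic.

## Enrichment and selectivity

The enrichment filter operationalizes "enriched in BP3 and BP4 over BP1 and
BP2" as a ratio of summed pseudocounted proportions:
$(p_3 + p_4)/(p_1 + p_2)$ with 0.5 added to every clone's count in every
round, passing when the ratio exceeds 1 *and* the raw BP3+BP4 count reaches
`min_late_count` (2). The pseudocount makes the ratio defined for
round-absent clones, and proportions make it invariant to per-round
sequencing depth. All three constants are exposed in the configuration.
Under a neutral null (all affinities equal) the pass probability is bounded
by 1/2: passing requires strictly greater late than early mass, which by
exchangeability of rounds has probability at most one half — in practice
the realized neutral pass rate is far lower (~0.3) because the late-count
guard removes most drifting singletons.

Subtype selectivity of the filtered clones is the share matrix
$r_{c,s} = a_{c,s} / \sum_{s'} a_{c,s'}$, where $a_{c,s}$ is the clone's
mean pseudocounted proportion over BP3–BP4 in subtype $s$. Rows sum to 1;
the argmax subtype is the assigned specificity, exact ties are flagged
ambiguous and broken toward the input subtype order. Share-of-total was
chosen over row z-scores for interpretability (a z-score mode exists behind
a flag). With disjoint planted binders, a binder of subtype $t$ has expected
share $\kappa/(\kappa + 4)$ in its own column — about 0.67 at $\kappa = 8$ —
so assignment is robust.

## What the validation scenarios show — and what they do not

The package's end-to-end validation scenario is 5,000 clones, 20 planted
binders per sorted subtype, $\kappa \sim$ lognormal($\ln 8$, 0.3), four
rounds, one sequencing replicate of 4,500 read pairs per sample, seed 1.
At those sizes the full pipeline runs in about half a minute; the test
suite asserts binder recovery precision and recall against their 0.9
targets within three binomial standard errors, and ≥ 90% correct subtype
assignment of recovered binders.

Two genuine limitations of the late-over-early mass-ratio filter are worth
stating plainly, because the simulator makes them measurable:

* **Chance late occurrences scale with depth while the count guard does
  not.** `min_late_count = 2` filters Poisson noise well at a few thousand
  reads per stratum but admits progressively more drifting non-binders as
  depth (or replicate pooling) grows. At three pooled desk-scale replicates
  precision drops visibly. For deeper data, raise `min_late_count` roughly
  in proportion to depth.
* **Weak binders can enrich early and then lose *relative* share** to
  stronger binders once non-binders are exhausted (the greatest enrichment
  happens between BP1 and BP2). A clone can be a true binder and still show
  a late-over-early ratio below 1. This caps recall around 0.85–0.9 in the
  default scenario and is a property of ratio-based filters, not of the
  implementation.

The generator emulates: heavy-tailed naive abundances, the observed CDR3
length law, multi-round selection seeded from the bulk pool, per-clone
amplification bias, position-dependent substitution error with matching
Phred values, and synonymous-codon nucleotide diversity beneath shared
amino-acid clonotypes. It does **not** emulate indels, chimeric PCR
artifacts, helper-phage contamination, per-animal biological replicates, or
absolute titers — so passing tests demonstrate the correctness and
calibration of the analysis chain under the stated model, not performance
on any particular real dataset.

## Numerical and determinism notes

* All randomness flows from one integer seed; per-sample substreams derive
  deterministically from (seed, round, subtype, replicate), so outputs are
  byte-identical across reruns and insensitive to sample ordering.
* Rarefaction terms are computed via `lchoose` differences; proportions are
  validated to sum to 1 within $10^{-9}$ everywhere they appear.
* Clonotype ordering is count-descending with lexicographic tie-break;
  merge-offset ties prefer the longer overlap; framework-placement ties
  prefer the smallest offset. Every tie-break is fixed so tables never
  depend on hash order.
* Amino-acid coordinates are 0-based half-open throughout.

```{r quick-example}
cfg <- simulation_config(n_clones = 300, n_binders_per_subtype = 3,
                         reads_per_sample = 300, capture_size = 2e4,
                         n_replicates = 1, seed = 7)
sim <- simulate_biopanning(cfg, emit = "counts")
tt <- sim$truth
sapply(paste0("BP", 1:4), function(r) {
  true_diversity(tt$reads[tt$round == r & tt$subtype == "CD11c"], q = 1)
})
```
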