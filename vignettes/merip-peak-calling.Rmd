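---
title: "Window-based m6A-seq peak calling and target triage with meripr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based m6A-seq peak calling and target triage with meripr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripr)
```

## The problem

MeRIP/m6A-seq measures N6-methyladenosine on mRNA by sequencing an
antibody-enriched library (IP) next to an unenriched input library from
the same fragmented mRNA pool. Methylated regions show IP-over-input
enrichment. `meripr` implements a window-based caller for such data, the
comparison of peak sets between two conditions, the intersection of
condition-unique methylation with differential-expression evidence that
is used to nominate candidate target genes, and the small quantitative
models that accompany such studies (decay half-lives, qPCR relative
expression, caliper tumor volumes, rank correlations).

## The peak-calling model

All scanning happens in *isoform coordinates*: one isoform per gene (the
longest; ties broken by lexicographically smallest transcript id, so
builds are reproducible) is used as the coordinate frame, and aligned
fragments are projected onto it. Working on the spliced mRNA means
windows never straddle introns. Fragment 5' ends are projected
strand-aware and each read is extended to the average fragment size (150
nt by default) along the transcript.

The procedure per gene:

1. **Windows.** 100-nt windows every 10 nt (`window_grid()`). If the
   transcript length is not reached exactly, one extra right-anchored
   window ending at the transcript end is added; transcripts shorter
   than one window get a single full-length window. A fragment counts in
   every window it overlaps by at least 1 nt.
2. **Low-coverage filter.** Windows below 1/20 of the gene's top window
   in *both* IP and input are excluded — a guard against annotation
   inaccuracies at transcript tails. Exclusion removes a window from
   testing, from the normalization medians and from the FDR
   multiplicity. A gene with all-zero coverage in a library counts as
   "low" in that library, so fully silent genes drop out entirely.
3. **Normalization and score.** Counts are normalized by the per-gene
   median over retained windows (`b` for IP, `d` for input; an even
   number of windows takes the mean of the middle pair). The enrichment
   score of a window with IP count `a` and input count `c` is

   $$ES = \frac{a \cdot d}{b \cdot c}.$$

   When either product is zero, 1 is added to all four terms before
   evaluating; this keeps $\log_2 ES$ finite and is pinned by tests.
4. **Test.** A two-sided Fisher exact test on the 2x2 table
   `[[a, A - a], [c, C - c]]`, where `A` and `C` are the gene's total
   retained IP/input counts — window versus rest-of-gene, IP versus
   input. The published procedure names the test but not the table; this
   construction has well-defined integer margins, while the median-based
   quantities enter only the enrichment score. The alternative table
   `[[a, round(b)], [c, round(d)]]` is available as
   `fisher_table = "medians"` for sensitivity checks. The test uses raw
   counts; testing median-normalized counts is the other conceivable
   reading, and the option above exists to probe how much it matters.
5. **FDR.** Benjamini–Hochberg across all retained windows
   transcriptome-wide (the field default; per-gene scope would be the
   alternative). Windows with FDR < 0.01 and $\log_2 ES \ge 1$ are
   positive.
6. **Merging.** Overlapping (≥ 1 nt) positive windows merge into peaks
   per gene. Each peak's ES is recomputed from the counts on the merged
   interval with the same four-number formula (not the maximum of window
   scores), and the minimum window FDR is kept for ranking. Peaks are
   projected back to genome intervals for BED output.

Antisense fragments are discarded during projection by default, matching
stranded library preparation; `stranded = FALSE` disables this for
unstranded data.

### Condition comparison and metagene profile

`unique_peaks()` classifies a peak as *shared* when any peak on the same
gene in the other condition overlaps it by at least 1 nt in isoform
coordinates, and *unique* otherwise; gene-level unique lists feed the
triage. `metagene_distribution()` bins each peak's isoform midpoint into
region-scaled blocks (30 bins for the 5'UTR, 40 for the CDS, 30 for the
3'UTR by default), producing the familiar normalized profile of
methylation along the message; non-coding models are skipped and
counted.

## Target triage

`triage()` intersects four evidence sets after applying the published
cutoffs: the condition-unique methylation gene list (taken as given);
the cell-line expression contrast (|log2 TPM difference| > 0.5, no
p-value rule); and two tumor contrasts (p < 0.05 together with
|log2 fold change| > 0.5). Inequalities are strict, so boundary genes
are excluded deterministically. The p-values are consumed as the
adjusted values their source pipeline produced — the tool never
re-adjusts them, because differential-expression estimation is upstream
of its scope. Genes in all four sets with agreeing expression directions
are called `shared_down`/`shared_up`; discordant four-way members are
reported separately. Symbols are matched case-insensitively after
whitespace stripping; harmonizing symbols across species is the caller's
responsibility and must happen upstream.

## The synthetic-data generator

Every stage is exercisable without downloads. The generator's defaults
describe the package's reference conditions: 50 multi-exon genes (1–8
exons, 1–3 kb spliced length, random strands across five chromosomes, a
10%/60%/30% UTR/CDS/UTR split), negative-binomial background coverage
with a mean of 50 fragments per 100-nt window, dispersion (NB size) 10,
and one planted 150-nt, 8-fold-enriched site per gene. Fragments are
simulated in isoform space and projected to the genome, so splice
junctions are exercised automatically.

Two design points deserve emphasis:

* **Shared coverage propensity.** The per-tile Gamma multiplier that
  makes counts overdispersed is drawn once per 100-nt tile and applied
  to *both* libraries, with independent Poisson sampling on top. This
  models what the overdispersion physically is — variation in abundance
  and fragmentation of the common mRNA pool from which both libraries
  are drawn. Each library's tile counts are marginally
  negative-binomial, while the IP/input split of a window's total
  remains exchangeable under the null, which is exactly the conditional
  model the Fisher test assumes. Had the multipliers been independent
  per library (e.g. strong per-window IP-efficiency noise), window
  ratios would fluctuate beyond the conditional null and no count-based
  test could hold its FDR; that regime is deliberately not emulated, so
  null-calibration results here say nothing about antibody-batch
  variability in real data.
* **Enrichment acts on fragments, not positions.** The IP rate is
  multiplied by the planted fold for every fragment that would *overlap*
  a planted site (its 5' start within `fragment_length - 1` nt upstream
  through the site's end). Windows inside a planted site are then
  enriched by the full fold, and windows within one fragment length of
  its edges partially — mirroring how immunoprecipitated fragments
  carry their methylated site with them.

The evidence-table generator plants `n_down = 10` concordant-down,
`n_up = 3` concordant-up and `n_discordant = 27` direction-discordant
four-way members by default — a 40-member four-way overlap whose
structure mirrors the kind of study the triage logic serves — plus 150
background genes each failing at least one cutoff. The decay generator
produces $y(t) = 2^{-t/t_{1/2}}$ with multiplicative lognormal noise of
a given CV, renormalized to 1 at $t = 0$ as chase experiments are.

What the generator does *not* emulate: sequencing errors and alignment
artifacts, GC and positional coverage bias, isoform mixtures (reads are
generated from the chosen isoform only), antibody off-target binding,
and real inter-replicate variability. Passing tests therefore
demonstrate the correctness and calibration of the computation under its
own model assumptions, not performance on any particular real library.

## Quantitative models

* `fit_half_life()` fits $\log y = \alpha - k t$ by ordinary least
  squares (the fitting procedure behind published half-life panels is
  rarely stated; log-linear OLS is the transparent default), with
  $t_{1/2} = \ln 2 / k$, $R^2$ on the log scale, and
  $se(t_{1/2}) = \ln 2 / k^2 \cdot se(k)$ by the delta method. A
  response-scale single-exponential fit (`method = "nls"`) is provided;
  the two agree as noise vanishes. Non-decaying series return an
  infinite half-life with a flag instead of an error. When replicates
  exist, the default is to fit each replicate and summarize the fits,
  not to fit the replicate means.
* `relative_expression()` is the Livak $2^{-\Delta\Delta Cq}$ method —
  the published assays state only normalization against GAPDH, and
  Livak is the standard reading of that statement.
* `tumor_volume()` is $d^2 D / 2$ in mm^3^.
* `spearman_rho()` uses mid-ranks; for $n \le 9$ the two-sided p-value
  comes from complete enumeration of all $n!$ permutations, above that
  from the normal approximation $z = \rho\sqrt{n - 1}$.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GTF (1-based
  closed) is converted on read, BED is emitted natively. A single
  convention avoids off-by-one drift.
* The Fisher p-value sums support probabilities not exceeding the
  observed one, with the customary 1e-7 relative tie tolerance.
  Internally, tables sharing margins are evaluated as one group (the
  support is enumerated once and shared), so transcriptome-scale runs
  and exhaustive verification sweeps stay fast.
* Zero medians, empty fragment sets, all-zero genes, empty peak lists
  and constant decay series all take defined paths (pseudocounts,
  all-zero counts, exclusion, a warning plus zero density, an
  infinite-half-life flag) rather than erroring.
* `A = C = 0` gives p = 1 by convention.

## Problem sizes used in the checks

The shipped checks run the caller on 50-gene transcriptomes at
background mean 50 across five seeds for recovery (sensitivity ≥ 90%,
precision ≥ 95% against planted truth), 500 null genes for calibration
(at most one called peak), 1000 random multi-exon models for exhaustive
coordinate round-trips, every 2x2 table with grand total ≤ 200 for
Fisher oracle equivalence, 10^4 random vectors for the BH definition,
and 500 replicates for half-life recovery. These sizes are the package's
chosen desk-scale reference conditions; the pipeline itself has no
built-in limits and streams any number of genes.

## Known limitations

* One isoform per gene: methylation on minor isoforms is invisible, and
  reads from them are either projected onto the chosen isoform or
  dropped.
* The caller tests each window against its own gene, so a uniformly
  methylated transcript (no within-gene contrast) cannot yield peaks.
* DEG tables are consumed, never computed; cross-species symbol mapping
  is the caller's responsibility.
* BAM input is out of the core path; convert alignments to fragment BED
  upstream (any standard toolchain works — only chrom/start/end/strand
  are used).
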