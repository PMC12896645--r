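---
title: "Methods: retroviral integration-site resistance screens with retrovis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retroviral integration-site resistance screens with retrovis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screen and its read-out

Retroviral insertional mutagenesis screens exploit the fact that a
replication-defective retrovirus integrates semi-randomly into the host
genome.  Each transduced cell becomes a uniquely barcoded clone: the
integration site both perturbs nearby genes and serves as the clone's
identifier.  After months of drug selection, clones whose integration
confers a growth advantage expand; sequencing the LTR--genome junctions
(VIS-NGS) reads out the clonal composition of every culture.  Candidate
resistance genes are the genes near integration sites that are
reproducibly over-represented in treated cultures relative to untreated
controls.

`retrovis` implements the full post-sequencing analysis — adapter
trimming, locus calling, replicate-concordance filtering, enrichment
statistics, candidate selection, and a single-cell expression validation —
together with a generative simulator so the whole chain is testable
against known ground truth.

# The synthetic-data model

`plant_integrations()` draws clones uniformly over a toy genome with
symmetric-Dirichlet baseline abundances and per-treatment multiplicative
fitness weights (`NC`, the untreated control, is neutral by definition).
`evolve_population()` models selection as discrete passages: at each
passage the expected share of clone $i$ under treatment $t$ is

$$ p_i \;\propto\; a_i \, f_i(t), $$

after which a finite population of $N$ cells is resampled
multinomially, capturing drift at the passage bottleneck.  This is the
simplest generative model that produces enrichment, depletion and
stochastic clone loss; it makes no attempt to model cell-cycle kinetics
or density-dependent growth.  The defaults encode the study conditions:
passages are biweekly splits (two per month), so the default 8 passages
correspond to four months of selection; the population bottleneck
defaults to $2 \times 10^4$ cells, the seeding density of a culture
well.  Selection acts identically in both biological replicates
(pLN1/pLN2), which are independent cultures of the same clone pool.

`simulate_sample()` converts final abundances into junction reads: each
read picks a clone proportionally to abundance, and its alignment
position is the integration point plus a shear-site offset bounded by
`offset_spread` (default 500 bp, on the junction side given by the
clone's orientation).  Because offsets are bounded, the reads of one
clone always fall inside a single 1000 bp merge window — making
clustering correctness decidable from truth.  Mapping quality is drawn
from a mixture (95 % at 60, 5 % uniform below 20 by default) purely to
exercise the MAPQ filter.  Read *sequences* are LTR adapter + random
flank + linker, for the trimming stage; they are not re-aligned, so the
alignment records carry the positional truth.

What the simulator deliberately does **not** emulate: base-call errors
and realistic quality strings, PCR duplicates, chimeric junctions,
mappability structure of a real genome, or cross-sample index hopping.
Passing recovery tests therefore demonstrate the correctness of the
statistical machinery under the stated clonal model, not robustness to
artefacts of real libraries.

The single-cell generator (`simulate_scrna()`) is a zero-inflated
negative-binomial: a gene is expressed in a cell with its population's
probability, expressed cells draw a strictly positive NB count scaled
by a log-normal library-size factor.  It emulates exactly the quantity
the validation tests — the fraction of expressing cells per population —
and nothing else (no dropout--depth coupling, no cell cycle, no batch).

# Trimming

`find_adapter()` is a semiglobal edit-distance search (substitutions
and indels).  A match is accepted when its distance is at most
$\lfloor e \cdot L \rfloor$ with $e$ the error rate (default 0.25) and
$L$ the matched adapter length; `N` matches nothing.  Partial adapter
matches at the appropriate read end are allowed down to a 3 nt overlap,
which mirrors standard amplicon geometry; with a 4-letter alphabet this
admits occasional spurious end matches, the accepted cost of tolerating
adapters running off reads.  Ties are resolved deterministically
(distance, then leftmost start for 5' / rightmost for 3', then longer
adapter part, then span end), and the whole contract is pinned by a
brute-force all-span oracle in the tests.  Reads in which neither the
LTR nor the linker is found are discarded by default, as are reads
shorter than 36 bp after trimming.

# Locus calling and quantification

Alignments with MAPQ below 20 are removed.  `call_vis()` pools the
remaining records across **all** samples and chains sorted positions per
chromosome by single linkage with an inclusive 1000 bp window: a gap of
exactly 1000 bp still merges.  Pooled clustering (rather than per-sample
clustering followed by interval matching) guarantees shared locus
identities across the sample matrix; the inclusive boundary is covered
by an explicit test so the choice stays visible.  Clustering is
orientation-agnostic; per-locus strand tallies are recorded.  The locus
representative is the read-weighted median position, and nearest-gene
distances are measured to the interval boundary (0 inside a gene;
ties go to the smaller gene start, then the lexicographically smaller
name).

`quantify()` normalises read counts per sample to reads per million of
*VIS-assigned* reads (the natural denominator once all loci are called
from the same filtered pool), asserts $\sum_\ell \mathrm{RPM}(\ell, s)
= 10^6$ for every sample with reads, and calls detection at
`min_reads_detect` (default 1) reads.

# The filtering cascade and enrichment tests

Three monotone filters implement the screen's credibility rules, each
logging input/removed/retained counts whose arithmetic is asserted:

1. **Singletons** — loci detected in exactly one sample are random
   integration events.
2. **Replicate concordance** — a locus must appear in both pLN1 and
   pLN2 (any condition).
3. **Treatment concordance** — some single non-control treatment must
   show the locus in both replicates.  Cross-treatment mixing and
   control-only detection do not qualify; this is the stricter of the
   two defensible readings, chosen because the screen treats replicate
   concordance *within* a condition as its surrogate control.

Two complementary tests then compare each locus between a treatment
group and the untreated controls, timepoints pooled within groups:

* **Detection frequency** — a 2×2 Fisher exact test on detected/not ×
  treated/control.  The two-sided p is the probability-mass sum over
  tables with the observed margins (tie tolerance $10^{-7}$ relative,
  the convention of mainstream implementations); a zero margin gives
  $p = 1$.
* **Read-depth coverage** — a pooled-variance two-sample Student
  t-test on RPM, two-sided, with non-detected samples contributing RPM
  0 so group sizes stay fixed and the two tests stay coupled
  (a detected-only variant and Welch's test sit behind switches).
  Degenerate inputs follow explicit conventions: zero pooled variance
  with equal means gives $t = 0, p = 1$; with unequal means $p = 0$,
  flagged degenerate; groups smaller than two are not computable and
  flagged `ns`.

Both tests use the exploratory threshold $p < 0.1$, with $p < 0.05$
marked separately; no multiple-testing correction is applied at this
stage — replicate concordance is the screen's stated control, and the
exploratory tier exists to be permissive.  The nesting
\{significant\} ⊆ \{exploratory\} is asserted as an invariant.

## Candidate selection

A locus qualifies as candidate evidence when either test reaches at
least the exploratory tier for a candidate treatment **with an
enrichment-direction signal** (`enriched` or `exclusive_treated`).
Restricting to enrichment is a deliberate design choice: RPM is
compositional, so when selected clones take over a treated culture
every neutral clone is passively diluted and would show a "depleted"
signal; resistance candidates are the loci that expand, and the
depleted tail is reported in the result tables but does not nominate
genes.  A `directions = NULL` switch restores direction-blind
selection.  Qualifying loci collapse to genes by nearest-gene
annotation (loci without a gene keep their locus id), genes keep their
full locus lists — distinct loci near one gene can behave differently
and remain visible — and `verify_candidates()` categorises each gene by
how many independent verification treatment groups detect any
supporting locus (all / one-or-two / none).

`summarize_partitions()` does the cascade bookkeeping (totals,
exclusions, per-category tallies) and errors on any inconsistent
identity, so every reported count is arithmetically closed.

# Single-cell validation

For candidate genes with single-cell data, cells are CPM-normalised
(zero-count cells excluded with a warning; per-cell CPM sums to $10^6$,
asserted), a cell is positive at CPM ≥ 1 (inclusive boundary, covered
by a test), and the parental vs resistant positive fractions are
compared by the Pearson chi-squared test on one degree of freedom
without continuity correction (Yates behind a flag; zero margins give
$p = 1$).  Bonferroni correction multiplies by the number of genes
*actually tested* in the run, not the full candidate count — genes
without usable annotation in the expression data never enter the
family.  Symbol matching is case-sensitive through an explicit,
auditable alias map.  `concordance()` labels each gene `consistent`,
`opposite`, or `not_in_screen` by comparing the RNA direction with the
pooled detection-fraction direction of the gene's supporting loci.

# Numerical and interface conventions

* Coordinates are 0-based half-open internally and in BED; SAM output
  is 1-based as the format requires.
* Every stochastic entry point takes a single integer `rng_seed`;
  top-level simulations split it hierarchically into per-sample child
  seeds (all below $2^{31}$), so fixed seed + fixed inputs give
  byte-identical outputs, asserted down to file digests.
* Conservation tolerances are $10^{-6}$ absolute on the $10^6$-scale
  RPM/CPM sums and $10^{-9}$ on abundance sums.
* Fisher enumeration is compared against an independent
  binomial-coefficient oracle to $10^{-12}$ for all tables with
  $n \le 24$.

# Problem sizes used in the test-suite

The suite exercises the full study geometry once — 41 discovery samples
(19 controls, 15 fulvestrant, 7 ribociclib), 300 clones with 12 + 6
planted at fitness 1.6, $5 \times 10^4$ reads/sample — and otherwise
uses reduced fixtures (tens of clones, a few thousand reads) chosen so
each property is still decidable; the single-cell recovery runs 20
seeds at the full 2000 + 2000 cells over 30 genes.  These sizes are the
package's chosen test conditions, stated here so that reported
recovery rates are reproducible.

# Known limitations

* The simulator's clonal model has no read-error or duplicate
  structure, so trimming and MAPQ filtering are exercised on synthetic
  noise only.
* Candidate selection inherits the compositional nature of RPM;
  absolute abundance changes are not identifiable from this assay.
* The coverage t-test treats RPM as approximately normal within
  groups; with few samples and many zeros this is a coarse
  approximation, which is why it is paired with the exact frequency
  test rather than used alone.
* No false-discovery-rate control is applied in the discovery phase by
  design; downstream verification and expression validation carry that
  burden.
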