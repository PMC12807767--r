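---
title: "The ACTG haplotype nomenclature: model, statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ACTG haplotype nomenclature: model, statistics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actghap)
```

# The model

A phased, full-length assembly of a gene region carries every variant of
one haplotype in a single contiguous sequence. `actghap` decomposes that
sequence, against a single transcript model per gene (MANE-style), into
nested levels:

* **A** — the encoded protein (amino-acid sequence up to the first stop);
* **C** — the spliced coding nucleotide sequence;
* **T** — exonic non-coding sequence: 5'UTR followed by 3'UTR in
  transcript order for coding genes, all exons for non-coding genes;
* **G** — the concatenated introns in transcript order;
* **U/D** — optional fields for the 5 kb upstream and downstream flanks.

Within each level, identical sequences across the analysis panel are
clustered and numbered `1..K` in descending global count. Reference
assemblies are ordinary panel rows (one haplotype each), so a reference
genome's haplotype receives a rank inside the same global numbering —
which is what makes cross-assembly comparisons (`a1` on one assembly,
`a10` on the other) directly readable. Zero is reserved for
"non-applicable": non-coding genes render `a0c0`, a disrupted reading
frame renders `a0` while keeping its C-level id, intronless transcripts
render `g0`, and a gene with no annotated UTRs has no T sequence.

Composite codes (`a1c2`, `a1c2t2`, `a1c2t2g2`) are concatenations of the
*independently ranked* per-level ids — clustering happens within each
level, not per parent branch. A nested (per-parent) renumbering is a
defensible alternative reading of the hierarchy; we did not implement it
because global per-level ranking keeps ids stable under the addition of
deeper levels and makes the id of each level meaningful on its own. U/D
ids are carried in the data model but never rendered in canonical code
strings, since flank variation is an optional annotation, not part of
the gene-body identity.

## Translation disruption

A haplotype's protein is reported only when its reading frame is intact
*relative to the reference model*: a CDS length change not divisible by 3
is a frameshift; loss of the reference ATG is a start-loss; an in-frame
stop before the final codon is a stop-gain; a missing terminal stop
(when the reference has one) is a stop-loss. Any of these forces the
A-level to 0 rather than clustering truncated or nonsense products; a
`cluster_truncated` switch restores clustering of stop-gain products for
users who want allele-series resolution. Anchoring disruption detection
to the reference model (rather than absolute rules) keeps models whose
annotation lacks a stop codon from flagging every haplotype.

# Variant filtering: the homopolymer-calibrated VQV

Long-read assemblies are accurate except for indels in homopolymer
tracts. Each candidate variant gets a quality value from a calibration
table indexed by (contig, base, homopolymer run length); run lengths are
measured independently on the reference context and on the
variant-applied context, and the *lower* of the two QVs is converted to a
per-contig error probability `p = 10^(-QV/10)`. Under an error-only null
in which each of the `covering` panel contigs shows the allele
independently with probability `p`, the chance of seeing at least the
observed `supporting` count is the upper binomial tail, and

$$\mathrm{VQV} = -10\log_{10}\Pr[X \ge \text{supporting}],\qquad
X \sim \mathrm{Binomial}(\text{covering},\ p).$$

Retention is `VQV >= 100` for A/C variants (error probability at most
1e-10) and `VQV >= 50` for T/G/U/D (at most 1e-5); both boundaries are
inclusive. Three design points deserve note:

* the Phred pairing (100 ↔ 1e-10, 50 ↔ 1e-5) uniquely forces the
  `-10 log10` transform;
* we use the **upper** tail `Pr[X >= k]`: "at least as many supporting
  contigs by chance" is the natural extremeness ordering under an
  error-only null;
* all variant types are filtered through the same machinery —
  substitutions simply carry run-length-1 contexts; a
  `vqv_indels_only` switch restricts filtering to indels for users who
  want to mirror a frameshift-focused cleaning step.

`covering` defaults to the panel size (the number of haplotype contigs
at the locus); it is a parameter because per-sample and per-panel
covering are both defensible and the calibration's provenance decides
which is appropriate.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `flank` | 5000 | bp | window of contig trimming and of U/D variant recording; a separate 7000 default is reserved for cross-assembly anchoring contexts (not used in core paths) |
| VQV thresholds | A/C 100, T/G/U/D 50 | Phred | printed retention boundaries (1e-10, 1e-5) |
| tie-break | lexicographic | — | equal-count clusters need a deterministic, input-order-independent rule; the sequence string is the only canonical key |
| min QTL group size | 3 | samples | below this a rank-sum test is meaningless; undersized contrasts are skipped with a reason, not zero-filled |
| QTL test | Wilcoxon rank-sum (two-sided) | — | robust for boxplot-style group contrasts of normalized expression; Welch t available |
| fold change | mean ratio `mean(b)/mean(a)` | — | median ratio available; neither is canonical |
| subsampling | 200 haploids × 100 replicates | — | the standard control for unequal per-gene sample sizes |

No multiple-testing correction is applied by default (significance
tables are reported across a grid of raw `-log10 p` cutoffs);
Benjamini–Hochberg can be applied downstream by the user.

# The synthetic generator: what a green test establishes

The generator is first-class, tested code that emulates the *stated
world* of a desk-scale panel:

* `make_gene_model` builds a gene whose CDS is ATG + leucine (CTG)
  codons + TAA, with codon-aligned homopolymer tracts in the CDS and
  first intron. CTG bodies make third-base changes synonymous and
  second-base changes missense by construction, so planted variants have
  known levels.
* `make_panel` realizes a frequency spectrum exactly
  (largest-remainder apportionment), defaulting to 30 haploids over a
  decreasing 4-cluster spectrum (0.50/0.25/0.15/0.10) — a desk-scale
  stand-in for a few-hundred-genome panel in which the rarest cluster
  still has ≥3 carriers.
* `inject_homopolymer_errors` corrupts contigs with single-base indels
  at per-run-length rates (defaults 1e-3 at run 4 rising to 2e-2 at run
  8, emulating homopolymer-length-dependent consensus error) and emits
  the *matched* calibration, `QV = -10 log10(rate)`; untabulated
  contexts get QV 50, a typical consensus base quality for
  high-fidelity assemblies.
* `make_cohort_and_expression` draws diploid cohorts from catalog
  frequencies and adds `baseline + beta × dosage + N(0, sd)` expression
  in three unequal panels (150/100/90 samples by default, echoing the
  shape of real lymphoblastoid expression panel trios).

What it does **not** emulate: real read error profiles, assembly or
phasing failures, structural variation, recombination, linkage between
genes, population structure, or expression covariates. A green
end-to-end test therefore establishes that the *algorithmic pipeline* is
faithful — calling, classification, filtering, ranking, statistics — not
that the defaults reproduce any genome-wide figure from real data.
Genome-wide percentages printed for the real 258-genome release
(e.g. cover-ratio fractions per level) require the original data and are
out of scope by design; `release_summary_counts` carries the printed
summary tables so their internal arithmetic can be checked.

# Numerical and degenerate-case choices

* Coordinates are 0-based half-open internally; GFF3/BED/SAM/TSV
  convert at the boundary. This removes off-by-one ambiguity from all
  interval arithmetic.
* Indels are VCF-normalized: parsimony-trimmed to one anchor base and
  left-aligned against the reference (verified against a brute-force
  leftmost-representation oracle).
* `VQV` is computed on the log scale (`pbinom(..., log.p = TRUE)`), so
  tail probabilities far below double precision (e.g. 1e-300) still map
  to finite VQVs.
* A variant whose reference span straddles a region boundary is flagged
  `splice_unmodeled` and assigned conservatively (A if CDS is touched,
  else G at an intron boundary); no splice-consequence prediction is
  attempted.
* Chao1 uses the classical estimator `S_obs + f1^2/(2 f2)` and switches
  to the bias-corrected `S_obs + f1(f1-1)/(2(f2+1))` when `f2 = 0`
  (avoids division by zero); both forms are available because the
  appropriate variant is a judgment call.
* Length-normalized z-scores use the sample standard deviation; zero
  variance across genes is an error, not a silent zero.
* A gene annotated with a UTR on only one side keeps a shorter T
  sequence; `t0` is reserved for genes with no exonic non-coding
  sequence at all. Treating partial absence as absence would conflate
  genuinely UTR-less genes with asymmetric annotations.
* Genes missing from a sample contribute no haplotypes; ranks are based
  on raw counts, not proportions, so no denominator adjustment is made.
* Seeded routines (`subsample_median_count`, all generators) scope the
  RNG locally and restore the caller's `.Random.seed`.

# Limitations

* One transcript per gene is the analysis unit; alternative transcripts
  are supported only as separately prefixed codes, never merged.
* The calibration-table estimation procedure itself is out of scope: the
  package consumes a table and the generator emits a matched one, with
  no claim that the simple rate-to-QV mapping reproduces any production
  calibration pipeline.
* No cross-release id liftover: version tags are metadata and ids are
  reassigned per release.
* Copy-number-variable loci are not given per-copy ids.
* The QTL layer consumes already-normalized expression and fits no
  covariates.
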