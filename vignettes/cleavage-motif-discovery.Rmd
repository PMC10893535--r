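---
title: "Mapping endoribonuclease cleavage motifs from coverage profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endoribonuclease cleavage motifs from coverage profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cleavemap)
```

## The problem

Type II toxin–antitoxin systems pair a stable toxin with a labile antitoxin.
Many of the toxins, the MazF family among them, are ribosome-independent
endoribonucleases that cleave single-stranded RNA at a short specific
sequence (three to seven bases depending on the host organism).  Determining
that recognition sequence is the central characterisation step for a new
MazF homolog: it decides which cellular transcripts are plausible targets
and which fluorometric probes will report the enzyme's activity.

`cleavemap` implements the sequencing-based workflow for that determination.
A defined mixture of synthetic RNA substrates is partially digested by the
enzyme; cleavage exposes 5′ ends that are ligated to a known 45-nt RNA
barcode; after size selection and library preparation, reads beginning with
the barcode testify to genuine cut positions.  Mapping those reads back to
the known substrate sequences produces a per-position coverage profile
whose upward steps mark cleavage sites.

## The RCI statistic

The site-calling statistic is the **relative coverage increase**,

$$\mathrm{RCI}(n) \;=\; \frac{c(n)}{c(n-1)},$$

where $c(n)$ is the read coverage of position $n$ (positions are 1-based,
sense strand).  When $c(n-1) = 0$ the ratio is undefined and the RCI is
defined to equal $c(n)$ itself; position 1 takes $c(0) = 0$, so
$\mathrm{RCI}(1) = c(1)$.  A cleavage-generated 5′ end produces a step in
coverage and therefore a large RCI at the first base downstream of the cut:
if the backbone is cut between positions $s$ and $s+1$, the called site is
$s+1$, and by the window convention used throughout the package the cut lies
between window offsets $-1$ and $0$.

The $K = 10$ positions with the highest RCI, pooled across all substrates,
are retained, and the 11-base windows centred on them are stacked into a
position frequency matrix (PFM).  Per-offset information content is
$2 + \sum_b f_b \log_2 f_b$ bits ($0$ for a uniform column, $2$ for an
invariant one; no small-sample correction).  The consensus core is the
maximal contiguous run of offsets at or above the core threshold that
contains offset 0, read off by column majority.  Consensus positions whose
majority frequency falls below 0.9 are flagged *low-consistency* and become
the targets of the verification probe series.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `K` | 10 | sites | top-RCI sites pooled across substrates |
| `window_w` | 11 | nt | window width centred on each site |
| `min_fragment_len` | 200 | nt | size-selection threshold |
| `barcode` | packaged 45-mer | – | 5′ ligation barcode |
| `max_barcode_mismatches` | 1 | subst. | barcode prefix matching |
| `max_mismatches` | 3 | subst. | full-read mapping tolerance |
| `min_match_len` | 30 | nt | shortest mappable read |
| `min_depth` | 5 | reads | depth floor before RCI ranking |
| `core_threshold` | 1.0 | bits | consensus core membership |
| `low_consistency_threshold` | 0.9 | frequency | weak-position flag |

Two of these deserve comment.

**Depth floor.** The raw ratio $c(n)/c(n-1)$ is violently unstable at
depths 0 and 1: a single stray read lands a position an RCI of 1/0 → 1 or
2/1 → 2, and a background-breakage position covered by one barcoded read
would outrank a genuine site.  Positions with $c(n) <$ `min_depth` (default
5 reads) are therefore ineligible for ranking.  The threshold is
configurable because the appropriate floor scales with sequencing depth.

**Core threshold.** With only ten windows, the information content of a
*nonconserved* column has substantial sampling mass well above zero: a 7/10
majority already scores 0.64 bits and a 5/5 two-letter split scores exactly
1.0, while truly motif-determined columns sit at or near 2 bits.  The core
membership threshold is set at 1.0 bits, which cleanly separates the two
regimes at this window count and excises the six-base core from the 11-base
window on the emulated experiments; both thresholds remain configurable for
deeper site sets, where smaller values become usable.

## What the simulator emulates — and what it does not

`simulate_library()` generates the full study design in code: eight
substrates of 1000/1500/2000 nt carrying 2–4 planted, non-overlapping
UACAUA sites (placed ≥ 250 nt apart and ≥ 220 nt from the ends so that
size selection cannot silently delete a site's fragment), partial digestion
at 70% per site per molecule, cleavage between the U and the first A,
uniform nonspecific breakage at $10^{-4}$ per position, exclusion of
fragments under 200 nt, barcode ligation at 80% efficiency, and 50,000
single-end 150-nt reads sampled from the fragment pool with a 0.1%
substitution error rate.  Sample sizes and rates that the study design
fixes (substrate count and lengths, site motif and cut position, the 200-nt
threshold, the 45-nt barcode) are taken as given; depth, read length,
ligation efficiency and error rate are not printed anywhere and are set to
values typical of a MiSeq amplicon-scale run (50k reads, 150 nt, 80%, 0.1%).

The generator deliberately does **not** model reverse-transcription bias,
adapter chemistry, indels, quality-score structure, or sequence-dependent
breakage.  Passing tests on simulated libraries therefore demonstrate that
the statistic and its implementation recover planted signal under realistic
depth, partial digestion and substitution noise — not that the pipeline is
robust to every artefact of a real library preparation.  Ground truth
(planted positions, fragment origins) travels in substrate annotations and
read ids only; no pipeline stage reads it.

## Read assignment

References here are short, known, synthetic sequences, so mapping uses a
bespoke exact-seed assigner instead of an external aligner: the first 20
bases of a read are looked up in a hash of all substrate 20-mers, and every
candidate position is scored over the full read allowing up to
`max_mismatches` substitutions (no indels, T ≡ U).  Reads with no
acceptable position, or two equally good distinct positions, are discarded
— the discard rules are explicit and tested rather than inherited from an
aligner's defaults.  A read whose seed contains a sequencing error is lost
(about 2% of reads at the default error rate), which costs depth but never
mis-places a read.

## FRET verification

The probe set for a called motif is the consensus insert plus, for each
low-consistency position, the three single-base substitutions at that
position — for UACAUA with weak positions 1, 4 and 6, ten probes in total.
Each probe is the RNA insert flanked by five deoxyadenosines on either
side, 5′ 6-FAM, 3′ BHQ-1 ("DR-" + insert).

Cleavage kinetics are modelled as pseudo-first-order dequenching,
$F(t) = F_0 + A\,(1 - e^{-kt})$ plus Gaussian noise, the classical form for
single-turnover separation of fluorophore from quencher.  The classifier
averages replicates and compares the *baseline-subtracted rise* (endpoint
mean minus first-timepoint mean) of each reaction against its no-enzyme
control: a probe is called cleaved when its rise is at least
`fold_threshold` (default 2) times the control rise, with the control rise
floored at a first-difference estimate of the control noise so that pure
noise cannot clear the bar.  Working on rises rather than raw endpoint
means keeps verdicts invariant under affine rescaling of the recorded
intensities (gain and offset are instrument properties, not chemistry); the
noise floor inherits the same invariance because first differences are
offset-free.  The rate $k$ is estimated by Levenberg–Marquardt least
squares against the exponential model; a failed fit is reported as NA and
flagged rather than silently dropped.  No numeric threshold for "notable
increase" is asserted as the original experiment's — the fold threshold is
an exposed parameter.

## Motif prevalence in coding sequences

`scan_cds()` counts (possibly overlapping) motif occurrences on the sense
strand of each CDS — MazF attacks single-stranded transcripts, so the
antisense strand is irrelevant, and UACAUA cannot overlap itself, so the
overlap rule is moot for the headline motif.  The expectation attached to
each gene is a zeroth-order composition null declared by this package: with
per-CDS base frequencies $f$, a motif of length $m$ matches a window with
probability $p = \prod_j f_{m_j}$, the expected count is $(L - m + 1)p$,
and the enrichment p-value is the Poisson upper tail
$P(X \ge \text{observed} \mid \lambda = E)$.  The per-CDS (rather than
genome-wide) null is the conservative local choice for a genome of high,
heterogeneous G+C content; a genome-wide-frequency mode and
Benjamini–Hochberg adjustment are available behind flags, and no
multiple-testing correction is applied by default because the headline
output is occurrence counts, not significance calls.

## Pairwise protein comparison

The alignment utility wraps Needleman–Wunsch global alignment with affine
gaps (BLOSUM62, gap open 10, extend 0.5 — the community defaults for
pairwise protein comparison) and reports percentages under the EMBOSS
conventions: identity is identical columns over the full alignment length
including gap columns, similarity is columns with a positive substitution
score (identities included).  Under these conventions a gap-free
120-column alignment with 78 identical and 103 positively scoring columns
prints as exactly 65.0% identity and 85.8% similarity — the only integer
column counts that do.

## Numerical and degenerate-input choices

* Coverage is full-read depth computed by a difference-array accumulation;
  depth sums always equal total mapped bases.
* RCI ties in top-K selection break deterministically: higher depth, then
  substrate id, then smaller position.
* Sites whose window would overhang a substrate end are skipped with a
  logged warning — this also disposes of the spurious RCI spike at
  position 1, where the zero rule makes RCI(1) = depth(1) under the
  full-length 5′ ends of undigested molecules.
* All-N PFM columns are flagged unusable and excluded from the core;
  consensus ties resolve in A < C < G < U order with a logged warning.
* Empty read sets, zero barcoded reads, all-zero coverage and zero-length
  CDSs raise explicit errors rather than propagating NaN.
* Every stochastic stage takes an integer seed; derived child seeds stay
  within 32-bit range, and seeded reruns are byte-identical.

## Problem sizes used in the test suite

Unit tests run on reduced libraries (hundreds to a few thousand reads, two
or three substrates) chosen so each property is still decisively exercised;
the end-to-end recovery checks run the full study-scale configuration
(eight substrates, 50,000 reads) across 20 seeds, which completes in a few
minutes.  The prevalence scan's published-table check ingests the printed
31-gene table as a fixture and, separately, reproduces the group structure
from sequence alone on a 60-gene synthetic CDS set with 31 single-site
genes — scanning the original annotation requires the archived genome
release it was computed from and is inherently version-sensitive.

## Known limitations

* The consensus model is a single ungapped PFM — no mixtures, spaced
  motifs, or degenerate IUPAC consensus.
* Windows are weighted uniformly in the PFM, not by RCI magnitude.
* Mapping tolerates substitutions only; indel-containing reads are lost.
* The FRET simulator abstracts instrument photophysics; verdicts depend on
  a configurable fold threshold, not a physical model of quencher escape.
* High-enzyme off-target activity (weak cleavage of near-cognate probes)
  is not modelled quantitatively.
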