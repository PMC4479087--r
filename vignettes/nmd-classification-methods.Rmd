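---
title: "Methods: NMD-susceptibility classification and downstream RNA-seq interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMD-susceptibility classification and downstream RNA-seq interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdscope)
```

## Scope and model

`nmdscope` implements the interpretation layer that sits downstream of read
alignment, expression estimation and splicing quantification. It consumes
four standard artifacts — a GTF annotation, a gene-level two-condition
FPKM/q-value table, GMT gene-set collections, and a splicing-event table
with per-condition ψ and a Bayes factor — and produces NMD-susceptibility
calls, a filtered DE set partitioned by biotype, hypergeometric
over-representation statistics, and a splicing-event summary. It does not
estimate FPKM, q-values or ψ; those are upstream quantities consumed as
inputs (an optional Benjamini–Hochberg step, `bh_fdr()`, is available for
tables that carry raw p-values only).

## Coordinate conventions

All internal coordinates are 0-based half-open; GTF input/output converts
from/to the 1-based inclusive GTF convention at the boundary. Half-open
arithmetic makes lengths and gaps simple differences and removes the ±1
bookkeeping that plagues inclusive intervals. Exons are stored in genomic
(ascending-start) order for both strands; transcript 5′→3′ orientation is
applied in one place, the projection `genomic_to_spliced()`, so every
downstream quantity is strand-agnostic by construction. The spliced
position of an exon–exon junction is defined as the offset of the last
exonic base 5′ of it, in transcript orientation.

## The NMD susceptibility rule

A transcript with a resolvable stop codon is prone to nonsense-mediated
decay when at least one of three conditions holds, all measured along the
mature mRNA:

| rule | condition | boundary |
|---|---|---|
| `LONG_UTR3` | 3′UTR length ≥ `utr3_min_bp` | inclusive, default 1250 bp |
| `UTR3_INTRON` | ≥ 1 intron entirely within the 3′UTR | — |
| `DOWNSTREAM_JUNCTION` | a junction > `junction_min_nt` past the stop | exclusive, default 50 nt |

The 3′UTR is the set of exonic bases strictly 3′ of the stop codon's last
base; a junction's distance is its spliced offset minus that reference
offset. The boundary asymmetry (≥ 1250 but > 50) is deliberate and is
pinned by dedicated sharpness tests on both sides of both thresholds.

**Rule separability.** Any junction downstream of a stop codon implies an
intron downstream of the stop, so a naive reading of "intron in the 3′UTR"
would subsume the 50-nt rule entirely and make the junction-distance
threshold inert: a single junction 30 nt past the stop would already flag
the transcript through the intron rule, and prone status could never flip
at the 50-nt boundary. We therefore define a 3′UTR intron as one whose
*upstream flanking exon* is itself entirely untranslated. The boundary
intron — the one directly following the stop-bearing exon — is governed
solely by the junction-distance rule. Under this definition the three rules
are logically independent, each can be the unique trigger of a prone call,
and the classifier's behaviour at both thresholds is sharp. The biological
cost is that a transcript whose only NMD-relevant feature is a single
junction ≤ 50 nt downstream of the stop is called not-prone — consistent
with EJC displacement by the terminating ribosome at short distances, which
is the rationale for the 50-nt rule in the first place.

**Stop-codon resolution.** GTF dialects disagree on whether the CDS
includes the stop codon. When explicit `stop_codon` features are present
they win (their union defines the stop, supporting codons split across
exons). Otherwise the CDS 3′ end is used: with `cds_includes_stop = TRUE`
(default, Ensembl-style) the stop's last base is the CDS's last spliced
base; with `FALSE` the stop occupies the 3 spliced bases after the CDS, and
a CDS ending within 3 bases of the transcript end renders the transcript
non-evaluable. Transcripts with neither CDS nor stop codon (non-coding
biotypes) are reported with `evaluable = FALSE`, never prone, and kept in
the output so denominators remain auditable.

**Gene aggregation.** A gene is prone when at least one of its transcripts
is (`policy = "any"`); this is the weakest defensible lift from RNA-level
features to gene-level counts and is made explicit rather than buried. An
`"all"` policy is available.

## Differential expression and biotypes

Fold change is case FPKM / control FPKM, computed literally: with the
default pseudocount of 0, case-only expression gives `Inf` (counted as
upregulated) and 0/0 is undefined — such records are excluded from DE and
their count is attached to the result as an attribute rather than silently
dropped. A user-set pseudocount shifts both numerator and denominator. The
filter keeps genes with q ≤ 0.05 and fold change strictly > 1.5 or
strictly < 0.67 (q-boundary inclusive, fold-change boundaries strict — a
direct transcription of the cutoff's wording). The biotype breakdown
reports counts and percentages of the DE set, collapsing pseudogene
sub-biotypes into one `pseudogene` category by default (the GRCh37.75
vocabulary is much finer than the categories one reports); the collapse map
is a plain named vector a user can replace. DE fractions are reported
against two denominators — all annotated genes and all detected genes
(nonzero FPKM in either condition) — because the choice materially changes
the headline percentage and input tables do not say which was meant.

## Over-representation

`hypergeom_overrep(k, K, n, N)` is the upper tail P(X ≥ k) of the
hypergeometric distribution, evaluated through R's log-space tail
(`phyper(k − 1, K, N − K, n, lower.tail = FALSE)`), which is numerically
stable at genome-scale arguments; k = 0 returns exactly 1. The test suite
checks it against two independent oracles: draw-by-draw enumeration of all
C(N, n) subsets for small universes, and exact binomial-coefficient tail
sums (exact in double precision) for every valid (K, n, k) with N ≤ 20.
Sets and query are intersected with the universe before any counting. The
default universe in the pipeline is the detected genes; no multiple-testing
correction is applied across disease sets by default (per-set p < 0.05 is
the reported criterion), with BH across sets behind a flag. Identifier
matching is case-insensitive by default with an optional offline synonym
map; no network lookups ever happen.

## Splicing events

Events pass when Bayes factor > 10 (strict; `Inf` passes, the
overwhelming-evidence convention of MISO output), |Δψ| > 0.2 (strict;
signed mode available), and informative reads ≥ 20. The read floor is a
deliberate surrogate for the upstream quantifier's per-event coverage
thresholds, which cannot be reproduced from a summary table; it is
configurable and documented as such. Summaries report counts and
percentages over the five-type vocabulary (SE, A3SS, A5SS, ALE, AFE) plus
the distinct-gene count.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, with planted
truth recorded alongside:

* `generate_annotation()` builds transcripts in spliced space first (5′UTR
  100–300 bp, CDS 300–900 bp, 0–2 junctions upstream of the stop) and then
  lays exons onto the genome with 60–500 bp introns on a random strand.
  Prone transcripts receive exactly one trigger, chosen uniformly: a 3′UTR
  of 1250–5000 bp with no downstream junction; one UTR-internal intron with
  both junctions ≤ 50 nt past the stop (so only the intron rule fires); or
  a single junction 51–500 nt downstream in a < 1250 bp UTR. Non-prone
  transcripts have a < 1250 bp UTR and at most one boundary junction ≤ 50
  nt downstream; a configurable fraction is non-coding. Half the coding
  transcripts annotate explicit stop codons (occasionally split across
  junctions), the other half only a stop-inclusive CDS, so both dialect
  paths are exercised continuously.
* `generate_expression()` plants DE genes at exactly the configured fold
  changes (defaults 2.0 and 0.5) with q in (0, 0.05]; nulls sit at fold
  change 0.9–1.1 with q in (0.05, 1]; control FPKM is log-uniform on
  [1, 100]. Parameter combinations that would make planted genes
  undetectable at the standard cutoffs are rejected at generation time.
* `generate_genesets()` plants one set with an exact overlap against a
  designated query; all other sets are uniform draws from the universe.
* `generate_events()` plants significant events (BF log-uniform on
  (10, 10⁶], a few `Inf`; |Δψ| in (0.2, 0.8]; reads ≥ floor) and nulls that
  each violate one criterion; event types follow a composition vector
  mapped to exact integer counts by largest-remainder rounding, so planted
  compositions are reproduced exactly, not just in expectation.

Each generator call consumes one integer seed driving a single RNG stream
with a fixed generation order, so outputs are byte-identical across runs
and platforms.

What the synthetic data deliberately does **not** model: read-level
sampling noise and its propagation into FPKM/q-value/ψ uncertainty,
overdispersion, correlated transcript structures within genes, overlapping
genes, multi-chromosome annotations, and realistic biotype frequencies.
Passing the planted-truth tests therefore demonstrates that the decision
rules, geometry and bookkeeping are implemented exactly — not that the
thresholds are well-calibrated for any particular real dataset, which is a
property of the upstream estimators, not of this package.

## Numerical and degenerate-input choices

* Thresholds must be positive (classifier) or non-negative (filters);
  violations are configuration errors, not silent clamps.
* An empty DE set is an error in every consumer (breakdown, intersection,
  enrichment) rather than an empty report; pipeline stage errors carry the
  stage name and the underlying message, and no report is written on
  failure.
* Gene sets with no member in the universe yield k = 0, p = 1 and a
  `degenerate` flag instead of being dropped.
* Ties at filter boundaries follow the documented inclusivity exactly
  (q = 0.05 in; fold change 1.5/0.67 out; BF = 10 and Δψ = 0.2 out;
  reads = floor in); tests pin each side of each boundary.
* All tabular outputs are plain TSV and the report is JSON with no
  timestamps, making reruns byte-comparable.

## Problem sizes

The test suite validates the classifier against a brute-force per-base
oracle on 220+ randomized transcripts (1–8 exons, random strand and CDS
placement), the hypergeometric tail on every valid configuration up to
N = 20 plus full draw enumeration at small N, BH adjustment on 1000 random
p-vectors, and end-to-end pipelines on 50-gene fixtures; the acceptance
script runs a 300-gene, 500-event study. These sizes give exhaustive or
near-exhaustive coverage of the discrete geometry while keeping the whole
suite fast enough to run on every change.

## Known limitations

* NMD susceptibility here is an annotation property; actual decay
  efficiency, PTC detection from variants, and uORF effects are out of
  scope.
* Biotype attachment is gene-level; annotations whose transcripts disagree
  on biotype produce a warning and first-transcript precedence.
* The splicing read floor approximates, but is not, the upstream coverage
  filter.
* GFF3 and FASTA inputs are unsupported by design; the rules are purely
  positional and GTF-based.
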