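---
title: "Methods: pseudoexon discovery, interpretation and classification"
author: "pseudoexon maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudoexon discovery, interpretation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoexon)
```

# The problem

A family with a dominantly inherited polyposis phenotype can remain
unsolved after exon-targeted sequencing because the causal variant
lies deep in an intron. Such a variant can activate a cryptic splice
donor (GT) and recruit a nearby upstream acceptor (AG), so that an
intronic segment — a pseudoexon — is spliced into the mature mRNA. If
the insertion length is not a multiple of three, the reading frame
shifts, a premature termination codon (PTC) appears, and the
transcript is typically degraded by nonsense-mediated decay (NMD),
producing a loss-of-function allele. This package implements the
computational path from an affected/unaffected duo genome to that
mechanistic conclusion and its classification.

# Coordinate model

Transcript positions use HGVS coding-DNA notation: `base` is the
1-based CDS position and `offset` places intronic bases relative to
the nearest exon boundary (`+k` after an exon's final base, `-k`
before an exon's first base). Conversions to and from genomic
coordinates are exact, strand-aware inverses, and all out-of-range
input errors rather than clamps.

Numerical choices worth stating explicitly:

* **Intron midpoint ties.** `gToC()` assigns `+` offsets up to and
  including the midpoint and `-` beyond; in an even-length intron the
  two central bases take `+` and `-` respectively, so the `+`/`-`
  counts per intron never differ by more than one. Because a variant
  deep in a long intron may still be named from its donor side (its
  activated donor is what matters), `locateInIntron()` always reports
  the donor-side offset; the pipeline uses it to anchor pseudoexon
  coordinates, while `gToC()` keeps the canonical nearest-boundary
  name.
* **UTRs are out of scope.** The events handled here are CDS-internal;
  negative (`c.-k`) and star (`c.*k`) positions are rejected rather
  than half-supported.
* **Containers.** Exons are held as 1-based closed `IRanges` — the
  native convention of the interval container used throughout — and
  1-based inclusive coordinates are also what GFF3 and HGVS exchange.
  BED12's 0-based half-open convention is translated at the
  `rtracklayer` boundary.
* **Both strands are first-class.** Minus-strand genes mirror offsets
  and reverse-complement extracted sequence; the test suite runs
  strand-mirrored scenarios and expects byte-identical molecular calls.

# Prioritization

Five independent predicates are applied in a fixed order (quality →
panel → frequency → duo → splice) purely for the interpretability of
the survivor funnel; the final candidate set is provably
order-independent and the tests assert it. Defaults:

| parameter | default | rationale |
|---|---|---|
| min DP | 20 | conventional germline short-variant depth floor |
| min alt AD | 5 | guards against stray alt reads |
| VF range | 0.2–0.8 | heterozygous germline expectation |
| max AF | 0.01 (strict `<`) | rare-disease frequency gate |
| splice gate | 0.2 (strict `>`) | screening threshold for delta scores |

The depth/VF cut-offs are conventional heuristics, not derived
quantities, and are deliberately exposed in `filterConfig()` rather
than hidden. A missing population AF is treated as "novel" and kept —
the variant class of interest is precisely the one absent from
population databases. A missing unaffected genotype cannot
discriminate carrier status; such variants are dropped but counted
separately as indeterminate. Multi-allelic records are split before
filtering, with allele depths re-paired and genotypes re-read against
each alternate allele.

Splice delta scores are consumed from a pluggable INFO key (default
`SPLICEAI`, pipe-delimited `ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|...`);
the predictor itself is out of scope, and the maximum of the four
delta scores is the gated quantity.

# Pseudoexon derivation

Both routes of the original analysis exist: explicit boundary input
(when the activated sites are known) and `scanCrypticSites()`
discovery. The boundary convention follows the splicing biology: the
acceptor AG is intronic and ends 1 nt before the first exonized base;
the donor GT is intronic and begins 1 nt after the last exonized base.
Inserted length is the inclusive span, the frame remainder is length
mod 3, and the r. description is
`r.<a>_<a+1>ins<acceptor>_<donor>`.

The scan searches GT dinucleotides within a window (default 300 nt) of
the predicted donor-gain position and AG dinucleotides upstream within
the same window, discards pairs shorter than 20 nt (sterically
implausible pseudoexons), and ranks candidates by
`|length − window/2|`, nearest acceptor first on ties. This ranking is
a documented design choice of this package: how the original analysis
chose among candidate upstream AGs is not stated in the source
material, so the rule prefers mid-sized pseudoexons, which is where
reported exonization events concentrate, and it is configurable.

The protein consequence splices the inserted sequence into the CDS
between the anchor bases and translates from codon 1. Frameshifts are
reported as `p.(<Ref><i><New>fs<k>*)` with `k` counting the novel
residue at the first altered codon as position 1 (standard HGVS fs
semantics); a shifted frame that reaches the transcript end without a
stop is reported as a no-stop outcome, not an error. In-frame
insertions report the inserted peptide and leave the downstream
protein unchanged.

NMD is predicted by the 50-nt rule — PTC at least 50 nt (configurable)
upstream of the last exon–exon junction of the *mutant* transcript,
with the pseudoexon's two new junctions included. The flag is named
`nmdPredicted` deliberately: the rule is a prediction, and in the
motivating analysis NMD was demonstrated empirically by allelic
imbalance, not assumed from the rule.

# RNA assays

The allelic-imbalance statistic is the gDNA-normalised ratio of ratios
`(alt/ref)_cDNA ÷ (alt/ref)_gDNA` at heterozygous exonic markers; the
gDNA denominator cancels locus- and dye-specific amplification bias,
making the statistic scale-invariant (property-tested). Peak areas and
peak heights are accepted interchangeably — source descriptions of
such assays use both — and heteroduplex bands never enter the peak
sets. The default imbalance bound 0.8 (two-sided, strict) classifies a
transcript "reduced by about half" (ratios near 0.5) as imbalanced
with margin.

The completeness test asks whether the normal-length transcript is fed
by one allele only: every gDNA-heterozygous tagging marker must show
exactly one allele in the wild-type-selective amplicon. True phase is
not derivable from `{marker, genotype, observed alleles}` alone, so
phase agreement is checked only when the caller supplies the expected
wild-type-haplotype allele per marker; this keeps the verdict
invariant under ref/alt relabelling, which the tests enforce.

# ACMG evidence engine

The point scheme is taken at face value: exactly five criteria, PVS1
weight 8 and PM2/PP1/PP3/PP4 weight 1, pathogenic iff the sum is ≥ 10
(inclusive). No weights are invented for criteria the scheme does not
use; asserting an unknown criterion without an explicit weight is an
error. Because benign-side evidence has no place in this scheme,
scores below threshold are reported as `not_demonstrated` rather than
as intermediate classes.

`autoAssert()` encodes the loss-of-function argument as this package's
interpretation: PVS1 requires *out-of-frame* + *complete aberrant
splicing* + *predicted NMD* simultaneously — completeness is what
makes the aberrant allele a true null. PM2 follows from an absent or
zero population AF, PP3 from a splice score above the gate, and PP1
(co-segregation) and PP4 (phenotype specificity) are never asserted
without explicit user flags, which the tests verify.

# The synthetic scenario

The generator emulates the study design, not generic variation. Its
defaults are the study conditions: an 8-exon gene whose fifth exon
ends at CDS base 531; a 3200-nt host intron (long enough that the
variant's donor-side offset +1482 is also its canonical
nearest-boundary name) carrying a 56-bp pseudoexon at offsets
+1422..+1477 with the acceptor AG and donor GT immediately outside it;
the A>G variant 5 nt downstream of the donor; a planted splice delta
score of 0.93; NMD efficiency 0.5; 500 background duo variants; 5%
multiplicative log-normal peak noise. The reference codon 178 is TTT
and the first pseudoexon codon ATC, with a TAA planted at
shifted-frame codon 14, so the default consequence is exactly
`p.(Phe178Ilefs14*)` — a deterministic worked example rather than a
lucky draw. An `inFrame` flag plants a 57-bp pseudoexon instead, to
exercise PVS1 withholding.

Construction guarantees, each asserted by tests: the CDS translates
end to end (ATG start, single terminal stop); the donor/acceptor
search window contains no spurious GT (the pseudoexon itself is built
G-free and the window is scrubbed), so discovery mode finds exactly
the planted pair; background variants are drawn across seven deliberate
rejection categories (low depth, bad allele fraction, off-panel,
common, shared, missing unaffected genotype, sub-gate splice score) so
every filter's rejection path is exercised and exactly the planted
variant survives; and all generators are byte-identical under a fixed
seed.

What the generator does *not* emulate: sequencing reads and their
error processes, real splice-site strength (the GT/AG dinucleotides
are positional signals only, with no MaxEnt-like scoring), linkage
structure among background variants, and real genome annotation.
Passing tests therefore demonstrate the correctness of the arithmetic,
the filters, the consequence derivation and the evidence logic — not
the wet-lab performance of the assays or the splice predictor, whose
scores are consumed as annotations. In the same spirit, the published
imbalance ratios (0.57/0.56) are not reproduction targets — the
underlying peak areas were never published — so the assay tests check
parameter recovery instead: across NMD efficiencies
{0, 0.25, 0.5, 0.8, 1.0} the simulated mean ratio recovers
`1 − efficiency` within ±0.03 at 50 replicates.

# Problem sizes and determinism

The test suite runs exhaustive coordinate enumerations over six
transcript models (every exonic and intronic base), a 100-gene
protein-consequence comparison against a naive codon-walk oracle, a
20-seed end-to-end sweep (501-record VCFs each), and the five-point
NMD-efficiency recovery at 50 replicates per setting — sizes chosen to
exercise every code path with comfortable statistical margins while
keeping the default suite in the low minutes on a single core. Every
stochastic step derives from a single integer seed per scenario; the
acceptance script threads its `--seed` through all of them.

# Known limitations

* Only single pseudoexon insertions are modelled — no multi-exon
  events, intron retention, or exon skipping.
* The HGVS surface is the subset these events need (`c.` positions
  with one offset, the `r.` insertion form, `p.` frameshift/insertion);
  delins, inversions and repeat notations are out of scope.
* UTR coordinates and multi-transcript projection are unsupported.
* The duo predicate covers an affected/unaffected pair; trio de-novo
  logic is not implemented.
* The evidence engine implements this five-criterion point scheme, not
  the full ACMG/AMP criterion set or Bayesian point frameworks.
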