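---
title: "Discovering miRNA genes from small RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering miRNA genes from small RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`mirforge` implements a classic small RNA-seq miRNA discovery analysis as a
reusable, tested pipeline. Raw 35-nt reads are quality filtered, stripped of
their 3′ sequencing adapter, cleaned of 5′-adapter ligation artefacts, and
collapsed into unique *tags* with per-library read counts. Tags are mapped to
the genome by perfect full-length match on both strands, categorised against
genome annotation with a fixed priority, and piled up into candidate
expression loci. For each locus the pipeline excises two candidate precursor
windows around the presumptive mature miRNA, folds them, computes
miRNA/miRNA\* duplex metrics, applies a structural filter, and finally calls
known and novel miRNA genes, which are then characterised (isomiR structure,
genomic clusters, paralog families, conservation tiers, sense/antisense
pairs, genomic context).

A first-class synthetic-data generator produces a toy genome with planted
hairpins, decoy non-coding RNAs and library artefacts, together with a
ground-truth manifest, so that every stage of the pipeline can be validated
quantitatively without access to real libraries.

```{r}
library(mirforge)
cfg <- sim_config(seed = 1)
ref <- build_reference(cfg)
sim <- simulate_reads(ref, n_libraries = 3)
paths <- write_simulation(ref, sim, "simulated")
pp <- preprocess_reads(paths[sim$libraries], sim$libraries,
                       adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
res <- discover_mirnas(pp$tags, ref$genome, ref$annotations,
                       ref$ref_matures, seed = 1)
res$report$totals
```

## Preprocessing model

**Quality.** A read passes when its mean Phred score is at least 20 and it
contains no N. Whole reads are accepted or rejected — no end trimming — which
matches how short-insert small-RNA reads are usually handled: with a 16–30 nt
insert inside a 35-nt read there is no room for partial salvage. The
threshold (`quality_threshold`) is shared between the simulator's "failing
read" model and the filter, so the two sides of every test agree on what
"low quality" means.

**3′ adapter.** Clipping uses an ungapped semi-global alignment of the
adapter prefix against every read suffix: the *leftmost* cut point with an
overlap of at least 6 nt and a mismatch rate of at most 10% wins. Gapped
alignment adds nothing at these lengths (a 21-nt adapter in a 35-nt read)
while complicating the cut-point semantics. Reads with no detectable adapter
are discarded — their insert length is indeterminate — and tallied
separately in the stage summary.

**5′ contaminants.** An insert whose 5′ end reproduces a suffix of the 5′
adapter over ≥ 8 nt with at most one mismatch is treated as an
adapter–adapter ligation artefact and dropped.

**Collapse.** Identical inserts are merged within and across libraries into
tags with per-library counts; inserts shorter than 18 nt or longer than
30 nt (the size-selected window) are excluded and tallied. Tags are ordered
by total count, ties broken lexicographically, which makes every downstream
output reproducible byte for byte.

## Mapping and categorisation

Only tags that match the genome **perfectly along their entire length** are
used, on either strand; all loci of each tag are reported. Tags with more
than 20 genomic hits are flagged hyper-repetitive: they stay in the
repeat-category bookkeeping but are excluded from hairpin discovery, and
each retained multi-mapper contributes its full count at every locus (the
hit count is recorded so reports can note the ambiguity).

Each tag receives exactly one category via annotation overlap (≥ 1 bp, any
of its loci) resolved by fixed priority:

> known miRNA > rRNA/tRNA/snRNA/snoRNA (discard) > repeat-associated >
> exon-sense > exon-antisense > intron > intergenic.

Tags in the discard class never enter discovery. Repeat-associated tags
remain eligible — repeat-embedded miRNAs are a substantial catalogue class —
as do exon-antisense tags (antisense hairpins are reported in real
catalogues). Exon-sense tags are likely mRNA degradation, so they are
admitted only when their precursor's folding p-value falls below 0.01.

## Hairpin discovery core

**Pileups.** Overlapping same-strand alignments merge into loci by a linear
sweep; loci longer than 200 nt are split recursively at the deepest coverage
minimum. The locus's *mature guess* is the member tag with the highest total
count (ties: 5′-most on the locus strand, then lexicographic). This pileup
heuristic stands in for scoring individual read starts as Drosha/Dicer
processing sites, which the source method does not operationalise further.

**Excision.** Two windows are excised around the mature guess in transcript
orientation: 10 nt upstream + 70 nt downstream, and 70 nt upstream + 10 nt
downstream, clipped (and flagged) at chromosome ends. Both are always
evaluated; if both pass the filter the lower-MFE window is selected, ties
going to the 10/70 window.

**Folding.** Structures are minimum-free-energy fold predictions at 37 °C
without pseudoknots. The engine sits behind the `fold_rna()` contract; the
default calls ViennaRNA's `RNAfold` in one batched process per call site,
and any `function(seqs) data.frame(structure, mfe)` can be substituted via
`options(mirforge.fold_engine = ...)`. Folding is deterministic; tests pin
reproducibility at 0.01 kcal/mol.

**Duplex metrics.** The star span is inferred from the structure under the
Dicer convention of 2-nt 3′ overhangs: with mature span $[m_1, m_2]$ and
$p(\cdot)$ the pairing partner (extrapolated across unpaired positions from
the nearest paired mature base), the star is $[p(m_2)+2,\; p(m_1)+2]$.
Metrics are then: unpaired bases within the mature and within the star
(counted from the structure over each full span); the maximum bulge, i.e.
the longest run of consecutive unpaired bases on either strand of the
duplex; asymmetry, defined as |unpaired(mature) − unpaired(star)| (the
source method never defines asymmetry; this absolute-difference reading is
the simplest consistent one and is applied uniformly); and a 3′-overhang
flag that is true when each strand's 3′ end extends at least 1 nt past the
partner of the other strand's 5′-most duplex-paired base. A mature that
spans the loop, or whose star span would fall off the precursor or collide
with the mature, is rejected with an explicit reason.

**Structural filter.** A candidate passes when **all** hold, every boundary
inclusive:

| criterion | bound |
|---|---|
| folding energy | ≤ −25 kcal/mol |
| mature and star | on different arms |
| unpaired bases in mature | ≤ 6 |
| unpaired bases in star | ≤ 6 |
| maximum duplex bulge | ≤ 4 nt |
| duplex asymmetry | ≤ 3 |
| 3′ overhangs at both ends | required only when star reads were sequenced |

The overhang criterion is conditional because it is evidence *about* the
sequenced duplex: when no star read exists there is no observed duplex end
to test.

**Folding p-value.** For exon-sense candidates the precursor is compared
with dinucleotide-preserving shuffles of itself (Altschul–Erickson walk):
$p = (1 + \#\{\mathrm{MFE}_{\mathrm{shuffle}} \le \mathrm{MFE}_{\mathrm{obs}}\})/(n+1)$.
The default is $n = 100$ shuffles, making the smallest attainable p-value
$1/101 \approx 0.0099$ — just below the strict 0.01 acceptance threshold.
With 99 shuffles the minimum would be exactly 0.01 and *no* candidate could
ever be rescued under a strict inequality; 100 is the smallest round count
that keeps the published threshold meaningful. Dinucleotide (not
mononucleotide) shuffling is used because MFE is dominated by stacking
energies, which are dinucleotide properties.

## Catalogue layer

**Known calls** require a mature match to a *native-species* reference
mature (≤ 2 mismatches and ≤ 3 nt end shift — sequenced dominant isoforms
frequently differ from database annotations by a shifted end) and at least
2 mature-arm reads in one library. Cross-species reference matches do not
make a locus "known"; they feed the conservation tiers, so a novel locus
with a fly ortholog stays novel (new to this species) but is classified
`ins`.

**Novel calls** require: not known; not annotation-discarded; ≥ 5 reads in
at least **one** library (read strictly per library — "five independent
reads originating from at least one library" — with a pooled mode available
by flag); a passing structural filter; and for exon-sense candidates a
folding p-value < 0.01.

Because the mature and star arms of one hairpin are separated by the loop,
their tags form two disjoint pileup loci, and a well-expressed star arm can
pass the filter on its own (its inferred "star" is the true mature). After
calling, same-strand overlapping precursors are therefore collapsed onto
the locus whose own pileup carries the most reads — the mature arm — which
implements catalogue merging by locus overlap.

Downstream characterisation: clusters are single-linkage chains of
same-chromosome, same-strand loci with inter-precursor gaps strictly below
2.5 kb (polycistronic transcription implies one strand; a strand-agnostic
mode exists); paralog families are the union-find closure of mature/mature
and mature/star similarity links (≤ 2 mismatches); conservation tiers are
`inv-ver` (invertebrate *and* vertebrate evidence), `inv` (non-insect
invertebrate), `ins` (non-native insect), `sw` (native only);
sense/antisense pairs are opposite-strand precursors with ≥ 50% reciprocal
overlap; genomic context resolves by priority TE > exon > intron >
intergenic. Novel loci are named `nov-mir-<n>` in chromosome order, with
`-1`, `-2` suffixes for duplicated names.

## The synthetic-data generator

The generator is the package's study design, not a test fixture, and its
defaults are the conditions under which the pipeline's guarantees are
stated.

**What it emulates.** Planted hairpins are mature (20–23 nt, GC ≈ 0.6) +
AT-rich 8–15 nt loop + near-reverse-complement star carrying 1–2 engineered
mismatches. Every design is folded with the pipeline's own engine and
redesigned until its MFE is ≤ −25 kcal/mol, so planted loci genuinely
satisfy the filter they are meant to probe. The 1–2 mismatch floor (rather
than 0) is deliberate: a perfect-complement stem is a genomic palindrome,
its reads map to both strands, and every such locus would generate a
spurious antisense twin. Repeat-embedded hairpins sit inside
repeat-annotated intervals; decoy rRNA/tRNA loci emit uniformly positioned
degradation fragments; gene models contribute exon/intron annotation and an
exonic mRNA-degradation hotspot each; intergenic noise loci emit 0–4 reads
(background noise is low-abundance by nature, and a "noise" locus that
reached the novel threshold with a valid hairpin would be indistinguishable
from a real miRNA by any sequencing analysis). One optional sense/antisense
pair plants reads on both strands of one hairpin — the reverse complement of
a hairpin is itself a hairpin, which is exactly how real antisense miRNAs
arise.

**Counts and isoforms.** Per locus per library, total reads are negative
binomial (mean 40, dispersion 0.5), giving the heavily skewed abundance of
real libraries. Reads split into loop reads (1%), star reads (5% — star
recovery in tissues is far below mature recovery), and mature isoforms
whose 5′/3′ end offsets are drawn from separate distributions over
−2..+2 nt: 0.90 of the 5′ mass and only 0.60 of the 3′ mass sits at
offset 0, encoding the empirically stronger 3′-end heterogeneity of miRNA
tags. A configurable subset (default 40%) of true miRNAs is copied, with up
to 2 substitutions, into the reference database under the native species
tag plus ortholog tags spanning all four conservation tiers; every fifth
remaining novel locus receives a fly ortholog only.

**Artefacts.** Each insert is extended with the 3′ adapter and truncated to
35 nt; 10% of reads get failing qualities (mean Phred < 20, the shared
definition); 2% become 5′-adapter ligation artefacts; substitution errors
occur per base at 0.005 (no indels, no quality-by-cycle structure — the
generator makes no claim of instrument realism).

**What passing tests do not show.** The simulator draws genome sequence
uniformly at random, so it underestimates the structured background of real
genomes (low-complexity regions, dense repeat families, expressed
structured ncRNAs that resemble hairpins). Recovery and false-positive
figures on synthetic data therefore validate the *mechanics* of the
pipeline, not its specificity on a real transcriptome.

## Numerical choices and degenerate inputs

* Percentages in printed tables are rounded half-up to two decimals
  (`round_half_up()`), matching hand arithmetic on published totals; base
  R's round-half-even would print 52.08 where a reader expects 52.09.
* Precursors shorter than 40 nt auto-fail; sequences shorter than 4 nt
  cannot be dinucleotide-shuffled and error out.
* All tie-breaks are deterministic and documented: mature guess (count,
  then 5′-most, then sequence), dominant isoform (count, longest, 5′-most),
  precursor selection (pass, lower MFE, 10/70 window), tag ordering (total,
  sequence).
* Coordinates are 0-based half-open throughout the tabular interfaces;
  `GRanges` objects use the usual 1-based closed convention internally.
* Validation problem sizes: the unit suite runs on a 1 × 30 kb genome with
  11 planted hairpin loci and 2 libraries; the end-to-end validation uses
  the default study design of 2 × 100 kb, 30 true + 10 repeat-embedded
  miRNAs, 20 rRNA/tRNA decoys and 3 libraries; the p-value null check uses
  200 random 80-nt sequences (precursor scale — at much shorter lengths the
  coarse 0.1 kcal/mol energy grid produces heavy MFE ties that visibly
  discretise the null) with 99 shuffles each.

## Known limitations

* No gapped or mismatched mapping: a single sequencing error unmaps a read.
  At realistic error rates this costs a small, quantified fraction of depth.
* Multi-mapped counts are not apportioned; each locus sees the full count.
* The Drosha/Dicer site model is the pileup mature-guess heuristic; true
  processing-site scoring (as in probabilistic discovery tools) is out of
  scope.
* No target prediction, no cross-library normalisation, no differential
  expression.
* The structural filter's thresholds are the published constants; they are
  exposed as arguments but the defaults are the validated configuration.
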