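---
title: "Methods: small-RNA annotation, differential expression, and degradome target calling in sylvamir"
author: "sylvamir maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA annotation, differential expression, and degradome target calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`sylvamir` implements the complete analysis chain used to characterize
miRNA regulation between the phloem and the developing xylem of poplar:
small-RNA read QC, contaminant removal, hairpin-based miRNA locus
annotation, reads-per-ten-million (RPTM) quantification with a
negative-binomial (NB) differential-expression test, degradome-guided
cleavage-site calling, and hypergeometric enrichment of target genes.
Because the original sequencing libraries are far beyond desk scale, the
package pairs every stage with a synthetic-data generator that plants
hairpin loci, counts, and cleavage sites with known ground truth; the test
suite demonstrates each stage by recovering what was planted.

# Read QC

Reads are 1 x 50 bp, Phred+33. The 3' adapter may be supplied or inferred:
`infer_adapter3()` collects 10-mers at the offsets where an adapter would
start after an 18-30 nt insert, and keeps the most frequent one provided it
occurs in at least 25% of reads. Because every 10-mer *inside* the adapter
is nearly equally frequent, the candidate set (within 90% of the maximum)
is reduced to its upstream-most member under 9-nt overlap chaining — the
adapter's first 10 nt. Trimming truncates at the leftmost occurrence of
that seed with at most one mismatch.

`filter_reads()` assigns every read to exactly one category, testing in a
fixed order: low quality (more than 30% of bases below Q20), high N (more
than 10% ambiguous), 5' adapter contamination (the read starts with the
last 10 nt of the 3' adapter's reverse complement, one mismatch allowed —
the convention chosen because the category is standard but its test is
not), missing 3' adapter, homopolymer (one base at 80% or more of the
trimmed insert; the threshold is configurable and follows common vendor
practice), and insert length outside 18-30 nt. The fixed order makes the
per-category counts additive, so the report satisfies the exact integer
identity `raw = clean + sum(categories)` on every input; this identity is
property-tested on random fixtures and is the same bookkeeping by which
the published library table balances.

One deliberate wrinkle: a read whose adapter is absent is flagged only
when the read is longer than the maximum insert (30 nt). An already
trimmed 18-30 nt read therefore passes through unchanged, which makes
filtering idempotent — re-filtering clean output discards nothing.

# Contaminant removal

Reads matching rRNA, tRNA, or organelle references are removed before
annotation. Matching is ungapped, end-to-end, substitutions only, with a
default budget of one mismatch, on both strands. For 18-30 nt reads this
Hamming criterion is the conventional reading of "one base mismatch
permitted"; the implementation (Biostrings pattern matching) is checked
exhaustively against a full-scan Hamming oracle in the test suite. An
empty reference list is an error: silent pass-through would corrupt the
downstream catalog.

# miRNA locus annotation

Clean unique reads are mapped exhaustively (all end-to-end placements, 0
mismatches by default, both strands); reads with more than 20 placements
are discarded as unassignable repeats. Overlapping placements within 2 nt
on one strand merge into read stacks; each stack's most abundant member
(ties broken lexicographically) is the candidate mature. Multi-mapping
reads contribute their full counts to every stack they hit, the same
family-level accounting used when members share one sequence.

Each candidate window extends the stack 150 nt on each side. The mature is
aligned (global in the mature, local in the window) against the reverse
complement of the window with a wobble-aware scoring matrix: under that
transformation Watson-Crick pairs become identities and the two G:U
wobbles become the directional pairs (G,A) and (T,C), which are scored as
pairings — G:U counts as paired, the standard convention in plant miRNA
annotation. Affine gap costs (opening 4, extension 1) are set low enough
that a genuine internal loop appears as a gap run rather than being
smeared into a mismatch run; this matters because the criteria distinguish
the two.

The duplex criteria audited per candidate are: at most 5 total mismatches
(substitutions plus gapped positions); at most 3 mismatches at
bulge/internal-loop positions — the package's reading of "in the loop
region", since the terminal loop is by definition outside the duplex; no
single internal loop longer than 5 nt (the "large loop" bound, a
configurable default because no numeric bound is conventionally fixed); a
mature of 20-24 nt; a star arm with the canonical 2-nt 3' overhangs
falling inside the window; and a trimmed precursor (duplex span plus up to
15 nt flanks) of at most 300 nt. Loci below 10 reads in every sample are
removed; overlapping same-strand loci are deduplicated keeping the
higher-count one. Known/novel classification allows 2 substitutions and
2 nt of length difference against a family-labelled reference; novel loci
are named `miRN1`, `miRN2`, ... in genomic order.

Secondary structure is assessed on the arm-vs-arm alignment rather than by
thermodynamic folding: every criterion above is expressible on the duplex
alignment, and a folding backend could be slotted in behind the same
interface. A consequence, measured on random sequence, is that the bare
duplex criteria alone admit an appreciable false-positive rate on
arbitrary ~600 nt windows; the synthetic generator therefore
rejection-samples its decoy stacks so they genuinely fail the criteria,
making planted-locus precision a test of the pipeline machinery, not of a
statistical specificity the criteria never claimed.

# Quantification and differential expression

RPTM is `count / total mapped reads * 1e7` per locus and sample. Size
factors are plain median-of-ratios over loci with nonzero counts in every
sample. The DE test is a defined NB Wald test, not a re-implementation of
any specific package: per locus, group means of normalized counts give the
log2 fold change; dispersion comes from method-of-moments on normalized
counts (pooled within groups), floored at 1e-8 and shrunk 50% toward a
fitted mean-dispersion trend (`a + b/mean`), which stabilizes the n=3
regime without empirical-Bayes machinery; the Wald statistic divides the
log2 fold change by its delta-method standard error, with two-sided normal
p-values and Benjamini-Hochberg adjustment across tested loci (all-zero
loci are excluded from the family). A locus with an all-zero group gets a
signed-infinite fold change, a p-value from a +0.5 pseudo-count path, and
a flag. Calls are strict: up means `log2fc > 1.5` and `padj < 0.05`.

Calibration is tested, not assumed: on a null simulation the BH rejection
fraction stays at or below nominal, and at a planted fold change of 8
(mean 200, dispersion 0.05, n = 3 per group, embedded in a mostly-null
study so size factors are identifiable) power exceeds 0.9.

# Degradome target calling

Degradome 5' tags are placed by exact 20-nt prefix match on the transcript
sense strand; each tag's 5' end increments a per-position counter.
Complementarity uses Allen-style penalties: mismatch 1, G:U wobble 0.5,
gap 1 per nt, all doubled at miRNA positions 2-13, with sites above score
7.0 rejected — conventional values, exposed as arguments.
`score_complementarity()` supports a single gap absorbing up to 4 nt of
length difference; transcriptome-wide scanning (`call_targets()`) and the
permutation null both use the identical ungapped seed-anchored scan, so
observed and null sites are scored by the same rule. Cleavage is located
on the transcript base paired opposite miRNA position 10 — the first base
of the downstream fragment.

Site confidence follows the five-tier degradome convention: category 4, a
single supporting tag; 0, the transcript's unique maximum; 1, a tied
maximum; 2, above the average; 3, at or below it. "Average" is the mean
over positions with nonzero tag count: including the zeros of a long
transcript would make category 2 nearly universal, which would defeat the
tier's purpose. The default report keeps categories 0-2, as tiers 3-4 are
conventionally unreliable. Significance is a permutation p-value:
`(1 + #{shuffled miRNAs whose best same-transcript site is at least as
good in both category and score}) / (R + 1)`, with `R = 1000` by default
(200 in the bundled pipeline runs, keeping the end-to-end suite fast at an
attainable p floor of 1/201).

# Enrichment

Term enrichment is the hypergeometric upper tail with BH adjustment. The
rich factor is the number of target genes in a term divided by the number
of annotated genome genes in that term; the universe is all genes with at
least one annotation in the tested ontology, matching that denominator.
Only over-representation is tested. The family utilities partition family
catalogs by the exact group set carrying each family; by default a family
counts for a group only when every member species carries it, with
`mode = "any"` available for presence-in-any-species semantics.

# The synthetic generator

The generator's defaults are the study conditions the package models:
1 x 50 bp reads, three replicates per tissue (developing xylem `X` vs
phloem `P`), the standard small-RNA kit 3' adapter
(`AGATCGGAAGAGCACACGTCT`), NB counts with dispersion 0.1 and planted fold
changes straddling the |log2FC| > 1.5 threshold, and defect-class
fractions patterned on the published per-category bookkeeping (high-N
0.4%, 5' adapter 0.16%, missing 3' adapter 1.7%, homopolymer 0.08%, plus
small low-quality and out-of-range fractions; real libraries additionally
lose roughly 20% of *clean* reads to the 18-30 nt window, which the
generator represents only at reduced scale to keep desk-scale depth
useful). Contaminants are 5% of reads, drawn as exact substrings of the
simulated rRNA/tRNA/organelle references. Desk-scale problem sizes — a
40 kb genome, 8 planted loci, 15 decoys, 4,000 reads per library, 4,000
degradome tags over 30 transcripts — were chosen so the full pipeline and
its property suites run in minutes on one core while leaving every stage
statistically non-trivial.

Planted hairpins are a random arm, its reverse complement with up to 3
substitutions, and an 8-40 nt loop, embedded on a random strand in i.i.d.
uniform background (which minimizes accidental hairpins and makes recovery
a clean oracle). Each planted locus is verified at generation time to pass
the annotation criteria, map uniquely, trim safely (the leftmost 1-mismatch
adapter-seed hit falls exactly at the insert boundary — without this check
roughly one read per thousand would trim at a spurious junction hit), and
sit more than one mismatch away from every contaminant reference. Defect
injection is mutually exclusive per read, so QC category counts are
exactly recoverable. Degradome truth places a perfectly complementary site
for about half the planted matures, each in its own transcript, with 80%
of that transcript's tags starting exactly at the planted cleavage
position.

What the generator does **not** emulate — base-call error models, isomiR
5'/3' heterogeneity, ligation bias, transcriptome-level expression
structure, genuine secondary-structure thermodynamics — bounds what
passing tests show: they certify the correctness and internal calibration
of the algorithms on data satisfying the model's assumptions, not
performance on real libraries.

# Numerical and degenerate-input choices

- Coordinates are 1-based closed throughout (the Bioconductor convention),
  including GFF3 output.
- Stack merging uses `min.gapwidth = 3`, i.e. intervals overlapping or
  within 2 nt merge.
- Representative-read ties break lexicographically; locus deduplication
  keeps the higher total count, then the smaller coordinate.
- `estimate_size_factors()` refuses matrices with no all-nonzero locus
  rather than silently switching to a pseudo-reference.
- Empty inputs (zero loci, zero reads, empty degradome) produce empty,
  well-formed tables end to end; this is tested.
- Determinism: every simulation stage seeds the RNG from the single config
  seed plus a fixed per-stage offset, so identical config and seed give
  byte-identical artifacts and manifest digests.

# Known limitations

No thermodynamic folding; no phasiRNA/hc-siRNA classes; no isomiR
quantification; the DE test is intentionally simpler than shrinkage-based
estimators and is validated by calibration properties rather than by
matching another tool's output; permutation p-values have a resolution
floor of `1/(R+1)` and are not comparable to analytic degradome p-values
computed under other null models.
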