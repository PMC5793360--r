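---
title: "Mapping peptide-spectrum matches to the genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peptide-spectrum matches to the genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptrack)
```

# The problem and the model

A peptide-spectrum match (PSM) assigns a peptide sequence to an MS/MS
spectrum with a search-engine score. To place that peptide on the genome,
`peptrack` walks it through the gene model of the protein it comes from:
the transcript's coding exons are concatenated in translation order
(ascending genomic coordinates on the plus strand, descending on the
minus strand) into a coding-nucleotide axis; protein position `a` (1-based)
with length `l` occupies coding nucleotides `[3(a-1), 3(a-1)+3l)`; those
nucleotides are projected back through the exon structure, split at exon
boundaries and merged where genomically adjacent. The result — an ordered
set of disjoint genomic blocks on one strand — is the peptide's footprint,
from which both output dialects are generated: a spliced SAM CIGAR
(`M` blocks separated by `N` gaps) for proBAM, and the BED12
`blockCount`/`blockSizes`/`blockStarts` triple for proBed.

Assumptions: peptides begin on codon boundaries (they come from a
translated protein, so the reading-frame offset of the first base is
always 0), gene models are colinear on a single chromosome and strand (no
trans-splicing, no circular chromosomes), and translation uses the
standard genetic code (no selenocysteine or read-through handling).
Peptides that would extend past the annotated stop codon are emitted as
unmapped rather than given speculative coordinates.

## Coordinate conventions

All internal coordinates are 0-based half-open. Conversion happens only at
format boundaries: GTF input is 1-based inclusive (starts get 1
subtracted), SAM POS adds 1 on output, BED passes through unchanged. Using
one internal convention eliminates an entire class of off-by-one errors;
the worked examples in the tests pin the boundary conversions.

## Stop codons in GTF input

GTF dialects disagree on whether CDS features include the stop codon.
`build_cds_map()` is tolerant: when a genome is available and the final
codon of the assembled CDS is a stop (TAA/TAG/TGA read in transcript
orientation), the trailing 3 nucleotides are trimmed; otherwise the CDS is
taken as-is. After optional trimming the CDS length must be divisible by
3, or the transcript is rejected as malformed.

## Locating peptides in proteins

When a PSM does not state its protein position, the peptide is located by
exact string match against every protein (I and L distinct, overlapping
occurrences included). Each occurrence yields one mapping, mirroring
multi-mapped reads in BAM: the mapping with the smallest (chromosome,
start) — lexicographic chromosome, then numeric start, a deterministic
tie-break — is primary; the rest carry SAM flag bit 256, and the `NH` tag
counts the distinct loci. Occurrences in different proteins that project
to the *same* genomic locus (e.g. two gene models sharing an exon) are
deduplicated into one record, so `NH` counts loci, not proteins; the
sharing surfaces downstream through gene inference instead.

A peptide that matches nowhere but whose input names a protein and start
position is placed at those coordinates as a single-substitution variant:
peptide type `XG:A:V`, with the reference peptide in `XR` — this is how
variant peptides, which by definition differ from the reference proteome,
retain coordinates.

# The two formats

A proBAM record always carries the 11 mandatory SAM columns and exactly 21
proteomics tags, in a fixed order (`NH, XO, XL, XP, YP, XF, XI, XB, XR,
YB, YA, XS, XQ, XC, XA, XM, XN, XT, XE, XG, XU`). Fixed arity is a design
choice: it makes the record geometry checkable by counting fields.
Unknown values take typed null sentinels: `-1` for integer/float tags
whose genuine values are non-negative, `*` for strings, and `U` for the
single-character peptide-type tag `XG` (SAM forbids `*` as an `A` value).
Two tags are dialect decisions left open by the format's public
description and documented here as such: `XE` is a small integer enzyme
code (0 = trypsin, -1 = unknown) and `XF` is the codon phase of the first
mapped base (always "0" by construction here). `XB` is the signed
monoisotopic mass error in daltons, `charge × (exp_mz − calc_mz)`; its
`-1` sentinel could in principle collide with a true error of exactly
−1 Da, which at the sub-0.01 Da scale of real mass errors is a
measure-zero concern, accepted for the uniformity of the sentinel rule.
The peptide-type alphabet is `N` (canonical), `J` (splice-junction
spanning, set automatically when a footprint has more than one block), `V`
(variant), `D` (decoy), `G` (intergenic), `U` (unknown/unmapped); `ZZ:Z`
is reserved for experimental `key=value` payloads as the extension
mechanism.

A proBed line has exactly 25 tab-separated fields. The BED `score` is
fixed at 1000 and `itemRgb` at "0": both are presentational, browsers
shade by score, and rescaling a search-engine score into 0–1000 would be
lossy — the true score lives in `psmScore`. `thickStart`/`thickEnd` equal
the record span because all of a peptide is coding. The null token for the
13 proteomics fields is `.`; in the `modifications` field `.` is the
explicit "no modifications" value rather than "unknown", and it survives
read/write unchanged. No header line is written by default because
`bedToBigBed` rejects headers; a track line can be prepended on request.
Unmapped PSMs are representable in proBAM (flag 4, `rname *`) but not in
proBed; conversions drop them with a logged count.

Converting proBed back to proBAM necessarily leaves the tags that have no
proBed counterpart (`XL, XI, XB, XR, YB, YA, XN, XT, XE, XF, XA`) at their
null sentinels — the leaner format simply does not carry that
information. This null contract is asserted field-by-field in the tests.
The experimental m/z, by contrast, *is* recoverable in the other
direction: proBAM → proBed recomputes `calcMassToCharge` from peptide,
modifications and charge, and reconstitutes `expMassToCharge` from the
`XB` mass error.

# Target–decoy q-values

For a target PSM with score `s`, the false-discovery-rate estimate at
threshold `t` is `#{decoys ≥ t} / max(1, #{targets ≥ t})`, and the
q-value is the minimum FDR over all thresholds `t ≤ s`, which makes
q-values monotone non-increasing in score. Tied scores share one
threshold, the standard convention that keeps the estimate deterministic.
Higher scores are better by package-wide convention; ascending-is-better
scores must be negated upstream. Decoy PSMs receive no q-value. The
proBed `fdr` field stores this PSM-level q-value (the format's public
description leaves open whether the field is a PSM-level q-value or a
dataset-level threshold; the PSM-level choice is strictly more
informative, since any dataset threshold can be applied to it later).

# Aggregation, gene inference, counting

Peptide-level aggregation groups mapped records by (peptide sequence,
chromosome, strand, block structure) — location is part of the key because
a BED line is location-addressed, so a multi-mapped peptide keeps one
record per locus. The representative is the best-scoring member;
`psm_count`, `best_score` and `best_qvalue` are added. Peptide-level FDR
is *not* recomputed — the best member's q-value is reported — because
aggregating PSM q-values into a peptide-level error rate requires a model
this package deliberately does not impose. Similarly the representative's
m/z (not a combination) is reported for peptide records.

Gene inference assigns a record to every gene one of whose transcripts'
CDS contains all of the record's blocks on the same chromosome and
strand; exactly one gene means "unique", more means "shared". Spectral
counts follow a unique-counts model: a gene's `spectral_count` is the
number of PSMs assigned uniquely to it; shared PSMs appear in
`shared_peptide_count` only. This is the simplest defensible inference
and is documented so that distributed/weighted alternatives can be layered
on later.

# The synthetic data generator

`sim_config()` defaults describe the study conditions: 2 chromosomes of
30 kb, 8 genes with 1–4 exons (introns 50–400 nt), half on the minus
strand, proteins of 80–220 aa, and the last two genes sharing their first
coding exon in frame so that shared peptides genuinely exist. Gene
construction edits the random genome in place: the spliced CDS is forced
to start ATG, internal stops are rewritten, and a terminal TAA is
appended, so the GTF/genome/proteome triple is exactly self-consistent
(the CDS features include the stop codon, exercising the trimming logic).
Tryptic digestion cleaves after K/R except before P, with up to 1 missed
cleavage and a 6–40 aa length filter — ordinary search-engine settings.
500 PSMs are split evenly between targets and decoys (full-peptide
reversal preserving the C-terminal K/R, the standard construction);
scores are Normal(40, 8) for targets and Normal(25, 8) for decoys;
charges are 2 or 3; the observed m/z adds Normal(0, 0.005) Th noise;
5% of targets carry one substituted residue (placed at their source
coordinates with peptide type V); 10% of methionine-containing peptides
get an oxidation. Each generator stage seeds its stream deterministically
from the single configured seed, so identical seeds give byte-identical
outputs.

A note on separation: with the default score distributions (means 40
vs 25, sd 8, equal numbers of targets and decoys) an FDR filter at 0.05
retains roughly half the targets — at 90% target recall the decoy tail
alone puts the FDR estimate near 0.3, so >90% recall at 5% FDR is
arithmetically impossible there. The "high recall under good separation"
property is therefore exercised at parameters that actually satisfy its
premise (means 45 vs 15, sd 5), where recall exceeds 90% robustly across
seeds. The defaults were kept deliberately overlapping because an FDR
machinery is best tested where it has real work to do.

What the simulator does not emulate: real spectra (scores are drawn, not
computed), retention times, isotope patterns, shared peptides between
unrelated genes (sequence space is random, so cross-gene exact repeats
are vanishingly rare — multi-locus mappings are exercised through
constructed cases instead), UTRs (exons equal CDS), and realistic
chromosome scale. Passing tests therefore demonstrate the correctness of
the coordinate arithmetic, the format contracts and the statistical
machinery — not search-engine behaviour on biological data.

# Numerical and degenerate-input choices

* Floating-point fields are serialized with the shortest representation
  that parses back to the identical double (15 significant digits when
  sufficient, 17 otherwise), so write∘read is an exact identity without
  rounding policy.
* Monoisotopic masses only; `calc_mz` is
  `(Σ residues + 18.010565 + Σ modification deltas + z × 1.007276) / z`.
  Modifications are `pos-ACCESSION` tokens resolved against a small
  built-in Unimod subset (acetyl, carbamidomethyl, phospho, oxidation);
  unknown accessions are an error at mass-calculation time, not at parse
  time.
* Adjacent CDS segments separated by a zero-length gap are merged before
  mapping, so no `0N` CIGAR element can be produced.
* Sorting is stable (radix) everywhere; proBAM coordinate sort places
  unmapped records last, matching samtools.
* Degenerate inputs fail with classed conditions (`peptrack_*_error`)
  naming the offending transcript/row/line, and the CLI converts them to
  nonzero exits before any output file is opened.

# Problem sizes

The default test and acceptance runs use the full simulated dataset
(8 genes, 500 PSMs), 1000 random peptides for the per-base mapping
oracle, and 100 random score sets for the q-value properties; the whole
suite completes in well under a minute. These sizes were chosen so that
every stochastic check has enough mass to be meaningful while the
fixtures remain desk-scale.

# Known limitations

GFF3 is not parsed (GTF only); mzIdentML and pepXML readers are out of
scope (the tabular schema and the mzTab PSM section are the input
formats); binary BAM/bigBed encoding is delegated to samtools/bedToBigBed;
protein-level parsimony inference and intensity-based quantification are
not implemented.
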