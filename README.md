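# peptrack

Proteogenomics asks where the peptides identified in a shotgun proteomics
experiment sit on the genome. Answering it requires two things that plain
proteomics formats do not provide: a projection of each peptide-spectrum
match (PSM) through spliced, stranded gene models onto genome coordinates,
and file formats that genome browsers and genomics tooling already
understand. `peptrack` implements both ends for the two genomics-compatible
proteogenomics dialects:

* **proBAM** — a SAM dialect in which each alignment record is a PSM. The
  11 mandatory SAM columns are kept (QNAME is the spectrum identifier, POS
  and a spliced `M`/`N` CIGAR give the genomic footprint, SEQ the
  forward-strand coding nucleotides) and a fixed payload of **21
  proteomics tags** in `TAG:TYPE:VALUE` form carries scores, q-values,
  charge, modifications, protein context, enzyme information and peptide
  type. Output is SAM text that `samtools` converts, sorts and indexes
  out of the box.
* **proBed** — a 25-column BED dialect: the 12 standard BED fields
  (including the BED12 block model for splice junctions) followed by **13
  proteomics fields** (protein accession, peptide sequence, uniqueness,
  genome build, PSM score, FDR, modifications, charge, experimental and
  calculated m/z, rank, dataset, URI). Sorted output is accepted by
  `bedtools` and by the `bedToBigBed` converter; a companion autoSql
  schema is emitted for bigBed typing.

Around the coordinate mapping the package provides the standard
downstream operations: target–decoy q-value estimation
(`FDR(t) = #decoys ≥ t / #targets ≥ t`, q = minimum FDR over thresholds
`t ≤ s`), FDR filtering, aggregation of PSMs into peptide-level records,
gene inference by CDS containment, and spectral counting — plus a fully
synthetic genome/annotation/proteome/PSM simulator with known ground
truth, so the entire pipeline is testable offline.

Audience: proteogenomics tool builders and analysts who need to put
MS-based identifications into a genome browser or intersect them with
genomic annotation.

## Worked example

```r
library(peptrack)

sim <- simulate_dataset(sim_config(seed = 1))      # toy genome + 500 PSMs
res <- map_psms(sim$psms, sim$transcripts, sim$genome,
                meta = list(genome_version = "simg1"))
str(res$stats)
#> List of 5
#>  $ n_psms      : int 500
#>  $ mapped      : int 250
#>  $ unmapped    : int 250
#>  $ multi_mapped: int 0
#>  $ records     : int 500

head(res$probam[res$probam$rname != "*",
     c("qname","flag","rname","pos","cigar","XP","XG","XS","XQ")], 3)
#>        qname flag rname  pos cigar                 XP XG      XS         XQ
#> 1 scan=00001   16  chr1 1177   54M YFAPNTGAVHYTQVRQLK  N 40.9302 0.04411765
#> 2 scan=00002    0  chr1 3031   18M             VILEWR  N 35.1482 0.17368421
#> 3 scan=00003   16  chr2 2470   75M IWSQ...SILSSLSLR    V 24.7317 0.60655738
```

Every simulated decoy fails to map (flag 4, peptide type `XG:A:D`), every
target maps; record 1 is a minus-strand PSM (flag 16) whose 54 nt CIGAR
equals 3 × its 18-aa peptide; record 3 is a single-residue variant (`V`)
placed at its source locus. `XQ` is the PSM-level q-value, so

```r
nrow(filter_by_fdr(res$probam, 0.01))
#> [1] 71
```

keeps the 71 records confidently identified at 1% FDR. Gene-level
inference and spectral counting:

```r
head(spectral_counts(res$probam, sim$transcripts), 4)
#>   gene_id unique_peptide_count shared_peptide_count spectral_count
#> 1      g1                    7                    0             16
#> 2      g2                   24                    0             41
#> 3      g3                   17                    0             26
#> 4      g4                   30                    0             45
```

Writing and converting:

```r
write_probam(res$probam, "out.sam", seqlengths = sim$genome, sort = TRUE)
write_probed(res$probed, "out.bed", sort = TRUE)   # bedToBigBed-ready
emit_autosql("probed.as")
validate_probam("out.sam")                          # character(0) = valid
```

The same pipeline is available from the shell via the bundled executable
(`exec/peptrack`): `simulate`, `map`, `convert`, `validate`, `peptides`
and `counts` subcommands, e.g.

```sh
peptrack map --psms psms.tsv --gtf annotation.gtf --fasta genome.fasta \
         --out-probam out.sam --out-probed out.bed --sort --fdr 0.05
```

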