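# circfleval

Long-read validation of assembled full-length circRNA sequences.

## What this is for

Circular RNAs (circRNAs) are defined by a back-splice junction (BSJ), and
their function depends on the complete internal sequence between the
back-splice sites. Short-read assemblers reconstruct these full-length
sequences, but linear transcripts from the same locus make the assemblies
error-prone — incomplete sequences, skipped exons, retained introns and
outright false junctions all occur. Rolling-circle long reads of the same
sample, which traverse the circle several times, can arbitrate.

`circfleval` is for people benchmarking or quality-controlling circRNA
full-length assemblies. It provides:

* **Rotation validation** — move the first 20 bp of an assembled sequence
  to its end so the BSJ becomes internal, align long reads to the rotated
  reference, and keep a candidate when an alignment has
  `0.8 <= mapped_ratio = M/L <= 1` (M = aligned read bases, L = candidate
  length) and at most 2 bp of mismatch + insertion + deletion.
* **Isoform-set validation** — verify a candidate by BSJ agreement plus
  rotation-invariant sequence identity (cyclic LCS / max length, default
  threshold 0.95) against a reference full-length isoform set (e.g.
  converted isoCirc or CIRI-long output).
* **Ensemble + metrics** — k-of-n combination of strategy verdicts
  (default: at least 2), cross-strategy TP/FP/FN with
  precision = TP/(TP+FP), sensitivity = TP/(TP+FN), F1 their harmonic
  mean, assembly rate A/I, and precision stratified by back-splice read
  support.
* **Structure screening** — classify each exonic candidate against the
  annotated exon chain between its back-splice sites (Type 1: one full
  exon; Type 2: two complete adjacent exons; Type 3: the complete chain of
  three or more) and retain only full-chain sequences.
* **A synthetic-data module** — deterministic toy genome, gene models,
  true circRNA isoforms, rolling-circle reads with an error model, and
  corrupted candidate sets with planted correctness, so the whole pipeline
  is verifiable without downloads.

## Worked example

```r
library(circfleval)

cfg    <- sim_config(seed = 42)           # 20 genes, 60 true circRNAs,
genome <- simulate_genome(cfg)            # error-free rolling-circle reads,
ann    <- simulate_annotation(genome, cfg)  # 60% planted-correct candidates
truth  <- simulate_circ_truth(ann, genome, cfg)
reads  <- simulate_long_reads(truth, ann, genome, cfg)
cands  <- corrupt_candidates(truth, ann, genome, cfg)
table(cands$label)
#>          correct        exon_skip        false_bsj intron_retention
#>               40                4                5                5
#>       truncation
#>                6

rot <- validate_by_reads(cands, reads)     # strategy 3: read alignment
iso <- validate_by_isoforms(cands, truth)  # strategies 1/2: isoform match
ens <- combine_verdicts(list(rot, iso), k = 2)
sum(ens$verified)
#> [1] 40
```

All 40 planted-correct candidates — and only those — survive the 2-of-2
ensemble, so the verified set has precision 1.0 against the planted labels.
Support stratification shows the precision-vs-support trend the support
model plants (the fraction of correct candidates rises with the back-splice
read count):

```r
stratified_precision(cands, ens, thresholds = c(2, 4, 6, 8))
#>    threshold precision     n
#> 1:         2 0.6666667    60
#> 2:         4 0.8611111    36
#> 3:         6 0.9130435    23
#> 4:         8 0.9444444    18
```

Screening the candidates against the annotated exon chains discards every
corrupted candidate and keeps the 40 correct ones:

```r
screen_full_exon(cands, ann, genome)$report
#>    asm_tool n_candidates n_retained n_discarded
#> 1:  sim_asm           60         40          20
```

The same pipeline runs from the command line on files
(FASTA/BED/TSV candidates, FASTQ reads, genome FASTA, GTF):

```sh
Rscript inst/cli/circfleval.R simulate --out fx --seed 42
Rscript inst/cli/circfleval.R evaluate --out ev \
    --candidates-fasta fx/candidates.fa --candidates-bed fx/candidates.bed \
    --candidates-tsv fx/candidates.tsv --reads fx/reads.fastq \
    --genome fx/genome.fa --gtf fx/annotation.gtf \
    --ref-isoforms fx/truth.fa=fx/truth.bed
```

`ev/` then contains per-strategy verdict TSVs, the ensemble table,
metrics (TSV + JSON), stratified precision, structure classes and the
screening comparison, plus the fully resolved run configuration for
reproducibility.

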