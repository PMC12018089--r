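# triplexr

`triplexr` predicts DNA–RNA triple helices: given a DNA duplex sequence and an
RNA sequence (both 5′→3′), it reports every triplex target site (TTS) on the
DNA and the corresponding triplex-forming oligonucleotide (TFO) on the RNA.
It is aimed at researchers studying how nuclear noncoding RNAs — lncRNAs in
particular, but also short RNAs — bind duplex DNA in the major groove without
unwinding it, and who need candidate TFO/TTS pairs for mechanistic follow-up
(probe design, methylation studies, reporter assays).

## The model

A triplex forms when a third RNA strand Hoogsteen-pairs with the purine-rich
strand of a Watson–Crick duplex. Only four canonical base-triplet codes are
admitted, written duplex-pair : third-base with the purine-strand base second:

| Frame                | Orientation   | Codes        |
|----------------------|---------------|--------------|
| Parallel pyrimidine  | parallel      | TA:U, CG:C   |
| Parallel mixed       | parallel      | TA:U, CG:G   |
| Antiparallel purine  | antiparallel  | TA:A, CG:G   |
| Antiparallel mixed   | antiparallel  | TA:U, CG:G   |

The TTS is constrained to an uninterrupted A/G tract on one duplex strand
(both strands are scanned; a C or T terminates the tract rather than counting
as a mismatch). In parallel frames the TFO runs 5′→3′ along the purine
strand; in antiparallel frames it runs 3′→5′ against it. A candidate
alignment of length *L* with *m* code-violating positions has error rate
*m/L*; it is reported when

* *L* ≥ `min_consecutive` (default 7),
* it contains a run of `min_consecutive` consecutive matches,
* *m/L* ≤ `max_error_rate` (default 0.20),
* its first and last triplets are matched,

and it survives two redundancy rules: within one TTS/TFO region only the
longest triplex of a given error rate is kept (shorter ones survive only at
strictly lower error), and continuous sliding matches on repeats are reduced
to the central placement(s). Each hit is reported with 1-based coordinates,
strand, frame, length, error rate, and the percentage of G+U in the TFO (a
composition linked to triplex stability).

Optionally, CpG islands are predicted on the DNA with a running-sum scan
(+17 per CpG step, −1 otherwise; spans qualifying when length > 200 bp,
GC > 50%, observed/expected CpG > 0.6) and hits are annotated with the
overlapping or nearest island.

## Worked example

```r
library(triplexr)

# a synthetic pair with one planted 14-triplet triplex carrying 1 mismatch
fx   <- plant_triplex(seed = 11, tts_len = 14, n_errors = 1)
hits <- search_triplexes(fx$dna, fx$rna)
hits[, c("tts_start", "tts_end", "tts_strand", "tfo_start", "tfo_end",
         "frame", "length", "error_rate_pct", "gu_pct")]
#>   tts_start tts_end tts_strand tfo_start tfo_end               frame length
#> 1         8      21          +        39      52 PARALLEL_PYRIMIDINE     14
#> 2         8      14          +        39      45 PARALLEL_PYRIMIDINE      7
#>   error_rate_pct gu_pct
#> 1          7.143  35.71
#> 2          0.000  42.86
```

The planted triplex (DNA 8–21 against RNA 39–52) is recovered at its planted
error rate (1/14 = 7.14%); the error-free 7-triplet run inside it is reported
as well, because a shorter triplex with a strictly lower error rate remains a
valid result in the same region. `find_cpg_islands()` works the same way on
any DNA record, and `write_report()` produces a TSV plus BED files.

From a shell, the same workflow is:

```sh
Rscript inst/scripts/triplexr --dna dna.fa --rna rna.fa \
    --min-consecutive 7 --max-error-rate 20 --cpg --out results/run1
```

which writes `run1.triplexes.tsv`, `run1.tts.bed` and `run1.cpg.bed`
(`--cpg-only` skips the RNA and predicts islands alone; a `fixtures`
subcommand emits deterministic synthetic inputs with their ground truth).

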