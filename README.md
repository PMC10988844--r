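# renrich

Genome-wide **repeat-element (RE) enrichment analysis** for ChIP-seq and
similar chromatin pulldown experiments, for researchers who want to know
which RE subfamilies and families their pulldown enriches or depletes —
not where individual peaks sit. Reads from repeats are multimapping and
per-locus signals unreliable, so `renrich` aggregates: it counts primary
alignments onto *all* genomic instances of each named RE subfamily, sums
per name, normalises, and compares pulldown against input chromatin.

## What it computes

Given two replicate chip/input pairs (SAM/BAM) and a RepeatMasker BED12
annotation:

1. **Annotation adjustment** — BED12 blocks are expanded to exon
   intervals, and overlapping intervals of identical name are sorted and
   merged (twice); the result is exported as a GTF with `gene_id` = RE
   name.
2. **Counting** — each primary alignment (flags 256/2048 excluded, no
   MAPQ filter, mates independent) increments every distinct RE name it
   overlaps by ≥ 1 bp, once per name.
3. **Enrichment statistics** — per library, densities
   `d = max(count, 0.1) / library_size`; per replicate the ratio
   `e = d_chip / d_input`; across the two replicates

   ```
   Z = |mean(e) - 1| / SD_pop(e),   p = P(N(0,1) > Z)
   ```

   with population SD (n = 2 divisor). For the volcano plot, p-values are
   floored at 1e-16, ranked ascending and adjusted to `p·N/k` (capped at
   1). Family summaries divide summed member densities by family size.
4. **Figures** — a volcano plot (x = log2 fold-change, y = −log10 p,
   colour by FDR ≤ 0.05, grey band at |log2| ≤ 0.5) and top/bottom family
   bar diagrams (Simple_repeat, Low_complexity, Unknown and tRNA excluded
   by default). Every figure ships with a TSV of exactly the plotted
   values.
5. **Validation loop** — a paired-end simulator with ground-truth
   coordinates (toy genomes with planted repeat subfamilies, uniform or
   family-enriched libraries) plus recovery metrics: per-RE relative
   error `200·|Ref − Ana| / (Ref + Ana)` (%), recovery `100·Ana/Ref` and
   Pearson correlation of densities.

Coverage utilities (RPKM tracks in 10 bp bins, ≥ 90% reciprocal-overlap
full-length filtering, strand-aware 50 bp anchored profile matrices) round
out the toolkit.

## Worked example

`demo_run()` builds a 1 Mb toy genome (8 RE subfamilies in 5 families),
simulates two replicate chip/input pairs with a 4× enrichment planted on
the ERV1 family, runs the full pipeline and validates against the ground
truth:

```r
library(renrich)
res <- demo_run(seed = 2, n_pairs = 20000)
#> demo: building toy genome (seed 2)
#> demo: simulated 4 libraries of 40000 reads each
#> demo check [PASS]: truth/analysis closure (mean relative error == 0)
#> demo check [PASS]: truth/analysis correlation r > 0.999
#> demo check [PASS]: planted 4x family mean enrichment in [3, 5]
#> demo check [PASS]: planted family FDR-significant
#> demo check [PASS]: all annotation names counted
#> demo: all checks passed

res$planted_family[, c("family", "mean", "sd", "z", "p_fdr")]
#>   family     mean         sd        z p_fdr
#> 2   ERV1 4.143966 0.03092221 101.6734 5e-16
```

Reading the row: across the two replicates the ERV1 family is 4.14-fold
enriched over input (planted: 4), the replicate ratios agree to an SD of
0.03, and the reproducibility statistic is far beyond the 0.05 FDR level
(the adjusted p sits at the 1e-16 floor). The slight deviation from the
planted factor is binomial sampling noise at this depth plus the small
zero-sum renormalisation bias discussed in the vignette.

The output directory additionally contains the per-RE `enrichment.tsv`,
`families.tsv`/`classes.tsv`, per-library count tables with QC
(`qc.json`: library sizes, MAPQ ≥ 40 counts, insert-size quartiles and
outlier fractions), the volcano and bar figures with companion TSVs, and
a `run.log` recording versions, parameters and input checksums.

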