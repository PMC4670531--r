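# contigdedup

Redundancy removal for de novo transcriptome assemblies by homology search,
with a full evaluation framework for its effect on differential-expression
calling.

## The problem

For species without a sequenced genome, RNA-Seq analysis has to use a de novo
assembly of the reads themselves as the reference. Assemblers reconstruct far
more contigs than there are genes: incomplete read coverage fragments one
transcript into several partial contigs (*redundant contigs*), and
mis-assembly produces contigs with no gene behind them at all (*erroneous
contigs*). When such a contig set is used as the mapping reference, several
contigs of one gene are called as distinct "differentially expressed contigs"
(DECs), and erroneous contigs surface as differential signals that correspond
to no gene — both corrupt the gene lists a breeding or functional-genomics
project actually wants.

`contigdedup` implements and compares three ways to reduce a raw contig set
to a non-redundant reference:

1. **Longest per subcomponent** — keep the longest contig of each assembler
   subcomponent (isoform group). Fails when one gene is split across several
   subcomponents.
2. **Cluster representative** — keep one representative per sequence cluster
   (e.g. CD-HIT at 0.9 identity). Fails when non-overlapping fragments of one
   gene never cluster together.
3. **Annotated best hit** (the method of interest) — BLAST every contig
   against a gene or protein database with no e-value or identity cut-off,
   assign each contig the gene with the highest bit score, and keep, per
   gene, the single contig with the highest bit score:

   kept(g) = argmax_{c : gene(c) = g} max_HSP bitscore(c → g)

   By construction the result has at most one contig per gene and no contig
   without homology, i.e. re-classification of the kept set yields 100%
   unique-hit contigs, 0 multiple-hit, 0 no-hit.

The evaluation framework quantifies each strategy against a gold-standard
gene set: RPKM quantification, pseudocounted log2 fold change
`log2((RPKM_B + 1)/(RPKM_A + 1))` with DEC/DEG calls at `|log2FC| > 1`,
Pearson correlation of contig vs gene fold changes (axis-aligned orphan
points included), co-identity of DECs with DEGs, and GO slim term
distribution comparison via a two-sample Kolmogorov–Smirnov test plus
per-term Fisher's exact tests.

A synthetic-assembly simulator with known truth (gene fragmentation,
subcomponent splitting, erroneous contigs, planted fold changes) makes the
whole workflow runnable and testable without any external aligner, assembler
or clustering tool.

## Worked example

```r
library(contigdedup)
bm <- run_redundancy_benchmark(seed = 1)
bm
#> <redundancy_benchmark> seed 1: 328 contigs over 100 genes
#>
#> Length summary:
#> # A tibble: 5 × 6
#>   contig_set       n min_len median_len   n50 mean_len
#>   <chr>        <int>   <dbl>      <dbl> <dbl>    <dbl>
#> 1 gene_dataset   100     517       1674  1917     1671
#> 2 raw            328     126        897  1306     1023
#> 3 longest        122     136       1317  1785     1424
#> 4 clustered      287     126        935  1337     1073
#> 5 annotated      100     471       1526  1825     1576
#>
#> Evaluation summary:
#> # A tibble: 4 × 8
#>   contig_set n_contigs correlation_all n_dec_identical n_dec_nonidentical
#>   <chr>          <int>           <dbl>           <int>              <int>
#> 1 raw              328           0.842              62                 12
#> 2 longest          122           0.817              21                  7
#> 3 clustered        287           0.849              54                 11
#> 4 annotated        100           0.907              20                  1
```

Reading the output: the simulated assembly holds 328 contigs for 100 genes.
The longest-per-subcomponent and cluster-representative strategies still keep
122 and 287 contigs, while the best-bit-score method collapses the set to
exactly one contig per gene (100) with the longest, most gene-like length
profile (N50 1825 vs 1306 for the raw set). On the evaluation side the
annotated set gives the highest fold-change correlation with the gold
standard (0.91 vs 0.84) and leaves only 1 differential contig that matches no
differentially expressed gene, against 12 for the raw set — redundant and
erroneous contigs, not the genes, were producing those calls.

Individual steps are ordinary tibble-in/tibble-out functions
(`read_contig_fasta()`, `read_blast_tab()`, `best_hit_per_contig()`,
`select_annotated()`, `expression_table()`, `co_identity()`,
`compare_go_distributions()`, ...), with `tidy()`/`glance()` methods on
result objects and `plot_fold_change_scatter()` / `plot_go_counts()` /
`plot_go_qq()` / `autoplot()` for the standard figures. A thin command-line
front-end with the same workflow as subcommands lives in
`inst/cli/contigdedup.R`.

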