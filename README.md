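# miRTarPC

Predicting microRNA–target interactions from matched multi-omic profiles
by **miRNA-conditioned partial correlation**.

## The problem

MicroRNAs repress genes post-transcriptionally, partly by translational
inhibition — repression that is invisible in mRNA data alone. Given three
expression matrices over the same samples — mRNA `M`, protein `P`
(sharing gene row IDs) and miRNA `MI` — the package asks, for every gene
*g* and miRNA *z*: does conditioning the gene's mRNA–protein correlation
on the miRNA make it more significant? With pairwise Pearson estimates,
the first-order partial correlation is

    r_yx.z = (r_yx − r_yz · r_xz) / (sqrt(1 − r_yz²) · sqrt(1 − r_xz²))

with two-sided p-values from t = r·sqrt(df/(1−r²)) (df = n−2 bivariate,
n−3 partial). The per-pair **improvement** is
`bivariate_p − partial_p`; candidate targets are the top quartile of the
positive improvements. Results come with Benjamini–Hochberg adjusted
p-values (over all tested pairs), validation flags and hypergeometric
enrichment against user-supplied target-pair databases, two
bivariate-correlation comparator screens, optional miRNA-seed scanning
(bases 2–8 from the 5' end, exact match against each gene's
longest-transcript sequence from genome FASTA + GTF), and a chromosomally
ordered summary heatmap (red = significant, scaled by partial estimate;
dark green = significant and database-validated).

It is aimed at computational biologists with matched
transcriptome/proteome/miRNA cohorts (e.g. proteogenomic tumour studies)
who want a regulator-aware alternative to plain miRNA–mRNA correlation
screens.

## Worked example

Simulate a matched workspace with planted repression (100 samples,
50 genes, 10 miRNAs, 20 planted pairs at repression strength b = 1.5) and
run the full pipeline:

```r
library(miRTarPC)

ws <- simulateWorkspace("demo", synthSpec(seed = 7L))
res <- runPipeline(list(
  mrna = ws$mrna, protein = ws$protein, mirna = ws$mirna,
  outdir = "demo/out",
  databases = list(planted = ws$database),
  coordinates = ws$coordinates,
  genome = ws$genome, gtf = ws$gtf, mirnaFasta = ws$mirnaFasta,
  pseudocount = 0))

head(res$table[, 1:7], 3)
#>   gene  mirna partial_estimate    partial_p partial_p_fdr bivariate_p improvement
#> 1  G50 miR-02        0.4343049 7.076321e-06  2.855358e-05   0.8972512   0.8972441
#> 2  G49 miR-01        0.3978693 4.539185e-05  1.740021e-04   0.8875446   0.8874992
#> 3  G22 miR-02        0.2091344 3.775859e-02  7.177253e-02   0.9243515   0.8865929

print(res$summary)
#>                              mRNA-miRNA bivariate protein-miRNA bivariate partial correlation
#> % of predicted miRNA-targets                0.00%                   9.13%              10.87%
#> planted enrichment                              1                 5.2e-24            4.94e-08
```

Reading the table: `G50`/`miR-02` has a near-zero mRNA–protein
association marginally (p = 0.897) that becomes strongly significant once
miR-02 is conditioned on (partial r = 0.43, p = 7·10⁻⁶) — the signature
of translational repression, and indeed a planted pair. The summary
mirrors the standard three-method comparison: the partial-correlation
screen selects 10.9% of the tested pairs and is strongly enriched
(p ≈ 5·10⁻⁸) in the planted-pair database, while the mRNA–miRNA baseline
finds nothing (the simulation plants purely translational repression, so
miRNA and mRNA are uncorrelated). The run also writes
`interactions.tsv`, `validation_summary.tsv`, `seed_summary.tsv`,
`heatmap.png` (+ a `heatmap_colors.tsv` dump) and a `manifest.yaml` that
reproduces the run bit-identically.

A thin command-line front end wraps the same functions:

```sh
inst/scripts/mirtarpc simulate --outdir ws --seed 1
inst/scripts/mirtarpc run --mrna ws/mrna.tsv --protein ws/protein.tsv \
    --mirna ws/mirna.tsv --outdir out --coordinates ws/coordinates.tsv \
    --pseudocount 0
```

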