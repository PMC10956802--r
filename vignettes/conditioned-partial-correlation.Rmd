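---
title: "Predicting miRNA targets by miRNA-conditioned partial correlation"
author: "miRTarPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA targets by miRNA-conditioned partial correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

MicroRNAs repress their target genes post-transcriptionally, through a
mixture of translational inhibition and mRNA destabilisation. Under
translational inhibition the repression is invisible at the mRNA level: the
miRNA lowers the protein output per mRNA molecule. Consider a gene with
mRNA profile $x$, protein profile $y$ and a candidate regulator miRNA with
profile $z$, measured over the same $n$ samples. If the miRNA represses the
protein, part of the variance of $y$ is explained by $z$ rather than by
$x$, and the marginal (bivariate) mRNA--protein correlation $r_{yx}$
understates the true coupling. Removing the linear effect of $z$ with the
first-order partial correlation

$$ r_{yx.z} = \frac{r_{yx} - r_{yz}\,r_{xz}}
  {\sqrt{1 - r_{yz}^2}\,\sqrt{1 - r_{xz}^2}} $$

should then *increase* the association: for a genuine target the
miRNA-conditioned correlation is more significant than the bivariate one.
`miRTarPC` turns this contrast into a screen. For every (gene, miRNA) pair
it computes both correlations with their two-sided p-values from the
classical $t$ transforms ($t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df for the
bivariate estimate, $n-3$ df for the partial one), forms the
**improvement** `bivariate_p - partial_p`, and calls candidate targets the
pairs in the top quartile of the *positive* improvement values. The output
is an interaction table (estimates, raw and Benjamini--Hochberg adjusted
p-values, improvement, database validation flags) and a chromosomally
ordered heatmap (red intensity = partial estimate; dark green = also found
in a validation database).

The selection acts on raw p-values; BH-adjusted partial p-values are
reported alongside, with the adjustment taken over *all* tested grid cells
so that multiplicity is never understated by adjusting within the selected
subset.

## Preprocessing

The recipe mirrors common proteogenomic practice and runs in a fixed
order:

1. **Missingness filter** (protein and miRNA matrices): keep features with
   strictly less than `maxMissingFraction` (default 10%) missing entries
   across samples.
2. **Median imputation**: remaining gaps are filled with the per-feature
   median across samples — the same axis the filter uses.
3. **log2 transform** of the mRNA and miRNA matrices
   (`pseudocount` default 1; use 0 for strictly positive data). The
   protein matrix is left on its original scale by default, as proteomic
   quantifications are typically already ratio-scale; a flag extends the
   transform to it.
4. **Top-variance protein selection**: keep the
   `ceiling(keepFraction * features)` most variable proteins (default
   50%) — the conditioning contrast needs variance in the protein
   profiles. Ties break lexicographically by feature ID, so the cut is
   deterministic.
5. **Alignment**: samples are intersected across all three matrices into
   one canonical sorted order and genes intersected between mRNA and
   protein, *after* the protein variance cut, so both matrices end with
   identical row sets.

The cleaning stages reach a fixed point: re-running the recipe on its own
output (with the transform and variance cut already applied) changes
nothing, and any consistent permutation of samples leaves every downstream
correlation unchanged.

## Numerical choices

* Correlation estimates are clamped to $[-1, 1]$ against floating-point
  round-off before the $t$ transform.
* The quartile threshold is the empirical quantile with linear
  interpolation (R's default type 7); selection keeps cells with
  improvement $\ge$ the threshold. On grids with all-distinct positive
  improvements the selected fraction of candidates is within
  $1/\#\text{candidates}$ of 25%.
* Degenerate cells — a constant profile, or a conditioning correlation of
  magnitude 1 (zero denominator in the partial-correlation formula) — are
  set to `NA` and excluded from the candidate set, the quantile, the FDR
  universe and the enrichment universe. Zero-filling them would leak
  fabricated values into the selection threshold.
* The hypergeometric enrichment p-value is the upper-tail *inclusive*
  probability $P(X \ge k)$ computed exactly via `phyper`; database pairs
  are intersected with the universe of tested cells before testing, which
  is the only choice that makes the three compared methods commensurable.
* The two comparator screens (`bivariateBaseline`) correlate mRNA—or
  protein—directly with miRNA expression, adjust by BH over all tested
  pairs and select adjusted $p <$ `alpha` (default 0.05, strict). Sign is
  not restricted by default; a `negativeOnly` flag restricts calls to
  anticorrelated (repression-signed) pairs.

## Seed scanning

Selected interactions can be annotated with the presence of the miRNA seed
in the target gene. The seed is bases 2–8 from the miRNA 5' end (7 nt).
Each gene is represented by its **longest transcript** (largest genomic
span, ties broken by transcript ID); the scanned sequence is that
transcript's unspliced genomic span, read 5'→3' in transcript orientation
(reverse-complemented for minus-strand genes). A spliced-mRNA mode is
deliberately not the default: the span-based reading keeps intronic hits
observable and matches the "start to end coordinates" convention of the
gene models. By default the scanner searches the DNA reverse complement of
the seed — a target site pairs antiparallel to the miRNA — but a `literal`
mode (seed transliterated U→T) is available because "exact match" is
ambiguous between the two conventions. Matches are mapped back to genomic
coordinates (GTF-style 1-based inclusive throughout) and intersected with
the 5'UTR, CDS and 3'UTR intervals of the longest transcript; one
interaction may hit several regions, so the "any annotated region"
percentage is at most, not equal to, the sum of the three region
percentages. When a GTF lacks explicit UTR features, UTRs are derived as
exonic regions outside the CDS span, assigned 5' or 3' by strand.

## The synthetic generator

`synthSpec()`/`generateDataset()` emulate a matched triple with planted
translational repression: per sample, miRNA abundances $z \sim N(0,1)$ and
mRNA abundances $x \sim N(0,1)$; protein $y = a\,x + \varepsilon$ for
unregulated genes and $y = a\,x - b\,z + \varepsilon$ for a planted
(gene, miRNA) pair, $\varepsilon \sim N(0, \sigma)$. Conditioning on $z$
removes the $b^2$ variance term, so the partial correlation
$a/\sqrt{a^2+\sigma^2}$ strictly exceeds the bivariate
$a/\sqrt{a^2+b^2+\sigma^2}$ for planted pairs — the exact phenomenon the
method screens for. An optional decay channel additionally subtracts
$\mathit{decay}\cdot z$ from the mRNA to probe behaviour when both
repression channels act.

Defaults, chosen once: 100 samples, 50 genes, 10 miRNAs, 20 planted pairs,
repression $b = 1.5$, noise $\sigma = 0.5$, 5% injected missingness in the
protein and miRNA matrices, and transcription coupling $a = 0.3$ — with
$\sigma = 0.5$ this gives unregulated genes an mRNA--protein correlation
of $a/\sqrt{a^2+\sigma^2} \approx 0.51$, in the range reported for
proteogenomic tumour cohorts. mRNA and miRNA matrices are exported as
$2^{\text{value}}$ (count-like, strictly positive) so that the standard
log2 preprocessing recovers the Gaussian scale exactly (`pseudocount = 0`
is used when running the pipeline on these data); proteins are exported on
their raw ratio-like scale. All draws derive from one recorded seed, and
identical specs yield bit-identical matrices.

What the generator does **not** emulate: count overdispersion
(negative-binomial mRNA/miRNA noise), intensity-dependent (MNAR)
proteomic missingness, correlated miRNA families, batch structure, and
many-to-many regulation with heterogeneous effect sizes. Tests passing on
these data therefore demonstrate the statistical machinery, not
performance on real tumour cohorts.

`generateGenomeFixture()` complements this with a deterministic toy genome
for the seed scanner: each gene sits on its own chromosome over an
AC-dinucleotide repeat background (which cannot contain any seed site
whose reverse complement includes G or T, so every match is an implant,
never chance), carries a 700-bp coding transcript (5'UTR / split CDS
around an intron / 3'UTR) plus a shorter non-coding transcript *outside*
the long transcript's span, and strands alternate across genes. Implants
can target the 5'UTR, CDS, 3'UTR, the intron (hit with no region flag) or
the short transcript only (invisible to the longest-transcript rule).

## Problem sizes used in the tests

The packaged checks run the full pipeline at the generator defaults
(100 × 50 × 10, 20 planted pairs), 20 replicates of the no-repression
control, five 50-gene × 20-miRNA pure-noise baselines, an exhaustive
hypergeometric lattice up to population size 60 against a log-space
tail-sum oracle, and 200 random triples against a residual-regression
oracle for the partial correlation. These sizes were chosen as the
smallest at which the distributional properties under test are stable.

## Known limitations

* **Improvement is an absolute p-value difference.** Its scale is set by
  the gene's bivariate p-value, which varies over orders of magnitude
  across genes through sampling alone (the SD of a correlation estimate is
  $\approx (1-r^2)/\sqrt{n}$). The global top-quartile threshold therefore
  favours genes whose *observed* bivariate correlation is weak: a true
  target on a gene with a strong observed bivariate correlation has a
  numerically tiny improvement and can rank below conditioning noise from
  unrelated miRNAs on other genes. On the synthetic study conditions above
  this caps end-to-end sensitivity near 55–65% at the default coupling
  (and lower for stronger coupling), even though planted pairs' median
  improvement clearly exceeds the null distribution's upper tail. A
  rank- or ratio-based improvement (e.g. log-p ratios, or per-gene
  normalisation) would remove this heterogeneity but would be a different
  selection rule, so it is not the default.
* Only first-order conditioning is computed: one miRNA at a time, no
  joint models of co-targeting, and no Spearman or permutation-based
  p-values.
* Database matching is exact string equality of identifiers; curate ID
  conventions (e.g. `hsa-` prefixes, arm suffixes) before loading pair
  files.
* The seed scanner enforces exact 7-mer matches: no wobble pairing,
  context scores or conservation filtering.
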