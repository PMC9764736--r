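# clumpscan

Detection and scoring of local enrichments ("clumps") of expressed
variant alleles on low-dimensional embeddings of single-cell and bulk
RNA-seq data.

## What it does and for whom

When cells are embedded by their transcriptomes (t-SNE, UMAP, PCA),
cells expressing the alternate allele of a somatic variant — or
carrying a copy-number event — often sit close together, because the
variant marks a biologically distinct subpopulation.  `clumpscan` takes
mapped reads (or an existing VCF), per-cell CNV calls, and embedding
coordinates, and reports for every variant the embedding locations
where its alternate-allele expression is locally enriched.  It is aimed
at analysts of heterogeneous samples — tumors above all — who want
variant-level structure overlaid on the embeddings they already use.

The pipeline: strand-aware pileup SNV/indel calling with relaxed
filters (coverage ≥ 10, ≥ 4 alternate reads, alternate AF ≥ 0.2, mapq
> 30, strand-bias check) → coding-impact annotation from GTF/GFF and
rare/damaging filtering (population AF < 1%) → per-cell allele count
matrices via `CB:Z` barcodes (bulk: one column per BAM) → multiscale
clump detection → plots.

## The statistic

Per variant, the per-cell alternate allele frequency
φ<sub>j</sub> = n<sup>alt</sup><sub>j</sub>/(n<sup>alt</sup><sub>j</sub>+n<sup>ref</sup><sub>j</sub>)
is smoothed on the embedding at data-driven scales σ<sub>a</sub>
(medians of the distances to the N<sub>ν</sub>-th neighbor for
0.1·N<sub>cells</sub> > N<sub>ν</sub> > max(0.01·N<sub>cells</sub>, 10)):

φ̄<sub>i</sub> = (1/|N(i)|) Σ<sub>j∈N(i)\i</sub> φ<sub>j</sub> exp(−d²<sub>ij</sub>/σ²<sub>a</sub>)

Strict local maxima of φ̄ are candidate clump centers.  Each candidate
gets a **read-depth-aware permutation z-score** (AFs shuffled only among
cells with coverage, so expression structure alone cannot fake a
clump), an upper-tail **binomial** test of the clump's pooled reads
against the bulk AF, a one-sided **Fisher** test of high-AF
(φ > η = 0.5) cell counts in the clump versus the sample, and an
**effective radius** (the neighborhood radius minimizing the Fisher p).
Reported clumps satisfy z > 2, > 10 mutated member cells, and both
p-values < 0.05.  CNV calls are decomposed into chromosome-arm and
minimal disjoint segment binary matrices and flow through the same
detector.

## Worked example

Simulate a 500-cell dataset with three planted clumps, detect, and
score recovery:

```r
library(clumpscan)
ds <- generateSyntheticDataset(nCells = 500, nVariants = 10,
                               plantClumps = 3, seed = 42)
ladder <- selectScales(ds$embedding)
ladder
#> ScaleLadder: 5 scales in [36.82, 112.6] (N_nu bounds 10..50 over 500 cells)
clumps <- detectClumps(ds$counts, ds$embedding, ladder,
                       DetectionParams(K = 200, seed = 42))
clumps
#> ClumpSet: 2 clumps over 2 variants
#>     variantId    center   scale smoothedAF        z     nullMu     nullSd
#> 1 variant_002 cell_0178 52.0718  0.3636161 12.07442 0.02506627 0.02803859
#> 2 variant_003 cell_0393 52.0718  0.4213945 10.73726 0.04301313 0.03524004
#>   degenerate       binomP      fisherP effectiveRadius nCells nMutated
#> 1      FALSE 1.795623e-55 1.434430e-10        38.99523     21       11
#> 2      FALSE 5.566342e-48 7.119786e-12        39.74991     24       14
matchClumps(ds$centers, clumps, ds$embedding)
#>     variantId nDetected minCenterDistance matched
#> 1 variant_001         0                NA   FALSE
#> 2 variant_002         1                 0    TRUE
#> 3 variant_003         1                 0    TRUE
```

Two of the three planted clumps are recovered with their centers found
exactly (`minCenterDistance` 0; a match requires the detected center
within 1% of the embedding radius of the planted cell).  The z-scores
(~11–12 permutation standard deviations above the null), the tiny
binomial/Fisher p-values, and the effective radii (~39 embedding units)
say each clump concentrates alternate-allele expression far beyond
read-depth structure.  The third variant's clump fell below the
"more than 10 mutated member cells" filter at this small cell count.

`plotClumps(ds$embedding, altAF(ds$counts)["variant_002", ], clumps,
variantId = "variant_002")` draws the cells colored white→red by AF
with a blue circle of the effective radius at each detected center.

A thin CLI wraps the same functions
(`exec/clumpscan call|simulate|detect|scales|score-sim|pipeline|plot`),
and `runPipeline()` drives whole configurations from YAML with a
checksummed artifact manifest.

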