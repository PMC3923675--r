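# pmdseq

Sequence determinants of single-CpG methylation in partially methylated
domains (PMDs).

## The problem

PMDs are genomic domains of hundreds of kilobases — common in fibroblasts,
many cancer samples and placenta — in which average CpG methylation is
reduced. At single-CpG resolution, methylation inside PMDs (outside CpG
islands and DNase I hypersensitive sites) is not uniformly dimmed but
spans 0–100% in a roughly uniform, seemingly disordered fashion; yet those
single-CpG states are strongly conserved across PMD-containing cell
types, implying a local mechanism. `pmdseq` implements the analyses that
test whether the surrounding DNA sequence itself sets each CpG's
methylation probability, for computational biologists working with
whole-genome bisulfite sequencing (WGBS) data or wanting a fully
controlled synthetic testbed.

At its core is a **positional dinucleotide regression**: the ±78 bp
environment of each CpG (the CpG itself excluded) is tiled into 78
non-overlapping dinucleotide blocks, each a 16-state categorical
predictor; with one reference state dropped per block, the methylation
level is fitted by ordinary least squares on 78 × 15 = 1170 one-hot
columns plus an intercept,

    y_i = b0 + sum_b s_b(d_ib) + e_i ,

trained and evaluated on disjoint random subsets (reported as held-out
Pearson r and R² = 1 − SSE/SST). Coefficients are displayed as a 16 × 78
per-block mean-centered heatmap, which is invariant to the dropped
reference state. The companion analyses are:

* **Preprocessing**: strand combining, coverage/island(±100 bp)/DHS/SNP
  filters, ≥200 kb PMD annotation, repeat classes.
* **Identical-context pairs**: Pearson correlation between CpGs whose
  L-bp centered windows are exactly identical (L = 10…140), with repeat
  stratification.
* **Allele-specific validation**: for homozygous CpGs with exactly one
  heterozygous SNP within ±40 bp and ≥10 reads per allele, the allelic
  difference dm = m_A − m_R is regressed per block position as
  dm = s_d(A) − s_d(R) with s(TT) ≡ 0 (15 free variables, no intercept),
  giving an independent estimate of the same contributions.
* **Spatial structure**: distance-dependent correlation of consecutive
  CpGs and per-PMD cross-sample concordance.
* **Nucleosomes**: MNase read shifting (±74 bp by strand, CpG-start
  exclusion), methylation-stratified composite profiles, and a positional
  count regression bounding how much nucleosome positioning can predict.
* **Synthetic methylome**: a generator with known ground truth — genome,
  PMDs, islands, repeats, a known coefficient matrix, binomial read
  sampling, diploid alleles, nucleosomal MNase reads — so everything above
  is testable end-to-end without external data.

## Worked example

Everything runs on a simulated methylome with known ground truth:

```r
library(pmdseq)

gt    <- make_ground_truth(sim_config(duplicate_segments = 2), seed = 7)
calls <- simulate_methylome(gt, seed = 7)
cpgs  <- combine_strands(calls, gt$genome)
ann   <- annotate_intervals(apply_filters(cpgs, gt$islands, min_cov = 10),
                            gt$pmds, gt$repeats)
pmd   <- ann[ann$in_pmd, ]

design <- encode_contexts(pmd, gt$genome)
fit    <- fit_dinuc_model(design, seed = 7)
fit
#> <dinuc_model> positional dinucleotide regression (78 blocks x 15 dummies)
#>   intercept 0.2115; 0 dropped (absent) predictor column(s)
#>   held-out: r = 0.782, R2 = 0.608 (train 8954 / test 2239)
```

The held-out r of 0.78 sits at the binomial noise ceiling for this
coverage (`attenuation_model_r()`); the centered coefficient heatmap
(`autoplot(fit)`, `tidy(fit)`) recovers the generating structure: a
positive CG band within ±20 bp, strongest immediately next to the CpG.
Identical-context pairs show the same determinism directly:

```r
correlation_curve(pmd, gt$genome, lengths = c(10, 80, 140), seed = 7)
#>     L         r n_pairs
#> 1  10 0.4666779    1838
#> 2  80 0.6688495     977
#> 3 140 0.6692901     977
```

r rises with context length and saturates at the noise ceiling for
coverage 30. The allele-specific route estimates the same contributions
from SNP-induced methylation differences:

```r
dip   <- simulate_diploid(gt, n_snps = 2000, seed = 7)
sites <- select_allelic_cpgs(dip$ref_calls, dip$alt_calls, dip$snps, gt$genome)
afit  <- fit_allelic_positionwise(sites)
afit
#> <allelic_fit> 39/40 blocks fitted (15 free variables each, TT = 0); 2943 equations total
allelic_concordance(afit, fit)$r
#> [1] 0.857
```

The two independent estimates of the per-block contributions agree
(r = 0.86 at this small scale; above 0.9 at the scale the acceptance
script uses). Real data enter through `read_meth_calls()`,
`read_bed_regions()`, `read_snps_vcf()` and `read_genome_fasta()` in place
of the simulator.

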