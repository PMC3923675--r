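---
title: "Sequence determinants of single-CpG methylation in PMDs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence determinants of single-CpG methylation in PMDs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

Partially methylated domains (PMDs) are large genomic domains — hundreds of
kilobases — found in fibroblasts, several cultured and cancer tissues, and
placenta, in which average CpG methylation is reduced. At single-CpG
resolution the reduction is not a uniform dimming: outside of CpG islands
and DNase I hypersensitive sites, individual CpGs span the whole range from
0% to 100% methylation in a roughly uniform fashion, with little similarity
between neighbours. These seemingly disordered single-CpG states are
nevertheless strongly conserved across PMD-containing cell types, which
demands a local, cell-intrinsic mechanism. `pmdseq` implements a family of
analyses that together test one candidate mechanism: that the DNA sequence
surrounding each CpG sets its methylation probability.

The package covers five analysis stages plus a fully specified synthetic
methylome so every stage is testable end-to-end with known ground truth:

1. **Preprocessing** (`combine_strands()`, `apply_filters()`,
   `annotate_intervals()`): per-strand cytosine calls are combined per CpG;
   CpGs are removed when they fall on non-configured chromosomes, are
   covered by fewer than 10 reads, lie within 100 bp of a CpG island,
   overlap a DHS (when a DHS set is available), or carry a known SNP on
   either base of the dinucleotide. PMDs shorter than 200 kb are discarded
   as low confidence.
2. **Identical-context similarity** (`context_pairs()`,
   `correlation_curve()`, `stratify_by_repeat()`).
3. **The positional dinucleotide model** (`encode_contexts()`,
   `fit_dinuc_model()`, `predict()`, `normalize_heatmap()`).
4. **Allele-specific validation** (`select_allelic_cpgs()`,
   `fit_allelic_positionwise()`, `allelic_concordance()`).
5. **Spatial correlation** (`distance_correlation()`,
   `pmd_cross_sample_correlation()`) and **nucleosome profiling**
   (`shift_and_count()`, `composite_profiles()`, `mnase_regression()`).

PMD *segmentation* is out of scope: PMD intervals are consumed as
annotations (they can be produced with MethylSeekR on real data, and are
known by construction in simulation). Read alignment and methylation
calling are likewise upstream of this package.

## The positional dinucleotide model

For a CpG with the C at position 0, the sequence environment is the 78 bp
on each side of the dinucleotide: offsets $-78..-1$ and $+2..+79$. The
environment is tiled into 78 non-overlapping dinucleotide blocks — left
blocks $(-78,-77),\dots,(-2,-1)$ and right blocks $(+2,+3),\dots,(+78,+79)$
— and each block is treated as a categorical predictor with 16 states. With
one reference state dropped per block, ordinary least squares of the
methylation level $y_i$ on the one-hot encoding uses exactly
$78 \times 15 = 1170$ columns plus an intercept:

$$ y_i = \beta_0 + \sum_{b=1}^{78} s_b(d_{ib}) + \varepsilon_i, $$

where $d_{ib}$ is the dinucleotide observed in block $b$ of CpG $i$.
Training and evaluation use disjoint seeded random subsets; performance is
reported both as the Pearson correlation $r$ between predicted and observed
levels and as $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ on the held-out set
(both are computed because "accuracy" of such a model can be read either
way; $R^2$ is the headline number).

Two geometry choices are deliberately explicit, because a tiling has a
phase: blocks tile **outward starting adjacent to the CpG**, and the right
flank starts **after the G** (the CpG itself is excluded from its own
environment). Both are fixed in `block_table()` so they are auditable; any
consistent phase yields an equivalent model, but coefficients are only
comparable across analyses if the phase is shared — which is also why the
allelic analysis (below) reuses the same block grid.

**Heatmap normalisation.** The dropped reference state is reinserted as a
zero and each block's 16 coefficients are centered to mean exactly zero
(`normalize_heatmap()`). Within a block, only coefficient *differences*
are identified — adding a constant to all 16 states of a block and
subtracting it from the intercept changes no prediction — so the centered
matrix is the canonical representation. It is invariant to the choice of
dropped reference state (tested to below `1e-8`), and it is what should be
displayed or compared, typically cropped to ±60 bp for display.

**Numerical choices.** The design is built as a sparse matrix and the
normal equations are solved by Cholesky with an SVD pseudoinverse fallback
(singular values below `1e-10` of the maximum treated as zero). States
absent from the training rows of a block are reported as coefficient 0 and
flagged rather than failing the fit. The default dropped state is the
lexicographically first state observed per block; the invariance above
makes the choice immaterial.

## Allele-specific validation

Heterozygous SNPs near homozygous CpGs give an internal, within-sample
test of the model: reads covering both the SNP and the CpG can be assigned
to one allele, giving methylation levels $m_R$ and $m_A$ for the same CpG
on the two haplotypes. A site qualifies when the CpG is intact on both
alleles, exactly one heterozygous SNP falls within ±40 bp (whole blocks:
offsets $-40..-1$ and $+2..+41$; the window is narrower than the model's
±78 bp because data thin out with distance), and both alleles have
coverage ≥ 10. The methylation difference is modelled as

$$ \Delta m = m_A - m_R = s_d(A) - s_d(R), $$

the difference of the contributions of the two block dinucleotides that the
SNP exchanges. Because each site involves exactly one SNP, the regression
decouples across block positions. Each per-block system is singular — a
constant added to all 16 coefficients cancels in every difference — so the
gauge is fixed by setting $s(\mathrm{TT}) = 0$, leaving exactly 15 free
variables per block and no intercept. Dinucleotides appearing in no
equation are reported as missing, not zero; blocks with fewer than 50
equations (configurable; a threshold scaled to simulation sizes) are
reported entirely missing. For comparison with the positional model, both
matrices are per-block mean-centered, which removes the gauge from both
sides; `allelic_concordance()` correlates the two centered matrices over
the cells where both are defined.

## Identical-context similarity and attenuation ceilings

`context_pairs()` groups PMD CpGs by the exact $L$-bp window centered on
the CpG ($L/2-1$ bases, `CG`, $L/2-1$ bases; reverse complements are *not*
merged — grouping is by literal sequence identity), drops singleton
groups, and emits one uniformly random pair per group so that no CpG is
reused. The correlation of the paired levels as a function of $L$ measures
how much of the methylation state is pinned down by increasingly long
sequence context. The 140 bp ceiling on $L$ reflects the read-length
constraint of the motivating data (87 bp reads must still anchor uniquely
outside the window while overlapping the CpG, leaving
$87 - 140/2 = 17$ bp; `context_read_overhang()`).

Measured levels are binomial estimates of the latent probability $p$, so
even a perfect sequence determinism cannot produce $r = 1$: with latent
variance $v = \mathrm{Var}(p)$ and average noise
$\sigma^2 = E[p(1-p)/c]$ at coverage $c$, two independent measurements of
the same sites correlate at most $v/(v+\sigma^2)$
(`attenuation_pair_r()`), and a perfect predictor correlates with one
noisy measurement at most $\sqrt{v/(v+\sigma^2)}$
(`attenuation_model_r()`). These ceilings are used throughout the tests:
the fitted model is judged against the ceiling rather than against 1, and
the identical-context and cross-replicate correlations on simulated data
are checked to sit at their analytic ceilings rather than merely "high".

## Spatial correlation and nucleosome profiling

`distance_correlation()` computes the Pearson correlation of the levels of
*consecutive* CpGs per exact distance (no pooling, distances up to 300 bp;
whether to pool distance bins is a free choice — exact bins are used here
as the most conservative reading). `pmd_cross_sample_correlation()`
reports one correlation per PMD with at least 10 CpGs shared between two
identically filtered samples; a common PMD set for two annotations is each
connected component of their interval intersection
(`intersect_regions()`).

For MNase data, read 5′ ends are shifted 74 bp (half the 147 bp footprint)
toward the fragment midpoint: plus-strand centers are `start + 74`,
minus-strand centers `start − 74` with the minus-strand 5′ end recorded as
the largest coordinate. Reads starting exactly on either base of an
interrogated CpG are excluded before shifting — around a CpG the MNase
cutting preference produces sharp artefacts — with exact accounting
(`input = excluded + off-chromosome + retained`). Composite profiles
stratify CpGs into 5 equally spaced methylation bins (half-open, top bin
closed) and report the mean center count per offset divided by the grand
mean over all CpGs and offsets, so the CpG-weighted average enrichment is
1 by construction. `mnase_regression()` bounds the predictive power of
nucleosome positioning by regressing levels on the positional counts
within ±200 bp (the window is not dictated by the design — one nucleosome
repeat per side is used and exposed as a parameter); its held-out $r$ is
compared with the sequence model's $r$ on the same CpGs. Counts enter raw;
no normalisation is applied, and no correction for MNase sequence bias is
attempted (a known confounder of any such upper bound).

## The synthetic methylome

`make_ground_truth()` builds, deterministically per `(config, seed)`, the
smallest world in which all of the above is meaningful and checkable:

* **Genome and CpGs**: random sequence with CG dinucleotides thinned to
  ~1 CpG per 100 bp (the empirical PMD spacing scale); destroyed CGs are
  replaced so no new CpG arises.
* **Domains**: alternating PMD/non-PMD segments (PMDs 250–400 kb, half of
  the genome by default), CpG-dense rewritten islands placed inside and
  outside PMDs, and non-overlapping repeat intervals with class labels
  (LINE/SINE/LTR/DNA/SVA at plausible proportions). Repeats are
  *annotation only*: the generator gives them no methylation behaviour of
  their own, which is exactly what makes them useful for the
  exchangeability checks of the stratified analyses.
* **Methylation law**: inside PMDs (outside islands),
  $p = \mathrm{clamp}(\beta_0 + \sum_b s_b(d_b),\ 0,\ 1)$ from a known
  coefficient matrix; islands are near-unmethylated (p = 0.05) and
  everything else near-fully methylated (p = 0.95).
* **Counts**: total coverage per CpG is Poisson truncated at ≥ 1 (mean 30
  by default), split binomially between strands; methylated counts are
  binomial in $p$. Coverage is otherwise unmodelled.
* **Diploid mode** (`simulate_diploid()`): heterozygous SNPs placed within
  ±40 bp of focal PMD CpGs, never on a CpG dinucleotide, spaced so that
  every affected CpG sees exactly one SNP; the alternative-allele
  probability is recomputed from the substituted sequence, so the true
  allelic difference equals the coefficient difference exactly wherever
  clamping is inactive.
* **MNase mode** (`simulate_mnase_reads()`): nucleosome dyads at ~180 bp
  spacing with occupancy weakly anti-coupled to local methylation
  (`weight = 1 − 0.3·p`), read centers jittered around dyads, a uniform
  background fraction, strands at random.

### Default parameter choices, with reasons

The generating coefficients mirror the known structure of the sequence
preference: a positive CG-state contribution within a ±20 bp band (+0.18),
exceptionally large in the two innermost blocks (+0.35) and small outside
the band (+0.03); flanking-dinucleotide effects at the innermost blocks
with TT/AA negative on both sides and TG/CT/CA/AG of opposite sign on the
two sides (±0.06–0.10); and a low-amplitude 10 bp periodic component on
AA/TT (0.015), echoing the helical repeat. With intercept 0.40 these
magnitudes produce PMD probabilities with a standard deviation of ~0.15 —
comparable to the spread a purely sequence-based predictor explains on
real PMD methylomes — while keeping clamping below 1% of CpGs so that
recovery analyses stay in the linear regime.

Two scale choices matter for reproducing the analyses at desk scale rather
than at multi-gigabase scale:

* The acceptance-scale genome is 12 Mb (two chromosomes), giving ~60,000
  usable PMD CpGs at coverage 30 — enough to train on 40,000 and test on
  10,000 held-out CpGs with coefficient standard errors a few thousandths.
* The diploid simulation defaults to per-allele coverage 150 at ~5,000
  qualifying sites. This is a precision-matching choice: the real allelic
  analysis rests on an order of magnitude more sites at low per-allele
  coverage, and per-cell coefficient standard errors scale as
  $\sqrt{2\,E[p(1-p)]/c}\,/\sqrt{n_\text{eff}}$, so fewer simulated sites
  at higher coverage hold the precision of the allelic heatmap at a
  comparable level. Five duplicated 25 kb PMD segments per chromosome
  guarantee identical-context pairs at all context lengths.

### What passing tests do and do not show

The generator's $p$ is an *exactly linear, fully sequence-determined*
function: there is no unexplained biological variance, no mappability
structure, no bisulfite conversion error, no repeat-induced homology
beyond the explicitly duplicated segments, and no sequence bias in the
simulated MNase digestion. Recovery of the generating coefficients, null
heatmaps outside PMDs, and agreement with the attenuation ceilings
therefore validate the *machinery* — encodings, solvers, selections,
accountings — and the statistical reasoning around it. They do not show
that real PMD methylation is this predictable; on real data the same
pipeline measures rather than assumes the sequence-determined share.

## Known limitations

* The model is purely linear in positional dinucleotides; interactions
  between blocks and longer-range composition are not modelled, matching
  the analysis it implements rather than improving on it.
* Repeat-class stratification uses a first-overlap rule for nested
  repeats; ties are resolved by sorted interval order.
* The distance-correlation periodicity (10 bp, ~180 bp) is descriptive
  output; no spectral significance machinery is provided.
* `simulate_diploid()` treats SNPs independently; CpGs falling between two
  SNP windows are dropped rather than given a two-SNP haplotype, matching
  the selection rule that excludes them anyway.
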