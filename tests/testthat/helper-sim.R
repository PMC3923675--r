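# Shared simulated fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small genome for unit tests (fast): ~1.4 Mb, one duplicated PMD segment.
small_config <- function(...) {
  sim_config(
    chrom_lengths = c(chrA = 8e5, chrB = 6e5),
    pmd_length_range = c(2e5, 3e5),
    duplicate_segments = 1,
    duplicate_length = 1e4,
    ...
  )
}

small_gt <- function() memo("small_gt", make_ground_truth(small_config(), seed = 101))

small_sim <- function() {
  memo("small_sim", {
    gt <- small_gt()
    calls <- simulate_methylome(gt, seed = 101)
    cpgs <- combine_strands(calls, gt$genome)
    ann <- annotate_intervals(
      apply_filters(cpgs, gt$islands, min_cov = 10),
      gt$pmds, gt$repeats
    )
    list(
      gt = gt, calls = calls, cpgs = cpgs, ann = ann,
      pmd = ann[ann$in_pmd, ],
      chrom_lengths = vapply(gt$genome, nchar, integer(1))
    )
  })
}

# Acceptance-scale genome (~12 Mb) shared by the heavier checks.
acc_config <- function() {
  sim_config(
    chrom_lengths = c(chr1 = 7e6, chr2 = 5e6),
    duplicate_segments = 5
  )
}

acc_gt <- function() memo("acc_gt", make_ground_truth(acc_config(), seed = 1))

acc_sim <- function() {
  memo("acc_sim", {
    gt <- acc_gt()
    calls <- simulate_methylome(gt, coverage_mean = 30, seed = 1)
    cpgs <- combine_strands(calls)
    ann <- annotate_intervals(apply_filters(cpgs, gt$islands, min_cov = 10), gt$pmds)
    list(gt = gt, ann = ann, pmd = ann[ann$in_pmd, ], out = ann[!ann$in_pmd, ])
  })
}

acc_fit <- function() {
  memo("acc_fit", {
    s <- acc_sim()
    design <- encode_contexts(s$pmd, s$gt$genome)
    fit <- fit_dinuc_model(design, n_train = 40000, n_test = 10000, seed = 1)
    list(design = design, fit = fit)
  })
}

# Independent brute-force re-encoder: dinucleotide codes per block from raw
# per-base string arithmetic (no shared code with the package encoder).
oracle_block_dinucs <- function(genome, chrom, pos) {
  offsets <- c(seq(-78, -2, by = 2), seq(2, 78, by = 2))
  seq_ch <- genome[[chrom]]
  vapply(offsets, function(o) {
    paste0(
      substr(seq_ch, pos + o, pos + o),
      substr(seq_ch, pos + o + 1, pos + o + 1)
    )
  }, character(1))
}

# Independent per-CpG methylation probability from the coefficient matrix.
oracle_p <- function(gt, chrom, pos) {
  d <- oracle_block_dinucs(gt$genome, chrom, pos)
  din16 <- dinucleotides()
  s <- vapply(seq_along(d), function(b) gt$coeffs[match(d[b], din16), b], numeric(1))
  min(max(gt$intercept + sum(s), 0), 1)
}

# Brute-force interval membership for one position.
oracle_in_interval <- function(chrom, pos, regions) {
  any(regions$chrom == chrom & regions$start <= pos + 1 & regions$end >= pos)
}
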