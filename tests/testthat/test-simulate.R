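# The synthetic-methylome generator: determinism, the linear probability
# model, binomial sampling, diploid alleles, nucleosomal reads.

test_that("generation is bit-identical for a fixed config and seed", {
  cfg <- sim_config(chrom_lengths = c(z = 1e5), pmd_length_range = c(3e4, 5e4))
  a <- make_ground_truth(cfg, seed = 9)
  b <- make_ground_truth(cfg, seed = 9)
  expect_identical(a, b)
  expect_identical(simulate_methylome(a, seed = 3), simulate_methylome(b, seed = 3))
  expect_false(identical(a$genome, make_ground_truth(cfg, seed = 10)$genome))
})

test_that("zero coefficients give a flat probability inside PMDs", {
  cfg <- small_config(
    cg_inner = 0, cg_band = 0, cg_outer = 0,
    flank_left = c(TT = 0), flank_right = c(TT = 0),
    periodic_amplitude = 0, intercept = 0.5,
    duplicate_segments = 0
  )
  gt <- make_ground_truth(cfg, seed = 3)
  p <- gt$cpgs$p[gt$cpgs$in_pmd & !gt$cpgs$in_island]
  expect_true(all(p == 0.5))
})

test_that("the generator is linear in the coefficients (CG counting case)", {
  # only the two innermost blocks contribute, +0.2 per CG state
  cfg <- small_config(
    cg_inner = 0.2, cg_band = 0, cg_outer = 0,
    flank_left = c(TT = 0), flank_right = c(TT = 0),
    periodic_amplitude = 0, intercept = 0.5,
    duplicate_segments = 0
  )
  gt <- make_ground_truth(cfg, seed = 4)
  pm <- gt$cpgs[gt$cpgs$in_pmd & !gt$cpgs$in_island, ]
  pm <- pm[pm$pos > 100 & pm$pos < 5e5, ]
  idx <- withr::with_seed(1, sample.int(nrow(pm), 200))
  for (i in idx) {
    ch <- gt$genome[[pm$chrom[i]]]
    left <- substr(ch, pm$pos[i] - 2, pm$pos[i] - 1)
    right <- substr(ch, pm$pos[i] + 2, pm$pos[i] + 3)
    expected <- 0.5 + 0.2 * ((left == "CG") + (right == "CG"))
    expect_equal(pm$p[i], min(expected, 1))
  }
})

test_that("PMD probabilities match an independent re-encoding oracle and span [0,1]", {
  gt <- small_gt()
  pm <- gt$cpgs[gt$cpgs$in_pmd & !gt$cpgs$in_island, ]
  interior <- pm[pm$pos > 100, ]
  idx <- withr::with_seed(2, sample.int(nrow(interior), 100))
  oracle <- vapply(
    idx,
    function(i) oracle_p(gt, interior$chrom[i], interior$pos[i]),
    numeric(1)
  )
  expect_equal(interior$p[idx], oracle, tolerance = 1e-12)
  # distribution: wide spread, coefficient of variation as enumerated
  cv_gen <- sd(pm$p) / mean(pm$p)
  all_oracle <- vapply(
    withr::with_seed(3, sample.int(nrow(interior), 500)),
    function(i) oracle_p(gt, interior$chrom[i], interior$pos[i]),
    numeric(1)
  )
  cv_oracle <- sd(all_oracle) / mean(all_oracle)
  expect_lt(abs(cv_gen - cv_oracle) / cv_oracle, 0.1)
  expect_lt(min(pm$p), 0.2)
  expect_gt(max(pm$p), 0.8)
  expect_true(all(pm$p >= 0 & pm$p <= 1))
  # region invariants: near-full methylation outside PMDs, low on islands
  expect_true(all(gt$cpgs$p[!gt$cpgs$in_pmd & !gt$cpgs$in_island] >= 0.9))
  expect_true(all(gt$cpgs$p[gt$cpgs$in_island] <= 0.1))
  expect_lt(gt$frac_clamped, 0.01)
})

test_that("binomial sampling respects degenerate and concentrated probabilities", {
  gt <- small_gt()
  gt1 <- gt
  gt1$cpgs$p <- 1
  calls1 <- simulate_methylome(gt1, seed = 5)
  expect_true(all(calls1$meth == calls1$total))
  gt0 <- gt
  gt0$cpgs$p <- 0
  calls0 <- simulate_methylome(gt0, seed = 5)
  expect_true(all(calls0$meth == 0))
  gth <- gt
  gth$cpgs$p <- 0.5
  ch <- combine_strands(simulate_methylome(gth, coverage_mean = 1000, seed = 5))
  expect_gt(mean(ch$level), 0.49)
  expect_lt(mean(ch$level), 0.51)
})

test_that("counts are binomial given p and coverage (aggregate z-test)", {
  s <- small_sim()
  d <- dplyr::inner_join(s$cpgs, s$gt$cpgs[, c("chrom", "pos", "p")], by = c("chrom", "pos"))
  d <- d[d$p > 0.02 & d$p < 0.98, ]
  z <- (d$meth - d$total * d$p) / sqrt(d$total * d$p * (1 - d$p))
  stat <- mean(z) * sqrt(nrow(d))
  expect_gt(2 * pnorm(-abs(stat)), 0.01)
  # variance also consistent with binomial sampling
  expect_lt(abs(var(z) - 1), 0.1)
})

test_that("simulated calls round-trip through the core readers and combiner", {
  s <- small_sim()
  expect_true(all(s$cpgs$meth <= s$cpgs$total))
  # every simulated CpG has reference dinucleotide CG: none is rejected
  expect_silent(combined <- combine_strands(s$calls, s$gt$genome))
  expect_identical(combined, s$cpgs)
})

test_that("diploid truth equals the coefficient difference at the SNP block", {
  gt <- small_gt()
  dip <- simulate_diploid(gt, n_snps = 400, seed = 6)
  sites <- dip$sites
  col <- pmdseq:::signed_block_to_column(sites$block)
  s_ref <- gt$coeffs[cbind(match(sites$d_R, dinucleotides()), col)]
  s_alt <- gt$coeffs[cbind(match(sites$d_A, dinucleotides()), col)]
  interior <- sites$p_R > 0.01 & sites$p_R < 0.99 & sites$p_A > 0.01 & sites$p_A < 0.99
  expect_gt(mean(interior), 0.95)
  expect_equal(sites$dm_true[interior], (s_alt - s_ref)[interior], tolerance = 1e-12)
  # a SNP exchanging two equal-coefficient dinucleotides leaves dm at 0
  same <- abs(s_alt - s_ref) < 1e-12 & interior
  if (any(same)) expect_true(all(abs(sites$dm_true[same]) < 1e-12))
})

test_that("observed allelic differences average to the true difference per cell", {
  gt <- small_gt()
  dip <- simulate_diploid(gt, n_snps = 1500, seed = 7)
  sel <- select_allelic_cpgs(dip$ref_calls, dip$alt_calls, dip$snps, gt$genome)
  m <- dplyr::inner_join(sel, dip$sites, by = c("chrom", "pos"), suffix = c("", ".truth"))
  cells <- m |>
    dplyr::summarise(
      n = dplyr::n(), dm_obs = mean(dm), dm_true = mean(dm_true),
      se = sd(dm) / sqrt(dplyr::n()),
      .by = c("d_R", "d_A") # pooled over positions; means taken over identical site sets
    ) |>
    dplyr::filter(n >= 30)
  expect_gt(nrow(cells), 5)
  expect_true(all(abs(cells$dm_obs - cells$dm_true) < 4.5 * cells$se))
})

test_that("uncoupled MNase occupancy yields a flat composite profile", {
  s <- small_sim()
  reads <- simulate_mnase_reads(s$gt, coupling = 0, reads_per_kb = 600, seed = 8)
  track <- shift_and_count(reads, s$pmd, s$chrom_lengths)
  prof <- composite_profiles(track, s$pmd, window = 300)
  by_bin <- prof |> dplyr::summarise(m = mean(enrichment), .by = bin)
  expect_true(all(abs(by_bin$m - 1) < 0.05))
})

test_that("shifted centers autocorrelate at the nucleosome spacing", {
  s <- small_sim()
  reads <- simulate_mnase_reads(s$gt, reads_per_kb = 600, seed = 9)
  track <- shift_and_count(reads, s$pmd[0, ], s$chrom_lengths)
  v <- track$counts[["chrA"]]
  lags <- 100:260
  ac <- vapply(lags, function(l) {
    n <- length(v)
    cor(v[1:(n - l)], v[(l + 1):n])
  }, numeric(1))
  peak <- lags[which.max(ac)]
  expect_gte(peak, 170)
  expect_lte(peak, 190)
})
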