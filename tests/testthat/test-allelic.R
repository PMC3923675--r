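# Allelic site selection and the per-position singular regression.

test_that("offsets map to signed blocks with the CpG excluded", {
  expect_equal(offset_to_block(c(-1L, -2L, -3L, -4L, -40L)), c(-1L, -1L, -2L, -2L, -20L))
  expect_equal(offset_to_block(c(2L, 3L, 4L, 5L, 41L)), c(1L, 1L, 2L, 2L, 20L))
  expect_true(all(is.na(offset_to_block(c(0L, 1L)))))
  expect_equal(block_offsets(-1L), cbind(first = -2L, second = -1L))
  expect_equal(block_offsets(2L), cbind(first = 4L, second = 5L))
})

test_that("site selection enforces the exactly-one-SNP and coverage rules", {
  genome <- c(chr = strrep("ACTA", 100)) # no CpGs needed for the selection logic
  mk <- function(pos, total = 20L) {
    tibble::tibble(chrom = "chr", pos = pos, meth = 5L, total = total)
  }
  ref <- mk(c(100L, 200L, 300L, 400L))
  alt <- mk(c(100L, 200L, 300L, 400L), total = c(20L, 20L, 20L, 9L))
  snps <- tibble::tibble(
    chrom = "chr",
    pos = c(110L, 210L, 215L, 300L, 410L), # one for 100; two for 200; on-CpG for 300; one for 400
    ref = "A", alt = "T"
  )
  out <- select_allelic_cpgs(ref, alt, snps, genome, window = 40, min_cov = 10)
  expect_equal(out$pos, 100L) # 200: two SNPs; 300: SNP on the CpG; 400: alt coverage 9
  expect_equal(out$offset, 10L)
  expect_equal(out$block, 5L)
  # a CpG with no SNP in the window is never selected
  ref2 <- mk(1000L)
  alt2 <- mk(1000L)
  expect_equal(nrow(select_allelic_cpgs(ref2, alt2, snps, genome)), 0L)
})

test_that("selection reads the block dinucleotides from both alleles", {
  genome <- c(chr = paste0(strrep("A", 98), "TACGGT", strrep("A", 96)))
  # CpG at 101-102; right block 1 covers offsets +2,+3 = "GT"
  ref <- tibble::tibble(chrom = "chr", pos = 101L, meth = 10L, total = 20L)
  alt <- tibble::tibble(chrom = "chr", pos = 101L, meth = 16L, total = 20L)
  snps <- tibble::tibble(chrom = "chr", pos = 103L, ref = "G", alt = "C")
  out <- select_allelic_cpgs(ref, alt, snps, genome)
  expect_equal(out$block, 1L)
  expect_equal(out$d_R, "GT")
  expect_equal(out$d_A, "CT")
  expect_equal(out$dm, 0.3)
})

test_that("selected site count matches a brute-force configuration scan", {
  gt <- small_gt()
  dip <- simulate_diploid(gt, n_snps = 500, seed = 20)
  sel <- select_allelic_cpgs(dip$ref_calls, dip$alt_calls, dip$snps, gt$genome,
    window = 40, min_cov = 10
  )
  # independent scan: nested loops over CpGs present on both alleles
  ref <- dip$ref_calls
  alt <- dip$alt_calls
  keys_alt <- paste(alt$chrom, alt$pos)
  n_expected <- 0L
  for (i in seq_len(nrow(ref))) {
    j <- match(paste(ref$chrom[i], ref$pos[i]), keys_alt)
    if (is.na(j)) next
    if (ref$total[i] < 10 || alt$total[j] < 10) next
    d <- dip$snps$pos[dip$snps$chrom == ref$chrom[i]] - ref$pos[i]
    in_win <- d >= -40 & d <= 41
    if (sum(in_win) != 1) next
    if (d[in_win] %in% c(0L, 1L)) next
    n_expected <- n_expected + 1L
  }
  expect_equal(nrow(sel), n_expected)
})

test_that("a single-difference system solves exactly", {
  sites <- tibble::tibble(
    chrom = "c", pos = 1:60, snp_pos = 1:60 + 4L, offset = 4L, block = 2L,
    d_R = "TT", d_A = "CG", m_R = 0.4, m_A = 0.6, dm = 0.2,
    total_R = 20L, total_A = 20L
  )
  fit <- fit_allelic_positionwise(sites, min_sites = 50)
  expect_equal(fit$n_free, 15L)
  expect_equal(fit$coefficients["CG", "2"], 0.2)
  expect_equal(fit$coefficients["TT", "2"], 0)
  # dinucleotides in no equation are missing, not zero
  expect_true(is.na(fit$coefficients["AC", "2"]))
  # blocks without data are entirely missing
  expect_true(all(is.na(fit$coefficients[, "1"])))
})

test_that("the centered fit is invariant to the gauge of the true coefficients", {
  # dm depends only on coefficient differences: shifting all 16 true values
  # of a block by a constant changes nothing observable
  din <- dinucleotides()
  s_true <- withr::with_seed(21, rnorm(16, sd = 0.1))
  names(s_true) <- din
  mk_sites <- function(shift) {
    withr::with_seed(22, {
      d_R <- sample(din, 400, replace = TRUE)
      d_A <- vapply(d_R, function(d) sample(setdiff(din, d), 1), character(1))
      dm <- (s_true[d_A] + shift) - (s_true[d_R] + shift) + rnorm(400, sd = 0.02)
      tibble::tibble(
        chrom = "c", pos = seq_len(400), snp_pos = seq_len(400) + 4L,
        offset = 4L, block = 2L, d_R = d_R, d_A = unname(d_A),
        m_R = 0.5, m_A = 0.5 + dm, dm = unname(dm),
        total_R = 20L, total_A = 20L
      )
    })
  }
  f0 <- fit_allelic_positionwise(mk_sites(0), min_sites = 50)
  f1 <- fit_allelic_positionwise(mk_sites(0.7), min_sites = 50)
  expect_equal(f0$centered, f1$centered, tolerance = 1e-10)
  # and the centered estimate matches the centered truth
  est <- f0$centered[, "2"]
  truth_centered <- s_true - mean(s_true)
  expect_lt(max(abs(est - truth_centered), na.rm = TRUE), 0.02)
})

test_that("relabelling reference and alternative behaves like a sign flip of dm", {
  gt <- small_gt()
  dip <- simulate_diploid(gt, n_snps = 1200, seed = 23)
  sel <- select_allelic_cpgs(dip$ref_calls, dip$alt_calls, dip$snps, gt$genome)
  f <- fit_allelic_positionwise(sel)
  # a full swap (labels and dm together) describes the same data: identical fit
  swapped <- sel |>
    dplyr::mutate(tmp = d_R, d_R = d_A, d_A = tmp, dm = -dm)
  g <- fit_allelic_positionwise(swapped)
  keep <- !is.na(f$centered) & !is.na(g$centered)
  expect_equal(f$centered[keep], g$centered[keep], tolerance = 1e-8)
  # flipping only the sign of dm negates every fitted contribution
  flipped <- dplyr::mutate(sel, dm = -dm)
  h <- fit_allelic_positionwise(flipped)
  keep2 <- !is.na(f$centered) & !is.na(h$centered)
  expect_equal(f$centered[keep2], -h$centered[keep2], tolerance = 1e-8)
})

test_that("tidy and autoplot expose the allelic heatmap", {
  gt <- small_gt()
  dip <- simulate_diploid(gt, n_snps = 800, seed = 24)
  sel <- select_allelic_cpgs(dip$ref_calls, dip$alt_calls, dip$snps, gt$genome)
  fit <- fit_allelic_positionwise(sel, min_sites = 10)
  td <- tidy(fit)
  expect_true(all(c("block", "offset", "dinucleotide", "estimate", "centered") %in% names(td)))
  expect_equal(nrow(td), 16 * ncol(fit$coefficients))
  expect_s3_class(autoplot(fit), "ggplot")
})
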