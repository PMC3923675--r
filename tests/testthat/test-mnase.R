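# MNase read shifting, composite profiles and the positional regression.

test_that("read shifting follows the strand-dependent +-74 bp rule", {
  reads <- tibble::tibble(
    chrom = "c", start = c(100L, 300L), strand = c("+", "-")
  )
  track <- shift_and_count(reads, tibble::tibble(chrom = character(), pos = integer()),
    c(c = 1000L)
  )
  expect_equal(track$counts[["c"]][174], 1L) # plus: start + 74
  expect_equal(track$counts[["c"]][226], 1L) # minus: start - 74
  expect_equal(sum(track$counts[["c"]]), 2L)
})

test_that("reads starting on an interrogated CpG are excluded", {
  cpgs <- tibble::tibble(chrom = "c", pos = 500L)
  reads <- tibble::tibble(
    chrom = "c", start = c(500L, 501L, 502L), strand = "+"
  )
  track <- shift_and_count(reads, cpgs, c(c = 1000L))
  expect_equal(track$n_excluded_cpg_start, 2L)
  expect_equal(track$n_retained, 1L)
  expect_equal(track$counts[["c"]][502 + 74], 1L)
})

test_that("counts on a toy read set match a per-read manual tally", {
  withr::with_seed(40, {
    reads <- tibble::tibble(
      chrom = "c",
      start = sample(80:920, 20),
      strand = sample(c("+", "-"), 20, replace = TRUE)
    )
  })
  cpgs <- tibble::tibble(chrom = "c", pos = reads$start[1]) # excludes reads 1 (and any at pos+1)
  track <- shift_and_count(reads, cpgs, c(c = 1000L))
  manual <- integer(1000)
  excluded <- 0L
  for (i in seq_len(20)) {
    if (reads$start[i] %in% c(cpgs$pos, cpgs$pos + 1L)) {
      excluded <- excluded + 1L
      next
    }
    ctr <- if (reads$strand[i] == "+") reads$start[i] + 74L else reads$start[i] - 74L
    manual[ctr] <- manual[ctr] + 1L
  }
  expect_equal(track$counts[["c"]], manual)
  expect_equal(track$n_excluded_cpg_start, excluded)
})

test_that("read accounting is exact, including off-chromosome centers", {
  s <- small_sim()
  reads <- simulate_mnase_reads(s$gt, reads_per_kb = 100, seed = 41)
  # push some reads off the end after shifting
  edge <- tibble::tibble(
    chrom = "chrA",
    start = c(10L, 20L, as.integer(s$chrom_lengths[["chrA"]] - 10L)),
    strand = c("-", "-", "+")
  )
  all_reads <- dplyr::bind_rows(reads, edge)
  track <- shift_and_count(all_reads, s$pmd, s$chrom_lengths)
  expect_equal(
    track$n_input,
    track$n_excluded_cpg_start + track$n_off_chrom + track$n_retained
  )
  expect_gte(track$n_off_chrom, 3L)
  expect_equal(sum(vapply(track$counts, sum, numeric(1))), track$n_retained)
})

test_that("methylation bins are half-open with a closed top bin", {
  expect_equal(pmdseq:::level_bin(c(0, 0.19, 0.2, 0.99, 1)), c(1L, 1L, 2L, 5L, 5L))
})

test_that("a uniform track gives flat unit enrichment", {
  withr::with_seed(42, {
    counts <- rpois(2e5, 3)
    cpgs <- tibble::tibble(
      chrom = "c", pos = sample(2000:198000, 3000), level = runif(3000)
    )
  })
  track <- structure(
    list(
      counts = list(c = counts), chrom_lengths = c(c = 2e5L),
      n_input = sum(counts), n_excluded_cpg_start = 0L, n_off_chrom = 0L,
      n_retained = sum(counts)
    ),
    class = "mnase_track"
  )
  prof <- composite_profiles(track, cpgs, window = 300)
  expect_true(all(abs(prof$enrichment - 1) < 0.15))
  # CpG-weighted mean enrichment over bins and offsets is 1 by construction
  grand <- sum(prof$enrichment * prof$n_cpgs) / sum(unique(prof$n_cpgs)) /
    length(unique(prof$offset))
  expect_equal(grand, 1, tolerance = 1e-12)
})

test_that("profiles are invariant under strand flip with coordinate mirroring", {
  s <- small_sim()
  reads <- simulate_mnase_reads(s$gt, reads_per_kb = 50, seed = 43)
  reads_a <- reads[reads$chrom == "chrA", ]
  len <- s$chrom_lengths[["chrA"]]
  mirrored <- tibble::tibble(
    chrom = "chrA",
    start = len + 1L - reads_a$start,
    strand = ifelse(reads_a$strand == "+", "-", "+")
  )
  cpgs_a <- s$pmd[s$pmd$chrom == "chrA", ]
  cpgs_m <- cpgs_a
  cpgs_m$pos <- len - cpgs_a$pos # mirrored CpG: [pos, pos+1] -> [len-pos, len+1-pos]
  t1 <- shift_and_count(reads_a, cpgs_a, c(chrA = len))
  t2 <- shift_and_count(mirrored, cpgs_m, c(chrA = len))
  expect_equal(t2$n_retained, t1$n_retained)
  expect_equal(t2$counts[["chrA"]], rev(t1$counts[["chrA"]]))
})

test_that("a methylation-independent track has no held-out predictive power", {
  s <- small_sim()
  reads <- simulate_mnase_reads(s$gt, coupling = 0, reads_per_kb = 300, seed = 44)
  track <- shift_and_count(reads, s$pmd, s$chrom_lengths)
  res <- mnase_regression(track, s$pmd, window = 200, seed = 44)
  expect_lt(abs(res$r), 0.1)
})

test_that("a deterministic count-methylation link is recovered", {
  withr::with_seed(45, {
    counts <- rpois(3e5, 5)
    pos <- sort(sample(3000:297000, 5000))
  })
  level <- pmin(1, counts[pos] / 10) # level is a function of the count at offset 0
  track <- structure(
    list(
      counts = list(c = as.integer(counts)), chrom_lengths = c(c = 3e5L),
      n_input = sum(counts), n_excluded_cpg_start = 0L, n_off_chrom = 0L,
      n_retained = sum(counts)
    ),
    class = "mnase_track"
  )
  cpgs <- tibble::tibble(chrom = "c", pos = pos, level = level)
  res <- mnase_regression(track, cpgs, window = 50, seed = 45)
  expect_gt(res$r, 0.95)
})

test_that("methylation-coupled occupancy orders the composite profiles", {
  s <- small_sim()
  reads <- simulate_mnase_reads(s$gt, reads_per_kb = 600, seed = 46)
  track <- shift_and_count(reads, s$pmd, s$chrom_lengths)
  prof <- composite_profiles(track, s$pmd, window = 400)
  by_bin <- prof |>
    dplyr::summarise(m = mean(enrichment), .by = bin) |>
    dplyr::arrange(bin)
  # occupancy decreases with methylation: lowest bin most enriched
  expect_gt(by_bin$m[1], by_bin$m[nrow(by_bin)])
  expect_s3_class(autoplot(prof), "ggplot")
})
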