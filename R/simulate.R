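# Synthetic methylome with known ground truth: a genome with CpGs at
# realistic density (~1 per 100 bp), PMD/non-PMD domains, CpG islands,
# repeat-class intervals, single-CpG methylation probabilities generated
# inside PMDs from a known positional dinucleotide coefficient matrix,
# near-full methylation outside PMDs, binomial read sampling, heterozygous
# SNPs with allele-resolved counts, and MNase read starts with ~180 bp
# nucleosome spacing.

#' Configuration of the synthetic methylome generator
#'
#' Returns the default generator configuration; any field can be
#' overridden by name. Lengths are in bp, probabilities in \[0, 1\].
#'
#' Defaults emulate the statistical structure of fibroblast-like PMD
#' methylomes: ~1 CpG per 100 bp, PMDs of 250-400 kb covering half the
#' genome, CpG-dense unmethylated islands, a strong positive CpG-density
#' contribution within +-20 bp of the central CpG (largest for the two
#' innermost blocks), flanking-dinucleotide effects with TT/AA negative on
#' both sides and TG/CT/CA/AG antisymmetric between the sides, and a
#' low-amplitude 10-bp periodic component.
#'
#' @param ... Named overrides of the default fields.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chrA = 1.5e6, chrB = 1.0e6),
    base_probs = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
    cpg_retention = 0.25,
    pmd_fraction = 0.5,
    pmd_length_range = c(2.5e5, 4.0e5),
    islands_per_mb = 8,
    island_length_range = c(500, 1200),
    island_base_probs = c(A = 0.20, C = 0.30, G = 0.30, T = 0.20),
    island_p = 0.05,
    background_p = 0.95,
    repeat_fraction = 0.4,
    repeat_length_range = c(300, 5000),
    repeat_classes = c(LINE = 0.35, SINE = 0.35, LTR = 0.15, DNA = 0.10, SVA = 0.05),
    coverage_mean = 30,
    intercept = 0.40,
    cg_inner = 0.35,
    cg_band = 0.18,
    cg_outer = 0.03,
    band_blocks = 10,
    flank_left = c(TT = -0.10, AA = -0.08, TG = 0.08, CA = -0.08, CT = 0.06, AG = -0.06),
    flank_right = c(TT = -0.10, AA = -0.08, TG = -0.08, CA = 0.08, CT = -0.06, AG = 0.06),
    periodic_amplitude = 0.015,
    periodic_period = 10,
    duplicate_segments = 0,
    duplicate_length = 2.5e4,
    nucleosome_spacing = 180,
    footprint = 147,
    mnase_coupling = 0.3,
    reads_per_kb = 300
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) abort(paste0("unknown sim_config field(s): ", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Ground-truth positional dinucleotide coefficients
#'
#' Builds the 16 x 78 coefficient matrix used to generate single-CpG
#' methylation probabilities inside PMDs: positive CG-state weights within
#' the +-20 bp band (largest in the two innermost blocks, a small positive
#' weight outside the band), flanking-dinucleotide effects at the two
#' innermost blocks, and a low-amplitude periodic component on AA/TT.
#'
#' @param config A [sim_config()].
#' @return 16 x 78 matrix (rows = dinucleotides, columns = block offsets).
#' @export
default_dinuc_coeffs <- function(config = sim_config()) {
  blocks <- block_table()
  m <- matrix(0, nrow = 16L, ncol = nrow(blocks), dimnames = list(DINUCS, blocks$offset))
  cg <- match("CG", DINUCS)
  m[cg, ] <- ifelse(blocks$k == 1, config$cg_inner,
    ifelse(blocks$k <= config$band_blocks, config$cg_band, config$cg_outer)
  )
  inner_left <- which(blocks$side == "left" & blocks$k == 1)
  inner_right <- which(blocks$side == "right" & blocks$k == 1)
  m[names(config$flank_left), inner_left] <-
    m[names(config$flank_left), inner_left] + config$flank_left
  m[names(config$flank_right), inner_right] <-
    m[names(config$flank_right), inner_right] + config$flank_right
  per <- config$periodic_amplitude * cos(2 * pi * blocks$center / config$periodic_period)
  m["AA", ] <- m["AA", ] + per
  m["TT", ] <- m["TT", ] + per
  m
}

# Random sequence with CG dinucleotides thinned to a realistic density.
# Destroyed CGs have the G replaced by A/T so no new CG can arise.
random_sequence <- function(len, base_probs, cpg_retention) {
  b <- sample(BASES, len, replace = TRUE, prob = base_probs)
  cg <- which(b[-len] == "C" & b[-1] == "G")
  kill <- cg[stats::runif(length(cg)) > cpg_retention]
  if (length(kill) > 0) {
    b[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
  }
  paste(b, collapse = "")
}

# Alternating PMD / non-PMD segmentation of one chromosome.
layout_pmds <- function(len, fraction, length_range) {
  pmds <- list()
  gap_scale <- (1 - fraction) / fraction
  pos <- 1 + round(stats::runif(1, 0.2, 1) * mean(length_range) * gap_scale)
  while (pos + length_range[1] <= len) {
    w <- round(stats::runif(1, length_range[1], min(length_range[2], len - pos + 1)))
    pmds[[length(pmds) + 1L]] <- c(pos, pos + w - 1)
    gap <- round(w * gap_scale * stats::runif(1, 0.7, 1.3))
    pos <- pos + w + max(gap, 1000)
  }
  if (length(pmds) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, pmds)
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Non-overlapping random intervals until the target coverage is reached.
layout_intervals <- function(len, target_fraction, length_range, margin = 100) {
  covered <- 0
  taken <- matrix(numeric(0), ncol = 2)
  out <- list()
  tries <- 0
  while (covered < target_fraction * len && tries < 1e5) {
    tries <- tries + 1
    w <- round(stats::runif(1, length_range[1], length_range[2]))
    s <- sample.int(max(len - w - margin, 1), 1) + margin %/% 2
    e <- s + w - 1
    if (nrow(taken) > 0 && any(s <= taken[, 2] + margin & e >= taken[, 1] - margin)) next
    taken <- rbind(taken, c(s, e))
    out[[length(out) + 1L]] <- c(s, e)
    covered <- covered + w
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2])) |> arrange(.data$start)
}

in_any_interval <- function(pos, intervals) {
  if (nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  iv <- IRanges::IRanges(start = intervals$start, end = intervals$end)
  IRanges::overlapsAny(IRanges::IRanges(start = pos, end = pos + 1L), iv)
}

#' Generate a synthetic methylome ground truth
#'
#' Builds, deterministically for a fixed `(config, seed)`, a genome with
#' CpGs at realistic density, PMD and CpG-island annotations, repeat-class
#' intervals, and a true methylation probability `p` for every CpG: inside
#' PMDs (outside islands) `p = clamp(intercept + sum of the positional
#' dinucleotide coefficients over the observed +-78 bp context, 0, 1)`;
#' island CpGs are near-unmethylated and CpGs outside PMDs near-fully
#' methylated. Optionally copies `duplicate_segments` segments of PMD
#' sequence elsewhere in the genome so that identical-context analyses
#' have guaranteed duplicate contexts.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `ground_truth`: `genome`, `cpgs`
#'   (`chrom, pos, p, in_pmd, in_island`), region tibbles `pmds`,
#'   `islands`, `repeats`, `duplicates`, the generating `coeffs` matrix
#'   and `intercept`, the fraction of clamped probabilities
#'   `frac_clamped`, `config` and `seed`.
#' @export
make_ground_truth <- function(config = sim_config(), seed = 1) {
  if (config$pmd_fraction <= 0 || config$pmd_fraction > 1) {
    abort("pmd_fraction must be in (0, 1]")
  }
  if (any(config$chrom_lengths < 1e4)) abort("chromosomes must be at least 10 kb")
  coeffs <- default_dinuc_coeffs(config)
  chroms <- names(config$chrom_lengths)

  genome <- list()
  pmds <- list()
  islands <- list()
  repeats <- list()
  dups <- list()

  with_stage_seed(seed, "genome", {
    for (ch in chroms) {
      len <- as.integer(config$chrom_lengths[[ch]])
      seq_ch <- random_sequence(len, config$base_probs, config$cpg_retention)
      pmd_ch <- layout_pmds(len, config$pmd_fraction, config$pmd_length_range)

      # CpG islands: CpG-dense rewritten segments, inside and outside PMDs
      n_isl <- max(1L, round(config$islands_per_mb * len / 1e6))
      isl <- layout_intervals(
        len, n_isl * mean(config$island_length_range) / len,
        config$island_length_range,
        margin = 500
      )
      for (i in seq_len(nrow(isl))) {
        w <- isl$end[i] - isl$start[i] + 1L
        substr(seq_ch, isl$start[i], isl$end[i]) <-
          random_sequence(w, config$island_base_probs, 1)
      }

      # duplicated PMD segments (identical-context pairs by construction)
      if (config$duplicate_segments > 0 && nrow(pmd_ch) >= 1) {
        dl <- as.integer(config$duplicate_length)
        margin <- 1500L
        wide <- pmd_ch[pmd_ch$end - pmd_ch$start + 1 >= dl + 2 * margin, ]
        slots <- list()
        for (i in seq_len(nrow(wide))) {
          lo <- wide$start[i] + margin
          hi <- wide$end[i] - margin - dl
          k <- 0L
          while (lo + k * (dl + margin) + dl <= hi + dl) {
            slots[[length(slots) + 1L]] <- lo + k * (dl + margin)
            k <- k + 1L
          }
        }
        slots <- unlist(slots)
        # avoid slots overlapping islands
        if (length(slots) > 0 && nrow(isl) > 0) {
          bad <- vapply(slots, function(s) {
            any(s <= isl$end + 100 & (s + dl - 1) >= isl$start - 100)
          }, logical(1))
          slots <- slots[!bad]
        }
        n_dup <- min(config$duplicate_segments, length(slots) %/% 2)
        if (n_dup > 0) {
          pick <- sample(slots, 2L * n_dup)
          for (d in seq_len(n_dup)) {
            src <- pick[2 * d - 1]
            dst <- pick[2 * d]
            substr(seq_ch, dst, dst + dl - 1L) <- substr(seq_ch, src, src + dl - 1L)
            dups[[length(dups) + 1L]] <- tibble(
              chrom = ch,
              src_start = as.integer(src), src_end = as.integer(src + dl - 1L),
              dst_start = as.integer(dst), dst_end = as.integer(dst + dl - 1L)
            )
          }
        }
      }

      rep_ch <- layout_intervals(len, config$repeat_fraction, config$repeat_length_range, margin = 10)
      rep_ch$class <- sample(
        names(config$repeat_classes), nrow(rep_ch),
        replace = TRUE, prob = config$repeat_classes
      )

      genome[[ch]] <- seq_ch
      if (nrow(pmd_ch) > 0) pmds[[ch]] <- mutate(pmd_ch, chrom = ch, .before = 1)
      if (nrow(isl) > 0) islands[[ch]] <- mutate(isl, chrom = ch, .before = 1)
      if (nrow(rep_ch) > 0) repeats[[ch]] <- mutate(rep_ch, chrom = ch, .before = 1)
    }
  })

  genome <- unlist(genome)
  pmds <- bind_rows(pmds)
  islands <- bind_rows(islands)
  repeats <- bind_rows(repeats)
  duplicates <- if (length(dups) > 0) bind_rows(dups) else NULL
  if (nrow(pmds) == 0) abort("configuration yields no PMDs; enlarge chromosomes or shorten pmd_length_range")

  # all CpGs and their true methylation probabilities
  cpg_list <- list()
  for (ch in names(genome)) {
    pos <- as.integer(gregexpr("CG", genome[[ch]], fixed = TRUE)[[1]])
    if (length(pos) == 1 && pos[1] == -1L) next
    cpg_list[[ch]] <- tibble(chrom = ch, pos = pos)
  }
  cpgs <- bind_rows(cpg_list)
  if (nrow(cpgs) == 0) abort("configuration yields no CpGs")

  cpgs <- cpgs |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      ch <- key$chrom[[1]]
      df$in_pmd <- in_any_interval(df$pos, pmds[pmds$chrom == ch, ])
      df$in_island <- in_any_interval(df$pos, islands[islands$chrom == ch, ])
      df
    }) |>
    ungroup()

  p <- ifelse(cpgs$in_island, config$island_p, config$background_p)
  pmd_idx <- which(cpgs$in_pmd & !cpgs$in_island)
  frac_clamped <- 0
  if (length(pmd_idx) > 0) {
    cw <- context_windows_flank(cpgs[pmd_idx, ], genome, FLANK_BP, FLANK_BP + 1L)
    p_lin <- rep(config$intercept, length(pmd_idx))
    if (any(cw$ok)) {
      codes <- window_codes(cw$window[cw$ok])
      contrib <- coeffs[cbind(as.vector(codes), rep(seq_len(ncol(codes)), each = nrow(codes)))]
      p_lin[cw$ok] <- config$intercept + rowSums(matrix(contrib, nrow = nrow(codes)))
    }
    frac_clamped <- mean(p_lin < 0 | p_lin > 1)
    p[pmd_idx] <- clamp01(p_lin)
  }
  cpgs$p <- p

  structure(
    list(
      genome = genome, cpgs = cpgs,
      pmds = pmds, islands = islands, repeats = repeats,
      duplicates = duplicates,
      coeffs = coeffs, intercept = config$intercept,
      frac_clamped = frac_clamped,
      config = config, seed = seed
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d chromosome(s), %d CpGs (%d in PMDs), %d PMDs, %d islands; %.2f%% clamped\n",
    length(x$genome), nrow(x$cpgs), sum(x$cpgs$in_pmd), nrow(x$pmds), nrow(x$islands), 100 * x$frac_clamped
  ))
  invisible(x)
}

#' Simulate a per-strand bisulfite call table from a ground truth
#'
#' Total coverage per CpG follows a Poisson law truncated at >= 1 with the
#' given mean, split binomially between the strands; methylated counts are
#' `Binomial(total, p)` per strand. The output is valid input to
#' [combine_strands()].
#'
#' @param gt A `ground_truth`.
#' @param coverage_mean Mean combined coverage (default from the config).
#' @param seed Integer seed.
#' @return Tibble of per-strand calls (`chrom, pos, strand, meth, total`).
#' @export
simulate_methylome <- function(gt, coverage_mean = NULL, seed = 1) {
  coverage_mean <- coverage_mean %||% gt$config$coverage_mean
  stopifnot(coverage_mean >= 1)
  cpgs <- gt$cpgs
  n <- nrow(cpgs)
  with_stage_seed(seed, "methylome", {
    total <- rpois_pos(n, coverage_mean)
    plus <- stats::rbinom(n, total, 0.5)
    minus <- total - plus
    meth_plus <- stats::rbinom(n, plus, cpgs$p)
    meth_minus <- stats::rbinom(n, minus, cpgs$p)
    bind_rows(
      tibble(
        chrom = cpgs$chrom, pos = cpgs$pos, strand = "+",
        meth = meth_plus, total = plus
      )[plus > 0, ],
      tibble(
        chrom = cpgs$chrom, pos = cpgs$pos + 1L, strand = "-",
        meth = meth_minus, total = minus
      )[minus > 0, ]
    ) |>
      arrange(.data$chrom, .data$pos)
  })
}

#' Simulate allele-resolved methylation around heterozygous SNPs
#'
#' Places heterozygous SNPs inside PMDs, each within +-`window` bp of a
#' focal CpG but never on the CpG dinucleotide itself, spaced so that each
#' affected CpG sees exactly one SNP. For every CpG within the window of a
#' SNP, the true methylation probability is recomputed on each allele's
#' sequence from the generating coefficients, so that the true allelic
#' difference equals the coefficient difference of the two block
#' dinucleotides (up to rare clamping). Allele-resolved counts are then
#' sampled per allele. CpGs destroyed by the SNP on the alternative allele
#' appear only in the reference table.
#'
#' @param gt A `ground_truth`.
#' @param n_snps Number of heterozygous SNPs to place.
#' @param window Half-window in bp around the CpG (default 40; SNP offsets
#'   span `-window..-1` and `+2..+(window+1)`, i.e. whole blocks).
#' @param coverage_mean Mean per-allele coverage (default 150; chosen so
#'   the allelic regression at simulation scale matches the precision of a
#'   much larger low-coverage dataset).
#' @param seed Integer seed.
#' @return List with `ref_calls` / `alt_calls` (allele-resolved CpG
#'   tables with an `allele` column), `snps` (`chrom, pos, ref, alt`) and
#'   `sites` (ground truth per affected CpG: SNP offset, signed block,
#'   `d_R`, `d_A`, `p_R`, `p_A`, `dm_true`).
#' @export
simulate_diploid <- function(gt, n_snps = 2000, window = 40, coverage_mean = 150, seed = 1) {
  spacing <- 2L * (as.integer(window) + 2L)
  margin <- FLANK_BP + as.integer(window) + 2L
  cand <- gt$cpgs |>
    filter(.data$in_pmd, !.data$in_island) |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      len <- nchar(gt$genome[[key$chrom[[1]]]])
      filter(df, .data$pos > margin, .data$pos + margin <= len)
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$pos)

  # greedy spacing so focal windows never share a SNP
  spaced <- cand |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      keep <- logical(nrow(df))
      last <- -Inf
      for (i in seq_len(nrow(df))) {
        if (df$pos[i] - last >= spacing) {
          keep[i] <- TRUE
          last <- df$pos[i]
        }
      }
      df[keep, ]
    }) |>
    ungroup()
  if (nrow(spaced) < n_snps) {
    abort(sprintf(
      "requested %d SNPs but only %d suitably spaced PMD CpGs are available",
      n_snps, nrow(spaced)
    ))
  }

  with_stage_seed(seed, "diploid", {
    focal <- spaced[sort(sample.int(nrow(spaced), n_snps)), ]
    offsets_allowed <- c(seq(-window, -1L), seq(2L, window + 1L))
    snp_off <- sample(offsets_allowed, n_snps, replace = TRUE)
    snp_pos <- focal$pos + snp_off
    ref_base <- substr_genome(gt$genome, focal$chrom, snp_pos, snp_pos)
    alt_base <- vapply(ref_base, function(b) sample(setdiff(BASES, b), 1), character(1))
    snps <- tibble(chrom = focal$chrom, pos = as.integer(snp_pos), ref = unname(ref_base), alt = unname(alt_base))

    # every CpG whose +-window sees a SNP (focal plus incidental neighbours)
    cg <- GenomicRanges::GRanges(gt$cpgs$chrom, IRanges::IRanges(gt$cpgs$pos - window, gt$cpgs$pos + window + 1L))
    sg <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
    hits <- GenomicRanges::findOverlaps(cg, sg)
    ci <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    # a CpG between two SNP windows has no single well-defined alternative
    # context here; such CpGs would be excluded downstream anyway
    single <- ci %in% which(tabulate(ci, nbins = length(cg)) == 1L)
    ci <- ci[single]
    si <- si[single]
    sites <- tibble(
      chrom = gt$cpgs$chrom[ci], pos = gt$cpgs$pos[ci], p_R = gt$cpgs$p[ci],
      in_pmd = gt$cpgs$in_pmd[ci], in_island = gt$cpgs$in_island[ci],
      snp_pos = snps$pos[si], ref = snps$ref[si], alt = snps$alt[si]
    ) |>
      mutate(offset = .data$snp_pos - .data$pos)

    destroyed <- sites$offset %in% c(0L, 1L)
    sites$destroyed <- destroyed

    # recompute the alt-allele probability from the substituted context
    w_ref <- substr_genome(gt$genome, sites$chrom, sites$pos - FLANK_BP, sites$pos + FLANK_BP + 1L)
    ok <- !is.na(w_ref) & !destroyed & sites$in_pmd & !sites$in_island
    w_alt <- w_ref
    idx <- sites$offset + FLANK_BP + 1L
    substr(w_alt, idx, idx) <- sites$alt
    sites$block <- offset_to_block(sites$offset)
    sites$d_R <- NA_character_
    sites$d_A <- NA_character_
    sites$p_A <- sites$p_R
    if (any(ok)) {
      codes_r <- window_codes(w_ref[ok])
      codes_a <- window_codes(w_alt[ok])
      bcol <- signed_block_to_column(sites$block[ok])
      sites$d_R[ok] <- DINUCS[codes_r[cbind(seq_len(sum(ok)), bcol)]]
      sites$d_A[ok] <- DINUCS[codes_a[cbind(seq_len(sum(ok)), bcol)]]
      contrib <- gt$coeffs[cbind(as.vector(codes_a), rep(seq_len(ncol(codes_a)), each = nrow(codes_a)))]
      sites$p_A[ok] <- clamp01(gt$intercept + rowSums(matrix(contrib, nrow = nrow(codes_a))))
    }
    sites$dm_true <- sites$p_A - sites$p_R
    sites <- sites[ok | destroyed, ]

    # allele-resolved counts for CpGs present on each allele
    draw <- function(p) {
      total <- rpois_pos(length(p), coverage_mean)
      meth <- stats::rbinom(length(p), total, p)
      tibble(meth = meth, total = total, level = meth / total)
    }
    ref_rows <- sites
    ref_counts <- draw(ref_rows$p_R)
    ref_calls <- bind_cols(
      ref_rows[, c("chrom", "pos")], ref_counts,
      tibble(allele = "R")
    )
    alt_rows <- sites[!sites$destroyed, ]
    alt_counts <- draw(alt_rows$p_A)
    alt_calls <- bind_cols(
      alt_rows[, c("chrom", "pos")], alt_counts,
      tibble(allele = "A")
    )

    list(
      ref_calls = ref_calls, alt_calls = alt_calls, snps = snps,
      sites = sites[!sites$destroyed, setdiff(names(sites), c("in_pmd", "in_island", "destroyed"))]
    )
  })
}

#' Simulate MNase-seq read starts with nucleosomal structure
#'
#' Nucleosome dyads are laid along each chromosome with the configured
#' spacing (default 180 bp) and jitter; dyad occupancy is weakly coupled
#' to the local methylation probability (`weight = 1 - coupling * p` of
#' the nearest CpG), so that highly methylated CpGs overlap positioned
#' nucleosomes less often. Read starts are placed so that shifted centers
#' (`start + 74` on plus, `start - 74` on minus) cluster at the dyads; a
#' uniform background fraction is added and strands are assigned with
#' probability 0.5.
#'
#' @param gt A `ground_truth`.
#' @param reads_per_kb Reads per kb of genome (default from config).
#' @param spacing,footprint Nucleosome spacing and footprint in bp.
#' @param coupling Occupancy-methylation coupling in \[0, 1\]; 0 gives a
#'   methylation-independent track.
#' @param dyad_jitter,read_jitter Gaussian jitter (bp) of dyad placement
#'   and of read centers around the dyad.
#' @param bg_fraction Fraction of uniform background reads.
#' @param seed Integer seed.
#' @return Tibble of stranded read starts (`chrom, start, strand`); the
#'   start of a minus-strand read is its 5' end, i.e. its largest
#'   coordinate.
#' @export
simulate_mnase_reads <- function(gt, reads_per_kb = NULL, spacing = NULL,
                                 footprint = NULL, coupling = NULL,
                                 dyad_jitter = 10, read_jitter = 20,
                                 bg_fraction = 0.3, seed = 1) {
  cfg <- gt$config
  reads_per_kb <- reads_per_kb %||% cfg$reads_per_kb
  spacing <- spacing %||% cfg$nucleosome_spacing
  footprint <- footprint %||% cfg$footprint
  coupling <- coupling %||% cfg$mnase_coupling
  shift <- (footprint + 1L) %/% 2L

  with_stage_seed(seed, "mnase", {
    out <- list()
    for (ch in names(gt$genome)) {
      len <- nchar(gt$genome[[ch]])
      phase <- stats::runif(1, 1, spacing)
      dyads <- round(seq(phase, len, by = spacing) + stats::rnorm(length(seq(phase, len, by = spacing)), 0, dyad_jitter))
      dyads <- dyads[dyads > shift + 1 & dyads < len - shift - 1]
      cp <- gt$cpgs[gt$cpgs$chrom == ch, ]
      if (nrow(cp) > 0) {
        nearest <- findInterval(dyads, cp$pos)
        lo <- pmax(nearest, 1L)
        hi <- pmin(nearest + 1L, nrow(cp))
        d_lo <- abs(dyads - cp$pos[lo])
        d_hi <- abs(dyads - cp$pos[hi])
        m <- ifelse(d_lo <= d_hi, cp$p[lo], cp$p[hi])
        m[pmin(d_lo, d_hi) > 200] <- mean(cp$p)
      } else {
        m <- rep(0.5, length(dyads))
      }
      w <- pmax(0.05, 1 - coupling * m)

      n_total <- round(reads_per_kb * len / 1000)
      n_bg <- round(bg_fraction * n_total)
      n_nuc <- n_total - n_bg
      centers <- c(
        dyads[sample.int(length(dyads), n_nuc, replace = TRUE, prob = w)] +
          round(stats::rnorm(n_nuc, 0, read_jitter)),
        sample.int(len, n_bg, replace = TRUE)
      )
      strand <- sample(c("+", "-"), length(centers), replace = TRUE)
      start <- ifelse(strand == "+", centers - shift, centers + shift)
      keep <- start >= 1 & start <= len
      out[[ch]] <- tibble(chrom = ch, start = as.integer(start[keep]), strand = strand[keep])
    }
    bind_rows(out) |> arrange(.data$chrom, .data$start)
  })
}
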