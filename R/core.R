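# Core preprocessing: strand combining, filtering, interval annotation.

regions_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
}

cpg_gr <- function(cpgs) {
  GenomicRanges::GRanges(
    seqnames = cpgs$chrom,
    ranges = IRanges::IRanges(start = cpgs$pos, end = cpgs$pos + 1L)
  )
}

# TRUE for CpGs whose dinucleotide [pos, pos+1] overlaps any interval.
cpg_overlaps <- function(cpgs, regions, flank = 0L) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(rep(FALSE, nrow(cpgs)))
  }
  r <- regions
  r$start <- pmax(1L, r$start - as.integer(flank))
  r$end <- r$end + as.integer(flank)
  IRanges::overlapsAny(cpg_gr(cpgs), regions_gr(r))
}

#' Merge intervals within a region set
#'
#' Collapses overlapping or adjacent intervals per chromosome into
#' non-overlapping sorted intervals.
#'
#' @param regions Tibble `chrom, start, end` (1-based closed).
#' @return Tibble of merged intervals.
#' @export
merge_regions <- function(regions) {
  gr <- GenomicRanges::reduce(regions_gr(regions))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Intersect two region sets
#'
#' Each connected component of the overlap of the two sets becomes one
#' interval; used e.g. to define PMDs common to two samples.
#'
#' @param a,b Tibbles `chrom, start, end`.
#' @return Tibble of intersected intervals.
#' @export
intersect_regions <- function(a, b) {
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(regions_gr(a)),
    GenomicRanges::reduce(regions_gr(b))
  )
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Combine per-strand cytosine calls into CpG records
#'
#' Methylation calls from the two strands of a CpG are summed: the
#' plus-strand C at `pos` and the minus-strand C at `pos + 1` report on the
#' same CpG. CpGs observed on only one strand keep that strand's counts.
#' The level is recomputed from the summed counts.
#'
#' @param calls Tibble `chrom, pos, strand, meth, total` of per-strand calls
#'   (1-based positions of the called C on its own strand).
#' @param genome Optional named character vector of chromosome sequences.
#'   When supplied, calls whose reference dinucleotide is not `CG` are
#'   rejected with a warning.
#' @return Tibble `chrom, pos, meth, total, level`, one row per CpG, `pos`
#'   the position of the plus-strand C.
#' @export
combine_strands <- function(calls, genome = NULL) {
  stopifnot(all(c("chrom", "pos", "strand", "meth", "total") %in% names(calls)))
  if (any(calls$meth < 0 | calls$total < 0)) {
    abort("negative read counts in per-strand calls")
  }
  if (any(calls$meth > calls$total)) {
    abort("methylated count exceeds total count")
  }
  cpg_pos <- ifelse(calls$strand == "-", calls$pos - 1L, calls$pos)
  if (!is.null(genome)) {
    din <- substr_genome(genome, calls$chrom, cpg_pos, cpg_pos + 1L)
    bad <- is.na(din) | din != "CG"
    if (any(bad)) {
      warn(sprintf("rejected %d call(s) whose reference dinucleotide is not CG", sum(bad)))
      calls <- calls[!bad, ]
      cpg_pos <- cpg_pos[!bad]
    }
  }
  tibble(chrom = calls$chrom, pos = as.integer(cpg_pos), meth = calls$meth, total = calls$total) |>
    summarise(meth = sum(.data$meth), total = sum(.data$total), .by = c("chrom", "pos")) |>
    filter(.data$total > 0) |>
    mutate(level = .data$meth / .data$total) |>
    arrange(.data$chrom, .data$pos)
}

# Vectorised substring lookup across chromosomes; NA when out of range.
substr_genome <- function(genome, chrom, start, end) {
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(genome)) next
    len <- nchar(genome[[ch]])
    ok <- idx[start[idx] >= 1 & end[idx] <= len]
    out[ok] <- substring(genome[[ch]], start[ok], end[ok])
  }
  out
}

#' Filter CpGs for PMD analyses
#'
#' Retains CpGs that (a) lie on the configured autosomes, (b) reach the
#' minimum combined coverage, (c) do not overlap any CpG island extended by
#' `island_flank` bp on each side, (d) do not overlap a DNase I
#' hypersensitive site when a DHS set is supplied, and (e) do not carry a
#' known SNP on either base of the CpG dinucleotide.
#'
#' @param cpgs Tibble of combined-strand CpG records.
#' @param islands CpG-island intervals (`chrom, start, end`).
#' @param snps Optional tibble `chrom, pos` of SNPs; CpGs with a SNP at
#'   `pos` or `pos + 1` are removed.
#' @param dhs Optional DHS intervals.
#' @param min_cov Minimum combined coverage (default 10).
#' @param autosomes Optional character vector of chromosomes to keep; `NULL`
#'   keeps all.
#' @param island_flank Island extension in bp (default 100).
#' @return The surviving subset of `cpgs`, unchanged.
#' @export
apply_filters <- function(cpgs, islands, snps = NULL, dhs = NULL,
                          min_cov = 10, autosomes = NULL, island_flank = 100) {
  if (min_cov < 1) abort("min_cov must be >= 1")
  keep <- rep(TRUE, nrow(cpgs))
  if (!is.null(autosomes)) keep <- keep & cpgs$chrom %in% autosomes
  keep <- keep & cpgs$total >= min_cov
  keep <- keep & !cpg_overlaps(cpgs, islands, flank = island_flank)
  if (!is.null(dhs)) keep <- keep & !cpg_overlaps(cpgs, dhs)
  if (!is.null(snps) && nrow(snps) > 0) {
    snp_key <- paste0(snps$chrom, ":", snps$pos)
    keep <- keep &
      !(paste0(cpgs$chrom, ":", cpgs$pos) %in% snp_key) &
      !(paste0(cpgs$chrom, ":", cpgs$pos + 1L) %in% snp_key)
  }
  out <- cpgs[keep, ]
  if (nrow(out) == 0) inform("no CpGs survive filtering")
  out
}

#' Annotate CpGs with PMD membership and repeat class
#'
#' PMDs shorter than `min_pmd_length` are discarded before annotation
#' (high-confidence PMD set); a CpG is "outside" when it overlaps no
#' retained PMD. The repeat class is that of the first overlapping repeat
#' interval in sorted order, or `"none"`.
#'
#' @param cpgs Tibble of CpG records.
#' @param pmds PMD intervals.
#' @param repeats Optional repeat intervals with a `class` column.
#' @param min_pmd_length Minimum PMD length in bp (default 200 kb).
#' @return `cpgs` with added columns `in_pmd` (logical) and `repeat_class`.
#' @export
annotate_intervals <- function(cpgs, pmds, repeats = NULL, min_pmd_length = 2e5) {
  pmds <- pmds[pmds$end - pmds$start + 1 >= min_pmd_length, ]
  out <- cpgs
  out$in_pmd <- cpg_overlaps(cpgs, pmds)
  out$repeat_class <- "none"
  if (!is.null(repeats) && nrow(repeats) > 0) {
    reps <- arrange(repeats, .data$chrom, .data$start)
    hit <- GenomicRanges::findOverlaps(cpg_gr(cpgs), regions_gr(reps), select = "first")
    has <- !is.na(hit)
    out$repeat_class[has] <- reps$class[hit[has]]
  }
  out
}

#' Summarise methylation-level distributions per stratum
#'
#' Groups CpGs by the given columns and reports the count, mean, standard
#' deviation and quartiles of the methylation level; strata with fewer than
#' `min_n` CpGs are suppressed so that only well-populated classes are
#' reported.
#'
#' @param cpgs Annotated CpG tibble.
#' @param by Character vector of grouping columns
#'   (default `c("in_pmd", "repeat_class")`).
#' @param min_n Minimum CpGs per reported stratum (default 1000).
#' @return Tibble of per-stratum summaries.
#' @export
level_summary <- function(cpgs, by = c("in_pmd", "repeat_class"), min_n = 1000) {
  cpgs |>
    summarise(
      n = n(),
      mean = mean(.data$level),
      sd = stats::sd(.data$level),
      q25 = stats::quantile(.data$level, 0.25),
      median = stats::quantile(.data$level, 0.5),
      q75 = stats::quantile(.data$level, 0.75),
      .by = all_of(by)
    ) |>
    filter(.data$n >= min_n)
}
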