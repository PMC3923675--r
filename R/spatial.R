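# Spatial structure of PMD methylation: distance-dependent correlation of
# consecutive CpGs and per-PMD concordance between two samples.

#' Distance-dependent correlation of consecutive CpGs
#'
#' Pairs are consecutive CpGs on the same chromosome; the distance is the
#' difference of their C positions. For each exact distance up to
#' `max_dist` with at least `min_pairs` pairs, the Pearson correlation of
#' the two levels is reported. A lowess-smoothed curve is attached when
#' `smooth = TRUE` for periodicity inspection (descriptive only).
#'
#' @param cpgs Tibble of CpG records with `level`, typically restricted to
#'   PMDs.
#' @param max_dist Maximum distance in bp (default 300).
#' @param min_pairs Minimum pairs per distance (default 50).
#' @param smooth Attach a smoothed column?
#' @return Tibble `distance, r, n_pairs` of class `distance_corr`.
#' @export
distance_correlation <- function(cpgs, max_dist = 300, min_pairs = 50, smooth = FALSE) {
  dat <- cpgs |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(
      next_level = lead(.data$level),
      distance = lead(.data$pos) - .data$pos
    ) |>
    ungroup() |>
    filter(!is.na(.data$distance), .data$distance <= max_dist)
  out <- dat |>
    summarise(
      r = if (n() >= 3) stats::cor(.data$level, .data$next_level) else NA_real_,
      n_pairs = n(),
      .by = "distance"
    ) |>
    filter(.data$n_pairs >= min_pairs) |>
    arrange(.data$distance)
  if (smooth && nrow(out) > 5) {
    sm <- stats::lowess(out$distance, out$r, f = 0.3)
    out$r_smooth <- sm$y[match(out$distance, sm$x)]
  }
  class(out) <- c("distance_corr", class(out))
  out
}

#' Per-PMD cross-sample correlation of single-CpG methylation
#'
#' Joins two identically filtered CpG tables on position, assigns shared
#' CpGs to PMDs, and reports one Pearson correlation per PMD with at least
#' `min_shared` shared CpGs. PMDs with fewer shared CpGs are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param a,b CpG tibbles of the two samples (both already filtered).
#' @param pmds PMD intervals common to the samples (see
#'   [intersect_regions()] for building a common set from two
#'   annotations).
#' @param min_shared Minimum shared CpGs per PMD (default 10).
#' @return Tibble `chrom, start, end, n, r` of class `pmd_concordance`.
#' @export
pmd_cross_sample_correlation <- function(a, b, pmds, min_shared = 10) {
  shared <- inner_join(
    a[, c("chrom", "pos", "level")],
    b[, c("chrom", "pos", "level")],
    by = c("chrom", "pos"), suffix = c("_a", "_b")
  )
  if (nrow(shared) == 0) {
    return(structure(tibble(
      chrom = character(), start = integer(), end = integer(),
      n = integer(), r = double()
    ), n_skipped = nrow(pmds), class = c("pmd_concordance", class(tibble()))))
  }
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(shared$chrom, IRanges::IRanges(shared$pos, shared$pos + 1L)),
    regions_gr(pmds),
    select = "first"
  )
  shared$pmd <- hit
  out <- shared |>
    filter(!is.na(.data$pmd)) |>
    summarise(
      n = n(),
      r = if (n() >= 3) stats::cor(.data$level_a, .data$level_b) else NA_real_,
      .by = "pmd"
    ) |>
    filter(.data$n >= min_shared)
  res <- tibble(
    chrom = pmds$chrom[out$pmd],
    start = pmds$start[out$pmd],
    end = pmds$end[out$pmd],
    n = out$n, r = out$r
  ) |>
    arrange(.data$chrom, .data$start)
  attr(res, "n_skipped") <- nrow(pmds) - nrow(res)
  class(res) <- c("pmd_concordance", class(res))
  res
}

#' @export
autoplot.distance_corr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "distance between consecutive CpGs (bp)", y = "Pearson r",
      title = "Distance-dependent correlation of adjacent CpG methylation"
    )
}

#' @export
autoplot.pmd_concordance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::labs(
      x = "per-PMD Pearson r", y = "PMDs",
      title = "Cross-sample concordance of single-CpG methylation per PMD"
    )
}
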