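# MNase-seq nucleosome analysis: read shifting, methylation-stratified
# composite profiles around CpGs, and the positional-count regression that
# bounds the predictive power of nucleosome positioning.

#' Shift MNase read starts and accumulate per-base center counts
#'
#' Given the 147 bp nucleosome footprint, read 5' ends are shifted 74 bp
#' toward the fragment midpoint: plus-strand center = start + 74,
#' minus-strand center = start - 74 (the 5' end of a minus-strand read is
#' recorded as its largest coordinate). Reads whose unshifted start falls
#' exactly on either base of an interrogated CpG are dropped (MNase
#' cutting bias at the CpG itself), as are reads whose shifted center
#' falls off the chromosome; both are counted.
#'
#' @param reads Tibble of stranded read starts (`chrom, start, strand`).
#' @param cpgs Interrogated CpG set (`chrom, pos`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param shift Shift in bp (default 74 = half the 147 bp footprint).
#' @return An object of class `mnase_track`: per-chromosome integer count
#'   vectors plus an exact accounting (`n_input = n_excluded_cpg_start +
#'   n_off_chrom + n_retained`).
#' @export
shift_and_count <- function(reads, cpgs, chrom_lengths, shift = 74L) {
  stopifnot(all(reads$chrom %in% names(chrom_lengths)))
  cpg_key <- c(
    paste0(cpgs$chrom, ":", cpgs$pos),
    paste0(cpgs$chrom, ":", cpgs$pos + 1L)
  )
  at_cpg <- paste0(reads$chrom, ":", reads$start) %in% cpg_key
  kept <- reads[!at_cpg, ]
  center <- ifelse(kept$strand == "+", kept$start + shift, kept$start - shift)
  len <- unname(chrom_lengths[kept$chrom])
  off <- center < 1 | center > len
  kept <- kept[!off, ]
  center <- center[!off]

  counts <- lapply(names(chrom_lengths), function(ch) {
    tabulate(center[kept$chrom == ch], nbins = chrom_lengths[[ch]])
  })
  names(counts) <- names(chrom_lengths)
  structure(
    list(
      counts = counts, chrom_lengths = chrom_lengths,
      n_input = nrow(reads),
      n_excluded_cpg_start = sum(at_cpg),
      n_off_chrom = sum(off),
      n_retained = nrow(kept)
    ),
    class = "mnase_track"
  )
}

#' @export
print.mnase_track <- function(x, ...) {
  cat(sprintf(
    "<mnase_track> %d chromosome(s); %d reads in, %d excluded at CpG starts, %d off-chromosome, %d retained\n",
    length(x$counts), x$n_input, x$n_excluded_cpg_start, x$n_off_chrom, x$n_retained
  ))
  invisible(x)
}

# methylation-level bin in 1..n_bins: [0,1/n), ..., [1-1/n, 1] (top closed)
level_bin <- function(level, n_bins = 5L) {
  pmin(floor(level * n_bins) + 1L, n_bins)
}

#' Methylation-stratified composite MNase profiles around CpGs
#'
#' CpGs are stratified by methylation level into `n_bins` equally spaced
#' bins (half-open, top bin closed). For each bin, the mean shifted-center
#' count at each offset from the CpG is divided by the grand mean count
#' over all CpGs and offsets, giving an enrichment relative to the average
#' over all CpGs; the CpG-count-weighted average enrichment over bins and
#' offsets is 1 by construction.
#'
#' @param track An `mnase_track` from [shift_and_count()].
#' @param cpgs CpG records with `level`; CpGs without a full window on the
#'   chromosome are skipped.
#' @param window Half-window in bp (default 1000).
#' @param n_bins Number of methylation bins (default 5).
#' @return Tibble `bin, bin_label, n_cpgs, offset, enrichment` of class
#'   `mnase_profiles`.
#' @export
composite_profiles <- function(track, cpgs, window = 1000, n_bins = 5) {
  window <- as.integer(window)
  use <- cpgs |>
    filter(.data$chrom %in% names(track$counts)) |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      len <- track$chrom_lengths[[key$chrom[[1]]]]
      filter(df, .data$pos - window >= 1, .data$pos + window <= len)
    }) |>
    ungroup()
  if (nrow(use) == 0) abort("no CpGs with a full profile window")
  use$bin <- level_bin(use$level, n_bins)
  bin_n <- tabulate(use$bin, nbins = n_bins)

  offsets <- seq(-window, window)
  sums <- matrix(0, nrow = n_bins, ncol = length(offsets))
  for (ch in unique(use$chrom)) {
    v <- track$counts[[ch]]
    sel <- use[use$chrom == ch, ]
    for (b in seq_len(n_bins)) {
      pb <- sel$pos[sel$bin == b]
      if (length(pb) == 0) next
      for (o in seq_along(offsets)) {
        sums[b, o] <- sums[b, o] + sum(v[pb + offsets[o]])
      }
    }
  }
  grand_mean <- sum(sums) / (nrow(use) * length(offsets))
  labels <- sprintf(
    "[%.1f,%.1f%s", (seq_len(n_bins) - 1) / n_bins, seq_len(n_bins) / n_bins,
    ifelse(seq_len(n_bins) == n_bins, "]", ")")
  )
  out <- tibble(
    bin = rep(seq_len(n_bins), each = length(offsets)),
    bin_label = rep(labels, each = length(offsets)),
    n_cpgs = rep(bin_n, each = length(offsets)),
    offset = rep(offsets, times = n_bins),
    enrichment = as.vector(t(sums / bin_n)) / grand_mean
  ) |>
    filter(.data$n_cpgs > 0)
  class(out) <- c("mnase_profiles", class(out))
  out
}

#' Predict methylation from positional MNase counts
#'
#' Ordinary least squares of the methylation level on the shifted-center
#' counts at every offset within +-`window` bp of the CpG (2*window + 1
#' positional predictors), fitted on a seeded random training subset and
#' evaluated as the Pearson correlation between prediction and observation
#' on a disjoint held-out subset. The resulting correlation bounds the
#' predictive power of nucleosome positioning for methylation.
#'
#' @param track An `mnase_track`.
#' @param cpgs CpG records with `level`.
#' @param window Predictor half-window in bp (default 200).
#' @param n_train,n_test Disjoint subset sizes (default 80/20 split).
#' @param seed Integer seed.
#' @return List with `r`, `n_train`, `n_test`, `window`.
#' @export
mnase_regression <- function(track, cpgs, window = 200, n_train = NULL, n_test = NULL, seed = 1) {
  window <- as.integer(window)
  use <- cpgs |>
    filter(.data$chrom %in% names(track$counts)) |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      len <- track$chrom_lengths[[key$chrom[[1]]]]
      filter(df, .data$pos - window >= 1, .data$pos + window <= len)
    }) |>
    ungroup()
  n <- nrow(use)
  if (is.null(n_train)) n_train <- floor(0.8 * n)
  if (is.null(n_test)) n_test <- n - n_train
  if (n_train + n_test > n) abort("n_train + n_test exceeds the number of usable CpGs")

  offsets <- seq(-window, window)
  X <- matrix(0, nrow = n, ncol = length(offsets))
  row0 <- 0L
  for (ch in unique(use$chrom)) {
    v <- track$counts[[ch]]
    sel <- use[use$chrom == ch, ]
    for (o in seq_along(offsets)) {
      X[row0 + seq_len(nrow(sel)), o] <- v[sel$pos + offsets[o]]
    }
    row0 <- row0 + nrow(sel)
  }
  y <- use$level # rows already grouped by chromosome in first-appearance order

  idx <- with_stage_seed(seed, "mnase_split", sample.int(n, n_train + n_test))
  train <- idx[seq_len(n_train)]
  test <- idx[n_train + seq_len(n_test)]
  fit <- stats::lm.fit(cbind(1, X[train, , drop = FALSE]), y[train])
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  pred <- cbind(1, X[test, , drop = FALSE]) %*% beta
  list(
    r = stats::cor(as.numeric(pred), y[test]),
    n_train = n_train, n_test = n_test, window = window
  )
}

#' @export
autoplot.mnase_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$offset, y = .data$enrichment,
    colour = .data$bin_label, group = .data$bin_label
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "offset from CpG (bp)", y = "MNase enrichment (vs all CpGs)",
      colour = "methylation bin",
      title = "Composite nucleosome profiles by methylation level"
    )
}
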