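# Identical-flanking-context analysis: do CpGs embedded in exactly the
# same L bp of sequence carry the same methylation level?

context_window_string <- function(cpgs, genome, L) {
  stopifnot(L %% 2 == 0, L >= 4)
  left <- L / 2 - 1 # bases left of the C; CG included; L/2 - 1 bases right of the G
  w <- substr_genome(genome, cpgs$chrom, cpgs$pos - left, cpgs$pos + L / 2)
  w[!is.na(w) & stringr::str_detect(w, "[^ACGT]")] <- NA_character_
  w
}

#' Pairs of CpGs with identical flanking sequence
#'
#' Groups CpGs by the exact `L` bp sequence centered on the CpG
#' (`L/2 - 1` bases, then `CG`, then `L/2 - 1` bases). Groups of size one
#' are dropped; groups of size two yield their pair; larger groups yield
#' exactly one uniformly random pair (seeded). CpGs whose window runs off
#' the chromosome or contains `N` are skipped.
#'
#' @param cpgs Tibble of CpG records with `level` (restricted to PMDs by
#'   the caller); a `repeat_class` column is carried through when present.
#' @param genome Named character vector of chromosome sequences.
#' @param L Even context length in bp (10 to 140 in typical use).
#' @param seed Integer seed for the within-group pair draw.
#' @return Tibble of pairs: coordinates, levels and (when available)
#'   repeat classes of the two CpGs, plus `L`.
#' @export
context_pairs <- function(cpgs, genome, L, seed = 1) {
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), ] # canonical order: output independent of input row order
  w <- context_window_string(cpgs, genome, L)
  ok <- which(!is.na(w))
  groups <- split(ok, w[ok])
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) {
    return(tibble(
      L = integer(), chrom1 = character(), pos1 = integer(), level1 = double(),
      chrom2 = character(), pos2 = integer(), level2 = double()
    ))
  }
  pick <- with_stage_seed(seed, paste0("context_pairs_", L), {
    lapply(groups, function(g) if (length(g) == 2) g else sort(sample(g, 2)))
  })
  i <- vapply(pick, `[`, numeric(1), 1)
  j <- vapply(pick, `[`, numeric(1), 2)
  out <- tibble(
    L = as.integer(L),
    chrom1 = cpgs$chrom[i], pos1 = cpgs$pos[i], level1 = cpgs$level[i],
    chrom2 = cpgs$chrom[j], pos2 = cpgs$pos[j], level2 = cpgs$level[j]
  )
  if ("repeat_class" %in% names(cpgs)) {
    out$class1 <- cpgs$repeat_class[i]
    out$class2 <- cpgs$repeat_class[j]
  }
  out[order(out$chrom1, out$pos1), ]
}

#' Correlation of methylation between identical-context CpG pairs
#'
#' For each context length, emits the Pearson correlation of the paired
#' methylation levels, with the within-pair order randomised (seeded) so
#' the correlation is symmetric in expectation. Lengths with fewer than 3
#' pairs are reported with `r = NA`.
#'
#' @param cpgs,genome,seed As in [context_pairs()].
#' @param lengths Even context lengths in bp (default `seq(10, 140, 10)`).
#' @return Tibble `L, r, n_pairs` of class `context_curve`.
#' @export
correlation_curve <- function(cpgs, genome, lengths = seq(10, 140, by = 10), seed = 1) {
  rows <- lapply(lengths, function(L) {
    pairs <- context_pairs(cpgs, genome, L, seed = seed)
    if (nrow(pairs) < 3) {
      return(tibble(L = as.integer(L), r = NA_real_, n_pairs = nrow(pairs)))
    }
    sw <- with_stage_seed(seed, paste0("pair_order_", L), stats::runif(nrow(pairs)) < 0.5)
    x <- ifelse(sw, pairs$level2, pairs$level1)
    y <- ifelse(sw, pairs$level1, pairs$level2)
    tibble(L = as.integer(L), r = stats::cor(x, y), n_pairs = nrow(pairs))
  })
  out <- bind_rows(rows)
  class(out) <- c("context_curve", class(out))
  out
}

#' Stratify identical-context pairs by repeat class
#'
#' A pair belongs to a repeat class only when both CpGs share it;
#' otherwise it is `"mixed"`. CpGs outside repeats form their own
#' `"none"` class. Classes with fewer than `min_n` pairs are suppressed.
#'
#' @param pairs Output of [context_pairs()] carrying `class1`/`class2`.
#' @param min_n Minimum pairs per reported class (default 100).
#' @return Tibble `repeat_class, r, n_pairs`.
#' @export
stratify_by_repeat <- function(pairs, min_n = 100) {
  stopifnot(all(c("class1", "class2") %in% names(pairs)))
  pairs |>
    mutate(repeat_class = ifelse(.data$class1 == .data$class2, .data$class1, "mixed")) |>
    summarise(
      r = if (n() >= 3) stats::cor(.data$level1, .data$level2) else NA_real_,
      n_pairs = n(),
      .by = "repeat_class"
    ) |>
    filter(.data$n_pairs >= min_n) |>
    arrange(desc(.data$n_pairs))
}

#' @export
autoplot.context_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs)) +
    ggplot2::labs(
      x = "context length (bp)", y = "Pearson r between identical-context pairs",
      size = "pairs",
      title = "Methylation similarity of CpGs with identical flanking sequence"
    )
}
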