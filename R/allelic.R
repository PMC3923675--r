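# Allele-specific validation of dinucleotide effects: homozygous CpGs
# flanked by exactly one heterozygous SNP give per-position equations
# dm = s_d(alt) - s_d(ref), solved per block with TT fixed to zero.

#' Select homozygous CpGs with exactly one flanking heterozygous SNP
#'
#' Keeps CpGs present on both alleles whose +-`window` bp environment
#' (whole blocks: offsets `-window..-1` and `+2..+(window+1)` relative to
#' the C) contains exactly one heterozygous SNP, with coverage of at least
#' `min_cov` on both alleles. Sites with a SNP on the CpG dinucleotide
#' itself, or with two or more SNPs in the window, are excluded. The
#' reference and alternative dinucleotides of the block containing the SNP
#' are read from the two allele sequences.
#'
#' @param ref_calls,alt_calls Allele-resolved CpG tables
#'   (`chrom, pos, meth, total, level`), reference and alternative allele.
#' @param snps Heterozygous SNPs (`chrom, pos, ref, alt`, 1-based).
#' @param genome Named character vector of reference chromosome sequences.
#' @param window Half-window in bp (default 40, i.e. 20 blocks per side).
#' @param min_cov Minimum coverage per allele (default 10).
#' @return Tibble of allelic sites: CpG coordinate, SNP `offset`, signed
#'   `block`, `d_R`, `d_A`, allele levels `m_R`, `m_A`, `dm = m_A - m_R`
#'   and the two coverages.
#' @export
select_allelic_cpgs <- function(ref_calls, alt_calls, snps, genome,
                                window = 40, min_cov = 10) {
  both <- inner_join(
    ref_calls[, c("chrom", "pos", "meth", "total")],
    alt_calls[, c("chrom", "pos", "meth", "total")],
    by = c("chrom", "pos"), suffix = c("_R", "_A")
  )
  if (nrow(both) == 0) {
    return(empty_allelic_sites())
  }
  # SNPs per CpG window, including the CpG's own two bases to veto them
  cg <- GenomicRanges::GRanges(both$chrom, IRanges::IRanges(both$pos - window, both$pos + window + 1L))
  sg <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(cg, sg)
  ci <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  off <- snps$pos[si] - both$pos[ci]
  on_cpg <- off %in% c(0L, 1L)
  tab_all <- tabulate(ci, nbins = nrow(both))
  tab_cpg <- tabulate(ci[on_cpg], nbins = nrow(both))
  usable <- which(tab_all == 1L & tab_cpg == 0L)

  keep <- ci %in% usable & !on_cpg
  sites <- tibble(
    chrom = both$chrom[ci[keep]], pos = both$pos[ci[keep]],
    meth_R = both$meth_R[ci[keep]], total_R = both$total_R[ci[keep]],
    meth_A = both$meth_A[ci[keep]], total_A = both$total_A[ci[keep]],
    snp_pos = snps$pos[si[keep]], alt = snps$alt[si[keep]],
    offset = off[keep]
  ) |>
    filter(.data$total_R >= min_cov, .data$total_A >= min_cov)
  if (nrow(sites) == 0) {
    return(empty_allelic_sites())
  }

  sites$block <- offset_to_block(sites$offset)
  bo <- block_offsets(sites$block)
  d1 <- sites$pos + bo[, 1]
  sites$d_R <- substr_genome(genome, sites$chrom, d1, d1 + 1L)
  within <- sites$offset - bo[, 1] + 1L # 1 or 2: position of the SNP in its block
  d_A <- sites$d_R
  substr(d_A, within, within) <- sites$alt
  sites$d_A <- d_A
  sites |>
    mutate(
      m_R = .data$meth_R / .data$total_R,
      m_A = .data$meth_A / .data$total_A,
      dm = .data$m_A - .data$m_R
    ) |>
    select(
      "chrom", "pos", "snp_pos", "offset", "block", "d_R", "d_A",
      "m_R", "m_A", "dm", "total_R", "total_A"
    ) |>
    arrange(.data$chrom, .data$pos)
}

empty_allelic_sites <- function() {
  tibble(
    chrom = character(), pos = integer(), snp_pos = integer(),
    offset = integer(), block = integer(), d_R = character(), d_A = character(),
    m_R = double(), m_A = double(), dm = double(),
    total_R = integer(), total_A = integer()
  )
}

#' Per-position allelic dinucleotide regression
#'
#' For each block position independently, solves the least-squares system
#' `dm = s(d_A) - s(d_R)` over the sites whose SNP falls in that block.
#' The system is invariant to adding a constant to all 16 coefficients, so
#' the gauge is fixed by setting `s(TT) = 0`; the regression then has
#' exactly 15 free variables and no intercept. Dinucleotides that appear
#' in no equation of a block have an undefined coefficient and are
#' reported as missing (`NA`), not zero; blocks with fewer than
#' `min_sites` equations are reported entirely missing. For display the
#' coefficients (including the zero for TT) are mean-centered per block,
#' exactly as in [normalize_heatmap()].
#'
#' @param sites Allelic sites from [select_allelic_cpgs()].
#' @param min_sites Minimum equations per block to attempt a fit
#'   (default 50).
#' @param reference Gauge-fixing dinucleotide (default `"TT"`).
#' @return An object of class `allelic_fit`: `coefficients` and
#'   `centered` (16 x blocks matrices), per-block equation counts `n`,
#'   `n_free` (= 15) and the block geometry.
#' @export
fit_allelic_positionwise <- function(sites, min_sites = 50, reference = "TT") {
  stopifnot(reference %in% DINUCS)
  blocks_k <- sort(unique(sites$block))
  all_k <- c(seq(-max(abs(blocks_k)), -1L), seq(1L, max(abs(blocks_k))))
  ref_ix <- match(reference, DINUCS)

  coefs <- matrix(NA_real_,
    nrow = 16L, ncol = length(all_k),
    dimnames = list(DINUCS, all_k)
  )
  n_eq <- setNames(integer(length(all_k)), all_k)
  for (k in all_k) {
    rows <- sites[sites$block == k, ]
    n_eq[as.character(k)] <- nrow(rows)
    if (nrow(rows) < min_sites) next
    A <- matrix(0, nrow = nrow(rows), ncol = 16L)
    A[cbind(seq_len(nrow(rows)), match(rows$d_A, DINUCS))] <- 1
    A[cbind(seq_len(nrow(rows)), match(rows$d_R, DINUCS))] <-
      A[cbind(seq_len(nrow(rows)), match(rows$d_R, DINUCS))] - 1
    A <- A[, -ref_ix, drop = FALSE]
    seen <- colSums(A != 0) > 0
    est <- rep(NA_real_, 15L)
    if (any(seen)) {
      fit <- stats::lm.fit(A[, seen, drop = FALSE], rows$dm)
      est[seen] <- fit$coefficients
    }
    col <- rep(NA_real_, 16L)
    col[ref_ix] <- 0
    col[setdiff(1:16, ref_ix)] <- est
    coefs[, as.character(k)] <- col
  }
  centered <- sweep(coefs, 2, colMeans(coefs, na.rm = TRUE))
  centered[, colSums(!is.na(coefs)) == 0] <- NA_real_

  structure(
    list(
      coefficients = coefs, centered = centered,
      n = n_eq, n_free = 15L, reference = reference,
      blocks = tibble(
        block = all_k,
        offset = block_offsets(all_k)[, 1],
        n = as.integer(n_eq)
      )
    ),
    class = "allelic_fit"
  )
}

#' @export
print.allelic_fit <- function(x, ...) {
  fitted <- sum(colSums(!is.na(x$coefficients)) > 0)
  cat(sprintf(
    "<allelic_fit> %d/%d blocks fitted (%d free variables each, %s = 0); %d equations total\n",
    fitted, ncol(x$coefficients), x$n_free, x$reference, sum(x$n)
  ))
  invisible(x)
}

#' @export
tidy.allelic_fit <- function(x, ...) {
  tibble(
    block = rep(x$blocks$block, each = 16L),
    offset = rep(x$blocks$offset, each = 16L),
    dinucleotide = rep(DINUCS, times = ncol(x$coefficients)),
    estimate = as.vector(x$coefficients),
    centered = as.vector(x$centered),
    n_equations = rep(as.integer(x$n), each = 16L)
  )
}

#' @export
autoplot.allelic_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset + 0.5, y = .data$dinucleotide, fill = .data$centered)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red", midpoint = 0, na.value = "grey85") +
    ggplot2::labs(
      x = "offset from CpG (bp)", y = NULL, fill = "contribution",
      title = "Allelic dinucleotide contributions to methylation differences"
    )
}

#' Concordance between an allelic fit and a reference coefficient matrix
#'
#' Compares the per-block mean-centered allelic coefficients with a 16 x 78
#' positional coefficient matrix (e.g. the generating ground truth or a
#' fitted [dinuc_model] coefficient matrix), centering the reference over
#' the same non-missing cells per block, and returns the Pearson
#' correlation across all comparable cells. Because both the allelic
#' regression and the positional model estimate the same per-block
#' contributions up to a per-block constant, centered agreement is the
#' meaningful comparison.
#'
#' @param fit An `allelic_fit`.
#' @param coeffs 16 x 78 coefficient matrix (or a `dinuc_model`).
#' @return List with `r` (Pearson correlation) and `n_cells`.
#' @export
allelic_concordance <- function(fit, coeffs) {
  if (inherits(coeffs, "dinuc_model")) coeffs <- coeffs$coefficients
  k <- as.integer(colnames(fit$coefficients))
  col78 <- signed_block_to_column(k)
  ref <- coeffs[, col78, drop = FALSE]
  cen_ref <- ref
  for (j in seq_along(k)) {
    ok <- !is.na(fit$coefficients[, j])
    cen_ref[!ok, j] <- NA
    if (any(ok)) cen_ref[ok, j] <- ref[ok, j] - mean(ref[ok, j])
  }
  a <- as.vector(fit$centered)
  b <- as.vector(cen_ref)
  keep <- !is.na(a) & !is.na(b)
  list(r = stats::cor(a[keep], b[keep]), n_cells = sum(keep))
}
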