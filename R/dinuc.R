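# Positional dinucleotide model: the +-78 bp sequence environment of each
# CpG is split into 78 non-overlapping dinucleotide blocks (39 per side,
# tiled outward from the CpG; the CpG itself is excluded), each treated as
# a 16-state categorical predictor. With one reference state dropped per
# block the design has exactly 78 * 15 = 1170 columns.

FLANK_BP <- 78L # bases of sequence environment per side
N_BLOCKS <- 78L
N_PRED <- 78L * 15L

#' Block geometry of the positional dinucleotide model
#'
#' Left blocks cover plus-strand offsets (-78,-77), ..., (-2,-1) relative
#' to the C of the CpG; right blocks cover (+2,+3), ..., (+78,+79), i.e.
#' the 78 bases after the G. Blocks are ordered left to right along the
#' genome.
#'
#' @return Tibble with one row per block: `block` (1..78), `side`, `k`
#'   (1 = innermost), `offset` (start offset of the block relative to the
#'   C) and `center` (block midpoint offset).
#' @export
block_table <- function() {
  left <- tibble(
    side = "left", k = 39:1,
    offset = as.integer(seq(-78L, -2L, by = 2L))
  )
  right <- tibble(
    side = "right", k = 1:39,
    offset = as.integer(seq(2L, 78L, by = 2L))
  )
  out <- bind_rows(left, right)
  out$block <- seq_len(nrow(out))
  out$center <- out$offset + 0.5
  out[, c("block", "side", "k", "offset", "center")]
}

# Map a signed offset from the C of the CpG (0 = C, 1 = G) to a signed
# block index: -k for the k-th left block, +k for the k-th right block,
# NA for offsets inside the CpG.
#' Map an offset relative to the CpG to its dinucleotide block
#'
#' @param offset Integer offsets relative to the C of the CpG (0 is the C,
#'   1 the G).
#' @return Signed block indices (-k = k-th block left of the CpG, +k =
#'   k-th block right); `NA` for offsets 0 and 1 (inside the CpG).
#' @export
offset_to_block <- function(offset) {
  out <- ifelse(offset <= -1L, -ceiling(-offset / 2),
    ifelse(offset >= 2L, floor(offset / 2), NA_real_)
  )
  as.integer(out)
}

#' @rdname offset_to_block
#' @param k Signed block index.
#' @return `block_offsets()`: integer matrix with the two offsets covered
#'   by each block.
#' @export
block_offsets <- function(k) {
  stopifnot(all(k != 0, na.rm = TRUE))
  first <- ifelse(k < 0, 2L * k, 2L * k)
  cbind(first = as.integer(first), second = as.integer(first + 1L))
}

# Signed block index -> column of the 78-block table (left 39..1, right 1..39).
signed_block_to_column <- function(k) {
  as.integer(ifelse(k < 0, 40L + k, 39L + k))
}

# Extract the 160 bp context window (pos-78 .. pos+79) for each CpG.
# Returns the window strings plus the logical vector of encodable CpGs
# (full non-N flanks on both sides).
context_windows_flank <- function(cpgs, genome, left, right) {
  w <- substr_genome(genome, cpgs$chrom, cpgs$pos - left, cpgs$pos + right)
  ok <- !is.na(w) & !stringr::str_detect(w, "[^ACGT]")
  list(window = w, ok = ok)
}

# n x 78 integer matrix of dinucleotide codes (1..16) from 160 bp windows.
window_codes <- function(windows) {
  blocks <- block_table()
  n <- length(windows)
  codes <- matrix(NA_integer_, nrow = n, ncol = N_BLOCKS)
  for (b in seq_len(N_BLOCKS)) {
    idx <- blocks$offset[b] + FLANK_BP + 1L # window string index of block start
    codes[, b] <- match(substr(windows, idx, idx + 1L), DINUCS)
  }
  codes
}

#' Encode CpG sequence environments as a dinucleotide design
#'
#' Extracts the +-78 bp sequence environment of each CpG, tiles it into 78
#' non-overlapping dinucleotide blocks and records the observed state per
#' block. CpGs lacking a full non-N flank on either side are skipped with a
#' message. With the per-block reference state dropped, the implied
#' one-hot design has exactly `78 * 15 = 1170` predictor columns.
#'
#' @param cpgs Tibble of CpG records (needs `chrom`, `pos`; `level` is
#'   carried through when present).
#' @param genome Named character vector of chromosome sequences.
#' @param reference Reference (dropped) dinucleotide per block: `"first"`
#'   (default) drops the lexicographically first state observed in each
#'   block, or give a single dinucleotide (e.g. `"AA"`) used for all blocks.
#' @return An object of class `dinuc_design`: the retained CpGs, the
#'   per-block state codes, the block geometry and the reference states.
#' @export
encode_contexts <- function(cpgs, genome, reference = "first") {
  cw <- context_windows_flank(cpgs, genome, FLANK_BP, FLANK_BP + 1L)
  n_skip <- sum(!cw$ok)
  if (n_skip > 0) inform(sprintf("skipped %d CpG(s) without a full +-78 bp non-N flank", n_skip))
  kept <- cpgs[cw$ok, ]
  codes <- window_codes(cw$window[cw$ok])
  if (identical(reference, "first")) {
    ref <- apply(codes, 2, function(col) min(col))
  } else {
    stopifnot(reference %in% DINUCS)
    ref <- rep(match(reference, DINUCS), N_BLOCKS)
  }
  structure(
    list(
      cpgs = kept, codes = codes, blocks = block_table(),
      reference = as.integer(ref), n_predictors = N_PRED, n_skipped = n_skip
    ),
    class = "dinuc_design"
  )
}

#' @export
print.dinuc_design <- function(x, ...) {
  cat(sprintf(
    "<dinuc_design> %d CpGs x %d blocks (%d predictor columns), %d skipped\n",
    nrow(x$codes), ncol(x$codes), x$n_predictors, x$n_skipped
  ))
  invisible(x)
}

#' Materialise the sparse one-hot design matrix
#'
#' @param design A `dinuc_design`.
#' @param rows Optional row subset.
#' @return A sparse `dgCMatrix` with `78 * 15 = 1170` columns named
#'   `"<offset>:<dinucleotide>"`.
#' @export
design_matrix <- function(design, rows = NULL) {
  codes <- design$codes
  if (!is.null(rows)) codes <- codes[rows, , drop = FALSE]
  n <- nrow(codes)
  # per block: map state code -> column index (0 for the reference state)
  colmap <- matrix(0L, nrow = 16L, ncol = N_BLOCKS)
  cn <- character(N_PRED)
  for (b in seq_len(N_BLOCKS)) {
    states <- setdiff(1:16, design$reference[b])
    colmap[states, b] <- (b - 1L) * 15L + seq_len(15L)
    cn[(b - 1L) * 15L + seq_len(15L)] <- paste0(design$blocks$offset[b], ":", DINUCS[states])
  }
  j <- colmap[cbind(as.vector(codes), rep(seq_len(N_BLOCKS), each = n))]
  i <- rep(seq_len(n), times = N_BLOCKS)
  keep <- j != 0L
  Matrix::sparseMatrix(
    i = i[keep], j = j[keep], x = 1,
    dims = c(n, N_PRED), dimnames = list(NULL, cn)
  )
}

# Solve least squares from normal equations with a pseudoinverse fallback
# (singular values below tol * max treated as zero).
solve_ls <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, backsolve(ch, b, transpose = TRUE)))
  }
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% ((crossprod(s$u[, pos, drop = FALSE], b)) / s$d[pos])
}

#' Fit the positional dinucleotide model
#'
#' Ordinary least squares of the single-CpG methylation level on the 1170
#' positional dinucleotide predictors plus an intercept, fitted on a seeded
#' random training subset and evaluated on a disjoint held-out subset.
#' Dinucleotide states absent from the training rows of a block are
#' reported as coefficient 0 and flagged.
#'
#' @param design A `dinuc_design` from [encode_contexts()].
#' @param levels Methylation levels, one per design row; defaults to the
#'   `level` column carried in the design.
#' @param n_train,n_test Sizes of the disjoint random training and test
#'   subsets; default 80/20 split.
#' @param seed Integer seed for the subset draw.
#' @return An object of class `dinuc_model` with elements `coefficients`
#'   (16 x 78 matrix, reference states 0), `intercept`, `heatmap` (the
#'   mean-centered 16 x 78 matrix, see [normalize_heatmap()]), and
#'   `evaluation` (`r`, `R2` = 1 - SSE/SST on the held-out set, `n_train`,
#'   `n_test`).
#' @export
fit_dinuc_model <- function(design, levels = NULL, n_train = NULL, n_test = NULL, seed = 1) {
  y_all <- levels %||% design$cpgs$level
  n <- nrow(design$codes)
  stopifnot(length(y_all) == n)
  if (is.null(n_train)) n_train <- floor(0.8 * n)
  if (is.null(n_test)) n_test <- n - n_train
  if (n_train + n_test > n) abort("n_train + n_test exceeds the number of encodable CpGs")
  idx <- with_stage_seed(seed, "dinuc_split", sample.int(n, n_train + n_test))
  train <- idx[seq_len(n_train)]
  test <- idx[n_train + seq_len(n_test)]

  X <- design_matrix(design, rows = train)
  y <- y_all[train]
  present <- Matrix::colSums(X) > 0
  dropped <- colnames(X)[!present]
  Xp <- X[, present, drop = FALSE]
  XtX <- as.matrix(Matrix::crossprod(Xp))
  Xty <- as.numeric(Matrix::crossprod(Xp, y))
  sx <- Matrix::colSums(Xp)
  # augment with the intercept row/column
  A <- rbind(
    c(length(y), sx),
    cbind(sx, XtX)
  )
  b <- c(sum(y), Xty)
  beta <- as.numeric(solve_ls(A, b))
  intercept <- beta[1]
  coef_cols <- numeric(N_PRED)
  coef_cols[present] <- beta[-1]

  coefs <- matrix(0, nrow = 16L, ncol = N_BLOCKS, dimnames = list(DINUCS, block_table()$offset))
  for (b_ix in seq_len(N_BLOCKS)) {
    states <- setdiff(1:16, design$reference[b_ix])
    coefs[states, b_ix] <- coef_cols[(b_ix - 1L) * 15L + seq_len(15L)]
  }

  fit <- structure(
    list(
      coefficients = coefs, intercept = intercept,
      reference = design$reference, blocks = design$blocks,
      dropped = dropped, heatmap = NULL, evaluation = NULL
    ),
    class = "dinuc_model"
  )
  fit$heatmap <- normalize_heatmap(coefs)

  pred <- predict(fit, design, rows = test)
  obs <- y_all[test]
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  r <- if (stats::sd(pred) > 0 && stats::sd(obs) > 0) stats::cor(pred, obs) else NA_real_
  fit$evaluation <- list(
    r = r,
    R2 = if (sst > 0) 1 - sse / sst else 0,
    n_train = n_train, n_test = n_test
  )
  fit$train_rows <- train
  fit$test_rows <- test
  fit
}

#' Predict methylation levels from a fitted dinucleotide model
#'
#' Linear prediction `intercept + sum of the 78 observed block
#' coefficients`; values are reported unclipped unless `clip = TRUE`.
#'
#' @param object A `dinuc_model`.
#' @param design A `dinuc_design` encoded with the same geometry.
#' @param rows Optional row subset.
#' @param clip Clip predictions to \[0, 1\]?
#' @param ... Unused.
#' @return Numeric vector of predicted levels.
#' @export
predict.dinuc_model <- function(object, design, rows = NULL, clip = FALSE, ...) {
  codes <- design$codes
  if (!is.null(rows)) codes <- codes[rows, , drop = FALSE]
  if (ncol(codes) != ncol(object$coefficients)) {
    abort("design block count does not match the fitted model")
  }
  n <- nrow(codes)
  contrib <- object$coefficients[cbind(
    as.vector(codes),
    rep(seq_len(ncol(codes)), each = n)
  )]
  out <- object$intercept + rowSums(matrix(contrib, nrow = n))
  if (clip) out <- clamp01(out)
  out
}

#' Mean-center a positional coefficient matrix for display
#'
#' The dropped reference dinucleotide is already present as a zero in the
#' 16 x 78 coefficient matrix; each block (column) is then centered to mean
#' exactly 0, which makes the heatmap invariant to the choice of reference
#' state.
#'
#' @param x A 16 x 78 coefficient matrix or a `dinuc_model`.
#' @return The centered 16 x 78 matrix; each column sums to 0.
#' @export
normalize_heatmap <- function(x) {
  if (inherits(x, "dinuc_model")) x <- x$coefficients
  sweep(x, 2, colMeans(x))
}

#' @export
print.dinuc_model <- function(x, ...) {
  ev <- x$evaluation
  cat("<dinuc_model> positional dinucleotide regression (78 blocks x 15 dummies)\n")
  cat(sprintf("  intercept %.4f; %d dropped (absent) predictor column(s)\n", x$intercept, length(x$dropped)))
  if (!is.null(ev)) {
    cat(sprintf(
      "  held-out: r = %.3f, R2 = %.3f (train %d / test %d)\n",
      ev$r, ev$R2, ev$n_train, ev$n_test
    ))
  }
  invisible(x)
}

#' @export
tidy.dinuc_model <- function(x, ...) {
  blocks <- block_table()
  tibble(
    offset = rep(blocks$offset, each = 16L),
    center = rep(blocks$center, each = 16L),
    dinucleotide = rep(DINUCS, times = N_BLOCKS),
    estimate = as.vector(x$coefficients),
    normalized = as.vector(x$heatmap)
  )
}

#' @export
glance.dinuc_model <- function(x, ...) {
  ev <- x$evaluation
  tibble(
    r = ev$r, R2 = ev$R2, n_train = ev$n_train, n_test = ev$n_test,
    intercept = x$intercept, n_dropped = length(x$dropped)
  )
}

#' @export
autoplot.dinuc_model <- function(object, window = 60, ...) {
  df <- tidy(object)
  df <- df[abs(df$center) <= window, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$dinucleotide, fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red", midpoint = 0) +
    ggplot2::labs(
      x = "offset from CpG (bp)", y = NULL, fill = "contribution",
      title = "Positional dinucleotide contributions to methylation"
    )
}
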