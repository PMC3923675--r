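# Shared small helpers: dinucleotide alphabet, seeding, clamping.

# The 16 dinucleotide states in fixed lexicographic order. All coefficient
# matrices in the package are indexed by this order.
DINUCS <- c(
  "AA", "AC", "AG", "AT",
  "CA", "CC", "CG", "CT",
  "GA", "GC", "GG", "GT",
  "TA", "TC", "TG", "TT"
)

BASES <- c("A", "C", "G", "T")

#' Dinucleotide alphabet
#'
#' The 16 dinucleotide states, in the fixed order used by every coefficient
#' matrix in the package.
#'
#' @return Character vector of length 16 (`"AA"` ... `"TT"`).
#' @export
dinucleotides <- function() DINUCS

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic per-stage substream seeds derived from one user seed, kept
# within 32-bit integer range so set.seed() accepts them.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 2654435 + h * 97 + 12345) %% 2147483647L)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(derive_seed(seed, stage), code)
}

# Poisson truncated at >= 1 (coverage law for simulated read totals).
rpois_pos <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(z <- x == 0L)) x[z] <- stats::rpois(sum(z), lambda)
  x
}

#' Maximum read overhang outside a centered sequence context
#'
#' For a bisulfite read of `read_length` bp that must overlap the central
#' CpG of a context window of `context_length` bp (CpG in the middle), the
#' closed-form maximum number of bases the read can extend beyond the
#' window is `read_length - context_length / 2`. With 87 bp reads and a
#' 140 bp context this leaves 17 bp to anchor a unique alignment, which is
#' why identical-context analyses cap the context length.
#'
#' @param read_length Read length in bp.
#' @param context_length Even context window length in bp, CpG centered.
#' @return Maximum overhang in bp (can be negative if the read fits
#'   entirely inside the window).
#' @export
context_read_overhang <- function(read_length = 87, context_length = 140) {
  stopifnot(context_length %% 2 == 0)
  read_length - context_length / 2
}

# Attenuation (noise) ceilings: the maximum correlation achievable given
# latent variance v and measurement noise variance sigma2.
# Two noisy measurements of the same latent value:
#' Attenuation ceilings for noisy methylation measurements
#'
#' With latent single-CpG methylation probabilities of variance `v` and
#' binomial measurement noise of average variance `noise` (`E[p(1-p)/c]`
#' for coverage `c`), the expected Pearson correlation between two
#' independent noisy measurements of the same sites is `v / (v + noise)`
#' (`attenuation_pair_r`), and the ceiling for the correlation between a
#' perfect predictor and one noisy measurement is
#' `sqrt(v / (v + noise))` (`attenuation_model_r`).
#'
#' @param v Variance of the latent methylation probabilities.
#' @param noise Average measurement noise variance.
#' @return A correlation bound in \[0, 1\].
#' @export
attenuation_pair_r <- function(v, noise) v / (v + noise)

#' @rdname attenuation_pair_r
#' @export
attenuation_model_r <- function(v, noise) sqrt(v / (v + noise))

#' Fisher confidence interval of a sample Pearson correlation
#'
#' @param r Sample correlation.
#' @param n Number of pairs.
#' @param level Confidence level (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
cor_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}
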