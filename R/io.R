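# File I/O. Coordinates are 1-based closed internally (R/Bioconductor
# convention); BED is 0-based half-open on disk and converted on read/write;
# VCF positions are 1-based and consumed natively.

#' Read and write per-strand cytosine call tables
#'
#' Tab-delimited with header `chrom, pos, strand, meth, total`: one row per
#' cytosine call, `pos` the 1-based position of the called C on its strand
#' (plus-strand C of a CpG at the C, minus-strand C at the G position),
#' `meth`/`total` the methylated and total read counts.
#'
#' @param path File path.
#' @return A tibble of per-strand calls.
#' @export
read_meth_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    strand = readr::col_character(),
    meth = readr::col_integer(),
    total = readr::col_integer()
  ))
}

#' @rdname read_meth_calls
#' @param calls Tibble of per-strand calls.
#' @export
write_meth_calls <- function(calls, path) {
  readr::write_tsv(calls[, c("chrom", "pos", "strand", "meth", "total")], path)
  invisible(path)
}

#' Read and write combined-strand CpG tables
#'
#' Tab-delimited with header `chrom, pos, meth, total, level` (plus any
#' extra annotation columns); `pos` is the 1-based position of the C of the
#' CpG on the plus strand.
#'
#' @param path File path.
#' @return A tibble of CpG sites.
#' @export
read_cpg_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    meth = readr::col_integer(),
    total = readr::col_integer(),
    level = readr::col_double(),
    .default = readr::col_guess()
  ))
}

#' @rdname read_cpg_table
#' @param cpgs Tibble of CpG sites.
#' @export
write_cpg_table <- function(cpgs, path) {
  readr::write_tsv(cpgs, path)
  invisible(path)
}

#' Read and write genomic interval sets as BED
#'
#' BED intervals (0-based half-open on disk) are converted to the package's
#' 1-based closed convention on read. Column 4, when present, is kept as
#' the interval class (e.g. a repeat class).
#'
#' @param path File path.
#' @param label Optional label attached to the set (e.g. `"PMD"`).
#' @return A tibble with columns `chrom, start, end` and optionally `class`.
#' @export
read_bed_regions <- function(path, label = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = readr::col_character()))
  out <- tibble(
    chrom = raw$X1,
    start = as.integer(raw$X2) + 1L,
    end = as.integer(raw$X3)
  )
  if (ncol(raw) >= 4) out$class <- raw$X4
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' @rdname read_bed_regions
#' @param regions Tibble of intervals (1-based closed).
#' @export
write_bed_regions <- function(regions, path) {
  bed <- tibble(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end
  )
  if ("class" %in% names(regions)) bed$class <- regions$class
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read heterozygous SNPs from a VCF file
#'
#' Uses `vcfR` to parse the file; returns single-nucleotide biallelic
#' records only.
#'
#' @param path VCF file path.
#' @return A tibble `chrom, pos, ref, alt` (1-based positions).
#' @export
read_snps_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  out[nchar(out$ref) == 1 & nchar(out$alt) == 1 &
    out$ref %in% BASES & out$alt %in% BASES, ]
}

#' @rdname read_snps_vcf
#' @param snps Tibble with `chrom, pos, ref, alt`.
#' @export
write_snps_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(snps) > 0) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tHET",
      snps$chrom, snps$pos, snps$ref, snps$alt
    ), con)
  }
  invisible(path)
}

#' Read and write a genome as FASTA
#'
#' @param path FASTA file path.
#' @return A named character vector, one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path
  )
  invisible(path)
}
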