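# Internal sequence helpers. All pipeline-internal sequences are plain
# uppercase character scalars; RNA alphabet (ACGU) in transcript orientation,
# DNA alphabet (ACGT) in genomic plus-strand orientation.

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Errors on any character outside ACGTU.
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @return character scalar over ACGU.
#' @keywords internal
#' @noRd
as_rna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- regexpr("[^ACGTU]", x)
  if (bad > 0L) {
    stop(sprintf("non-ACGTU character '%s' in %s at offset %d",
                 substr(x, bad, bad), what, bad), call. = FALSE)
  }
  chartr("T", "U", x)
}

# DNA counterpart (U -> T), same validation.
as_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- regexpr("[^ACGTU]", x)
  if (bad > 0L) {
    stop(sprintf("non-ACGTU character '%s' in %s at offset %d",
                 substr(x, bad, bad), what, bad), call. = FALSE)
  }
  chartr("U", "T", x)
}

# Reverse complement in the given alphabet; input must already be normalized.
revcomp_rna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Watson-Crick complement of a single RNA base (vectorized over characters).
wc_complement_rna <- function(x) chartr("ACGU", "UGCA", x)
wc_complement_dna <- function(x) chartr("ACGT", "TGCA", x)

# TRUE if mirna base (5'->3') and target base form a Watson-Crick pair.
is_wc_pair <- function(mir_base, tgt_base) {
  paste0(mir_base, tgt_base) %in% c("AU", "UA", "GC", "CG")
}

# TRUE for a G:U wobble.
is_gu_pair <- function(mir_base, tgt_base) {
  paste0(mir_base, tgt_base) %in% c("GU", "UG")
}

# Canonical variant key used by control subtraction and recurrence.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, toupper(ref), toupper(alt), sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a character scalar into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
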