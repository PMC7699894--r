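# Strand-aware mapping between the genomic frame (1-based, plus-strand
# reference sequence) and the transcript frame (0-based offsets into the
# mRNA-orientation sequence), and application of somatic variants to produce
# wildtype/mutant allele pairs. The transcript frame (5'->3' of the mRNA) is
# the canonical frame for all site prediction; the genomic frame is I/O only.

#' Attach reference sequence to regions
#'
#' Extracts each region's plus-strand reference sequence from a set of
#' chromosome (or contig window) sequences and stores it in a `ref_seq`
#' column.
#'
#' @param regions region data.frame from [read_regions()].
#' @param reference named `DNAStringSet` (or named character vector), one
#'   entry per chromosome present in `regions`.
#' @param offsets optional named integer vector giving the genomic position
#'   of base 1 of each reference entry (default 1, i.e. full chromosomes).
#'   Lets small fixture windows stand in for whole chromosomes.
#' @return `regions` with a `ref_seq` column (uppercase DNA, plus strand).
#' @export
region_with_seq <- function(regions, reference, offsets = NULL) {
  seqs <- if (is.character(reference)) reference else as.character(reference)
  regions$ref_seq <- vapply(seq_len(nrow(regions)), function(i) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(seqs)) {
      stop("no reference sequence for ", chrom, call. = FALSE)
    }
    off <- if (!is.null(offsets) && chrom %in% names(offsets)) offsets[[chrom]] else 1L
    lo <- regions$start[i] - off + 1L
    hi <- regions$end[i] - off + 1L
    if (lo < 1L || hi > nchar(seqs[[chrom]])) {
      stop("region ", regions$region_id[i], " outside reference for ", chrom,
           call. = FALSE)
    }
    toupper(substr(seqs[[chrom]], lo, hi))
  }, character(1))
  if (any(nchar(regions$ref_seq) != regions$end - regions$start + 1L)) {
    stop("ref_seq length mismatch", call. = FALSE)
  }
  regions
}

#' Transcript-orientation sequence of a region
#'
#' @param region one-row region data.frame (or list) with `ref_seq` and
#'   `strand`.
#' @return the mRNA 5'->3' sequence: `ref_seq` on `+`, reverse complement
#'   on `-`.
#' @export
transcript_seq <- function(region) {
  if (region$strand == "+") region$ref_seq else revcomp_dna(region$ref_seq)
}

#' Map a genomic SNV to transcript coordinates
#'
#' On the plus strand offsets increase with genomic position and bases are
#' unchanged; on the minus strand offsets reverse and alleles are
#' complemented. The reference allele is checked against the region sequence
#' and a mismatch is a hard error (silently wrong strands are the main
#' failure mode of this analysis).
#'
#' @param region one-row region data.frame with `ref_seq`.
#' @param pos genomic position (1-based), `start <= pos <= end`.
#' @param ref,alt single-base genomic alleles.
#' @return list with `tx_offset` (0-based offset in the transcript-orientation
#'   sequence), `tx_ref`, `tx_alt`.
#' @export
genomic_to_transcript <- function(region, pos, ref, alt) {
  if (pos < region$start || pos > region$end) {
    stop(sprintf("position %d outside region %s (%d-%d)", pos,
                 region$region_id, region$start, region$end), call. = FALSE)
  }
  ref <- toupper(ref); alt <- toupper(alt)
  obs <- substr(region$ref_seq, pos - region$start + 1L, pos - region$start + 1L)
  if (obs != ref) {
    stop(sprintf("reference mismatch at %s:%d: expected %s, reference has %s",
                 region$chrom, pos, ref, obs), call. = FALSE)
  }
  if (region$strand == "+") {
    list(tx_offset = pos - region$start, tx_ref = ref, tx_alt = alt)
  } else {
    list(tx_offset = region$end - pos,
         tx_ref = wc_complement_dna(ref), tx_alt = wc_complement_dna(alt))
  }
}

#' Map a transcript offset back to its genomic position
#'
#' Inverse of the position part of [genomic_to_transcript()].
#'
#' @param region one-row region data.frame.
#' @param tx_offset 0-based transcript-orientation offset.
#' @return genomic position (1-based).
#' @export
transcript_to_genomic <- function(region, tx_offset) {
  len <- region$end - region$start + 1L
  if (tx_offset < 0L || tx_offset >= len) {
    stop("transcript offset out of range", call. = FALSE)
  }
  if (region$strand == "+") region$start + tx_offset else region$end - tx_offset
}

#' Apply a variant to a region, yielding a wildtype/mutant allele pair
#'
#' The variant (anchored VCF-style alleles) is applied in the genomic frame
#' and both sequences are returned in transcript orientation. `tx_offset` is
#' the 0-based offset of the first base at which the two transcript
#' sequences differ.
#'
#' @param region one-row region data.frame with `ref_seq`.
#' @param variant one-row variant data.frame (or list) with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @return list of class `allele_pair`: `region_id`, `wt_seq`, `mut_seq`,
#'   `variant`, `tx_offset`.
#' @export
apply_variant <- function(region, variant) {
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  classify_variant(ref, alt)  # validates allele shape
  pos <- variant$pos
  if (variant$chrom != region$chrom) {
    stop("variant on ", variant$chrom, " does not lie in region on ",
         region$chrom, call. = FALSE)
  }
  lo <- pos - region$start + 1L
  hi <- lo + nchar(ref) - 1L
  if (lo < 1L || hi > nchar(region$ref_seq)) {
    stop("variant not fully contained in region ", region$region_id,
         call. = FALSE)
  }
  obs <- substr(region$ref_seq, lo, hi)
  if (obs != ref) {
    stop(sprintf("reference mismatch at %s:%d: expected %s, reference has %s",
                 region$chrom, pos, ref, obs), call. = FALSE)
  }
  mut_plus <- paste0(substr(region$ref_seq, 1L, lo - 1L), alt,
                     substr(region$ref_seq, hi + 1L, nchar(region$ref_seq)))
  wt <- transcript_seq(region)
  mut <- if (region$strand == "+") mut_plus else revcomp_dna(mut_plus)
  stopifnot(wt != mut)
  # first differing offset, 0-based, in transcript orientation
  n <- min(nchar(wt), nchar(mut))
  wt_c <- chars(wt); mut_c <- chars(mut)
  diffs <- which(wt_c[seq_len(n)] != mut_c[seq_len(n)])
  tx_offset <- if (length(diffs)) diffs[1L] - 1L else n
  structure(list(region_id = region$region_id, wt_seq = wt, mut_seq = mut,
                 variant = as.list(variant)[c("chrom", "pos", "ref", "alt")],
                 tx_offset = tx_offset),
            class = "allele_pair")
}

#' Extract a site window with flanks
#'
#' Returns the transcript-orientation subsequence covering a site plus up to
#' `flank` bases on each side, truncated silently at the region boundaries;
#' the actually obtained flank lengths are reported.
#'
#' @param region one-row region data.frame with `ref_seq`.
#' @param tx_start,tx_end 0-based half-open site offsets in transcript
#'   orientation.
#' @param flank non-negative integer, default 150 (the flank length used when
#'   cloning binding sites into reporter constructs).
#' @return list: `seq`, `win_start`, `win_end` (0-based half-open window
#'   offsets), `up_flank`, `down_flank` (obtained lengths).
#' @export
extract_flanked_window <- function(region, tx_start, tx_end, flank = 150L) {
  stopifnot(flank >= 0L, tx_end > tx_start)
  txs <- transcript_seq(region)
  len <- nchar(txs)
  if (tx_start < 0L || tx_end > len) stop("site outside region", call. = FALSE)
  win_start <- max(0L, tx_start - flank)
  win_end <- min(len, tx_end + flank)
  list(seq = substr(txs, win_start + 1L, win_end),
       win_start = win_start, win_end = win_end,
       up_flank = tx_start - win_start, down_flank = win_end - tx_end)
}

#' Write paired wildtype/mutant FASTA files
#'
#' Mirrors the pipeline intermediate of a UTR FASTA without mutations and a
#' matching mutant FASTA; headers are `<region_id>|<chrom>:<pos>:<ref>/<alt>|wt`
#' and `...|mut`.
#'
#' @param pairs list of `allele_pair` objects from [apply_variant()].
#' @param wt_path,mut_path output FASTA paths.
#' @export
write_allele_fasta <- function(pairs, wt_path, mut_path) {
  hdr <- vapply(pairs, function(p) {
    sprintf("%s|%s:%d:%s/%s", p$region_id, p$variant$chrom, p$variant$pos,
            p$variant$ref, p$variant$alt)
  }, character(1))
  wt <- Biostrings::DNAStringSet(vapply(pairs, `[[`, character(1), "wt_seq"))
  mut <- Biostrings::DNAStringSet(vapply(pairs, `[[`, character(1), "mut_seq"))
  names(wt) <- paste0(hdr, "|wt"); names(mut) <- paste0(hdr, "|mut")
  Biostrings::writeXStringSet(wt, wt_path)
  Biostrings::writeXStringSet(mut, mut_path)
  invisible(c(wt_path, mut_path))
}
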