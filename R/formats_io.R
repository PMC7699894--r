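# Readers and writers for the standard formats the pipeline touches, plus
# normalization into the internal data model:
#   * mature miRNAs     -> data.frame(name, sequence, seed)
#   * somatic variants  -> data.frame(chrom, pos, ref, alt, sample_id,
#                                      coverage, vaf, [gene])
#   * transcript regions-> data.frame(region_id, chrom, start, end, strand,
#                                      gene, kind, [ref_seq])
# All genomic coordinates are 1-based inclusive internally; BED is converted
# at the boundary.

#' Read mature miRNA sequences from FASTA
#'
#' Reads a miRBase-style mature FASTA. Sequences are normalized to the RNA
#' alphabet (T is converted to U) and the canonical 7-nt seed (positions 2-8,
#' 1-based from the 5' end) is extracted.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `name` (first whitespace-delimited header
#'   token), `sequence` (5'->3', ACGU) and `seed` (characters 2-8), in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-miR-X toy", "UACAGUAUAGAUGAUGUACU"), fa)
#' read_mirna_fasta(fa)$seed  # "ACAGUAU"
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(name = character(), sequence = character(),
                      seed = character(), stringsAsFactors = FALSE))
  }
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate miRNA name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    as_rna(seqs[i], what = sprintf("record '%s'", nm[i]))
  }, character(1))
  mirna_table(nm, seqs)
}

#' Construct a mature miRNA table from names and sequences
#'
#' @param name character vector of miRNA names.
#' @param sequence character vector of 5'->3' sequences (ACGU or ACGT;
#'   normalized to RNA). Lengths must be between 15 and 30 nt.
#' @return data.frame with columns `name`, `sequence`, `seed`.
#' @export
mirna_table <- function(name, sequence) {
  sequence <- vapply(seq_along(sequence), function(i) {
    as_rna(sequence[i], what = sprintf("miRNA '%s'", name[i]))
  }, character(1))
  n <- nchar(sequence)
  if (any(n < 15L | n > 30L)) {
    stop("miRNA sequence length outside [15, 30] nt for: ",
         paste(name[n < 15L | n > 30L], collapse = ", "), call. = FALSE)
  }
  data.frame(name = as.character(name), sequence = sequence,
             seed = substr(sequence, 2L, 8L), stringsAsFactors = FALSE)
}

#' Classify a variant as SNV, insertion or deletion
#'
#' Alleles follow the anchored VCF convention: an insertion's ALT extends its
#' REF prefix, a deletion's REF extends its ALT prefix. Anything else with
#' both alleles longer than one base is rejected as an unsupported complex
#' variant.
#'
#' @param ref,alt character vectors of reference/alternate alleles.
#' @return character vector in `c("snv", "insertion", "deletion")`.
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  mapply(function(r, a) {
    if (nchar(r) == 0L || nchar(a) == 0L) stop("empty allele", call. = FALSE)
    if (r == a) stop("ref and alt alleles identical: ", r, call. = FALSE)
    if (nchar(r) == 1L && nchar(a) == 1L) return("snv")
    if (nchar(a) > nchar(r) && startsWith(a, r)) return("insertion")
    if (nchar(r) > nchar(a) && startsWith(r, a)) return("deletion")
    stop(sprintf("unsupported complex variant %s/%s (no shared anchor prefix)",
                 r, a), call. = FALSE)
  }, ref, alt, USE.NAMES = FALSE)
}

#' Read somatic variants
#'
#' Two dialects are supported. `coord_tsv` is a headered TSV carrying either
#' the columns `chrom`, `pos`, `ref`, `alt` or the compact columns `position`
#' ("chr7:148508727") and `mutation` ("T/A"); optional columns `sample_id`,
#' `coverage`, `vaf` and `gene` are carried through. `vcf` reads VCF v4.x via
#' VariantAnnotation; multi-allelic records are split, per-sample coverage is
#' taken from FORMAT `DP` and VAF from FORMAT `AF` (or computed from `AD`),
#' and one row is emitted per carrier sample (samples with no ALT evidence
#' are skipped).
#'
#' @param path input file.
#' @param dialect `"coord_tsv"` or `"vcf"`.
#' @return variant data.frame (see package overview); positions are 1-based.
#' @export
read_variants <- function(path, dialect = c("coord_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "coord_tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

read_variants_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "", quote = "", check.names = FALSE)
  if (all(c("position", "mutation") %in% names(df))) {
    toks <- strsplit(df$position, ":", fixed = TRUE)
    bad <- which(lengths(toks) != 2L | is.na(suppressWarnings(
      as.integer(vapply(toks, function(t) t[min(2L, length(t))], character(1))))))
    if (length(bad)) {
      stop("malformed position token at data line ", bad[1L], ": ",
           df$position[bad[1L]], call. = FALSE)
    }
    df$chrom <- vapply(toks, `[`, character(1), 1L)
    df$pos <- as.integer(vapply(toks, `[`, character(1), 2L))
    al <- strsplit(df$mutation, "/", fixed = TRUE)
    if (any(lengths(al) != 2L)) {
      stop("malformed mutation token at data line ",
           which(lengths(al) != 2L)[1L], call. = FALSE)
    }
    df$ref <- toupper(vapply(al, `[`, character(1), 1L))
    df$alt <- toupper(vapply(al, `[`, character(1), 2L))
  }
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(df))) {
    stop("variant TSV needs columns chrom/pos/ref/alt or position/mutation",
         call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  if (anyNA(df$pos)) {
    stop("malformed position at data line ", which(is.na(df$pos))[1L],
         call. = FALSE)
  }
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  df$type <- classify_variant(df$ref, df$alt)
  if (!"sample_id" %in% names(df)) df$sample_id <- NA_character_
  if (!"coverage" %in% names(df)) df$coverage <- NA_integer_
  if (!"vaf" %in% names(df)) df$vaf <- NA_real_
  keep <- c("chrom", "pos", "ref", "alt", "type", "sample_id", "coverage", "vaf",
            intersect("gene", names(df)))
  df[, keep, drop = FALSE]
}

read_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # split multi-allelic records
  n <- length(vcf)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), type = character(),
                      sample_id = character(), coverage = integer(),
                      vaf = double(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  geno <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  if (length(samples) == 0L) {
    return(data.frame(chrom = chrom, pos = pos, ref = toupper(ref),
                      alt = toupper(alt), type = classify_variant(ref, alt),
                      sample_id = NA_character_, coverage = NA_integer_,
                      vaf = NA_real_, stringsAsFactors = FALSE))
  }
  out <- list()
  for (s in samples) {
    gt <- if ("GT" %in% names(geno)) geno$GT[, s] else rep("1", n)
    carrier <- !gt %in% c("0/0", "0|0", "./.", ".", "0")
    if (!any(carrier)) next
    dp <- if ("DP" %in% names(geno)) as.integer(geno$DP[, s]) else rep(NA_integer_, n)
    if ("AF" %in% names(geno)) {
      af <- as.numeric(geno$AF[, s])
    } else if ("AD" %in% names(geno)) {
      ad <- geno$AD
      if (length(dim(ad)) == 3L) {  # expand() yields [record, sample, ref/alt]
        tot <- ad[, s, 1L] + ad[, s, 2L]
        af <- ifelse(tot > 0, ad[, s, 2L] / tot, NA_real_)
      } else {
        af <- vapply(ad[, s], function(x) {
          x <- as.numeric(x)
          if (length(x) < 2L || sum(x) == 0) NA_real_ else x[2L] / sum(x)
        }, double(1))
      }
    } else {
      af <- rep(NA_real_, n)
    }
    out[[s]] <- data.frame(
      chrom = chrom[carrier], pos = pos[carrier],
      ref = toupper(ref[carrier]), alt = toupper(alt[carrier]),
      type = classify_variant(ref[carrier], alt[carrier]),
      sample_id = s, coverage = dp[carrier], vaf = af[carrier],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read stranded transcript regions
#'
#' Accepts BED6 (0-based half-open, converted losslessly to 1-based
#' inclusive) or a headered internal TSV that is already 1-based inclusive
#' with columns `chrom`, `start`, `end`, `strand` and optional `region_id`,
#' `gene`, `kind`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return region data.frame (1-based inclusive, `strand` in `+`/`-`).
#' @export
read_regions <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(GenomicRanges::width(gr) < 1L)) {
      stop("zero-length BED interval(s) in ", path, call. = FALSE)
    }
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*")) stop("BED strand column required", call. = FALSE)
    nm <- gr$name
    if (is.null(nm) || anyNA(nm)) nm <- paste0("region", seq_along(gr))
    df <- data.frame(
      region_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = strand, gene = nm, kind = "utr3", stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    req <- c("chrom", "start", "end", "strand")
    if (!all(req %in% names(df))) {
      stop("region TSV needs columns chrom/start/end/strand", call. = FALSE)
    }
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    if (!"region_id" %in% names(df)) df$region_id <- paste0("region", seq_len(nrow(df)))
    if (!"gene" %in% names(df)) df$gene <- df$region_id
    if (!"kind" %in% names(df)) df$kind <- "utr3"
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$start > df$end)) stop("region start > end", call. = FALSE)
  df[, c("region_id", "chrom", "start", "end", "strand", "gene", "kind")]
}

#' Write regions as BED6
#'
#' Inverse of [read_regions()] for the BED dialect (1-based inclusive back to
#' 0-based half-open).
#'
#' @param regions region data.frame.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                    regions$region_id, 0L, regions$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `patient_id`, `group` (one of `antFL`,
#' `tFL`, `ntFL`, `control_pool`) and optional `timepoint`.
#'
#' @param path input TSV.
#' @return metadata data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "group")
  if (!all(req %in% names(df))) {
    stop("sample metadata needs columns sample_id/patient_id/group", call. = FALSE)
  }
  ok <- c("antFL", "tFL", "ntFL", "control_pool")
  if (!all(df$group %in% ok)) {
    stop("unknown sample group: ",
         paste(unique(setdiff(df$group, ok)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (!"timepoint" %in% names(df)) df$timepoint <- NA_character_
  df[, c("sample_id", "patient_id", "group", "timepoint")]
}

impact_report_columns <- c(
  "gene", "region_id", "region_kind", "chrom", "pos", "ref", "alt", "mirna",
  "site_start", "site_end", "offset", "seed_class", "score_wt", "score_mut",
  "dg_wt", "dg_mut", "delta_score", "delta_dg", "impact")

#' Write a site-impact report
#'
#' One row per (variant, miRNA, site) triple, deterministic column order,
#' stable sort by (chrom, pos, mirna). Round-trips through
#' [read_impact_report()].
#'
#' @param calls data.frame of impact calls (from [run_discovery()] or
#'   [score_mutation_effect()]).
#' @param path output TSV path.
#' @export
write_impact_report <- function(calls, path) {
  cols <- impact_report_columns
  if (nrow(calls) == 0L) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    write.table(empty, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  for (cc in setdiff(cols, names(calls))) calls[[cc]] <- NA
  calls <- calls[order(calls$chrom, calls$pos, calls$mirna), cols, drop = FALSE]
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-impact report written by [write_impact_report()]
#'
#' @param path TSV path.
#' @return data.frame of impact calls.
#' @export
read_impact_report <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(pos = "integer", site_start = "integer",
                                  site_end = "integer", offset = "integer"))
  df
}
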