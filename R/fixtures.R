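# Worked-example fixtures: the recurrent miRNA-binding-site variants and
# candidate site windows reported in a follicular-lymphoma amplicon
# resequencing cohort, plus a synthetic validation-cohort fixture that
# reproduces the published filtering arithmetic (85 variants -> 36 removed
# as control-pool hits -> 26 removed as homopolymer/repeat artifacts -> 23
# kept in 21 genes, 10 of them exclusive to transformed-FL patients).
# Printed coordinates and alleles are used as-is; all flanking sequence is
# synthetic (the fixtures exercise coordinate/strand logic, not real hg19
# content).

#' Recurrent miRNA-binding-site variants (worked example)
#'
#' The 16 recurrent variants of the FL validation cohort: genomic position
#' (hg19-style 1-based coordinates as printed), anchored REF/ALT alleles,
#' gene, region kind, cognate miRNA, and the number of carrier cases out of
#' 55 patients.
#'
#' @return data.frame with columns `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `kind` (`utr3`/`exon`/`intron`), `mirna`, `cases`.
#' @export
fl_recurrent_variants <- function() {
  txt <- c(
    "EZH2|chr7:148508727|T/A|exon|hsa-mir-144|8",
    "ARMC10|chr7:102739179|A/G|utr3|hsa-mir-222|18",
    "TUBB|chr6:30692754|C/CTT|utr3|hsa-mir-1302|7",
    "MEF2B|chr19:19260045|T/A|exon|hsa-mir-1265|3",
    "METTL15|chr11:28353434|G/A|utr3|hsa-mir-4313|12",
    "ZNF195|chr11:3380000|t/TC|utr3|hsa-mir-1915|16",
    "BCL2|chr18:60793447|G/A|utr3|hsa-mir-5008|2",
    "THOC3|chr5:175386586|A/G|utr3|hsa-mir-371a|15",
    "TXNDC2|chr18:9887493|T/C|exon|hsa-mir-2110|3",
    "PCDH7|chr4:30732983|GTA/G|intron|hsa-mir-329|4",
    "RC3H1|chr1:173901940|A/AAAT|utr3|hsa-mir-548an|2",
    "AQP3|chr9:33441702|C/A|utr3|hsa-mir-146b|8",
    "DPY19L2|chr12:63953768|T/C|utr3|hsa-mir-1303|11",
    "MYO5B|chr18:47352742|T/G|utr3|hsa-mir-216b|55",
    "MYO5B|chr18:47352754|A/G|utr3|hsa-mir-2681|55",
    "YY2|chrX:21876221|A/G|utr3|hsa-mir-448|36")
  f <- strsplit(txt, "|", fixed = TRUE)
  pos_tok <- strsplit(vapply(f, `[`, character(1), 2L), ":", fixed = TRUE)
  al <- strsplit(vapply(f, `[`, character(1), 3L), "/", fixed = TRUE)
  data.frame(
    gene = vapply(f, `[`, character(1), 1L),
    chrom = vapply(pos_tok, `[`, character(1), 1L),
    pos = as.integer(vapply(pos_tok, `[`, character(1), 2L)),
    ref = toupper(vapply(al, `[`, character(1), 1L)),
    alt = toupper(vapply(al, `[`, character(1), 2L)),
    kind = vapply(f, `[`, character(1), 4L),
    mirna = vapply(f, `[`, character(1), 5L),
    cases = as.integer(vapply(f, `[`, character(1), 6L)),
    stringsAsFactors = FALSE)
}

#' Candidate binding-site windows selected for functional testing
#'
#' The six candidate (gene, site window, mutation) rows taken forward to
#' reporter assays: genomic site windows, cognate miRNA, the
#' transcript-level change (`c_label`, carried as an annotation -- no CDS
#' model is used), its genomic equivalent, the strand making the two
#' equivalent, and the printed patient tallies (one tFL/ntFL split is
#' internally inconsistent with its total as printed; it is preserved
#' as-is).
#'
#' @return data.frame with columns `gene`, `chrom`, `g_start`, `g_end`,
#'   `mirna`, `c_label`, `pos`, `ref`, `alt`, `strand`, `total_patients`,
#'   `tfl_cases`, `ntfl_cases`.
#' @export
fl_candidate_sites <- function() {
  df <- data.frame(
    gene = c("ARMC10", "BCL2", "METTL15", "EZH2", "EZH2", "MEF2B"),
    chrom = c("chr7", "chr18", "chr11", "chr7", "chr7", "chr19"),
    g_start = c(102739177L, 60793436L, 28353429L, 148508722L, 148508722L,
                19260038L),
    g_end = c(102739198L, 60793458L, 28353448L, 148508742L, 148508742L,
              19260055L),
    mirna = c("hsa-mir-222", "hsa-mir-5008", "hsa-mir-4313", "hsa-mir-144",
              "hsa-mir-144", "hsa-mir-1265"),
    c_label = c("c.1320A>G", "c.3623C>T", "c.2588G>A", "c.2115A>T",
                "c.2114T>A", "c.336A>T"),
    pos = c(102739179L, 60793447L, 28353434L, 148508727L, 148508728L,
            19260045L),
    ref = c("A", "G", "G", "T", "A", "T"),
    alt = c("G", "A", "A", "A", "T", "A"),
    strand = c("+", "-", "+", "-", "-", "-"),
    total_patients = c(18L, 2L, 12L, 8L, 5L, 3L),
    tfl_cases = c(13L, 2L, 1L, 11L, 4L, 3L),
    ntfl_cases = c(7L, 0L, 11L, 2L, 2L, 1L),
    stringsAsFactors = FALSE)
  df
}

#' Candidate-site regions with synthetic flanking sequence
#'
#' One region per distinct candidate site window, extended by `flank` bases
#' each side. Reference sequence is synthetic random DNA with the printed
#' REF alleles planted at the printed positions (plus-strand orientation),
#' so coordinate and strand logic -- not real genome content -- is what
#' these fixtures test.
#'
#' @param seed RNG seed fixing the synthetic flanks.
#' @param flank flank length in bp (default 150).
#' @return region data.frame with `ref_seq`, suitable for
#'   [genomic_to_transcript()] / [apply_variant()].
#' @export
fl_candidate_regions <- function(seed = 1L, flank = 150L) {
  sites <- fl_candidate_sites()
  vars <- rbind(
    fl_recurrent_variants()[, c("chrom", "pos", "ref")],
    data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
               stringsAsFactors = FALSE))
  first <- !duplicated(sites[, c("gene", "chrom", "g_start", "g_end")])
  regions <- sites[first, , drop = FALSE]
  set.seed(seed)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    start <- r$g_start - flank
    end <- r$g_end + flank
    seq <- rand_dna(end - start + 1L)
    hit <- vars[vars$chrom == r$chrom & vars$pos >= start &
                  vars$pos + nchar(vars$ref) - 1L <= end, , drop = FALSE]
    for (j in seq_len(nrow(hit))) {
      lo <- hit$pos[j] - start + 1L
      substr(seq, lo, lo + nchar(hit$ref[j]) - 1L) <- hit$ref[j]
    }
    data.frame(region_id = paste0(r$gene, "_site"), chrom = r$chrom,
               start = start, end = end, strand = r$strand, gene = r$gene,
               kind = if (r$gene %in% c("EZH2", "MEF2B")) "exon" else "utr3",
               ref_seq = seq, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic validation-cohort fixture reproducing the filtering arithmetic
#'
#' Builds a cohort of 85 distinct variants on one synthetic chromosome whose
#' planted composition mirrors the published validation ledger: 36 variants
#' are present in healthy control pools, 26 sit immediately adjacent to a
#' planted 6-base homopolymer run (the artifact contexts of semiconductor
#' amplicon sequencing), all calls pass coverage/VAF QC, and the 23
#' remaining variants span 21 genes. Carrier patients are allocated so that
#' 10 of the 23 surviving variants occur exclusively in transforming (tFL)
#' patients, with 73 variant occurrences across the 34 tFL cases and 46
#' across the 21 ntFL cases. All sequence context is synthetic; clean loci
#' are resampled until they contain no artifact tract near the variant, so
#' the filters -- not the bookkeeping -- produce the counts.
#'
#' @param seed RNG seed.
#' @return list: `variants` (per-sample calls with `gene`), `controls`,
#'   `meta`, `reference` (named character, one chromosome), `offsets`.
#' @export
make_validation_fixture <- function(seed = 1L) {
  set.seed(seed)
  n_total <- 85L; n_control <- 36L; n_artifact <- 26L
  n_kept <- n_total - n_control - n_artifact
  ctx_w <- 41L; spacer <- 10L; center <- 21L
  clean_context <- function() {
    repeat {
      s <- rand_dna(ctx_w)
      tr <- find_artifact_tracts(s)
      if (nrow(tr) == 0L ||
          all(center < tr$lo - 1L | center > tr$hi + 1L)) return(s)
    }
  }
  fate <- c(rep("kept", n_kept), rep("control", n_control),
            rep("artifact", n_artifact))
  chrom_seq <- ""
  pos <- integer(n_total); ref <- character(n_total); alt <- character(n_total)
  for (i in seq_len(n_total)) {
    ctx <- clean_context()
    if (fate[i] == "artifact") {  # 6-base run starting right after the call
      run_base <- sample(c("A", "C", "G", "T"), 1L)
      substr(ctx, center + 1L, center + 6L) <- strrep(run_base, 6L)
    }
    pos[i] <- nchar(chrom_seq) + center
    ref[i] <- substr(ctx, center, center)
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
    chrom_seq <- paste0(chrom_seq, ctx, rand_dna(spacer))
  }
  # genes: the 23 survivors span 21 genes (two genes carry two variants)
  gene <- character(n_total)
  gene[fate == "kept"] <- sprintf("KG%02d", c(seq_len(21L), 1L, 2L))
  gene[fate != "kept"] <- sprintf("RG%02d", seq_len(n_total - n_kept))
  meta <- sim_meta(sim_config())  # 34 tFL + 21 ntFL patients, 5 pools
  tfl <- sprintf("PT%03d", 1:34); ntfl <- sprintf("PN%03d", 1:21)
  # carriers of the 23 survivors: 10 tFL-exclusive; 73 tFL / 46 ntFL
  # occurrences overall
  n_tfl_car <- c(rep(3L, 10L), 4L, 4L, 4L, 4L, rep(3L, 9L))   # sums 73
  n_ntfl_car <- c(rep(0L, 10L), rep(4L, 7L), rep(3L, 6L))     # sums 46
  take <- function(pool, n, at) pool[(at + seq_len(n) - 1L) %% length(pool) + 1L]
  rows <- list()
  add_call <- function(i, pid) {
    smp <- meta$sample_id[meta$patient_id == pid][1L]
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = "chrV", pos = pos[i], ref = ref[i], alt = alt[i], type = "snv",
      sample_id = smp, coverage = 800L + 13L * i, vaf = 0.30,
      gene = gene[i], stringsAsFactors = FALSE)
  }
  ki <- which(fate == "kept")
  at_t <- 0L; at_n <- 0L
  for (j in seq_along(ki)) {
    for (pid in take(tfl, n_tfl_car[j], at_t)) add_call(ki[j], pid)
    at_t <- at_t + n_tfl_car[j]
    if (n_ntfl_car[j] > 0L) {
      for (pid in take(ntfl, n_ntfl_car[j], at_n)) add_call(ki[j], pid)
      at_n <- at_n + n_ntfl_car[j]
    }
  }
  for (i in which(fate != "kept")) {  # removed variants: 1-2 carriers each
    for (pid in take(c(tfl, ntfl), 1L + i %% 2L, i)) add_call(i, pid)
  }
  variants <- do.call(rbind, rows)
  controls <- do.call(rbind, lapply(which(fate == "control"), function(i) {
    data.frame(chrom = "chrV", pos = pos[i], ref = ref[i], alt = alt[i],
               sample_id = sprintf("pool%d", 1L + i %% 5L),
               stringsAsFactors = FALSE)
  }))
  list(variants = variants, controls = controls, meta = meta,
       reference = c(chrV = chrom_seq), offsets = c(chrV = 1L))
}
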