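# The validation-cohort variant ledger: per-call QC thresholds, healthy
# control-pool subtraction, homopolymer/tandem-repeat artifact masking,
# patient-level recurrence and tFL/ntFL exclusivity. Variant identity
# throughout is the key (chrom, pos, ref, alt); filters run in the fixed
# order QC -> controls -> artifact, and a variant's recorded fate is the
# first filter that removes it.

#' Coverage / VAF quality filter
#'
#' A call is kept iff `coverage > min_cov` and `vaf > min_vaf` -- strict
#' inequalities, matching the usual "coverage >30x and VAF >5%" phrasing of
#' amplicon panels. Use `strict = FALSE` for >=.
#'
#' @param variants variant data.frame with `coverage` and `vaf`.
#' @param min_cov minimum read coverage (default 30).
#' @param min_vaf minimum variant allele fraction (default 0.05).
#' @param strict strict (`>`) or inclusive (`>=`) comparison.
#' @return list with data.frames `kept` and `removed`.
#' @export
qc_filter <- function(variants, min_cov = 30, min_vaf = 0.05, strict = TRUE) {
  if (nrow(variants) > 0L && (anyNA(variants$coverage) || anyNA(variants$vaf))) {
    bad <- which(is.na(variants$coverage) | is.na(variants$vaf))[1L]
    stop("missing coverage/vaf for variant ",
         variant_key(variants$chrom[bad], variants$pos[bad],
                     variants$ref[bad], variants$alt[bad]),
         call. = FALSE)
  }
  ok <- if (strict) {
    variants$coverage > min_cov & variants$vaf > min_vaf
  } else {
    variants$coverage >= min_cov & variants$vaf >= min_vaf
  }
  list(kept = variants[ok, , drop = FALSE],
       removed = variants[!ok, , drop = FALSE])
}

#' Remove variants present in any healthy control pool
#'
#' Matching is allele-exact on the (chrom, pos, ref, alt) key: a variant seen
#' in any one control pool is removed for all tumor samples; a different alt
#' allele at the same position is kept.
#'
#' @param variants tumor variant data.frame.
#' @param control_variants data.frame of control-pool calls with `chrom`,
#'   `pos`, `ref`, `alt` (pool identity irrelevant).
#' @return list with data.frames `kept` and `removed`.
#' @export
subtract_controls <- function(variants, control_variants) {
  ck <- unique(variant_key(control_variants$chrom, control_variants$pos,
                           control_variants$ref, control_variants$alt))
  vk <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  hit <- vk %in% ck
  list(kept = variants[!hit, , drop = FALSE],
       removed = variants[hit, , drop = FALSE])
}

#' Locate homopolymer and tandem-repeat tracts in a sequence
#'
#' @param seq DNA sequence (character scalar).
#' @param min_homopolymer minimum run length of identical bases (default 5).
#' @param repeat_units minimum tandem copies of a short motif (default 3).
#' @param motif_range motif lengths considered tandem repeats (default 2-4 nt).
#' @return data.frame with 1-based inclusive `lo`, `hi` and `type`
#'   (`homopolymer` / `repeat`) spans; possibly overlapping.
#' @export
find_artifact_tracts <- function(seq, min_homopolymer = 5L, repeat_units = 3L,
                                 motif_range = c(2L, 4L)) {
  seq <- toupper(seq)
  n <- nchar(seq)
  spans <- list()
  # homopolymer runs
  r <- rle(chars(seq))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hp <- which(r$lengths >= min_homopolymer)
  for (i in hp) {
    spans[[length(spans) + 1L]] <-
      data.frame(lo = starts[i], hi = ends[i], type = "homopolymer")
  }
  # tandem repeats of 2-4 nt motifs, >= repeat_units copies
  for (k in seq.int(motif_range[1L], motif_range[2L])) {
    s <- 1L
    while (s + k * repeat_units - 1L <= n) {
      motif <- substr(seq, s, s + k - 1L)
      copies <- 1L
      while (substr(seq, s + copies * k, s + (copies + 1L) * k - 1L) == motif) {
        copies <- copies + 1L
      }
      if (copies >= repeat_units) {
        spans[[length(spans) + 1L]] <-
          data.frame(lo = s, hi = s + copies * k - 1L, type = "repeat")
        s <- s + copies * k  # jump past the array
      } else {
        s <- s + 1L
      }
    }
  }
  if (length(spans) == 0L) {
    return(data.frame(lo = integer(), hi = integer(), type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, spans)
  rownames(out) <- NULL
  out
}

#' Mask variants in homopolymer or repetitive regions
#'
#' A variant is removed iff any of its changed reference bases lies within
#' `pad` bases of a homopolymer run of at least `min_homopolymer` identical
#' bases or of at least `repeat_units` tandem copies of a 2-4 nt motif --
#' the classic artifact contexts of semiconductor amplicon sequencing.
#'
#' @param variants variant data.frame.
#' @param reference named `DNAStringSet`/character vector of chromosome (or
#'   contig window) sequences.
#' @param offsets optional named integer vector: genomic position of base 1
#'   of each reference entry (default 1).
#' @param min_homopolymer,repeat_units,pad rule parameters (defaults 5, 3, 1).
#' @return list with data.frames `kept` and `removed`.
#' @export
mask_artifact_regions <- function(variants, reference, offsets = NULL,
                                  min_homopolymer = 5L, repeat_units = 3L,
                                  pad = 1L) {
  seqs <- if (is.character(reference)) reference else as.character(reference)
  if (nrow(variants) == 0L) {
    return(list(kept = variants, removed = variants))
  }
  sp <- variant_span(variants$pos, variants$ref, variants$alt)
  ctx <- max(min_homopolymer, 4L * repeat_units) + pad + 2L
  flagged <- vapply(seq_len(nrow(variants)), function(i) {
    chrom <- variants$chrom[i]
    if (!chrom %in% names(seqs)) {
      stop("no reference sequence for ", chrom, call. = FALSE)
    }
    off <- if (!is.null(offsets) && chrom %in% names(offsets)) offsets[[chrom]] else 1L
    slen <- nchar(seqs[[chrom]])
    lo <- sp$lo[i] - off + 1L  # local 1-based
    hi <- sp$hi[i] - off + 1L
    if (lo < 1L || hi > slen) {
      stop("variant at ", chrom, ":", variants$pos[i],
           " beyond reference end", call. = FALSE)
    }
    wlo <- max(1L, lo - ctx)
    whi <- min(slen, hi + ctx)
    tracts <- find_artifact_tracts(substr(seqs[[chrom]], wlo, whi),
                                   min_homopolymer, repeat_units)
    if (nrow(tracts) == 0L) return(FALSE)
    tlo <- tracts$lo + wlo - 1L  # back to local chromosome coordinates
    thi <- tracts$hi + wlo - 1L
    any(lo <= thi + pad & hi >= tlo - pad)
  }, logical(1))
  list(kept = variants[!flagged, , drop = FALSE],
       removed = variants[flagged, , drop = FALSE])
}

# patient-level group label: transforming patients (with tFL and/or
# antecedent antFL samples) are "tFL"; never-transforming patients "ntFL".
patient_groups <- function(meta) {
  meta <- meta[meta$group != "control_pool", , drop = FALSE]
  vapply(split(meta$group, meta$patient_id), function(g) {
    if (any(g %in% c("tFL", "antFL"))) "tFL" else "ntFL"
  }, character(1))
}

#' Count distinct carrier patients per variant
#'
#' Paired longitudinal samples (antFL + tFL) of one patient count once; a
#' variant is recurrent iff seen in at least two patients. Sample-level
#' counts are reported alongside for comparability.
#'
#' @param variants variant data.frame with `sample_id`.
#' @param meta sample metadata ([read_sample_meta()]).
#' @return data.frame, one row per variant key: `chrom`, `pos`, `ref`,
#'   `alt`, `n_patients`, `n_samples`, `recurrent`.
#' @export
tally_recurrence <- function(variants, meta) {
  if (nrow(variants) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), n_patients = integer(),
                      n_samples = integer(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  }
  unmapped <- setdiff(unique(variants$sample_id), meta$sample_id)
  if (length(unmapped)) {
    stop("sample(s) missing from metadata: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  patient <- meta$patient_id[match(variants$sample_id, meta$sample_id)]
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  first <- !duplicated(key)
  out <- data.frame(chrom = variants$chrom[first], pos = variants$pos[first],
                    ref = variants$ref[first], alt = variants$alt[first],
                    stringsAsFactors = FALSE)
  np <- vapply(split(patient, key), function(p) length(unique(p)), integer(1))
  ns <- vapply(split(variants$sample_id, key), function(s) length(unique(s)),
               integer(1))
  k0 <- key[first]
  out$n_patients <- unname(np[k0])
  out$n_samples <- unname(ns[k0])
  out$recurrent <- out$n_patients >= 2L
  out
}

#' Summarize tFL/ntFL carriage and tFL exclusivity
#'
#' Counts variant occurrences per patient group (one occurrence = one
#' carrier patient of one variant) and the variants whose carriers are all
#' transforming (tFL) patients. The exclusive fraction is reported to the
#' nearest percent.
#'
#' @param kept_variants variant data.frame (post-filter) with `sample_id`.
#' @param meta sample metadata.
#' @return list of class `cohort_summary`: `n_variants`, `n_tfl_cases`,
#'   `n_ntfl_cases`, `variants_in_tfl`, `variants_in_ntfl`,
#'   `n_exclusive_tfl`, `exclusive_fraction` (percent).
#' @export
exclusivity_summary <- function(kept_variants, meta) {
  pg <- patient_groups(meta)
  n_tfl <- sum(pg == "tFL"); n_ntfl <- sum(pg == "ntFL")
  if (nrow(kept_variants) == 0L) {
    return(structure(list(n_variants = 0L, n_tfl_cases = n_tfl,
                          n_ntfl_cases = n_ntfl, variants_in_tfl = 0L,
                          variants_in_ntfl = 0L, n_exclusive_tfl = 0L,
                          exclusive_fraction = 0),
                     class = "cohort_summary"))
  }
  unmapped <- setdiff(unique(kept_variants$sample_id), meta$sample_id)
  if (length(unmapped)) {
    stop("sample(s) missing from metadata: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  patient <- meta$patient_id[match(kept_variants$sample_id, meta$sample_id)]
  key <- variant_key(kept_variants$chrom, kept_variants$pos,
                     kept_variants$ref, kept_variants$alt)
  per_var_groups <- lapply(split(patient, key),
                           function(p) unname(pg[unique(p)]))
  occ_tfl <- sum(vapply(per_var_groups, function(g) sum(g == "tFL"), integer(1)))
  occ_ntfl <- sum(vapply(per_var_groups, function(g) sum(g == "ntFL"), integer(1)))
  excl <- sum(vapply(per_var_groups, function(g) all(g == "tFL"), logical(1)))
  n_var <- length(per_var_groups)
  structure(list(n_variants = n_var, n_tfl_cases = n_tfl,
                 n_ntfl_cases = n_ntfl, variants_in_tfl = occ_tfl,
                 variants_in_ntfl = occ_ntfl, n_exclusive_tfl = excl,
                 exclusive_fraction = round(100 * excl / n_var)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort summary: %d variants\n", x$n_variants))
  cat(sprintf("  tFL:  %d occurrences across %d cases\n",
              x$variants_in_tfl, x$n_tfl_cases))
  cat(sprintf("  ntFL: %d occurrences across %d cases\n",
              x$variants_in_ntfl, x$n_ntfl_cases))
  cat(sprintf("  tFL-exclusive: %d/%d (%d%%)\n",
              x$n_exclusive_tfl, x$n_variants, round(x$exclusive_fraction)))
  invisible(x)
}

#' Run the full filter cascade and build the variant ledger
#'
#' Stages run in the fixed order QC -> control subtraction -> artifact
#' masking, each at the distinct-variant level: QC removes a variant only
#' when *all* its per-sample calls fail; control and artifact removal act on
#' the variant key. Each variant receives exactly one fate (`kept`, `qc`,
#' `control`, `artifact`) and the counts satisfy the conservation invariant
#' `n_input = n_remaining + n_removed_qc + n_removed_controls +
#' n_removed_artifact`.
#'
#' @param variants per-sample variant calls (with `coverage`, `vaf`;
#'   optional `gene`).
#' @param control_variants control-pool calls (may have 0 rows).
#' @param reference,offsets reference sequences for artifact masking (see
#'   [mask_artifact_regions()]); pass `NULL` to skip that stage.
#' @param min_cov,min_vaf QC thresholds (defaults 30, 0.05).
#' @param min_homopolymer,repeat_units,pad artifact-rule parameters.
#' @return list of class `filter_ledger`: the stage counts, `fates` (named
#'   character vector, one fate per variant key), `kept_records` (surviving
#'   per-sample calls) and `n_genes_remaining` (NA without a `gene` column).
#' @export
build_ledger <- function(variants, control_variants = NULL,
                         reference = NULL, offsets = NULL,
                         min_cov = 30, min_vaf = 0.05,
                         min_homopolymer = 5L, repeat_units = 3L, pad = 1L) {
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  all_keys <- unique(key)
  fates <- setNames(rep(NA_character_, length(all_keys)), all_keys)
  # QC (per-call; a variant fails only if every call fails)
  qc <- qc_filter(variants, min_cov = min_cov, min_vaf = min_vaf)
  surviving <- unique(variant_key(qc$kept$chrom, qc$kept$pos,
                                  qc$kept$ref, qc$kept$alt))
  fates[setdiff(all_keys, surviving)] <- "qc"
  recs <- qc$kept
  # control-pool subtraction
  if (!is.null(control_variants) && nrow(control_variants) > 0L) {
    cs <- subtract_controls(recs, control_variants)
    gone <- unique(variant_key(cs$removed$chrom, cs$removed$pos,
                               cs$removed$ref, cs$removed$alt))
    fates[gone] <- "control"
    recs <- cs$kept
  }
  # homopolymer / repeat masking
  if (!is.null(reference) && nrow(recs) > 0L) {
    first <- !duplicated(variant_key(recs$chrom, recs$pos, recs$ref, recs$alt))
    ar <- mask_artifact_regions(recs[first, , drop = FALSE], reference, offsets,
                                min_homopolymer = min_homopolymer,
                                repeat_units = repeat_units, pad = pad)
    gone <- variant_key(ar$removed$chrom, ar$removed$pos,
                        ar$removed$ref, ar$removed$alt)
    fates[gone] <- "artifact"
    rk <- variant_key(recs$chrom, recs$pos, recs$ref, recs$alt)
    recs <- recs[!rk %in% gone, , drop = FALSE]
  }
  fates[is.na(fates)] <- "kept"
  counts <- table(factor(fates, levels = c("kept", "qc", "control", "artifact")))
  n_genes <- if ("gene" %in% names(recs)) {
    length(unique(recs$gene))
  } else {
    NA_integer_
  }
  stopifnot(sum(counts) == length(all_keys))
  structure(list(n_input = length(all_keys),
                 n_removed_qc = unname(counts[["qc"]]),
                 n_removed_controls = unname(counts[["control"]]),
                 n_removed_artifact = unname(counts[["artifact"]]),
                 n_remaining = unname(counts[["kept"]]),
                 n_genes_remaining = n_genes,
                 fates = fates, kept_records = recs),
            class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("variant filter ledger\n")
  cat(sprintf("  input variants:     %d\n", x$n_input))
  cat(sprintf("  removed by QC:      %d\n", x$n_removed_qc))
  cat(sprintf("  removed (controls): %d\n", x$n_removed_controls))
  cat(sprintf("  removed (artifact): %d\n", x$n_removed_artifact))
  cat(sprintf("  remaining:          %d", x$n_remaining))
  if (!is.na(x$n_genes_remaining)) {
    cat(sprintf(" in %d genes", x$n_genes_remaining))
  }
  cat("\n")
  invisible(x)
}

#' Write a filter ledger as TSV
#'
#' Two files: `<path>` with the stage counts and `<path>` suffixed
#' `.fates.tsv` with one row per variant and its fate.
#'
#' @param ledger a `filter_ledger`.
#' @param path output TSV path.
#' @export
write_ledger_tsv <- function(ledger, path) {
  counts <- data.frame(
    stage = c("input", "removed_qc", "removed_controls", "removed_artifact",
              "remaining", "genes_remaining"),
    n = c(ledger$n_input, ledger$n_removed_qc, ledger$n_removed_controls,
          ledger$n_removed_artifact, ledger$n_remaining,
          ledger$n_genes_remaining))
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fates <- data.frame(variant = names(ledger$fates),
                      fate = unname(ledger$fates))
  write.table(fates, sub("(\\.tsv)?$", ".fates.tsv", path, perl = TRUE)[1],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
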