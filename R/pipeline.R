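# End-to-end orchestration: the discovery arm (predict sites -> keep the
# most confident fraction per miRNA -> intersect variants -> rescore
# wildtype vs mutant) and the validation arm (QC -> control subtraction ->
# artifact masking -> recurrence -> exclusivity).

#' Run the discovery arm: site prediction and mutation impact
#'
#' Predicts binding sites on the wildtype regions, keeps the
#' `keep_fraction` most confident sites per miRNA ([rank_and_filter_sites()]),
#' intersects the variants with the retained sites and rescores each
#' (variant, site, miRNA) triple on both alleles
#' ([score_mutation_effect()]). Output is deterministic for fixed inputs.
#'
#' @param variants variant data.frame.
#' @param regions region data.frame with `ref_seq` (see [region_with_seq()]).
#' @param mirnas miRNA data.frame.
#' @param params [align_params()].
#' @param nn [nn_params()].
#' @param keep_fraction per-miRNA confidence filter (default 0.75).
#' @param tol dead zone for weakened/strengthened (default 0).
#' @param out_report,out_bed optional output paths (impact TSV, site BED).
#' @return list: `sites` (all predicted), `kept_sites` (post filter),
#'   `calls` (impact report rows), `log` (per-stage counts).
#' @export
run_discovery <- function(variants, regions, mirnas,
                          params = align_params(), nn = nn_params(),
                          keep_fraction = 0.75, tol = 0,
                          out_report = NULL, out_bed = NULL) {
  sites <- predict_sites(mirnas, regions, params, nn)
  kept <- rank_and_filter_sites(sites, keep_fraction)
  hits <- intersect_variants_sites(variants, kept)
  calls <- list()
  for (i in seq_len(nrow(hits))) {
    site <- kept[hits$site_idx[i], ]
    region <- regions[match(site$region_id, regions$region_id), ]
    mirna <- mirnas[match(site$mirna, mirnas$name), ]
    pair <- apply_variant(region, hits[i, c("chrom", "pos", "ref", "alt")])
    call <- score_mutation_effect(mirna, pair, site$tx_start, site$tx_end,
                                  params, nn, tol)
    call$gene <- region$gene
    call$kind <- region$kind
    call$region_kind <- region$kind
    call$offset <- hits$offset_in_site[i]
    call$seed_class <- site$seed_class
    call$confidence_rank <- site$confidence_rank
    calls[[length(calls) + 1L]] <- call
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(region_id = character(), mirna = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), site_start = integer(),
               site_end = integer(), seed_wt = character(),
               seed_mut = character(), score_wt = double(),
               score_mut = double(), dg_wt = double(), dg_mut = double(),
               delta_score = double(), delta_dg = double(),
               impact = character(), gene = character(), kind = character(),
               region_kind = character(), offset = integer(),
               seed_class = character(), confidence_rank = double(),
               stringsAsFactors = FALSE)
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos, calls$mirna), , drop = FALSE]
    rownames(calls) <- NULL
  }
  if (!is.null(out_report)) write_impact_report(calls, out_report)
  if (!is.null(out_bed)) write_sites_bed(kept, out_bed)
  log <- c(n_variants = length(unique(variant_key(variants$chrom, variants$pos,
                                                  variants$ref, variants$alt))),
           n_sites = nrow(sites), n_sites_kept = nrow(kept),
           n_pairs = nrow(hits), n_calls = nrow(calls))
  list(sites = sites, kept_sites = kept, calls = calls, log = log)
}

#' Run the validation arm: filter cascade and cohort summaries
#'
#' Executes the cohort-filter stages in the fixed order QC -> control-pool
#' subtraction -> homopolymer/repeat masking ([build_ledger()]), then
#' tallies patient-level recurrence and tFL/ntFL exclusivity on the
#' surviving calls.
#'
#' @param variants per-sample variant calls.
#' @param meta sample metadata.
#' @param controls control-pool calls (or NULL).
#' @param reference,offsets reference sequences for artifact masking (or
#'   NULL to skip).
#' @param min_cov,min_vaf,min_homopolymer,repeat_units,pad filter
#'   parameters.
#' @param out_dir optional directory for `ledger.tsv`, `summary.tsv`,
#'   `recurrence.tsv`.
#' @return list: `ledger` ([build_ledger()]), `summary`
#'   ([exclusivity_summary()]), `recurrence` ([tally_recurrence()]).
#' @export
run_validation <- function(variants, meta, controls = NULL,
                           reference = NULL, offsets = NULL,
                           min_cov = 30, min_vaf = 0.05,
                           min_homopolymer = 5L, repeat_units = 3L, pad = 1L,
                           out_dir = NULL) {
  ledger <- build_ledger(variants, controls, reference, offsets,
                         min_cov = min_cov, min_vaf = min_vaf,
                         min_homopolymer = min_homopolymer,
                         repeat_units = repeat_units, pad = pad)
  recurrence <- tally_recurrence(ledger$kept_records, meta)
  summary <- exclusivity_summary(ledger$kept_records, meta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ledger_tsv(ledger, file.path(out_dir, "ledger.tsv"))
    write.table(recurrence, file.path(out_dir, "recurrence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    s <- summary
    write.table(data.frame(metric = names(unclass(s)),
                           value = unlist(unclass(s))),
                file.path(out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(ledger = ledger, summary = summary, recurrence = recurrence)
}
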