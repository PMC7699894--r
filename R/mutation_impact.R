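# Intersecting somatic variants with predicted sites and quantifying the
# binding change between the wildtype and mutant alleles.

# Genomic span of a variant's changed reference bases. SNV: the substituted
# base. Deletion: the deleted bases (after the shared anchor prefix).
# Insertion: the anchor base -- an inserted base between site bases can still
# break spacing, which the rescoring captures.
variant_span <- function(pos, ref, alt) {
  type <- classify_variant(ref, alt)
  lo <- ifelse(type == "deletion", pos + nchar(alt), pos)
  hi <- ifelse(type == "deletion", pos + nchar(ref) - 1L, pos)
  data.frame(lo = as.integer(lo), hi = as.integer(hi))
}

#' Intersect variants with predicted binding sites
#'
#' A (variant, site) pair is emitted iff any changed reference base of the
#' variant overlaps the site's genomic interval (inclusive).
#' `offset_in_site` is the genomic offset of the first overlapping changed
#' base from the site start.
#'
#' @param variants variant data.frame; duplicate (chrom, pos, ref, alt) keys
#'   (e.g. per-sample records) are intersected once.
#' @param sites site data.frame from [predict_sites()] (needs `chrom`,
#'   `g_start`, `g_end`).
#' @return data.frame with the variant key columns, `site_idx` (row index
#'   into `sites`), the site's `region_id`/`mirna` and `offset_in_site`.
#' @export
intersect_variants_sites <- function(variants, sites) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), site_idx = integer(),
                      region_id = character(), mirna = character(),
                      offset_in_site = integer(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0L || nrow(sites) == 0L) return(empty)
  keys <- !duplicated(variant_key(variants$chrom, variants$pos,
                                  variants$ref, variants$alt))
  v <- variants[keys, , drop = FALSE]
  sp <- variant_span(v$pos, v$ref, v$alt)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(sp$lo, sp$hi))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$g_start, sites$g_end))
  ov <- GenomicRanges::findOverlaps(vgr, sgr)
  if (length(ov) == 0L) return(empty)
  vi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  data.frame(chrom = v$chrom[vi], pos = v$pos[vi], ref = v$ref[vi],
             alt = v$alt[vi], site_idx = si,
             region_id = sites$region_id[si], mirna = sites$mirna[si],
             offset_in_site = pmax(sp$lo[vi], sites$g_start[si]) -
               sites$g_start[si],
             stringsAsFactors = FALSE)
}

best_seed_class <- function(mirna, window_seq) {
  hits <- find_seed_matches(mirna, window_seq)
  if (nrow(hits) == 0L) return("none")
  seed_classes[min(match(hits$seed_class, seed_classes))]
}

#' Score the effect of a mutation on miRNA binding
#'
#' Rescores a fixed window (the site interval extended by one miRNA length
#' on each side, so gained sites adjacent to the original footprint are
#' detectable) on both alleles of an [apply_variant()] pair. A window
#' "qualifies" when it contains a canonical seed match and reaches
#' `params$min_score` in the duplex alignment. Classification:
#' `disrupted` -- wildtype qualifies, mutant does not; `gained` -- the
#' reverse; otherwise `weakened` / `strengthened` when the score change
#' exceeds `tol` downward/upward, else `unchanged`.
#'
#' @param mirna one-row miRNA data.frame/list.
#' @param pair `allele_pair` from [apply_variant()].
#' @param tx_start,tx_end 0-based half-open site offsets on the wildtype
#'   transcript sequence.
#' @param params [align_params()].
#' @param nn [nn_params()].
#' @param tol dead zone for weakened/strengthened (default 0; the default
#'   integer scoring makes any change meaningful).
#' @return one-row data.frame: `region_id`, `mirna`, `chrom`, `pos`, `ref`,
#'   `alt`, `site_start`, `site_end`, `seed_wt`, `seed_mut`, `score_wt`,
#'   `score_mut`, `dg_wt`, `dg_mut`, `delta_score`, `delta_dg`, `impact`.
#' @export
score_mutation_effect <- function(mirna, pair, tx_start, tx_end,
                                  params = align_params(), nn = nn_params(),
                                  tol = 0) {
  mirlen <- nchar(mirna$sequence)
  len_wt <- nchar(pair$wt_seq); len_mut <- nchar(pair$mut_seq)
  d <- len_mut - len_wt
  ws <- max(0L, tx_start - mirlen)
  we <- min(len_wt, tx_end + mirlen)
  ws_mut <- max(0L, ws + if (pair$tx_offset < ws) d else 0L)
  we_mut <- min(len_mut, we + if (pair$tx_offset < we) d else 0L)
  wt_win <- substr(pair$wt_seq, ws + 1L, we)
  mut_win <- substr(pair$mut_seq, ws_mut + 1L, we_mut)
  wt_aln <- align_duplex(mirna, wt_win, params)
  mut_aln <- align_duplex(mirna, mut_win, params)
  seed_wt <- best_seed_class(mirna, wt_win)
  seed_mut <- best_seed_class(mirna, mut_win)
  wt_q <- seed_wt != "none" && wt_aln$score >= params$min_score
  mut_q <- seed_mut != "none" && mut_aln$score >= params$min_score
  if (!wt_q && !mut_q) {
    stop("no site context: neither allele carries a qualifying site in the ",
         "rescoring window", call. = FALSE)
  }
  delta <- mut_aln$score - wt_aln$score
  impact <- if (wt_q && !mut_q) {
    "disrupted"
  } else if (!wt_q && mut_q) {
    "gained"
  } else if (delta < -tol) {
    "weakened"
  } else if (delta > tol) {
    "strengthened"
  } else {
    "unchanged"
  }
  dg <- function(aln) {
    if (grepl("[|:]", aln$pairing)) duplex_free_energy(aln, nn) else NA_real_
  }
  dg_wt <- dg(wt_aln); dg_mut <- dg(mut_aln)
  data.frame(region_id = pair$region_id, mirna = mirna$name,
             chrom = pair$variant$chrom, pos = pair$variant$pos,
             ref = pair$variant$ref, alt = pair$variant$alt,
             site_start = tx_start, site_end = tx_end,
             seed_wt = seed_wt, seed_mut = seed_mut,
             score_wt = wt_aln$score, score_mut = mut_aln$score,
             dg_wt = dg_wt, dg_mut = dg_mut,
             delta_score = delta,
             delta_dg = if (is.na(dg_wt) || is.na(dg_mut)) NA_real_
                        else dg_mut - dg_wt,
             impact = impact, stringsAsFactors = FALSE)
}

#' Tally impact calls by region kind, gene and impact class
#'
#' @param calls data.frame of impact calls carrying `kind` (region kind),
#'   `gene` and `impact` columns (extra columns ignored). An empty input
#'   yields all-zero tallies.
#' @return list of data.frames `by_kind` (with `fraction`), `by_gene`,
#'   `by_impact`.
#' @export
summarize_impacts <- function(calls) {
  tab <- function(x) {
    if (length(x) == 0L) {
      return(data.frame(level = character(), n = integer(),
                        fraction = double(), stringsAsFactors = FALSE))
    }
    t <- table(x)
    data.frame(level = names(t), n = as.integer(t),
               fraction = as.integer(t) / length(x),
               stringsAsFactors = FALSE)
  }
  list(n = nrow(calls),
       by_kind = tab(calls$kind),
       by_gene = tab(calls$gene),
       by_impact = tab(calls$impact))
}
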