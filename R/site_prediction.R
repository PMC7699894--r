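# miRNA target-site prediction: canonical seed-match classification
# (8mer > 7mer-m8 > 7mer-A1 > 6mer, Watson-Crick only), seed-weighted local
# duplex alignment of the miRNA (3'->5') against the target (5'->3'), and a
# per-miRNA confidence rank with the keep-75% filter.

#' Alignment parameters for the duplex aligner
#'
#' Dimensionless scores for the seed-weighted local alignment. Columns that
#' pair miRNA positions 2-8 (the extended seed) are multiplied by
#' `seed_weight`; gap penalties are never weighted. G:U wobbles score as weak
#' pairs in the alignment but never satisfy a seed class.
#'
#' @param match score of a Watson-Crick paired column (default +5).
#' @param gu_wobble score of a G:U wobble column (default +1).
#' @param mismatch score of a mismatched column (default -3).
#' @param gap_open cost of opening a gap (default -8).
#' @param gap_extend cost of extending a gap (default -2);
#'   `gap_open <= gap_extend <= 0` is required.
#' @param seed_weight multiplier (>= 1) applied to match/wobble/mismatch
#'   scores in columns pairing miRNA positions 2-8 (default 4).
#' @param min_score minimum alignment score for a reported site (default 80).
#' @return list of class `align_params`.
#' @export
align_params <- function(match = 5, gu_wobble = 1, mismatch = -3,
                         gap_open = -8, gap_extend = -2,
                         seed_weight = 4, min_score = 80) {
  stopifnot(seed_weight >= 1, gap_open <= gap_extend, gap_extend <= 0)
  structure(list(match = match, gu_wobble = gu_wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_weight = seed_weight, min_score = min_score),
            class = "align_params")
}

seed_classes <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Find canonical seed matches of a miRNA in a target sequence
#'
#' Scans the transcript-orientation target for Watson-Crick matches to the
#' miRNA seed. Every maximal site is reported once with the strongest
#' applicable class (precedence 8mer > 7mer-m8 > 7mer-A1 > 6mer):
#' a 6mer is the reverse complement of miRNA positions 2-7; m8 adds a
#' Watson-Crick pair to position 8 on the site's 5' side; A1 adds an adenine
#' opposite miRNA position 1 on the site's 3' side. Site coordinates cover
#' the matched target bases.
#'
#' @param mirna one-row miRNA data.frame (or list) with `name` and
#'   `sequence`, e.g. a row of [read_mirna_fasta()] output.
#' @param target transcript-orientation sequence (DNA or RNA alphabet).
#' @return data.frame with columns `mirna`, `tx_start`, `tx_end` (0-based
#'   half-open) and `seed_class`; empty if the target is shorter than 6 nt.
#' @export
find_seed_matches <- function(mirna, target) {
  empty <- data.frame(mirna = character(), tx_start = integer(),
                      tx_end = integer(), seed_class = character(),
                      stringsAsFactors = FALSE)
  tgt <- as_rna(target, what = "target")
  n <- nchar(tgt)
  if (n < 6L) return(empty)
  seq <- as_rna(mirna$sequence, what = "miRNA")
  core <- revcomp_rna(substr(seq, 2L, 7L))       # pairs miRNA positions 7..2
  p8c <- wc_complement_rna(substr(seq, 8L, 8L))  # target base pairing pos 8
  tgt_c <- chars(tgt)
  starts <- integer(0)
  for (j in seq_len(n - 5L)) {
    if (substr(tgt, j, j + 5L) == core) starts <- c(starts, j)
  }
  if (length(starts) == 0L) return(empty)
  rows <- lapply(starts, function(j) {
    m8 <- j >= 2L && tgt_c[j - 1L] == p8c
    a1 <- j + 6L <= n && tgt_c[j + 6L] == "A"
    if (m8 && a1) {
      c(j - 2L, j + 6L, "8mer")
    } else if (m8) {
      c(j - 2L, j + 5L, "7mer-m8")
    } else if (a1) {
      c(j - 1L, j + 6L, "7mer-A1")
    } else {
      c(j - 1L, j + 5L, "6mer")
    }
  })
  data.frame(mirna = mirna$name %||% NA_character_,
             tx_start = vapply(rows, function(r) as.integer(r[1L]), integer(1)),
             tx_end = vapply(rows, function(r) as.integer(r[2L]), integer(1)),
             seed_class = vapply(rows, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

# Column score between miRNA base (5'->3' identity) and target base,
# unweighted.
base_score <- function(mir_base, tgt_base, params) {
  if (is_wc_pair(mir_base, tgt_base)) {
    params$match
  } else if (is_gu_pair(mir_base, tgt_base)) {
    params$gu_wobble
  } else {
    params$mismatch
  }
}

#' Align a miRNA against a target window
#'
#' Seed-weighted local alignment (affine gaps) of the miRNA, read 3'->5',
#' against the target window, read 5'->3' -- the antiparallel geometry of a
#' miRNA:mRNA duplex. The score is the maximum over all local alignments;
#' columns pairing miRNA positions 2-8 are weighted by
#' `params$seed_weight`.
#'
#' @param mirna one-row miRNA data.frame/list with `sequence`, or a plain
#'   sequence string.
#' @param target_window target subsequence (<= 80 nt, DNA or RNA).
#' @param params [align_params()].
#' @return list of class `duplex_alignment`: `score`; `mir_align` (aligned
#'   miRNA, 3'->5'), `tgt_align` (aligned target, 5'->3'); `pairing`
#'   (per-column symbols: `|` Watson-Crick, `:` G:U, `.` mismatch, `-` gap);
#'   `mir_positions` (original 1-based miRNA position per column, NA at
#'   gaps); `tgt_start`, `tgt_end` (1-based aligned span in the window).
#'   An empty window gives score 0 and an empty alignment.
#' @export
align_duplex <- function(mirna, target_window, params = align_params()) {
  seq <- if (is.character(mirna)) mirna else mirna$sequence
  seq <- as_rna(seq, what = "miRNA")
  tgt <- if (nchar(target_window) > 0L) as_rna(target_window, "window") else ""
  m <- nchar(seq); n <- nchar(tgt)
  empty <- structure(list(score = 0, mir_align = "", tgt_align = "",
                          pairing = "", mir_positions = integer(0),
                          tgt_start = NA_integer_, tgt_end = NA_integer_),
                     class = "duplex_alignment")
  if (n == 0L || m == 0L) return(empty)
  if (n > 80L) stop("target window longer than 80 nt", call. = FALSE)
  M <- rev(chars(seq))                 # miRNA 3'->5'
  mpos <- rev(seq_len(m))              # original miRNA position per row
  w <- ifelse(mpos >= 2L & mpos <= 8L, params$seed_weight, 1)
  TGT <- chars(tgt)
  NEG <- -1e9
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(NEG, m + 1L, n + 1L)  # gap in miRNA row (target base unpaired)
  F <- matrix(NEG, m + 1L, n + 1L)  # gap in target (miRNA base unpaired)
  ptrH <- matrix(0L, m + 1L, n + 1L)  # 1 diag, 2 E, 3 F, 0 local start
  ptrE <- matrix(0L, m + 1L, n + 1L)  # 1 open from H, 2 extend
  ptrF <- matrix(0L, m + 1L, n + 1L)
  for (k in seq_len(m)) {
    for (j in seq_len(n)) {
      eo <- H[k + 1L, j] + params$gap_open
      ee <- E[k + 1L, j] + params$gap_extend
      E[k + 1L, j + 1L] <- max(eo, ee)
      ptrE[k + 1L, j + 1L] <- if (eo >= ee) 1L else 2L
      fo <- H[k, j + 1L] + params$gap_open
      fe <- F[k, j + 1L] + params$gap_extend
      F[k + 1L, j + 1L] <- max(fo, fe)
      ptrF[k + 1L, j + 1L] <- if (fo >= fe) 1L else 2L
      diag <- H[k, j] + w[k] * base_score(M[k], TGT[j], params)
      best <- max(0, diag, E[k + 1L, j + 1L], F[k + 1L, j + 1L])
      H[k + 1L, j + 1L] <- best
      ptrH[k + 1L, j + 1L] <-
        if (best == 0) 0L else if (best == diag) 1L
        else if (best == E[k + 1L, j + 1L]) 2L else 3L
    }
  }
  score <- max(H)
  if (score <= 0) return(empty)
  idx <- which(H == score, arr.ind = TRUE)[1L, ]  # deterministic: first max
  k <- idx[1L] - 1L; j <- idx[2L] - 1L
  cols_mir <- character(0); cols_tgt <- character(0); cols_pos <- integer(0)
  state <- "H"
  tgt_end <- j
  while (k > 0L || j > 0L) {
    if (state == "H") {
      p <- ptrH[k + 1L, j + 1L]
      if (p == 0L) break
      if (p == 1L) {
        cols_mir <- c(M[k], cols_mir); cols_tgt <- c(TGT[j], cols_tgt)
        cols_pos <- c(mpos[k], cols_pos)
        k <- k - 1L; j <- j - 1L
      } else if (p == 2L) state <- "E" else state <- "F"
    } else if (state == "E") {
      p <- ptrE[k + 1L, j + 1L]
      cols_mir <- c("-", cols_mir); cols_tgt <- c(TGT[j], cols_tgt)
      cols_pos <- c(NA_integer_, cols_pos)
      j <- j - 1L
      if (p == 1L) state <- "H"
    } else {
      p <- ptrF[k + 1L, j + 1L]
      cols_mir <- c(M[k], cols_mir); cols_tgt <- c("-", cols_tgt)
      cols_pos <- c(mpos[k], cols_pos)
      k <- k - 1L
      if (p == 1L) state <- "H"
    }
  }
  tgt_start <- j + 1L
  pairing <- vapply(seq_along(cols_mir), function(i) {
    if (cols_mir[i] == "-" || cols_tgt[i] == "-") {
      "-"
    } else if (is_wc_pair(cols_mir[i], cols_tgt[i])) {
      "|"
    } else if (is_gu_pair(cols_mir[i], cols_tgt[i])) {
      ":"
    } else {
      "."
    }
  }, character(1))
  structure(list(score = score,
                 mir_align = paste(cols_mir, collapse = ""),
                 tgt_align = paste(cols_tgt, collapse = ""),
                 pairing = paste(pairing, collapse = ""),
                 mir_positions = cols_pos,
                 tgt_start = tgt_start, tgt_end = tgt_end),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("duplex alignment, score %.1f\n", x$score))
  if (nchar(x$tgt_align)) {
    cat("  target 5' ", x$tgt_align, " 3'\n", sep = "")
    cat("            ", x$pairing, "\n", sep = "")
    cat("  miRNA  3' ", x$mir_align, " 5'\n", sep = "")
  }
  invisible(x)
}

#' Rank sites per miRNA and keep the most confident fraction
#'
#' Confidence is the alignment score. Per miRNA, the top
#' `ceiling(keep_fraction * n)` sites are retained; ties at the cutoff score
#' are all retained. `confidence_rank` records the fractional rank
#' (rank / n, 1/n = most confident).
#'
#' @param sites data.frame with at least `mirna` and `align_score`.
#' @param keep_fraction fraction in (0, 1], default 0.75.
#' @return the retained rows with a `confidence_rank` column, original
#'   order preserved.
#' @export
rank_and_filter_sites <- function(sites, keep_fraction = 0.75) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  }
  if (nrow(sites) == 0L) {
    sites$confidence_rank <- numeric(0)
    return(sites)
  }
  sites$.row <- seq_len(nrow(sites))
  kept <- lapply(split(sites, sites$mirna), function(g) {
    n <- nrow(g)
    r <- rank(-g$align_score, ties.method = "min")
    g$confidence_rank <- r / n
    k <- ceiling(keep_fraction * n)
    cutoff <- sort(g$align_score, decreasing = TRUE)[k]
    g[g$align_score >= cutoff, , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  rownames(out) <- NULL
  out
}

#' Predict miRNA-binding sites in transcript regions
#'
#' For every (region, miRNA) pair: seed matches are located with
#' [find_seed_matches()], each match is rescored by [align_duplex()] over a
#' window extending one miRNA length 5' of the site (where the miRNA 3' end
#' pairs) plus a short 3' margin, and duplex stability is computed with
#' [duplex_free_energy()]. Overlapping sites of the same miRNA in a region
#' are merged to the highest-scoring representative. Under the default
#' `site_policy = "both"` a site needs a seed class and an alignment score
#' of at least `params$min_score`; `"seed_only"` drops the score
#' requirement.
#'
#' @param mirnas miRNA data.frame ([read_mirna_fasta()]).
#' @param regions region data.frame with `ref_seq` ([region_with_seq()]).
#' @param params [align_params()].
#' @param nn [nn_params()].
#' @param site_policy `"both"`, `"seed_only"` or `"align_only"`.
#' @return data.frame of sites: region/gene/kind columns, `mirna`,
#'   `tx_start`, `tx_end` (0-based half-open, transcript orientation),
#'   `seed_class`, `align_score`, `delta_g`, and the genomic projection
#'   `chrom`, `g_start`, `g_end`, `strand`.
#' @export
predict_sites <- function(mirnas, regions, params = align_params(),
                          nn = nn_params(),
                          site_policy = c("both", "seed_only", "align_only")) {
  site_policy <- match.arg(site_policy)
  out <- list()
  for (ri in seq_len(nrow(regions))) {
    region <- regions[ri, ]
    txs <- as_rna(transcript_seq(region), what = region$region_id)
    len <- nchar(txs)
    for (mi in seq_len(nrow(mirnas))) {
      mirna <- mirnas[mi, ]
      hits <- find_seed_matches(mirna, txs)
      if (nrow(hits) == 0L) next
      mirlen <- nchar(mirna$sequence)
      rows <- lapply(seq_len(nrow(hits)), function(h) {
        ws <- max(0L, hits$tx_start[h] - mirlen)
        we <- min(len, hits$tx_end[h] + 3L)
        aln <- align_duplex(mirna, substr(txs, ws + 1L, we), params)
        dg <- if (grepl("[|:]", aln$pairing)) {
          duplex_free_energy(aln, nn)
        } else {
          NA_real_
        }
        data.frame(region_id = region$region_id, gene = region$gene,
                   kind = region$kind, mirna = mirna$name,
                   tx_start = hits$tx_start[h], tx_end = hits$tx_end[h],
                   seed_class = hits$seed_class[h],
                   align_score = aln$score, delta_g = dg,
                   stringsAsFactors = FALSE)
      })
      sites <- do.call(rbind, rows)
      if (site_policy %in% c("both", "align_only")) {
        sites <- sites[sites$align_score >= params$min_score, , drop = FALSE]
      }
      # merge overlapping same-miRNA sites: best score wins
      if (nrow(sites) > 1L) {
        sites <- sites[order(-sites$align_score, sites$tx_start), , drop = FALSE]
        keep <- rep(TRUE, nrow(sites))
        for (a in seq_len(nrow(sites))) {
          if (!keep[a]) next
          for (b in seq_len(nrow(sites))) {
            if (b == a || !keep[b]) next
            if (sites$tx_start[b] < sites$tx_end[a] &&
                sites$tx_end[b] > sites$tx_start[a]) {
              keep[b] <- FALSE
            }
          }
        }
        sites <- sites[keep, , drop = FALSE]
        sites <- sites[order(sites$tx_start), , drop = FALSE]
      }
      if (nrow(sites)) out[[length(out) + 1L]] <- sites
    }
  }
  if (length(out) == 0L) {
    return(data.frame(region_id = character(), gene = character(),
                      kind = character(), mirna = character(),
                      tx_start = integer(), tx_end = integer(),
                      seed_class = character(), align_score = double(),
                      delta_g = double(), chrom = character(),
                      g_start = integer(), g_end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  ix <- match(sites$region_id, regions$region_id)
  sites$chrom <- regions$chrom[ix]
  sites$strand <- regions$strand[ix]
  plus <- sites$strand == "+"
  sites$g_start <- ifelse(plus, regions$start[ix] + sites$tx_start,
                          regions$end[ix] - sites$tx_end + 1L)
  sites$g_end <- ifelse(plus, regions$start[ix] + sites$tx_end - 1L,
                        regions$end[ix] - sites$tx_start)
  sites
}

#' Write predicted sites as BED6+
#'
#' Region-relative offsets are written 0-based half-open; the score column
#' carries the alignment score; extra columns carry miRNA, seed class and
#' free energy.
#'
#' @param sites site data.frame from [predict_sites()].
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$g_start - 1L, sites$g_end,
                    paste(sites$region_id, sites$mirna, sep = "|"),
                    sites$align_score, sites$strand,
                    sites$seed_class, round(sites$delta_g, 2))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
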