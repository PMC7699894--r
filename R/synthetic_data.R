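# Fully self-contained synthetic cohorts with the statistical structure the
# analysis assumes: UTR-like regions carrying planted miRNA-response
# elements, seed-disrupting and background somatic SNVs, per-call coverage
# and VAF, longitudinal tFL/ntFL patients, healthy control pools and
# homopolymer tracts -- plus a truth table so every pipeline stage can be
# checked against ground truth without any download.

#' Simulation configuration
#'
#' Defaults mirror the structure of an amplicon-validation FL cohort:
#' 34 transforming (tFL) patients sampled longitudinally (antecedent +
#' transformed sample) and 21 non-transforming (ntFL) patients, five healthy
#' control pools, negative-binomial amplicon coverage around a 2270x mean
#' depth and clonal-ish Beta-distributed VAFs.
#'
#' @param n_genes number of genes (one UTR region each; default 20).
#' @param utr_len_range min/max UTR length in nt (default 300-600).
#' @param n_mirnas number of simulated miRNAs -- random 22-mers with
#'   pairwise-distinct seeds (default 10).
#' @param planted_sites_per_gene perfect 8mer sites planted per gene
#'   (default 2).
#' @param decoy_sites_per_gene weaker 6mer-only sites planted per gene
#'   (default 3). Decoys carry no mutation; they emulate the genome-wide
#'   tail of low-confidence sites that the per-miRNA keep-75% filter is
#'   meant to discard.
#' @param p_site_mutation probability that a planted site receives a
#'   seed-disrupting SNV (default 0.5).
#' @param p_background_mutation_per_kb background SNV rate per kb outside
#'   planted elements (default 2).
#' @param n_patients_tfl,n_patients_ntfl cohort sizes (defaults 34, 21).
#' @param n_control_pools healthy control pools (default 5).
#' @param control_contamination fraction of variants copied into at least
#'   one control pool (default 0.1).
#' @param artifact_fraction fraction of background variants given an
#'   adjacent planted homopolymer tract (default 0.05).
#' @param homopolymer_rate additional homopolymer runs planted per kb of
#'   UTR (default 0.5).
#' @param coverage_mean,coverage_dispersion negative-binomial coverage model
#'   (defaults 2270, 3).
#' @param vaf_alpha,vaf_beta Beta VAF model (defaults 8, 12; mean 0.4).
#' @param rng_seed integer seed; identical seeds give byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20L, utr_len_range = c(300L, 600L),
                       n_mirnas = 10L, planted_sites_per_gene = 2L,
                       decoy_sites_per_gene = 3L, p_site_mutation = 0.5,
                       p_background_mutation_per_kb = 2,
                       n_patients_tfl = 34L, n_patients_ntfl = 21L,
                       n_control_pools = 5L, control_contamination = 0.1,
                       artifact_fraction = 0.05, homopolymer_rate = 0.5,
                       coverage_mean = 2270, coverage_dispersion = 3,
                       vaf_alpha = 8, vaf_beta = 12, rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1L, cfg$n_mirnas >= 1L,
            cfg$utr_len_range[1L] <= cfg$utr_len_range[2L],
            cfg$p_site_mutation >= 0, cfg$p_site_mutation <= 1,
            cfg$control_contamination >= 0, cfg$control_contamination <= 1,
            cfg$artifact_fraction >= 0, cfg$artifact_fraction <= 1)
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random 22-mer miRNAs with pairwise distinct 7-nt seeds
sim_mirnas <- function(n) {
  seqs <- character(0)
  while (length(seqs) < n) {
    s <- chartr("T", "U", rand_dna(22L))
    if (!substr(s, 2L, 8L) %in% substr(seqs, 2L, 8L)) seqs <- c(seqs, s)
  }
  mirna_table(sprintf("sim-miR-%d", seq_len(n)), seqs)
}

sim_meta <- function(cfg) {
  rows <- list()
  for (i in seq_len(cfg$n_patients_tfl)) {
    pid <- sprintf("PT%03d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = c(paste0(pid, "_ant"), paste0(pid, "_tfl")),
      patient_id = pid, group = c("antFL", "tFL"),
      timepoint = c("pre", "post"), stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_patients_ntfl)) {
    pid <- sprintf("PN%03d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(pid, "_fl"), patient_id = pid, group = "ntFL",
      timepoint = "dx", stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_control_pools)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("pool%d", i), patient_id = sprintf("pool%d", i),
      group = "control_pool", timepoint = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# place an element of width w in 1..L, at least `gap` away from spans
# already in `taken` (data.frame lo/hi, 1-based); NA if no room after tries
place_span <- function(L, w, taken, gap = 2L, tries = 200L) {
  for (t in seq_len(tries)) {
    lo <- sample.int(L - w + 1L, 1L)
    hi <- lo + w - 1L
    if (nrow(taken) == 0L ||
        all(hi < taken$lo - gap | lo > taken$hi + gap)) {
      return(c(lo, hi))
    }
  }
  NA_integer_
}

# Remove accidental seed matches of `mirna` from tx sequence `seq` within
# [wlo, whi] (1-based), except the protected span [plo, phi]; mutates one
# base of each offending core until clean.
scrub_seed_matches <- function(seq, mirna, wlo, whi, plo, phi) {
  core <- chartr("U", "T", revcomp_rna(substr(mirna$sequence, 2L, 7L)))
  for (iter in 1:25) {
    win <- substr(seq, wlo, whi)
    hits <- integer(0)
    for (j in seq_len(max(0L, nchar(win) - 5L))) {
      if (substr(win, j, j + 5L) == core) hits <- c(hits, wlo + j - 1L)
    }
    hits <- hits[!(hits >= plo - 5L & hits <= phi)]  # cores inside/overlapping
    hits <- hits[!(hits + 5L >= plo & hits <= phi)]
    if (length(hits) == 0L) return(seq)
    j <- hits[1L]
    # pick a core base outside the protected span and flip it
    cand <- setdiff(j:(j + 5L), plo:phi)
    p <- cand[1L]
    old <- substr(seq, p, p)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(seq, p, p) <- new
  }
  stop("could not scrub accidental seed matches", call. = FALSE)
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds reference sequence, regions, miRNAs, per-sample somatic variant
#' calls, control-pool calls and sample metadata according to a
#' [sim_config()], together with a truth table of planted sites and
#' mutations. Planted sites are exact 8mer seed matches; each planted
#' mutation is a seed-core SNV chosen so that the mutant window carries no
#' residual canonical seed match of its miRNA (expected impact
#' `disrupted`). Background SNVs fall outside planted elements via
#' per-position uniform draws, so raising the background rate adds variants
#' without moving existing ones.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all pieces are written as
#'   FASTA / BED / TSV files and the file list is returned in `$files`.
#' @return list: `mirnas`, `regions` (with `ref_seq`), `reference` (named
#'   character, one chromosome per gene), `variants` (per-sample calls),
#'   `controls`, `meta`, `truth` (`$sites`, `$mutations`), `config`.
#' @export
generate_cohort <- function(config = sim_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$rng_seed)
  mirnas <- sim_mirnas(cfg$n_mirnas)
  meta <- sim_meta(cfg)
  patients <- unique(meta$patient_id[meta$group != "control_pool"])

  utr_len <- sample(seq.int(cfg$utr_len_range[1L], cfg$utr_len_range[2L]),
                    cfg$n_genes, replace = TRUE)
  pad <- 100L
  regions <- data.frame(
    region_id = sprintf("utr3_G%03d", seq_len(cfg$n_genes)),
    chrom = sprintf("chr%d", seq_len(cfg$n_genes)),
    start = pad + 1L, end = pad + utr_len,
    strand = ifelse(seq_len(cfg$n_genes) %% 2L == 0L, "-", "+"),
    gene = sprintf("G%03d", seq_len(cfg$n_genes)),
    kind = "utr3", stringsAsFactors = FALSE)

  site_rows <- list(); mut_rows <- list()
  tx_seqs <- character(cfg$n_genes)
  site_counter <- 0L

  for (g in seq_len(cfg$n_genes)) {
    L <- utr_len[g]
    seq <- rand_dna(L)  # transcript orientation, DNA alphabet
    taken <- data.frame(lo = integer(), hi = integer())
    # extra homopolymer runs
    n_hp <- rbinom(1L, L, cfg$homopolymer_rate / 1000)
    for (h in seq_len(n_hp)) {
      sp <- place_span(L, 6L, taken, gap = 2L)
      if (anyNA(sp)) next
      substr(seq, sp[1L], sp[2L]) <- strrep(sample(c("A", "C", "G", "T"), 1L), 6L)
      taken <- rbind(taken, data.frame(lo = sp[1L], hi = sp[2L]))
    }
    gene_sites <- list()
    # planted strong sites (these may receive a mutation): an 8mer seed
    # match preceded by 3'-supplementary pairing (complement of miRNA
    # positions 13-19), the canonical architecture of a high-confidence
    # miRNA-response element
    for (s in seq_len(cfg$planted_sites_per_gene)) {
      mi <- ((g - 1L) * cfg$planted_sites_per_gene + s - 1L) %% cfg$n_mirnas + 1L
      m <- mirnas[mi, ]
      mirlen <- nchar(m$sequence)
      sp <- place_span(L, 19L, taken, gap = mirlen + 10L)
      if (anyNA(sp)) stop("UTR too short for requested sites (gene ", g, ")",
                          call. = FALSE)
      elem <- chartr("U", "T", paste0(
        revcomp_rna(substr(m$sequence, 13L, 19L)), rand_dna(4L),
        revcomp_rna(substr(m$sequence, 2L, 8L)), "A"))
      substr(seq, sp[1L], sp[2L]) <- elem
      taken <- rbind(taken, data.frame(lo = sp[1L], hi = sp[2L]))
      site_counter <- site_counter + 1L
      gene_sites[[length(gene_sites) + 1L]] <- list(
        site_id = sprintf("site%04d", site_counter), mirna_idx = mi,
        lo = sp[1L] + 11L, hi = sp[2L], decoy = FALSE)  # seed 8mer span
    }
    # decoy 6mer-only sites (never mutated), spread evenly over the miRNAs
    for (s in seq_len(cfg$decoy_sites_per_gene)) {
      mi <- ((g - 1L) * cfg$decoy_sites_per_gene + s - 1L) %% cfg$n_mirnas + 1L
      m <- mirnas[mi, ]
      sp <- place_span(L, 6L, taken, gap = nchar(m$sequence) + 10L)
      if (anyNA(sp)) next
      core <- chartr("U", "T", revcomp_rna(substr(m$sequence, 2L, 7L)))
      substr(seq, sp[1L], sp[2L]) <- core
      taken <- rbind(taken, data.frame(lo = sp[1L], hi = sp[2L]))
      site_counter <- site_counter + 1L
      gene_sites[[length(gene_sites) + 1L]] <- list(
        site_id = sprintf("site%04d", site_counter), mirna_idx = mi,
        lo = sp[1L], hi = sp[2L], decoy = TRUE)
    }
    # clean each mutation-eligible site's rescoring window of accidental
    # same-miRNA matches, so `disrupted` is the well-defined expected impact
    for (st in gene_sites) {
      if (st$decoy) next
      m <- mirnas[st$mirna_idx, ]
      mirlen <- nchar(m$sequence)
      seq <- scrub_seed_matches(seq, m, max(1L, st$lo - mirlen - 2L),
                                min(L, st$hi + mirlen + 2L), st$lo, st$hi)
    }
    tx_seqs[g] <- seq
    for (st in gene_sites) {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        site_id = st$site_id, gene = regions$gene[g],
        region_id = regions$region_id[g], mirna = mirnas$name[st$mirna_idx],
        tx_start = st$lo - 1L, tx_end = st$hi,
        seed_class = if (st$decoy) "6mer" else "8mer",
        decoy = st$decoy, stringsAsFactors = FALSE)
    }
  }

  truth_sites <- do.call(rbind, site_rows)
  # genomic projection of truth sites
  ix <- match(truth_sites$region_id, regions$region_id)
  plus <- regions$strand[ix] == "+"
  truth_sites$chrom <- regions$chrom[ix]
  truth_sites$g_start <- ifelse(plus, regions$start[ix] + truth_sites$tx_start,
                                regions$end[ix] - truth_sites$tx_end + 1L)
  truth_sites$g_end <- ifelse(plus, regions$start[ix] + truth_sites$tx_end - 1L,
                              regions$end[ix] - truth_sites$tx_start)

  # --- planted seed-disrupting mutations -------------------------------
  region_of <- function(rid) regions[match(rid, regions$region_id), ]
  for (i in seq_len(nrow(truth_sites))) {
    st <- truth_sites[i, ]
    if (st$decoy || runif(1L) >= cfg$p_site_mutation) next
    g <- match(st$region_id, regions$region_id)
    m <- mirnas[mirnas$name == st$mirna, ]
    mirlen <- nchar(m$sequence)
    seq <- tx_seqs[g]
    L <- nchar(seq)
    o <- st$tx_start + 4L  # central seed-core base, 0-based tx offset
    old <- substr(seq, o + 1L, o + 1L)
    wlo <- max(1L, st$tx_start + 1L - mirlen); whi <- min(L, st$tx_end + mirlen)
    core <- chartr("U", "T", revcomp_rna(substr(m$sequence, 2L, 7L)))
    alt_tx <- NA_character_
    for (cand in sample(setdiff(c("A", "C", "G", "T"), old))) {
      mut <- seq
      substr(mut, o + 1L, o + 1L) <- cand
      if (!grepl(core, substr(mut, wlo, whi), fixed = TRUE)) {
        alt_tx <- cand
        break
      }
    }
    if (is.na(alt_tx)) next  # no disrupting base found (never seen in practice)
    region <- regions[g, ]
    if (region$strand == "+") {
      pos <- region$start + o
      ref <- old; alt <- alt_tx
    } else {
      pos <- region$end - o
      ref <- wc_complement_dna(old); alt <- wc_complement_dna(alt_tx)
    }
    mut_rows[[length(mut_rows) + 1L]] <- data.frame(
      chrom = region$chrom, pos = pos, ref = ref, alt = alt,
      gene = region$gene, region_id = region$region_id,
      in_site = TRUE, site_id = st$site_id, site_mirna = st$mirna,
      expected_impact = "disrupted", stringsAsFactors = FALSE)
  }

  # --- background mutations (nested across rates via per-position u) ---
  set.seed(cfg$rng_seed + 777L)
  for (g in seq_len(cfg$n_genes)) {
    L <- utr_len[g]
    u <- runif(L)
    blocked <- rep(FALSE, L)
    gs <- truth_sites[truth_sites$region_id == regions$region_id[g], ]
    for (i in seq_len(nrow(gs))) {
      blocked[(gs$tx_start[i] + 1L):gs$tx_end[i]] <- TRUE
    }
    hit <- which(u < cfg$p_background_mutation_per_kb / 1000 & !blocked)
    region <- regions[g, ]
    for (p in hit) {
      old <- substr(tx_seqs[g], p, p)
      alt_tx <- c(A = "G", C = "T", G = "A", T = "C")[[old]]
      if (region$strand == "+") {
        pos <- region$start + p - 1L
        ref <- old; alt <- alt_tx
      } else {
        pos <- region$end - p + 1L
        ref <- wc_complement_dna(old); alt <- wc_complement_dna(alt_tx)
      }
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        chrom = region$chrom, pos = pos, ref = ref, alt = alt,
        gene = region$gene, region_id = region$region_id,
        in_site = FALSE, site_id = NA_character_, site_mirna = NA_character_,
        expected_impact = NA_character_, stringsAsFactors = FALSE)
    }
  }

  truth_muts <- if (length(mut_rows)) {
    do.call(rbind, mut_rows)
  } else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(), region_id = character(),
               in_site = logical(), site_id = character(),
               site_mirna = character(), expected_impact = character(),
               stringsAsFactors = FALSE)
  }

  # --- homopolymer tracts adjacent to a subset of background variants --
  set.seed(cfg$rng_seed + 1555L)
  truth_muts$artifact <- logical(nrow(truth_muts))
  bg <- which(!truth_muts$in_site)
  n_art <- round(cfg$artifact_fraction * length(bg))
  if (n_art > 0L) {
    for (i in sample(bg, n_art)) {
      g <- match(truth_muts$region_id[i], regions$region_id)
      region <- regions[g, ]
      o <- if (region$strand == "+") {
        truth_muts$pos[i] - region$start + 1L
      } else {
        region$end - truth_muts$pos[i] + 1L
      }
      L <- nchar(tx_seqs[g])
      if (o + 6L > L) next
      gs <- truth_sites[truth_sites$region_id == region$region_id, ]
      if (any(abs(gs$tx_start - o) < nchar(mirnas$sequence[1L]) + 10L)) next
      # never overwrite another variant's reference base with the tract
      same <- truth_muts$region_id == region$region_id
      o_others <- ifelse(regions$strand[g] == "+",
                         truth_muts$pos[same] - region$start + 1L,
                         region$end - truth_muts$pos[same] + 1L)
      if (any(o_others > o & o_others <= o + 7L)) next
      substr(tx_seqs[g], o + 1L, o + 6L) <-
        strrep(substr(tx_seqs[g], o + 1L, o + 1L), 6L)
      truth_muts$artifact[i] <- TRUE
    }
  }

  # region/reference sequences (genomic plus strand, padded chromosomes)
  regions$ref_seq <- vapply(seq_len(cfg$n_genes), function(g) {
    if (regions$strand[g] == "+") tx_seqs[g] else revcomp_dna(tx_seqs[g])
  }, character(1))
  set.seed(cfg$rng_seed + 2333L)
  reference <- vapply(seq_len(cfg$n_genes), function(g) {
    paste0(rand_dna(pad), regions$ref_seq[g], rand_dna(pad))
  }, character(1))
  names(reference) <- regions$chrom

  # --- carriers, coverage, VAF, control pools --------------------------
  set.seed(cfg$rng_seed + 3999L)
  var_rows <- list()
  carriers_str <- character(nrow(truth_muts))
  for (i in seq_len(nrow(truth_muts))) {
    n_car <- 1L + rbinom(1L, 4L, 0.25)
    car <- sample(patients, min(n_car, length(patients)))
    carriers_str[i] <- paste(sort(car), collapse = ",")
    for (pid in car) {
      smp <- meta$sample_id[meta$patient_id == pid & meta$group != "control_pool"]
      if (length(smp) > 1L) {  # longitudinal tFL patient
        smp <- if (runif(1L) < 0.5) smp else smp[grepl("_tfl$", smp)]
      }
      for (s in smp) {
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          chrom = truth_muts$chrom[i], pos = truth_muts$pos[i],
          ref = truth_muts$ref[i], alt = truth_muts$alt[i], type = "snv",
          sample_id = s,
          coverage = rnbinom(1L, mu = cfg$coverage_mean,
                             size = cfg$coverage_dispersion),
          vaf = rbeta(1L, cfg$vaf_alpha, cfg$vaf_beta),
          gene = truth_muts$gene[i], stringsAsFactors = FALSE)
      }
    }
  }
  truth_muts$carriers <- carriers_str
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), type = character(), sample_id = character(),
               coverage = integer(), vaf = double(), gene = character(),
               stringsAsFactors = FALSE)

  truth_muts$in_controls <- logical(nrow(truth_muts))
  ctl_rows <- list()
  n_ctl <- round(cfg$control_contamination * nrow(truth_muts))
  if (n_ctl > 0L) {
    for (i in sample(seq_len(nrow(truth_muts)), n_ctl)) {
      pools <- sample.int(cfg$n_control_pools,
                          1L + rbinom(1L, cfg$n_control_pools - 1L, 0.2))
      truth_muts$in_controls[i] <- TRUE
      for (p in pools) {
        ctl_rows[[length(ctl_rows) + 1L]] <- data.frame(
          chrom = truth_muts$chrom[i], pos = truth_muts$pos[i],
          ref = truth_muts$ref[i], alt = truth_muts$alt[i],
          sample_id = sprintf("pool%d", p), stringsAsFactors = FALSE)
      }
    }
  }
  controls <- if (length(ctl_rows)) do.call(rbind, ctl_rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), sample_id = character(),
               stringsAsFactors = FALSE)

  out <- list(mirnas = mirnas, regions = regions, reference = reference,
              variants = variants, controls = controls, meta = meta,
              truth = list(sites = truth_sites, mutations = truth_muts),
              config = cfg)
  if (!is.null(out_dir)) out$files <- write_cohort(out, out_dir)
  out
}

# write all cohort pieces as plain-text standard formats
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  ref <- Biostrings::DNAStringSet(cohort$reference)
  Biostrings::writeXStringSet(ref, f("reference.fa"))
  mir <- Biostrings::RNAStringSet(setNames(cohort$mirnas$sequence,
                                           cohort$mirnas$name))
  Biostrings::writeXStringSet(mir, f("mirnas.fa"))
  write_regions_bed(cohort$regions, f("regions.bed"))
  wt <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(cohort$regions[, setdiff(names(cohort$regions), "ref_seq")],
     f("regions.tsv"))
  wt(cohort$variants, f("variants.tsv"))
  wt(cohort$controls, f("controls.tsv"))
  wt(cohort$meta, f("meta.tsv"))
  wt(cohort$truth$sites, f("truth_sites.tsv"))
  wt(cohort$truth$mutations, f("truth_mutations.tsv"))
  setNames(file.path(out_dir, c("reference.fa", "mirnas.fa", "regions.bed",
                                "regions.tsv", "variants.tsv", "controls.tsv",
                                "meta.tsv", "truth_sites.tsv",
                                "truth_mutations.tsv")),
           c("reference", "mirnas", "regions_bed", "regions_tsv", "variants",
             "controls", "meta", "truth_sites", "truth_mutations"))
}
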