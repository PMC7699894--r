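# Independent oracles used across the suite.

# Brute-force duplex alignment score: enumerates every monotone pairing of
# miRNA positions (strictly decreasing 5'->3' position as the target index
# increases -- the antiparallel geometry) and scores columns plus affine gap
# runs between consecutive pairs directly. No dynamic programming; feasible
# for miRNA <= 10 nt and windows <= 12 nt.
oracle_align <- function(mir_seq, tgt_seq, params = mirsitemut::align_params()) {
  mir <- strsplit(chartr("T", "U", toupper(mir_seq)), "")[[1]]
  tgt <- strsplit(chartr("T", "U", toupper(tgt_seq)), "")[[1]]
  m <- length(mir); n <- length(tgt)
  pair_score <- function(p, j) {
    duo <- paste0(mir[p], tgt[j])
    s <- if (duo %in% c("AU", "UA", "GC", "CG")) {
      params$match
    } else if (duo %in% c("GU", "UG")) {
      params$gu_wobble
    } else {
      params$mismatch
    }
    if (p >= 2 && p <= 8) s * params$seed_weight else s
  }
  gap_cost <- function(d) {
    if (d == 0) 0 else params$gap_open + (d - 1) * params$gap_extend
  }
  best <- 0
  recurse <- function(last_p, last_j, acc) {
    if (acc > best) best <<- acc
    if (last_j >= n || last_p <= 1) return(invisible())
    for (p in seq_len(last_p - 1)) {
      for (j in seq.int(last_j + 1, n)) {
        recurse(p, j, acc + pair_score(p, j) +
                  gap_cost(last_p - p - 1) + gap_cost(j - last_j - 1))
      }
    }
  }
  for (p in seq_len(m)) {
    for (j in seq_len(n)) {
      recurse(p, j, pair_score(p, j))
    }
  }
  best
}

# Exhaustive hypergeometric upper tail: enumerates every draw of size
# n_hits from the universe and counts those overlapping the set at least as
# much as observed. Feasible for universes of <= 12 genes.
oracle_hyper <- function(hits, gene_set, universe) {
  k_obs <- length(intersect(hits, gene_set))
  draws <- utils::combn(universe, length(hits))
  hit_ge <- apply(draws, 2, function(d) {
    length(intersect(d, gene_set)) >= k_obs
  })
  mean(hit_ge)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

vkey <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")

# study conditions for parameter-recovery runs: every planted site mutated,
# no control contamination, no homopolymer planting
clean_sim_config <- function(seed) {
  mirsitemut::sim_config(p_site_mutation = 1, control_contamination = 0,
                         artifact_fraction = 0, homopolymer_rate = 0,
                         rng_seed = seed)
}
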