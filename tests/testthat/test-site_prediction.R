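# The worked miRNA throughout: 5'-UACAGUAUAGAUGAUGUACU-3', seed ACAGUAU
# (positions 2-8). Reverse complement of the seed is AUACUGU, so an 8mer
# site on the target reads AUACUGUA.
toy_mirna <- function() mirna_table("miR-toy", "UACAGUAUAGAUGAUGUACU")

test_that("seed matches classify by the canonical site hierarchy", {
  m <- toy_mirna()[1, ]
  hit <- find_seed_matches(m, "CCCAUACUGUACCC")
  expect_equal(hit$seed_class, "8mer")
  expect_equal(substr("CCCAUACUGUACCC", hit$tx_start + 1, hit$tx_end),
               "AUACUGUA")  # coordinates cover the matched bases
  expect_equal(find_seed_matches(m, "CCCAUACUGUGCCC")$seed_class, "7mer-m8")
  expect_equal(find_seed_matches(m, "CCCUACUGUACCC")$seed_class, "7mer-A1")
  expect_equal(find_seed_matches(m, "CCCUACUGUGCCC")$seed_class, "6mer")
  expect_equal(nrow(find_seed_matches(m, "CCCCCCCCCC")), 0L)
  expect_equal(nrow(find_seed_matches(m, "AUACU")), 0L)  # shorter than 6 nt
  # DNA targets are accepted and normalized
  expect_equal(find_seed_matches(m, "CCCATACTGTACCC")$seed_class, "8mer")
  # G:U wobble in the core never satisfies a seed class
  expect_equal(nrow(find_seed_matches(m, "CCCAUAUUGUACCC")), 0L)
})

test_that("duplex alignment reproduces the seed-weighted worked examples", {
  m <- toy_mirna()[1, ]
  # perfect Watson-Crick pairing of positions 1-8: one unweighted column
  # (position 1) plus seven weighted columns: 5 + 7 * 5 * 4 = 145
  aln <- align_duplex(m, "AUACUGUA")
  expect_equal(aln$score, 145)
  expect_equal(aln$pairing, "||||||||")
  expect_equal(oracle_align(m$sequence, "AUACUGUA"), 145)
  # one G:U wobble in a weighted column drops (5 - 1) * 4 = 16:
  # target C pairing position 5 (G) becomes U
  aln <- align_duplex(m, "AUAUUGUA")
  expect_equal(aln$score, 145 - 16)
  expect_equal(oracle_align(m$sequence, "AUAUUGUA"), 129)
  # no complementarity: no alignment reaches the reporting threshold
  aln <- align_duplex("AAAAAAAAAAAAAAAA", "AAAAAAAA")
  expect_lt(aln$score, align_params()$min_score)
  expect_equal(align_duplex(m, "")$score, 0)
})

test_that("duplex alignment equals the brute-force pairing oracle", {
  set.seed(99)
  for (i in 1:25) {
    mir <- random_dna(sample(5:8, 1))
    tgt <- random_dna(sample(6:10, 1))
    expect_equal(align_duplex(mir, tgt)$score, oracle_align(mir, tgt),
                 info = paste(mir, tgt))
  }
  # non-default parameters, including unit seed weight
  p2 <- align_params(match = 4, gu_wobble = 2, mismatch = -5, gap_open = -6,
                     gap_extend = -1, seed_weight = 1, min_score = 10)
  for (i in 1:10) {
    mir <- random_dna(sample(5:8, 1))
    tgt <- random_dna(sample(6:10, 1))
    expect_equal(align_duplex(mir, tgt, p2)$score, oracle_align(mir, tgt, p2),
                 info = paste(mir, tgt))
  }
})

test_that("an intact 8mer site never scores below its seed-mismatched copy", {
  m <- toy_mirna()[1, ]
  intact <- paste0("CCG", "AUACUGUA", "GCC")
  set.seed(4)
  for (core_pos in 4:10) {
    broken <- intact
    old <- substr(broken, core_pos, core_pos)
    substr(broken, core_pos, core_pos) <-
      sample(setdiff(c("A", "C", "G", "U"), old), 1)
    expect_gte(align_duplex(m, intact)$score, align_duplex(m, broken)$score)
  }
})

test_that("per-miRNA confidence filter keeps the top fraction with ties", {
  sites <- data.frame(mirna = "m1", align_score = c(10, 8, 6, 2))
  kept <- rank_and_filter_sites(sites, 0.75)
  expect_equal(kept$align_score, c(10, 8, 6))  # ceiling(0.75 * 4) = 3
  ties <- data.frame(mirna = "m1", align_score = rep(7, 4))
  expect_equal(nrow(rank_and_filter_sites(ties, 0.75)), 4L)  # ties retained
  one <- data.frame(mirna = "m1", align_score = 5)
  expect_equal(nrow(rank_and_filter_sites(one, 0.75)), 1L)
  expect_error(rank_and_filter_sites(sites, 0), "keep_fraction")
  expect_error(rank_and_filter_sites(sites, 1.2), "keep_fraction")
  # ranks are per miRNA, not global
  two <- data.frame(mirna = c("m1", "m1", "m2", "m2"),
                    align_score = c(100, 90, 10, 5))
  kept <- rank_and_filter_sites(two, 0.5)
  expect_equal(kept$align_score, c(100, 10))
})

test_that("raising the keep fraction never drops a previously kept site", {
  set.seed(17)
  sites <- data.frame(mirna = sample(paste0("m", 1:3), 40, replace = TRUE),
                      align_score = sample(80:160, 40, replace = TRUE))
  sites$id <- seq_len(nrow(sites))
  prev <- integer(0)
  for (f in c(0.25, 0.5, 0.75, 1)) {
    kept <- rank_and_filter_sites(sites, f)$id
    expect_gte(length(kept), ceiling(f * 0))  # vacuous floor; real check below
    expect_true(all(prev %in% kept))
    n_per <- table(sites$mirna)
    k_per <- table(sites$mirna[sites$id %in% kept])
    expect_true(all(k_per >= ceiling(f * n_per[names(k_per)])))
    prev <- kept
  }
})

test_that("site prediction projects planted sites to genomic coordinates", {
  set.seed(8)
  m <- toy_mirna()
  site <- "AUACUGUA"
  tx_plus <- paste0("CCTGCCGTCC", random_dna(30), chartr("U", "T", site),
                    random_dna(20), "GCCTGCCGCC")
  regions <- data.frame(
    region_id = c("rp", "rm"), chrom = c("c1", "c2"),
    start = 101L, end = 101L + nchar(tx_plus) - 1L,
    strand = c("+", "-"), gene = c("gp", "gm"), kind = "utr3",
    stringsAsFactors = FALSE)
  regions$ref_seq <- c(tx_plus,
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(tx_plus))))
  sites <- predict_sites(m, regions)
  sites <- sites[sites$seed_class == "8mer", ]
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$tx_start, c(40L, 40L))
  # same transcript offset, mirrored genomic projection
  expect_equal(sites$g_start[sites$region_id == "rp"], 101L + 40L)
  expect_equal(sites$g_end[sites$region_id == "rm"],
               regions$end[2] - 40L)
  expect_true(all(sites$align_score >= 145))
  expect_true(all(sites$delta_g < 0))
})

test_that("overlapping same-miRNA sites merge to the best representative", {
  set.seed(12)
  m <- toy_mirna()
  # two 6mer cores back to back overlap after the first is extended
  tx <- paste0(random_dna(30), "AUACUGUAUACUGUA", random_dna(30))
  regions <- data.frame(region_id = "r", chrom = "c1", start = 1L,
                        end = nchar(tx), strand = "+", gene = "g",
                        kind = "utr3", ref_seq = chartr("U", "T", tx),
                        stringsAsFactors = FALSE)
  sites <- predict_sites(m, regions, site_policy = "seed_only")
  per_span <- sites[sites$mirna == "miR-toy", ]
  overlaps <- sum(per_span$tx_start < 45 & per_span$tx_end > 30)
  expect_lte(overlaps, 2L)  # merged, not every raw seed hit
})
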