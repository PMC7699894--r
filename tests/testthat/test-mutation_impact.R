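toy_mirna2 <- function() mirna_table("miR-toy", "UACAGUAUAGAUGAUGUACU")

test_that("variant/site intersection matches the reported worked offsets", {
  sites <- data.frame(
    region_id = c("EZH2", "BCL2"), mirna = c("hsa-mir-144", "hsa-mir-5008"),
    chrom = c("chr7", "chr18"),
    g_start = c(148508722L, 60793436L), g_end = c(148508742L, 60793458L),
    stringsAsFactors = FALSE)
  v <- data.frame(chrom = c("chr7", "chr18", "chr7"),
                  pos = c(148508727L, 60793447L, 148508721L),
                  ref = "T", alt = "A", stringsAsFactors = FALSE)
  hits <- intersect_variants_sites(v, sites)
  expect_equal(nrow(hits), 2L)  # the one-base-upstream variant pairs nothing
  expect_equal(hits$offset_in_site[hits$region_id == "EZH2"], 5L)
  expect_equal(hits$offset_in_site[hits$region_id == "BCL2"], 11L)
})

test_that("indels intersect via deleted span or insertion anchor", {
  sites <- data.frame(region_id = "s", mirna = "m", chrom = "c",
                      g_start = 100L, g_end = 110L, stringsAsFactors = FALSE)
  # deletion anchored at 98 removes bases 99-101: overlaps the site at 100
  del <- data.frame(chrom = "c", pos = 98L, ref = "GTAC", alt = "G",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_variants_sites(del, sites)), 1L)
  expect_equal(intersect_variants_sites(del, sites)$offset_in_site, 0L)
  # deletion strictly upstream does not
  del2 <- data.frame(chrom = "c", pos = 96L, ref = "GTA", alt = "G",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_variants_sites(del2, sites)), 0L)
  # insertion overlaps only via its anchor base
  ins <- data.frame(chrom = "c", pos = c(99L, 100L), ref = "T",
                    alt = "TC", stringsAsFactors = FALSE)
  expect_equal(intersect_variants_sites(ins, sites)$pos, 100L)
})

impact_region <- function(tx_seq) {
  data.frame(region_id = "r", chrom = "c1", start = 1L, end = nchar(tx_seq),
             strand = "+", gene = "G", kind = "utr3",
             ref_seq = chartr("U", "T", tx_seq), stringsAsFactors = FALSE)
}

test_that("a seed-breaking SNV is called disrupted with a negative delta", {
  set.seed(3)
  m <- toy_mirna2()[1, ]
  tx <- paste0("CCTGACGGTC", random_dna(20), "ATACTGTA", random_dna(20))
  region <- impact_region(tx)
  # break the central core base (site tx offsets 30..38)
  pos <- 35L
  ref <- substr(tx, pos, pos)
  pair <- apply_variant(region, list(chrom = "c1", pos = pos, ref = ref,
                                     alt = "C"))
  call <- score_mutation_effect(m, pair, 30L, 38L)
  expect_equal(call$impact, "disrupted")
  expect_lt(call$delta_score, 0)
  expect_equal(call$seed_wt, "8mer")
  expect_equal(call$seed_mut, "none")
  expect_gt(call$delta_dg, 0)  # mutant duplex is less stable
})

test_that("a variant outside the rescoring window leaves the site unchanged", {
  set.seed(6)
  m <- toy_mirna2()[1, ]
  tx <- paste0("CCTGACGGTCCTGGACCGGATCCTGGACGGTC", random_dna(30),
               "ATACTGTA", "CGGATCCTGGACGGTCCTGGACCGGATCCTGG")
  region <- impact_region(tx)
  pair <- apply_variant(region, list(chrom = "c1", pos = 2L, ref = "C",
                                     alt = "A"))
  call <- score_mutation_effect(m, pair, 62L, 70L)
  expect_equal(call$impact, "unchanged")
  expect_equal(call$delta_score, 0)
})

test_that("a mismatch-to-match SNV gains a site with a positive delta", {
  set.seed(9)
  m <- toy_mirna2()[1, ]
  broken <- "ATACCGTA"  # core base T -> C relative to the 8mer ATACTGTA
  tx <- paste0("CCTGACGGTCCTGGACCGGATCCTGGACGG", broken, "CCTGGACGGTCCTGGACC")
  region <- impact_region(tx)
  pos <- 35L  # the C inside the broken core
  expect_equal(substr(tx, pos, pos), "C")
  pair <- apply_variant(region, list(chrom = "c1", pos = pos, ref = "C",
                                     alt = "T"))
  call <- score_mutation_effect(m, pair, 30L, 38L)
  expect_equal(call$impact, "gained")
  expect_gt(call$delta_score, 0)
  # the independent oracle confirms the score increase on the site itself
  expect_gt(oracle_align(m$sequence, "AUACUGUA"),
            oracle_align(m$sequence, "AUACCGUA"))
})

test_that("swapping alleles flips disrupted to gained and negates the delta", {
  set.seed(13)
  m <- toy_mirna2()[1, ]
  tx <- paste0("CCTGACGGTC", random_dna(20), "ATACTGTA", random_dna(20))
  region <- impact_region(tx)
  pos <- 35L
  ref <- substr(tx, pos, pos)
  pair <- apply_variant(region, list(chrom = "c1", pos = pos, ref = ref,
                                     alt = "C"))
  fwd <- score_mutation_effect(m, pair, 30L, 38L)
  swapped <- pair
  swapped$wt_seq <- pair$mut_seq
  swapped$mut_seq <- pair$wt_seq
  rev <- score_mutation_effect(m, swapped, 30L, 38L)
  expect_equal(rev$delta_score, -fwd$delta_score)
  expect_equal(fwd$impact, "disrupted")
  expect_equal(rev$impact, "gained")
})

test_that("calls without any qualifying site context error out", {
  m <- toy_mirna2()[1, ]
  tx <- strrep("CT", 30)
  region <- impact_region(tx)
  pair <- apply_variant(region, list(chrom = "c1", pos = 30L, ref = "T",
                                     alt = "A"))
  expect_error(score_mutation_effect(m, pair, 25L, 33L), "no site context")
})

test_that("impact tallies report counts and fractions by kind and gene", {
  calls <- data.frame(kind = c(rep("utr3", 9), "exon"),
                      gene = rep(c("A", "B"), 5),
                      impact = c(rep("disrupted", 6), rep("weakened", 4)),
                      stringsAsFactors = FALSE)
  s <- summarize_impacts(calls)
  expect_equal(s$by_kind$fraction[s$by_kind$level == "utr3"], 0.9)
  expect_equal(s$by_gene$n, c(5L, 5L))
  empty <- summarize_impacts(calls[0, ])
  expect_equal(empty$n, 0L)
  expect_equal(nrow(empty$by_kind), 0L)
})

test_that("the recurrent-variant table tallies 12 UTR, 3 exon, 1 intron", {
  t1 <- fl_recurrent_variants()
  s <- summarize_impacts(data.frame(kind = t1$kind, gene = t1$gene,
                                    impact = NA))
  expect_equal(s$by_kind$n[s$by_kind$level == "utr3"], 12L)
  expect_equal(s$by_kind$n[s$by_kind$level == "exon"], 3L)
  expect_equal(s$by_kind$n[s$by_kind$level == "intron"], 1L)
  expect_equal(s$by_kind$fraction[s$by_kind$level == "utr3"], 0.75)
})
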