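mkvar <- function(pos, ref = "A", alt = "G", sample_id = "s1",
                  coverage = 1000L, vaf = 0.3, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             type = "snv", sample_id = sample_id, coverage = coverage,
             vaf = vaf, stringsAsFactors = FALSE)
}

test_that("QC keeps calls strictly above the coverage and VAF thresholds", {
  v <- rbind(mkvar(1, coverage = 31L, vaf = 0.06),
             mkvar(2, coverage = 30L, vaf = 0.50),
             mkvar(3, coverage = 1000L, vaf = 0.05))
  r <- qc_filter(v)
  expect_equal(r$kept$pos, 1L)          # 31x / 6% passes
  expect_equal(r$removed$pos, c(2L, 3L))  # both boundaries are strict
  r2 <- qc_filter(v, strict = FALSE)
  expect_equal(nrow(r2$kept), 3L)
  v$vaf[1] <- NA
  expect_error(qc_filter(v), "chr1:1")
})

test_that("control subtraction is any-pool and allele-exact", {
  v <- rbind(mkvar(10), mkvar(20), mkvar(30, alt = "T"))
  ctl <- rbind(mkvar(10, sample_id = "pool3"),
               mkvar(30, alt = "C", sample_id = "pool1"))
  r <- subtract_controls(v, ctl)
  expect_equal(r$removed$pos, 10L)      # one pool suffices
  expect_equal(r$kept$pos, c(20L, 30L)) # same position, other allele kept
})

test_that("artifact tracts are found as runs and tandem repeats", {
  tr <- find_artifact_tracts("CCGTAAAAAAGTC")
  expect_equal(tr[tr$type == "homopolymer", c("lo", "hi")],
               data.frame(lo = 5L, hi = 10L))
  tr <- find_artifact_tracts("GGCATATATATCC")
  expect_true(any(tr$type == "repeat" & tr$lo == 4L & tr$hi == 11L))
  expect_equal(nrow(find_artifact_tracts("ACGTACGGTCA")), 0L)
})

test_that("variants in or next to artifact tracts are masked", {
  #           1234567890123456789012345
  ref <- c(chr1 = "ACGTCTGCAAAAAAGCATGCATGCGGACT")
  # run of six A at 9-14; SNV at 15 is adjacent (pad 1)
  adjacent <- mkvar(15, ref = "G", alt = "T")
  inside <- mkvar(11, ref = "A", alt = "G")
  clean <- mkvar(28, ref = "C", alt = "A")
  r <- mask_artifact_regions(rbind(adjacent, inside, clean), ref)
  expect_equal(r$removed$pos, c(15L, 11L))
  expect_equal(r$kept$pos, 28L)
  # tandem repeat context
  ref2 <- c(chr1 = "GGCCGGATATATATCCGGACCGGAACCTT")
  r2 <- mask_artifact_regions(mkvar(10, ref = "T", alt = "C"), ref2)
  expect_equal(nrow(r2$removed), 1L)
  expect_error(mask_artifact_regions(mkvar(99), ref), "beyond reference")
})

cohort_meta <- function() {
  data.frame(
    sample_id = c("p1_ant", "p1_tfl", "p2_ant", "p2_tfl", "p3_fl", "pool1"),
    patient_id = c("p1", "p1", "p2", "p2", "p3", "pool1"),
    group = c("antFL", "tFL", "antFL", "tFL", "ntFL", "control_pool"),
    timepoint = NA_character_, stringsAsFactors = FALSE)
}

test_that("recurrence counts patients, not samples", {
  meta <- cohort_meta()
  v <- rbind(mkvar(5, sample_id = "p1_ant"), mkvar(5, sample_id = "p1_tfl"),
             mkvar(7, sample_id = "p1_tfl"), mkvar(7, sample_id = "p3_fl"))
  r <- tally_recurrence(v, meta)
  expect_equal(r$n_patients[r$pos == 5], 1L)  # paired samples dedup
  expect_equal(r$n_samples[r$pos == 5], 2L)
  expect_false(r$recurrent[r$pos == 5])
  expect_true(r$recurrent[r$pos == 7])
  # duplicating a sample of an already-counted patient changes nothing
  v2 <- rbind(v, mkvar(5, sample_id = "p1_ant"))
  expect_equal(tally_recurrence(v2, meta)$n_patients,
               r$n_patients)
  expect_error(tally_recurrence(mkvar(1, sample_id = "ghost"), meta),
               "ghost")
})

test_that("exclusivity summaries split occurrences by patient group", {
  meta <- cohort_meta()
  # variant 5: tFL-only carrier; variant 7: both groups
  v <- rbind(mkvar(5, sample_id = "p1_tfl"),
             mkvar(7, sample_id = "p2_ant"), mkvar(7, sample_id = "p3_fl"))
  s <- exclusivity_summary(v, meta)
  expect_equal(s$n_variants, 2L)
  expect_equal(s$n_exclusive_tfl, 1L)
  expect_equal(s$exclusive_fraction, 50)
  expect_equal(s$variants_in_tfl, 2L)   # p1 for var5, p2 (antFL) for var7
  expect_equal(s$variants_in_ntfl, 1L)
  # all variants in both groups -> no exclusivity
  v2 <- rbind(mkvar(7, sample_id = "p2_ant"), mkvar(7, sample_id = "p3_fl"))
  expect_equal(exclusivity_summary(v2, meta)$exclusive_fraction, 0)
  # single variant with a single tFL carrier -> 100%
  expect_equal(exclusivity_summary(mkvar(5, sample_id = "p1_tfl"),
                                   meta)$exclusive_fraction, 100)
})

test_that("the ledger conserves every variant through the cascade", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(10:60, 1)
    ref_len <- 40L * n + 60L
    reference <- c(chrZ = random_dna(ref_len))
    v <- mkvar(sample(seq(20, ref_len - 20), n), chrom = "chrZ")
    v$ref <- substring(reference, v$pos, v$pos)
    v$alt <- ifelse(v$ref == "G", "T", "G")
    v$coverage <- sample(c(10L, 500L), n, replace = TRUE, prob = c(0.2, 0.8))
    ctl <- v[runif(n) < 0.3, c("chrom", "pos", "ref", "alt")]
    led <- build_ledger(v, ctl, reference)
    expect_equal(led$n_input,
                 led$n_remaining + led$n_removed_qc +
                   led$n_removed_controls + led$n_removed_artifact)
    expect_equal(sort(unique(names(led$fates))), sort(unique(vkey(v))))
    expect_true(all(table(names(led$fates)) == 1))
  }
})

test_that("a variant caught by two filters takes the fate of the first", {
  reference <- c(chr1 = "ACGTCTGCAAAAAAGCATGCATGCGGACT")
  v <- mkvar(15, ref = "G", alt = "T")  # adjacent to the A-run
  ctl <- v[, c("chrom", "pos", "ref", "alt")]
  led <- build_ledger(v, ctl, reference)
  expect_equal(unname(led$fates), "control")  # controls run before masking
  led2 <- build_ledger(v, NULL, reference)
  expect_equal(unname(led2$fates), "artifact")
})

test_that("degenerate ledgers stay consistent", {
  v <- mkvar(1)[0, ]
  led <- build_ledger(v)
  expect_equal(led$n_input, 0L)
  expect_equal(led$n_remaining, 0L)
  v <- rbind(mkvar(1), mkvar(2))
  led <- build_ledger(v, v[, c("chrom", "pos", "ref", "alt")])
  expect_equal(led$n_remaining, 0L)
  expect_true(all(led$fates == "control"))
})
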