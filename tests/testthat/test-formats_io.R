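test_that("miRNA FASTA reading normalizes alphabet and extracts seeds", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hsa-miR-X MIMAT toy", "UACAGUAUAGAUGAUGUACU",
               ">hsa-miR-Y", "TACAGTCTAGATGATGTACT"), fa)
  m <- read_mirna_fasta(fa)
  expect_equal(m$name, c("hsa-miR-X", "hsa-miR-Y"))
  expect_equal(m$seed[1], "ACAGUAU")
  expect_equal(m$sequence[2], "UACAGUCUAGAUGAUGUACU")  # T -> U
  expect_false(any(grepl("T", m$sequence)))

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_equal(nrow(read_mirna_fasta(empty)), 0L)

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGUACGUACGUACGU", ">a", "ACGUACGUACGUACGU"), dup)
  expect_error(read_mirna_fasta(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">z", "ACGUACGNACGUACGU"), bad)
  expect_error(read_mirna_fasta(bad), "non-ACGTU.*offset 8")
})

test_that("coordinate-TSV variants parse the compact position/mutation style", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tmutation\tsample_id",
               "chr7:148508727\tT/A\ts1",
               "chr11:3380000\tt/TC\ts1",     # mixed case
               "chr4:30732983\tGTA/G\ts2"), tsv)
  v <- read_variants(tsv, "coord_tsv")
  expect_equal(v$chrom, c("chr7", "chr11", "chr4"))
  expect_equal(v$pos, c(148508727L, 3380000L, 30732983L))
  expect_equal(v$ref, c("T", "T", "GTA"))
  expect_equal(v$alt, c("A", "TC", "G"))
  expect_equal(v$type, c("snv", "insertion", "deletion"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tmutation", "chr7-999\tT/A"), bad)
  expect_error(read_variants(bad, "coord_tsv"), "line 1")
})

test_that("variant classification is exclusive and rejects complex alleles", {
  expect_equal(classify_variant(c("T", "T", "GTA"), c("A", "TC", "G")),
               c("snv", "insertion", "deletion"))
  expect_error(classify_variant("GT", "CA"), "complex")
  expect_error(classify_variant("T", "T"), "identical")
  # exactly one class holds for any supported allele pair
  set.seed(11)
  for (i in 1:50) {
    anchor <- random_dna(1)
    tail_len <- sample(0:3, 1)
    ref <- paste0(anchor, random_dna(tail_len))
    alt <- if (tail_len > 0 && runif(1) < 0.5) anchor else
      paste0(ref, random_dna(sample(1:3, 1)))
    if (ref == alt) next
    type <- classify_variant(ref, alt)
    expect_length(type, 1L)
    expect_true(type %in% c("snv", "insertion", "deletion"))
    expect_equal(type == "snv", nchar(ref) == 1 && nchar(alt) == 1)
  }
})

test_that("VCF variants split multi-allelics and carry per-sample support", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##contig=<ID=chr1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:DP:AD\t0/1:100:60,40,0\t0/0:80:80,0,0",
    "chr1\t200\t.\tC\tCA\t.\tPASS\t.\tGT:DP:AD\t0/0:50:50,0\t0/1:60:30,30"), vcf)
  v <- read_variants(vcf, "vcf")
  a <- v[v$sample_id == "sampA", ]
  expect_equal(nrow(a), 2L)  # the multi-allelic record split into two rows
  expect_setequal(a$alt, c("G", "T"))
  expect_equal(a$coverage, c(100L, 100L))
  expect_equal(a$vaf[a$alt == "G"], 0.4)
  b <- v[v$sample_id == "sampB", ]
  expect_equal(b$pos, 200L)
  expect_equal(b$type, "insertion")
  expect_equal(b$vaf, 0.5)
})

test_that("BED regions convert losslessly to 1-based inclusive and back", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr7\t148508721\t148508742\tsite1\t0\t-", bed)
  r <- read_regions(bed)
  expect_equal(r$start, 148508722L)
  expect_equal(r$end, 148508742L)
  expect_equal(r$strand, "-")
  # round trip is the identity for random valid intervals
  set.seed(5)
  rnd <- data.frame(
    region_id = sprintf("r%d", 1:20),
    chrom = sample(paste0("chr", 1:5), 20, replace = TRUE),
    start = sample.int(1e6, 20), gene = "g", kind = "utr3",
    strand = sample(c("+", "-"), 20, replace = TRUE))
  rnd$end <- rnd$start + sample.int(500, 20)
  out <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(rnd, out)
  back <- read_regions(out)
  expect_equal(back[, c("chrom", "start", "end", "strand")],
               rnd[, c("chrom", "start", "end", "strand")])

  zero <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100\tx\t0\t+", zero)
  expect_error(read_regions(zero), "zero-length")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand", "chr18\t60793436\t60793458\t*"),
             tsv)
  expect_error(read_regions(tsv), "strand")
})

test_that("impact reports round-trip and sort deterministically", {
  calls <- data.frame(
    gene = c("B", "A"), region_id = c("rB", "rA"), region_kind = "utr3",
    chrom = c("chr2", "chr1"), pos = c(5L, 9L), ref = "A", alt = "G",
    mirna = c("m2", "m1"), site_start = c(1L, 2L), site_end = c(9L, 10L),
    offset = c(4L, 7L), seed_class = "8mer", score_wt = c(145, 150),
    score_mut = c(100, 99), dg_wt = c(-11.5, -12), dg_mut = c(-3, -4),
    delta_score = c(-45, -51), delta_dg = c(8.5, 8), impact = "disrupted",
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_impact_report(calls, path)
  back <- read_impact_report(path)
  expect_equal(back$chrom, c("chr1", "chr2"))  # stable (chrom, pos, mirna) sort
  reordered <- calls[order(calls$chrom, calls$pos, calls$mirna), ]
  rownames(reordered) <- NULL
  expect_equal(back, reordered[, names(back)])

  write_impact_report(calls[0, ], path)
  expect_equal(nrow(read_impact_report(path)), 0L)
})
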