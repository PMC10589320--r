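test_that("normalize_variant canonicalizes SNVs, indels and delins", {
  k <- normalize_variant("chr1", 100, "A", "G")
  expect_equal(k$position, 100L)
  expect_equal(k$ref, "A")
  expect_equal(k$alt, "G")
  expect_equal(k$variant_class, "SNV")

  # suffix-then-prefix trimming of a redundant insertion encoding;
  # expected key verified with the haplotype-application oracle below
  k2 <- normalize_variant("chr1", 100, "ATG", "ATGTG")
  expect_equal(k2$position, 100L)
  expect_equal(k2$ref, "A")
  expect_equal(k2$alt, "ATG")
  expect_equal(k2$variant_class, "insertion")

  expect_equal(normalize_variant("chr2", 5, "TTC", "T")$variant_class,
               "deletion")
  expect_equal(normalize_variant("chr2", 5, "AT", "GC")$variant_class,
               "delins")
  expect_error(normalize_variant("chr1", 10, "A", "A"), "ref equals alt")
  expect_error(normalize_variant("chr1", 10, "", ""), "empty")
  expect_error(normalize_variant("chr1", 10, "AN", "A"), "DNA")
})

test_that("trimmed key preserves the haplotype of the raw encoding", {
  ctx <- "CCGCATGTGC"  # positions 96..105; 100..102 spell ATG
  raw_hap <- apply_edit(ctx, 96L, 100L, "ATG", "ATGTG")
  k <- normalize_variant("chr1", 100, "ATG", "ATGTG")
  norm_hap <- apply_edit(ctx, 96L, k$position, k$ref, k$alt)
  expect_equal(norm_hap, raw_hap)
})

test_that("normalization is idempotent on random variants", {
  set.seed(11)
  for (i in 1:200) {
    nr <- sample(1:4, 1)
    na <- sample(1:4, 1)
    ref <- random_dna(nr)
    alt <- random_dna(na)
    if (ref == alt) next
    k1 <- normalize_variant("chr1", sample(10:500, 1), ref, alt)
    k2 <- normalize_variant(k1$chromosome, k1$position, k1$ref, k1$alt)
    expect_identical(k2$id, k1$id)
  }
})

test_that("all equivalent encodings of an edit map to one key", {
  set.seed(22)
  for (i in 1:60) {
    ctx <- random_dna(30)
    pos <- sample(8:20, 1)
    type <- sample(c("snv", "ins", "del"), 1)
    i0 <- pos  # 1-based equals genomic here (context_start = 1)
    if (type == "snv") {
      ref <- substr(ctx, i0, i0)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (type == "ins") {
      ref <- substr(ctx, i0, i0)
      alt <- paste0(ref, random_dna(sample(1:2, 1)))
    } else {
      ref <- substr(ctx, i0, i0 + sample(1:2, 1))
      alt <- substr(ctx, i0, i0)
    }
    reps <- equivalent_representations(ctx, 1L, pos, ref, alt)
    # oracle: every representation yields the same edited haplotype
    haps <- vapply(reps, function(r) {
      apply_edit(ctx, 1L, r$pos, r$ref, r$alt)
    }, character(1))
    expect_length(unique(haps), 1L)
    keys <- vapply(reps, function(r) {
      normalize_variant("chr1", r$pos, r$ref, r$alt,
                        context = ctx, context_start = 1L)$id
    }, character(1))
    expect_length(unique(keys), 1L)
  }
})

test_that("FILTER strings map onto the three-status vocabulary", {
  expect_equal(map_filter_status(c("PASS", ".", "", "q20", "LowQual",
                                   "strand_bias")),
               c("PASS", "PASS", "PASS", "quality_filtered",
                 "quality_filtered", "other_filtered"))
})

test_that("variant TSV round-trips through write and read", {
  calls <- make_calls(list(A = c(vid(100), vid(200, "T", "C")),
                           B = vid(100)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_calls(calls, f)
  back <- read_variant_calls(f)
  expect_equal(back[order(back$institution_id, back$pos), ],
               calls[order(calls$institution_id, calls$pos), ],
               ignore_attr = TRUE)
})

test_that("variant reader validates rows and names offending lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\tchrom\tpos\tref\talt\tvaf\tdepth\tfilter",
               "c1\tA\tchr1\t100\tA\tG\t0.5\t100\tPASS",
               "c1\tA\tchr1\t200\tA\tG\t1.2\t100\tPASS"), f)
  expect_error(read_variant_calls(f), "VAF outside \\[0,1\\].*line.*3")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\tchrom\tpos\tref\talt\tvaf",
               "c1\tA\tchr1\t100\tA\tG\t0.5"), f2)
  expect_error(read_variant_calls(f2), "missing mandatory column")
})

test_that("VCF records are parsed with FILTER and FORMAT AF/DP", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"AF\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AF:DP\t0/1:0.42:180",
    "chr1\t250\t.\tAT\tA\t50\tq20\t.\tGT:AF:DP\t0/1:0.08:95"
  ), f)
  calls <- read_variant_calls(f, dialect = "vcf", case_id = "c1",
                              institution_id = "A")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$filter_status, c("PASS", "quality_filtered"))
  expect_equal(calls$vaf, c(0.42, 0.08))
  expect_equal(calls$depth, c(180L, 95L))
  expect_equal(calls$variant_class, c("SNV", "deletion"))
})

test_that("segment reader enforces overlap-freedom and dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\tchrom\tstart\tend\ttotal_cn",
               "c1\tA\tchr1\t0\t100\t3",
               "c1\tA\tchr1\t150\t300\t1"), f)
  segs <- read_cn_segments(f)
  expect_equal(nrow(segs), 2L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\tchrom\tstart\tend\ttotal_cn",
               "c1\tA\tchr1\t0\t100\t3",
               "c1\tA\tchr1\t50\t150\t1"), f2)
  expect_error(read_cn_segments(f2), "overlapping segments.*\\[50,150\\)")

  # 1-based inclusive (1,100) converts to [0,100)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\tchrom\tstart\tend\ttotal_cn",
               "c1\tA\tchr1\t1\t100\t4"), f3)
  segs3 <- read_cn_segments(f3, dialect = "onebased")
  expect_equal(segs3$start, 0)
  expect_equal(segs3$end, 100)

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\tchrom\tstart\tend\ttotal_cn",
               "c1\tA\tchr1\t0\t100\t-1"), f4)
  expect_error(read_cn_segments(f4), "negative")
})

test_that("biomarker table handles missing purity and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\thrd_sum\ttmb\tmsi\tpurity\tploidy",
               "c1\tA\t42\t9.4\t2.1\t\t2",
               "c1\tB\t37\t10.2\t1.8\t0.6\t2"), f)
  bm <- read_biomarker_table(f)
  expect_true(is.na(bm$purity[1]))
  expect_equal(bm$hrd_sum[1], 42)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\thrd_sum\ttmb\tmsi",
               "c1\tA\t42\t9.4\t2.1",
               "c1\tA\t40\t9.0\t2.0"), f2)
  expect_error(read_biomarker_table(f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tinstitution_id\thrd_sum\ttmb\tmsi",
               "c1\tA\t42\t9.4\t120"), f3)
  expect_error(read_biomarker_table(f3), "MSI outside")
})
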