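gm1mb <- genome_model("chr1", 1e6)

test_that("fill_profile tiles unreported regions at CN 2 and merges", {
  empty <- data.frame(case_id = character(0), institution_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), total_cn = integer(0),
                      major_cn = integer(0), minor_cn = integer(0))
  p <- fill_profile(empty, gm1mb)
  expect_equal(nrow(p$segments), 1L)
  expect_equal(p$segments$total_cn, 2L)
  expect_equal(p$segments$end - p$segments$start, 1e6)

  one <- data.frame(case_id = "c", institution_id = "A", chrom = "chr1",
                    start = 100, end = 200, total_cn = 4L,
                    major_cn = NA_integer_, minor_cn = NA_integer_)
  p2 <- fill_profile(one, gm1mb)
  expect_equal(p2$segments$total_cn, c(2L, 4L, 2L))
  expect_equal(p2$segments$start, c(0, 100, 200))

  beyond <- one
  beyond$end <- 2e6
  expect_error(fill_profile(beyond, gm1mb), "beyond chromosome length")
})

test_that("filling is a round trip for non-neutral segments", {
  set.seed(66)
  g <- tiny_genome()
  for (rep in 1:30) {
    p <- random_profile(g, k = sample(1:6, 1))
    non2 <- p$segments[p$segments$total_cn != 2L, , drop = FALSE]
    non2$case_id <- "case_01"
    non2$institution_id <- "I1"
    p2 <- fill_profile(non2[, c("case_id", "institution_id", "chrom",
                                "start", "end", "total_cn", "major_cn",
                                "minor_cn")], g)
    expect_equal(p2$segments[, c("chrom", "start", "end", "total_cn")],
                 p$segments[, c("chrom", "start", "end", "total_cn")],
                 ignore_attr = TRUE)
  }
})

test_that("predominant ploidy is the modal CN with ties toward lower", {
  p_all2 <- fill_profile(
    data.frame(case_id = character(0), institution_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               total_cn = integer(0), major_cn = integer(0),
               minor_cn = integer(0)), gm1mb)
  expect_equal(predominant_ploidy(p_all2), 2L)

  maj4 <- data.frame(case_id = "c", institution_id = "A", chrom = "chr1",
                     start = 0, end = 6e5, total_cn = 4L,
                     major_cn = NA_integer_, minor_cn = NA_integer_)
  expect_equal(fill_profile(maj4, gm1mb)$predominant_ploidy, 4L)

  tie <- maj4
  tie$end <- 5e5
  expect_equal(fill_profile(tie, gm1mb)$predominant_ploidy, 2L)
})

test_that("identical profiles match exactly; doubling is fully explained", {
  set.seed(77)
  g <- tiny_genome()
  a <- random_profile(g, k = 4)
  self <- compare_profiles(a, a)
  expect_equal(unname(self$fractions[["exact"]]), 1)

  b <- a
  b$segments$total_cn <- 2L * b$segments$total_cn
  b$predominant_ploidy <- predominant_ploidy(b)
  cmp <- compare_profiles(a, b)
  expect_equal(unname(cmp$fractions[["duplication"]] +
                        cmp$fractions[["exact"]]), 1)
  expect_equal(cmp$mismatch_bp, 0)
})

test_that("interval comparison equals the per-base brute-force oracle", {
  set.seed(88)
  g <- tiny_genome()
  for (rep in 1:15) {
    a <- random_profile(g, inst = "A", k = sample(2:6, 1))
    b <- random_profile(g, inst = "B", k = sample(2:6, 1))
    for (rule in c("ratio", "delta")) {
      cmp <- compare_profiles(a, b, rule = rule)
      oracle <- compare_by_base(a, b, rule = rule)
      expect_identical(cmp$exact_bp, as.numeric(oracle$exact))
      expect_identical(cmp$duplication_bp, as.numeric(oracle$dup))
      expect_identical(cmp$mismatch_bp, as.numeric(oracle$mism))
      expect_equal(unname(cmp$diff_histogram),
                   unname(as.numeric(oracle$hist)))
    }
  }
})

test_that("comparison is symmetric and conserves base counts", {
  set.seed(99)
  g <- tiny_genome()
  for (rep in 1:20) {
    a <- random_profile(g, inst = "A", k = sample(1:6, 1))
    b <- random_profile(g, inst = "B", k = sample(1:6, 1))
    ab <- compare_profiles(a, b)
    ba <- compare_profiles(b, a)
    expect_equal(ab$exact_bp, ba$exact_bp)
    expect_equal(ab$mismatch_bp, ba$mismatch_bp)
    expect_equal(ab$diff_histogram, ba$diff_histogram)
    expect_equal(ab$exact_bp + ab$duplication_bp + ab$mismatch_bp,
                 genome_size(g))
    if (length(ab$diff_histogram)) {
      expect_equal(sum(ab$diff_histogram), ab$mismatch_bp)
    }
  }
})

test_that("pooled |dCN| distribution normalizes mismatch histograms", {
  g <- genome_model("chr1", 4000)
  neutral <- fill_profile(
    data.frame(case_id = character(0), institution_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               total_cn = integer(0), major_cn = integer(0),
               minor_cn = integer(0)), g)
  # 750 bases off by 1 and 250 off by 2 against a neutral profile
  b <- fill_profile(data.frame(
    case_id = "c", institution_id = "B", chrom = "chr1",
    start = c(0, 750), end = c(750, 1000), total_cn = c(3L, 4L),
    major_cn = NA_integer_, minor_cn = NA_integer_), g)
  cmp <- compare_profiles(neutral, b)
  d <- cn_diff_summary(list(cmp))
  expect_equal(unname(d[c("1", "2")]), c(0.75, 0.25))

  only1 <- fill_profile(data.frame(
    case_id = "c", institution_id = "B", chrom = "chr1",
    start = 0, end = 1000, total_cn = 3L,
    major_cn = NA_integer_, minor_cn = NA_integer_), g)
  expect_equal(unname(cn_diff_summary(
    list(compare_profiles(neutral, only1)))), 1)

  none <- compare_profiles(b, b)
  expect_length(cn_diff_summary(list(none)), 0L)
})

test_that("gene events classify amplifications relative to ploidy", {
  g <- gm1mb
  mk <- function(cn, start = 1000, end = 2000) {
    fill_profile(data.frame(
      case_id = "c", institution_id = "A", chrom = "chr1",
      start = start, end = end, total_cn = cn,
      major_cn = NA_integer_, minor_cn = NA_integer_), g)
  }
  expect_equal(call_gene_event(mk(7L), "G", "chr1", 1200, 1800)$classification,
               "high_amp")
  expect_equal(call_gene_event(mk(1L), "G", "chr1", 1200, 1800)$classification,
               "monoallelic_del")
  expect_equal(call_gene_event(mk(0L), "G", "chr1", 1200, 1800)$classification,
               "deep_del")
  expect_equal(call_gene_event(mk(4L), "G", "chr1", 1200, 1800)$classification,
               "low_amp")
  expect_equal(call_gene_event(mk(7L), "G", "chr1", 5000, 6000)$classification,
               "neutral")
  expect_error(call_gene_event(mk(7L), "G", "chr1", 5000, 2e6),
               "outside the comparable genome")
})

test_that("gene matrix categorizes agreement across institutions", {
  g <- gm1mb
  mk <- function(inst, cn) {
    fill_profile(data.frame(
      case_id = "c", institution_id = inst, chrom = "chr1",
      start = 1000, end = 2000, total_cn = cn,
      major_cn = NA_integer_, minor_cn = NA_integer_), g)
  }
  genes <- data.frame(gene = "G", chrom = "chr1", start = 1200,
                      end = 1800, stringsAsFactors = FALSE)
  insts <- paste0("I", 1:5)

  all8 <- stats::setNames(lapply(insts, function(i) mk(i, 8L)), insts)
  expect_equal(gene_event_matrix(all8, genes)$agreement$category,
               "all_agree")

  cns <- c(7L, 7L, 6L, 4L, 7L)
  mix <- stats::setNames(
    lapply(seq_along(insts), function(i) mk(insts[i], cns[i])), insts)
  expect_equal(gene_event_matrix(mix, genes)$agreement$category,
               "threshold_disagreement")

  cns2 <- c(0L, 0L, 0L, 0L, 1L)
  mix2 <- stats::setNames(
    lapply(seq_along(insts), function(i) mk(insts[i], cns2[i])), insts)
  expect_equal(gene_event_matrix(mix2, genes)$agreement$category,
               "presence_disagreement")
})

test_that("aggregate matched fraction ignores chromosome order", {
  set.seed(101)
  g <- tiny_genome()
  a <- random_profile(g, inst = "A", k = 4)
  b <- random_profile(g, inst = "B", k = 4)
  cmp1 <- compare_profiles(a, b)
  flip <- function(p) {
    p$segments <- p$segments[order(p$segments$chrom,
                                   decreasing = TRUE), ]
    p$genome$included <- rev(p$genome$included)
    p
  }
  cmp2 <- compare_profiles(flip(a), flip(b))
  expect_equal(cmp1$fractions, cmp2$fractions)
})
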