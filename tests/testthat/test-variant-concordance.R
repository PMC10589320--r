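test_that("consensus references include variants by institution support", {
  calls <- make_calls(list(
    A = c(vid(100), vid(200)),
    B = c(vid(100), vid(200)),
    C = vid(100),
    D = vid(300),
    E = character(0)
  ))
  roster <- c("A", "B", "C", "D", "E")
  ref3 <- build_consensus(calls, "case_01", 3, roster = roster)
  ref2 <- build_consensus(calls, "case_01", 2, roster = roster)
  expect_setequal(ref3$variants, vid(100))          # 3 of 5
  expect_setequal(ref2$variants, c(vid(100), vid(200)))
  expect_equal(unname(ref3$support[vid(100)]), 3L)
  expect_error(build_consensus(calls, "case_99", 3), "unknown case")
  expect_error(build_consensus(calls, "case_01", 1), ">= 2")

  # a known case without any call yields a legal empty reference
  ref_empty <- build_consensus(calls, "case_29", 3, roster = roster,
                               known_cases = c("case_01", "case_29"))
  expect_length(ref_empty$variants, 0L)
})

test_that("consensus is monotone in k on random call sets", {
  set.seed(33)
  roster <- paste0("I", 1:5)
  for (rep in 1:50) {
    sets <- lapply(stats::setNames(roster, roster), function(i) {
      vapply(sample(100:120, sample(0:12, 1)), vid, character(1))
    })
    calls <- make_calls(sets)
    if (is.null(calls)) next
    refs <- lapply(2:5, function(k) {
      build_consensus(calls, "case_01", k, roster = roster)$variants
    })
    for (k in 1:3) {
      expect_true(all(refs[[k + 1]] %in% refs[[k]]))
    }
  }
})

test_that("scoring counts TP/FP/FN and leaves 0/0 ratios undefined", {
  calls <- make_calls(list(
    A = c(vid(1), vid(2), vid(4)),
    B = c(vid(1), vid(2), vid(3)),
    C = c(vid(1), vid(2), vid(3))
  ))
  ref <- list(case_id = "case_01", min_support = 2L,
              variants = c(vid(1), vid(2), vid(3)))
  r <- score_against_reference(calls, ref, "A")
  expect_equal(r[, c("tp", "fn", "fp")],
               data.frame(tp = 2L, fn = 1L, fp = 1L))
  expect_equal(r$ppa, 2 / 3)
  expect_equal(r$ppv, 2 / 3)

  # identity: calls equal to the reference
  rB <- score_against_reference(calls, ref, "B")
  expect_equal(rB$ppa, 1)
  expect_equal(rB$ppv, 1)

  # empty reference leaves PPA undefined, not zero
  ref0 <- list(case_id = "case_01", variants = character(0))
  r0 <- score_against_reference(calls, ref0, "A")
  expect_true(is.na(r0$ppa))
  expect_false(is.na(r0$ppv))
  expect_error(score_against_reference(calls, ref, "Z"),
               "not in the roster")
})

test_that("sum rules hold on randomized call sets", {
  set.seed(44)
  roster <- paste0("I", 1:4)
  for (rep in 1:100) {
    sets <- lapply(stats::setNames(roster, roster), function(i) {
      vapply(sample(50:70, sample(1:15, 1)), vid, character(1))
    })
    calls <- make_calls(sets)
    ref <- build_consensus(calls, "case_01", 2, roster = roster)
    inst <- sample(roster, 1)
    r <- score_against_reference(calls, ref, inst)
    expect_equal(r$tp + r$fn, length(ref$variants))
    expect_equal(r$tp + r$fp,
                 length(unique(calls$variant_id[
                   calls$institution_id == inst])))
  }
})

test_that("support histogram counts unique variants per support level", {
  calls <- make_calls(list(A = vid(1), B = vid(1), C = vid(1),
                           D = vid(1), E = vid(1)))
  h <- support_histogram(calls, n_institutions = 5)
  expect_equal(unname(h$counts["5"]), 1L)
  expect_equal(h$total, 1L)

  calls2 <- make_calls(list(A = c(vid(1), vid(2)), B = vid(1)))
  h2 <- support_histogram(calls2, n_institutions = 2)
  expect_equal(unname(h2$counts[c("1", "2")]), c(1L, 1L))
  expect_equal(sum(h2$buckets$count), h2$total)
})

test_that("histogram buckets partition the unique (case, variant) pairs", {
  set.seed(55)
  roster <- paste0("I", 1:5)
  for (rep in 1:40) {
    sets <- lapply(stats::setNames(roster, roster), function(i) {
      vapply(sample(10:40, sample(0:20, 1)), vid, character(1))
    })
    calls <- make_calls(sets)
    if (is.null(calls)) next
    h <- support_histogram(calls, n_institutions = 5)
    u <- unique(calls[, c("case_id", "variant_id")])
    expect_equal(h$total, nrow(u))
    expect_equal(sum(h$buckets$count), h$total)
    expect_equal(sum(h$counts), h$total)
  }
})

test_that("discordance causes follow the documented precedence", {
  ev <- data.frame(
    case_id = "c1", institution_id = "A", variant_id = vid(100),
    variant_class = "SNV", vaf = 0.053, depth = 78L,
    filter_status = "PASS", flags = "", evidence_reads = 4L,
    stringsAsFactors = FALSE
  )
  r <- classify_discordance(vid(100), "c1", "A",
                            "missed_by_institution", evidence = ev)
  expect_equal(r$cause, "low_vaf_or_coverage")

  # detected pre-filter with adequate evidence but removed by a filter
  ev$vaf <- 0.35; ev$depth <- 210L
  ev$filter_status <- "quality_filtered"
  r2 <- classify_discordance(vid(100), "c1", "A",
                             "missed_by_institution", evidence = ev)
  expect_equal(r2$cause, "quality_or_pass_filter")

  # low VAF takes precedence over the filter flag
  ev$vaf <- 0.04
  r3 <- classify_discordance(vid(100), "c1", "A",
                             "missed_by_institution", evidence = ev)
  expect_equal(r3$cause, "low_vaf_or_coverage")

  ev$vaf <- 0.35; ev$filter_status <- "PASS"
  ev$flags <- "annotation_merged"
  expect_equal(classify_discordance(vid(100), "c1", "A",
                                    "missed_by_institution",
                                    evidence = ev)$cause,
               "annotation_merged")

  ev$flags <- "reported_as_SV"
  expect_equal(classify_discordance(vid(100), "c1", "A",
                                    "called_only_by_institution",
                                    evidence = ev)$cause,
               "structural_variant_call")

  ev$flags <- "intronic"
  ev$filter_status <- "other_filtered"
  expect_equal(classify_discordance(vid(100), "c1", "A",
                                    "missed_by_institution",
                                    evidence = ev)$cause,
               "intron_or_polymorphism_filter")

  ev$flags <- ""; ev$filter_status <- "PASS"; ev$evidence_reads <- 0L
  expect_equal(classify_discordance(vid(100), "c1", "A",
                                    "missed_by_institution",
                                    evidence = ev)$cause,
               "no_supporting_reads_or_off_target")

  # no evidence at all
  expect_equal(classify_discordance(vid(100), "c1", "A",
                                    "missed_by_institution")$cause,
               "unexplained")
})

test_that("clopper_pearson matches closed forms and contains k/n", {
  ci <- clopper_pearson(0, 10)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - 0.025^(1 / 10), tolerance = 1e-12)
  ci2 <- clopper_pearson(10, 10)
  expect_equal(ci2[["lower"]], 0.025^(1 / 10), tolerance = 1e-12)
  expect_equal(ci2[["upper"]], 1)

  for (n in c(1, 5, 17, 50)) {
    for (k in 0:n) {
      ci <- clopper_pearson(k, n)
      expect_true(ci[["lower"]] <= k / n + 1e-12)
      expect_true(ci[["upper"]] >= k / n - 1e-12)
    }
  }
  # interval width shrinks with n at fixed k/n
  w10 <- diff(clopper_pearson(5, 10))
  w40 <- diff(clopper_pearson(20, 40))
  expect_lt(w40, w10)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(1, 4, alpha = 0), "alpha")
})

test_that("panel restriction filters genes and subtracts pooled germline", {
  calls <- make_calls(list(A = c(vid(1), vid(2)), B = vid(3)))
  calls$gene <- c("BRCA1", "OFFPANEL", "BRCA1")
  kept <- restrict_to_panel(calls, genes = "BRCA1")
  expect_setequal(kept$variant_id, c(vid(1), vid(3)))

  kept2 <- restrict_to_panel(calls, genes = c("BRCA1", "OFFPANEL"),
                             germline = vid(1))
  expect_setequal(kept2$variant_id, c(vid(2), vid(3)))

  # disjoint germline set leaves the call set unchanged
  kept3 <- restrict_to_panel(calls, genes = c("BRCA1", "OFFPANEL"),
                             germline = vid(999))
  expect_equal(nrow(kept3), nrow(calls))
  expect_error(restrict_to_panel(calls, genes = character(0)),
               "empty gene list")
})

test_that("therapeutic annotation tags and summarizes druggable variants", {
  # 17 druggable variants, 16 called by all five institutions
  roster <- paste0("I", 1:5)
  ids <- vapply(1:17, vid, character(1))
  sets <- lapply(stats::setNames(roster, roster), function(i) ids)
  sets[["I2"]] <- setdiff(ids, vid(17))
  sets[["I3"]] <- setdiff(ids, vid(17))
  sets[["I4"]] <- setdiff(ids, vid(17))
  sets[["I5"]] <- setdiff(ids, vid(17))
  calls <- make_calls(sets)
  ann <- data.frame(gene = "GENE001", alteration = "*", level = 1,
                    treatment = "drugX", stringsAsFactors = FALSE)
  tagged <- annotate_therapeutic(calls, ann)
  expect_true(all(tagged$evidence_level == 1))
  tc <- therapeutic_concordance(tagged, roster = roster)
  expect_equal(sum(tc$summary$full_agreement), 16L)
  expect_equal(nrow(tc$summary), 17L)

  # unlisted gene stays untagged
  calls2 <- calls
  calls2$gene <- "OTHER"
  expect_true(all(is.na(annotate_therapeutic(calls2,
                                             ann)$evidence_level)))
  bad <- data.frame(gene = "G", alteration = "*", level = 7,
                    treatment = "t")
  expect_error(annotate_therapeutic(calls, bad), "levels must be 1-4")
})
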