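# Consensus references, PPA/PPV scoring, detection-support histogram and
# the discordance-cause taxonomy.

.case_calls <- function(calls, case) {
  calls[calls$case_id == case, , drop = FALSE]
}

#' Build a consensus variant reference for one case
#'
#' A variant enters the consensus reference when at least `min_support`
#' distinct institutions called it. With no ground truth available for
#' clinical tissue, such consensus call sets (typically 2x and 3x) serve
#' as surrogate references for agreement scoring.
#'
#' @param calls normalized call table ([read_variant_calls()] output),
#'   possibly covering many cases and institutions.
#' @param case_id case to build the reference for.
#' @param min_support minimum number of distinct supporting institutions
#'   (k >= 2, at most the roster size).
#' @param roster optional character vector of institution ids; defaults to
#'   all institutions present in `calls`.
#' @param known_cases case universe; a case in `known_cases` with no
#'   calls yields a legal empty reference (a case where no institution
#'   detected anything), while a case outside it is an error. Defaults
#'   to the cases present in `calls`.
#' @return Object of class `consensus_reference`: list with `case_id`,
#'   `min_support`, `variants` (character vector of variant ids) and
#'   `support` (named integer vector of support counts, all >= k).
#' @export
build_consensus <- function(calls, case_id, min_support = 3L,
                            roster = NULL, known_cases = NULL) {
  if (is.null(roster)) roster <- unique(calls$institution_id)
  if (is.null(known_cases)) known_cases <- unique(calls$case_id)
  min_support <- as.integer(min_support)
  if (min_support < 2L) stop("min_support must be >= 2")
  if (min_support > length(roster)) {
    stop("min_support exceeds the institution roster size")
  }
  if (!case_id %in% known_cases) {
    stop("unknown case '", case_id, "'")
  }
  cc <- .case_calls(calls, case_id)
  cc <- cc[!duplicated(cc[, c("institution_id", "variant_id")]), ]
  support <- table(cc$variant_id)
  keep <- support[support >= min_support]
  structure(
    list(
      case_id = case_id,
      min_support = min_support,
      variants = names(keep),
      support = stats::setNames(as.integer(keep), names(keep))
    ),
    class = "consensus_reference"
  )
}

#' @export
print.consensus_reference <- function(x, ...) {
  cat("<consensus_reference> case ", x$case_id, ", k = ", x$min_support,
      ": ", length(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Score one institution's call set against a reference
#'
#' Counts exact-key matches: TP = calls also in the reference,
#' FN = reference variants not called, FP = calls outside the reference.
#' PPA = TP/(TP+FN) and PPV = TP/(TP+FP); a ratio with zero denominator
#' (e.g. an empty reference) is reported as `NA`, never coerced to 0.
#'
#' @param calls normalized call table.
#' @param reference a [build_consensus()] object, or any list with
#'   `case_id` and `variants` elements (e.g. an external panel reference).
#' @param institution_id institution to score.
#' @param roster institution roster; an institution on the roster with
#'   no calls scores with an empty call set (TP = FP = 0), while an
#'   institution outside it is an error. Defaults to the institutions
#'   present in `calls`.
#' @return One-row data frame: `case_id`, `institution_id`, `reference`,
#'   `tp`, `fp`, `fn`, `ppa`, `ppv`.
#' @export
score_against_reference <- function(calls, reference, institution_id,
                                    roster = NULL) {
  if (is.null(roster)) roster <- unique(calls$institution_id)
  if (!institution_id %in% roster) {
    stop("institution '", institution_id, "' not in the roster")
  }
  cc <- .case_calls(calls, reference$case_id)
  mine <- unique(cc$variant_id[cc$institution_id == institution_id])
  ref <- reference$variants
  tp <- length(intersect(mine, ref))
  fn <- length(setdiff(ref, mine))
  fp <- length(setdiff(mine, ref))
  label <- if (!is.null(reference$min_support)) {
    paste0("consensus", reference$min_support, "x")
  } else if (!is.null(reference$label)) reference$label else "reference"
  data.frame(
    case_id = reference$case_id,
    institution_id = institution_id,
    reference = label,
    tp = tp, fp = fp, fn = fn,
    ppa = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Per-case, per-institution concordance against consensus references
#'
#' Convenience wrapper running [build_consensus()] and
#' [score_against_reference()] over every case and institution, for one or
#' more consensus thresholds.
#'
#' @param calls normalized call table.
#' @param min_support integer vector of consensus thresholds (default
#'   `c(2, 3)`).
#' @param roster optional institution roster.
#' @return Data frame of [score_against_reference()] rows.
#' @export
concordance_table <- function(calls, min_support = c(2L, 3L),
                              roster = NULL) {
  if (is.null(roster)) roster <- sort(unique(calls$institution_id))
  cases <- sort(unique(calls$case_id))
  out <- list()
  for (k in min_support) {
    for (case in cases) {
      ref <- build_consensus(calls, case, k, roster = roster)
      for (inst in roster) {
        out[[length(out) + 1L]] <-
          score_against_reference(calls, ref, inst, roster = roster)
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate PPA/PPV across cases
#'
#' Pooled aggregation (summing TP/FP/FN over cases, primary) and the
#' per-case mean of defined ratios (secondary). Cases with undefined
#' ratios (empty reference or empty call set) are excluded from the mean.
#'
#' @param results data frame from [concordance_table()].
#' @return Data frame with one row per (institution, reference):
#'   pooled `ppa`/`ppv`, per-case `ppa_mean`/`ppv_mean`, pooled counts.
#' @export
aggregate_concordance <- function(results) {
  key <- interaction(results$institution_id, results$reference, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    tp <- sum(d$tp); fp <- sum(d$fp); fn <- sum(d$fn)
    data.frame(
      institution_id = d$institution_id[1L],
      reference = d$reference[1L],
      tp = tp, fp = fp, fn = fn,
      ppa = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
      ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
      ppa_mean = mean(d$ppa, na.rm = TRUE),
      ppv_mean = mean(d$ppv, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection-support histogram
#'
#' Counts unique (case, variant) pairs by the number of distinct
#' institutions detecting them and summarizes the canonical buckets:
#' detected by all institutions, by two-to-(N-1) institutions, or by a
#' single institution.
#'
#' @param calls normalized call table.
#' @param cases optional subset of case ids.
#' @param n_institutions roster size N; defaults to the number of
#'   institutions present in `calls`.
#' @return Object of class `support_histogram`: list with `counts`
#'   (named integer vector over support 1..N), `total` unique variants,
#'   and `buckets` (data frame with counts and percentages for
#'   all/some/single).
#' @export
support_histogram <- function(calls, cases = NULL, n_institutions = NULL) {
  if (is.null(n_institutions)) {
    n_institutions <- length(unique(calls$institution_id))
  }
  if (n_institutions < 1L) stop("need at least one institution")
  if (!is.null(cases)) calls <- calls[calls$case_id %in% cases, ]
  u <- unique(calls[, c("case_id", "institution_id", "variant_id")])
  support <- table(paste(u$case_id, u$variant_id, sep = "\r"))
  counts <- stats::setNames(integer(n_institutions),
                            as.character(seq_len(n_institutions)))
  tb <- table(factor(as.integer(support),
                     levels = seq_len(n_institutions)))
  counts[] <- as.integer(tb)
  total <- sum(counts)
  bucket_counts <- c(
    all = counts[[as.character(n_institutions)]],
    some = if (n_institutions > 2L) {
      sum(counts[as.character(2:(n_institutions - 1L))])
    } else 0L,
    single = counts[["1"]]
  )
  structure(
    list(
      counts = counts,
      total = total,
      buckets = data.frame(
        bucket = names(bucket_counts),
        count = as.integer(bucket_counts),
        percent = if (total > 0L) 100 * bucket_counts / total
                  else rep(NA_real_, 3L),
        stringsAsFactors = FALSE
      )
    ),
    class = "support_histogram"
  )
}

#' @export
print.support_histogram <- function(x, ...) {
  cat("<support_histogram> ", x$total, " unique variants\n", sep = "")
  print(x$buckets, row.names = FALSE)
  invisible(x)
}

.get_flags <- function(flag_string) {
  if (is.na(flag_string) || !nzchar(flag_string)) character(0)
  else strsplit(flag_string, ";", fixed = TRUE)[[1L]]
}

#' Classify the cause of one discordant detection
#'
#' For a variant missed by an institution (but called by others) or
#' called only by a single institution, assigns exactly one cause from
#' the documented taxonomy, using the discordant institution's evidence
#' record (pre-filter call, VAF, coverage, supporting reads, flags).
#' Causes are tested in a fixed precedence order: low VAF or coverage
#' first, then filter removal, annotation merging, germline
#' mislabeling, structural-variant calling, intron/polymorphism
#' filtering, absence of supporting reads or off-target location, then
#' the remaining flag-driven causes (splice classification, indel
#' representation, promoter region, somatic LOH, homologous region), and
#' `unexplained` when no evidence is available.
#'
#' @param variant_id normalized variant id.
#' @param case_id case id.
#' @param institution_id the discordant institution.
#' @param direction `"missed_by_institution"` or
#'   `"called_only_by_institution"`.
#' @param evidence evidence table with the call-table columns plus
#'   optionally `on_target` (logical); it should contain pre-filter
#'   records for the discordant institution when available.
#' @param calls normalized call table (used for the singleton's own call
#'   record).
#' @param vaf_threshold,cov_threshold thresholds for the low-evidence
#'   cause (defaults 0.10 and 100).
#' @return One-row data frame: `case_id`, `variant_id`,
#'   `institution_id`, `direction`, `cause`.
#' @export
classify_discordance <- function(variant_id, case_id, institution_id,
                                 direction = c("missed_by_institution",
                                               "called_only_by_institution"),
                                 evidence = NULL, calls = NULL,
                                 vaf_threshold = 0.10,
                                 cov_threshold = 100) {
  direction <- match.arg(direction)
  ev <- NULL
  if (!is.null(evidence)) {
    sel <- evidence$case_id == case_id &
      evidence$variant_id == variant_id &
      evidence$institution_id == institution_id
    if (any(sel)) ev <- evidence[which(sel)[1L], , drop = FALSE]
  }
  if (is.null(ev) && direction == "called_only_by_institution" &&
      !is.null(calls)) {
    sel <- calls$case_id == case_id & calls$variant_id == variant_id &
      calls$institution_id == institution_id
    if (any(sel)) ev <- calls[which(sel)[1L], , drop = FALSE]
  }

  cause <- "unexplained"
  if (!is.null(ev)) {
    flags <- .get_flags(ev$flags)
    low <- (!is.na(ev$vaf) && ev$vaf < vaf_threshold) ||
      (!is.na(ev$depth) && ev$depth < cov_threshold)
    no_reads <- (!is.na(ev$evidence_reads) && ev$evidence_reads == 0L) ||
      ("on_target" %in% names(ev) && isFALSE(ev$on_target))
    filtered <- ev$filter_status %in% c("quality_filtered",
                                        "other_filtered")
    cause <-
      if (low) "low_vaf_or_coverage"
      else if (filtered && !any(c("intronic", "polymorphism") %in% flags))
        "quality_or_pass_filter"
      else if ("annotation_merged" %in% flags) "annotation_merged"
      else if ("germline_overlap" %in% flags) {
        if (direction == "missed_by_institution") "germline_mislabel"
        else "germline_missed"
      }
      else if ("reported_as_SV" %in% flags) "structural_variant_call"
      else if (any(c("intronic", "polymorphism") %in% flags))
        "intron_or_polymorphism_filter"
      else if (no_reads) "no_supporting_reads_or_off_target"
      else if ("splice_site" %in% flags) "splice_classification"
      else if ("promoter" %in% flags) "promoter_region"
      else if ("LOH_event" %in% flags) "somatic_LOH"
      else if ("homologous_region" %in% flags) "homologous_region"
      else if (direction == "called_only_by_institution" &&
               !is.na(ev$variant_class) && ev$variant_class != "SNV")
        "indel_representation"
      else "unexplained"
  }
  data.frame(
    case_id = case_id,
    variant_id = variant_id,
    institution_id = institution_id,
    direction = direction,
    cause = cause,
    stringsAsFactors = FALSE
  )
}

#' Classify every discordant detection in a cohort
#'
#' Finds, per case, the variants detected by some but not all
#' institutions. Variants detected by two or more (but not all)
#' institutions yield one `missed_by_institution` record per
#' non-detecting institution; variants detected by a single institution
#' yield one `called_only_by_institution` record.
#'
#' @param calls normalized call table.
#' @param evidence optional evidence table (see [classify_discordance()]).
#' @param roster institution roster; defaults to institutions in `calls`.
#' @inheritParams classify_discordance
#' @return Data frame of discordance records.
#' @export
classify_all_discordances <- function(calls, evidence = NULL,
                                      roster = NULL,
                                      vaf_threshold = 0.10,
                                      cov_threshold = 100) {
  if (is.null(roster)) roster <- sort(unique(calls$institution_id))
  n <- length(roster)
  u <- unique(calls[, c("case_id", "institution_id", "variant_id")])
  out <- list()
  for (case in unique(u$case_id)) {
    uc <- u[u$case_id == case, ]
    detecting <- split(uc$institution_id, uc$variant_id)
    for (vid in names(detecting)) {
      insts <- unique(detecting[[vid]])
      if (length(insts) == n) next
      if (length(insts) == 1L) {
        out[[length(out) + 1L]] <- classify_discordance(
          vid, case, insts, "called_only_by_institution",
          evidence = evidence, calls = calls,
          vaf_threshold = vaf_threshold, cov_threshold = cov_threshold)
      } else {
        for (inst in setdiff(roster, insts)) {
          out[[length(out) + 1L]] <- classify_discordance(
            vid, case, inst, "missed_by_institution",
            evidence = evidence, calls = calls,
            vaf_threshold = vaf_threshold, cov_threshold = cov_threshold)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(case_id = character(0), variant_id = character(0),
                      institution_id = character(0),
                      direction = character(0), cause = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion from Beta
#' distribution quantiles: the lower bound is the `alpha/2` quantile of
#' `Beta(k, n - k + 1)` (0 when `k = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when `k = n`).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param alpha two-sided error rate in (0, 1); default 0.05 for a 95%
#'   interval.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(0, 10)   # upper = 1 - 0.025^(1/10)
#' clopper_pearson(5, 10)
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n) {
    stop("require integers 0 <= k <= n with n >= 1")
  }
  if (!is.numeric(alpha) || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Restrict a call set to a gene panel and subtract germline variants
#'
#' Keeps calls whose gene is on the panel gene list and/or whose position
#' falls inside a target interval (both filters applied when both are
#' given), then removes any call whose normalized variant key appears in
#' the pooled germline set from all institutions. Germline subtraction
#' matches on the variant key only.
#'
#' @param calls normalized call table.
#' @param genes character vector of panel gene symbols (may be `NULL`).
#' @param intervals optional data frame of target intervals with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param germline optional character vector of germline variant ids, or
#'   a call table whose `variant_id` column is used.
#' @return The filtered call table.
#' @export
restrict_to_panel <- function(calls, genes = NULL, intervals = NULL,
                              germline = NULL) {
  if (is.null(genes) && is.null(intervals)) {
    stop("provide a gene list and/or target intervals")
  }
  if (!is.null(genes)) {
    if (!length(genes)) stop("empty gene list")
    calls <- calls[calls$gene %in% genes, , drop = FALSE]
  }
  if (!is.null(intervals)) {
    keep <- vapply(seq_len(nrow(calls)), function(i) {
      any(intervals$chrom == calls$chrom[i] &
            intervals$start < calls$pos[i] &
            calls$pos[i] <= intervals$end)
    }, logical(1))
    calls <- calls[keep, , drop = FALSE]
  }
  if (!is.null(germline)) {
    ids <- if (is.data.frame(germline)) unique(germline$variant_id)
           else unique(as.character(germline))
    calls <- calls[!calls$variant_id %in% ids, , drop = FALSE]
  }
  calls
}

#' Tag calls with therapeutic evidence levels
#'
#' Joins calls against an annotation table of (gene, alteration matcher,
#' evidence level 1-4, treatment). The alteration matcher is a regular
#' expression tested against the variant id, or `"*"`/empty to match any
#' alteration in the gene.
#'
#' @param calls normalized call table.
#' @param annotation data frame with columns `gene`, `alteration`
#'   (regex or `"*"`), `level` (integer 1-4), `treatment`.
#' @return `calls` with added `evidence_level` (integer, `NA` when
#'   untagged) and `treatment` columns.
#' @export
annotate_therapeutic <- function(calls, annotation) {
  req <- c("gene", "alteration", "level", "treatment")
  if (!all(req %in% names(annotation))) {
    stop("annotation table needs columns ", paste(req, collapse = ", "))
  }
  lev <- suppressWarnings(as.integer(annotation$level))
  if (any(is.na(lev)) || any(!lev %in% 1:4)) {
    stop("malformed annotation table: evidence levels must be 1-4")
  }
  annotation$level <- lev
  calls$evidence_level <- NA_integer_
  calls$treatment <- NA_character_
  for (i in seq_len(nrow(annotation))) {
    hit <- calls$gene == annotation$gene[i]
    pat <- annotation$alteration[i]
    if (!is.na(pat) && nzchar(pat) && pat != "*") {
      hit <- hit & grepl(pat, calls$variant_id)
    }
    hit <- hit & is.na(calls$evidence_level)
    calls$evidence_level[hit] <- annotation$level[i]
    calls$treatment[hit] <- annotation$treatment[i]
  }
  calls
}

#' Detection matrix for therapeutically relevant variants
#'
#' For each tagged variant, records which institutions detected it and
#' whether all agreed, mirroring a per-variant concordance matrix of
#' druggable targets.
#'
#' @param tagged output of [annotate_therapeutic()].
#' @param roster institution roster; defaults to institutions present.
#' @return List with `matrix` (variants x institutions logical) and
#'   `summary` data frame (`variant_id`, `case_id`, `gene`, `level`,
#'   `n_detecting`, `full_agreement`).
#' @export
therapeutic_concordance <- function(tagged, roster = NULL) {
  if (is.null(roster)) roster <- sort(unique(tagged$institution_id))
  t2 <- tagged[!is.na(tagged$evidence_level), , drop = FALSE]
  key <- unique(t2[, c("case_id", "variant_id", "gene",
                       "evidence_level")])
  if (nrow(key) == 0L) {
    return(list(matrix = matrix(logical(0), 0, length(roster)),
                summary = data.frame()))
  }
  m <- matrix(FALSE, nrow(key), length(roster),
              dimnames = list(paste(key$case_id, key$variant_id,
                                    sep = "|"), roster))
  for (i in seq_len(nrow(key))) {
    det <- unique(t2$institution_id[t2$case_id == key$case_id[i] &
                                      t2$variant_id == key$variant_id[i]])
    m[i, roster %in% det] <- TRUE
  }
  list(
    matrix = m,
    summary = data.frame(
      case_id = key$case_id,
      variant_id = key$variant_id,
      gene = key$gene,
      level = key$evidence_level,
      n_detecting = rowSums(m),
      full_agreement = rowSums(m) == length(roster),
      stringsAsFactors = FALSE
    )
  )
}
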