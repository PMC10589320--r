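# Base-resolution pairwise copy-number comparison with correction for
# discordant whole-genome-duplication calls, and gene-level event calling.

#' Fill a segmentation to a complete genome tiling
#'
#' Regions without a reported copy-number change are set to the neutral
#' copy number of two (major 1 / minor 1 in allele-specific mode), so
#' that every base of every included chromosome carries a defined CN.
#' Adjacent segments with equal copy number are merged. The result also
#' carries the profile's predominant ploidy.
#'
#' @param segments data frame of segments (0-based half-open; see
#'   [read_cn_segments()]) for one case and institution. May be empty.
#' @param genome a [genome_model()].
#' @param baseline_cn copy number assigned to unreported regions
#'   (default 2).
#' @param allele_specific also fill `major_cn`/`minor_cn` (1/1 baseline).
#' @return Object of class `cn_profile`: list with `case_id`,
#'   `institution_id`, `segments` (complete tiling), `genome`,
#'   `predominant_ploidy`, `purity` (NA unless set by the caller).
#' @export
fill_profile <- function(segments, genome, baseline_cn = 2L,
                         allele_specific = FALSE) {
  stopifnot(inherits(genome, "genome_model"))
  case_id <- if (nrow(segments)) segments$case_id[1L] else NA_character_
  inst_id <- if (nrow(segments)) segments$institution_id[1L]
             else NA_character_
  if (nrow(segments)) {
    if (length(unique(segments$case_id)) > 1L ||
        length(unique(segments$institution_id)) > 1L) {
      stop("fill_profile expects segments of a single (case, institution)")
    }
    unknown <- !segments$chrom %in% genome$chromosomes
    if (any(unknown)) {
      stop("segment chromosome(s) not in genome: ",
           paste(unique(segments$chrom[unknown]), collapse = ", "))
    }
    beyond <- segments$end > genome$lengths[segments$chrom]
    if (any(beyond)) {
      stop("segment(s) extend beyond chromosome length: ",
           paste(segments$chrom[beyond], collapse = ", "))
    }
    .check_segment_overlap(segments)
  }
  tiles <- list()
  for (chrom in genome$included) {
    len <- genome$lengths[[chrom]]
    cs <- segments[segments$chrom == chrom, , drop = FALSE]
    cs <- cs[order(cs$start), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(cs$start, cs$end)), len)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    cn <- rep(as.integer(baseline_cn), length(starts))
    maj <- rep(if (allele_specific) 1L else NA_integer_, length(starts))
    mnr <- maj
    if (nrow(cs)) {
      seg_idx <- seq(2L, by = 2L, length.out = nrow(cs))
      cn[seg_idx] <- cs$total_cn
      if (allele_specific) {
        maj[seg_idx] <- ifelse(is.na(cs$major_cn),
                               ceiling(cs$total_cn / 2), cs$major_cn)
        mnr[seg_idx] <- ifelse(is.na(cs$minor_cn),
                               floor(cs$total_cn / 2), cs$minor_cn)
      }
    }
    keep <- starts < ends
    tiles[[chrom]] <- data.frame(
      chrom = chrom, start = starts[keep], end = ends[keep],
      total_cn = cn[keep], major_cn = maj[keep], minor_cn = mnr[keep],
      stringsAsFactors = FALSE
    )
  }
  tiling <- do.call(rbind, tiles)
  rownames(tiling) <- NULL
  tiling <- .merge_adjacent(tiling)
  prof <- structure(
    list(case_id = case_id, institution_id = inst_id,
         segments = tiling, genome = genome,
         predominant_ploidy = NA_integer_, purity = NA_real_),
    class = "cn_profile"
  )
  prof$predominant_ploidy <- predominant_ploidy(prof)
  prof
}

.merge_adjacent <- function(tiling) {
  if (nrow(tiling) < 2L) return(tiling)
  same <- tiling$chrom[-1L] == tiling$chrom[-nrow(tiling)] &
    tiling$start[-1L] == tiling$end[-nrow(tiling)] &
    tiling$total_cn[-1L] == tiling$total_cn[-nrow(tiling)]
  grp <- cumsum(c(TRUE, !same))
  merged <- lapply(split(seq_len(nrow(tiling)), grp), function(idx) {
    r <- tiling[idx[1L], , drop = FALSE]
    r$end <- tiling$end[idx[length(idx)]]
    r
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("<cn_profile> case ", x$case_id, ", institution ", x$institution_id,
      ": ", nrow(x$segments), " segments, predominant ploidy ",
      x$predominant_ploidy, "\n", sep = "")
  invisible(x)
}

#' Predominant ploidy of a filled profile
#'
#' The copy number covering the largest fraction of the comparable
#' genome; ties are broken toward the lower copy number.
#'
#' @param profile a [fill_profile()] object.
#' @return Integer predominant ploidy.
#' @export
predominant_ploidy <- function(profile) {
  stopifnot(inherits(profile, "cn_profile"))
  seg <- profile$segments
  bp <- tapply(seg$end - seg$start, seg$total_cn, sum)
  cn_vals <- as.integer(names(bp))
  best <- which(bp == max(bp))
  as.integer(min(cn_vals[best]))
}

#' Genome fraction per copy-number state
#'
#' @param profile a [fill_profile()] object.
#' @return Named numeric vector: fraction of the comparable genome at
#'   each observed total CN.
#' @export
cn_state_fractions <- function(profile) {
  seg <- profile$segments
  bp <- tapply(seg$end - seg$start, seg$total_cn, sum)
  bp / sum(bp)
}

#' Compare two copy-number profiles at base resolution
#'
#' Every base of the comparable genome is classified as (1) an exact
#' match of total CN, (2) a discrepancy explained by the difference of
#' the two profiles' predominant ploidies — e.g. one center called a
#' genome duplication the other did not — or (3) an unexplained
#' mismatch, whose absolute CN difference feeds a |dCN| histogram.
#' Implemented over interval intersections (shared breakpoints), which
#' is exactly equivalent to a per-base loop.
#'
#' The default `"ratio"` rule declares a base duplication-explained when
#' `cn_a / ploidy_a == cn_b / ploidy_b`; a profile compared against its
#' exact doubling is then fully explained, matching the canonical
#' genome-duplication scenario. The alternative `"delta"` rule
#' (`cn_a - ploidy_a == cn_b - ploidy_b`) only credits bases whose
#' offset from ploidy agrees, which penalizes altered regions of a
#' doubled genome.
#'
#' @param a,b [fill_profile()] objects on the same genome.
#' @param rule duplication-correction rule, `"ratio"` (default) or
#'   `"delta"`.
#' @return Object of class `cn_comparison`: list with `case_id`, `pair`,
#'   base counts `exact_bp`, `duplication_bp`, `mismatch_bp`, the
#'   corresponding `fractions`, and `diff_histogram` (named base counts
#'   by |dCN| >= 1 over mismatched bases).
#' @export
compare_profiles <- function(a, b, rule = c("ratio", "delta")) {
  rule <- match.arg(rule)
  stopifnot(inherits(a, "cn_profile"), inherits(b, "cn_profile"))
  if (!identical(a$genome$included, b$genome$included) ||
      !identical(a$genome$lengths[a$genome$included],
                 b$genome$lengths[b$genome$included])) {
    stop("profiles are tiled on different genomes")
  }
  pa <- a$predominant_ploidy
  pb <- b$predominant_ploidy
  exact_bp <- 0; dup_bp <- 0; mism_bp <- 0
  hist_env <- new.env(parent = emptyenv())
  for (chrom in a$genome$included) {
    sa <- a$segments[a$segments$chrom == chrom, , drop = FALSE]
    sb <- b$segments[b$segments$chrom == chrom, , drop = FALSE]
    bounds <- sort(unique(c(sa$start, sa$end, sb$start, sb$end)))
    starts <- bounds[-length(bounds)]
    widths <- diff(bounds)
    cn_a <- sa$total_cn[findInterval(starts, sa$start)]
    cn_b <- sb$total_cn[findInterval(starts, sb$start)]
    eq <- cn_a == cn_b
    dup <- !eq & (if (rule == "delta") (cn_a - pa) == (cn_b - pb)
                  else pa > 0 & pb > 0 & cn_a / pa == cn_b / pb)
    mism <- !eq & !dup
    exact_bp <- exact_bp + sum(widths[eq])
    dup_bp <- dup_bp + sum(widths[dup])
    mism_bp <- mism_bp + sum(widths[mism])
    if (any(mism)) {
      d <- abs(cn_a[mism] - cn_b[mism])
      for (dd in unique(d)) {
        key <- as.character(dd)
        prev <- if (is.null(hist_env[[key]])) 0 else hist_env[[key]]
        hist_env[[key]] <- prev + sum(widths[mism][d == dd])
      }
    }
  }
  hk <- ls(hist_env)
  hist <- stats::setNames(vapply(hk, function(k) hist_env[[k]],
                                 numeric(1)), hk)
  hist <- hist[order(as.numeric(names(hist)))]
  total <- exact_bp + dup_bp + mism_bp
  structure(
    list(
      case_id = a$case_id,
      pair = c(a$institution_id, b$institution_id),
      exact_bp = exact_bp,
      duplication_bp = dup_bp,
      mismatch_bp = mism_bp,
      fractions = c(exact = exact_bp / total,
                    duplication = dup_bp / total,
                    mismatch = mism_bp / total),
      diff_histogram = hist
    ),
    class = "cn_comparison"
  )
}

#' @export
print.cn_comparison <- function(x, ...) {
  cat("<cn_comparison> case ", x$case_id, ", ", x$pair[1L], " vs ",
      x$pair[2L], ": exact ", round(100 * x$fractions[["exact"]], 1),
      "%, duplication-explained ",
      round(100 * x$fractions[["duplication"]], 1), "%, mismatch ",
      round(100 * x$fractions[["mismatch"]], 1), "%\n", sep = "")
  invisible(x)
}

#' Pooled |dCN| distribution over mismatched bases
#'
#' Pools the mismatch histograms of many pairwise comparisons and
#' normalizes to fractions (e.g. "off by 1" vs "off by 2" shares of all
#' discordant bases).
#'
#' @param comparisons list of [compare_profiles()] results.
#' @return Named numeric vector of fractions by |dCN|; empty when there
#'   are no mismatched bases.
#' @export
cn_diff_summary <- function(comparisons) {
  if (!length(comparisons)) stop("need at least one comparison")
  pooled <- list()
  for (cmp in comparisons) {
    for (k in names(cmp$diff_histogram)) {
      pooled[[k]] <- (if (is.null(pooled[[k]])) 0 else pooled[[k]]) +
        cmp$diff_histogram[[k]]
    }
  }
  if (!length(pooled)) return(stats::setNames(numeric(0), character(0)))
  v <- unlist(pooled)
  v <- v[order(as.numeric(names(v)))]
  v / sum(v)
}

#' Pairwise CN agreement across a cohort
#'
#' Runs [compare_profiles()] for every institution pair of every case and
#' aggregates matched fractions both pooled over base pairs (primary)
#' and as a mean over pairs (secondary).
#'
#' @param profiles nested list: `profiles[[case_id]][[institution_id]]`
#'   of [fill_profile()] objects.
#' @param rule passed to [compare_profiles()].
#' @return List with `comparisons` (flat list of `cn_comparison`),
#'   `table` (one row per case-pair with fractions), `pooled` (overall
#'   exact/duplication/mismatch fractions weighted by base pairs),
#'   `pair_mean` (unweighted mean of per-pair matched fractions), and
#'   `diff_fractions` from [cn_diff_summary()].
#' @export
cna_concordance <- function(profiles, rule = "ratio") {
  comparisons <- list()
  rows <- list()
  for (case in names(profiles)) {
    insts <- names(profiles[[case]])
    if (length(insts) < 2L) next
    for (i in seq_len(length(insts) - 1L)) {
      for (j in seq(i + 1L, length(insts))) {
        cmp <- compare_profiles(profiles[[case]][[insts[i]]],
                                profiles[[case]][[insts[j]]],
                                rule = rule)
        comparisons[[length(comparisons) + 1L]] <- cmp
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case, inst_a = insts[i], inst_b = insts[j],
          exact = cmp$fractions[["exact"]],
          duplication = cmp$fractions[["duplication"]],
          mismatch = cmp$fractions[["mismatch"]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  tot_exact <- sum(vapply(comparisons, `[[`, numeric(1), "exact_bp"))
  tot_dup <- sum(vapply(comparisons, `[[`, numeric(1), "duplication_bp"))
  tot_mism <- sum(vapply(comparisons, `[[`, numeric(1), "mismatch_bp"))
  tot <- tot_exact + tot_dup + tot_mism
  list(
    comparisons = comparisons,
    table = tab,
    pooled = c(exact = tot_exact / tot, duplication = tot_dup / tot,
               mismatch = tot_mism / tot,
               matched = (tot_exact + tot_dup) / tot),
    pair_mean = if (!is.null(tab)) {
      mean(tab$exact + tab$duplication)
    } else NA_real_,
    diff_fractions = cn_diff_summary(comparisons)
  )
}

#' Call a gene-level copy-number event
#'
#' Representative copy numbers over a gene interval are the minimum CN
#' of overlapping segments for deletion calling and the maximum for
#' amplification calling. Classification: `deep_del` (min CN 0),
#' `monoallelic_del` (min CN 1), `high_amp` (max CN at least 5 above the
#' profile's predominant ploidy), `low_amp` (max CN above ploidy but
#' below the high-level threshold), else `neutral`. Deletion thresholds
#' are absolute (CN 0/1) while amplification is relative to ploidy — a
#' deliberate asymmetry.
#'
#' @param profile a [fill_profile()] object.
#' @param gene gene symbol.
#' @param chrom,start,end gene interval (0-based half-open) within the
#'   genome.
#' @param amp_delta high-level amplification threshold on CN minus
#'   ploidy (default 5).
#' @return One-row data frame: `gene`, `chrom`, `start`, `end`,
#'   `institution_id`, `cn_min`, `cn_max`, `ploidy`, `classification`.
#' @export
call_gene_event <- function(profile, gene, chrom, start, end,
                            amp_delta = 5L) {
  stopifnot(inherits(profile, "cn_profile"))
  if (!chrom %in% profile$genome$included ||
      start < 0 || end > profile$genome$lengths[[chrom]] || start >= end) {
    stop("gene interval outside the comparable genome")
  }
  seg <- profile$segments
  ov <- seg$chrom == chrom & seg$start < end & seg$end > start
  cn <- seg$total_cn[ov]
  cn_min <- min(cn)
  cn_max <- max(cn)
  ploidy <- profile$predominant_ploidy
  classification <-
    if (cn_min == 0L) "deep_del"
    else if (cn_min == 1L) "monoallelic_del"
    else if (cn_max >= ploidy + amp_delta) "high_amp"
    else if (cn_max > ploidy) "low_amp"
    else "neutral"
  data.frame(
    gene = gene, chrom = chrom, start = start, end = end,
    institution_id = profile$institution_id,
    cn_min = cn_min, cn_max = cn_max, ploidy = ploidy,
    classification = classification,
    stringsAsFactors = FALSE
  )
}

#' Gene-level event matrix across institutions
#'
#' Calls [call_gene_event()] for every gene and institution of one case
#' and categorizes per-gene agreement: `all_agree` when all institutions
#' report the same class; `threshold_disagreement` when they disagree
#' only between high- and low-level amplification; `presence_disagreement`
#' for any other mixture (including deep vs monoallelic deletion, or
#' event vs neutral).
#'
#' @param profiles named list of [fill_profile()] objects (one per
#'   institution) for a single case.
#' @param genes data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param amp_delta passed to [call_gene_event()].
#' @return List with `calls` (long data frame), `matrix` (gene x
#'   institution classification matrix) and `agreement` (per-gene
#'   category data frame).
#' @export
gene_event_matrix <- function(profiles, genes, amp_delta = 5L) {
  insts <- names(profiles)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (inst in insts) {
      rows[[length(rows) + 1L]] <- call_gene_event(
        profiles[[inst]], genes$gene[i], genes$chrom[i],
        genes$start[i], genes$end[i], amp_delta = amp_delta)
    }
  }
  calls <- do.call(rbind, rows)
  m <- matrix(NA_character_, nrow(genes), length(insts),
              dimnames = list(genes$gene, insts))
  for (r in seq_len(nrow(calls))) {
    m[calls$gene[r], calls$institution_id[r]] <- calls$classification[r]
  }
  agreement <- data.frame(
    gene = genes$gene,
    category = apply(m, 1L, function(cl) {
      u <- unique(cl)
      if (length(u) == 1L) "all_agree"
      else if (all(u %in% c("high_amp", "low_amp")))
        "threshold_disagreement"
      else "presence_disagreement"
    }),
    stringsAsFactors = FALSE
  )
  list(calls = calls, matrix = m, agreement = agreement)
}
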