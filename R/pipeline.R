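# Orchestration: run every analysis stage over a cohort directory and
# emit the summary artifacts. The pipeline is a thin layer — every
# number it writes is recomputable by calling the module functions
# directly.

#' Run the full concordance pipeline over a cohort directory
#'
#' Reads the cohort files (`variants.tsv`, optional `evidence.tsv`,
#' `segments.tsv`, `biomarkers.tsv`, optional `replicates.tsv`), runs
#' the variant-, copy-number-, biomarker- and variance-decomposition
#' stages, and writes each stage's tables plus a markdown summary to
#' `out_dir`. A stage whose inputs are missing or that fails is skipped
#' with a warning; the other stages are still emitted. Deterministic
#' given identical inputs and configuration.
#'
#' @param cohort_dir directory containing the cohort files.
#' @param out_dir output directory (created if needed).
#' @param genome [genome_model()] on which CN profiles are tiled
#'   (default [toy_genome()]).
#' @param consensus_k consensus thresholds (default `c(2, 3)`).
#' @param vaf_threshold,cov_threshold discordance-cause thresholds.
#' @param hrd_cutoff,tmb_cutoff,msi_cutoff biomarker positivity cutoffs;
#'   `msi_cutoff` may be a named per-institution vector with a
#'   `default` entry.
#' @param gene_panel optional data frame (`gene`, `chrom`, `start`,
#'   `end`) for gene-level CN events; defaults to
#'   [toy_gene_panel()] on `genome`.
#' @param dup_rule duplication-correction rule for [compare_profiles()].
#' @return Invisibly, the results bundle (list per stage).
#' @export
run_pipeline <- function(cohort_dir, out_dir,
                         genome = toy_genome(),
                         consensus_k = c(2L, 3L),
                         vaf_threshold = 0.10, cov_threshold = 100,
                         hrd_cutoff = 42, tmb_cutoff = 10,
                         msi_cutoff = c(default = 10),
                         gene_panel = NULL,
                         dup_rule = "ratio") {
  if (!dir.exists(cohort_dir)) stop("cohort directory not found")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list()

  path <- function(f) file.path(cohort_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }

  ## ---- variants ----
  bundle$variants <- stage("variants", {
    if (!file.exists(path("variants.tsv"))) stop("no variants.tsv")
    calls <- read_variant_calls(path("variants.tsv"))
    evidence <- if (file.exists(path("evidence.tsv"))) {
      read_variant_calls(path("evidence.tsv"))
    } else NULL
    roster <- sort(unique(calls$institution_id))
    empty_conc <- data.frame(
      case_id = character(0), institution_id = character(0),
      reference = character(0), tp = integer(0), fp = integer(0),
      fn = integer(0), ppa = numeric(0), ppv = numeric(0),
      stringsAsFactors = FALSE)
    conc <- if (nrow(calls)) {
      concordance_table(calls, min_support = consensus_k,
                        roster = roster)
    } else empty_conc
    agg <- if (nrow(conc)) aggregate_concordance(conc) else empty_conc
    hist <- support_histogram(calls,
                              n_institutions = max(1L, length(roster)))
    disc <- classify_all_discordances(calls, evidence, roster = roster,
                                      vaf_threshold = vaf_threshold,
                                      cov_threshold = cov_threshold)
    utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(agg,
                       file.path(out_dir, "concordance_aggregate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(disc, file.path(out_dir, "discordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hist_df <- data.frame(support = names(hist$counts),
                          count = as.integer(hist$counts))
    utils::write.table(hist_df,
                       file.path(out_dir, "support_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cis <- lapply(seq_len(nrow(hist$buckets)), function(i) {
      clopper_pearson(hist$buckets$count[i], max(1L, hist$total))
    })
    summary_json <- list(
      n_unique_variants = hist$total,
      buckets = cbind(hist$buckets,
                      ci_lower = 100 * vapply(cis, `[[`, 0, "lower"),
                      ci_upper = 100 * vapply(cis, `[[`, 0, "upper")),
      cause_counts = as.list(table(disc$cause))
    )
    jsonlite::write_json(summary_json,
                         file.path(out_dir, "variants_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(calls = calls, evidence = evidence, concordance = conc,
         aggregate = agg, histogram = hist, discordance = disc)
  })

  ## ---- cna ----
  bundle$cna <- stage("cna", {
    if (!file.exists(path("segments.tsv"))) stop("no segments.tsv")
    segs <- read_cn_segments(path("segments.tsv"))
    profiles <- list()
    for (case in unique(segs$case_id)) {
      profiles[[case]] <- list()
      cs <- segs[segs$case_id == case, ]
      for (inst in unique(cs$institution_id)) {
        profiles[[case]][[inst]] <-
          fill_profile(cs[cs$institution_id == inst, ], genome)
      }
    }
    res <- cna_concordance(profiles, rule = dup_rule)
    utils::write.table(res$table,
                       file.path(out_dir, "cn_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(pooled = as.list(res$pooled),
           pair_mean = res$pair_mean,
           diff_fractions = as.list(res$diff_fractions)),
      file.path(out_dir, "cn_summary.json"),
      auto_unbox = TRUE, digits = NA)
    if (is.null(gene_panel)) gene_panel <- toy_gene_panel(genome)
    gene_rows <- list()
    for (case in names(profiles)) {
      if (length(profiles[[case]]) < 2L) next
      gm <- gene_event_matrix(profiles[[case]], gene_panel)
      nonneutral <- gm$agreement$gene[
        apply(gm$matrix, 1L, function(r) any(r != "neutral"))]
      if (length(nonneutral)) {
        sub <- gm$agreement[gm$agreement$gene %in% nonneutral, ]
        sub$case_id <- case
        gene_rows[[length(gene_rows) + 1L]] <- sub
      }
    }
    gene_agreement <- if (length(gene_rows)) {
      do.call(rbind, gene_rows)
    } else {
      data.frame(gene = character(0), category = character(0),
                 case_id = character(0), stringsAsFactors = FALSE)
    }
    utils::write.table(gene_agreement,
                       file.path(out_dir, "gene_cn_agreement.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(profiles = profiles, concordance = res,
         gene_agreement = gene_agreement)
  })

  ## ---- biomarkers ----
  bundle$biomarkers <- stage("biomarkers", {
    if (!file.exists(path("biomarkers.tsv"))) stop("no biomarkers.tsv")
    bm <- read_biomarker_table(path("biomarkers.tsv"))
    out <- list(records = bm)
    cutoffs <- list(hrd_sum = hrd_cutoff, tmb = tmb_cutoff,
                    msi = msi_cutoff)
    for (score in c("hrd_sum", "tmb", "msi", "purity", "ploidy")) {
      m <- score_matrix(bm, score)
      pw <- suppressWarnings(biomarker_pairwise(m))
      utils::write.table(
        pw, file.path(out_dir, paste0("biomarker_", score, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      st <- if (score %in% names(cutoffs)) {
        classify_status(m, cutoffs[[score]])
      } else NULL
      if (!is.null(st)) {
        utils::write.table(
          st$summary,
          file.path(out_dir, paste0("status_", score, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out[[score]] <- list(matrix = m, pairwise = pw, status = st)
    }
    out
  })

  ## ---- variance decomposition ----
  bundle$variance <- stage("variance", {
    if (!file.exists(path("replicates.tsv"))) stop("no replicates.tsv")
    rep_df <- utils::read.delim(path("replicates.tsv"),
                                stringsAsFactors = FALSE)
    out <- list()
    for (bmk in unique(rep_df$biomarker)) {
      sub <- rep_df[rep_df$biomarker == bmk, ]
      mats <- lapply(split(sub, sub$axis), function(d) {
        replicate_matrix(d, axis = d$axis[1L])
      })
      if (!all(c("bioinformatic_pipelines", "sequencing_labs") %in%
               names(mats))) next
      dec <- compare_sources(mats$bioinformatic_pipelines,
                             mats$sequencing_labs)
      out[[bmk]] <- dec
      utils::write.table(
        data.frame(sample_id = names(dec$sd_wetlab),
                   sd_wetlab = dec$sd_wetlab,
                   sd_bioinf = dec$sd_bioinf),
        file.path(out_dir, paste0("variance_", bmk, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })

  emit_report(bundle, file.path(out_dir, "summary.md"))
  invisible(bundle)
}

#' Write the cohort summary document
#'
#' Renders a markdown summary of every computed stage: support-bucket
#' percentages with exact binomial confidence intervals, pooled PPA/PPV
#' per institution and reference, copy-number match fractions and the
#' |dCN| distribution, biomarker correlation/deviation ranges and
#' status agreement, and variance-decomposition medians.
#'
#' @param bundle results bundle from [run_pipeline()].
#' @param path output markdown file.
#' @return Invisibly, `path`.
#' @export
emit_report <- function(bundle, path) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  add("# Multi-institution WES concordance summary")
  add("")

  v <- bundle$variants
  add("## Somatic variant concordance")
  if (is.null(v)) {
    add("_Stage not computed._")
  } else if (v$histogram$total == 0L) {
    add("No variants detected in the cohort.")
  } else {
    h <- v$histogram
    for (i in seq_len(nrow(h$buckets))) {
      ci <- clopper_pearson(h$buckets$count[i], h$total)
      add("- Detected by ", h$buckets$bucket[i], " institutions: ",
          h$buckets$count[i], "/", h$total, " (",
          sprintf("%.1f%%", h$buckets$percent[i]), ", 95% CI ",
          pct(ci[["lower"]]), "-", pct(ci[["upper"]]), ")")
    }
    add("")
    add("Pooled agreement vs consensus references:")
    add("")
    add("| institution | reference | PPA | PPV |")
    add("|---|---|---|---|")
    a <- v$aggregate
    for (i in seq_len(nrow(a))) {
      add("| ", a$institution_id[i], " | ", a$reference[i], " | ",
          ifelse(is.na(a$ppa[i]), "n/a", pct(a$ppa[i])), " | ",
          ifelse(is.na(a$ppv[i]), "n/a", pct(a$ppv[i])), " |")
    }
    if (nrow(v$discordance)) {
      add("")
      add("Discordance causes: ",
          paste(sprintf("%s: %d", names(table(v$discordance$cause)),
                        as.integer(table(v$discordance$cause))),
                collapse = ", "))
    }
  }
  add("")

  add("## Copy-number concordance")
  cna <- bundle$cna
  if (is.null(cna)) {
    add("_Stage not computed._")
  } else {
    p <- cna$concordance$pooled
    add("- Exact CN match: ", pct(p[["exact"]]),
        "; duplication-explained: ", pct(p[["duplication"]]),
        "; mismatch: ", pct(p[["mismatch"]]),
        " (base-pair weighted over all pairs)")
    add("- Matched overall: ", pct(p[["matched"]]),
        " (per-pair mean ", pct(cna$concordance$pair_mean), ")")
    df <- cna$concordance$diff_fractions
    if (length(df)) {
      add("- |dCN| over mismatched bases: ",
          paste(sprintf("%s: %s", names(df), pct(df)), collapse = ", "))
    }
  }
  add("")

  add("## Complex biomarkers")
  b <- bundle$biomarkers
  if (is.null(b)) {
    add("_Stage not computed._")
  } else {
    for (score in c("hrd_sum", "tmb", "msi")) {
      pw <- b[[score]]$pairwise
      r <- pw$pearson_r[!is.na(pw$pearson_r)]
      dev <- pw$deviation_pct[!is.na(pw$deviation_pct)]
      st <- b[[score]]$status
      cat_tab <- table(st$summary$category)
      add("- ", toupper(sub("_sum", "", score)), ": Pearson r ",
          sprintf("%.2f-%.2f", min(r), max(r)),
          "; systematic deviation ",
          sprintf("%+.1f%% to %+.1f%%", min(dev), max(dev)),
          "; status ",
          paste(sprintf("%s: %d", names(cat_tab), as.integer(cat_tab)),
                collapse = ", "))
    }
  }
  add("")

  add("## Wet-lab vs bioinformatic variability")
  vv <- bundle$variance
  if (is.null(vv) || !length(vv)) {
    add("_Stage not computed._")
  } else {
    for (bmk in names(vv)) {
      d <- vv[[bmk]]
      add("- ", bmk, ": median SD wet-lab ",
          signif(d$median_wetlab, 3), " vs bioinformatic ",
          signif(d$median_bioinf, 3), " (one-sided Wilcoxon p = ",
          signif(d$wilcoxon_p, 3), ")")
    }
  }
  writeLines(ln, path)
  invisible(path)
}
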