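# Synthetic multi-institution cohort generator. Every downstream stage
# can be validated against the generative parameters: detection
# probabilities, filter-miss channels, CN noise kernels, WGD
# misclassification, and multiplicative biomarker biases are all ground
# truth here.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.fnv1a <- function(s) {
  # 32-bit FNV-1a over UTF-8 bytes, done in double arithmetic.
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2147483629)
}

.sub_seed <- function(master, case_idx, inst_id, channel) {
  code <- .fnv1a(paste(inst_id, channel, sep = "|"))
  as.integer((as.numeric(master) * 48271 + case_idx * 69621 + code) %%
               2147483629)
}

#' Institution observation-model parameters
#'
#' Parameterizes how one institution's wet lab and pipeline distort the
#' truth: two-regime variant detection (confident calls with VAF and
#' coverage above thresholds vs low-evidence calls), filter and
#' annotation-merge removal channels, a per-case false-positive rate
#' with a low-VAF spectrum, negative-binomial coverage, copy-number
#' noise and whole-genome-duplication misclassification, purity
#' estimation noise, and multiplicative biomarker biases.
#'
#' @param institution_id identifier.
#' @param p_detect_confident detection probability for variants with
#'   VAF >= `vaf_threshold` and depth >= `cov_threshold`.
#' @param p_detect_low detection probability below either threshold.
#' @param vaf_threshold,cov_threshold the confident-call thresholds
#'   (defaults 0.10 and 100).
#' @param filter_miss_prob probability a confidently detected variant is
#'   removed by a quality/other filter (kept in evidence).
#' @param annotation_merge_prob probability a confidently detected
#'   variant is merged into another alteration's annotation.
#' @param fp_rate mean false-positive calls per case (Poisson).
#' @param mean_coverage,coverage_dispersion negative-binomial coverage
#'   model (mu / size).
#' @param cn_noise_prob baseline probability of a +-1 copy-number error
#'   per segment at purity 0.7 (scaled inversely with purity).
#' @param wgd_misclass_prob probability the institution calls a genome
#'   duplication that is not in the truth (doubling its whole profile).
#' @param breakpoint_jitter maximal absolute shift (bp) applied to
#'   interior segment boundaries.
#' @param purity_noise_sd SD of Gaussian noise on the purity estimate.
#' @param bias named multiplicative biases for `hrd_sum`, `tmb`, `msi`.
#' @param noise_sd named Gaussian noise SDs for the same scores.
#' @param msi_cutoff the institution's MSI positivity cutoff (%).
#' @return List of class `institution_profile`.
#' @export
institution_profile <- function(institution_id,
                                p_detect_confident = 0.97,
                                p_detect_low = 0.40,
                                vaf_threshold = 0.10,
                                cov_threshold = 100,
                                filter_miss_prob = 0.02,
                                annotation_merge_prob = 0.01,
                                fp_rate = 1.5,
                                mean_coverage = 200,
                                coverage_dispersion = 12,
                                cn_noise_prob = 0.13,
                                wgd_misclass_prob = 0.05,
                                breakpoint_jitter = 5000,
                                purity_noise_sd = 0.03,
                                bias = c(hrd_sum = 1, tmb = 1, msi = 1),
                                noise_sd = c(hrd_sum = 1.5, tmb = 0.6,
                                             msi = 0.05),
                                msi_cutoff = 10) {
  probs <- c(p_detect_confident, p_detect_low, filter_miss_prob,
             annotation_merge_prob, wgd_misclass_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (any(bias <= 0)) stop("biomarker biases must be positive")
  if (any(noise_sd < 0)) stop("noise SDs must be non-negative")
  structure(
    list(
      institution_id = institution_id,
      p_detect_confident = p_detect_confident,
      p_detect_low = p_detect_low,
      vaf_threshold = vaf_threshold,
      cov_threshold = cov_threshold,
      filter_miss_prob = filter_miss_prob,
      annotation_merge_prob = annotation_merge_prob,
      fp_rate = fp_rate,
      mean_coverage = mean_coverage,
      coverage_dispersion = coverage_dispersion,
      cn_noise_prob = cn_noise_prob,
      wgd_misclass_prob = wgd_misclass_prob,
      breakpoint_jitter = breakpoint_jitter,
      purity_noise_sd = purity_noise_sd,
      bias = bias,
      noise_sd = noise_sd,
      msi_cutoff = msi_cutoff
    ),
    class = "institution_profile"
  )
}

#' Default five-institution roster
#'
#' Five centers with mean coverages spanning the wide range seen across
#' exome protocols, HRD biases spanning roughly -15% to +9%, near-unity
#' TMB biases, and one center using a 40% MSI cutoff (different MSI
#' tool) while the others use 10%.
#'
#' @return Named list of [institution_profile()] objects.
#' @export
default_institutions <- function() {
  list(
    `ZPM-1` = institution_profile(
      "ZPM-1", mean_coverage = 180,
      bias = c(hrd_sum = 1.00, tmb = 1.00, msi = 1.00),
      noise_sd = c(hrd_sum = 1.5, tmb = 0.6, msi = 0.7),
      msi_cutoff = 40),
    `ZPM-2` = institution_profile(
      "ZPM-2", mean_coverage = 320,
      bias = c(hrd_sum = 0.95, tmb = 0.99, msi = 0.95)),
    `ZPM-3` = institution_profile(
      "ZPM-3", mean_coverage = 150,
      bias = c(hrd_sum = 1.04, tmb = 1.02, msi = 1.04),
      noise_sd = c(hrd_sum = 6, tmb = 0.6, msi = 0.05)),
    `ZPM-4` = institution_profile(
      "ZPM-4", mean_coverage = 250,
      bias = c(hrd_sum = 0.89, tmb = 0.97, msi = 0.98)),
    `ZPM-5` = institution_profile(
      "ZPM-5", mean_coverage = 220,
      bias = c(hrd_sum = 0.97, tmb = 1.03, msi = 1.02))
  )
}

#' Cohort-level simulation parameters
#'
#' Defaults emulate a 30-case, five-institution comparison: roughly 32
#' true somatic variants per case (Poisson) with a clonal/subclonal
#' Beta-mixture VAF distribution, about eight non-neutral copy-number
#' segments per case with occasional true genome duplication,
#' histology-style purity between 0.46 and 0.90 (about twelve altered
#' segments per case on the toy genome), and independent truth
#' distributions for the HRD sum (Gamma, mean 30), TMB (log-normal,
#' median 5 mut/MB) and MSI (Gamma, mean ~3%, i.e. a microsatellite-
#' stable cohort).
#'
#' @param seed master seed (mandatory; all case/institution/channel
#'   streams derive sub-seeds from it).
#' @param n_cases number of cases (default 30).
#' @param institutions named list of [institution_profile()]s.
#' @param genome a [genome_model()] (default [toy_genome()]).
#' @param variants_per_case Poisson mean of true variants per case.
#' @param clonal_fraction mixture weight of the clonal VAF component.
#' @param vaf_clonal,vaf_subclonal Beta shape pairs for the two VAF
#'   components.
#' @param indel_fraction fraction of true variants that are indels.
#' @param cn_segments_mean Poisson mean of non-neutral CN segments.
#' @param cn_levels,cn_level_probs support and probabilities of altered
#'   total copy numbers.
#' @param wgd_prob probability a case's truth carries a genome
#'   duplication.
#' @param purity_range uniform range of true tumor purity.
#' @param hrd_shape,hrd_scale Gamma parameters of the true HRD sum.
#' @param tmb_meanlog,tmb_sdlog log-normal parameters of true TMB.
#' @param msi_shape,msi_scale Gamma parameters of the true MSI score (%).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_cases = 30L,
                              institutions = default_institutions(),
                              genome = toy_genome(),
                              variants_per_case = 32,
                              clonal_fraction = 0.8,
                              vaf_clonal = c(7, 13),
                              vaf_subclonal = c(2, 30),
                              indel_fraction = 0.15,
                              cn_segments_mean = 12,
                              cn_levels = c(0L, 1L, 3L, 4L, 5L, 6L, 7L),
                              cn_level_probs = c(0.04, 0.16, 0.38, 0.20,
                                                 0.10, 0.06, 0.06),
                              wgd_prob = 0.15,
                              purity_range = c(0.46, 0.90),
                              hrd_shape = 2, hrd_scale = 15,
                              tmb_meanlog = log(5), tmb_sdlog = 0.8,
                              msi_shape = 1.5, msi_scale = 2) {
  if (missing(seed)) stop("a master seed is mandatory")
  stopifnot(inherits(genome, "genome_model"),
            length(cn_levels) == length(cn_level_probs),
            abs(sum(cn_level_probs) - 1) < 1e-9)
  structure(
    list(seed = as.integer(seed), n_cases = as.integer(n_cases),
         institutions = institutions, genome = genome,
         variants_per_case = variants_per_case,
         clonal_fraction = clonal_fraction,
         vaf_clonal = vaf_clonal, vaf_subclonal = vaf_subclonal,
         indel_fraction = indel_fraction,
         cn_segments_mean = cn_segments_mean,
         cn_levels = cn_levels, cn_level_probs = cn_level_probs,
         wgd_prob = wgd_prob, purity_range = purity_range,
         hrd_shape = hrd_shape, hrd_scale = hrd_scale,
         tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
         msi_shape = msi_shape, msi_scale = msi_scale),
    class = "simulation_config"
  )
}

#' Toy gene panel on a genome
#'
#' Tiles each included chromosome with evenly spaced 20 kb "genes"; used
#' to give simulated variants gene symbols and gene-level CN intervals.
#'
#' @param genome a [genome_model()].
#' @param genes_per_chrom genes placed on each included chromosome.
#' @return Data frame with `gene`, `chrom`, `start`, `end`.
#' @export
toy_gene_panel <- function(genome, genes_per_chrom = 12L) {
  rows <- list()
  g <- 0L
  for (chrom in genome$included) {
    len <- genome$lengths[[chrom]]
    step <- floor(len / genes_per_chrom)
    for (i in seq_len(genes_per_chrom)) {
      g <- g + 1L
      start <- (i - 1L) * step
      rows[[g]] <- data.frame(
        gene = sprintf("GENE%03d", g), chrom = chrom,
        start = start, end = min(start + 20000, len),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the ground truth of one case
#'
#' Draws the true somatic variants (position, alleles, VAF), the true
#' copy-number profile (with possible genome duplication), the true
#' biomarker values and the true tumor purity for one case, reproducibly
#' from the master seed.
#'
#' @param config a [simulation_config()].
#' @param case_idx case index in `1..n_cases`.
#' @return List of class `case_truth` with `case_id`, `variants` (data
#'   frame), `cn_segments` (non-neutral segments data frame), `wgd`
#'   (logical), `purity`, `biomarkers` (named list hrd_sum/tmb/msi) and
#'   `profile` (the filled truth [fill_profile()] object).
#' @export
simulate_truth <- function(config, case_idx) {
  stopifnot(inherits(config, "simulation_config"))
  case_id <- sprintf("case_%02d", case_idx)
  genome <- config$genome
  panel <- toy_gene_panel(genome)
  .with_seed(.sub_seed(config$seed, case_idx, "truth", "case"), {
    purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
    n_var <- stats::rpois(1, config$variants_per_case)
    variants <- NULL
    if (n_var > 0) {
      gi <- sample(nrow(panel), n_var, replace = TRUE)
      pos <- panel$start[gi] +
        sample.int(20000, n_var, replace = TRUE)
      keep <- !duplicated(paste(panel$chrom[gi], pos))
      gi <- gi[keep]; pos <- pos[keep]; n_var <- length(gi)
      clonal <- stats::runif(n_var) < config$clonal_fraction
      vaf <- ifelse(
        clonal,
        stats::rbeta(n_var, config$vaf_clonal[1], config$vaf_clonal[2]),
        stats::rbeta(n_var, config$vaf_subclonal[1],
                     config$vaf_subclonal[2]))
      is_indel <- stats::runif(n_var) < config$indel_fraction
      ref <- character(n_var); alt <- character(n_var)
      for (i in seq_len(n_var)) {
        if (!is_indel[i]) {
          ref[i] <- .random_bases(1)
          alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
        } else if (stats::runif(1) < 0.5) {   # insertion
          ref[i] <- .random_bases(1)
          alt[i] <- paste0(ref[i], .random_bases(sample(1:3, 1)))
        } else {                              # deletion
          alt[i] <- .random_bases(1)
          ref[i] <- paste0(alt[i], .random_bases(sample(1:3, 1)))
        }
      }
      variants <- data.frame(
        case_id = case_id, chrom = panel$chrom[gi], pos = pos,
        ref = ref, alt = alt, vaf = round(vaf, 4),
        gene = panel$gene[gi], stringsAsFactors = FALSE
      )
      variants <- normalize_calls(variants)
    } else {
      variants <- data.frame(
        case_id = character(0), chrom = character(0), pos = integer(0),
        ref = character(0), alt = character(0), vaf = numeric(0),
        gene = character(0), variant_class = character(0),
        variant_id = character(0), stringsAsFactors = FALSE
      )
    }

    # Non-neutral CN segments, non-overlapping by construction.
    n_seg <- stats::rpois(1, config$cn_segments_mean)
    segs <- list()
    for (i in seq_len(n_seg)) {
      chrom <- sample(genome$included, 1,
                      prob = genome$lengths[genome$included])
      len <- genome$lengths[[chrom]]
      width <- min(len, round(stats::rexp(1, 1 / 5e5)) + 5e4)
      start <- sample.int(max(1L, len - width), 1) - 1L
      cn <- sample(config$cn_levels, 1, prob = config$cn_level_probs)
      segs[[i]] <- data.frame(
        case_id = case_id, institution_id = "truth", chrom = chrom,
        start = start, end = start + width, total_cn = cn,
        major_cn = NA_integer_, minor_cn = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
    cn_segments <- if (length(segs)) do.call(rbind, segs) else
      data.frame(case_id = character(0), institution_id = character(0),
                 chrom = character(0), start = numeric(0),
                 end = numeric(0), total_cn = integer(0),
                 major_cn = integer(0), minor_cn = integer(0),
                 stringsAsFactors = FALSE)
    if (nrow(cn_segments)) {
      cn_segments <- cn_segments[order(cn_segments$chrom,
                                       cn_segments$start), ]
      drop <- logical(nrow(cn_segments))
      for (ch in unique(cn_segments$chrom)) {
        idx <- which(cn_segments$chrom == ch)
        if (length(idx) > 1L) {
          last_end <- cn_segments$end[idx[1L]]
          for (k in idx[-1L]) {
            if (cn_segments$start[k] < last_end) drop[k] <- TRUE
            else last_end <- cn_segments$end[k]
          }
        }
      }
      cn_segments <- cn_segments[!drop, , drop = FALSE]
      rownames(cn_segments) <- NULL
    }
    wgd <- stats::runif(1) < config$wgd_prob
    profile <- fill_profile(cn_segments, genome)
    if (wgd) {
      profile$segments$total_cn <- 2L * profile$segments$total_cn
      profile$predominant_ploidy <- predominant_ploidy(profile)
      cn_segments <- profile$segments
      cn_segments$case_id <- case_id
      cn_segments$institution_id <- "truth"
      cn_segments$major_cn <- NA_integer_
      cn_segments$minor_cn <- NA_integer_
      cn_segments <- cn_segments[cn_segments$total_cn != 2L, , drop = FALSE]
    }
    profile$case_id <- case_id
    profile$institution_id <- "truth"
    profile$purity <- purity

    biomarkers <- list(
      hrd_sum = stats::rgamma(1, config$hrd_shape,
                              scale = config$hrd_scale),
      tmb = stats::rlnorm(1, config$tmb_meanlog, config$tmb_sdlog),
      msi = min(100, stats::rgamma(1, config$msi_shape,
                                   scale = config$msi_scale))
    )
    structure(
      list(case_id = case_id, variants = variants,
           cn_segments = cn_segments, wgd = wgd, purity = purity,
           biomarkers = biomarkers, profile = profile),
      class = "case_truth"
    )
  })
}

#' Simulate one institution's variant call set
#'
#' Applies the institution's observation model to a case truth: coverage
#' is drawn per variant from a negative binomial, detection follows the
#' two-regime probability (confident vs low-evidence), confidently
#' detected variants may be removed by a filter or merged into another
#' alteration's annotation, and false positives are added from a
#' low-VAF spectrum. Every miss and removal keeps an evidence record
#' with its generative mechanism label, so cause classification can be
#' validated against ground truth.
#'
#' @param truth a [simulate_truth()] object.
#' @param profile an [institution_profile()].
#' @param master_seed master seed (institution sub-streams derive from
#'   it; defaults are independent across institutions and channels).
#' @param case_idx case index used in the sub-seed.
#' @return List with `calls` (call table rows actually reported),
#'   `evidence` (pre-filter records for misses/removals, with
#'   `on_target` column) and `labels` (data frame `variant_id`,
#'   `mechanism` for every true variant not reported, plus
#'   `false_positive` rows for added calls).
#' @export
simulate_institution_callset <- function(truth, profile, master_seed,
                                         case_idx) {
  .with_seed(.sub_seed(master_seed, case_idx, profile$institution_id,
                       "calls"), {
    tv <- truth$variants
    n <- nrow(tv)
    calls <- list(); evidence <- list(); labels <- list()
    add_row <- function(lst, row) { lst[[length(lst) + 1L]] <- row; lst }
    if (n > 0) {
      depth <- stats::rnbinom(n, mu = profile$mean_coverage,
                              size = profile$coverage_dispersion) + 1L
      vaf_obs <- round(pmin(1, pmax(0.001, tv$vaf +
                                      stats::rnorm(n, 0, 0.01))), 4)
      confident <- vaf_obs >= profile$vaf_threshold &
        depth >= profile$cov_threshold
      detected <- stats::runif(n) <
        ifelse(confident, profile$p_detect_confident,
               profile$p_detect_low)
      u_removal <- stats::runif(n)
      for (i in seq_len(n)) {
        base <- data.frame(
          case_id = truth$case_id,
          institution_id = profile$institution_id,
          chrom = tv$chrom[i], pos = tv$pos[i], ref = tv$ref[i],
          alt = tv$alt[i], variant_class = tv$variant_class[i],
          variant_id = tv$variant_id[i],
          vaf = vaf_obs[i], depth = depth[i],
          filter_status = "PASS", gene = tv$gene[i], flags = "",
          evidence_reads = as.integer(round(vaf_obs[i] * depth[i])),
          stringsAsFactors = FALSE
        )
        if (!detected[i]) {
          mech <- if (!confident[i]) "low_vaf_or_coverage"
                  else "no_supporting_reads_or_off_target"
          ev <- base
          if (mech == "no_supporting_reads_or_off_target") {
            ev$evidence_reads <- 0L
          }
          ev$on_target <- TRUE
          evidence <- add_row(evidence, ev)
          labels <- add_row(labels, data.frame(
            case_id = truth$case_id,
            institution_id = profile$institution_id,
            variant_id = tv$variant_id[i], mechanism = mech,
            stringsAsFactors = FALSE))
        } else if (confident[i] &&
                   u_removal[i] < profile$filter_miss_prob) {
          ev <- base
          ev$filter_status <- if (stats::runif(1) < 0.6) {
            "quality_filtered"
          } else "other_filtered"
          ev$on_target <- TRUE
          evidence <- add_row(evidence, ev)
          labels <- add_row(labels, data.frame(
            case_id = truth$case_id,
            institution_id = profile$institution_id,
            variant_id = tv$variant_id[i],
            mechanism = "quality_or_pass_filter",
            stringsAsFactors = FALSE))
        } else if (confident[i] &&
                   u_removal[i] < profile$filter_miss_prob +
                     profile$annotation_merge_prob) {
          ev <- base
          ev$flags <- "annotation_merged"
          ev$on_target <- TRUE
          evidence <- add_row(evidence, ev)
          labels <- add_row(labels, data.frame(
            case_id = truth$case_id,
            institution_id = profile$institution_id,
            variant_id = tv$variant_id[i],
            mechanism = "annotation_merged",
            stringsAsFactors = FALSE))
        } else {
          calls <- add_row(calls, base)
        }
      }
    }
    # False positives from the low-VAF spectrum, at novel positions.
    n_fp <- stats::rpois(1, profile$fp_rate)
    if (n_fp > 0) {
      panel <- toy_gene_panel(truth$profile$genome)
      taken <- tv$variant_id
      for (i in seq_len(n_fp)) {
        gi <- sample(nrow(panel), 1)
        pos <- panel$start[gi] + sample.int(20000, 1)
        ref <- .random_bases(1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        vid <- paste(panel$chrom[gi], pos, ref, alt, sep = ":")
        if (vid %in% taken) next
        taken <- c(taken, vid)
        depth <- stats::rnbinom(1, mu = profile$mean_coverage,
                                size = profile$coverage_dispersion) + 1L
        vaf <- round(stats::rbeta(1, 1.2, 25), 4)
        calls <- add_row(calls, data.frame(
          case_id = truth$case_id,
          institution_id = profile$institution_id,
          chrom = panel$chrom[gi], pos = pos, ref = ref, alt = alt,
          variant_class = "SNV", variant_id = vid, vaf = vaf,
          depth = depth, filter_status = "PASS",
          gene = panel$gene[gi], flags = "",
          evidence_reads = as.integer(round(vaf * depth)),
          stringsAsFactors = FALSE))
        labels <- add_row(labels, data.frame(
          case_id = truth$case_id,
          institution_id = profile$institution_id,
          variant_id = vid, mechanism = "false_positive",
          stringsAsFactors = FALSE))
      }
    }
    bind <- function(lst, template_cols) {
      if (length(lst)) do.call(rbind, lst) else NULL
    }
    list(calls = bind(calls), evidence = bind(evidence),
         labels = bind(labels))
  })
}

#' Simulate one institution's copy-number observation
#'
#' Perturbs the truth profile with a discrete +-1 copy-number noise
#' kernel whose probability scales inversely with tumor purity, applies
#' whole-profile doubling with the institution's WGD-misclassification
#' probability, jitters interior breakpoints, and draws a noisy purity
#' estimate.
#'
#' @param truth a [simulate_truth()] object.
#' @param profile an [institution_profile()].
#' @param master_seed,case_idx sub-seed inputs as in
#'   [simulate_institution_callset()].
#' @return List with `segments` (observed non-neutral segments data
#'   frame), `purity_estimate`, and `wgd_called` (logical).
#' @export
simulate_cn_observation <- function(truth, profile, master_seed,
                                    case_idx) {
  .with_seed(.sub_seed(master_seed, case_idx, profile$institution_id,
                       "cn"), {
    seg <- truth$profile$segments
    genome <- truth$profile$genome
    p_eff <- min(0.45, profile$cn_noise_prob * 0.7 / truth$purity)
    u <- stats::runif(nrow(seg))
    delta <- ifelse(u < p_eff / 2, -1L,
                    ifelse(u < p_eff, 1L, 0L))
    cn <- pmax(0L, seg$total_cn + delta)
    wgd_called <- stats::runif(1) < profile$wgd_misclass_prob
    if (wgd_called) cn <- 2L * cn
    out <- data.frame(
      case_id = truth$case_id,
      institution_id = profile$institution_id,
      chrom = seg$chrom, start = seg$start, end = seg$end,
      total_cn = cn, major_cn = NA_integer_, minor_cn = NA_integer_,
      stringsAsFactors = FALSE
    )
    # Jitter interior breakpoints, preserving segment order and width > 0.
    if (profile$breakpoint_jitter > 0 && nrow(out) > 1L) {
      for (ch in unique(out$chrom)) {
        idx <- which(out$chrom == ch)
        if (length(idx) < 2L) next
        for (k in seq_len(length(idx) - 1L)) {
          i <- idx[k]; j <- idx[k + 1L]
          b <- out$end[i]
          shift <- round(stats::runif(1, -profile$breakpoint_jitter,
                                      profile$breakpoint_jitter))
          nb <- min(out$end[j] - 1, max(out$start[i] + 1, b + shift))
          out$end[i] <- nb
          out$start[j] <- nb
        }
      }
    }
    out <- out[out$total_cn != 2L, , drop = FALSE]
    rownames(out) <- NULL
    purity_estimate <- min(1, max(0.05, truth$purity +
                                    stats::rnorm(1, 0,
                                                 profile$purity_noise_sd)))
    list(segments = out, purity_estimate = purity_estimate,
         wgd_called = wgd_called)
  })
}

#' Simulate one institution's biomarker record
#'
#' Observed score = bias x truth + Gaussian noise, clipped at zero (MSI
#' additionally at 100); `extra_sd` adds an independent wet-lab noise
#' component when the replicate represents a sequencing lab rather than
#' a pipeline.
#'
#' @param truth a [simulate_truth()] object.
#' @param profile an [institution_profile()].
#' @param master_seed,case_idx sub-seed inputs.
#' @param purity_estimate purity estimate to report (e.g. from
#'   [simulate_cn_observation()]); defaults to the true purity.
#' @param ploidy reported tumor ploidy (e.g. the observed profile's
#'   predominant ploidy); defaults to the truth ploidy.
#' @param extra_sd named vector of additional noise SDs (same names as
#'   `profile$noise_sd`), default zero.
#' @return One-row biomarker data frame.
#' @export
simulate_biomarkers <- function(truth, profile, master_seed, case_idx,
                                purity_estimate = truth$purity,
                                ploidy = truth$profile$predominant_ploidy,
                                extra_sd = c(hrd_sum = 0, tmb = 0,
                                             msi = 0)) {
  .with_seed(.sub_seed(master_seed, case_idx, profile$institution_id,
                       "biomarker"), {
    obs <- function(name, upper = Inf) {
      sd_tot <- sqrt(profile$noise_sd[[name]]^2 +
                       (if (name %in% names(extra_sd))
                         extra_sd[[name]]^2 else 0))
      v <- profile$bias[[name]] * truth$biomarkers[[name]] +
        stats::rnorm(1, 0, sd_tot)
      min(upper, max(0, v))
    }
    data.frame(
      case_id = truth$case_id,
      institution_id = profile$institution_id,
      hrd_sum = obs("hrd_sum"),
      tmb = obs("tmb"),
      msi = obs("msi", upper = 100),
      purity = purity_estimate,
      ploidy = ploidy,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a wet-lab vs bioinformatic replicate study
#'
#' Emulates the replicate design that separates the two variability
#' sources: the same samples are measured once per bioinformatic
#' pipeline (raw data from a single lab) and once per sequencing lab
#' (single pipeline). Replicate r observes
#' `bias_r * truth + N(0, sd_axis)`; per-replicate multiplicative biases
#' are drawn log-uniformly within `bias_range` (the reference replicate
#' has bias 1).
#'
#' @param n_samples number of samples (default 30).
#' @param sd_bioinf,sd_wetlab Gaussian noise SDs on the two axes.
#' @param n_pipelines,n_labs replicates per axis (defaults 3 and 3).
#' @param truth_mean,truth_sd distribution of the true score
#'   (normal truncated at 0).
#' @param bias_range multiplicative bias range for non-reference
#'   replicates.
#' @param seed RNG seed.
#' @return List with `bioinf` and `wetlab` [replicate_matrix()] objects
#'   and `truth` (numeric vector).
#' @export
simulate_replicate_study <- function(n_samples = 30L,
                                     sd_bioinf = 1,
                                     sd_wetlab = 2,
                                     n_pipelines = 3L, n_labs = 3L,
                                     truth_mean = 30, truth_sd = 12,
                                     bias_range = c(0.9, 1.1),
                                     seed = 1L) {
  .with_seed(seed, {
    truth <- pmax(0.5, stats::rnorm(n_samples, truth_mean, truth_sd))
    samples <- sprintf("S%03d", seq_len(n_samples))
    draw_axis <- function(n_rep, sdv, prefix) {
      bias <- c(1, exp(stats::runif(n_rep - 1L, log(bias_range[1]),
                                    log(bias_range[2]))))
      vals <- sapply(seq_len(n_rep), function(r) {
        pmax(0, bias[r] * truth + stats::rnorm(n_samples, 0, sdv))
      })
      colnames(vals) <- paste0(prefix, seq_len(n_rep))
      rownames(vals) <- samples
      vals
    }
    b <- draw_axis(n_pipelines, sd_bioinf, "pipeline_")
    w <- draw_axis(n_labs, sd_wetlab, "lab_")
    long <- function(m) {
      data.frame(
        sample_id = rep(rownames(m), ncol(m)),
        replicate_id = rep(colnames(m), each = nrow(m)),
        value = as.vector(m), stringsAsFactors = FALSE
      )
    }
    list(
      bioinf = replicate_matrix(long(b), "bioinformatic_pipelines",
                                reference = "pipeline_1"),
      wetlab = replicate_matrix(long(w), "sequencing_labs",
                                reference = "lab_1"),
      truth = truth
    )
  })
}

#' Simulate a full in-memory cohort
#'
#' Runs [simulate_truth()], [simulate_institution_callset()],
#' [simulate_cn_observation()] and [simulate_biomarkers()] for every
#' case and institution.
#'
#' @param config a [simulation_config()].
#' @return List of class `cohort` with `calls`, `evidence`, `labels`,
#'   `segments`, `biomarkers` (pooled data frames), `truths` (list of
#'   `case_truth`), and `config`.
#' @export
simulate_cohort_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  calls <- list(); evidence <- list(); labels <- list()
  segments <- list(); biomarkers <- list(); truths <- list()
  for (ci in seq_len(config$n_cases)) {
    truth <- simulate_truth(config, ci)
    truths[[truth$case_id]] <- truth
    for (prof in config$institutions) {
      cs <- simulate_institution_callset(truth, prof, config$seed, ci)
      if (!is.null(cs$calls)) calls[[length(calls) + 1L]] <- cs$calls
      if (!is.null(cs$evidence)) {
        evidence[[length(evidence) + 1L]] <- cs$evidence
      }
      if (!is.null(cs$labels)) labels[[length(labels) + 1L]] <- cs$labels
      cn <- simulate_cn_observation(truth, prof, config$seed, ci)
      if (nrow(cn$segments)) {
        segments[[length(segments) + 1L]] <- cn$segments
      }
      biomarkers[[length(biomarkers) + 1L]] <-
        simulate_biomarkers(
          truth, prof, config$seed, ci,
          purity_estimate = cn$purity_estimate,
          ploidy = truth$profile$predominant_ploidy *
            (if (cn$wgd_called) 2L else 1L))
    }
  }
  structure(
    list(
      calls = do.call(rbind, calls),
      evidence = do.call(rbind, evidence),
      labels = do.call(rbind, labels),
      segments = do.call(rbind, segments),
      biomarkers = do.call(rbind, biomarkers),
      truths = truths,
      config = config
    ),
    class = "cohort"
  )
}

#' Write a simulated cohort to disk
#'
#' Emits `variants.tsv`, `evidence.tsv`, `segments.tsv`,
#' `biomarkers.tsv` in the dialects the readers accept, plus
#' `truth.json` (generative labels, truth biomarkers, purity, WGD
#' status) and `manifest.json` (seed and a config hash).
#'
#' @param config a [simulation_config()], or an existing `cohort` from
#'   [simulate_cohort_data()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory (default `FALSE`).
#' @return Invisibly, the cohort object.
#' @export
simulate_cohort <- function(config, dir, force = FALSE) {
  cohort <- if (inherits(config, "cohort")) config
            else simulate_cohort_data(config)
  cfg <- cohort$config
  if (dir.exists(dir) && length(dir(dir)) && !force) {
    stop("output directory '", dir, "' is not empty; use force = TRUE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  empty_calls <- data.frame(
    case_id = character(0), institution_id = character(0),
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), variant_class = character(0),
    variant_id = character(0), vaf = numeric(0), depth = integer(0),
    filter_status = character(0), gene = character(0),
    flags = character(0), evidence_reads = integer(0),
    stringsAsFactors = FALSE
  )
  write_variant_calls(if (is.null(cohort$calls)) empty_calls else
    cohort$calls, file.path(dir, "variants.tsv"))
  ev <- if (is.null(cohort$evidence)) empty_calls else cohort$evidence
  ev$on_target <- NULL
  write_variant_calls(ev, file.path(dir, "evidence.tsv"))
  write_cn_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_biomarker_table(cohort$biomarkers,
                        file.path(dir, "biomarkers.tsv"))
  truth_json <- lapply(cohort$truths, function(tr) {
    list(
      case_id = tr$case_id,
      purity = tr$purity,
      wgd = tr$wgd,
      biomarkers = tr$biomarkers,
      variants = tr$variants$variant_id,
      vaf = tr$variants$vaf
    )
  })
  jsonlite::write_json(
    list(cases = truth_json,
         labels = cohort$labels),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  cfg_plain <- cfg
  cfg_plain$institutions <- lapply(cfg_plain$institutions, unclass)
  cfg_plain$genome <- unclass(cfg_plain$genome)
  cfg_str <- as.character(jsonlite::toJSON(unclass(cfg_plain),
                                           auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(
    list(seed = cfg$seed, config_hash = sprintf("%08x", .fnv1a(cfg_str))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(cohort)
}
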