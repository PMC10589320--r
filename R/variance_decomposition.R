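# Separating wet-lab from bioinformatic variability: replicate matrices,
# zero-intercept normalization to a reference pipeline, per-sample SDs.

#' Build a samples x replicates matrix
#'
#' A replicate axis is either a set of bioinformatic pipelines applied to
#' one lab's raw data, or a set of sequencing labs processed through one
#' pipeline. The reference replicate anchors the normalization scale.
#'
#' @param data long-format data frame with columns `sample_id`,
#'   `replicate_id`, `value`.
#' @param axis `"bioinformatic_pipelines"` or `"sequencing_labs"`.
#' @param reference id of the reference replicate (default: first).
#' @param biomarker optional biomarker label carried as an attribute.
#' @return Numeric matrix (samples x replicates) with attributes `axis`,
#'   `reference`, `biomarker`.
#' @export
replicate_matrix <- function(data,
                             axis = c("bioinformatic_pipelines",
                                      "sequencing_labs"),
                             reference = NULL, biomarker = NULL) {
  axis <- match.arg(axis)
  samples <- sort(unique(data$sample_id))
  reps <- sort(unique(data$replicate_id))
  if (length(reps) < 2L) stop("need at least two replicates")
  if (length(samples) < 3L) stop("need at least three samples")
  m <- matrix(NA_real_, length(samples), length(reps),
              dimnames = list(samples, reps))
  m[cbind(match(data$sample_id, samples),
          match(data$replicate_id, reps))] <- data$value
  if (is.null(reference)) reference <- reps[1L]
  if (!reference %in% reps) stop("unknown reference replicate")
  attr(m, "axis") <- axis
  attr(m, "reference") <- reference
  attr(m, "biomarker") <- biomarker
  m
}

#' Normalize replicate columns to the reference replicate
#'
#' Each non-reference column is divided by its zero-intercept slope
#' against the reference column, putting every replicate on the
#' reference scale before standard deviations are computed. The
#' reference column is unchanged. Idempotent.
#'
#' @param m matrix from [replicate_matrix()] (or any samples x
#'   replicates matrix with a `reference` attribute / explicit
#'   `reference` argument).
#' @param reference reference column name; defaults to the matrix
#'   attribute.
#' @return The normalized matrix (attributes preserved).
#' @export
normalize_to_reference <- function(m, reference = attr(m, "reference")) {
  if (is.null(reference) || !reference %in% colnames(m)) {
    stop("reference replicate not found among columns")
  }
  ref <- m[, reference]
  out <- m
  for (cn in setdiff(colnames(m), reference)) {
    ok <- !is.na(ref) & !is.na(m[, cn])
    if (sum(ok) < 2L) next
    slope <- zero_intercept_slope(ref[ok], m[ok, cn])
    if (slope == 0) stop("zero slope against reference for '", cn, "'")
    out[, cn] <- m[, cn] / slope
  }
  out
}

#' Per-sample standard deviation across replicates
#'
#' Unbiased (n-1) SD of each sample's replicate values; samples with
#' fewer than two non-missing replicates are dropped.
#'
#' @param m samples x replicates matrix.
#' @return Named numeric vector of SDs over retained samples.
#' @export
per_sample_sd <- function(m) {
  n_ok <- rowSums(!is.na(m))
  keep <- n_ok >= 2L
  sds <- apply(m[keep, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  stats::setNames(sds, rownames(m)[keep])
}

#' Median per-sample SD
#'
#' @param m samples x replicates matrix.
#' @return Median of [per_sample_sd()] over retained samples.
#' @export
median_sd <- function(m) {
  sds <- per_sample_sd(m)
  if (length(sds) < 3L) stop("fewer than three samples with >= 2 replicates")
  stats::median(sds)
}

#' Compare wet-lab and bioinformatic variability
#'
#' Computes per-sample SDs on the shared samples of two replicate
#' matrices (one varying the sequencing lab at fixed pipeline, one
#' varying the pipeline at fixed lab), both normalized to their
#' reference replicate, and tests whether wet-lab variability exceeds
#' bioinformatic variability with a one-sided paired Wilcoxon test.
#' Samples beyond the 1.5 x IQR whiskers of either SD distribution are
#' flagged as outliers.
#'
#' @param bioinf matrix with `axis = "bioinformatic_pipelines"`.
#' @param wetlab matrix with `axis = "sequencing_labs"`.
#' @param alternative Wilcoxon direction for (wetlab SD, bioinf SD);
#'   default `"greater"`.
#' @param normalize normalize both matrices to their reference first
#'   (default `TRUE`).
#' @return Object of class `decomposition_summary`: list with `sd_wetlab`
#'   and `sd_bioinf` (per-sample vectors on shared samples),
#'   `median_wetlab`, `median_bioinf`, `wilcoxon_p`, and `outliers`
#'   (list of sample ids per axis).
#' @export
compare_sources <- function(bioinf, wetlab, alternative = "greater",
                            normalize = TRUE) {
  if (normalize) {
    bioinf <- normalize_to_reference(bioinf)
    wetlab <- normalize_to_reference(wetlab)
  }
  sd_b <- per_sample_sd(bioinf)
  sd_w <- per_sample_sd(wetlab)
  shared <- intersect(names(sd_b), names(sd_w))
  if (!length(shared)) stop("no shared samples between the two matrices")
  sd_b <- sd_b[shared]
  sd_w <- sd_w[shared]
  p <- paired_wilcoxon(sd_w, sd_b, alternative = alternative)
  iqr_outliers <- function(v) {
    st <- grDevices::boxplot.stats(v)
    names(v)[v %in% st$out]
  }
  structure(
    list(
      sd_wetlab = sd_w,
      sd_bioinf = sd_b,
      median_wetlab = stats::median(sd_w),
      median_bioinf = stats::median(sd_b),
      wilcoxon_p = p,
      outliers = list(wetlab = iqr_outliers(sd_w),
                      bioinf = iqr_outliers(sd_b))
    ),
    class = "decomposition_summary"
  )
}

#' @export
print.decomposition_summary <- function(x, ...) {
  cat("<decomposition_summary> median SD wet-lab ",
      signif(x$median_wetlab, 3), " vs bioinformatic ",
      signif(x$median_bioinf, 3), " (one-sided Wilcoxon p = ",
      signif(x$wilcoxon_p, 3), ")\n", sep = "")
  invisible(x)
}
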