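# Pairwise correlation, zero-intercept systematic deviation, cutoff
# status agreement and paired Wilcoxon testing for complex biomarker
# scores (HRD, TMB, MSI, purity, ploidy).

#' Build a case x institution score matrix for one biomarker
#'
#' @param records biomarker table ([read_biomarker_table()] output).
#' @param biomarker one of `"hrd_sum"`, `"tmb"`, `"msi"`, `"purity"`,
#'   `"ploidy"`.
#' @return Numeric matrix (cases x institutions) with `NA` for missing
#'   scores; attribute `biomarker` records the score name.
#' @export
score_matrix <- function(records,
                         biomarker = c("hrd_sum", "tmb", "msi",
                                       "purity", "ploidy")) {
  biomarker <- match.arg(biomarker)
  cases <- sort(unique(records$case_id))
  insts <- sort(unique(records$institution_id))
  if (length(insts) < 2L) stop("need at least two institutions")
  m <- matrix(NA_real_, length(cases), length(insts),
              dimnames = list(cases, insts))
  idx <- cbind(match(records$case_id, cases),
               match(records$institution_id, insts))
  m[idx] <- records[[biomarker]]
  attr(m, "biomarker") <- biomarker
  m
}

#' Zero-intercept regression slope
#'
#' Least-squares slope of the model `y = b * x` (intercept fixed at
#' zero): `b = sum(x*y) / sum(x^2)`, computed over pairwise-complete
#' observations.
#'
#' @param x,y numeric vectors of equal length (missing pairs dropped).
#' @return The slope `b`.
#' @export
zero_intercept_slope <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least two complete pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("cannot fit a zero-intercept slope to all-zero x")
  sum(x * y) / sxx
}

#' Systematic deviation between two score vectors
#'
#' Percent deviation implied by the zero-intercept slope:
#' `(slope - 1) * 100`. A value of -15 means scores in `y` run 15%
#' systematically lower than in `x`.
#'
#' @inheritParams zero_intercept_slope
#' @return Deviation in percent.
#' @export
systematic_deviation <- function(x, y) {
  (zero_intercept_slope(x, y) - 1) * 100
}

#' Pairwise Pearson correlations over complete observations
#'
#' @param m score matrix from [score_matrix()].
#' @param min_pairs minimum complete pairs required (default 3).
#' @return List with `r` (institution x institution correlation matrix,
#'   `NA` off-diagonal where undefined, e.g. zero variance) and `n`
#'   (complete-pair counts). Undefined correlations are flagged in the
#'   `undefined` logical matrix.
#' @export
pearson_pairwise <- function(m, min_pairs = 3L) {
  insts <- colnames(m)
  p <- length(insts)
  r <- matrix(NA_real_, p, p, dimnames = list(insts, insts))
  n <- matrix(0L, p, p, dimnames = list(insts, insts))
  undef <- matrix(FALSE, p, p, dimnames = list(insts, insts))
  diag(r) <- 1
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      n[i, j] <- sum(ok)
      if (n[i, j] < min_pairs) {
        undef[i, j] <- TRUE
        next
      }
      if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
        undef[i, j] <- TRUE
        next
      }
      r[i, j] <- stats::cor(m[ok, i], m[ok, j])
    }
  }
  list(r = r, n = n, undefined = undef)
}

#' Pairwise biomarker statistics between institutions
#'
#' For every ordered institution pair computes the complete-pair count,
#' Pearson r, the zero-intercept slope of column j on column i, the
#' implied systematic deviation in percent, and a one-sided paired
#' Wilcoxon p-value.
#'
#' @param m score matrix from [score_matrix()].
#' @param alternative direction of the Wilcoxon test for (x = column i,
#'   y = column j); default `"two.sided"`.
#' @return Data frame with one row per ordered pair.
#' @export
biomarker_pairwise <- function(m, alternative = "two.sided") {
  insts <- colnames(m)
  pp <- pearson_pairwise(m)
  rows <- list()
  for (i in seq_along(insts)) {
    for (j in seq_along(insts)) {
      if (i == j) next
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      slope <- if (sum(ok) >= 2L && sum(m[ok, i]^2) > 0) {
        zero_intercept_slope(m[ok, i], m[ok, j])
      } else NA_real_
      pw <- if (sum(ok) >= 2L) {
        paired_wilcoxon(m[ok, j], m[ok, i], alternative = alternative)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        inst_x = insts[i], inst_y = insts[j],
        n_complete = sum(ok),
        pearson_r = pp$r[i, j],
        slope = slope,
        deviation_pct = (slope - 1) * 100,
        wilcoxon_p = pw,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Classify biomarker status against clinical cutoffs
#'
#' A score is positive when it is greater than or equal to the cutoff
#' (so a score exactly at the cutoff counts positive). Cutoffs may be
#' institution-specific (as for MSI, where tool differences motivate a
#' different threshold at one center). Cases are summarized as
#' `all_positive`, `all_negative` or `discordant`; a case with any
#' missing score is excluded from the summary (listwise).
#'
#' @param m score matrix from [score_matrix()].
#' @param cutoff single numeric cutoff, or named numeric vector with one
#'   entry per institution (names matching `colnames(m)`; a `default`
#'   entry covers unnamed institutions).
#' @return List with `status` (character matrix `"positive"`/
#'   `"negative"`/`NA`) and `summary` data frame (`case_id`, `category`,
#'   `discordant_institutions`).
#' @export
classify_status <- function(m, cutoff) {
  insts <- colnames(m)
  if (length(cutoff) == 1L && is.null(names(cutoff))) {
    cuts <- stats::setNames(rep(cutoff, length(insts)), insts)
  } else {
    cuts <- stats::setNames(rep(NA_real_, length(insts)), insts)
    named <- intersect(names(cutoff), insts)
    cuts[named] <- cutoff[named]
    if ("default" %in% names(cutoff)) {
      cuts[is.na(cuts)] <- cutoff[["default"]]
    }
    if (any(is.na(cuts))) {
      stop("missing cutoff for institution(s): ",
           paste(insts[is.na(cuts)], collapse = ", "))
    }
  }
  if (any(cuts <= 0)) stop("cutoffs must be positive")
  status <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_along(insts)) {
    status[, j] <- ifelse(is.na(m[, j]), NA_character_,
                          ifelse(m[, j] >= cuts[j], "positive",
                                 "negative"))
  }
  summ <- data.frame(
    case_id = rownames(m),
    category = apply(status, 1L, function(s) {
      if (anyNA(s)) NA_character_
      else if (all(s == "positive")) "all_positive"
      else if (all(s == "negative")) "all_negative"
      else "discordant"
    }),
    discordant_institutions = apply(status, 1L, function(s) {
      if (anyNA(s) || length(unique(s)) == 1L) ""
      else {
        minority <- names(which(table(s) == min(table(s))))[1L]
        paste(colnames(m)[s == minority], collapse = ";")
      }
    }),
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  list(status = status, cutoffs = cuts, summary = summ)
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Drops zero differences, then applies the signed-rank test: exact null
#' distribution for up to 25 non-zero differences, normal approximation
#' with continuity correction above. When every difference is zero the
#' test is vacuous and p = 1 is returned with a warning.
#'
#' @param x,y paired numeric vectors.
#' @param alternative `"greater"` (x tends larger than y), `"less"`, or
#'   `"two.sided"`.
#' @param exact_max largest number of non-zero differences for which the
#'   exact distribution is used (default 25).
#' @return The p-value.
#' @export
paired_wilcoxon <- function(x, y,
                            alternative = c("greater", "less",
                                            "two.sided"),
                            exact_max = 25L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; test is vacuous")
    return(1)
  }
  res <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, mu = 0,
    exact = length(d) <= exact_max, correct = TRUE
  ))
  unname(res$p.value)
}
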