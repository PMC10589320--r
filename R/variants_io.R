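# Domain vocabularies shared across modules.

#' Controlled vocabularies
#'
#' Factor levels used throughout the package: variant classes, filter
#' statuses, evidence flags attached to calls, and the cause taxonomy for
#' discordant detections.
#'
#' @name vocabularies
#' @keywords internal
NULL

variant_classes <- c("SNV", "insertion", "deletion", "delins")

filter_statuses <- c("PASS", "quality_filtered", "other_filtered")

call_flags <- c(
  "germline_overlap", "splice_site", "promoter", "reported_as_SV",
  "annotation_merged", "intronic", "polymorphism", "LOH_event",
  "homologous_region"
)

discordance_causes <- c(
  "low_vaf_or_coverage", "quality_or_pass_filter", "annotation_merged",
  "germline_mislabel", "germline_missed", "structural_variant_call",
  "intron_or_polymorphism_filter", "no_supporting_reads_or_off_target",
  "splice_classification", "indel_representation", "promoter_region",
  "somatic_LOH", "homologous_region", "unexplained"
)

.valid_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]+$", x)
}

.last_char <- function(s) substr(s, nchar(s), nchar(s))

#' Normalize a somatic variant to a canonical key
#'
#' Puts a (chromosome, position, ref, alt) tuple into a canonical form so
#' that every representation of the same DNA edit maps to one key:
#' the shared allele suffix is trimmed, then the shared prefix is trimmed
#' with the position advanced (one anchor base is always retained), and
#' indels are left-aligned when a reference `context` string is supplied.
#' Exact matching of normalized keys is then representation-independent.
#'
#' @param chromosome chromosome name.
#' @param position 1-based position of the first `ref` base.
#' @param ref,alt non-empty uppercase DNA strings (A/C/G/T).
#' @param context optional reference sequence used to left-align indels.
#' @param context_start 1-based genomic position of the first base of
#'   `context` (default 1).
#' @return A list of class `variant_key` with elements `chromosome`,
#'   `position`, `ref`, `alt`, `variant_class` (one of SNV, insertion,
#'   deletion, delins) and `id`, a `"chrom:pos:ref:alt"` string.
#' @examples
#' normalize_variant("chr1", 100, "A", "G")
#' normalize_variant("chr1", 100, "ATG", "ATGTG")
#' @export
normalize_variant <- function(chromosome, position, ref, alt,
                              context = NULL, context_start = 1L) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if ((is.na(ref) || !nzchar(ref)) && (is.na(alt) || !nzchar(alt))) {
    stop("invalid variant: ref and alt are both empty")
  }
  if (!.valid_dna(ref) || !.valid_dna(alt)) {
    stop("ref and alt must be non-empty DNA strings over A/C/G/T")
  }
  if (ref == alt) stop("invalid variant: ref equals alt")
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("position must be >= 1")

  # Trim shared suffix, keeping at least one base per allele.
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         .last_char(ref) == .last_char(alt)) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # Trim shared prefix, advancing the position.
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    position <- position + 1L
  }

  if (!is.null(context)) {
    context <- toupper(as.character(context))
    context_start <- as.integer(context_start)
    ctx_base <- function(gpos) {
      i <- gpos - context_start + 1L
      if (i < 1L || i > nchar(context)) NA_character_
      else substr(context, i, i)
    }
    # Left-align: drop a shared terminal base whenever the anchor can be
    # re-grown from the reference context, then extend left as needed.
    repeat {
      nr <- nchar(ref); na <- nchar(alt)
      can_extend <- !is.na(ctx_base(position - 1L))
      if (nr > 0L && na > 0L && .last_char(ref) == .last_char(alt) &&
          (min(nr, na) > 1L || can_extend)) {
        ref <- substr(ref, 1L, nr - 1L)
        alt <- substr(alt, 1L, na - 1L)
      } else if (nr == 0L || na == 0L) {
        b <- ctx_base(position - 1L)
        if (is.na(b)) stop("context exhausted during left alignment")
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        position <- position - 1L
      } else break
    }
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      position <- position + 1L
    }
  }

  nr <- nchar(ref); na <- nchar(alt)
  variant_class <-
    if (nr == 1L && na == 1L) "SNV"
    else if (nr == 1L && na > 1L && substr(alt, 1L, 1L) == ref) "insertion"
    else if (na == 1L && nr > 1L && substr(ref, 1L, 1L) == alt) "deletion"
    else "delins"

  structure(
    list(
      chromosome = as.character(chromosome),
      position = position,
      ref = ref,
      alt = alt,
      variant_class = variant_class,
      id = paste(chromosome, position, ref, alt, sep = ":")
    ),
    class = "variant_key"
  )
}

#' @export
print.variant_key <- function(x, ...) {
  cat("<variant_key> ", x$id, " (", x$variant_class, ")\n", sep = "")
  invisible(x)
}

#' Normalize every variant row of a call table
#'
#' Applies [normalize_variant()] row-wise and rewrites `chrom`, `pos`,
#' `ref`, `alt`, adding `variant_class` and `variant_id` columns.
#'
#' @param calls a data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @inheritParams normalize_variant
#' @return The data frame with normalized coordinates and alleles.
#' @export
normalize_calls <- function(calls, context = NULL, context_start = 1L) {
  if (nrow(calls) == 0L) {
    calls$variant_class <- character(0)
    calls$variant_id <- character(0)
    return(calls)
  }
  keys <- lapply(seq_len(nrow(calls)), function(i) {
    normalize_variant(calls$chrom[i], calls$pos[i], calls$ref[i],
                      calls$alt[i], context = context,
                      context_start = context_start)
  })
  calls$pos <- vapply(keys, `[[`, integer(1), "position")
  calls$ref <- vapply(keys, `[[`, character(1), "ref")
  calls$alt <- vapply(keys, `[[`, character(1), "alt")
  calls$variant_class <- vapply(keys, `[[`, character(1), "variant_class")
  calls$variant_id <- vapply(keys, `[[`, character(1), "id")
  calls
}

#' Map a raw FILTER string to the filter-status vocabulary
#'
#' `PASS`, `.` and empty strings map to `PASS`; strings that look like
#' quality filters (`q20`, `LowQual`, anything containing "qual") map to
#' `quality_filtered`; everything else to `other_filtered`.
#'
#' @param filter character vector of raw FILTER values.
#' @return Character vector over `PASS`, `quality_filtered`, `other_filtered`.
#' @export
map_filter_status <- function(filter) {
  filter <- as.character(filter)
  out <- rep("other_filtered", length(filter))
  pass <- is.na(filter) | filter %in% c("PASS", ".", "")
  out[pass] <- "PASS"
  qual <- !pass & grepl("^q[0-9]+$|qual", filter, ignore.case = TRUE)
  out[qual] <- "quality_filtered"
  out[filter %in% filter_statuses] <- filter[filter %in% filter_statuses]
  out
}

.required_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("format error in '", path, "': missing mandatory column(s) ",
         paste(missing, collapse = ", "))
  }
}

.report_bad_rows <- function(bad, what, path) {
  if (any(bad)) {
    stop("validation error in '", path, "': ", what, " at line(s) ",
         paste(which(bad) + 1L, collapse = ", "))  # +1 for header line
  }
}

#' Read somatic variant calls
#'
#' Reads per-case, per-institution somatic calls from the package's TSV
#' dialect (columns `case_id`, `institution_id`, `chrom`, `pos`, `ref`,
#' `alt`, `vaf`, `depth`, `filter`, and optionally `gene`, `flags` as a
#' semicolon list, `evidence_reads`) or from a VCF 4.x file (FILTER and
#' FORMAT `AF`/`DP` of the first sample are honored; vcfR is required for
#' this dialect). Every record is normalized via [normalize_variant()]
#' unless `normalize = FALSE` reproduces literal exact matching.
#'
#' @param path file to read.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param case_id,institution_id identifiers used when the file itself
#'   does not carry them (mandatory for VCF input).
#' @param normalize normalize variant representations (default `TRUE`).
#' @return A data frame of calls with columns `case_id`, `institution_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_class`, `variant_id`, `vaf`,
#'   `depth`, `filter_status`, `gene`, `flags`, `evidence_reads`.
#' @export
read_variant_calls <- function(path, dialect = c("tsv", "vcf"),
                               case_id = NULL, institution_id = NULL,
                               normalize = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") {
    df <- .read_vcf_calls(path, case_id, institution_id)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    .required_cols(df, c("chrom", "pos", "ref", "alt", "vaf", "depth",
                         "filter"), path)
    if (!"case_id" %in% names(df)) {
      if (is.null(case_id)) stop("no case_id column and none supplied")
      df$case_id <- case_id
    }
    if (!"institution_id" %in% names(df)) {
      if (is.null(institution_id)) {
        stop("no institution_id column and none supplied")
      }
      df$institution_id <- institution_id
    }
    df$pos <- suppressWarnings(as.integer(df$pos))
    df$vaf <- suppressWarnings(as.numeric(df$vaf))
    df$depth <- suppressWarnings(as.integer(df$depth))
    .report_bad_rows(is.na(df$pos) | df$pos < 1L, "invalid position", path)
    .report_bad_rows(is.na(df$vaf) | df$vaf < 0 | df$vaf > 1,
                     "VAF outside [0,1]", path)
    .report_bad_rows(is.na(df$depth) | df$depth < 0L,
                     "invalid depth", path)
    df$filter_status <- map_filter_status(df$filter)
    df$filter <- NULL
    if (!"gene" %in% names(df)) df$gene <- ""
    if (!"flags" %in% names(df)) df$flags <- ""
    df$gene[is.na(df$gene)] <- ""
    df$flags[is.na(df$flags)] <- ""
    if ("evidence_reads" %in% names(df)) {
      df$evidence_reads <- suppressWarnings(as.integer(df$evidence_reads))
    } else {
      df$evidence_reads <- NA_integer_
    }
    bad_er <- !is.na(df$evidence_reads) & df$evidence_reads > df$depth
    .report_bad_rows(bad_er, "evidence_reads exceeds depth", path)
  }
  if (normalize) df <- normalize_calls(df) else {
    df$variant_class <- mapply(function(r, a) {
      if (nchar(r) == 1L && nchar(a) == 1L) "SNV"
      else if (nchar(r) < nchar(a)) "insertion"
      else if (nchar(r) > nchar(a)) "deletion"
      else "delins"
    }, df$ref, df$alt, USE.NAMES = FALSE)
    df$variant_id <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  }
  cols <- c("case_id", "institution_id", "chrom", "pos", "ref", "alt",
            "variant_class", "variant_id", "vaf", "depth", "filter_status",
            "gene", "flags", "evidence_reads")
  df[, cols]
}

.read_vcf_calls <- function(path, case_id, institution_id) {
  if (is.null(case_id) || is.null(institution_id)) {
    stop("case_id and institution_id must be supplied for VCF input")
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  vaf <- rep(NA_real_, nrow(fix))
  depth <- rep(NA_integer_, nrow(fix))
  if (ncol(v@gt) >= 2L) {
    af <- try(vcfR::extract.gt(v, element = "AF", as.numeric = TRUE),
              silent = TRUE)
    dp <- try(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
              silent = TRUE)
    if (!inherits(af, "try-error") && !is.null(af)) vaf <- as.numeric(af[, 1L])
    if (!inherits(dp, "try-error") && !is.null(dp)) {
      depth <- as.integer(dp[, 1L])
    }
  }
  bad <- !is.na(vaf) & (vaf < 0 | vaf > 1)
  if (any(bad)) {
    stop("validation error in '", path, "': VAF outside [0,1] for record(s) ",
         paste(which(bad), collapse = ", "))
  }
  data.frame(
    case_id = case_id,
    institution_id = institution_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vaf = vaf,
    depth = ifelse(is.na(depth), 0L, depth),
    filter_status = map_filter_status(fix$FILTER),
    gene = "",
    flags = "",
    evidence_reads = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Write variant calls in the package TSV dialect
#'
#' @param calls data frame as returned by [read_variant_calls()].
#' @param path output file.
#' @export
write_variant_calls <- function(calls, path) {
  out <- calls
  out$filter <- out$filter_status
  out$filter_status <- NULL
  out$variant_class <- NULL
  out$variant_id <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read copy-number segments
#'
#' Reads a SEG-like TSV with columns `case_id`, `institution_id`, `chrom`,
#' `start`, `end`, `total_cn` and optionally `major_cn`, `minor_cn`.
#' Coordinates are stored 0-based half-open (BED convention); use
#' `dialect = "onebased"` for 1-based inclusive input. Overlapping
#' segments within one (case, institution) profile are an error.
#'
#' @param path file to read.
#' @param dialect `"bed"` (0-based half-open, default) or `"onebased"`
#'   (1-based inclusive, converted on read).
#' @return Data frame of segments in 0-based half-open coordinates.
#' @export
read_cn_segments <- function(path, dialect = c("bed", "onebased")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .required_cols(df, c("case_id", "institution_id", "chrom", "start",
                       "end", "total_cn"), path)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (dialect == "onebased") df$start <- df$start - 1
  df$total_cn <- as.integer(df$total_cn)
  .report_bad_rows(is.na(df$total_cn) | df$total_cn < 0L,
                   "negative or missing copy number", path)
  .report_bad_rows(is.na(df$start) | is.na(df$end) | df$start >= df$end,
                   "empty or inverted interval", path)
  if (!all(c("major_cn", "minor_cn") %in% names(df))) {
    df$major_cn <- NA_integer_
    df$minor_cn <- NA_integer_
  } else {
    df$major_cn <- as.integer(df$major_cn)
    df$minor_cn <- as.integer(df$minor_cn)
    bad <- !is.na(df$major_cn) & !is.na(df$minor_cn) &
      (df$major_cn + df$minor_cn != df$total_cn)
    .report_bad_rows(bad, "major_cn + minor_cn != total_cn", path)
  }
  .check_segment_overlap(df, path)
  df[, c("case_id", "institution_id", "chrom", "start", "end",
         "total_cn", "major_cn", "minor_cn")]
}

.check_segment_overlap <- function(df, path = "<segments>") {
  key <- paste(df$case_id, df$institution_id, df$chrom, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- idx[order(df$start[idx])]
    if (length(o) > 1L) {
      ov <- which(df$start[o][-1L] < df$end[o][-length(o)])
      if (length(ov)) {
        i <- o[ov[1L]]; j <- o[ov[1L] + 1L]
        stop("validation error in '", path, "': overlapping segments ",
             df$chrom[i], ":[", df$start[i], ",", df$end[i], ") and [",
             df$start[j], ",", df$end[j], ") for case ", df$case_id[i],
             ", institution ", df$institution_id[i])
      }
    }
  }
  invisible(TRUE)
}

#' Write copy-number segments (0-based half-open TSV)
#'
#' @param segments data frame as returned by [read_cn_segments()].
#' @param path output file.
#' @export
write_cn_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a biomarker score table
#'
#' One row per (case, institution) with columns `case_id`,
#' `institution_id`, `hrd_sum`, `tmb`, `msi` and optionally `purity`,
#' `ploidy`. Empty cells become missing values (a center may, for
#' example, be unable to determine tumor purity for a sample).
#'
#' @param path TSV file.
#' @return Data frame of biomarker records.
#' @export
read_biomarker_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .required_cols(df, c("case_id", "institution_id", "hrd_sum", "tmb",
                       "msi"), path)
  for (col in c("hrd_sum", "tmb", "msi", "purity", "ploidy")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  dup <- duplicated(df[, c("case_id", "institution_id")])
  if (any(dup)) {
    stop("validation error in '", path, "': duplicate (case, institution) ",
         "row(s): ", paste(unique(paste(df$case_id[dup],
                                        df$institution_id[dup])),
                           collapse = "; "))
  }
  .report_bad_rows(!is.na(df$hrd_sum) & df$hrd_sum < 0,
                   "negative HRD sum", path)
  .report_bad_rows(!is.na(df$tmb) & df$tmb < 0, "negative TMB", path)
  .report_bad_rows(!is.na(df$msi) & (df$msi < 0 | df$msi > 100),
                   "MSI outside [0,100]", path)
  .report_bad_rows(!is.na(df$purity) & (df$purity <= 0 | df$purity > 1),
                   "purity outside (0,1]", path)
  .report_bad_rows(!is.na(df$ploidy) & df$ploidy <= 0,
                   "non-positive ploidy", path)
  df[, c("case_id", "institution_id", "hrd_sum", "tmb", "msi", "purity",
         "ploidy")]
}

#' Write a biomarker score table
#'
#' @param records data frame as returned by [read_biomarker_table()].
#' @param path output file.
#' @export
write_biomarker_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
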