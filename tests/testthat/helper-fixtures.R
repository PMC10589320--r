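# Shared fixtures and independent oracles used across the test files.

# Apply a (pos, ref, alt) edit to a context string; the resulting
# haplotype is the representation-independent identity of the edit.
apply_edit <- function(context, context_start, pos, ref, alt) {
  i <- pos - context_start + 1L
  stopifnot(substr(context, i, i + nchar(ref) - 1L) == ref)
  paste0(substr(context, 1L, i - 1L), alt,
         substr(context, i + nchar(ref), nchar(context)))
}

# All equivalent (pos, ref, alt) encodings of a variant on a context,
# obtained by padding with up to `pad` context bases on either side.
equivalent_representations <- function(context, context_start,
                                       pos, ref, alt, pad = 3L) {
  reps <- list()
  n <- nchar(context)
  for (a in 0:pad) {
    for (b in 0:pad) {
      i <- pos - context_start + 1L
      if (i - a < 1L || i + nchar(ref) - 1L + b > n) next
      left <- substr(context, i - a, i - 1L)
      right <- substr(context, i + nchar(ref),
                      i + nchar(ref) + b - 1L)
      reps[[length(reps) + 1L]] <- list(
        pos = pos - a,
        ref = paste0(left, ref, right),
        alt = paste0(left, alt, right)
      )
    }
  }
  reps
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small call table: list of institution -> character vector of
# variant ids, all for one case. Positions are synthesized.
make_calls <- function(sets, case_id = "case_01") {
  rows <- list()
  for (inst in names(sets)) {
    for (vid in sets[[inst]]) {
      parts <- strsplit(vid, ":", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case_id, institution_id = inst,
        chrom = parts[1], pos = as.integer(parts[2]),
        ref = parts[3], alt = parts[4],
        variant_class = "SNV", variant_id = vid,
        vaf = 0.4, depth = 200L, filter_status = "PASS",
        gene = "GENE001", flags = "", evidence_reads = 80L,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

vid <- function(pos, ref = "A", alt = "G", chrom = "chr1") {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Random filled CN profile on a genome: k alteration segments with CN
# drawn from 0..6 (!=2), then filled.
random_profile <- function(genome, inst = "I1", case = "case_01",
                           k = 5L, max_cn = 6L) {
  segs <- list()
  for (i in seq_len(k)) {
    chrom <- sample(genome$included, 1)
    len <- genome$lengths[[chrom]]
    w <- sample.int(max(2L, floor(len / 4)), 1)
    s <- sample.int(max(1L, len - w), 1) - 1L
    cn <- sample(setdiff(0:max_cn, 2L), 1)
    segs[[i]] <- data.frame(
      case_id = case, institution_id = inst, chrom = chrom,
      start = s, end = s + w, total_cn = cn,
      major_cn = NA_integer_, minor_cn = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  segs <- do.call(rbind, segs)
  # drop overlaps within chromosomes, keeping earlier segments
  segs <- segs[order(segs$chrom, segs$start), ]
  keep <- logical(nrow(segs))
  for (ch in unique(segs$chrom)) {
    idx <- which(segs$chrom == ch)
    last_end <- -1
    for (i in idx) {
      if (segs$start[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- segs$end[i]
      }
    }
  }
  fill_profile(segs[keep, , drop = FALSE], genome)
}

# Per-base oracle: expand a filled profile into one CN value per base.
profile_base_vector <- function(profile) {
  out <- list()
  for (chrom in profile$genome$included) {
    s <- profile$segments[profile$segments$chrom == chrom, ]
    out[[chrom]] <- rep(s$total_cn, s$end - s$start)
  }
  out
}

# Per-base brute-force comparison oracle mirroring the documented
# classification, independent of the interval implementation.
compare_by_base <- function(a, b, rule = "ratio") {
  va <- profile_base_vector(a)
  vb <- profile_base_vector(b)
  pa <- a$predominant_ploidy
  pb <- b$predominant_ploidy
  exact <- 0; dup <- 0; mism <- 0
  hist <- integer(0)
  for (chrom in names(va)) {
    x <- va[[chrom]]; y <- vb[[chrom]]
    eq <- x == y
    dd <- if (rule == "ratio") !eq & (x / pa == y / pb)
          else !eq & ((x - pa) == (y - pb))
    mm <- !eq & !dd
    exact <- exact + sum(eq)
    dup <- dup + sum(dd)
    mism <- mism + sum(mm)
    if (any(mm)) {
      t <- table(abs(x[mm] - y[mm]))
      for (k in names(t)) {
        hist[k] <- (if (is.na(hist[k])) 0L else hist[k]) + t[[k]]
      }
    }
  }
  list(exact = exact, dup = dup, mism = mism,
       hist = hist[order(as.numeric(names(hist)))])
}

tiny_genome <- function() {
  genome_model(c("chrA", "chrB"), c(60000, 40000))
}
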