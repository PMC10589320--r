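#' Define a genome model
#'
#' A genome model fixes the chromosome universe over which copy-number
#' profiles are tiled and compared at base resolution. Lengths are in base
#' pairs; `included` names the subset of chromosomes entering base-level
#' comparison (by default autosomes plus chrX; chrY is excluded because
#' sex-chromosome handling differs between centers).
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths positive integer vector of chromosome lengths (bp),
#'   same length as `chromosomes`.
#' @param included subset of `chromosomes` used for base-level CN
#'   comparison. Defaults to all chromosomes except `"chrY"`/`"Y"`.
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes`, `lengths` (named), and `included`.
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_size(gm)
#' @export
genome_model <- function(chromosomes, lengths,
                         included = setdiff(chromosomes, c("chrY", "Y"))) {
  chromosomes <- as.character(chromosomes)
  if (anyDuplicated(chromosomes)) {
    stop("chromosome names must be unique")
  }
  if (length(lengths) != length(chromosomes)) {
    stop("'lengths' must match 'chromosomes' in length")
  }
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (!all(included %in% chromosomes)) {
    stop("'included' must be a subset of 'chromosomes'")
  }
  structure(
    list(
      chromosomes = chromosomes,
      lengths = stats::setNames(lengths, chromosomes),
      included = as.character(included)
    ),
    class = "genome_model"
  )
}

#' Total size of the comparable genome
#'
#' @param genome a [genome_model()].
#' @param included_only if `TRUE` (default) sum only the chromosomes used
#'   for base-level comparison.
#' @return Total length in base pairs.
#' @export
genome_size <- function(genome, included_only = TRUE) {
  stopifnot(inherits(genome, "genome_model"))
  chroms <- if (included_only) genome$included else genome$chromosomes
  sum(genome$lengths[chroms])
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chromosomes), " chromosomes, ",
      format(sum(x$lengths), big.mark = ","), " bp (",
      length(x$included), " included for CN comparison)\n", sep = "")
  invisible(x)
}

#' Toy genome used in examples and simulations
#'
#' A small multi-chromosome genome (default 10 Mb over four autosomes and
#' chrX) on which whole-cohort simulation and base-level comparison run in
#' seconds. Not a subset of any real assembly.
#'
#' @param scale multiplier applied to all chromosome lengths.
#' @return A [genome_model()].
#' @export
toy_genome <- function(scale = 1) {
  genome_model(
    chromosomes = c("chr1", "chr2", "chr3", "chr4", "chrX", "chrY"),
    lengths = round(scale * c(3e6, 2.5e6, 2e6, 1.5e6, 1e6, 5e5)),
    included = c("chr1", "chr2", "chr3", "chr4", "chrX")
  )
}
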