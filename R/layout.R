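#' Genome layout
#'
#' A minimal description of an assembly: chromosome names and lengths.
#' Used as the denominator for per-chromosome rate normalization and as the
#' coordinate frame for the simulator.
#'
#' @param chromosome character vector of unique chromosome names
#' @param length positive integer vector of chromosome lengths (bp)
#' @return a `data.frame` with columns `chromosome`, `length`
#' @export
genome_layout <- function(chromosome, length) {
  chromosome <- as.character(chromosome)
  if (anyDuplicated(chromosome)) {
    stop("chromosome names must be unique")
  }
  if (length(chromosome) != length(length)) {
    stop("chromosome and length must have equal length")
  }
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  data.frame(chromosome = chromosome, length = length,
             stringsAsFactors = FALSE)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosome)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  layout$length[i]
}
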