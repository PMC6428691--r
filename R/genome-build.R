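#' Construct a genome build
#'
#' A genome build is the coordinate frame every windowed scan and breakpoint
#' simulation operates on: an ordered set of chromosomes with 1-based
#' inclusive start and end coordinates. Sex chromosomes are retained but
#' flagged so autosome-only analyses (e.g. the genome-wide LOH fraction)
#' can exclude them.
#'
#' @param chrom character vector of unique chromosome names, in order.
#' @param end integer-like vector of chromosome end coordinates (bp).
#' @param start start coordinate of each chromosome; defaults to 1.
#' @param sex character vector naming the sex chromosomes among `chrom`.
#'
#' @return A `data.frame` of class `genome_build` with columns
#'   `chrom`, `start`, `end`, `is_sex`.
#' @export
#' @examples
#' genome_build(c("1", "2"), c(2e8, 1.5e8))
genome_build <- function(chrom, end, start = 1L,
                         sex = c("X", "Y", "chrX", "chrY")) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  end <- as.numeric(end)
  start <- rep_len(as.numeric(start), length(chrom))
  if (length(end) != length(chrom)) stop("`chrom` and `end` lengths differ")
  if (any(!is.finite(end)) || any(end <= start))
    stop("every chromosome must satisfy end > start")
  build <- data.frame(chrom = chrom, start = start, end = end,
                      is_sex = chrom %in% sex, stringsAsFactors = FALSE)
  class(build) <- c("genome_build", "data.frame")
  build
}

#' Reference human genome build (GRCh37 main chromosomes)
#'
#' Chromosome lengths of the GRCh37/hg19 primary assembly, the coordinate
#' frame used by allele-specific copy-number callers in this domain.
#'
#' @param include_sex keep chromosomes X and Y (default `TRUE`).
#' @return A [genome_build()] object.
#' @export
human_build <- function(include_sex = TRUE) {
  len <- c(`1` = 249250621, `2` = 243199373, `3` = 198022430,
           `4` = 191154276, `5` = 180915260, `6` = 171115067,
           `7` = 159138663, `8` = 146364022, `9` = 141213431,
           `10` = 135534747, `11` = 135006516, `12` = 133851895,
           `13` = 115169878, `14` = 107349540, `15` = 102531392,
           `16` = 90354753, `17` = 81195210, `18` = 78077248,
           `19` = 59128983, `20` = 63025520, `21` = 48129895,
           `22` = 51304566, X = 155270560, Y = 59373566)
  if (!include_sex) len <- len[!names(len) %in% c("X", "Y")]
  genome_build(names(len), unname(len))
}

#' Read a chromosome-length table
#'
#' Two-column tab-separated file (chromosome name, length in bp), the
#' conventional `.chrom.sizes` layout.
#'
#' @param path file path.
#' @return A [genome_build()] object.
#' @export
read_chrom_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_build(tab$chrom, tab$length)
}

chrom_length <- function(build, chrom) {
  i <- match(as.character(chrom), build$chrom)
  if (anyNA(i)) stop("chromosome(s) not in build: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  build$end[i] - build$start[i] + 1
}

stopifnot_build <- function(build) {
  if (!inherits(build, "genome_build")) stop("`build` must be a genome_build")
  invisible(build)
}
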