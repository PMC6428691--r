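#' The 40 copy-number segment categories
#'
#' Allele-specific segments are classified along three axes: zygosity
#' (heterozygous, LOH, homozygous deletion), total-copy-number class
#' (0-1 deleted, 2 neutral, 3-4 duplicated, >4 amplified) and segment size
#' (0-0.01, 0.01-0.1, 0.1-1, 1-10, >10 Mb). Not every combination exists:
#' a heterozygous segment has total copy number at least 2, and a
#' homozygous deletion has total 0, so the enumeration has exactly
#' 40 members — 20 LOH, 15 heterozygous and 5 homozygous-deletion
#' categories.
#'
#' @return Character vector of the 40 category labels in canonical order
#'   (heterozygous block, then LOH, then homozygous deletion; within each
#'   block by copy-number class then increasing size).
#' @export
#' @examples
#' length(cn_categories())  # 40
cn_categories <- function() {
  sizes <- .cn_size_bins$label
  lab <- function(zyg, cls)
    as.vector(t(outer(cls, sizes, function(c, s) paste(zyg, c, s, sep = ":"))))
  c(lab("het", c("neutral", "duplicated", "amplified")),
    lab("LOH", c("deleted", "neutral", "duplicated", "amplified")),
    lab("homdel", "deleted"))
}

# size bins in bp, half-open on the right: (lower, upper]
.cn_size_bins <- data.frame(
  label = c("0-0.01Mb", "0.01-0.1Mb", "0.1-1Mb", "1-10Mb", ">10Mb"),
  lower = c(0, 1e4, 1e5, 1e6, 1e7),
  upper = c(1e4, 1e5, 1e6, 1e7, Inf),
  stringsAsFactors = FALSE)

.cn_size_label <- function(len) {
  i <- findInterval(len, .cn_size_bins$lower + 1)  # (lower, upper] in bp
  .cn_size_bins$label[i]
}

.cn_class_label <- function(total) {
  ifelse(total <= 1, "deleted",
         ifelse(total == 2, "neutral",
                ifelse(total <= 4, "duplicated", "amplified")))
}

#' Classify copy-number segments into the 40 categories
#'
#' Zygosity is derived from the allele copies: homozygous deletion iff the
#' total is 0, LOH iff the minor allele is 0 with total >= 1, heterozygous
#' otherwise. Segment length is `end - start + 1` (1-based inclusive
#' coordinates) and size bins are half-open on the right, so a segment of
#' exactly 10,000 bp falls in the 0-0.01 Mb bin.
#'
#' @param seg segment catalog (see [read_segments()]).
#' @return Factor of category labels with levels [cn_categories()].
#' @export
classify_segments <- function(seg) {
  validate_segments(seg)
  total <- seg$n_major + seg$n_minor
  zyg <- ifelse(total == 0, "homdel", ifelse(seg$n_minor == 0, "LOH", "het"))
  lab <- paste(zyg, .cn_class_label(total),
               .cn_size_label(seg$end - seg$start + 1), sep = ":")
  factor(lab, levels = cn_categories())
}

#' Build the 40 x samples copy-number count matrix
#'
#' Rows follow [cn_categories()]; column `s` sums to the number of
#' segments of sample `s`.
#'
#' @param seg segment catalog for one or more samples.
#' @param samples optional sample ordering (defaults to order of
#'   appearance); samples without segments yield zero columns.
#' @return Integer matrix, categories x samples.
#' @export
build_cn_matrix <- function(seg, samples = unique(seg$sample)) {
  cat <- classify_segments(seg)
  m <- table(category = cat, sample = factor(seg$sample, levels = samples))
  m <- matrix(as.integer(m), nrow = nlevels(cat),
              dimnames = list(cn_categories(), samples))
  m
}
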