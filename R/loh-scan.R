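#' Cohort LOH recurrence scan in sliding windows
#'
#' Slides windows (default 1 Mb, stepped by 100 kb) across every
#' chromosome of the build and reports, per window, the fraction of
#' samples whose overlapping segments are all minor-allele 0 — i.e. every
#' covered base in the window has lost heterozygosity. Samples without
#' segment coverage in a window are excluded from that window's
#' denominator. Windows with a fraction above `high` are flagged
#' `recurrent-LOH`, below `low` `retained-heterozygosity`.
#'
#' @param seg cohort segment catalog.
#' @param build [genome_build()].
#' @param window,step window width and step in bp.
#' @param high,low flag boundaries on the LOH proportion.
#' @return `data.frame` with one row per window: `chrom`, `start`, `end`,
#'   `n_loh`, `n_covered`, `proportion`, `flag`.
#' @export
loh_recurrence_scan <- function(seg, build, window = 1e6, step = 1e5,
                                high = 0.8, low = 0.2) {
  stopifnot_build(build)
  validate_segments(seg)
  samples <- unique(seg$sample)
  out <- vector("list", nrow(build))
  for (ci in seq_len(nrow(build))) {
    w_start <- seq(build$start[ci], build$end[ci], by = step)
    w_end <- pmin(w_start + window - 1, build$end[ci])
    keep <- w_end > w_start          # truncated tail windows retained
    w_start <- w_start[keep]; w_end <- w_end[keep]
    nw <- length(w_start)
    n_cov <- integer(nw); n_loh <- integer(nw)
    segc <- seg[seg$chrom == build$chrom[ci], , drop = FALSE]
    for (s in samples) {
      ss <- segc[segc$sample == s, , drop = FALSE]
      if (!nrow(ss)) next
      o <- order(ss$start)
      st <- ss$start[o]; en <- ss$end[o]
      het <- cumsum(c(0L, ss$n_minor[o] > 0))
      first <- findInterval(w_start - 0.5, en) + 1L
      last <- findInterval(w_end + 0.5, st)
      covered <- last >= first
      loh <- covered & (het[pmin(last, length(st)) + 1L] -
                          het[pmax(first, 1L)]) == 0L
      n_cov <- n_cov + covered
      n_loh <- n_loh + (covered & loh)
    }
    prop <- ifelse(n_cov > 0, n_loh / n_cov, NA_real_)
    flag <- rep(NA_character_, nw)
    flag[!is.na(prop) & prop > high] <- "recurrent-LOH"
    flag[!is.na(prop) & prop < low] <- "retained-heterozygosity"
    out[[ci]] <- data.frame(chrom = build$chrom[ci], start = w_start,
                            end = w_end, n_loh = n_loh, n_covered = n_cov,
                            proportion = prop, flag = flag,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-sample genome-wide LOH fraction
#'
#' Length-weighted fraction of the covered autosomal genome whose minor
#' allele copy number is 0 with at least one copy remaining. Samples
#' above 50% are labelled `widespread-LOH`; above 90%, `near-haploid`.
#'
#' @param seg cohort segment catalog.
#' @param build [genome_build()]; sex chromosomes are excluded.
#' @param autosomes_only drop segments on flagged sex chromosomes
#'   (default `TRUE`).
#' @return `data.frame` with `sample`, `loh_fraction`, `label`.
#' @export
sample_loh_fraction <- function(seg, build = human_build(),
                                autosomes_only = TRUE) {
  stopifnot_build(build)
  validate_segments(seg)
  if (autosomes_only)
    seg <- seg[!seg$chrom %in% build$chrom[build$is_sex], , drop = FALSE]
  len <- seg$end - seg$start + 1
  total <- seg$n_major + seg$n_minor
  is_loh <- seg$n_minor == 0 & total >= 1
  samples <- unique(seg$sample)
  frac <- vapply(samples, function(s) {
    i <- seg$sample == s
    sum(len[i & is_loh]) / sum(len[i])
  }, numeric(1))
  label <- rep(NA_character_, length(frac))
  label[frac > 0.5] <- "widespread-LOH"
  label[frac > 0.9] <- "near-haploid"
  data.frame(sample = samples, loh_fraction = unname(frac), label = label,
             stringsAsFactors = FALSE)
}
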