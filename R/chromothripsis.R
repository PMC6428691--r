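#' Breakpoint-spacing randomness test (chromosome-level)
#'
#' One-sample Kolmogorov-Smirnov test of the inter-breakpoint distances
#' of a whole chromosome against the exponential distribution with mean
#' equal to the observed mean spacing. Chromothriptic chromosomes show a
#' strong departure from exponential spacing (clustering), so a small
#' p-value is the chromothripsis-indicative outcome. Computed once per
#' chromosome, not per window.
#'
#' @param pos breakpoint positions on one chromosome.
#' @return KS p-value, or `NA` when fewer than 2 breakpoints.
#' @export
ks_spacing_test <- function(pos) {
  pos <- sort(pos)
  d <- diff(pos)
  if (length(d) < 1L || mean(d) <= 0) return(NA_real_)
  suppressWarnings(stats::ks.test(d, "pexp", rate = 1 / mean(d)))$p.value
}

#' Join-type randomness test
#'
#' Chi-square goodness-of-fit of the `{HH, HT, TH, TT}` join counts in a
#' window against the uniform null `{0.25, 0.25, 0.25, 0.25}`. Random
#' joins are a chromothripsis hallmark, so the test *accepts* the null: a
#' large p-value (> 0.8 by convention) is indicative.
#'
#' @param counts named or unnamed vector of the four join counts.
#' @return Goodness-of-fit p-value; `NA` when there are no joins (the
#'   window then fails this test).
#' @export
join_type_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L) stop("need counts for the four join classes")
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  stat <- sum((counts - n / 4)^2 / (n / 4))
  stats::pchisq(stat, df = 3, lower.tail = FALSE)
}

#' Fragment-order randomness test (Monte Carlo)
#'
#' Breakpoints in a window are indexed by genomic position (ties broken
#' by input order); each rearrangement with both breakpoints in the
#' window contributes the separation of its two indices. The p-value is
#' the proportion of `n_sim` simulated index pairs (uniform over distinct
#' pairs) whose separation exceeds the observed mean separation. A
#' not-too-ordered configuration gives a large p-value; p > 0.8 is
#' indicative (more random than independent rearrangement would be).
#'
#' @param idx1,idx2 breakpoint indices of the window's rearrangement
#'   pairs.
#' @param n_breakpoints number of indexed breakpoints in the window.
#' @param n_sim Monte Carlo draws (default 1000).
#' @param seed integer seed.
#' @return Monte Carlo p-value; `NA` if no pair or fewer than 2
#'   breakpoints.
#' @export
order_mc_test <- function(idx1, idx2, n_breakpoints, n_sim = 1000L,
                          seed = 1L) {
  if (!length(idx1) || n_breakpoints < 2L) return(NA_real_)
  obs <- mean(abs(idx1 - idx2))
  set.seed(seed)
  a <- sample.int(n_breakpoints, n_sim, replace = TRUE)
  b <- sample.int(n_breakpoints - 1L, n_sim, replace = TRUE)
  b <- ifelse(b >= a, b + 1L, b)     # second index distinct from first
  mean(abs(a - b) > obs)
}

#' Sliding-window chromothripsis detection
#'
#' Scans each chromosome carrying more than `min_breakpoints` breakpoints
#' with sliding windows (default 3 Mb, stepped by 100 kb; windows at
#' chromosome ends are truncated, not dropped). Three randomness tests
#' are combined: chromosome-level breakpoint spacing
#' ([ks_spacing_test()], indicative when p < `ks_alpha`), join-type
#' uniformity in the window ([join_type_test()], indicative when
#' p > `accept_p`) and fragment order in the window ([order_mc_test()],
#' indicative when p > `accept_p`). Joins and order pairs count
#' rearrangements with both breakpoints inside the window. Windows where
#' at least two tests indicate chromothripsis are flagged, and
#' overlapping flagged windows are merged into calls; every call carries
#' the three p-values of its best window for review.
#'
#' @param rr rearrangement catalog for one sample (column `sample` must
#'   be constant).
#' @param build [genome_build()].
#' @param window,step window width and step (bp).
#' @param min_breakpoints chromosome inclusion threshold (strictly more
#'   than this many breakpoints).
#' @param ks_alpha,accept_p test thresholds.
#' @param n_sim,seed Monte Carlo settings for the order test.
#' @return `data.frame` of merged calls: `sample`, `chrom`, `start`,
#'   `end`, `ks_p`, `join_p`, `order_p`, `tests_passed`, `n_breakpoints`.
#' @export
detect_chromothripsis <- function(rr, build, window = 3e6, step = 1e5,
                                  min_breakpoints = 30L, ks_alpha = 0.05,
                                  accept_p = 0.8, n_sim = 1000L,
                                  seed = 1L) {
  stopifnot_build(build)
  if (length(unique(rr$sample)) > 1L)
    stop("detect_chromothripsis() works on one sample at a time")
  bp <- data.frame(chrom = c(rr$chrom1, rr$chrom2),
                   pos = c(rr$pos1, rr$pos2),
                   id = rep(seq_len(nrow(rr)), 2L),
                   orientation = rep(rr$orientation, 2L))
  calls <- NULL
  for (ci in seq_len(nrow(build))) {
    cb <- bp[bp$chrom == build$chrom[ci], , drop = FALSE]
    if (nrow(cb) <= min_breakpoints) {
      if (nrow(cb) > 0)
        message("chromosome ", build$chrom[ci], " skipped: ",
                nrow(cb), " breakpoint(s) <= ", min_breakpoints)
      next
    }
    ks_p <- ks_spacing_test(cb$pos)
    ks_hit <- !is.na(ks_p) && ks_p < ks_alpha
    w_start <- seq(build$start[ci], build$end[ci], by = step)
    w_end <- pmin(w_start + window - 1, build$end[ci])
    ok <- w_end > w_start
    w_start <- w_start[ok]; w_end <- w_end[ok]
    o <- order(cb$pos)
    pos_s <- cb$pos[o]; id_s <- cb$id[o]
    flagged <- NULL
    for (wi in seq_along(w_start)) {
      inside <- which(pos_s >= w_start[wi] & pos_s <= w_end[wi])
      if (length(inside) < 2L) next
      ids <- id_s[inside]
      both_in <- ids[duplicated(ids)]          # both breakpoints inside
      if (!length(both_in)) next
      both_in <- unique(both_in)
      jt <- table(factor(rr$orientation[both_in],
                         levels = c("HH", "HT", "TH", "TT")))
      join_p <- join_type_test(as.numeric(jt))
      # window-local indices of each pair's two breakpoints
      local <- seq_along(inside)
      i1 <- i2 <- integer(length(both_in))
      for (k in seq_along(both_in)) {
        hits <- local[id_s[inside] == both_in[k]]
        i1[k] <- hits[1]; i2[k] <- hits[2]
      }
      order_p <- order_mc_test(i1, i2, length(inside), n_sim = n_sim,
                               seed = seed + wi)
      hits <- ks_hit +
        (!is.na(join_p) && join_p > accept_p) +
        (!is.na(order_p) && order_p > accept_p)
      if (hits >= 2L)
        flagged <- rbind(flagged, data.frame(
          start = w_start[wi], end = w_end[wi], ks_p = ks_p,
          join_p = join_p, order_p = order_p, tests_passed = hits,
          n_breakpoints = length(inside)))
    }
    if (is.null(flagged)) next
    merged <- merge_windows(flagged)
    merged$sample <- rr$sample[1]
    merged$chrom <- build$chrom[ci]
    calls <- rbind(calls, merged)
  }
  if (is.null(calls))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), ks_p = numeric(),
                      join_p = numeric(), order_p = numeric(),
                      tests_passed = integer(), n_breakpoints = integer()))
  calls[, c("sample", "chrom", "start", "end", "ks_p", "join_p",
            "order_p", "tests_passed", "n_breakpoints")]
}

# union of overlapping flagged windows; keeps the strongest window's
# statistics for review
merge_windows <- function(w) {
  w <- w[order(w$start), , drop = FALSE]
  out <- NULL
  cur <- w[1, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1]) {
    if (w$start[i] <= cur$end + 1) {
      cur$end <- max(cur$end, w$end[i])
      if (w$tests_passed[i] > cur$tests_passed ||
          (w$tests_passed[i] == cur$tests_passed &&
             w$n_breakpoints[i] > cur$n_breakpoints)) {
        cur[, c("ks_p", "join_p", "order_p", "tests_passed",
                "n_breakpoints")] <-
          w[i, c("ks_p", "join_p", "order_p", "tests_passed",
                 "n_breakpoints")]
      }
    } else {
      out <- rbind(out, cur)
      cur <- w[i, , drop = FALSE]
    }
  }
  rbind(out, cur)
}

#' Cohort recurrence of chromothripsis calls in genomic bins
#'
#' Bins the genome (default 100 kb) and counts, per bin, the number of
#' samples with a chromothripsis call overlapping the bin.
#'
#' @param calls output of [detect_chromothripsis()] over a cohort (rows
#'   from several samples).
#' @param build [genome_build()].
#' @param bin bin width in bp.
#' @return `data.frame` with `chrom`, `start`, `end`, `n_samples`,
#'   restricted to bins with at least one overlapping call.
#' @export
chromothripsis_recurrence <- function(calls, build, bin = 1e5) {
  stopifnot_build(build)
  out <- NULL
  for (ci in seq_len(nrow(build))) {
    cc <- calls[calls$chrom == build$chrom[ci], , drop = FALSE]
    if (!nrow(cc)) next
    b_start <- seq(build$start[ci], build$end[ci], by = bin)
    b_end <- pmin(b_start + bin - 1, build$end[ci])
    n <- integer(length(b_start))
    for (s in unique(cc$sample)) {
      cs <- cc[cc$sample == s, , drop = FALSE]
      hit <- rep(FALSE, length(b_start))
      for (j in seq_len(nrow(cs)))
        hit <- hit | (b_start <= cs$end[j] & b_end >= cs$start[j])
      n <- n + hit
    }
    keep <- n > 0
    if (any(keep))
      out <- rbind(out, data.frame(chrom = build$chrom[ci],
                                   start = b_start[keep],
                                   end = b_end[keep],
                                   n_samples = n[keep],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_samples = integer())
  out
}
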