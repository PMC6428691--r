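#' The 32 rearrangement categories
#'
#' Rearrangements are classified by clustering status, type and size.
#' Deletions, tandem duplications and inversions take one of five size
#' bins (1-10 kb, 10-100 kb, 100 kb-1 Mb, 1-10 Mb, >10 Mb); translocations
#' carry no size bin because the distance between breakpoints on different
#' chromosomes is undefined. With the clustered/unclustered split this
#' yields 2 x (3 x 5 + 1) = 32 categories.
#'
#' @return Character vector of the 32 category labels in canonical order.
#' @export
sv_categories <- function() {
  sizes <- .sv_size_bins$label
  one <- c(as.vector(t(outer(c("deletion", "tandem-duplication", "inversion"),
                             sizes, paste, sep = ":"))),
           "translocation")
  c(paste("unclustered", one, sep = ":"), paste("clustered", one, sep = ":"))
}

.sv_size_bins <- data.frame(
  label = c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb"),
  lower = c(0, 1e4, 1e5, 1e6, 1e7),   # events < 1 kb stay in the first bin
  upper = c(1e4, 1e5, 1e6, 1e7, Inf),
  stringsAsFactors = FALSE)

.sv_size_label <- function(size) {
  .sv_size_bins$label[findInterval(size, .sv_size_bins$lower,
                                   left.open = TRUE)]
}

#' Flag clustered rearrangements by piecewise-constant segmentation
#'
#' Per sample and chromosome, breakpoints are sorted and their
#' inter-breakpoint distances segmented by a penalized piecewise-constant
#' fit (least squares on log10 distances, penalty `gamma` per additional
#' segment, at least `min_points` distances per segment). A rearrangement
#' is clustered iff either of its breakpoints is adjacent to a fitted
#' segment whose mean inter-breakpoint distance is below `threshold` times
#' the mean inter-breakpoint distance across the whole data set — the
#' data-set-wide reference (rather than a per-sample one) keeps samples
#' dominated by a single massive cluster from having no rearrangement
#' called clustered.
#'
#' @param rr rearrangement catalog (cohort-level).
#' @param gamma segmentation penalty on the log10 distance scale.
#' @param min_points minimum number of distances per fitted segment.
#' @param threshold clustered cutoff as a fraction of the data-set mean
#'   inter-breakpoint distance.
#' @return `rr` with its `clustered` column filled.
#' @export
flag_clustered <- function(rr, gamma = 25, min_points = 2, threshold = 0.1) {
  bp <- data.frame(sample = rep(rr$sample, 2L),
                   chrom = c(rr$chrom1, rr$chrom2),
                   pos = c(rr$pos1, rr$pos2),
                   id = rep(seq_len(nrow(rr)), 2L))
  key <- paste(bp$sample, bp$chrom, sep = "\r")
  groups <- split(seq_len(nrow(bp)), key)
  all_d <- unlist(lapply(groups, function(i) diff(sort(bp$pos[i]))),
                  use.names = FALSE)
  clustered <- rep(FALSE, nrow(rr))
  if (!length(all_d)) {              # no chromosome with >= 2 breakpoints
    rr$clustered <- clustered
    return(rr)
  }
  ref <- threshold * mean(all_d)
  for (i in groups) {
    if (length(i) < 2L) next         # single breakpoint: unclustered
    o <- i[order(bp$pos[i])]
    d <- diff(bp$pos[o])
    segs <- pcf_segments(log10(d + 1), gamma = gamma,
                         min_points = min_points)
    seg_mean <- vapply(segs, function(s) mean(d[s]), numeric(1))
    low <- segs[seg_mean < ref]
    if (!length(low)) next
    # breakpoint j is adjacent to distances j-1 and j
    hot_d <- unlist(low, use.names = FALSE)
    hot_bp <- unique(c(hot_d, hot_d + 1L))
    clustered[bp$id[o][hot_bp]] <- TRUE
  }
  rr$clustered <- clustered
  rr
}

#' Penalized piecewise-constant segmentation
#'
#' Exact dynamic-programming minimizer of the residual sum of squares plus
#' `gamma` per additional segment, with a minimum number of points per
#' segment. Used on log10 inter-breakpoint distances by
#' [flag_clustered()].
#'
#' @param y numeric vector.
#' @param gamma per-segment penalty.
#' @param min_points minimum points per segment (shorter inputs form one
#'   segment).
#' @return List of integer index vectors, one per segment, partitioning
#'   `seq_along(y)` in order.
#' @export
pcf_segments <- function(y, gamma = 25, min_points = 2) {
  n <- length(y)
  if (n < 2L * min_points) return(list(seq_len(n)))
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {            # cost of segment y[i..j]
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  best <- rep(Inf, n + 1L); best[1] <- -gamma   # first segment unpenalized
  back <- integer(n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - min_points + 1L)) {
      if (j - i + 1L < min_points) next
      if (i > 1L && i - 1L < min_points) next   # left part must be fillable
      cand <- best[i] + gamma + sse(i, j)
      if (cand < best[j + 1L]) { best[j + 1L] <- cand; back[j] <- i }
    }
  }
  segs <- list(); j <- n
  while (j >= 1L) {
    i <- back[j]
    segs <- c(list(i:j), segs)
    j <- i - 1L
  }
  segs
}

#' Classify rearrangements into the 32 categories
#'
#' Requires the `clustered` flag (see [flag_clustered()]). Intra-chromosomal
#' events are binned by `abs(pos2 - pos1)`; events smaller than 1 kb are
#' kept in the smallest bin and reported with a message rather than
#' dropped.
#'
#' @param rr rearrangement catalog with `clustered` filled.
#' @param map_insertion treat input type `"insertion"` as
#'   tandem-duplication (`TRUE`) or reject it (default: reject) — the
#'   canonical category set has no insertion class.
#' @return Factor with levels [sv_categories()].
#' @export
classify_svs <- function(rr, map_insertion = FALSE) {
  if (any(is.na(rr$clustered)))
    stop("clustered flag missing; run flag_clustered() first")
  type <- rr$type
  if (any(type == "insertion")) {
    if (!map_insertion)
      stop("type 'insertion' present; set map_insertion = TRUE to fold it ",
           "into tandem-duplication")
    type[type == "insertion"] <- "tandem-duplication"
  }
  size <- sv_size(rr)
  small <- which(!is.na(size) & size < 1e3)
  if (length(small))
    message(length(small), " event(s) smaller than 1 kb kept in the ",
            "smallest size bin")
  lab <- ifelse(type == "translocation", "translocation",
                paste(type, .sv_size_label(pmax(size, 1)), sep = ":"))
  lab <- paste(ifelse(rr$clustered, "clustered", "unclustered"), lab,
               sep = ":")
  factor(lab, levels = sv_categories())
}

#' Build the 32 x samples rearrangement count matrix
#'
#' @param rr rearrangement catalog with `clustered` filled.
#' @param samples optional sample ordering.
#' @inheritParams classify_svs
#' @return Integer matrix, categories x samples.
#' @export
build_sv_matrix <- function(rr, samples = unique(rr$sample),
                            map_insertion = FALSE) {
  cat <- classify_svs(rr, map_insertion = map_insertion)
  m <- table(category = cat, sample = factor(rr$sample, levels = samples))
  matrix(as.integer(m), nrow = nlevels(cat),
         dimnames = list(sv_categories(), samples))
}
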