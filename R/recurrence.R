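#' Fit the breakpoint null model from a cohort
#'
#' Empirical ingredients of the Monte Carlo null for recurrently
#' rearranged regions: `p`, the fraction of rearrangements whose
#' breakpoint partners share a chromosome; `mu`, the per-chromosome mean
#' distance between the two breakpoints of an intra-chromosomal
#' rearrangement (chromosomes without such events fall back to the
#' global mean); and the gamma
#' shape/scale of per-sample rearrangement counts, fitted by maximum
#' likelihood (`MASS::fitdistr`). Identical per-sample counts make the
#' gamma fit degenerate; the model then falls back to that fixed count
#' with a warning.
#'
#' @param rr cohort rearrangement catalog (>= 2 samples).
#' @param build [genome_build()].
#' @return Object of class `sv_null_model`: `p`, `mu` (named by
#'   chromosome), `shape`, `scale`, `fixed_count` (`NA` unless
#'   degenerate), `n_samples`.
#' @export
fit_sv_null <- function(rr, build) {
  stopifnot_build(build)
  if (length(unique(rr$sample)) < 2L) stop("need at least 2 samples")
  p <- mean(rr$chrom1 == rr$chrom2)
  intra <- rr$chrom1 == rr$chrom2
  d <- abs(rr$pos2 - rr$pos1)[intra]
  d_chrom <- rr$chrom1[intra]
  global <- if (length(d)) mean(d) else
    mean(build$end - build$start + 1) / 4
  mu <- vapply(build$chrom, function(ch) {
    di <- d[d_chrom == ch]
    if (length(di)) mean(di) else global
  }, numeric(1))
  names(mu) <- build$chrom
  counts <- as.numeric(table(factor(rr$sample,
                                    levels = unique(rr$sample))))
  shape <- scale <- NA_real_; fixed <- NA_real_
  if (stats::sd(counts) == 0) {
    warning("all per-sample counts identical; gamma ML degenerate, ",
            "using the fixed count")
    fixed <- counts[1]
  } else {
    fit <- tryCatch(MASS::fitdistr(counts, "gamma"), error = function(e) NULL)
    if (is.null(fit)) {
      warning("gamma ML did not converge; using method-of-moments")
      shape <- mean(counts)^2 / stats::var(counts)
      scale <- stats::var(counts) / mean(counts)
    } else {
      shape <- unname(fit$estimate["shape"])
      scale <- 1 / unname(fit$estimate["rate"])
    }
  }
  structure(list(p = p, mu = mu, shape = shape, scale = scale,
                 fixed_count = fixed,
                 n_samples = length(unique(rr$sample))),
            class = "sv_null_model")
}

#' @export
print.sv_null_model <- function(x, ...) {
  cat("sv_null_model: p(same chromosome) =", round(x$p, 3),
      if (is.na(x$fixed_count))
        paste0("; counts ~ Gamma(shape = ", signif(x$shape, 3),
               ", scale = ", signif(x$scale, 3), ")")
      else paste0("; fixed count ", x$fixed_count),
      "over", x$n_samples, "samples\n")
  invisible(x)
}

.bin_table <- function(build, bin) {
  out <- lapply(seq_len(nrow(build)), function(ci) {
    b_start <- seq(build$start[ci], build$end[ci], by = bin)
    data.frame(chrom = build$chrom[ci], start = b_start,
               end = pmin(b_start + bin - 1, build$end[ci]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$bin <- seq_len(nrow(out))
  out
}

.bin_index <- function(chrom, pos, build, bin) {
  n_bins <- ceiling((build$end - build$start + 1) / bin)
  offset <- c(0, cumsum(n_bins))[match(chrom, build$chrom)]
  offset + pmin(floor((pos - build$start[match(chrom, build$chrom)]) / bin),
                n_bins[match(chrom, build$chrom)] - 1) + 1
}

#' Count samples with clustered breakpoints per genomic bin
#'
#' Bins the genome (default 1 Mb) and counts, per bin, the samples with
#' more than one rearrangement breakpoint inside the bin — the observed
#' recurrence statistic.
#'
#' @param rr rearrangement catalog.
#' @param build [genome_build()].
#' @param bin bin width (bp).
#' @return `data.frame` with `chrom`, `start`, `end`, `bin`, `count`.
#' @export
bin_breakpoint_counts <- function(rr, build, bin = 1e6) {
  stopifnot_build(build)
  bins <- .bin_table(build, bin)
  keep <- c(rr$chrom1, rr$chrom2) %in% build$chrom
  chrom <- c(rr$chrom1, rr$chrom2)[keep]
  pos <- c(rr$pos1, rr$pos2)[keep]
  sample <- rep(rr$sample, 2L)[keep]
  idx <- .bin_index(chrom, pos, build, bin)
  sf <- factor(sample)
  code <- (as.integer(sf) - 1L) * nrow(bins) + idx
  tab <- tabulate(code, nbins = nlevels(sf) * nrow(bins))
  hot <- which(tab > 1L)                       # (sample, bin) with >1 bp
  bins$count <- tabulate(((hot - 1L) %% nrow(bins)) + 1L,
                         nbins = nrow(bins))
  bins
}

#' Simulate the breakpoint null model
#'
#' Runs `n_sim` Monte Carlo simulations of the fitted null: per
#' simulation, `n_samples` samples each receive a rounded
#' Gamma(shape, scale) number of rearrangements (or the fixed count for a
#' degenerate model) with breakpoint partners placed by the cohort
#' geometry — chromosomes drawn with length-weighted probability, a
#' second chromosome with probability `1 - p`, uniform inter-chromosomal
#' positions and Exp(mean `mu_c`) intra-chromosomal partner distances
#' (bounded redraws when the distance exceeds the chromosome). For every
#' simulation the recurrence statistic is recorded per bin.
#'
#' @param model [fit_sv_null()] output.
#' @param build [genome_build()].
#' @param n_sim number of simulations (default
#'   10,000, the full-scale analysis setting).
#' @param seed integer seed.
#' @param bin bin width (bp).
#' @return Integer matrix, bins x simulations, of samples with more than
#'   one breakpoint; bin metadata as attribute `bins`.
#' @export
simulate_sv_null <- function(model, build, n_sim = 10000L, seed = 1L,
                             bin = 1e6) {
  stopifnot_build(build)
  if (n_sim < 1L) stop("n_sim must be at least 1")
  set.seed(seed)
  bins <- .bin_table(build, bin)
  n_bins <- nrow(bins)
  x <- model$n_samples
  n_events <- if (is.na(model$fixed_count)) {
    pmax(0L, as.integer(round(stats::rgamma(n_sim * x, shape = model$shape,
                                            scale = model$scale))))
  } else rep(as.integer(round(model$fixed_count)), n_sim * x)
  unit <- rep(seq_len(n_sim * x), n_events)    # (sim, sample) id per event
  bp <- .sim_breakpoint_pairs(sum(n_events), model$p,
                              model$mu[build$chrom], build)
  unit <- unit[attr(bp, "keep")]               # drop skipped events
  idx <- c(.bin_index(bp$chrom1, bp$pos1, build, bin),
           .bin_index(bp$chrom2, bp$pos2, build, bin))
  code <- (rep(unit, 2L) - 1) * n_bins + idx
  code <- sort.int(code, method = "radix")
  r <- rle(code)
  hot <- r$values[r$lengths > 1L]              # (sim,sample,bin) with >1 bp
  sim_of <- ((hot - 1) %/% n_bins) %/% x + 1
  bin_of <- (hot - 1) %% n_bins + 1
  m <- matrix(0L, n_bins, n_sim)
  cnt <- tabulate((sim_of - 1) * n_bins + bin_of, nbins = n_bins * n_sim)
  m[] <- cnt
  attr(m, "bins") <- bins
  m
}

#' Monte Carlo recurrence test with bespoke q-values
#'
#' For each genomic bin with observed recurrence count `i`, the p-value
#' is `(m + 1) / (M + 1)` where `m` is the number of simulations whose
#' count in that bin exceeds `i` and `M` the number of simulations — the
#' add-one correction keeps p strictly positive. Q-values follow the
#' step-down formula `q_i = min_{i <= j} (M_p * pi0 * P_j / j)` over the
#' `M_p` ordered p-values, with `pi0 = min(1, (2 / M_p) * sum(P))`;
#' bins with `q` below `q_threshold` are significant.
#'
#' Bin counts are small integers, so simulations tie with the observation
#' often. With `ties = "strict"` (the default) `m` counts strict
#' exceedances, which is anti-conservative under ties;
#' `ties = "conservative"` counts `sims >= i`, giving a super-uniform
#' p-value. `randomized = TRUE` additionally reports the tie-broken
#' Monte Carlo p-value
#' `(#\{sim > i\} + U * (#\{sim = i\} + 1)) / (M + 1)`, which is exactly
#' uniform under the null and is the appropriate calibration diagnostic
#' for a discrete test.
#'
#' @param observed output of [bin_breakpoint_counts()].
#' @param sims bins x simulations matrix from [simulate_sv_null()]
#'   (identical binning).
#' @param q_threshold significance boundary on q (default 0.2).
#' @param ties `"strict"` (the method's defining formula) or `"conservative"`.
#' @param randomized also compute tie-broken p-values.
#' @param seed seed for the tie-breaking uniforms.
#' @return `observed` with columns `m`, `p`, `q`, `significant` (and
#'   optionally `p_randomized`) appended.
#' @export
recurrence_test <- function(observed, sims, q_threshold = 0.2,
                            ties = c("strict", "conservative"),
                            randomized = FALSE, seed = 1L) {
  ties <- match.arg(ties)
  if (nrow(observed) != nrow(sims))
    stop("observed and simulated binnings differ")
  M <- ncol(sims)
  if (M == 0L) stop("no simulations")
  m <- if (ties == "strict") rowSums(sims > observed$count)
       else rowSums(sims >= observed$count)
  p <- (m + 1) / (M + 1)
  out <- observed
  out$m <- m
  out$p <- p
  out$q <- mc_qvalues(p)
  out$significant <- out$q < q_threshold
  if (randomized) {
    set.seed(seed)
    m_strict <- rowSums(sims > observed$count)
    n_tie <- rowSums(sims == observed$count)
    out$p_randomized <- (m_strict + stats::runif(length(m_strict)) *
                           (n_tie + 1)) / (M + 1)
  }
  out
}

#' Step-down q-values for Monte Carlo p-values
#'
#' `q_i = min_{i <= j} (M * pi0 * P_j / j)` on the ordered p-values, with
#' `pi0 = min(1, (2 / M) * sum(P))` and `M` the number of tests.
#'
#' @param p numeric vector of p-values.
#' @return q-values in the input order.
#' @export
#' @examples
#' mc_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.002
mc_qvalues <- function(p) {
  Mp <- length(p)
  o <- order(p)
  ps <- p[o]
  pi0 <- min(1, (2 / Mp) * sum(ps))
  q_sorted <- rev(cummin(rev(Mp * pi0 * ps / seq_len(Mp))))
  q <- numeric(Mp)
  q[o] <- q_sorted
  q
}
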