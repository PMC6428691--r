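#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-cohort generator: cohort size,
#' expected segments per sample, the true copy-number signature matrix
#' and the Dirichlet concentration of its exposures, the gamma
#' distribution of per-sample rearrangement counts, the breakpoint-partner
#' geometry (probability `p_same_chrom` that both breakpoints share a
#' chromosome, mean intra-chromosomal partner distance `mu_distance`),
#' optional chromothriptic windows, and the whole-genome-duplication block
#' (true relative timing `t`, expected per-copy mutation count `lambda`,
#' purity, age, sequencing depth).
#'
#' @param seed default integer seed used by the simulators.
#' @param n_samples cohort size.
#' @param segments_per_sample expected copy-number segments per sample
#'   (Poisson mean).
#' @param signatures categories x signatures non-negative matrix of true
#'   copy-number signatures (defaults to [default_cn_signatures()]).
#' @param exposure_alpha Dirichlet concentration for true exposures.
#' @param sv_shape,sv_scale gamma shape/scale of per-sample rearrangement
#'   counts.
#' @param p_same_chrom probability that breakpoint partners share a
#'   chromosome.
#' @param mu_distance mean intra-chromosomal inter-breakpoint distance
#'   (bp).
#' @param chromothripsis `NULL`, or a `data.frame` with columns `sample`,
#'   `chrom`, `start`, `end`, `n_breakpoints` describing clustered windows
#'   to superimpose.
#' @param wgd_t true relative timing of the (first) WGD in `[0, 1]`.
#' @param wgd_t2 timing of a second WGD (`NA` for a single WGD).
#' @param lambda expected mutations per allele copy over the tumour's
#'   lifetime.
#' @param purity tumour purity in (0, 1].
#' @param age age at diagnosis (years).
#' @param depth simulated sequencing depth for binomial VAF noise.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 30L,
                       segments_per_sample = 500,
                       signatures = default_cn_signatures(),
                       exposure_alpha = rep(1, ncol(signatures)),
                       sv_shape = 2, sv_scale = 50,
                       p_same_chrom = 0.65, mu_distance = 5e6,
                       chromothripsis = NULL,
                       wgd_t = 0.5, wgd_t2 = NA, lambda = 1000,
                       purity = 0.7, age = 60, depth = 70) {
  signatures <- as.matrix(signatures)
  if (any(signatures < 0)) stop("signatures must be non-negative")
  if (any(colSums(signatures) == 0))
    stop("signature with all-zero column")
  if (length(exposure_alpha) != ncol(signatures))
    stop("exposure_alpha length must match the number of signatures")
  if (sv_shape <= 0 || sv_scale <= 0 || lambda <= 0 || mu_distance <= 0 ||
      segments_per_sample <= 0)
    stop("all rates must be positive")
  if (p_same_chrom < 0 || p_same_chrom > 1)
    stop("p_same_chrom must lie in [0, 1]")
  if (wgd_t < 0 || wgd_t > 1) stop("wgd_t must lie in [0, 1]")
  if (!is.na(wgd_t2) && (wgd_t2 < wgd_t || wgd_t2 > 1))
    stop("wgd_t2 must lie in [wgd_t, 1]")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 segments_per_sample = segments_per_sample,
                 signatures = sweep(signatures, 2, colSums(signatures), "/"),
                 exposure_alpha = exposure_alpha,
                 sv_shape = sv_shape, sv_scale = sv_scale,
                 p_same_chrom = p_same_chrom, mu_distance = mu_distance,
                 chromothripsis = chromothripsis,
                 wgd_t = wgd_t, wgd_t2 = wgd_t2, lambda = lambda,
                 purity = purity, age = age, depth = depth),
            class = "sim_config")
}

#' Three reference copy-number signatures for simulation
#'
#' Caricatures of processes seen in complex sarcoma genomes: a
#' whole-genome-duplication-like signature of large heterozygous
#' duplicated segments, an LOH signature of deleted and copy-neutral LOH
#' segments, and a focal signature of small amplifications and homozygous
#' deletions. Columns sum to 1 over the 40 categories of
#' [cn_categories()].
#'
#' @return 40 x 3 matrix.
#' @export
default_cn_signatures <- function() {
  cats <- cn_categories()
  W <- matrix(0, length(cats), 3,
              dimnames = list(cats, c("dupWGD", "LOH", "focal")))
  w <- function(zyg, cls, weights) {
    lab <- paste(zyg, cls, .cn_size_bins$label, sep = ":")
    stats::setNames(weights, lab)
  }
  # size mixtures lean small so a ~1000-segment profile occupies a
  # plausible fraction of the genome
  s1 <- c(w("het", "duplicated", c(2, 6, 9, 3, 0.5)),
          w("het", "neutral", c(1, 3, 4, 1, 0)))
  s2 <- c(w("LOH", "deleted", c(1, 4, 7, 2, 0.5)),
          w("LOH", "neutral", c(1, 3, 5, 1, 0)))
  s3 <- c(w("het", "amplified", c(4, 6, 3, 0.5, 0)),
          w("LOH", "amplified", c(2, 3, 1, 0, 0)),
          w("homdel", "deleted", c(3, 4, 2, 0, 0)))
  W[names(s1), 1] <- s1
  W[names(s2), 2] <- s2
  W[names(s3), 3] <- s3
  sweep(W, 2, colSums(W), "/")
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              ncol = length(alpha), byrow = TRUE)
  g / rowSums(g)
}

# allele copies consistent with a category label, one draw per segment
.draw_alleles <- function(zyg, cls, n) {
  pick <- function(choices) choices[sample.int(nrow(choices), n,
                                               replace = TRUE), , drop = FALSE]
  key <- paste(zyg, cls)
  choices <- switch(key,
    "homdel deleted" = cbind(0, 0),
    "LOH deleted" = cbind(1, 0),
    "LOH neutral" = cbind(2, 0),
    "LOH duplicated" = rbind(c(3, 0), c(4, 0)),
    "LOH amplified" = rbind(c(5, 0), c(6, 0), c(8, 0)),
    "het neutral" = cbind(1, 1),
    "het duplicated" = rbind(c(2, 1), c(2, 2), c(3, 1)),
    "het amplified" = rbind(c(4, 1), c(4, 2), c(3, 2), c(5, 3)),
    stop("unknown category: ", key))
  if (nrow(choices) == 1L)
    matrix(rep(choices, each = n), n) else pick(choices)
}

.draw_length <- function(bin, n) {
  i <- match(bin, .cn_size_bins$label)
  lower <- pmax(.cn_size_bins$lower[i], 999)      # at least 1 kb
  upper <- ifelse(is.finite(.cn_size_bins$upper[i]),
                  .cn_size_bins$upper[i], 2e7)    # cap the open top bin
  # log-uniform inside the bin: realistic size decay, integer length
  len <- floor(10^stats::runif(n, log10(lower), log10(upper))) + 1
  pmin(pmax(len, lower + 1), upper)
}

#' Simulate a copy-number segment cohort from known signature mixtures
#'
#' Per sample, true exposures are drawn from a Dirichlet distribution,
#' category counts from the exposure-weighted signature mixture
#' (multinomial with Poisson segment totals), and each count is
#' materialized as a concrete segment consistent with its category:
#' allele copies matching the zygosity and total-copy-number class, an
#' integer length inside the size bin, and a uniform position on a
#' uniformly chosen chromosome subject to per-sample non-overlap.
#'
#' @param cfg [sim_config()].
#' @param build [genome_build()] to place segments on (default
#'   [human_build()] autosomes).
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return List with `segments` (catalog `data.frame`), `exposures`
#'   (signatures x samples true exposures) and `counts` (categories x
#'   samples true multinomial draws).
#' @export
simulate_cn_catalog <- function(cfg, build = human_build(include_sex = FALSE),
                                seed = cfg$seed) {
  stopifnot_build(build)
  set.seed(seed)
  W <- cfg$signatures
  nsig <- ncol(W)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  expo <- t(.rdirichlet(cfg$n_samples, cfg$exposure_alpha))
  dimnames(expo) <- list(colnames(W), samples)
  counts <- matrix(0L, nrow(W), cfg$n_samples,
                   dimnames = list(rownames(W), samples))
  seg_list <- vector("list", cfg$n_samples)
  chr_len <- build$end - build$start + 1
  for (s in seq_len(cfg$n_samples)) {
    n_seg <- stats::rpois(1, cfg$segments_per_sample)
    mix <- as.vector(W %*% expo[, s])
    counts[, s] <- as.integer(stats::rmultinom(1, n_seg, mix))
    parts <- strsplit(rownames(W), ":", fixed = TRUE)
    lens <- integer(0); maj <- integer(0); mnr <- integer(0)
    for (ci in which(counts[, s] > 0)) {
      n <- counts[ci, s]
      p <- parts[[ci]]
      al <- .draw_alleles(p[1], p[2], n)
      lens <- c(lens, .draw_length(p[3], n))
      maj <- c(maj, al[, 1]); mnr <- c(mnr, al[, 2])
    }
    # place without overlap: retry on collision against placed intervals
    n <- length(lens)
    chrom <- character(n); start <- numeric(n)
    placed <- lapply(seq_len(nrow(build)), function(i) NULL)
    for (j in order(lens, decreasing = TRUE)) {
      ok <- FALSE
      for (try in 1:200) {
        ci <- sample.int(nrow(build), 1)
        if (chr_len[ci] <= lens[j]) next
        st <- build$start[ci] + floor(stats::runif(1, 0,
                                                   chr_len[ci] - lens[j]))
        iv <- placed[[ci]]
        if (is.null(iv) ||
            all(st + lens[j] - 1 < iv[, 1] | st > iv[, 2])) {
          placed[[ci]] <- rbind(iv, c(st, st + lens[j] - 1))
          chrom[j] <- build$chrom[ci]; start[j] <- st
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place segment without overlap; ",
                    "reduce segments_per_sample or enlarge the build")
    }
    seg_list[[s]] <- data.frame(sample = samples[s], chrom = chrom,
                                start = start, end = start + lens - 1,
                                n_major = maj, n_minor = mnr,
                                stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg_list)
  validate_segments(seg)
  list(segments = seg, exposures = expo, counts = counts)
}

# shared breakpoint-pair generator for the SV simulator and the Monte
# Carlo recurrence null: length-weighted chromosome choice, uniform
# inter-chromosomal breakpoints, exponential intra-chromosomal distances
.sim_breakpoint_pairs <- function(n, p_same, mu, build, max_retry = 20L) {
  if (n == 0L)
    return(data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric()))
  chr_len <- build$end - build$start + 1
  wt <- chr_len / sum(chr_len)
  intra <- stats::runif(n) < p_same
  chrom1 <- sample.int(nrow(build), n, replace = TRUE, prob = wt)
  chrom2 <- chrom1
  n_inter <- sum(!intra)
  if (n_inter) {
    c2 <- sample.int(nrow(build), n_inter, replace = TRUE, prob = wt)
    clash <- which(c2 == chrom1[!intra])
    while (length(clash)) {   # partners must differ for inter events
      c2[clash] <- sample.int(nrow(build), length(clash), replace = TRUE,
                              prob = wt)
      clash <- clash[c2[clash] == chrom1[!intra][clash]]
    }
    chrom2[!intra] <- c2
  }
  pos1 <- pos2 <- numeric(n)
  i <- which(!intra)
  pos1[i] <- build$start[chrom1[i]] +
    floor(stats::runif(length(i)) * chr_len[chrom1[i]])
  pos2[i] <- build$start[chrom2[i]] +
    floor(stats::runif(length(i)) * chr_len[chrom2[i]])
  keep <- rep(TRUE, n)
  i <- which(intra)
  if (length(i)) {
    mu_i <- rep_len(mu, nrow(build))[chrom1[i]]
    d <- stats::rexp(length(i), rate = 1 / mu_i)
    for (r in seq_len(max_retry)) {
      bad <- which(d >= chr_len[chrom1[i]])
      if (!length(bad)) break
      d[bad] <- stats::rexp(length(bad), rate = 1 / mu_i[bad])
    }
    bad <- d >= chr_len[chrom1[i]]
    if (any(bad)) {
      message("skipping ", sum(bad), " intra-chromosomal event(s) whose ",
              "partner distance exceeded the chromosome length")
      keep[i[bad]] <- FALSE
    }
    p1 <- build$start[chrom1[i]] +
      floor(stats::runif(length(i)) * (chr_len[chrom1[i]] - d))
    pos1[i] <- p1
    pos2[i] <- p1 + round(d)
  }
  res <- data.frame(chrom1 = build$chrom[chrom1], pos1 = pos1,
                    chrom2 = build$chrom[chrom2],
                    pos2 = pos2)[keep, , drop = FALSE]
  attr(res, "keep") <- keep
  res
}

#' Simulate a rearrangement cohort
#'
#' Per sample, the rearrangement count is a rounded Gamma(shape, scale)
#' draw; each rearrangement picks one or two chromosomes (two with
#' probability `1 - p_same_chrom`) with length-weighted probabilities.
#' Inter-chromosomal breakpoints are uniform on their chromosomes;
#' intra-chromosomal partners sit an Exp(mean `mu_distance`) apart. Join
#' orientations are uniform over `HH`, `HT`, `TH`, `TT`, and types follow
#' from geometry and orientation. Optional chromothriptic windows from
#' `cfg$chromothripsis` superimpose the configured number of breakpoints
#' uniformly inside each window, randomly paired, with uniform joins.
#'
#' @inheritParams simulate_cn_catalog
#' @param build [genome_build()].
#' @return List with `rearrangements` (catalog `data.frame`, extra column
#'   `chromothriptic` marking simulated shattering events) and
#'   `config` echo.
#' @export
simulate_sv_catalog <- function(cfg, build = human_build(),
                                seed = cfg$seed) {
  stopifnot_build(build)
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  out <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    n <- max(0L, round(stats::rgamma(1, shape = cfg$sv_shape,
                                     scale = cfg$sv_scale)))
    bp <- .sim_breakpoint_pairs(n, cfg$p_same_chrom, cfg$mu_distance, build)
    if (nrow(bp)) {
      bp$sample <- samples[s]
      bp$orientation <- sample(c("HH", "HT", "TH", "TT"), nrow(bp),
                               replace = TRUE)
      bp$chromothriptic <- FALSE
      out[[s]] <- bp
    }
  }
  rr <- do.call(rbind, out)
  ct <- cfg$chromothripsis
  if (!is.null(ct)) {
    extra <- vector("list", nrow(ct))
    for (i in seq_len(nrow(ct))) {
      nb <- 2L * (ct$n_breakpoints[i] %/% 2L)   # breakpoints come in pairs
      pos <- sort(floor(stats::runif(nb, ct$start[i], ct$end[i] + 1)))
      pair <- matrix(sample.int(nb), ncol = 2)  # random fragment joins
      extra[[i]] <- data.frame(chrom1 = ct$chrom[i], pos1 = pos[pair[, 1]],
                               chrom2 = ct$chrom[i], pos2 = pos[pair[, 2]],
                               sample = ct$sample[i],
                               orientation = sample(c("HH", "HT", "TH", "TT"),
                                                    nb / 2, replace = TRUE),
                               chromothriptic = TRUE,
                               stringsAsFactors = FALSE)
    }
    rr <- rbind(rr, do.call(rbind, extra))
  }
  if (is.null(rr)) rr <- data.frame(chrom1 = character(), pos1 = numeric(),
                                    chrom2 = character(), pos2 = numeric(),
                                    sample = character(),
                                    orientation = character(),
                                    chromothriptic = logical())
  swap <- rr$chrom1 == rr$chrom2 & rr$pos2 < rr$pos1
  tmp <- rr$pos1[swap]; rr$pos1[swap] <- rr$pos2[swap]; rr$pos2[swap] <- tmp
  cat <- rearrangement_catalog(rr$sample, rr$chrom1, rr$pos1, rr$chrom2,
                               rr$pos2, rr$orientation)
  cat$chromothriptic <- rr$chromothriptic
  list(rearrangements = cat, config = cfg)
}

#' Simulate SNVs under known whole-genome-duplication timing
#'
#' For each sample, mutations accrue with a constant per-copy Poisson
#' rate: with a single WGD at relative time `t`, duplicated regions carry
#' `N2 ~ Poisson(lambda * t)` mutations at multiplicity 2 (acquired
#' before doubling, hence on both copies) and `N1 ~ Poisson(2 * lambda *
#' (1 - t))` at multiplicity 1. With two WGDs at `t1 <= t2`, counts at
#' multiplicity 4, 2 and 1 follow `Poisson(lambda * t1)`,
#' `Poisson(2 * lambda * (t2 - t1))` and `Poisson(4 * lambda * (1 - t2))`.
#' SNVs are split evenly between the LOH-duplicated (2+0 / 4+0) and
#' balanced (2+2 / 4+4) eligible region types, and observed VAFs are
#' binomial reads at the configured depth around the expectation given
#' purity and local copy number.
#'
#' @inheritParams simulate_cn_catalog
#' @return List with `snvs` (one row per variant: `sample`, `vaf`,
#'   `t_depth`, region genotype `n_major`/`n_minor`/`n_tot`, and
#'   `true_multiplicity`) and `truth` (per-sample `t1`, `t2`, `lambda`,
#'   `purity`, `age`, `depth`).
#' @export
simulate_wgd_snvs <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  two_wgd <- !is.na(cfg$wgd_t2)
  t1 <- cfg$wgd_t; t2 <- if (two_wgd) cfg$wgd_t2 else NA
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  out <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    if (two_wgd) {
      n_mu <- c(stats::rpois(1, 4 * cfg$lambda * (1 - t2)),
                stats::rpois(1, 2 * cfg$lambda * (t2 - t1)),
                stats::rpois(1, cfg$lambda * t1))
      mult <- rep(c(1L, 2L, 4L), n_mu)
      balanced <- stats::runif(length(mult)) < 0.5
      n_major <- rep(4L, length(mult))
      n_minor <- ifelse(balanced, 4L, 0L)
    } else {
      n_mu <- c(stats::rpois(1, 2 * cfg$lambda * (1 - t1)),
                stats::rpois(1, cfg$lambda * t1))
      mult <- rep(c(1L, 2L), n_mu)
      balanced <- stats::runif(length(mult)) < 0.5
      n_major <- rep(2L, length(mult))
      n_minor <- ifelse(balanced, 2L, 0L)
    }
    n_tot <- n_major + n_minor
    f_exp <- cfg$purity * mult /
      (cfg$purity * n_tot + (1 - cfg$purity) * 2)
    reads <- stats::rbinom(length(mult), cfg$depth, f_exp)
    out[[s]] <- data.frame(sample = samples[s],
                           vaf = reads / cfg$depth,
                           t_depth = cfg$depth,
                           n_major = n_major, n_minor = n_minor,
                           n_tot = n_tot, true_multiplicity = mult,
                           stringsAsFactors = FALSE)
  }
  truth <- data.frame(sample = samples, t1 = t1,
                      t2 = if (two_wgd) t2 else NA_real_,
                      lambda = cfg$lambda, purity = cfg$purity,
                      age = cfg$age, depth = cfg$depth)
  list(snvs = do.call(rbind, out), truth = truth)
}
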