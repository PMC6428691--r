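#' Infer SNV multiplicity from VAF, purity and local copy number
#'
#' The multiplicity of a somatic SNV is the number of tumour chromosome
#' copies carrying it. Its expected variant allele fraction is
#' `rho * mu / (rho * n_tot + 2 * (1 - rho))` — diluted by the normal
#' diploid contaminant — so the most likely multiplicity is the integer
#' in `[0, n_major]` whose expected VAF is nearest the observed one
#' (`method = "vaf"`, the default; equivalent to bounded rounding of
#' `f * (rho * n_tot + 2 * (1 - rho)) / rho` with midpoints rounding
#' down). `method = "ratio"` instead minimizes the relative
#' criterion `|f * (rho * mu)^-1 * (rho * n_tot + 2 * (1 - rho)) - 1|`,
#' whose decision boundaries sit at `2 mu (mu + 1) / (2 mu + 1)`.
#'
#' @param f variant allele fraction(s) in `[0, 1]`.
#' @param purity tumour purity in (0, 1].
#' @param n_tot total tumour copy number at the SNV.
#' @param n_major major-allele tumour copy number (upper bound for the
#'   multiplicity).
#' @param method `"vaf"` (nearest expected VAF) or `"ratio"`
#'   (relative criterion in multiplicity-ratio space).
#' @return Integer multiplicities; 0 flags a sub-threshold variant.
#' @export
infer_multiplicity <- function(f, purity, n_tot, n_major,
                               method = c("vaf", "ratio")) {
  method <- match.arg(method)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(n_major < 1)) stop("n_major must be at least 1")
  n <- max(length(f), length(n_tot), length(n_major))
  f <- rep_len(f, n); n_tot <- rep_len(n_tot, n)
  n_major <- rep_len(n_major, n); purity <- rep_len(purity, n)
  c0 <- f * (purity * n_tot + 2 * (1 - purity)) / purity
  if (method == "vaf") {
    mu <- as.integer(ceiling(c0 - 0.5))        # midpoint rounds down
  } else {
    mu <- integer(n)
    for (i in seq_len(n)) {
      cand <- seq_len(n_major[i])
      mu[i] <- if (c0[i] == 0) 0L else
        cand[which.min(abs(c0[i] / cand - 1))]
    }
  }
  pmin(pmax(mu, 0L), as.integer(n_major))
}

#' Count whole-genome duplications from the major-allele mode
#'
#' The modal major-allele copy number, weighted by segment length,
#' separates diploid (mode 1, no WGD), tetraploid (mode 2, one WGD) and
#' octoploid-range genomes (mode above 2, two WGDs). A tie between modes
#' resolves to the larger mode with a warning.
#'
#' @param seg segment catalog of one sample.
#' @return Integer 0, 1 or 2.
#' @export
count_wgd <- function(seg) {
  validate_segments(seg)
  len <- seg$end - seg$start + 1
  w <- tapply(len, seg$n_major, sum)
  top <- as.numeric(names(w)[w == max(w)])
  if (length(top) > 1L)
    warning("tied major-allele modes (", paste(top, collapse = ", "),
            "); using the larger")
  mode_major <- max(top)
  if (mode_major <= 1) 0L else if (mode_major == 2) 1L else 2L
}

#' Relative timing of a single whole-genome duplication
#'
#' In regions with two major-allele copies and zero or two minor copies
#' (2+0, 2+2), mutations acquired before the doubling sit on both copies
#' (multiplicity 2, count `N2`) and later mutations on one (`N1`). With
#' a constant per-copy rate, `t = N2 / (N1 / 2 + N2)` places the WGD on
#' the 0-1 mutational clock.
#'
#' @param N1,N2 SNV counts at multiplicity 1 and 2 in eligible regions.
#' @return `t` in `[0, 1]`, or `NA` when `N1 + N2 == 0`.
#' @export
time_wgd1 <- function(N1, N2) {
  ifelse(N1 + N2 == 0, NA_real_, N2 / (N1 / 2 + N2))
}

#' Relative timing of two whole-genome duplications
#'
#' In 4+0 and 4+4 regions, multiplicity 4 marks mutations before the
#' first doubling (`N4`), multiplicity 2 mutations between the two
#' (`N2`) and multiplicity 1 late mutations (`N1`). With
#' `Delta = N4 + N2 / 2 + N1 / 4`, the two events time at
#' `t1 = N4 / Delta` and `t2 = (N4 + N2 / 2) / Delta`, so `t1 <= t2`.
#'
#' @param N1,N2,N4 multiplicity-class SNV counts.
#' @return Named numeric `c(t1, t2)`, `NA` when `Delta == 0`.
#' @export
time_wgd2 <- function(N1, N2, N4) {
  delta <- N4 + N2 / 2 + N1 / 4
  if (delta == 0) return(c(t1 = NA_real_, t2 = NA_real_))
  c(t1 = N4 / delta, t2 = (N4 + N2 / 2) / delta)
}

#' Bootstrap confidence intervals for WGD timing
#'
#' Percentile intervals from `B` resamples of the multiplicity set. For
#' a single WGD, multiplicities are drawn from the eligible 2+0/2+2
#' SNVs and [time_wgd1()] applied to each resample; for two WGDs, from
#' 4+0/4+4 SNVs with [time_wgd2()].
#'
#' @param mult integer vector of inferred multiplicities of the eligible
#'   SNVs.
#' @param two_wgd time two duplications (default `FALSE`).
#' @param B bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return For one WGD, named vector `c(lower, upper)`; for two, a 2 x 2
#'   matrix with rows `t1`, `t2`.
#' @export
bootstrap_timing_ci <- function(mult, two_wgd = FALSE, B = 1000L,
                                level = 0.95, seed = 1L) {
  if (!length(mult)) stop("need at least one eligible SNV")
  set.seed(seed)
  n <- length(mult)
  a <- c((1 - level) / 2, 1 - (1 - level) / 2)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  if (!two_wgd) {
    N1 <- colSums(matrix(mult[idx] == 1L, n, B))
    N2 <- colSums(matrix(mult[idx] == 2L, n, B))
    t <- time_wgd1(N1, N2)
    stats::quantile(t, a, na.rm = TRUE, names = FALSE) |>
      stats::setNames(c("lower", "upper"))
  } else {
    N1 <- colSums(matrix(mult[idx] == 1L, n, B))
    N2 <- colSums(matrix(mult[idx] == 2L, n, B))
    N4 <- colSums(matrix(mult[idx] == 4L, n, B))
    ts <- vapply(seq_len(B), function(b) time_wgd2(N1[b], N2[b], N4[b]),
                 numeric(2))
    rbind(t1 = stats::quantile(ts[1, ], a, na.rm = TRUE, names = FALSE),
          t2 = stats::quantile(ts[2, ], a, na.rm = TRUE,
                               names = FALSE)) |>
      `colnames<-`(c("lower", "upper"))
  }
}

#' Chronological timing from relative timing and age
#'
#' Scales the 0-1 mutational clock by the age at diagnosis under a
#' constant mutation rate (no acceleration is modelled, so estimates are
#' upper bounds on the real time): `rt = a * t` years of life, and the
#' event occurred `tbd = a - rt` years before diagnosis.
#'
#' @param t relative timing in `[0, 1]`.
#' @param age age at diagnosis in years.
#' @return `data.frame` with `rt` and `tbd` (years).
#' @export
real_time_timing <- function(t, age) {
  if (any(t < 0 | t > 1, na.rm = TRUE)) stop("t must lie in [0, 1]")
  if (any(age < 0)) stop("age must be non-negative")
  data.frame(rt = age * t, tbd = age - age * t)
}

#' Time a driver mutation relative to the WGD(s)
#'
#' Early mutations in duplicated regions appear on all duplicated
#' copies, so a driver's multiplicity places it on the WGD clock: with
#' one WGD (2+0/2+2 regions), multiplicity 2 is pre-WGD and 1 post-WGD;
#' with two WGDs (4+0/4+4), multiplicity 4 is pre-first, 2 between the
#' two and 1 post-second. Drivers outside eligible regions are not
#' timeable.
#'
#' @param mult inferred driver multiplicity.
#' @param n_major,n_minor region genotype at the driver.
#' @param n_wgd 1 or 2 duplications in the sample.
#' @return Character: `"pre-WGD"`, `"between-WGDs"`, `"post-WGD"` or
#'   `"not-timeable"`.
#' @export
time_driver <- function(mult, n_major, n_minor, n_wgd = 1L) {
  n <- max(length(mult), length(n_major), length(n_minor))
  mult <- rep_len(mult, n); n_major <- rep_len(n_major, n)
  n_minor <- rep_len(n_minor, n)
  out <- rep("not-timeable", n)
  if (n_wgd == 1L) {
    ok <- n_major == 2 & n_minor %in% c(0, 2)
    out[ok & mult == 2] <- "pre-WGD"
    out[ok & mult == 1] <- "post-WGD"
  } else if (n_wgd == 2L) {
    ok <- n_major == 4 & n_minor %in% c(0, 4)
    out[ok & mult == 4] <- "pre-WGD"
    out[ok & mult == 2] <- "between-WGDs"
    out[ok & mult == 1] <- "post-WGD"
  }
  out
}

#' Per-sample WGD timing from SNVs and region genotypes
#'
#' Convenience wrapper: infers multiplicities for SNVs annotated with
#' their region genotype, restricts to the eligible regions for the
#' requested number of duplications (2+0/2+2 for one, 4+0/4+4 for two),
#' counts the multiplicity classes, times the event(s), bootstraps the
#' confidence interval and converts to chronological time.
#'
#' @param snv table with columns `vaf`, `n_major`, `n_minor`, `n_tot`.
#' @param purity tumour purity.
#' @param age age at diagnosis (years); `NA` skips chronological
#'   estimates.
#' @param n_wgd 1 or 2.
#' @param B,seed bootstrap settings.
#' @return List with `n_wgd`, counts `N1`, `N2`, `N4`, `t` (named
#'   vector), `ci`, and chronological `rt`/`tbd` when `age` is given.
#' @export
time_sample_wgd <- function(snv, purity, age = NA, n_wgd = 1L,
                            B = 1000L, seed = 1L) {
  mult <- infer_multiplicity(snv$vaf, purity, snv$n_tot, snv$n_major)
  if (n_wgd == 1L) {
    ok <- snv$n_major == 2 & snv$n_minor %in% c(0, 2)
  } else {
    ok <- snv$n_major == 4 & snv$n_minor %in% c(0, 4)
  }
  mult <- mult[ok]
  N1 <- sum(mult == 1L); N2 <- sum(mult == 2L); N4 <- sum(mult == 4L)
  if (n_wgd == 1L) {
    t <- c(t1 = time_wgd1(N1, N2))
  } else {
    t <- time_wgd2(N1, N2, N4)
  }
  ci <- if (length(mult))
    bootstrap_timing_ci(mult, two_wgd = n_wgd == 2L, B = B, seed = seed)
  else NULL
  out <- list(n_wgd = n_wgd, N1 = N1, N2 = N2, N4 = N4, t = t, ci = ci)
  if (!is.na(age) && !anyNA(t)) {
    rt <- real_time_timing(t, age)
    out$rt <- rt$rt
    out$tbd <- rt$tbd
  }
  out
}
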