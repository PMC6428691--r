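#' Single non-negative matrix factorization fit
#'
#' Multiplicative-update factorization of a non-negative matrix `V`
#' (categories x samples) into `W H` with the Frobenius objective, from
#' one random initialization. Building block of [extract_signatures()].
#'
#' @param V non-negative numeric matrix.
#' @param rank factorization rank.
#' @param seed integer seed for the random initialization.
#' @param max_iter,tol iteration cap and relative-change stopping
#'   tolerance on the reconstruction error.
#' @return List with `W`, `H`, final relative Frobenius error `error`,
#'   iterations used.
#' @export
nmf_fit <- function(V, rank, seed = 1L, max_iter = 500L, tol = 1e-6) {
  if (any(V < 0)) stop("V must be non-negative")
  set.seed(seed)
  eps <- .Machine$double.eps
  n <- nrow(V); m <- ncol(V)
  scale0 <- sqrt(mean(V) / rank)
  W <- matrix(stats::runif(n * rank, 0, 2 * scale0), n, rank)
  H <- matrix(stats::runif(rank * m, 0, 2 * scale0), rank, m)
  vnorm <- sqrt(sum(V^2))
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2)) / vnorm
      if (is.finite(err_old) && abs(err_old - err) < tol * max(err, eps))
        break
      err_old <- err
    }
  }
  err <- sqrt(sum((V - W %*% H)^2)) / vnorm
  list(W = W, H = H, error = err, iterations = it)
}

.normalize_model <- function(W, H) {
  cs <- colSums(W)
  cs[cs == 0] <- 1
  list(W = sweep(W, 2, cs, "/"), H = sweep(H, 1, cs, "*"))
}

.consensus_metrics <- function(consensus, rank) {
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  cop <- suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
  if (!is.finite(cop)) cop <- 1  # degenerate: identical clusterings
  disp <- mean(4 * (consensus - 0.5)^2)
  cl <- stats::cutree(hc, k = min(rank, nrow(consensus) - 1L))
  sil <- if (length(unique(cl)) < 2L) 0 else {
    s <- cluster::silhouette(cl, d)
    v <- mean(s[, "sil_width"])
    if (is.finite(v)) v else 0
  }
  c(silhouette = sil, cophenetic = cop, dispersion = disp)
}

.run_rank <- function(V, rank, runs, seed, max_iter, tol) {
  m <- ncol(V)
  consensus <- matrix(0, m, m)
  best <- NULL
  for (r in seq_len(runs)) {
    fit <- nmf_fit(V, rank, seed = seed + 7919L * rank + r,
                   max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$error < best$error) best <- fit
    assign <- apply(fit$H, 2, which.max)
    consensus <- consensus + outer(assign, assign, "==")
  }
  consensus <- consensus / runs
  list(best = best, consensus = consensus,
       metrics = .consensus_metrics(consensus, rank))
}

.select_rank <- function(diag, rand_diag = NULL, shortlist_frac = 0.95) {
  crit <- c("silhouette", "cophenetic", "dispersion")
  short <- rep(TRUE, nrow(diag))
  for (cn in crit)
    short <- short & diag[[cn]] >= shortlist_frac * max(diag[[cn]])
  zbest <- function(idx) {
    z <- scale(as.matrix(diag[, crit]))
    z[!is.finite(z)] <- 0
    idx[which.max(rowMeans(z)[idx])]
  }
  if (is.null(rand_diag)) {
    # stability-only rule: smallest shortlisted rank, else best average
    # standardized score
    if (any(short)) return(diag$rank[which(short)[1]])
    return(diag$rank[zbest(seq_len(nrow(diag)))])
  }
  # overfitting control: rank k is sufficient once the step to k+1 gains
  # no more than the same step does on row-permuted data
  gain <- -diff(diag$error)
  gain_r <- -diff(rand_diag$error)
  admissible <- c(gain <= gain_r, TRUE)   # top rank admissible by default
  admissible[-length(admissible)] <- gain <= gain_r
  if (!any(admissible[-length(admissible)])) {
    # structure never exhausted within the candidate range
    return(diag$rank[length(admissible)])
  }
  admissible[length(admissible)] <- FALSE
  both <- which(admissible & short)
  if (length(both)) return(diag$rank[both[1]])
  diag$rank[zbest(which(admissible))]
}

#' Extract mutational-process signatures by consensus NMF
#'
#' Runs multiplicative-update NMF with multiple random restarts at each
#' candidate rank, summarizes run-to-run stability with consensus
#' clustering (mean silhouette width, cophenetic correlation of the
#' consensus matrix, dispersion), and factorizes row-permuted data as an
#' overfitting control. Rank selection combines both: a rank is
#' *admissible* once moving one rank deeper improves the reconstruction
#' error by no more than the same step does on the permuted control
#' (beyond that point extra signatures fit noise), and among admissible
#' ranks the smallest one within 5% of every stability criterion's
#' maximum is selected (else the admissible rank with the best average
#' standardized stability). Without the randomized control the
#' stability-only rule is used: smallest rank within 5% of every
#' criterion's maximum, else best average standardized score.
#'
#' @param counts non-negative categories x samples count matrix.
#' @param ranks candidate ranks (default 2 through 12).
#' @param runs random restarts per rank (default 1000; desk-scale analyses
#'   use fewer).
#' @param seed integer seed; restarts use a counter-based stream so runs
#'   are reproducible and independent.
#' @param max_iter,tol passed to [nmf_fit()].
#' @param randomized_control also factorize row-permuted data (default
#'   `TRUE`).
#' @return Object of class `signature_model`: normalized signatures `W`
#'   (columns sum to 1), exposures `H`, per-sample normalized exposures
#'   `exposures`, `rank`, `diagnostics` (per-rank metric table),
#'   `random_diagnostics` for the permuted control, and the consensus
#'   matrix of the selected rank.
#' @export
extract_signatures <- function(counts, ranks = 2:12, runs = 1000L,
                               seed = 1L, max_iter = 500L, tol = 1e-6,
                               randomized_control = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("counts matrix is all zero")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (runs < 2L) stop("need at least 2 runs per rank for a consensus")
  ranks <- ranks[ranks < ncol(counts)]
  fits <- lapply(ranks, function(k)
    .run_rank(counts, k, runs, seed, max_iter, tol))
  diag <- data.frame(rank = ranks,
                     t(vapply(fits, `[[`, numeric(3), "metrics")),
                     error = vapply(fits, function(f) f$best$error,
                                    numeric(1)))
  rand_diag <- NULL
  if (randomized_control) {
    set.seed(seed + 104729L)
    perm <- t(apply(counts, 1, sample))
    rfits <- lapply(ranks, function(k)
      .run_rank(perm, k, max(2L, runs %/% 4L), seed + 1L, max_iter, tol))
    rand_diag <- data.frame(rank = ranks,
                            t(vapply(rfits, `[[`, numeric(3), "metrics")),
                            error = vapply(rfits, function(f) f$best$error,
                                           numeric(1)))
  }
  rank <- .select_rank(diag, rand_diag)
  pick <- fits[[match(rank, ranks)]]
  nm <- .normalize_model(pick$best$W, pick$best$H)
  dimnames(nm$W) <- list(rownames(counts), paste0("S", seq_len(rank)))
  dimnames(nm$H) <- list(paste0("S", seq_len(rank)), colnames(counts))
  expo <- sweep(nm$H, 2, pmax(colSums(nm$H), .Machine$double.eps), "/")
  structure(list(W = nm$W, H = nm$H, exposures = expo, rank = rank,
                 diagnostics = diag, random_diagnostics = rand_diag,
                 consensus = pick$consensus,
                 degenerate = diag$error[1] < 1e-6,
                 categories = rownames(counts)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("signature_model: rank", x$rank, "over", length(x$categories),
      "categories,", ncol(x$H), "samples\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Refit signature exposures with iterative pruning
#'
#' Non-negative least-squares fit of a sample's category counts onto a
#' fixed set of column-normalized signatures, with iterative removal of
#' signatures whose normalized exposure falls below `cutoff` (refit after
#' each removal). This constrained refit reduces overfitting of exposures
#' relative to the free NMF loadings.
#'
#' @param W categories x signatures matrix (columns are normalized
#'   internally).
#' @param counts numeric vector of category counts, or a matrix with one
#'   sample per column.
#' @param cutoff minimum normalized exposure a signature must reach to be
#'   retained (default 0.06).
#' @return Normalized exposure vector summing to 1 (or all zero for an
#'   empty sample, with a warning), with the residual norm as attribute
#'   `residual`; for matrix input, a signatures x samples matrix.
#' @export
fit_exposures <- function(W, counts, cutoff = 0.06) {
  W <- as.matrix(W)
  W <- sweep(W, 2, pmax(colSums(W), .Machine$double.eps), "/")
  if (is.matrix(counts)) {
    out <- apply(counts, 2, fit_exposures, W = W, cutoff = cutoff)
    rownames(out) <- colnames(W)
    return(out)
  }
  v <- as.numeric(counts)
  k <- ncol(W)
  if (sum(v) == 0) {
    warning("zero count vector; returning all-zero exposures")
    return(structure(stats::setNames(numeric(k), colnames(W)), residual = 0))
  }
  active <- seq_len(k)
  repeat {
    x <- pracma::lsqnonneg(W[, active, drop = FALSE], v)$x
    p <- if (sum(x) > 0) x / sum(x) else x
    weak <- which(p < cutoff & p > 0)
    if (!length(weak) || length(active) == 1L) break
    active <- active[-weak[which.min(p[weak])]]  # drop weakest, refit
  }
  expo <- stats::setNames(numeric(k), colnames(W))
  expo[active] <- if (sum(x) > 0) x / sum(x) else x
  resid <- sqrt(sum((v - W[, active, drop = FALSE] %*% x)^2))
  structure(expo, residual = resid)
}

#' Shannon diversity of signature exposures
#'
#' `H = -sum(p_i log p_i)` over the signatures active in a sample, with
#' exposures normalized to sum to 1; only entries greater than zero enter
#' the sum. Quantifies how evenly a sample spreads over the signature set
#' (0 for a single active signature, log(n) for a uniform spread over n).
#'
#' @param exposures non-negative exposure vector.
#' @return Non-negative scalar diversity (natural log).
#' @export
#' @examples
#' shannon_diversity(c(0.25, 0.25, 0.25, 0.25))  # log(4)
shannon_diversity <- function(exposures) {
  if (any(exposures < 0)) stop("exposures must be non-negative")
  s <- sum(exposures)
  if (s == 0) return(0)
  p <- exposures[exposures > 0] / s
  -sum(p * log(p))
}

#' Cosine similarity between signature sets
#'
#' @param A,B matrices with signatures in columns over the same
#'   categories.
#' @return Matrix of cosine similarities, `ncol(A)` x `ncol(B)`.
#' @export
cosine_similarity <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  num <- crossprod(A, B)
  den <- outer(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  num / pmax(den, .Machine$double.eps)
}

#' Match extracted signatures to a reference set
#'
#' Greedy one-to-one assignment by decreasing cosine similarity; used to
#' compare an extracted model against known (e.g. simulated) signatures.
#'
#' @inheritParams cosine_similarity
#' @return `data.frame` with columns `extracted`, `reference`, `cosine`.
#' @export
match_signatures <- function(A, B) {
  cs <- cosine_similarity(A, B)
  res <- NULL
  while (nrow(cs) && ncol(cs)) {
    ij <- arrayInd(which.max(cs), dim(cs))
    res <- rbind(res, data.frame(
      extracted = rownames(cs)[ij[1]] %||% ij[1],
      reference = colnames(cs)[ij[2]] %||% ij[2],
      cosine = cs[ij[1], ij[2]]))
    cs <- cs[-ij[1], -ij[2], drop = FALSE]
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
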