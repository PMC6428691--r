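# small coordinate frames and catalog builders shared across tests

toy_build <- function() genome_build(c("1", "2", "3"), c(1.2e8, 1e8, 8e7))

one_chrom_build <- function(len = 1.5e8, chrom = "1")
  genome_build(chrom, len)

# simple intra-chromosomal rearrangement catalog on one chromosome
make_rr <- function(sample, pos1, pos2, chrom = "1", orientation = "HT") {
  rearrangement_catalog(sample, chrom, pos1, chrom, pos2,
                        rep_len(orientation, length(pos1)))
}

# constructed chromothriptic sample: background events plus a dense window
# with exactly uniform join types and random fragment pairing
make_chromothriptic_rr <- function(seed = 11, n_cluster = 40,
                                   win = c(9e7, 9.3e7)) {
  set.seed(seed)
  n_bg <- 15
  p1 <- sort(floor(stats::runif(n_bg, 1, 1.6e8)))
  p2 <- pmin(p1 + round(stats::rexp(n_bg, 1 / 4e6)), 1.79e8)
  pos <- sort(floor(stats::runif(n_cluster, win[1], win[2])))
  pair <- matrix(sample(n_cluster), ncol = 2)
  rearrangement_catalog(
    "S1", "5", c(p1, pmin(pos[pair[, 1]], pos[pair[, 2]])),
    "5", c(p2, pmax(pos[pair[, 1]], pos[pair[, 2]])),
    c(sample(c("HH", "HT", "TH", "TT"), n_bg, TRUE),
      rep(c("HH", "HT", "TH", "TT"), each = n_cluster / 8)))
}

# nested (concentric) deletions only: all-HT joins fail the join test in
# every window, and with no other breakpoints on the chromosome the
# cluster's spacings match the exponential fitted to their own mean, so
# the KS test stays quiet — at most one indicative test anywhere
make_nested_deletion_rr <- function(seed = 11, n = 20, win = c(9e7, 9.3e7)) {
  set.seed(seed)
  pos <- sort(floor(stats::runif(2 * n, win[1], win[2])))
  left <- pos[seq_len(n)]
  right <- rev(pos)[seq_len(n)]          # concentric pairing
  rearrangement_catalog("S1", "5", left, "5", right, rep("HT", n))
}
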