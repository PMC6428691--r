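snv_row <- function(...) {
  base <- list(sample = "A", chrom = "1", pos = 100, ref = "C", alt = "T",
               vaf = 0.3)
  extra <- list(...)
  as.data.frame(c(base[setdiff(names(base), names(extra))], extra),
                stringsAsFactors = FALSE)
}

test_that("somatic triage follows the six rules in order", {
  expect_equal(as.character(triage_somatic_snv(
    snv_row(hotspot = TRUE, cadd = 5))$tier), "High confidence")
  expect_equal(as.character(triage_somatic_snv(
    snv_row(germline_fraction = 0.02))$tier), "Unreliable")
  expect_equal(as.character(triage_somatic_snv(
    snv_row(blacklist = TRUE))$tier), "Unreliable")
  expect_equal(as.character(triage_somatic_snv(
    snv_row(silent = TRUE, exac = TRUE))$tier), "Silent-retained")
  expect_equal(as.character(triage_somatic_snv(
    snv_row(exac = TRUE, recurrent_patients = 3))$tier), "Unreliable")
  # recurrent in 2 patients, CADD 15, MODIFIER: Medium demoted to Low
  v <- triage_somatic_snv(snv_row(recurrent_patients = 2, cadd = 15,
                                  impact = "MODIFIER"))
  expect_equal(as.character(v$tier), "Low confidence")
  expect_equal(v$rules, "5:recurrent,6:demote")
  # private variant promoted by pathogenic clinsig
  expect_equal(as.character(triage_somatic_snv(
    snv_row(clinsig = "pathogenic"))$tier), "Medium confidence")
  # CADD exactly 20 leaves both tiers unchanged
  expect_equal(as.character(triage_somatic_snv(
    snv_row(recurrent_patients = 2, cadd = 20))$tier), "Medium confidence")
  expect_equal(as.character(triage_somatic_snv(
    snv_row(cadd = 20))$tier), "Low confidence")
})

test_that("triage is deterministic and independent of row order", {
  set.seed(6)
  tab <- do.call(rbind, lapply(1:40, function(i)
    snv_row(hotspot = i %% 7 == 0, silent = i %% 5 == 0,
            exac = i %% 3 == 0, recurrent_patients = sample(1:3, 1),
            cadd = sample(c(NA, 10, 25), 1),
            germline_fraction = sample(c(0, 0.02), 1))))
  perm <- sample(nrow(tab))
  v1 <- triage_somatic_snv(tab)
  v2 <- triage_somatic_snv(tab[perm, ])
  expect_equal(as.character(v2$tier), as.character(v1$tier)[perm])
  # audit: each triggered-rule trail is consistent with its tier
  final_rule <- sub(".*,", "", v1$rules)
  expect_true(all((v1$tier == "High confidence") ==
                    (final_rule == "1:hotspot")))
  expect_true(all((v1$tier == "Silent-retained") ==
                    (final_rule == "3:silent")))
})

test_that("germline pathogenicity needs damage, coding status and filter", {
  expect_true(triage_germline(snv_row(coding = TRUE, filter_pass = TRUE,
                                      impact = "HIGH", cadd = 35)))
  expect_true(triage_germline(snv_row(coding = TRUE, filter_pass = TRUE,
                                      cadd = 30)))
  expect_false(triage_germline(snv_row(coding = TRUE, filter_pass = TRUE,
                                       impact = "MODERATE", cadd = 29.9,
                                       clinsig = "benign")))
  expect_false(triage_germline(snv_row(coding = TRUE, filter_pass = FALSE,
                                       cadd = 40)))
  expect_false(triage_germline(snv_row(filter_pass = TRUE, cadd = 40)))
})

test_that("rearrangement functional classes follow the flag rules", {
  v <- classify_rearrangement_function(
    flag = c("in-frame", "single-intron", "truncating", "no-fusion",
             "no-fusion", "mystery"),
    gene = c("EWSR1", "X", "RB1", "Y", "TP53", "Z"),
    partner_gene = c("FLI1", NA, NA, NA, NA, NA),
    breakpoint_location = c(NA, NA, NA, "intergenic", "intronic", NA),
    in_utr = FALSE,
    tsg_genes = c("RB1", "TP53"),
    fusion_genes = "EWSR1", cancer_genes = c("FLI1", "EWSR1"))
  expect_equal(as.character(v$class),
               c("Fusion", "Unknown significance", "Disruptive", "Benign",
                 "Disruptive", "Unknown significance"))
  expect_equal(v$driver, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  # UTR disruptions in a TSG are not drivers
  u <- classify_rearrangement_function("truncating", gene = "RB1",
                                       in_utr = TRUE, tsg_genes = "RB1")
  expect_false(u$driver)
})

test_that("copy-number driver calls use the ploidy-scaled threshold", {
  seg5 <- data.frame(n_major = c(3, 4), n_minor = c(2, 2))  # min total 5
  expect_equal(call_cn_drivers(seg5, ploidy = 2, role = "oncogene")$call,
               "Amplification")                             # 5 > 2^1.3 * 2
  seg49 <- data.frame(n_major = 3, n_minor = 1)             # total 4 < 4.92
  expect_equal(call_cn_drivers(seg49, ploidy = 2, role = "oncogene")$call,
               "none")
  expect_equal(call_cn_drivers(data.frame(n_major = 0, n_minor = 0),
                               ploidy = 2, role = "TSG")$call,
               "Homozygous deletion")
  expect_equal(call_cn_drivers(data.frame(n_major = 2, n_minor = 0),
                               ploidy = 2, role = "TSG")$call, "LOH")
  expect_message(nc <- call_cn_drivers(data.frame()[0, ], 2, "TSG",
                                       gene = "RB1"), "no-call")
  expect_equal(nc$call, "no-call")
})

test_that("burden subgrouping uses the documented inclusive boundaries", {
  meta <- data.frame(sample = c("a", "b", "c", "d", "e"),
                     n_snv = c(28370, 5000, 5000, 15000, 14999),
                     n_rearrangement = c(68, 150, 50, 20, 100))
  cls <- classify_burden(meta, "wgs")$burden_class
  expect_equal(cls, c("mutHi-rearrLo", "mutLo-rearrHi", "mutLo-rearrLo",
                      "mutHi-rearrLo", "mutLo-rearrHi"))
  t <- classify_burden(data.frame(sample = c("x", "y"),
                                  n_snv = c(1100, 900)),
                       "targeted", covered_mb = 100)
  expect_equal(t$burden_class, c("tMutHi", "tMutLo"))
  meta$platform <- "targeted"
  expect_error(classify_burden(meta, "wgs"), "platform")
})

test_that("LOH recurrence scan flags proportions against its boundaries", {
  b <- genome_build("1", 5e6)
  seg_for <- function(samples, minor) {
    do.call(rbind, lapply(seq_along(samples), function(i)
      segment_catalog(samples[i], "1", 1, 5e6, 2, minor[i])))
  }
  all_loh <- loh_recurrence_scan(seg_for(c("a", "b", "c"), c(0, 0, 0)), b)
  expect_true(all(all_loh$proportion == 1))
  expect_true(all(all_loh$flag == "recurrent-LOH"))
  none <- loh_recurrence_scan(seg_for(c("a", "b", "c"), c(1, 1, 1)), b)
  expect_true(all(none$proportion == 0))
  expect_true(all(none$flag == "retained-heterozygosity"))
  half <- loh_recurrence_scan(seg_for(c("a", "b", "c", "d"), c(0, 0, 1, 1)),
                              b)
  expect_true(all(half$proportion == 0.5))
  expect_true(all(is.na(half$flag)))
  # a sample without coverage leaves the window's denominator
  seg <- rbind(segment_catalog("a", "1", 1, 5e6, 1, 0),
               segment_catalog("b", "1", 1, 1e6, 1, 1))
  sc <- loh_recurrence_scan(seg, b)
  expect_equal(sc$n_covered[sc$start > 1e6], rep(1, sum(sc$start > 1e6)))
  expect_equal(sc$proportion[sc$start > 1e6],
               rep(1, sum(sc$start > 1e6)))
})

test_that("genome LOH fraction is length-weighted with severity labels", {
  seg <- rbind(segment_catalog("hap", "1", 1, 1e8, 1, 0),
               segment_catalog("dip", "1", 1, 1e8, 1, 1),
               segment_catalog("mix", "1", c(1, 6e7 + 1), c(6e7, 1e8),
                               c(2, 2), c(0, 1)))
  f <- sample_loh_fraction(seg, human_build())
  expect_equal(f$loh_fraction[f$sample == "hap"], 1)
  expect_equal(f$loh_fraction[f$sample == "dip"], 0)
  expect_equal(f$loh_fraction[f$sample == "mix"], 0.6)
  expect_equal(f$label[f$sample == "hap"], "near-haploid")
  expect_equal(f$label[f$sample == "mix"], "widespread-LOH")
})
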