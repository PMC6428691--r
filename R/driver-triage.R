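.col <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
}

#' Rule-based triage of somatic SNVs
#'
#' Applies the six prioritization rules in their fixed order to each
#' variant. Expected (all optional) annotation columns: `hotspot`
#' (membership of a curated cancer hotspot database), `blacklist`
#' (problematic-region list), `unidirectional` (strand support on one
#' strand only), `germline_fraction` (fraction of germline reads carrying
#' the variant), `silent`, `exac` (population database membership),
#' `recurrent_patients` (number of patients carrying the variant),
#' `cadd`, `impact` (`HIGH`/`MODERATE`/`LOW`/`MODIFIER`), `clinsig`.
#' Missing annotations degrade to the least-assuming branch.
#'
#' Rules, in order: (1) hotspot-database members are High confidence;
#' (2) blacklist, unidirectional or >1.5% of germline reads means
#' Unreliable; (3) silent variants are retained under their own label;
#' (4) population-database members are Unreliable; (5) variants in more
#' than one patient are Medium confidence, otherwise Low; (6) Medium is
#' demoted to Low if CADD < 20 or impact is LOW/MODIFIER, and Low is
#' promoted to Medium if CADD > 20, impact is HIGH/MODERATE, or clinical
#' significance is pathogenic (CADD exactly 20 leaves the tier
#' unchanged).
#'
#' @param snv SNV table (see [read_snvs()]).
#' @return `data.frame` with `tier` (factor: High confidence, Medium
#'   confidence, Low confidence, Unreliable, Silent-retained) and
#'   `rules`, the comma-separated audit trail of triggered rules in
#'   application order.
#' @export
triage_somatic_snv <- function(snv) {
  n <- nrow(snv)
  hotspot <- isTRUE_v(.col(snv, "hotspot", FALSE))
  blacklist <- isTRUE_v(.col(snv, "blacklist", FALSE))
  unidir <- isTRUE_v(.col(snv, "unidirectional", FALSE))
  germ <- .col(snv, "germline_fraction", 0)
  germ[is.na(germ)] <- 0
  silent <- isTRUE_v(.col(snv, "silent", FALSE))
  exac <- isTRUE_v(.col(snv, "exac", FALSE))
  rec <- .col(snv, "recurrent_patients", 1)
  rec[is.na(rec)] <- 1
  cadd <- .col(snv, "cadd", NA_real_)
  impact <- toupper(as.character(.col(snv, "impact", NA_character_)))
  clinsig <- tolower(as.character(.col(snv, "clinsig", NA_character_)))
  tier <- character(n)
  rules <- vector("list", n)
  add <- function(i, tag) for (j in i) rules[[j]] <<- c(rules[[j]], tag)
  open <- rep(TRUE, n)
  i <- which(open & hotspot)
  tier[i] <- "High confidence"; add(i, "1:hotspot"); open[i] <- FALSE
  i <- which(open & (blacklist | unidir | germ > 0.015))
  tier[i] <- "Unreliable"; add(i, "2:artifact"); open[i] <- FALSE
  i <- which(open & silent)
  tier[i] <- "Silent-retained"; add(i, "3:silent"); open[i] <- FALSE
  i <- which(open & exac)
  tier[i] <- "Unreliable"; add(i, "4:population"); open[i] <- FALSE
  i <- which(open & rec > 1)
  tier[i] <- "Medium confidence"; add(i, "5:recurrent")
  i <- which(open & rec <= 1)
  tier[i] <- "Low confidence"; add(i, "5:private")
  demote <- open & tier == "Medium confidence" &
    ((!is.na(cadd) & cadd < 20) | (!is.na(impact) &
                                     impact %in% c("LOW", "MODIFIER")))
  promote <- open & tier == "Low confidence" &
    ((!is.na(cadd) & cadd > 20) |
       (!is.na(impact) & impact %in% c("HIGH", "MODERATE")) |
       (!is.na(clinsig) & clinsig == "pathogenic"))
  tier[demote] <- "Low confidence"; add(which(demote), "6:demote")
  tier[promote] <- "Medium confidence"; add(which(promote), "6:promote")
  data.frame(snv[, intersect(c("sample", "chrom", "pos", "ref", "alt"),
                             names(snv)), drop = FALSE],
             tier = factor(tier, levels = c(
               "High confidence", "Medium confidence", "Low confidence",
               "Unreliable", "Silent-retained")),
             rules = vapply(rules, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Germline pathogenicity triage
#'
#' A germline variant is flagged pathogenic iff it is coding (including
#' splice region), passed the population-database quality filter, and has
#' pathogenic clinical significance, high impact, or CADD >= 30. Missing
#' annotations default to the non-pathogenic branch.
#'
#' @param snv variant table with optional columns `coding`,
#'   `filter_pass`, `clinsig`, `impact`, `cadd`.
#' @return Logical vector.
#' @export
triage_germline <- function(snv) {
  coding <- isTRUE_v(.col(snv, "coding", FALSE))
  pass <- isTRUE_v(.col(snv, "filter_pass", FALSE))
  clinsig <- tolower(as.character(.col(snv, "clinsig", NA_character_)))
  impact <- toupper(as.character(.col(snv, "impact", NA_character_)))
  cadd <- .col(snv, "cadd", NA_real_)
  damaging <- (!is.na(clinsig) & clinsig == "pathogenic") |
    (!is.na(impact) & impact == "HIGH") |
    (!is.na(cadd) & cadd >= 30)
  coding & pass & damaging
}

#' Functional classification of rearrangements
#'
#' Maps a fusion-flag vocabulary to a functional class, in rule order:
#' UTR-UTR, single-intron or ambiguous flags are of Unknown significance;
#' frame-mismatched exon-intron fusions, same-gene events, truncating
#' events, intron-intergenic events and opposite-orientation intron-exon
#' events are Disruptive; events with no predicted fusion are Disruptive
#' when a breakpoint is intronic or exonic, otherwise Benign; in-frame
#' fusions are Fusions. Driver status additionally requires
#' tumour-suppressor membership for Disruptive events outside the UTR,
#' or, for Fusions, a known fusion gene whose partner is also a known
#' cancer gene. Unknown flags fall to Unknown significance.
#'
#' @param flag character vector of fusion flags: `"UTR-UTR"`,
#'   `"single-intron"`, `"ambiguous"`, `"frame-mismatch"`, `"same-gene"`,
#'   `"truncating"`, `"intron-intergenic"`, `"opposite-orientation"`,
#'   `"no-fusion"`, `"in-frame"`.
#' @param gene,partner_gene gene symbols at the two breakpoints (`NA`
#'   allowed).
#' @param breakpoint_location for `"no-fusion"` events: `"intronic"`,
#'   `"exonic"` or `"intergenic"`.
#' @param in_utr logical; breakpoint falls in a UTR.
#' @param tsg_genes,fusion_genes,cancer_genes character vectors of known
#'   tumour-suppressor, fusion and cancer genes (user-supplied lists).
#' @return `data.frame` with `class` (Fusion, Disruptive, Unknown
#'   significance, Benign) and logical `driver`.
#' @export
classify_rearrangement_function <- function(flag, gene = NA,
                                            partner_gene = NA,
                                            breakpoint_location = NA,
                                            in_utr = FALSE,
                                            tsg_genes = character(),
                                            fusion_genes = character(),
                                            cancer_genes = character()) {
  n <- length(flag)
  gene <- rep_len(gene, n); partner_gene <- rep_len(partner_gene, n)
  breakpoint_location <- rep_len(breakpoint_location, n)
  in_utr <- rep_len(isTRUE_v(in_utr), n)
  cls <- rep("Unknown significance", n)
  unknown <- c("UTR-UTR", "single-intron", "ambiguous")
  disruptive <- c("frame-mismatch", "same-gene", "truncating",
                  "intron-intergenic", "opposite-orientation")
  cls[flag %in% disruptive] <- "Disruptive"
  nofusion <- flag == "no-fusion"
  cls[nofusion & breakpoint_location %in% c("intronic", "exonic")] <-
    "Disruptive"
  cls[nofusion & !breakpoint_location %in% c("intronic", "exonic")] <-
    "Benign"
  cls[flag == "in-frame"] <- "Fusion"
  cls[flag %in% unknown] <- "Unknown significance"
  driver <- (cls == "Disruptive" & gene %in% tsg_genes & !in_utr) |
    (cls == "Fusion" & gene %in% fusion_genes &
       partner_gene %in% cancer_genes)
  data.frame(flag = flag, gene = gene,
             class = factor(cls, levels = c("Fusion", "Disruptive",
                                            "Unknown significance",
                                            "Benign")),
             driver = driver, stringsAsFactors = FALSE)
}

#' Gene-level copy-number driver calls
#'
#' Given the segments overlapping one gene: Amplification iff the minimum
#' total copy number across the gene exceeds `2^1.3` times the sample
#' ploidy and the gene is a known amplified oncogene; Homozygous deletion
#' iff any region within a tumour suppressor has allele-specific copy
#' number {0,0}; LOH iff any region within a tumour suppressor has minor
#' allele 0 with at least one copy remaining.
#'
#' @param segments segments overlapping the gene (columns `n_major`,
#'   `n_minor`).
#' @param ploidy sample ploidy.
#' @param role `"oncogene"` or `"TSG"`.
#' @param gene optional gene symbol for the report.
#' @return One-row `data.frame` with `gene`, `call` (Amplification,
#'   `Homozygous deletion`, LOH, none, no-call), `min_total`.
#' @export
call_cn_drivers <- function(segments, ploidy, role = c("oncogene", "TSG"),
                            gene = NA_character_) {
  role <- match.arg(role)
  if (is.null(segments) || nrow(segments) == 0) {
    message("no segment overlaps gene ", gene, "; no-call")
    return(data.frame(gene = gene, call = "no-call",
                      min_total = NA_real_, stringsAsFactors = FALSE))
  }
  total <- segments$n_major + segments$n_minor
  call <- "none"
  if (role == "oncogene" && min(total) > 2^1.3 * ploidy) {
    call <- "Amplification"
  } else if (role == "TSG") {
    if (any(total == 0)) call <- "Homozygous deletion"
    else if (any(segments$n_minor == 0 & total >= 1)) call <- "LOH"
  }
  data.frame(gene = gene, call = call, min_total = min(total),
             stringsAsFactors = FALSE)
}

#' Mutational/rearrangement burden subgrouping
#'
#' Whole-genome samples split into three classes: hypermutators with at
#' least 15,000 SNV/indel mutations (`mutHi-rearrLo`), and among the
#' remainder those with 100 or more rearrangements (`mutLo-rearrHi`)
#' versus the rest (`mutLo-rearrLo`). Targeted-panel samples use a
#' mutations-per-megabase boundary instead: more than 10 mutations/Mb is
#' `tMutHi`, otherwise `tMutLo`. The two schemes are never mixed for one
#' sample: a metadata `platform` column conflicting with the `platform`
#' argument is an error.
#'
#' @param meta sample metadata with `n_snv` and (for WGS)
#'   `n_rearrangement`.
#' @param platform `"wgs"` or `"targeted"`.
#' @param covered_mb footprint of the targeted panel in Mb (required for
#'   `platform = "targeted"`).
#' @return `data.frame` with `sample` and `burden_class`.
#' @export
classify_burden <- function(meta, platform = c("wgs", "targeted"),
                            covered_mb = NULL) {
  platform <- match.arg(platform)
  if ("platform" %in% names(meta) &&
      any(meta$platform != platform))
    stop("sample(s) annotated for the other platform scheme: ",
         paste(meta$sample[meta$platform != platform], collapse = ", "))
  if (platform == "wgs") {
    if (!all(c("n_snv", "n_rearrangement") %in% names(meta)))
      stop("WGS burden classification needs n_snv and n_rearrangement")
    cls <- ifelse(meta$n_snv >= 15000, "mutHi-rearrLo",
                  ifelse(meta$n_rearrangement >= 100,
                         "mutLo-rearrHi", "mutLo-rearrLo"))
  } else {
    if (is.null(covered_mb)) stop("targeted scheme needs covered_mb")
    cls <- ifelse(meta$n_snv / covered_mb > 10, "tMutHi", "tMutLo")
  }
  data.frame(sample = meta$sample, burden_class = cls,
             stringsAsFactors = FALSE)
}
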