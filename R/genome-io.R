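#' @title Catalog constructors and validators
#' @description Internal record invariants shared by readers and simulators.
#' @name catalogs
#' @keywords internal
NULL

#' Assemble and validate a copy-number segment catalog
#'
#' Segments are allele-specific: `n_major` and `n_minor` are the integer
#' copy numbers of the two parental alleles (major >= minor >= 0).
#' Coordinates are 1-based inclusive. Per sample and chromosome, segments
#' must not overlap.
#'
#' @param sample,chrom,start,end,n_major,n_minor vectors of equal length.
#' @return Validated `data.frame` with those six columns.
#' @export
segment_catalog <- function(sample, chrom, start, end, n_major, n_minor) {
  seg <- data.frame(sample = as.character(sample), chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    n_major = as.integer(n_major), n_minor = as.integer(n_minor),
                    stringsAsFactors = FALSE)
  validate_segments(seg)
  seg
}

validate_segments <- function(seg) {
  bad <- which(!is.finite(seg$start) | !is.finite(seg$end) |
                 seg$end < seg$start)
  if (length(bad))
    stop("invalid segment coordinates (end < start) at row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(is.na(seg$n_major) | is.na(seg$n_minor) |
                 seg$n_minor < 0 | seg$n_major < seg$n_minor)
  if (length(bad))
    stop("invalid allele copies (need n_major >= n_minor >= 0) at row(s): ",
         paste(bad, collapse = ", "))
  # non-overlap within sample x chromosome
  key <- paste(seg$sample, seg$chrom, sep = "\r")
  for (k in unique(key)) {
    i <- which(key == k)
    o <- i[order(seg$start[i])]
    if (length(o) > 1L && any(seg$start[o][-1] <= seg$end[o][-length(o)]))
      stop("overlapping segments for sample '", seg$sample[i[1]],
           "' chromosome '", seg$chrom[i[1]], "'")
  }
  invisible(seg)
}

#' Read / write allele-specific copy-number segments
#'
#' Tab-separated table with header columns `sample`, `chr`, `start`, `end`,
#' `nMajor`, `nMinor` (the segment-caller convention). Rows violating the
#' record invariants abort the read with their row numbers.
#'
#' @param path file path.
#' @param build optional [genome_build()]; when given, chromosomes absent
#'   from the build are dropped with a message (windowed scans only operate
#'   on build chromosomes).
#' @return `data.frame` with columns `sample`, `chrom`, `start`, `end`,
#'   `n_major`, `n_minor`.
#' @export
read_segments <- function(path, build = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "chr", "start", "end", "nMajor", "nMinor")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("segment file is missing column(s): ", paste(miss, collapse = ", "))
  seg <- segment_catalog(tab$sample, tab$chr, tab$start, tab$end,
                         tab$nMajor, tab$nMinor)
  if (!is.null(build)) {
    stopifnot_build(build)
    drop <- !(seg$chrom %in% build$chrom)
    if (any(drop)) {
      message("dropping ", sum(drop), " segment(s) on chromosomes absent ",
              "from the build")
      seg <- seg[!drop, , drop = FALSE]
    }
  }
  seg
}

#' @rdname read_segments
#' @param seg segment catalog as returned by [read_segments()].
#' @export
write_segments <- function(seg, path) {
  validate_segments(seg)
  out <- data.frame(sample = seg$sample, chr = seg$chrom,
                    start = format(seg$start, scientific = FALSE, trim = TRUE),
                    end = format(seg$end, scientific = FALSE, trim = TRUE),
                    nMajor = seg$n_major, nMinor = seg$n_minor)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a rearrangement catalog
#'
#' Each record is a breakpoint pair with a join orientation class
#' (`HH`, `HT`, `TH`, `TT`: the head/tail pairing of the two DNA ends).
#' `type` is `translocation` exactly when the chromosomes differ; for
#' intra-chromosomal events it is derived from the orientation when not
#' supplied (`HT` deletion-type, `TH` tandem-duplication-type, `HH`/`TT`
#' inversion-type).
#'
#' @param sample,chrom1,pos1,chrom2,pos2,orientation vectors of equal length.
#' @param type optional event types; derived where `NA`.
#' @param clustered optional logical flag (filled by [flag_clustered()]).
#' @return Validated `data.frame`.
#' @export
rearrangement_catalog <- function(sample, chrom1, pos1, chrom2, pos2,
                                  orientation, type = NA, clustered = NA) {
  rr <- data.frame(sample = as.character(sample),
                   chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                   chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                   orientation = as.character(orientation),
                   type = rep_len(as.character(type), length(sample)),
                   clustered = rep_len(as.logical(clustered), length(sample)),
                   stringsAsFactors = FALSE)
  bad <- !(rr$orientation %in% c("HH", "HT", "TH", "TT"))
  if (any(bad))
    stop("unknown join orientation at row(s): ",
         paste(which(bad), collapse = ", "))
  derived <- sv_type_from_orientation(rr$chrom1, rr$chrom2, rr$orientation)
  rr$type[is.na(rr$type)] <- derived[is.na(rr$type)]
  inter <- rr$chrom1 != rr$chrom2
  if (any(inter != (rr$type == "translocation")))
    stop("type must be 'translocation' iff the chromosomes differ; row(s): ",
         paste(which(inter != (rr$type == "translocation")), collapse = ", "))
  rr
}

#' Derive a rearrangement type from chromosomes and join orientation
#'
#' @param chrom1,chrom2 chromosome names of the two breakpoints.
#' @param orientation join class among `HH`, `HT`, `TH`, `TT`.
#' @return Character vector of event types.
#' @export
sv_type_from_orientation <- function(chrom1, chrom2, orientation) {
  type <- c(HH = "inversion", HT = "deletion",
            TH = "tandem-duplication", TT = "inversion")[orientation]
  type[chrom1 != chrom2] <- "translocation"
  unname(type)
}

#' Size of an intra-chromosomal rearrangement
#'
#' `abs(pos2 - pos1)`; `NA` for translocations, where the distance between
#' breakpoints is undefined.
#'
#' @param rr rearrangement catalog.
#' @return Numeric vector of sizes in bp.
#' @export
sv_size <- function(rr) {
  size <- abs(rr$pos2 - rr$pos1)
  size[rr$chrom1 != rr$chrom2] <- NA_real_
  size
}

# fixed BEDPE strand dialect: (+,+)=HH, (+,-)=HT, (-,+)=TH, (-,-)=TT
.strand_to_orient <- c(`++` = "HH", `+-` = "HT", `-+` = "TH", `--` = "TT")

#' Read / write rearrangements as BEDPE
#'
#' BEDPE is 0-based half-open; on read the interval starts gain 1 bp to
#' land in the package's 1-based inclusive convention, and writing reverses
#' the shift, so write-then-read is the identity. Strand pairs map to join
#' orientations as `(+,+)=HH`, `(+,-)=HT`, `(-,+)=TH`, `(-,-)=TT` (a
#' declared dialect; callers differ).
#'
#' @param path file path.
#' @return Rearrangement catalog `data.frame` (see
#'   [rearrangement_catalog()]).
#' @export
read_rearrangements <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  names(tab) <- sub("^#", "", names(tab))
  need <- c("chrom1", "start1", "chrom2", "start2", "strand1", "strand2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("BEDPE file is missing column(s): ", paste(miss, collapse = ", "))
  key <- paste0(tab$strand1, tab$strand2)
  bad <- !(key %in% names(.strand_to_orient))
  if (any(bad))
    stop("unknown strand symbol(s) at row(s): ",
         paste(which(bad), collapse = ", "))
  sample <- if ("sample" %in% names(tab)) tab$sample else
    if ("name" %in% names(tab)) tab$name else "sample1"
  clustered <- if ("clustered" %in% names(tab)) as.logical(tab$clustered) else NA
  type <- if ("type" %in% names(tab)) tab$type else NA
  rearrangement_catalog(sample, tab$chrom1, tab$start1 + 1,
                        tab$chrom2, tab$start2 + 1,
                        .strand_to_orient[key], type = type,
                        clustered = clustered)
}

#' @rdname read_rearrangements
#' @param rr rearrangement catalog.
#' @export
write_rearrangements <- function(rr, path) {
  orient_to_strand <- stats::setNames(names(.strand_to_orient),
                                      .strand_to_orient)
  s <- orient_to_strand[rr$orientation]
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  out <- data.frame(chrom1 = rr$chrom1, start1 = fmt(rr$pos1 - 1),
                    end1 = fmt(rr$pos1), chrom2 = rr$chrom2,
                    start2 = fmt(rr$pos2 - 1), end2 = fmt(rr$pos2),
                    name = rr$sample, score = ".",
                    strand1 = substr(s, 1, 1), strand2 = substr(s, 2, 2),
                    sample = rr$sample, type = rr$type,
                    clustered = rr$clustered)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write somatic SNV tables
#'
#' Annotated tab-separated layout with mandatory columns `sample`, `chr`,
#' `pos`, `ref`, `alt`, `vaf` and optional depth/annotation columns
#' (`t_depth`, `n_depth`, database membership flags, `cadd`, `impact`,
#' `clinsig`, `germline_fraction`, `unidirectional`, ...). Extra columns
#' are carried through untouched so triage rules can consume them.
#'
#' @param path file path.
#' @return `data.frame`, one row per variant.
#' @export
read_snvs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "chr", "pos", "ref", "alt", "vaf")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("SNV file is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(tab$vaf) | tab$vaf < 0 | tab$vaf > 1))
    stop("vaf must lie in [0, 1]")
  for (d in intersect(c("t_depth", "n_depth"), names(tab)))
    if (any(tab[[d]] < 0, na.rm = TRUE)) stop(d, " must be non-negative")
  names(tab)[names(tab) == "chr"] <- "chrom"
  tab
}

#' @rdname read_snvs
#' @param snv SNV table.
#' @export
write_snvs <- function(snv, path) {
  out <- snv
  names(out)[names(out) == "chrom"] <- "chr"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Tab-separated table with columns `sample`, `purity`, `ploidy`, `age`
#' and optional `n_snv`, `n_rearrangement` totals. Purity must lie in
#' (0, 1]; age must be non-negative.
#'
#' @param path file path.
#' @return `data.frame`, one row per sample.
#' @export
read_sample_meta <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample", "purity", "ploidy", "age")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$purity <= 0 | tab$purity > 1))
    stop("purity must lie in (0, 1]")
  if (any(tab$age < 0)) stop("age must be non-negative")
  tab
}
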