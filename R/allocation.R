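#' Per-sample locus count table
#'
#' Holds the raw evidence for one sample: how many decoy-mapped reads were
#' assigned to each genomic STR locus, how many could not be assigned (per
#' repeat unit), and the sample's median coverage used for normalization.
#'
#' @param sample_id Sample identifier.
#' @param assigned Named integer vector, `locus_id` -> read count.
#' @param unassigned Named integer vector, canonical unit -> read count.
#' @param median_coverage Median per-base depth of the sample (> 0).
#' @return An object of class `locus_counts`.
#' @export
locus_counts <- function(sample_id, assigned = integer(0),
                         unassigned = integer(0), median_coverage) {
  assigned <- as.integer(assigned) |> stats::setNames(names(assigned))
  unassigned <- as.integer(unassigned) |> stats::setNames(names(unassigned))
  if (any(assigned < 0) || any(unassigned < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (!is.numeric(median_coverage) || median_coverage <= 0) {
    stop("median_coverage must be positive", call. = FALSE)
  }
  structure(list(sample_id = sample_id, assigned = assigned,
                 unassigned = unassigned,
                 median_coverage = as.numeric(median_coverage)),
            class = "locus_counts")
}

#' @export
print.locus_counts <- function(x, ...) {
  cat("locus_counts for sample '", x$sample_id, "': ",
      length(x$assigned), " loci (", sum(x$assigned), " assigned reads), ",
      sum(x$unassigned), " unassigned reads, median coverage ",
      format(x$median_coverage), "\n", sep = "")
  invisible(x)
}

decoy_scan_flag <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isDuplicate = FALSE)
}

#' Count reads mapping to each STR decoy chromosome
#'
#' Counts primary, non-duplicate, non-supplementary alignments on every
#' contig named with the `STR-` decoy convention, keyed by repeat unit.
#' Decoys present in the header but receiving no reads report 0.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM aligned against a
#'   decoy-augmented reference.
#' @return Named integer vector, canonical unit -> read count.
#' @export
count_decoy_reads <- function(bam) {
  header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  decoy_names <- names(header)[is_decoy_name(names(header))]
  units <- vapply(decoy_names, decoy_unit, character(1), USE.NAMES = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(flag = decoy_scan_flag(),
                                         what = "rname"))[[1]]
  rname <- as.character(res$rname)
  on_decoy <- rname[is_decoy_name(rname)]
  counts <- stats::setNames(integer(length(units)), units)
  if (length(on_decoy) > 0) {
    tab <- table(vapply(on_decoy, function(x) sub("^STR-", "", x),
                        character(1), USE.NAMES = FALSE))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Extract decoy-read records with their mate positions
#'
#' One row per primary, non-duplicate, non-supplementary alignment on a
#' decoy chromosome, carrying the repeat unit (from the decoy name) and the
#' mate's mapping interval (0-based half-open; the mate span is taken as the
#' read's own query length, adequate for same-length paired-end data).
#'
#' @inheritParams count_decoy_reads
#' @return A `data.frame` with columns `read_name`, `unit`, `mate_chrom`,
#'   `mate_start`, `mate_end`, `mate_mapped`.
#' @export
decoy_hits <- function(bam) {
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = decoy_scan_flag(),
      what = c("qname", "rname", "flag", "mrnm", "mpos", "cigar")))[[1]]
  rname <- as.character(res$rname)
  keep <- is_decoy_name(rname)
  if (!any(keep)) return(hits_frame(0L))
  rname <- rname[keep]
  unit <- vapply(unique(rname), decoy_unit, character(1))[rname]
  mate_unmapped <- bitwAnd(res$flag[keep], 8L) != 0L
  mrnm <- as.character(res$mrnm)[keep]
  mpos <- res$mpos[keep]
  qw <- cigar_query_width(res$cigar[keep])
  qw[is.na(qw)] <- 150L
  mapped <- !mate_unmapped & !is.na(mrnm) & !is.na(mpos)
  data.frame(read_name = res$qname[keep], unit = unname(unit),
             mate_chrom = ifelse(mapped, mrnm, NA_character_),
             mate_start = ifelse(mapped, mpos - 1L, NA_integer_),
             mate_end = ifelse(mapped, mpos - 1L + qw, NA_integer_),
             mate_mapped = mapped, stringsAsFactors = FALSE)
}

hits_frame <- function(n) {
  data.frame(read_name = character(n), unit = character(n),
             mate_chrom = character(n), mate_start = integer(n),
             mate_end = integer(n), mate_mapped = logical(n),
             stringsAsFactors = FALSE)
}

# build decoy hits directly from an in-memory SAM record table (simulator
# output), bypassing BAM serialization; same filtering as decoy_hits()
hits_from_records <- function(records) {
  primary <- bitwAnd(records$flag, bitwOr(256L, bitwOr(2048L, 1024L))) == 0L
  mapped <- bitwAnd(records$flag, 4L) == 0L
  keep <- primary & mapped & is_decoy_name(records$rname)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) return(hits_frame(0L))
  unit <- vapply(unique(rec$rname), decoy_unit, character(1))[rec$rname]
  mate_unmapped <- bitwAnd(rec$flag, 8L) != 0L
  mate_chrom <- ifelse(rec$rnext == "=", rec$rname, rec$rnext)
  qw <- cigar_query_width(rec$cigar)
  qw[is.na(qw)] <- 150L
  mapped_mate <- !mate_unmapped & mate_chrom != "*"
  data.frame(read_name = rec$qname, unit = unname(unit),
             mate_chrom = ifelse(mapped_mate, mate_chrom, NA_character_),
             mate_start = ifelse(mapped_mate, rec$pnext - 1L, NA_integer_),
             mate_end = ifelse(mapped_mate, rec$pnext - 1L + qw,
                               NA_integer_),
             mate_mapped = mapped_mate, stringsAsFactors = FALSE)
}

#' Assign decoy reads to genomic STR loci via their mates
#'
#' A decoy-mapped read is assigned to the closest annotated locus on its
#' mate's chromosome with the same canonical repeat unit, provided the mate
#' maps within `max_dist` bp of that locus. Reads whose mate is unmapped,
#' itself on a decoy, or not near any same-unit locus are tallied as
#' unassigned per unit; total reads are conserved per unit.
#'
#' @param hits Decoy-read table from [decoy_hits()].
#' @param index Locus index from [build_locus_index()].
#' @param sample_id Sample identifier for the resulting table.
#' @param median_coverage Median coverage of the sample.
#' @param max_dist Maximum mate-to-locus gap in bp.
#' @return A [locus_counts] object.
#' @export
assign_reads_to_loci <- function(hits, index, sample_id = "sample",
                                 median_coverage = 100, max_dist = 500L) {
  assigned <- integer(0)
  unassigned <- integer(0)
  bump <- function(v, key) {
    if (is.na(match(key, names(v)))) v[key] <- 0L
    v[key] <- v[key] + 1L
    v
  }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    loc <- NULL
    if (isTRUE(h$mate_mapped) && !is_decoy_name(h$mate_chrom)) {
      loc <- nearest_matching_locus(index, h$mate_chrom, h$mate_start,
                                    h$mate_end, h$unit, max_dist = max_dist)
    }
    if (is.null(loc)) {
      unassigned <- bump(unassigned, h$unit)
    } else {
      assigned <- bump(assigned, loc$locus_id)
    }
  }
  locus_counts(sample_id, assigned = assigned, unassigned = unassigned,
               median_coverage = median_coverage)
}

regions_as_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1L,
                                          end = regions$end))
}

#' Extract complete read pairs overlapping STR regions
#'
#' Selects read pairs in which at least one mate aligns inside the given
#' extraction regions or is unmapped — the subset worth re-mapping against a
#' decoy-augmented reference. Reads without a primary mate record in the
#' file (unpaired) are discarded.
#'
#' @param bam Path to a BAM file (any sort order; read fully).
#' @param regions Region table from [expand_extraction_regions()].
#' @return A `data.frame` of SAM-like records (both mates of every kept
#'   pair), with columns `qname`, `flag`, `rname`, `pos`, `seq`, `qual`.
#' @export
extract_candidate_reads <- function(bam, regions) {
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = flag,
      what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")))[[1]]
  n <- length(res$qname)
  if (n == 0L) return(candidate_frame(0L))
  rname <- as.character(res$rname)
  unmapped <- bitwAnd(res$flag, 4L) != 0L
  in_region <- logical(n)
  if (nrow(regions) > 0 && any(!unmapped)) {
    w <- cigar_query_width(res$cigar)
    w[is.na(w)] <- 1L
    idx <- which(!unmapped)
    gr <- GenomicRanges::GRanges(rname[idx],
                                 IRanges::IRanges(start = res$pos[idx],
                                                  width = w[idx]))
    hit <- IRanges::overlapsAny(gr, regions_as_granges(regions))
    in_region[idx] <- hit
  }
  qualifies <- unmapped | in_region
  pair_size <- table(res$qname)
  complete <- names(pair_size)[pair_size == 2L]
  keep_pair <- tapply(qualifies, res$qname, any)
  selected <- res$qname %in% complete & keep_pair[res$qname]
  out <- data.frame(qname = res$qname, flag = res$flag, rname = rname,
                    pos = res$pos, seq = as.character(res$seq),
                    qual = as.character(res$qual), stringsAsFactors = FALSE)
  out <- out[selected, , drop = FALSE]
  out[order(out$qname, bitwAnd(out$flag, 128L)), , drop = FALSE]
}

candidate_frame <- function(n) {
  data.frame(qname = character(n), flag = integer(n), rname = character(n),
             pos = integer(n), seq = character(n), qual = character(n),
             stringsAsFactors = FALSE)
}

#' Write extracted read pairs as FASTQ
#'
#' Emits name-matched R1/R2 files from [extract_candidate_reads()] output
#' for external re-mapping.
#'
#' @param pairs Output of [extract_candidate_reads()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @return `c(r1_path, r2_path)`, invisibly.
#' @export
write_pairs_fastq <- function(pairs, r1_path, r2_path) {
  is_r2 <- bitwAnd(pairs$flag, 128L) != 0L
  fq <- function(d) {
    as.vector(rbind(paste0("@", d$qname), d$seq, "+", d$qual))
  }
  writeLines(fq(pairs[!is_r2, , drop = FALSE]), r1_path)
  writeLines(fq(pairs[is_r2, , drop = FALSE]), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Median per-base coverage of a sample
#'
#' Estimates the sample's median depth by piling up reads at a deterministic
#' grid of single-base positions (every `stride` bases), over either the
#' supplied target regions or the full length of every non-decoy contig.
#' Secondary, supplementary and duplicate alignments are excluded. A strided
#' grid matches the precision of the streaming estimators used in practice
#' while remaining exactly reproducible.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param target Optional region table (`chrom`, `start`, `end`, 0-based
#'   half-open) restricting the estimate, e.g. an exome target.
#' @param stride Grid spacing in bp.
#' @return Median depth (numeric).
#' @export
median_coverage <- function(bam, target = NULL, stride = 1000L) {
  header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  contigs <- header[!is_decoy_name(names(header))]
  if (is.null(target)) {
    target <- data.frame(chrom = names(contigs), start = 0L,
                         end = as.integer(contigs),
                         stringsAsFactors = FALSE)
  }
  target <- target[target$end > target$start, , drop = FALSE]
  target <- target[target$chrom %in% names(contigs), , drop = FALSE]
  if (nrow(target) == 0L) stop("no usable positions in target",
                               call. = FALSE)
  pos_list <- mapply(function(s, e) seq.int(s + 1L, e, by = stride),
                     target$start, target$end, SIMPLIFY = FALSE)
  chrom <- rep(target$chrom, lengths(pos_list))
  pos <- unlist(pos_list, use.names = FALSE)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 0L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  res <- Rsamtools::pileup(bam,
                           scanBamParam = Rsamtools::ScanBamParam(
                             flag = decoy_scan_flag(), which = which),
                           pileupParam = pp)
  depth <- numeric(length(pos))
  if (nrow(res) > 0) {
    # which_label identifies the grid position each pileup row belongs to
    depth[as.integer(res$which_label)] <- res$count
  }
  stats::median(depth)
}
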