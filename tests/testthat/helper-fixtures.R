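# shared fixture builders; everything is generated in code at test time

# a small annotation spread over two chromosomes, units distinct enough
# that mate-based routing is unambiguous unless a test wants otherwise
make_test_loci <- function() {
  rbind(str_locus("chr1", 50000L, 50048L, "AGC", 16),
        str_locus("chr1", 120000L, 120060L, "AT", 30),
        str_locus("chr2", 80000L, 80044L, "AAAG", 11))
}

# write SAM records + header and convert to a sorted, indexed BAM; the
# temp dir must outlive this helper, hence the caller-scoped default
records_to_bam <- function(records, contigs,
                           dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  sam <- file.path(dir, "fixture.sam")
  write_sam(records, contigs, sam)
  sam_to_bam(sam)
}

# one mapped single-end-style record (enough for counting/pileup fixtures)
rec <- function(qname, flag, rname, pos, cigar = "150M", rnext = "*",
                pnext = 0L, seq = strrep("A", 150)) {
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = 60L, cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext), tlen = 0L,
             seq = seq, qual = strrep("I", nchar(seq)),
             stringsAsFactors = FALSE)
}

# decoy-hit rows built directly (unit tests of the allocation logic)
make_hits <- function(unit, mate_chrom, mate_start, mate_end,
                      mate_mapped = TRUE) {
  n <- max(length(unit), length(mate_chrom), length(mate_start))
  data.frame(read_name = sprintf("r%03d", seq_len(n)), unit = unit,
             mate_chrom = mate_chrom, mate_start = mate_start,
             mate_end = mate_end, mate_mapped = mate_mapped,
             stringsAsFactors = FALSE)
}

# brute-force nearest same-unit locus: linear scan, used as oracle
brute_nearest <- function(loci, chrom, pos_start, pos_end, unit,
                          max_dist = 500L) {
  best <- NULL
  best_gap <- Inf
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    if (l$chrom != chrom || l$unit != unit) next
    gap <- max(0L, l$start - pos_end, pos_start - l$end)
    if (gap > max_dist) next
    if (gap < best_gap || (gap == best_gap && l$start < best$start)) {
      best <- l
      best_gap <- gap
    }
  }
  best
}
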