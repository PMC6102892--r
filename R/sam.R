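# In-memory SAM records are plain data.frames with the eleven mandatory
# columns (qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
# qual); pos/pnext are 1-based as in SAM text. The simulator emits these and
# the writers below serialize them.

sam_record_frame <- function(n = 0L) {
  data.frame(qname = character(n), flag = integer(n), rname = character(n),
             pos = integer(n), mapq = integer(n), cigar = character(n),
             rnext = character(n), pnext = integer(n), tlen = integer(n),
             seq = character(n), qual = character(n),
             stringsAsFactors = FALSE)
}

#' Write SAM records to a file
#'
#' Serializes an in-memory record table (as produced by
#' [simulate_locus_reads()]) to SAM text with an `@HD`/`@SQ` header, sorted
#' by contig (header order) then position.
#'
#' @param records SAM record `data.frame`.
#' @param contigs Named integer vector of contig lengths, in header order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, contigs, path) {
  used <- unique(records$rname[records$rname != "*"])
  missing <- setdiff(used, names(contigs))
  if (length(missing) > 0) {
    stop("records reference contigs absent from header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ord <- order(match(records$rname, names(contigs)), records$pos,
               records$qname, records$flag)
  records <- records[ord, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                   as.integer(contigs)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, records$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a SAM file to a sorted, indexed BAM
#'
#' Thin wrapper over [Rsamtools::asBam()] used to stage simulator output for
#' the pipeline.
#'
#' @param sam_path SAM file.
#' @param bam_stub Output path without the `.bam` extension; defaults to the
#'   SAM path minus its extension.
#' @return Path to the BAM file.
#' @export
sam_to_bam <- function(sam_path, bam_stub = sub("\\.sam$", "", sam_path)) {
  Rsamtools::asBam(sam_path, destination = bam_stub, overwrite = TRUE,
                   indexDestination = TRUE)
}

# total query length implied by a cigar string (M/I/S/=/X consume query)
cigar_query_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
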