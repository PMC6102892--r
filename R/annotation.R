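#' Parse an STR annotation into locus records
#'
#' Reads a Tandem Repeats Finder style STR annotation and returns one record
#' per locus with its canonicalized repeat unit. Two dialects are supported:
#'
#' * `"bed"`: tab-separated with at least 5 columns
#'   `chrom, start, end, unit, ref_copies` (BED coordinates: 0-based,
#'   half-open).
#' * `"simpleRepeat"`: the UCSC `simpleRepeat.txt` table dump (leading `bin`
#'   column; coordinates in columns 2-4, copy number in column 7, consensus
#'   motif in column 17).
#'
#' Rows whose motif cannot be canonicalized (non-ACGT characters such as `N`,
#' or length over 6 bp) are skipped with a warning. All coordinates are kept
#' 0-based half-open throughout the package.
#'
#' @param path Path to the annotation file (plain text or gzipped).
#' @param dialect Column mapping, `"bed"` or `"simpleRepeat"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `unit`
#'   (canonical motif), `ref_copies`, and `locus_id`
#'   (`chrom:start-end:unit`).
#' @export
parse_str_bed <- function(path, dialect = c("bed", "simpleRepeat")) {
  dialect <- match.arg(dialect)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      ref_copies = numeric(0), locus_id = character(0),
                      stringsAsFactors = FALSE)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                      comment.char = "#", colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop(e)
    })
  if (is.null(tab) || nrow(tab) == 0L) return(empty)

  cols <- switch(dialect,
                 bed          = c(chrom = 1L, start = 2L, end = 3L,
                                  unit = 4L, copies = 5L),
                 simpleRepeat = c(chrom = 2L, start = 3L, end = 4L,
                                  unit = 17L, copies = 7L))
  if (ncol(tab) < max(cols)) {
    stop("annotation file has ", ncol(tab), " columns; dialect '", dialect,
         "' needs at least ", max(cols), call. = FALSE)
  }
  chrom <- tab[[cols["chrom"]]]
  start <- suppressWarnings(as.numeric(tab[[cols["start"]]]))
  end <- suppressWarnings(as.numeric(tab[[cols["end"]]]))
  copies <- suppressWarnings(as.numeric(tab[[cols["copies"]]]))

  bad_coord <- which(is.na(start) | is.na(end) | start != floor(start) |
                     end != floor(end) | start >= end)
  if (length(bad_coord) > 0) {
    stop("malformed coordinates at line ", bad_coord[1], " of ", path,
         call. = FALSE)
  }
  if (anyNA(copies)) {
    stop("non-numeric copy number at line ", which(is.na(copies))[1], " of ",
         path, call. = FALSE)
  }

  unit <- canonical_unit_vec(toupper(tab[[cols["unit"]]]))
  bad_unit <- is.na(unit)
  if (any(bad_unit)) {
    warning(sum(bad_unit), " annotation row(s) skipped: motif not ",
            "canonicalizable (non-ACGT or > 6 bp), e.g. line ",
            which(bad_unit)[1], call. = FALSE)
  }
  keep <- !bad_unit
  loci <- data.frame(chrom = chrom[keep], start = as.integer(start[keep]),
                     end = as.integer(end[keep]), unit = unit[keep],
                     ref_copies = copies[keep], stringsAsFactors = FALSE)
  loci$locus_id <- locus_id(loci)
  loci
}

locus_id <- function(loci) {
  paste0(loci$chrom, ":", loci$start, "-", loci$end, ":", loci$unit)
}

loci_as_granges <- function(loci) {
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(start = loci$start + 1L,
                                          end = loci$end))
}

#' Regions from which STR-informative reads are extracted
#'
#' Widens every STR locus by `flank` bases on each side (clamped at the
#' chromosome start) and merges overlapping or abutting intervals. Reads
#' aligned inside these regions, plus unmapped reads, are the candidates for
#' re-mapping against the decoy-augmented reference.
#'
#' @param loci Locus table from [parse_str_bed()].
#' @param flank Flank width in bp (default 800).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted and non-overlapping.
#' @export
expand_extraction_regions <- function(loci, flank = 800L) {
  stopifnot(flank >= 0)
  if (nrow(loci) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    loci$chrom,
    IRanges::IRanges(start = pmax(0L, loci$start - as.integer(flank)) + 1L,
                     end = loci$end + as.integer(flank)))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Index STR loci by chromosome and repeat unit
#'
#' Precomputes the per-(chromosome, unit) grouping used to route decoy reads
#' to their locus of origin.
#'
#' @param loci Locus table from [parse_str_bed()].
#' @return An opaque index object for [nearest_matching_locus()].
#' @export
build_locus_index <- function(loci) {
  key <- paste(loci$chrom, loci$unit, sep = "\r")
  structure(list(loci = loci, groups = split(seq_len(nrow(loci)), key)),
            class = "strexpand_locus_index")
}

# edge-to-edge gap between [a1,a2) and vectors of [b1,b2); 0 when overlapping
interval_gap <- function(a1, a2, b1, b2) {
  pmax(0L, b1 - a2, a1 - b2)
}

#' Closest STR locus with a matching repeat unit
#'
#' Among the annotated loci on `chrom` whose canonical unit equals `unit`,
#' returns the one whose edge-to-edge gap to the query interval is smallest,
#' provided that gap is at most `max_dist` (overlap counts as gap 0). Ties
#' are broken towards the smaller start coordinate. This implements the
#' mate-position rule: a decoy read is assigned to the closest same-unit
#' locus within `max_dist` (default 500 bp, which accommodates typical
#' fragment lengths) of its mate.
#'
#' @param index Index from [build_locus_index()].
#' @param chrom,pos_start,pos_end Query interval (0-based half-open).
#' @param unit Canonical repeat unit of the decoy read.
#' @param max_dist Maximum allowed gap in bp.
#' @return A one-row `data.frame` (a row of the locus table), or `NULL` when
#'   no same-unit locus lies within `max_dist`.
#' @export
nearest_matching_locus <- function(index, chrom, pos_start, pos_end, unit,
                                   max_dist = 500L) {
  stopifnot(inherits(index, "strexpand_locus_index"))
  idx <- index$groups[[paste(chrom, unit, sep = "\r")]]
  if (is.null(idx)) return(NULL)
  cand <- index$loci[idx, , drop = FALSE]
  gap <- interval_gap(pos_start, pos_end, cand$start, cand$end)
  ok <- gap <= max_dist
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  gap <- gap[ok]
  pick <- order(gap, cand$start)[1]
  cand[pick, , drop = FALSE]
}

#' Fraction of STR loci with a same-unit neighbor within a distance
#'
#' For every locus, asks whether at least one *other* locus on the same
#' chromosome with the same canonical repeat unit lies within `distance` bp
#' (edge-to-edge gap; overlapping loci count as distance 0). Close same-unit
#' pairs are the situations in which mate-based read allocation can pick the
#' wrong locus, so this statistic quantifies the risk of misallocation at a
#' given `max_dist` setting.
#'
#' @param loci Locus table from [parse_str_bed()].
#' @param distance Neighborhood radius in bp.
#' @return Fraction in \[0, 1\].
#' @export
proximity_fraction <- function(loci, distance) {
  if (nrow(loci) == 0L) stop("empty locus table", call. = FALSE)
  has_neighbor <- logical(nrow(loci))
  key <- paste(loci$chrom, loci$unit, sep = "\r")
  for (idx in split(seq_len(nrow(loci)), key)) {
    if (length(idx) < 2L) next
    ir <- IRanges::IRanges(start = loci$start[idx] + 1L, end = loci$end[idx])
    cnt <- IRanges::countOverlaps(ir, ir, maxgap = distance)
    has_neighbor[idx] <- cnt >= 2L
  }
  mean(has_neighbor)
}
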