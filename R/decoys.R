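#' Build the STR decoy chromosome set
#'
#' Each decoy chromosome is a pure tandem repeat of one canonical motif,
#' truncated to exactly `decoy_length` bases, and named `STR-<motif>`. Reads
#' made up mostly of repeat sequence preferentially align to these decoys
#' rather than to (or instead of failing to align near) the genomic locus;
#' the decoy name later identifies the repeat unit of such reads. The default
#' length of 2000 bp comfortably exceeds typical sequencing insert sizes.
#'
#' @param units Character vector of canonical motifs
#'   (see [enumerate_canonical_units()]).
#' @param decoy_length Length of every decoy sequence in bp.
#' @return A `data.frame` with columns `name`, `unit`, `sequence`.
#' @examples
#' d <- build_decoy_set(c("A", "AGC"), decoy_length = 10)
#' d$sequence
#' @export
build_decoy_set <- function(units, decoy_length = 2000L) {
  if (length(units) == 0L) {
    return(data.frame(name = character(0), unit = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  units <- vapply(units, validate_motif, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(units)) {
    stop("duplicate repeat units in decoy set: ",
         paste(unique(units[duplicated(units)]), collapse = ", "),
         call. = FALSE)
  }
  if (decoy_length < max(nchar(units))) {
    stop("decoy_length must be at least the longest unit length",
         call. = FALSE)
  }
  seqs <- vapply(units, function(u) {
    substr(strrep(u, ceiling(decoy_length / nchar(u))), 1L, decoy_length)
  }, character(1), USE.NAMES = FALSE)
  data.frame(name = paste0("STR-", units), unit = units, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Append STR decoy chromosomes to a reference genome
#'
#' Writes a FASTA containing every sequence of `reference_fasta` followed by
#' the decoy chromosomes, at a fixed line width. Existing output is
#' overwritten.
#'
#' @param reference_fasta Path to the reference genome FASTA.
#' @param decoys Decoy set from [build_decoy_set()].
#' @param out_fasta Output path.
#' @param width FASTA line width.
#' @return `out_fasta`, invisibly.
#' @export
augment_reference <- function(reference_fasta, decoys, out_fasta,
                              width = 70L) {
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  # keep only the sequence identifier (first whitespace-delimited token)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (nrow(decoys) > 0) {
    clash <- intersect(decoys$name, names(ref))
    if (length(clash) > 0) {
      stop("decoy name collides with reference sequence: ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
    dec <- Biostrings::DNAStringSet(decoys$sequence)
    names(dec) <- decoys$name
    out <- c(ref, dec)
  } else {
    out <- ref
  }
  Biostrings::writeXStringSet(out, filepath = out_fasta, width = width)
  invisible(out_fasta)
}

#' Write the decoy chromosomes alone as FASTA
#'
#' @inheritParams augment_reference
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decoy_fasta <- function(decoys, path, width = 70L) {
  dec <- Biostrings::DNAStringSet(decoys$sequence)
  names(dec) <- decoys$name
  Biostrings::writeXStringSet(dec, filepath = path, width = width)
  invisible(path)
}

# TRUE for contig names that follow the decoy naming convention
is_decoy_name <- function(x) startsWith(x, "STR-")

# parse the repeat unit out of a decoy contig name, validating canonicity
decoy_unit <- function(name) {
  u <- sub("^STR-", "", name)
  cu <- tryCatch(canonical_unit(u), error = function(e) NA_character_)
  if (is.na(cu) || cu != u) {
    stop("contig '", name, "' is named like an STR decoy but '", u,
         "' is not a canonical repeat unit", call. = FALSE)
  }
  u
}
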