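#' Canonical STR repeat motifs
#'
#' Short tandem repeat (STR) motifs of 1-6 bp are grouped into equivalence
#' classes under circular permutation (rotation) and reverse complementation:
#' a read composed of `CAGCAGCAG...` could equally be described by the motifs
#' `CAG`, `AGC`, `GCA`, or (on the opposite strand) `CTG`, `TGC`, `GCT`. Each
#' class is represented by its lexicographically smallest member (here `AGC`),
#' and motifs that are tandem multiples of a shorter motif (e.g. `ATAT`, a
#' double of `AT`) are reduced to their primitive root first. These canonical
#' motifs name the STR decoy chromosomes and index all downstream counting.
#'
#' @name canonical-motifs
NULL

# reverse complement of a plain character motif (short strings; avoids
# DNAString round trips in the hot enumeration loop)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

rotations_chr <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(s)
  d <- paste0(s, s)
  vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
}

validate_motif <- function(unit) {
  if (length(unit) != 1L || is.na(unit) || !nzchar(unit)) {
    stop("invalid motif: must be a single non-empty string", call. = FALSE)
  }
  u <- toupper(unit)
  if (grepl("[^ACGT]", u)) {
    stop("invalid motif '", unit, "': contains non-ACGT characters",
         call. = FALSE)
  }
  if (nchar(u) > 6L) {
    stop("invalid motif '", unit, "': length exceeds 6 bp", call. = FALSE)
  }
  u
}

#' Primitive root of a repeat motif
#'
#' The primitive root of a motif is its shortest period: `ATAT` has root
#' `AT`, `AAAAAA` has root `A`, and a primitive motif is its own root.
#'
#' @param unit A single DNA motif (A/C/G/T, case-insensitive, 1-6 bp).
#' @return The shortest motif whose tandem repetition yields `unit`.
#' @examples
#' primitive_root("ATAT")  # "AT"
#' @export
primitive_root <- function(unit) {
  u <- validate_motif(unit)
  n <- nchar(u)
  for (p in seq_len(n)) {
    if (n %% p == 0L && strrep(substr(u, 1L, p), n %/% p) == u) {
      return(substr(u, 1L, p))
    }
  }
  u # unreachable: p = n always matches
}

#' Test whether a motif is primitive
#'
#' @inheritParams primitive_root
#' @return `TRUE` if `unit` is not a tandem multiple of a shorter motif.
#' @examples
#' is_primitive("AGC")    # TRUE
#' is_primitive("ATAT")   # FALSE
#' @export
is_primitive <- function(unit) {
  u <- validate_motif(unit)
  nchar(primitive_root(u)) == nchar(u)
}

#' Canonical representative of a repeat-motif class
#'
#' Reduces `unit` to its primitive root, then returns the lexicographically
#' smallest string among all rotations of the root and all rotations of its
#' reverse complement.
#'
#' @inheritParams primitive_root
#' @return The canonical motif (uppercase).
#' @examples
#' canonical_unit("CTG")   # "AGC"
#' canonical_unit("ATAT")  # "AT"
#' canonical_unit("T")     # "A"
#' @export
canonical_unit <- function(unit) {
  u <- primitive_root(validate_motif(unit))
  min(c(rotations_chr(u), rotations_chr(revcomp_chr(u))))
}

# vectorised canonicalization with a small cache; returns NA (with the error
# message as an attribute consumer may ignore) for invalid motifs
canonical_unit_vec <- function(units) {
  uniq <- unique(units)
  mapped <- vapply(uniq, function(u) {
    tryCatch(canonical_unit(u), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  mapped[match(units, uniq)]
}

#' Enumerate all canonical STR motifs up to a maximum length
#'
#' Enumerates every DNA string of length 1 to `max_len`, keeps the primitive
#' ones, and collapses them to canonical representatives. With the default
#' `max_len = 6` this yields the 501 distinct repeat units that define the
#' STR decoy chromosome set.
#'
#' @param max_len Maximum motif length in bp (1-6).
#' @return Character vector of canonical motifs, sorted by length then
#'   lexicographically.
#' @examples
#' enumerate_canonical_units(1)          # "A" "C"
#' length(enumerate_canonical_units(6))  # 501
#' @export
enumerate_canonical_units <- function(max_len = 6L) {
  if (length(max_len) != 1L || is.na(max_len) || max_len < 1 || max_len > 6 ||
      max_len != as.integer(max_len)) {
    stop("max_len must be an integer between 1 and 6", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (k in seq_len(as.integer(max_len))) {
    grids <- do.call(expand.grid,
                     c(rep(list(bases), k), stringsAsFactors = FALSE))
    all_k <- do.call(paste0, grids)
    prim <- all_k[vapply(all_k, is_primitive, logical(1), USE.NAMES = FALSE)]
    canon <- unique(vapply(prim, canonical_unit, character(1),
                           USE.NAMES = FALSE))
    out <- c(out, sort(canon))
  }
  out
}
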