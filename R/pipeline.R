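#' Pipeline run configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. Exactly one
#' control mode is active: either `controls` is a path to a control
#' parameter TSV (reference-control mode) or `controls = "internal"` and
#' the provided samples act as controls for each other.
#'
#' @param annotation Path to the STR annotation (see [parse_str_bed()]).
#' @param annotation_dialect Annotation dialect.
#' @param controls `"internal"` or a control-parameter TSV path.
#' @param alpha Adjusted-p significance threshold.
#' @param max_dist Mate-to-locus assignment distance in bp.
#' @param flank Extraction-region flank in bp.
#' @param calibration Optional calibration JSON path; defaults to the model
#'   shipped with the package.
#' @param median_coverage Optional fixed median coverage (single value or
#'   named per sample); when `NULL` it is computed from each alignment over
#'   the annotation-derived regions.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(annotation, annotation_dialect = "bed",
                       controls = "internal", alpha = 0.05,
                       max_dist = 500L, flank = 800L, calibration = NULL,
                       median_coverage = NULL, out_dir = ".") {
  if (!file.exists(annotation)) {
    stop("annotation file not found: ", annotation, call. = FALSE)
  }
  if (!identical(controls, "internal") && !file.exists(controls)) {
    stop("control parameter file not found: ", controls, call. = FALSE)
  }
  if (!is.null(calibration) && !file.exists(calibration)) {
    stop("calibration file not found: ", calibration, call. = FALSE)
  }
  structure(list(annotation = annotation,
                 annotation_dialect = annotation_dialect,
                 controls = controls, alpha = alpha,
                 max_dist = as.integer(max_dist),
                 flank = as.integer(flank), calibration = calibration,
                 median_coverage = median_coverage, out_dir = out_dir),
            class = "run_config")
}

#' Run the full expansion-detection pipeline
#'
#' For each sample: read the decoy-aware alignment, allocate decoy reads to
#' STR loci via mates, normalize against median coverage, score every locus
#' with assigned reads against the control parameters, estimate allele
#' sizes, and write a per-sample report sorted with the most significant
#' expansions first. In internal-control mode the control parameters are
#' first built from all provided samples. A resolved copy of the
#' configuration is written next to the reports.
#'
#' @param config A [run_config()].
#' @param alignments Named character vector of BAM paths (names are sample
#'   ids; unnamed paths use the file stem).
#' @return Named character vector of report paths, invisibly.
#' @export
run_pipeline <- function(config, alignments) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    names(alignments) <- sub("\\.bam$", "", basename(alignments))
  }
  loci <- parse_str_bed(config$annotation,
                        dialect = config$annotation_dialect)
  index <- build_locus_index(loci)
  regions <- expand_extraction_regions(loci, flank = config$flank)

  # all alignments must share the same non-decoy contig universe, and it
  # must contain the annotation's chromosomes
  contig_sets <- lapply(alignments, function(b) {
    sort(names(Rsamtools::scanBamHeader(b)[[1]]$targets))
  })
  if (length(unique(contig_sets)) != 1L) {
    stop("alignments were mapped to different references", call. = FALSE)
  }
  missing_chrom <- setdiff(unique(loci$chrom), contig_sets[[1]])
  if (length(missing_chrom) > 0) {
    stop("annotation chromosomes absent from alignments: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }

  sample_cov <- function(sid, bam) {
    mc <- config$median_coverage
    if (is.null(mc)) return(median_coverage(bam, target = regions))
    if (!is.null(names(mc))) return(unname(mc[sid]))
    unname(mc[1])
  }
  tables <- lapply(names(alignments), function(sid) {
    bam <- alignments[[sid]]
    message("[allocate] ", sid)
    hits <- decoy_hits(bam)
    assign_reads_to_loci(hits, index, sample_id = sid,
                         median_coverage = sample_cov(sid, bam),
                         max_dist = config$max_dist)
  })
  names(tables) <- names(alignments)

  controls <- if (identical(config$controls, "internal")) {
    message("[controls] estimating from ", length(tables),
            " samples (internal mode)")
    build_control_parameters(tables)
  } else {
    read_control_parameters(config$controls)
  }
  model <- if (is.null(config$calibration)) {
    default_calibration()
  } else {
    read_calibration(config$calibration)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(resolved_config(config, alignments),
                   file.path(config$out_dir, "config.resolved.yaml"))
  paths <- vapply(names(tables), function(sid) {
    calls <- call_outliers(tables[[sid]], controls, alpha = config$alpha)
    rows <- report_rows(calls, loci, model)
    message("[report] ", sid, ": ", nrow(rows), " loci, ",
            sum(calls$significant), " significant")
    write_report(rows, file.path(config$out_dir,
                                 paste0(sid, ".report.tsv")))
  }, character(1))
  invisible(paths)
}

resolved_config <- function(config, alignments) {
  c(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    list(alignments = as.list(alignments)))
}

# join outlier calls with locus annotation and allele-size estimates
report_rows <- function(calls, loci, model) {
  m <- match(calls$locus_id, loci$locus_id)
  est_units <- vapply(seq_len(nrow(calls)), function(i) {
    if (is.na(m[i])) return(NA_real_)
    estimate_allele_size(calls$y[i], model,
                         loci[m[i], , drop = FALSE])$repeat_units_total
  }, numeric(1))
  data.frame(chrom = loci$chrom[m], start = loci$start[m],
             end = loci$end[m], unit = loci$unit[m],
             ref_copies = loci$ref_copies[m],
             sample_id = calls$sample_id, raw_count = calls$raw_count,
             normalized_count = calls$y, z = calls$z, p = calls$p,
             p_adj = calls$p_adj, estimated_size_units = est_units,
             stringsAsFactors = FALSE, row.names = NULL)
}

REPORT_COLUMNS <- c("chrom", "start", "end", "unit", "ref_copies",
                    "sample_id", "raw_count", "normalized_count", "z", "p",
                    "p_adj", "estimated_size_units")

#' Write a per-sample expansion report
#'
#' Tab-delimited with a fixed column order, sorted by ascending adjusted
#' p-value (ties broken by descending z, then locus position) so the most
#' significant expansions rank at the top. Floating-point columns are
#' rendered with 6 significant digits. Coordinates are 0-based half-open,
#' stated in a leading comment line.
#'
#' @param rows Report `data.frame` (columns as produced by
#'   [run_pipeline()]).
#' @param path Output path.
#' @return `path`, invisibly... the written file can be re-read with
#'   [read_report()].
#' @export
write_report <- function(rows, path) {
  rows <- rows[order(rows$p_adj, -rows$z, rows$chrom, rows$start), ,
               drop = FALSE]
  fmt <- rows
  for (col in names(fmt)) {
    if (is.double(fmt[[col]])) fmt[[col]] <- signif(fmt[[col]], 6)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# strexpand report; coordinates are 0-based, half-open",
             con)
  utils::write.table(fmt[, REPORT_COLUMNS, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
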