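#' Construct a single STR locus record
#'
#' Convenience constructor for the locus table rows used throughout the
#' package (coordinates 0-based half-open; the unit is canonicalized).
#'
#' @param chrom Chromosome name.
#' @param start,end Locus interval.
#' @param unit Repeat motif (canonicalized on input).
#' @param ref_copies Repeat copy number in the reference (may be fractional).
#' @return One-row locus `data.frame`.
#' @export
str_locus <- function(chrom, start, end, unit, ref_copies) {
  stopifnot(start < end)
  loci <- data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(end), unit = canonical_unit(unit),
                     ref_copies = as.numeric(ref_copies),
                     stringsAsFactors = FALSE)
  loci$locus_id <- locus_id(loci)
  loci
}

#' Specification of one simulated diploid expansion
#'
#' Describes the study design the simulator reproduces: a diploid locus in
#' which one allele stays at the reference length while the other carries an
#' expansion, sequenced as 150 bp paired-end reads with fragment sizes drawn
#' from Normal(500, 50) at 30x total coverage (shared proportionally between
#' the two haplotypes).
#'
#' @param locus One-row locus table (see [str_locus()]).
#' @param allele_a_units,allele_b_units Repeat copies on each haplotype.
#' @param coverage Total sequencing depth over the diploid locus.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment-length distribution in bp.
#' @param flank Unique flanking sequence simulated on each side of the
#'   repeat tract, in bp.
#' @param str_fraction Minimum fraction of a read's bases inside the repeat
#'   tract for the read to be emitted as decoy-aligned.
#' @param seed Mandatory RNG seed; simulations are reproducible by contract.
#' @return A list of class `expansion_spec`.
#' @export
expansion_spec <- function(locus, allele_a_units = 16L, allele_b_units,
                           coverage = 30, read_length = 150L,
                           insert_mean = 500, insert_sd = 50,
                           flank = 1000L, str_fraction = 0.9, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required: simulations must be reproducible",
         call. = FALSE)
  }
  stopifnot(read_length > 0, insert_mean > read_length, coverage > 0,
            allele_a_units >= 0, allele_b_units >= 0, flank >= 0)
  structure(list(locus = locus, allele_a_units = allele_a_units,
                 allele_b_units = allele_b_units, coverage = coverage,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 flank = as.integer(flank), str_fraction = str_fraction,
                 seed = as.integer(seed)),
            class = "expansion_spec")
}

DECOY_SIM_LENGTH <- 2000L

# map a haplotype coordinate (0-based; repeat tract at [flank, flank+tract))
# to a genomic 0-based coordinate; positions inside the tract are clamped
# into the reference tract
hap_to_genome <- function(x, locus, flank, tract) {
  ref_len <- locus$end - locus$start
  ifelse(x < flank,
         locus$start - (flank - x),
         ifelse(x >= flank + tract,
                locus$end + (x - flank - tract),
                locus$start + pmin(x - flank, max(ref_len - 1L, 0L))))
}

#' Simulate aligned read pairs from one diploid STR locus
#'
#' Emulates what a decoy-aware aligner would produce for a diploid locus
#' with one expanded allele, without running an aligner: fragments are
#' placed uniformly along each haplotype (flank + repeat tract + flank) at
#' depth proportional to haplotype length, and each 150 bp read is routed to
#' the decoy chromosome of the locus's repeat unit when at least
#' `str_fraction` of its bases fall inside the repeat tract, or to its
#' (clamped) genomic position otherwise. Mate fields are reciprocal and
#' pairing flags are set, so the records behave like a sorted SAM stream.
#'
#' @param spec An [expansion_spec()].
#' @param qname_prefix Prefix for read names (keeps names unique when
#'   records from several loci or samples are pooled).
#' @return A list with `records` (SAM record `data.frame`, see
#'   [write_sam()]), `truth` (one-row `data.frame` with the true allele
#'   sizes, generated pair count, realized decoy-read count and its
#'   analytic expectation), and `contigs` (named lengths for the SAM
#'   header).
#' @export
simulate_locus_reads <- function(spec, qname_prefix = "sim") {
  stopifnot(inherits(spec, "expansion_spec"))
  set.seed(spec$seed)
  locus <- spec$locus
  ulen <- nchar(locus$unit)
  rl <- spec$read_length
  fl <- spec$flank
  decoy_name <- paste0("STR-", locus$unit)
  chrom_len <- locus$end + fl + as.integer(ceiling(spec$insert_mean)) + rl

  all_recs <- list()
  truth_decoy <- 0L
  truth_exp <- 0
  n_pairs_total <- 0L
  for (hap in c("a", "b")) {
    units <- if (hap == "a") spec$allele_a_units else spec$allele_b_units
    tract <- as.integer(round(units * ulen))
    hap_len <- 2L * fl + tract
    n_frags <- max(0L, as.integer(round(
      (spec$coverage / 2) * hap_len / (2 * rl))))
    if (n_frags == 0L) next
    frag <- pmin(hap_len, pmax(rl, as.integer(round(
      stats::rnorm(n_frags, spec$insert_mean, spec$insert_sd)))))
    fstart <- as.integer(floor(stats::runif(n_frags, 0, hap_len - frag + 1)))
    r1s <- fstart
    r2s <- fstart + frag - rl

    read_frac <- function(a) {
      pmax(0L, pmin(a + rl, fl + tract) - pmax(a, fl)) / rl
    }
    routes <- function(a) {
      decoy <- read_frac(a) >= spec$str_fraction
      pos0 <- ifelse(decoy,
                     a %% (DECOY_SIM_LENGTH - rl + 1L),
                     pmax(0L, pmin(hap_to_genome(a, locus, fl, tract),
                                   chrom_len - rl)))
      list(decoy = decoy, rname = ifelse(decoy, decoy_name, locus$chrom),
           pos = as.integer(pos0) + 1L)
    }
    t1 <- routes(r1s)
    t2 <- routes(r2s)
    qn <- sprintf("%s_%s_%s_%06d", qname_prefix, locus$unit, hap,
                  seq_len(n_frags))
    same <- t1$rname == t2$rname
    seq_for <- function(decoy) {
      ifelse(decoy,
             substr(strrep(locus$unit, ceiling(rl / ulen) + 1L), 1L, rl),
             substr(strrep("ACGT", ceiling(rl / 4) + 1L), 1L, rl))
    }
    rec1 <- data.frame(
      qname = qn, flag = 99L, rname = t1$rname, pos = t1$pos, mapq = 60L,
      cigar = paste0(rl, "M"),
      rnext = ifelse(same, "=", t2$rname), pnext = t2$pos,
      tlen = ifelse(same, frag, 0L), seq = seq_for(t1$decoy),
      qual = strrep("I", rl), stringsAsFactors = FALSE)
    rec2 <- data.frame(
      qname = qn, flag = 147L, rname = t2$rname, pos = t2$pos, mapq = 60L,
      cigar = paste0(rl, "M"),
      rnext = ifelse(same, "=", t1$rname), pnext = t1$pos,
      tlen = ifelse(same, -frag, 0L), seq = seq_for(t2$decoy),
      qual = strrep("I", rl), stringsAsFactors = FALSE)
    all_recs[[hap]] <- rbind(rec1, rec2)
    truth_decoy <- truth_decoy + sum(t1$decoy) + sum(t2$decoy)
    # expected decoy reads at the mean fragment length: a read starting at
    # a is decoy when its overlap with the tract [fl, fl+tract) is at least
    # str_fraction * rl, i.e. a in [fl - (1-t)*rl, fl + tract - t*rl];
    # fragment starts are uniform on [0, hap_len - frag]
    if (tract >= spec$str_fraction * rl) {
      fbar <- min(hap_len, max(rl, round(spec$insert_mean)))
      a_max <- hap_len - fbar
      w0 <- fl - (1 - spec$str_fraction) * rl
      w1 <- fl + tract - spec$str_fraction * rl
      clip <- function(lo, hi) max(0, min(hi, a_max) - max(lo, 0) + 1)
      p1 <- clip(w0, w1) / (a_max + 1)                     # first read
      p2 <- clip(w0 - fbar + rl, w1 - fbar + rl) / (a_max + 1) # second
      truth_exp <- truth_exp + n_frags * (p1 + p2)
    }
    n_pairs_total <- n_pairs_total + n_frags
  }
  records <- if (length(all_recs) > 0) {
    do.call(rbind, c(all_recs, list(make.row.names = FALSE)))
  } else sam_record_frame(0L)
  contigs <- stats::setNames(c(chrom_len, DECOY_SIM_LENGTH),
                             c(locus$chrom, decoy_name))
  truth <- data.frame(locus_id = locus$locus_id,
                      allele_a_units = spec$allele_a_units,
                      allele_b_units = spec$allele_b_units,
                      n_pairs = n_pairs_total, decoy_reads = truth_decoy,
                      expected_decoy_reads = truth_exp,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth, contigs = contigs)
}

#' Simulate a cohort of samples with optional spiked expansions
#'
#' Every sample carries reference-length alleles at every locus, plus a
#' Poisson number of background decoy reads per locus (mate mapped next to
#' the locus, so they are assignable) emulating the low-level repeat-read
#' noise seen in real data. Selected samples instead embed a true expansion
#' at one locus. The truth table records every generated count, enabling
#' end-to-end verification of allocation and outlier testing.
#'
#' @param n_samples Number of samples (>= 3).
#' @param loci Locus table.
#' @param spike Named list: `sample_id -> expansion_spec`; each spec's locus
#'   must be one of `loci`.
#' @param seed RNG seed.
#' @param noise_rate Mean background decoy reads per locus per sample.
#' @param out_dir If non-`NULL`, one sorted SAM per sample is written here.
#' @param ... Defaults forwarded to [expansion_spec()] for the non-spiked
#'   (reference-genotype) simulations.
#' @return A list with `samples` (named list of SAM record tables),
#'   `truth` (`data.frame`), `contigs`, and `sam_paths` (or `NULL`).
#' @export
simulate_cohort <- function(n_samples, loci, spike = list(), seed,
                            noise_rate = 1, out_dir = NULL, ...) {
  stopifnot(n_samples >= 3)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  sample_ids <- sprintf("sample%02d", seq_len(n_samples))
  unknown <- setdiff(names(spike), sample_ids)
  if (length(unknown) > 0) {
    stop("spike references unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sp in spike) {
    if (!sp$locus$locus_id %in% loci$locus_id) {
      stop("spiked locus ", sp$locus$locus_id,
           " is not in the locus table", call. = FALSE)
    }
  }
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 n_samples * (nrow(loci) + 1L)),
                      nrow = n_samples)
  all_contigs <- integer(0)
  samples <- list()
  truth <- list()
  for (i in seq_len(n_samples)) {
    sid <- sample_ids[i]
    recs <- list()
    for (j in seq_len(nrow(loci))) {
      locus <- loci[j, , drop = FALSE]
      sp <- spike[[sid]]
      if (!is.null(sp) && sp$locus$locus_id == locus$locus_id) {
        spec <- sp
        spec$seed <- sub_seeds[i, j]
      } else {
        ref_units <- as.integer(round(locus$ref_copies))
        spec <- expansion_spec(locus, allele_a_units = ref_units,
                               allele_b_units = ref_units,
                               seed = sub_seeds[i, j], ...)
      }
      sim <- simulate_locus_reads(spec,
                                  qname_prefix = paste0(sid, "_L", j))
      nz <- stats::rpois(1L, noise_rate)
      noise <- noise_records(nz, locus, spec, prefix = paste0(sid, "_N", j))
      recs[[j]] <- rbind(sim$records, noise)
      for (cn in names(sim$contigs)) {
        all_contigs[cn] <- max(all_contigs[cn], sim$contigs[cn],
                               na.rm = TRUE)
      }
      tr <- sim$truth
      tr$sample_id <- sid
      tr$noise_decoy_reads <- nz
      truth[[length(truth) + 1L]] <- tr
    }
    samples[[sid]] <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  sam_paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sam_paths <- vapply(sample_ids, function(sid) {
      p <- file.path(out_dir, paste0(sid, ".sam"))
      write_sam(samples[[sid]], all_contigs, p)
      p
    }, character(1))
  }
  list(samples = samples, truth = truth, contigs = all_contigs,
       sam_paths = sam_paths)
}

# background decoy reads whose mates map just upstream of the locus
noise_records <- function(n, locus, spec, prefix) {
  if (n == 0L) return(sam_record_frame(0L))
  rl <- spec$read_length
  decoy_name <- paste0("STR-", locus$unit)
  mate_pos <- max(1L, locus$start - 200L) # 0-based 1-converted below
  qn <- sprintf("%s_%04d", prefix, seq_len(n))
  dec <- data.frame(qname = qn, flag = 99L, rname = decoy_name, pos = 1L,
                    mapq = 60L, cigar = paste0(rl, "M"),
                    rnext = locus$chrom, pnext = mate_pos, tlen = 0L,
                    seq = substr(strrep(locus$unit,
                                        ceiling(rl / nchar(locus$unit)) + 1L),
                                 1L, rl),
                    qual = strrep("I", rl), stringsAsFactors = FALSE)
  mate <- data.frame(qname = qn, flag = 147L, rname = locus$chrom,
                     pos = mate_pos, mapq = 60L, cigar = paste0(rl, "M"),
                     rnext = decoy_name, pnext = 1L, tlen = 0L,
                     seq = substr(strrep("ACGT", ceiling(rl / 4) + 1L),
                                  1L, rl),
                     qual = strrep("I", rl), stringsAsFactors = FALSE)
  rbind(dec, mate)
}

#' Simulate the allele-size calibration cohort
#'
#' Reproduces the calibration design: `n` individuals heterozygous at a
#' single CAG-type locus, one allele fixed at the reference 16 copies and
#' the other drawn uniformly from `size_range` repeat units. Each
#' individual's decoy-read count is normalized against the simulated
#' coverage and paired with the true inserted length on the log2 scale.
#' Individuals with zero decoy reads or no inserted sequence are dropped
#' (their logs are undefined); drops concentrate at small alleles.
#'
#' @param n Number of simulated individuals (>= 10).
#' @param size_range Range (repeat units) from which the expanded allele is
#'   drawn uniformly.
#' @param seed RNG seed.
#' @param locus Locus simulated; defaults to a synthetic 16-copy AGC locus.
#' @param ... Forwarded to [expansion_spec()].
#' @return A `data.frame` with columns `log2_coverage`, `log2_allele_bp`,
#'   `allele_b_units`, `inserted_bp`, `decoy_reads` (one row per retained
#'   individual), suitable for [fit_calibration()].
#' @export
simulate_calibration_dataset <- function(n = 100L, size_range = c(0L, 500L),
                                         seed, locus = NULL, ...) {
  stopifnot(n >= 10)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(locus)) {
    locus <- str_locus("chr13", 100000L, 100048L, "AGC", 16)
  }
  set.seed(seed)
  allele_b <- sample.int(size_range[2] - size_range[1] + 1L, n,
                         replace = TRUE) - 1L + size_range[1]
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ulen <- nchar(locus$unit)
  rows <- lapply(seq_len(n), function(i) {
    spec <- expansion_spec(locus, allele_a_units = 16L,
                           allele_b_units = allele_b[i],
                           seed = sub_seeds[i], ...)
    sim <- simulate_locus_reads(spec, qname_prefix = sprintf("cal%03d", i))
    cnt <- sim$truth$decoy_reads
    inserted <- (allele_b[i] - locus$ref_copies) * ulen
    if (cnt == 0L || inserted <= 0) return(NULL)
    data.frame(log2_coverage = normalize_count(cnt, spec$coverage),
               log2_allele_bp = log2(inserted),
               allele_b_units = allele_b[i], inserted_bp = inserted,
               decoy_reads = cnt, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no individuals retained: all had zero decoy reads", call. = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a null cohort of locus count tables
#'
#' Draws independent Poisson counts with a common mean for every locus and
#' sample — no expansions anywhere — for studying the outlier test's
#' behavior under the null hypothesis.
#'
#' @param n_samples,n_loci Cohort dimensions.
#' @param lambda Common Poisson mean of the per-locus counts.
#' @param median_cov Median coverage recorded in every table.
#' @param seed RNG seed.
#' @return A list of [locus_counts] objects.
#' @export
simulate_null_cohort_counts <- function(n_samples = 20L, n_loci = 200L,
                                        lambda = 5, median_cov = 100,
                                        seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("chr1:%d-%d:AGC", seq_len(n_loci) * 10000L,
                 seq_len(n_loci) * 10000L + 60L)
  lapply(seq_len(n_samples), function(i) {
    counts <- stats::rpois(n_loci, lambda)
    locus_counts(sprintf("null%02d", i),
                 assigned = stats::setNames(counts, ids),
                 median_coverage = median_cov)
  })
}

#' Simulate calibration points from a known linear model
#'
#' Generates `(log2_allele_bp, log2_coverage)` pairs directly from
#' `y = beta0 + beta * x + N(0, sd)` with `x` uniform over `x_range`. Used
#' to verify that [fit_calibration()] recovers known coefficients.
#'
#' @param n Number of points.
#' @param beta0,beta True intercept and slope.
#' @param sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param x_range Range of `x = log2(allele bp)`.
#' @return A `data.frame` with columns `log2_coverage`, `log2_allele_bp`.
#' @export
simulate_linear_calibration_points <- function(n = 100L, beta0 = -4,
                                               beta = 0.95, sd = 0.3, seed,
                                               x_range = log2(c(30, 1500))) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- beta0 + beta * x + stats::rnorm(n, 0, sd)
  data.frame(log2_coverage = y, log2_allele_bp = x,
             stringsAsFactors = FALSE)
}
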