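write_bed <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "strs.bed")
  writeLines(lines, p)
  p
}

test_that("BED parsing canonicalizes units and keeps 0-based coordinates", {
  p <- write_bed(c("chr1\t100\t130\tCAG\t10.0",
                   "chr2\t500\t560\tAT\t30"))
  loci <- parse_str_bed(p)
  expect_identical(loci$unit, c("AGC", "AT"))
  expect_identical(loci$start, c(100L, 500L))
  expect_identical(loci$end, c(130L, 560L))
  expect_identical(loci$locus_id[1], "chr1:100-130:AGC")
  expect_equal(loci$ref_copies, c(10, 30))
})

test_that("unparseable motifs are skipped with a warning, bad rows error", {
  p <- write_bed(c("chr1\t100\t130\tCAG\t10",
                   "chr1\t200\t230\tNNN\t10",
                   "chr1\t300\t330\tACGTACG\t10"))
  expect_warning(loci <- parse_str_bed(p), "skipped")
  expect_identical(nrow(loci), 1L)

  p2 <- write_bed(c("chr1\t100\t130\tCAG\t10", "chr1\t300\t250\tAT\t5"))
  expect_error(parse_str_bed(p2), "line 2")
  p3 <- write_bed("chr1\tx\t130\tCAG\t10")
  expect_error(parse_str_bed(p3), "line 1")
})

test_that("empty annotation yields an empty locus table", {
  p <- write_bed(character(0))
  loci <- parse_str_bed(p)
  expect_identical(nrow(loci), 0L)
})

test_that("the UCSC simpleRepeat dialect maps its fixed columns", {
  row <- c("585", "chr1", "10000", "10468", "trf", "6", "77.2", "6", "95",
           "3", "789", "33", "51", "0", "15", "1.43", "TAACCC")
  p <- write_bed(paste(row, collapse = "\t"))
  loci <- parse_str_bed(p, dialect = "simpleRepeat")
  expect_identical(loci$chrom, "chr1")
  expect_identical(loci$start, 10000L)
  expect_identical(loci$unit, canonical_unit("TAACCC"))
  expect_equal(loci$ref_copies, 77.2)
})

test_that("extraction regions are flanked, clamped and merged", {
  one <- str_locus("chr1", 1000L, 1030L, "AGC", 10)
  r <- expand_extraction_regions(one, flank = 800L)
  expect_identical(r$start, 200L)
  expect_identical(r$end, 1830L)

  near0 <- str_locus("chr1", 100L, 130L, "AGC", 10)
  expect_identical(expand_extraction_regions(near0, flank = 800L)$start, 0L)

  two <- rbind(str_locus("chr1", 1000L, 1030L, "AGC", 10),
               str_locus("chr1", 1130L, 1160L, "AT", 10))
  r2 <- expand_extraction_regions(two, flank = 800L)
  expect_identical(nrow(r2), 1L)

  # idempotent under a second flank-0 expansion
  again <- expand_extraction_regions(
    data.frame(chrom = r2$chrom, start = r2$start, end = r2$end,
               unit = "AT", ref_copies = 1,
               locus_id = "x", stringsAsFactors = FALSE), flank = 0L)
  expect_identical(again[, c("chrom", "start", "end")],
                   r2[, c("chrom", "start", "end")])
})

test_that("nearest_matching_locus honors unit, distance and ties", {
  loci <- rbind(str_locus("chr1", 10000L, 10050L, "AGC", 16),
                str_locus("chr1", 10450L, 10500L, "AGC", 16),
                str_locus("chr1", 10100L, 10150L, "AT", 20))
  idx <- build_locus_index(loci)

  # 600 bp away from the only same-unit locus on chr2: nothing
  solo <- build_locus_index(str_locus("chr2", 5000L, 5050L, "AGC", 16))
  expect_null(nearest_matching_locus(solo, "chr2", 5650L, 5800L, "AGC"))

  # gap 100 beats gap 300
  hit <- nearest_matching_locus(idx, "chr1", 10150L, 10250L, "AGC")
  expect_identical(hit$start, 10000L)

  # same distance but different unit does not match
  expect_null(nearest_matching_locus(idx, "chr1", 10200L, 10300L, "AAAG"))

  # equidistant same-unit loci: smaller start wins
  tie <- nearest_matching_locus(idx, "chr1", 10150L, 10350L, "AGC")
  expect_identical(tie$start, 10000L)
  expect_null(nearest_matching_locus(idx, "chr9", 1L, 100L, "AGC"))
})

test_that("indexed nearest-locus queries agree with a brute-force scan", {
  set.seed(42)
  units <- c("A", "AT", "AGC", "AAAG")
  for (rep in 1:15) {
    n <- sample(20:200, 1)
    loci <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(50000L, n), stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(20:80, n, replace = TRUE)
    loci$unit <- sample(units, n, replace = TRUE)
    loci$ref_copies <- 10
    loci$locus_id <- paste0(loci$chrom, ":", loci$start, "-", loci$end,
                            ":", loci$unit, ":", seq_len(n))
    idx <- build_locus_index(loci)
    for (q in 1:20) {
      qs <- sample.int(52000L, 1)
      qe <- qs + 150L
      qu <- sample(units, 1)
      qc <- sample(c("chr1", "chr2"), 1)
      got <- nearest_matching_locus(idx, qc, qs, qe, qu)
      want <- brute_nearest(loci, qc, qs, qe, qu)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_identical(got$locus_id, want$locus_id)
      }
    }
  }
})

test_that("same-unit proximity fraction matches a pairwise oracle and is monotone", {
  expect_identical(proximity_fraction(str_locus("chr1", 1e4, 1e4 + 50,
                                                "AGC", 16), 5000L), 0)
  two <- rbind(str_locus("chr1", 10000L, 10050L, "AGC", 16),
               str_locus("chr1", 10150L, 10200L, "AGC", 16))
  expect_identical(proximity_fraction(two, 500L), 1)
  expect_identical(proximity_fraction(two, 50L), 0)
  expect_error(proximity_fraction(two[0, ], 500L), "empty")

  brute_fraction <- function(loci, d) {
    hit <- logical(nrow(loci))
    for (i in seq_len(nrow(loci))) {
      for (j in seq_len(nrow(loci))) {
        if (i == j) next
        if (loci$chrom[i] != loci$chrom[j] ||
            loci$unit[i] != loci$unit[j]) next
        gap <- max(0L, loci$start[j] - loci$end[i],
                   loci$start[i] - loci$end[j])
        if (gap <= d) hit[i] <- TRUE
      }
    }
    mean(hit)
  }
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    loci <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(20000L, n), stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(20:80, n, replace = TRUE)
    loci$unit <- sample(c("A", "AT", "AGC"), n, replace = TRUE)
    prev <- -1
    for (d in c(0L, 100L, 500L, 2000L)) {
      f <- proximity_fraction(loci, d)
      expect_equal(f, brute_fraction(loci, d))
      expect_gte(f, prev) # monotone non-decreasing in distance
      prev <- f
    }
  }
})
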