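#' Log2-normalized locus counts
#'
#' Raw per-locus read counts are made comparable across samples by scaling
#' to a nominal median coverage of 100x and log-transforming:
#' `log2(100 * (raw + 1) / median_cov)`. The +1 keeps zero counts finite;
#' a raw count of 0 in a 100x sample maps to exactly 0.
#'
#' @param raw Raw read count(s), non-negative.
#' @param median_cov Sample median coverage, > 0.
#' @return Normalized count(s) on the log2 scale.
#' @examples
#' normalize_count(0, 100)   # 0
#' normalize_count(0, 50)    # 1
#' @export
normalize_count <- function(raw, median_cov) {
  if (any(median_cov <= 0)) stop("median_cov must be positive",
                                 call. = FALSE)
  if (any(raw < 0)) stop("raw counts must be non-negative", call. = FALSE)
  log2(100 * (raw + 1) / median_cov)
}

#' Huber M-estimates of location and scale
#'
#' Joint location/scale estimation by Huber's "Proposal 2": iterate
#' winsorizing the data at `M +- k * s`, updating `M` as the mean of the
#' winsorized values and `s` from their (consistency-corrected) variance,
#' until both stabilize. Robustness matters here because a repeat expansion
#' present in one control sample would otherwise inflate the per-locus null
#' variance and mask true outliers.
#'
#' Starting values are the median and normalized MAD (standard deviation
#' when the MAD is 0). If all values are equal the scale is degenerate and
#' the floor is returned directly. On non-convergence within `max_iter`
#' iterations the estimator falls back to the median and MAD with a warning.
#' The returned scale is never below `scale_floor`: without a floor, a locus
#' with constant control counts would give an infinite z-score for a single
#' extra read.
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @param tuning_k Winsorization constant `k` (default 1.5).
#' @param tol Relative convergence tolerance.
#' @param max_iter Maximum number of fixed-point iterations.
#' @param scale_floor Minimum returned scale, on the log2-count scale.
#' @return A list with elements `M`, `sigma_M`, `converged`, `n`.
#' @export
huber_location_scale <- function(values, tuning_k = 1.5, tol = 1e-6,
                                 max_iter = 50L, scale_floor = 0.01) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("at least 2 values required", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("all values must be finite", call. = FALSE)
  }
  n <- length(values)
  med <- stats::median(values)
  mu0 <- med
  s0 <- stats::mad(values)
  if (s0 == 0) s0 <- stats::sd(values)
  if (s0 == 0) {
    # all values identical: location exact, scale degenerate at the floor
    return(list(M = med, sigma_M = scale_floor, converged = TRUE, n = n))
  }
  k <- tuning_k
  # consistency factor: E[min(max(Z,-k),k)^2] for standard normal Z
  th <- 2 * stats::pnorm(k) - 1
  beta <- th + k^2 * (1 - th) - 2 * k * stats::dnorm(k)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    yy <- pmin(pmax(values, mu0 - k * s0), mu0 + k * s0)
    mu1 <- mean(yy)
    s1 <- sqrt(sum((yy - mu1)^2) / ((n - 1) * beta))
    if (abs(mu1 - mu0) < tol * s0 && abs(s1 - s0) < tol * s0) {
      mu0 <- mu1
      s0 <- s1
      converged <- TRUE
      break
    }
    if (s1 < scale_floor / 10) {
      # scale is collapsing (a majority of values coincide); in the s -> 0
      # limit the location settles on the majority value, i.e. the median
      mu0 <- med
      s0 <- s1
      converged <- TRUE
      break
    }
    mu0 <- mu1
    s0 <- s1
  }
  if (!converged) {
    warning("Huber Proposal-2 iteration did not converge in ", max_iter,
            " iterations; falling back to median/MAD", call. = FALSE)
    mu0 <- med
    s0 <- stats::mad(values)
  }
  list(M = mu0, sigma_M = max(s0, scale_floor), converged = converged,
       n = n)
}

#' Robust z-score and one-sided p-value for one locus
#'
#' The outlier score is `z = (y - M) / sigma_M`, where `y` is the sample's
#' normalized count and `M`, `sigma_M` are the robust control parameters.
#' The alternative hypothesis is one-sided: the sample has *more* repeat
#' reads than controls (an expansion), so `p` is the upper tail of the
#' standard normal at `z`.
#'
#' @param y Normalized count(s) of the tested sample.
#' @param M Robust location of the control values.
#' @param sigma_M Robust scale, strictly positive (apply the floor first).
#' @return A list with vectors `z` and `p`.
#' @examples
#' outlier_test(10, 4, 2)  # z = 3, p ~ 1.35e-3
#' @export
outlier_test <- function(y, M, sigma_M) {
  if (any(sigma_M <= 0)) {
    stop("sigma_M must be strictly positive", call. = FALSE)
  }
  z <- (y - M) / sigma_M
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: step-up
#' false-discovery-rate control across the tested loci, order-preserving
#' with the input.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Estimate per-locus control parameters from a cohort
#'
#' For every locus observed in any sample, each sample contributes its
#' normalized count — raw count 0 for samples with no reads assigned there,
#' since the absence of decoy reads is itself informative — and the robust
#' location and scale are estimated with [huber_location_scale()]. These
#' parameters define the null against which test samples are scored; they
#' can come from a dedicated control cohort or from the tested batch itself
#' ("internal controls", valid when fewer than half the samples share any
#' one expansion).
#'
#' @param count_tables List of [locus_counts] objects (>= 2 samples).
#' @param ... Passed on to [huber_location_scale()].
#' @return A `data.frame` with columns `locus_id`, `M`, `sigma_M`,
#'   `n_controls`.
#' @export
build_control_parameters <- function(count_tables, ...) {
  if (length(count_tables) < 2L) {
    stop("at least 2 control samples required", call. = FALSE)
  }
  all_loci <- sort(unique(unlist(lapply(count_tables,
                                        function(t) names(t$assigned)))))
  if (length(all_loci) == 0L) {
    return(data.frame(locus_id = character(0), M = numeric(0),
                      sigma_M = numeric(0), n_controls = integer(0),
                      stringsAsFactors = FALSE))
  }
  ymat <- vapply(count_tables, function(t) {
    raw <- t$assigned[all_loci]
    raw[is.na(raw)] <- 0L
    normalize_count(raw, t$median_coverage)
  }, numeric(length(all_loci)))
  ymat <- matrix(ymat, nrow = length(all_loci))
  est <- apply(ymat, 1L, function(v) {
    h <- huber_location_scale(v, ...)
    c(h$M, h$sigma_M)
  })
  data.frame(locus_id = all_loci, M = est[1, ], sigma_M = est[2, ],
             n_controls = length(count_tables), stringsAsFactors = FALSE)
}

#' Write / read control parameters as TSV
#'
#' The TSV carries the locus coordinates (recovered from the `locus_id`)
#' alongside the robust parameters, so a parameter set estimated once on a
#' large control cohort can be shipped and reused.
#'
#' @param controls Control table from [build_control_parameters()].
#' @param path File path.
#' @return `path` (write) or the control `data.frame` (read).
#' @export
write_control_parameters <- function(controls, path) {
  parts <- regmatches(controls$locus_id,
                      regexec("^(.*):(\\d+)-(\\d+):([ACGT]+)$",
                              controls$locus_id))
  out <- data.frame(
    locus_id = controls$locus_id,
    chrom = vapply(parts, `[`, character(1), 2L),
    start = as.integer(vapply(parts, `[`, character(1), 3L)),
    end = as.integer(vapply(parts, `[`, character(1), 4L)),
    unit = vapply(parts, `[`, character(1), 5L),
    M = sprintf("%.17g", controls$M),
    sigma_M = sprintf("%.17g", controls$sigma_M),
    n_controls = controls$n_controls, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_parameters
#' @export
read_control_parameters <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(locus_id = tab$locus_id, M = as.numeric(tab$M),
             sigma_M = as.numeric(tab$sigma_M),
             n_controls = as.integer(tab$n_controls),
             stringsAsFactors = FALSE)
}

#' Score one sample's loci against control parameters
#'
#' Every locus with at least one assigned read in the sample is tested. A
#' locus absent from the control table (e.g. added to the annotation after
#' the control parameters were computed) is still testable: its location
#' defaults to the normalized value of a zero count at 100x coverage and
#' its scale to the median control scale, with a message. BH adjustment is
#' applied across exactly this set of tested loci.
#'
#' @param sample A [locus_counts] object.
#' @param controls Control table from [build_control_parameters()] or
#'   [read_control_parameters()].
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A `data.frame` sorted by ascending `p` with columns `locus_id`,
#'   `sample_id`, `raw_count`, `y`, `z`, `p`, `p_adj`, `significant`.
#' @export
call_outliers <- function(sample, controls, alpha = 0.05) {
  if (nrow(controls) == 0L) stop("empty control table", call. = FALSE)
  tested <- names(sample$assigned)[sample$assigned >= 1L]
  if (length(tested) == 0L) {
    return(data.frame(locus_id = character(0), sample_id = character(0),
                      raw_count = integer(0), y = numeric(0),
                      z = numeric(0), p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  raw <- sample$assigned[tested]
  y <- normalize_count(raw, sample$median_coverage)
  m <- match(tested, controls$locus_id)
  M <- controls$M[m]
  sigma <- controls$sigma_M[m]
  missing <- is.na(m)
  if (any(missing)) {
    message(sum(missing), " tested locus/loci absent from controls; ",
            "using fallback parameters")
    M[missing] <- normalize_count(0L, 100)
    sigma[missing] <- stats::median(controls$sigma_M)
  }
  ot <- outlier_test(y, M, sigma)
  p_adj <- adjust_bh(ot$p)
  out <- data.frame(locus_id = tested, sample_id = sample$sample_id,
                    raw_count = as.integer(raw), y = y, z = ot$z, p = ot$p,
                    p_adj = p_adj, significant = p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, -out$z, out$locus_id), , drop = FALSE]
}
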