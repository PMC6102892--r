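#' Fit the coverage-vs-allele-size calibration
#'
#' The number of decoy reads allocated to a locus grows with the length of
#' the expanded allele, because a longer repeat tract yields more fragments
#' that are mostly repeat. On simulated expansions the relationship is
#' linear on the log-log scale, so allele sizes can be read off a fitted
#' line. The regression is of log2 normalized coverage (`y`, response) on
#' log2 allele size in inserted bp (`x`, predictor):
#' `y = beta0 + beta * x + e, e ~ N(0, sigma^2)`.
#'
#' @param points `data.frame` with columns `log2_coverage` and
#'   `log2_allele_bp` (>= 2 points, not all `x` identical).
#' @return An object of class `calibration_model`: list with `beta0`,
#'   `beta`, `residual_sd`, `n_points`.
#' @export
fit_calibration <- function(points) {
  x <- points$log2_allele_bp
  y <- points$log2_coverage
  if (length(x) < 2L) stop("at least 2 calibration points required",
                           call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("calibration points must span more than one allele size",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- unname(stats::coef(fit))
  df <- stats::df.residual(fit)
  rsd <- if (df > 0) sqrt(sum(stats::residuals(fit)^2) / df) else 0
  structure(list(beta0 = cf[1], beta = cf[2], residual_sd = rsd,
                 n_points = length(x)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("calibration_model: log2(coverage) = ", format(x$beta0), " + ",
      format(x$beta), " * log2(allele bp)  (residual sd ",
      format(x$residual_sd), ", n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Invert the calibration into an allele-size estimate
#'
#' Given a locus's normalized log2 coverage `y`, the point estimate of the
#' expanded allele is `inserted_bp = 2^((y - beta0) / beta)` (bases inserted
#' relative to the reference allele), also reported as total repeat units
#' `ref_copies + inserted_bp / unit_length`. Alleles much longer than the
#' sequencing insert size are systematically underestimated, because read
#' pairs fully contained in the repeat cannot be assigned to the locus; no
#' correction is attempted.
#'
#' @param y_log2_coverage Normalized count for the locus
#'   (see [normalize_count()]).
#' @param model A `calibration_model`.
#' @param locus One-row locus record (needs `unit` and `ref_copies`).
#' @return A list with `inserted_bp` and `repeat_units_total`.
#' @export
estimate_allele_size <- function(y_log2_coverage, model, locus) {
  if (!is.finite(model$beta) || model$beta == 0) {
    stop("calibration slope must be non-zero", call. = FALSE)
  }
  inserted <- 2^((y_log2_coverage - model$beta0) / model$beta)
  list(inserted_bp = inserted,
       repeat_units_total = locus$ref_copies + inserted / nchar(locus$unit))
}

#' Save / load a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @param note Free-text provenance note stored alongside the parameters.
#' @return `path` (write) / a `calibration_model` (read).
#' @export
write_calibration <- function(model, path, note = "") {
  jsonlite::write_json(list(beta0 = model$beta0, beta = model$beta,
                            residual_sd = model$residual_sd,
                            n_points = model$n_points, note = note),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beta0 = as.numeric(x$beta0), beta = as.numeric(x$beta),
                 residual_sd = as.numeric(x$residual_sd),
                 n_points = as.integer(x$n_points)),
            class = "calibration_model")
}

# default model shipped with the package (fitted on the bundled simulated
# calibration cohort; see inst/extdata/default_calibration.json)
default_calibration <- function() {
  read_calibration(system.file("extdata", "default_calibration.json",
                               package = "strexpand", mustWork = TRUE))
}
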